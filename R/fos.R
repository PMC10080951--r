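# Frequency-of-seeing curve fitting.
#
# MOCS data are fitted with a Bayesian hierarchical model (via JAGS):
# per-location thresholds mu_l and log-spreads share Gaussian population
# distributions, while lapse and guess rates are global with Beta(1, 19)
# priors. An independent (non-pooled) fit with flat location priors is
# provided for shrinkage comparisons.

fos_hierarchical_model <- "
model {
  for (i in 1:N) {
    p[i] <- gamma + (1 - gamma - lambda) * phi((mu[loc[i]] - x[i]) / sigma[loc[i]])
    seen[i] ~ dbern(max(1e-6, min(1 - 1e-6, p[i])))
  }
  for (l in 1:L) {
    mu[l] ~ dnorm(mu_pop, prec_mu)
    lsig[l] ~ dnorm(lsig_pop, prec_ls)
    sigma[l] <- exp(lsig[l])
  }
  mu_pop ~ dnorm(25, 0.0016)
  s_mu ~ dunif(0.01, 20)
  prec_mu <- pow(s_mu, -2)
  lsig_pop ~ dnorm(0.7, 0.25)
  s_ls ~ dunif(0.01, 3)
  prec_ls <- pow(s_ls, -2)
  lambda ~ dbeta(1, 19)
  gamma ~ dbeta(1, 19)
}"

fos_independent_model <- "
model {
  for (i in 1:N) {
    p[i] <- gamma + (1 - gamma - lambda) * phi((mu[loc[i]] - x[i]) / sigma[loc[i]])
    seen[i] ~ dbern(max(1e-6, min(1 - 1e-6, p[i])))
  }
  for (l in 1:L) {
    mu[l] ~ dunif(0, 50)
    lsig[l] ~ dunif(-1.61, 2.71)
    sigma[l] <- exp(lsig[l])
  }
  lambda ~ dbeta(1, 19)
  gamma ~ dbeta(1, 19)
}"

run_fos_mcmc <- function(model_string, trials, n_iter, n_burn, seed) {
  loc <- as.integer(factor(trials$location))
  L <- max(loc)
  for (l in seq_len(L)) {
    s <- trials$seen[loc == l]
    if (all(s) || !any(s)) {
      warnf("location %d has all-%s responses; its FOS fit is prior-dominated",
            l, if (all(s)) "seen" else "missed")
    }
  }
  dat <- list(N = nrow(trials), L = L, x = as.numeric(trials$stimulus_db),
              seen = as.integer(trials$seen), loc = loc)
  inits <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = if (is.null(seed)) 1L else as.integer(seed))
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = inits, n.chains = 1, n.adapt = 500,
                          quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu", "sigma", "lambda", "gamma"),
                              n.iter = n_iter, progress.bar = "none")[[1]]
  summarize <- function(name) {
    cols <- grep(paste0("^", name, "(\\[|$)"), colnames(samp))
    m <- samp[, cols, drop = FALSE]
    data.frame(parameter = colnames(samp)[cols],
               mean = colMeans(m),
               sd = apply(m, 2, sd),
               lower = apply(m, 2, quantile, 0.025),
               upper = apply(m, 2, quantile, 0.975),
               row.names = NULL)
  }
  list(mu = summarize("mu"), sigma = summarize("sigma"),
       lapse = summarize("lambda"), guess = summarize("gamma"),
       n_locations = L, samples = samp)
}

#' Fit frequency-of-seeing curves to MOCS trials
#'
#' @param trials data frame with columns `location`, `stimulus_db`, `seen`
#'   (logical or 0/1).
#' @param hierarchical pool locations through population distributions
#'   (default) or fit each location with flat priors.
#' @param n_iter,n_burn MCMC iterations after / for burn-in.
#' @param seed integer seed for the sampler.
#' @return list of posterior summaries (`mu`, `sigma` per location; global
#'   `lapse`, `guess`), each with mean, SD and 95% interval.
#' @export
fit_fos <- function(trials, hierarchical = TRUE, n_iter = 4000, n_burn = 1000,
                    seed = NULL) {
  need <- c("location", "stimulus_db", "seen")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("trials missing column(s): %s", paste(miss, collapse = ", "))
  model <- if (hierarchical) fos_hierarchical_model else fos_independent_model
  run_fos_mcmc(model, trials, n_iter, n_burn, seed)
}

#' Slope-threshold relation across conditions
#'
#' Ordinary least squares of log10(spread) on threshold, with a two-sided
#' t-test on the slope. A negative slope (spreads shallower at lower
#' sensitivity) is the signature of multiplicative response noise.
#'
#' @param mu thresholds, dB (>= 4 points).
#' @param sigma spreads, dB.
#' @return list with `slope`, `intercept`, `p_value` and the `lm` fit.
#' @export
slope_threshold_regression <- function(mu, sigma) {
  if (length(mu) < 4 || length(sigma) != length(mu)) {
    stopf("need >= 4 (mu, sigma) pairs")
  }
  if (any(sigma <= 0)) stopf("sigma must be positive")
  if (diff(range(mu)) < 1e-12) stopf("degenerate input: mu values are constant")
  fit <- lm(log10(sigma) ~ mu)
  cf <- summary(fit)$coefficients
  list(slope = cf["mu", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       p_value = cf["mu", "Pr(>|t|)"], fit = fit)
}
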