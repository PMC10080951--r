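test_that("the pooled response depends on S and T only through their product", {
  p <- st_params(1200)
  expect_equal(pooled_response(10, 100, p)$R, pooled_response(100, 10, p)$R)
  expect_equal(pooled_response(3, 400, p)$R, pooled_response(400, 3, p)$R)
  r <- pooled_response(10, 12, p)
  expect_equal(r$x, 10 * 12 / 1200)
  expect_equal(r$time_constant, 120)
  expect_error(pooled_response(-1, 10, p), "positive")
  expect_error(st_params(-5), "tau")
})

test_that("closed-form response values match the quadrature oracle and limits", {
  p <- st_params(1200)
  expect_equal(pooled_response(10, 12, p)$R, 0.40399, tolerance = 1e-4)
  # large-x limit: g(x) -> x - 11/6 for k = 4
  expect_equal(pooled_response(60, 2000, p)$R, (1200 * (100 - 11 / 6))^0.25,
               tolerance = 1e-6)
  for (tau in c(1e2, 1e3, 1e4)) {
    pp <- st_params(tau)
    for (x in 10^seq(-3, 3, by = 0.75)) {
      S <- x * tau / 100
      expect_equal(pooled_response(S, 100, pp)$R,
                   pooled_response_numeric(S, 100, pp),
                   tolerance = 5e-3)
    }
  }
})

test_that("log-log summation slopes run from 1 (Ricco/Bloch) to 1/k (partial)", {
  p <- st_params(1000, offset = 0)
  slope_S <- function(x) {
    S <- x * p$tau / 100
    h <- 1e-4
    (predicted_dls(S * 10^h, 100, p) - predicted_dls(S, 100, p)) / h
  }
  slope_T <- function(x) {
    T_ms <- x * p$tau / 50
    h <- 1e-4
    (predicted_dls(50, T_ms * 10^h, p) - predicted_dls(50, T_ms, p)) / h
  }
  expect_equal(slope_S(1e-3), 1, tolerance = 0.02)
  expect_equal(slope_S(1e3), 0.25, tolerance = 0.02)
  expect_equal(slope_T(1e-3), 1, tolerance = 0.02)
  expect_equal(slope_T(1e3), 0.25, tolerance = 0.02)
  # slope decreases monotonically along the curve
  s <- vapply(10^seq(-2, 2, length.out = 50), slope_S, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("the slope-0.5 critical point agrees with a numerical slope search", {
  xc <- critical_x(4)
  expect_equal(xc, 2.8822, tolerance = 1e-4)
  # independent oracle: finite-difference slope on a densely sampled curve
  p <- st_params(1000)
  lx <- seq(log10(0.5), log10(10), length.out = 400)
  dls <- predicted_dls(10^lx * p$tau / 100, 100, p)
  sl <- diff(dls) / diff(lx)
  i <- which(sl <= 0.5)[1]
  xc_num <- 10^(lx[i] - (sl[i] - 0.5) / (sl[i] - sl[i - 1]) * diff(lx)[1])
  expect_equal(xc_num, xc, tolerance = 0.01)
  expect_error(critical_x(2), "k <= 2")
})

test_that("critical input and duration obey the constant-product law", {
  p <- st_params(1211)
  xc <- critical_x(4)
  for (T_ms in c(15, 30, 55, 105, 200)) {
    cp <- critical_input(p, T_ms)
    expect_equal(cp$S_c * T_ms, xc * 1211)
  }
  expect_equal(critical_input(p, 100)$S_c, 2 * critical_input(p, 200)$S_c)
  cd <- critical_duration(p, 17.45)
  expect_equal(cd$T_c * 17.45, xc * 1211)
})

test_that("predicted sensitivity reads out as log10(R) + offset", {
  p <- st_params(1000, offset = 2.5)
  # R = 1 when tau * g(x) = 1
  S <- uniroot(function(S) pooled_response(S, 100, p)$R - 1, c(1e-4, 10))$root
  expect_equal(predicted_dls(S, 100, p), 2.5, tolerance = 1e-6)
  expect_true(all(diff(predicted_dls(seq(1, 50, by = 1), 100, p)) > 0))
  expect_true(all(diff(predicted_dls(10, seq(10, 500, by = 10), p)) > 0))
})

test_that("summation curves translate by -log10(2) when duration doubles", {
  map <- area_input_map(retinal_context(120, convergence = 3),
                        areas = 10^seq(-3.5, 0.5, by = 0.125), method = "product")
  p <- st_params(3465, offset = 2.36)
  areas <- 10^seq(-2, 0.3, by = 0.05)
  c1 <- summation_curve(p, map, 100, areas)
  c2 <- summation_curve(p, map, 200, areas / 2)
  expect_lt(max(abs(c2$dls - c1$dls)), 1e-6)
  # all durations collapse on the spatiotemporal input axis
  d1 <- summation_curve(p, map, 15, areas)
  d2 <- summation_curve(p, map, 200, areas * 15 / 200)
  expect_lt(max(abs(d2$dls - d1$dls)), 1e-9)
})

test_that("Ricco's area follows the inverse area-input mapping", {
  ctx <- retinal_context(100)
  map <- area_input_map(ctx, areas = 10^seq(-1.3, 0.5, by = 0.05),
                        method = "mosaic", phase_seed = 4)
  p <- st_params(694)  # S_c = 10 at 200 ms
  cp <- critical_input(p, 200)
  expect_equal(cp$S_c, 10, tolerance = 1e-3)
  # S ~ area x density: exact on the analytic map, within the lattice-phase
  # band on a single numeric mosaic
  expect_equal(ricco_area(p, 200, area_input_map(ctx, method = "product")),
               0.1, tolerance = 0.001)
  expect_equal(ricco_area(p, 200, map), 0.1, tolerance = 0.1)
  # halving density doubles the area at fixed tau and T
  half <- area_input_map(retinal_context(50), method = "product")
  full <- area_input_map(retinal_context(100), method = "product")
  expect_equal(ricco_area(p, 200, half), 2 * ricco_area(p, 200, full))
})

test_that("random RGC loss rescales Ricco's area by the survival reciprocal", {
  res <- ricco_loss_ratio(retinal_context(100), st_params(4163), T_ms = 200,
                          loss_fraction = 0.5, n_seeds = 20, seed = 3,
                          areas = 10^seq(-1, 0.55, by = 0.05))
  expect_equal(res$mean_ratio, 2, tolerance = 0.1)
})

test_that("Nelder-Mead fitting recovers the generating parameters", {
  map <- outer_map()
  grid <- design_grid(map)
  truth <- st_params(1200, offset = 2.6)
  grid$db <- 10 * predicted_dls(grid$S, grid$duration_ms, truth)
  fit <- fit_spatiotemporal(grid, k = 4)
  expect_equal(fit$tau, 1200, tolerance = 0.01)
  expect_equal(fit$offset, 2.6, tolerance = 0.005)
  expect_lt(fit$rmse_db, 1e-6)
  # fitted RMSE matches injected noise (SD 1 dB) across 50 replicates
  rmse <- vapply(1:50, function(r) {
    d <- grid
    d$db <- grid$db + perisum:::with_seed(r, rnorm(nrow(d), 0, 1))
    fit_spatiotemporal(d, k = 4)$rmse_db
  }, numeric(1))
  expect_equal(mean(rmse), 1.0, tolerance = 0.2)
  # degenerate design: constant S x T is unidentifiable
  dg <- data.frame(S = c(10, 20, 40), duration_ms = c(80, 40, 20), db = c(25, 25, 25))
  expect_error(fit_spatiotemporal(dg, k = 4), "unidentifiable")
})

test_that("rescaling convergence and tau together is a pure reparameterization", {
  lambda <- 7.13
  map1 <- area_input_map(retinal_context(450, convergence = 1), method = "product")
  mapl <- area_input_map(retinal_context(450, convergence = lambda), method = "product")
  grid <- expand.grid(area = goldmann_area(goldmann_labels), duration_ms = 200)
  truth <- st_params(1211, offset = 2.52)
  db <- 10 * predicted_dls(area_to_input(map1, grid$area), grid$duration_ms, truth)
  d1 <- cbind(grid, S = area_to_input(map1, grid$area), db = db)
  dl <- cbind(grid, S = area_to_input(mapl, grid$area), db = db)
  f1 <- fit_spatiotemporal(d1, k = 4)
  fl <- fit_spatiotemporal(dl, k = 4)
  expect_equal(fl$tau / f1$tau, lambda, tolerance = 0.01)
  expect_equal(fl$offset - f1$offset, -log10(lambda) / 4, tolerance = 0.005)
  # predictions are unchanged under the joint rescaling
  expect_equal(predicted_dls(lambda * 10, 100, st_params(lambda * 1211, offset = 2.52 - log10(lambda) / 4)),
               predicted_dls(10, 100, st_params(1211, offset = 2.52)),
               tolerance = 1e-10)
  # Ricco's area itself is unaffected: S_c scales by lambda, the map too
  expect_equal(ricco_area(fl$params, 200, mapl), ricco_area(f1$params, 200, map1),
               tolerance = 0.01)
})

test_that("fitted log10(tau) is nearly unbiased under 1-dB threshold noise", {
  map <- outer_map()
  grid <- design_grid(map)
  truth <- st_params(3465, offset = 2.36)
  db_true <- 10 * predicted_dls(grid$S, grid$duration_ms, truth)
  lt <- vapply(1:100, function(r) {
    d <- grid
    d$db <- db_true + perisum:::with_seed(r, rnorm(nrow(d), 0, 1))
    log10(fit_spatiotemporal(d, k = 4)$tau)
  }, numeric(1))
  expect_lt(abs(mean(lt) - log10(3465)), 0.05)
  expect_lt(sd(lt), 0.12)
})
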