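# Shared builders for the test suite. Everything is generated in code;
# sizes are kept small enough for interactive runs.

goldmann_labels <- c("I", "II", "III", "IV", "V")

# 5 sizes x 5 durations design grid with total inputs from a product map
design_grid <- function(map, durations = c(15, 30, 55, 105, 200)) {
  g <- expand.grid(area = goldmann_area(goldmann_labels),
                   duration_ms = durations)
  g$S <- area_to_input(map, g$area)
  g
}

# product-mapped context at the outer test eccentricity
outer_map <- function() {
  location_map(default_density_table(), 9.8995)
}

# uniform-field image covering a mosaic
uniform_image <- function(mosaic, value = 1) {
  ext <- mosaic$extent + 4 * mosaic$spacing
  img <- make_stimulus_image(diameter = max(ext) * 2, pitch = mosaic$spacing / 2,
                             extent = ext)
  img$pixels[] <- value
  img
}

# brute-force DoG pooling oracle: per-RGC double loop over all cones with the
# same truncation as the implementation kernel
brute_force_pool <- function(cone_values, cones, rgcs, dog, convergence = 1) {
  rad <- dog$truncate * dog$sigma_s
  norm <- perisum:::dog_lattice_kernel(dog, rgcs$spacing)$norm
  out <- numeric(nrow(rgcs$positions))
  for (i in seq_len(nrow(rgcs$positions))) {
    d <- sqrt((cones$positions[, 1] - rgcs$positions[i, 1])^2 +
                (cones$positions[, 2] - rgcs$positions[i, 2])^2)
    w <- dog_value(d, dog)
    w[d > rad] <- 0
    out[i] <- convergence * sum(w * cone_values) / norm
  }
  out
}
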