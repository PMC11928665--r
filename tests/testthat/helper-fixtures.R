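# Fixtures built in code: synthetic curves, brute-force oracles, and small
# model builders shared across the suite.

identity_curve <- function(lo = 8000, hi = 16000, sigma = 1, step = 20,
                           label = "ident") {
  theta <- seq(lo, hi, by = step)
  cal_curve(theta, theta, rep(sigma, length(theta)), label, "synthetic")
}

# Independent brute-force calibration: manual two-point interpolation and
# direct evaluation of the error-in-variables density at the same cell
# centres the package uses.
brute_calibrate <- function(cra, sigma, curve, resolution = 5) {
  rng <- range(curve$theta)
  k_lo <- ceiling(rng[1] / resolution - 0.5 + 1e-9)
  k_hi <- floor(rng[2] / resolution - 0.5 - 1e-9)
  grid <- resolution * (seq(k_lo, k_hi) + 0.5)
  dens <- vapply(grid, function(g) {
    i <- max(which(curve$theta <= g))
    if (i == length(curve$theta)) i <- i - 1L
    w <- (g - curve$theta[i]) / (curve$theta[i + 1] - curve$theta[i])
    mu <- (1 - w) * curve$mu[i] + w * curve$mu[i + 1]
    sg <- (1 - w) * curve$sigma[i] + w * curve$sigma[i + 1]
    v <- sigma^2 + sg^2
    exp(-(cra - mu)^2 / (2 * v)) / sqrt(v)
  }, numeric(1))
  dens / sum(dens)
}

# Dense-quadrature mixed-curve oracle (1001 midpoint nodes in m).
brute_mix <- function(cra, sigma, curve_n, curve_s, resolution = 5,
                      n_quad = 1001) {
  rng <- c(max(min(curve_n$theta), min(curve_s$theta)),
           min(max(curve_n$theta), max(curve_s$theta)))
  k_lo <- ceiling(rng[1] / resolution - 0.5 + 1e-9)
  k_hi <- floor(rng[2] / resolution - 0.5 - 1e-9)
  grid <- resolution * (seq(k_lo, k_hi) + 0.5)
  interp <- function(curve, g) {
    list(mu = approx(curve$theta, curve$mu, g)$y,
         sg = approx(curve$theta, curve$sigma, g)$y)
  }
  ln <- interp(curve_n, grid); ls <- interp(curve_s, grid)
  dens <- numeric(length(grid))
  for (m in (seq_len(n_quad) - 0.5) / n_quad) {
    mu <- m * ln$mu + (1 - m) * ls$mu
    sg <- m * ln$sg + (1 - m) * ls$sg
    v <- sigma^2 + sg^2
    dens <- dens + exp(-(cra - mu)^2 / (2 * v)) / sqrt(v)
  }
  dens / sum(dens)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# A single uniform phase of n dated events on one curve.
phase_model <- function(cras, errors, curve_key = "ident", label = "site",
                        outlier = NULL) {
  evs <- lapply(seq_along(cras), function(i)
    cal_event(sprintf("ev%02d", i),
              det = determination(cras[i], errors[i],
                                  lab_id = sprintf("L-%d", i),
                                  curve_key = curve_key),
              outlier = outlier))
  cal_sequence(label, cal_boundary("start"),
               do.call(cal_phase, c(list("ph"), evs)),
               cal_boundary("end"))
}

# Random valid model trees for the generator-validator agreement property.
random_model_tree <- function() {
  n_phase <- sample(1:3, 1)
  parts <- list(cal_boundary("b0"))
  ev <- 0
  for (p in seq_len(n_phase)) {
    evs <- lapply(seq_len(sample(1:4, 1)), function(i) {
      ev <<- ev + 1
      cal_event(sprintf("e%d", ev),
                det = determination(10000 + 100 * ev, 50,
                                    curve_key = "ident"))
    })
    parts[[length(parts) + 1L]] <- do.call(cal_phase,
                                           c(list(sprintf("p%d", p)), evs))
    parts[[length(parts) + 1L]] <- cal_boundary(sprintf("b%d", p))
  }
  do.call(cal_sequence, c(list("m"), parts))
}

# Default small pipeline curve registry.
pipeline_curves <- function() {
  list(south = gen_calibration_curve(c(25000, 8000), 20, 15, 15, seed = 11,
                                     label = "south", hemisphere = "south"),
       north = gen_calibration_curve(c(25000, 8000), 20, 15, 15, seed = 12,
                                     label = "north", hemisphere = "north"),
       marine = gen_calibration_curve(c(25000, 8000), 20, 25, 20, seed = 13,
                                      label = "marine", hemisphere = "marine"))
}

fast_settings <- function(...) {
  sampler_settings(initial_iterations = 2000, iterations = 6000, ...)
}

# Youngest included component median in a named category of a site stage
# (for checking that a category start never postdates its own evidence).
min_component_median <- function(stage, label, tl) {
  comps <- Filter(function(c) c$included, stage$components)
  sel <- switch(label,
                "high altitude" = Filter(function(c)
                  !is.na(c$altitude) && c$altitude >= 2500, comps),
                "megafauna" = Filter(function(c) isTRUE(c$megafauna), comps),
                if (startsWith(label, "lithic: "))
                  Filter(function(c) sub("lithic: ", "", label) %in% c$lithic,
                         comps)
                else Filter(function(c) identical(c$province, label), comps))
  min(vapply(sel, function(c) pdf_median(c$pdf), numeric(1)))
}
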