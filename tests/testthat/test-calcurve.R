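test_that("curve files parse, interpolate and round-trip", {
  cur <- read_14c("0,100,5\n10,110,5")
  expect_equal(length(cur$theta), 2L)
  expect_equal(curve_lookup(cur, 5)$mu, 105)

  with_comment <- read_14c("# header line\n0,100,5\n10,110,5")
  expect_equal(with_comment$theta, cur$theta)
  expect_equal(with_comment$mu, cur$mu)

  tabbed <- read_14c("0\t100\t5\n10\t110\t5")
  expect_equal(tabbed$mu, cur$mu)

  expect_error(read_14c("0,100,5\nnot,a,knot"), "line 2")
  expect_error(read_14c("0,100,5"), "fewer than 2")
  expect_error(cal_curve(c(0, 0, 10), c(1, 2, 3), c(1, 1, 1)), "duplicate")
  expect_error(cal_curve(c(0, 10), c(1, 2), c(1, 0)), "sigma")

  # 50-knot synthetic curve written then re-read: lossless to 1e-9
  set.seed(42)
  cur50 <- cal_curve(sort(sample(1000:20000, 50)),
                     rnorm(50, 12000, 500), runif(50, 5, 40))
  path <- withr::local_tempfile(fileext = ".14c")
  write_14c(cur50, path)
  back <- read_14c(path)
  expect_lt(max(abs(back$theta - cur50$theta)), 1e-9)
  expect_lt(max(abs(back$mu - cur50$mu)), 1e-9)
  expect_lt(max(abs(back$sigma - cur50$sigma)), 1e-9)
})

test_that("curve lookup is exact linear interpolation with range errors", {
  cur <- cal_curve(c(1000, 1100), c(900, 1000), c(10, 20))
  expect_equal(curve_lookup(cur, 1050), list(mu = 950, sigma = 15))
  expect_equal(curve_lookup(cur, 1000), list(mu = 900, sigma = 10))
  expect_equal(curve_lookup(cur, 1100), list(mu = 1000, sigma = 20))
  expect_error(curve_lookup(cur, 999), "outside")
  expect_error(curve_lookup(cur, 1101), "outside")

  # direct two-point formula oracle over 1000 random draws
  set.seed(1)
  cur2 <- cal_curve(seq(5000, 15000, by = 100),
                    seq(5000, 15000, by = 100) + rnorm(101, 0, 50),
                    runif(101, 5, 30))
  theta <- runif(1000, 5000, 15000)
  lk <- curve_lookup(cur2, theta)
  manual <- vapply(theta, function(g) {
    i <- findInterval(g, cur2$theta)
    w <- (g - cur2$theta[i]) / 100
    (1 - w) * cur2$mu[i] + w * cur2$mu[i + 1]
  }, numeric(1))
  expect_lt(max(abs(lk$mu - manual)), 1e-9)
})

test_that("marine reservoir offsets propagate in quadrature", {
  det <- determination(5000, 40, reservoir = "marine", delta_r = c(100, 30))
  adj <- apply_reservoir_offset(det)
  expect_equal(adj$cra, 4900)
  expect_equal(adj$sigma, 50)           # 3-4-5 triangle
  expect_equal(det$cra, 5000)           # original untouched

  none <- apply_reservoir_offset(
    determination(5000, 40, reservoir = "marine", delta_r = c(0, 0)))
  expect_equal(none$cra, 5000)
  expect_equal(none$sigma, 40)

  neg <- apply_reservoir_offset(
    determination(5000, 40, reservoir = "marine", delta_r = c(-150, 25)))
  expect_equal(neg$cra, 5150)
  expect_equal(neg$sigma, sqrt(40^2 + 25^2))

  expect_error(apply_reservoir_offset(determination(5000, 40)), "marine")
  expect_error(determination(5000, 40, delta_r = c(10, 5)), "marine")
  expect_error(determination(5000, 40, reservoir = "marine"), "delta_r")
})

test_that("calibration reproduces the flat and identity limits", {
  flat <- cal_curve(c(8000, 16000), c(10000, 10000), c(0.01, 0.01))
  pdf <- calibrate(determination(10000, 50), flat)
  expect_lt(max(pdf$mass) / min(pdf$mass), 1 + 1e-6)
  expect_equal(sum(pdf$mass), 1, tolerance = 1e-9)

  ident <- identity_curve(sigma = 0.01)
  p <- calibrate(determination(10000, 50), ident, resolution = 1)
  expect_equal(pdf_mean(p), 10000, tolerance = 0.5)
  expect_equal(sum(p$mass[p$grid >= 9900 & p$grid <= 10100]), 0.9545,
               tolerance = 0.002)

  expect_error(calibrate(determination(30000, 50), ident), "calibration error")
})

test_that("calibrate and mix_calibration match brute-force oracles on 20 curves", {
  worst_cal <- 0; worst_mix <- 0
  for (s in 1:20) {
    cur <- gen_calibration_curve(c(16000, 8000), 25, wiggle_sd = 40,
                                 error_level = 20, seed = 100 + s)
    cra <- runif(1, 9500, 14500)
    sig <- runif(1, 30, 80)
    pdf <- calibrate(determination(cra, sig), cur)
    oracle <- brute_calibrate(cra, sig, cur)
    worst_cal <- max(worst_cal, tv_dist(pdf$mass, oracle))

    cur2 <- gen_calibration_curve(c(16000, 8000), 25, wiggle_sd = 40,
                                  error_level = 20, seed = 300 + s)
    mixed <- mix_calibration(determination(cra, sig), cur, cur2)
    worst_mix <- max(worst_mix, tv_dist(mixed$mass,
                                        brute_mix(cra, sig, cur, cur2)))
  }
  expect_lt(worst_cal, 1e-6)
  expect_lt(worst_mix, 1e-4)
})

test_that("mixing degenerates correctly for equal curves and constant offsets", {
  cur <- gen_calibration_curve(c(16000, 9000), 25, 30, 15, seed = 5)
  det <- determination(11000, 40)
  same <- mix_calibration(det, cur, cur)
  plain <- calibrate(det, cur)
  expect_lt(tv_dist(same$mass, plain$mass), 1e-9)

  offset <- cal_curve(cur$theta, cur$mu + 40, cur$sigma, "off")
  mx <- mix_calibration(det, cur, offset)
  expect_lt(tv_dist(mx$mass, brute_mix(11000, 40, cur, offset)), 1e-4)
  expect_error(mix_calibration(det, cur, offset, n_quad = 5), "21")
})

test_that("HPD intervals are the smallest descending-mass cell sets", {
  ident <- identity_curve(sigma = 0.01)
  p <- calibrate(determination(10000, 50), ident, resolution = 1)
  h <- hpd_interval(p, 0.954)
  expect_equal(nrow(h), 1L)
  z <- qnorm(1 - (1 - 0.954) / 2)
  expect_equal(unname(h[1, "older"]), 10000 + z * 50, tolerance = 3e-4)
  expect_equal(unname(h[1, "younger"]), 10000 - z * 50, tolerance = 3e-4)

  # symmetric tie: both point masses enter
  tie <- cal_pdf(seq(50, 250, by = 50), c(0, 0.5, 0, 0.5, 0))
  ht <- hpd_interval(tie, 0.954)
  expect_equal(sort(as.vector(ht[, 1])), c(100, 200))

  # brute-force minimal-cardinality oracle on a bimodal 50-cell toy PDF
  set.seed(3)
  m <- dnorm(1:50, 15, 3) + 0.6 * dnorm(1:50, 35, 5)
  toy <- cal_pdf(seq(5, 250, by = 5), m)
  h2 <- hpd_interval(toy, 0.682)
  in_hpd <- unlist(lapply(seq_len(nrow(h2)), function(r)
    which(toy$grid <= h2[r, 1] & toy$grid >= h2[r, 2])))
  ord <- order(toy$mass, decreasing = TRUE)
  k_min <- which(cumsum(toy$mass[ord]) >= 0.682)[1]
  expect_equal(length(in_hpd), k_min)                 # minimal cardinality
  expect_true(sum(toy$mass[in_hpd]) >= 0.682)
  expect_setequal(in_hpd, sort(ord[seq_len(k_min)]))  # identical cell set

  expect_error(hpd_interval(p, 1.2), "level")
})

test_that("widening measurement error never narrows the 95.4% HPD", {
  ident <- identity_curve(sigma = 5)
  widths <- vapply(c(30, 60, 120, 240), function(s) {
    h <- hpd_interval(calibrate(determination(11000, s), ident), 0.954)
    sum(h[, "older"] - h[, "younger"])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("interval rounding is outward at half-way and stable otherwise", {
  expect_equal(round_interval(c(16663, 15907)), c(16660, 15910))
  expect_equal(round_interval(c(13750, 12830)), c(13750, 12830))
  expect_equal(round_interval(c(12345, 12335)), c(12350, 12330))
  m <- round_interval(rbind(c(16663, 15907), c(12345, 12335)))
  expect_equal(m[2, ], c(12350, 12330))
  expect_error(round_interval(c(100, 200)), "older")
})

test_that("calendar PDFs round-trip through their CSV form", {
  p <- calibrate(determination(10000, 60), identity_curve())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cal_pdf(p, path)
  back <- read_cal_pdf(path)
  expect_equal(back$grid, p$grid)
  expect_lt(max(abs(back$mass - p$mass)), 1e-12)
})
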