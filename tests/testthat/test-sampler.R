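curves1 <- list(ident = identity_curve(8000, 16000, sigma = 1))

test_that("a lone event reproduces its calibration", {
  set.seed(21)
  m <- cal_sequence("m", cal_event("e1", det = determination(10000, 50,
                                                             curve_key = "ident")))
  tr <- sample_posterior(m, curves1,
                         sampler_settings(initial_iterations = 2000,
                                          iterations = 10000))
  expect_equal(mean(tr$samples[, "e1"]), 10000, tolerance = 2e-4)
  expect_equal(sd(tr$samples[, "e1"]), 50, tolerance = 0.04)
})

test_that("sequence order is a hard constraint in every retained sample", {
  set.seed(22)
  d <- determination(10000, 50, curve_key = "ident")
  m <- cal_sequence("m", cal_event("older", det = d),
                    cal_event("younger", det = d))
  tr <- sample_posterior(m, curves1, fast_settings())
  expect_true(all(tr$samples[, "older"] >= tr$samples[, "younger"]))
  expect_equal(count_constraint_violations(tr), 0L)
})

test_that("uniform-phase start boundaries cover the truth at nominal rate", {
  # simulation-based calibration: 100 replicate datasets of 20 events truly
  # U(13000, 14000) observed through the curve with 30-yr errors
  set.seed(23)
  st <- sampler_settings(initial_iterations = 2000, iterations = 6000)
  hits <- 0L
  for (r in 1:100) {
    ages <- runif(20, 13000, 14000)
    cras <- rnorm(20, ages, sqrt(30^2 + 1))
    tr <- sample_posterior(phase_model(cras, rep(30, 20)), curves1, st)
    h <- hpd_interval(posterior_pdf(tr, "start"), 0.954)
    hits <- hits + any(h[, "older"] >= 14000 & h[, "younger"] <= 14000)
  }
  expect_gte(hits, 89L)
  expect_lte(hits, 99L)
})

test_that("a gross contaminant is flagged and down-weighted", {
  set.seed(24)
  ages <- runif(10, 13000, 14000)
  cras <- rnorm(10, ages, 30)
  st <- sampler_settings(initial_iterations = 4000, iterations = 12000)
  out <- outlier_spec("general", 0.05)

  clean <- sample_posterior(phase_model(cras, rep(30, 10), outlier = out),
                            curves1, st)
  cras2 <- cras
  cras2[4] <- cras[4] + 2000                      # +2000 14C yr contaminant
  dirty <- sample_posterior(phase_model(cras2, rep(30, 10), outlier = out),
                            curves1, st)

  activation <- colMeans(dirty$outlier_active)
  expect_gt(activation[["ev04"]], 0.8)
  shift <- abs(mean(dirty$samples[, "start"]) - mean(clean$samples[, "start"]))
  expect_lt(shift, 100)
  expect_equal(count_constraint_violations(dirty), 0L)
})

test_that("without likelihoods, boundaries reproduce their prior", {
  # one undated query event between two boundaries in a fixed window:
  # the prior is uniform on the ordered triple, so the start boundary has
  # CDF ((a - lo) / (hi - lo))^2
  set.seed(25)
  m <- cal_sequence("m", cal_boundary("a"), cal_phase("p", cal_event("q")),
                    cal_boundary("b"))
  st <- sampler_settings(initial_iterations = 5000, iterations = 1e5,
                         window = c(1000, 2000))
  tr <- sample_posterior(m, list(), st)
  a <- tr$samples[, "a"]
  ks <- suppressWarnings(
    ks.test(a, function(q) ((q - 1000) / 1000)^2))
  expect_lt(unname(ks$statistic), 0.02)
  # the Date query (the explicit undated event) stays between the boundaries
  expect_true(all(tr$samples[, "q"] <= tr$samples[, "a"]))
  expect_true(all(tr$samples[, "q"] >= tr$samples[, "b"]))
})

test_that("declaration order within a phase does not matter", {
  set.seed(26)
  cras <- c(13950, 13400, 13210, 13800, 13050)
  st <- sampler_settings(initial_iterations = 3000, iterations = 12000)
  a <- sample_posterior(phase_model(cras, rep(40, 5)), curves1, st)
  b <- sample_posterior(phase_model(rev(cras), rep(40, 5)), curves1, st)
  se <- sd(a$samples[, "start"]) / sqrt(200)   # generous effective n
  expect_lt(abs(mean(a$samples[, "start"]) - mean(b$samples[, "start"])),
            4 * se + 10)
})

test_that("runs are bit-identical under one seed and stable across seeds", {
  m <- phase_model(c(13900, 13500, 13100), rep(40, 3))
  st <- fast_settings()
  set.seed(31); t1 <- sample_posterior(m, curves1, st)
  set.seed(31); t2 <- sample_posterior(m, curves1, st)
  expect_identical(t1$samples, t2$samples)

  set.seed(99); t3 <- sample_posterior(m, curves1, st)
  mc_se <- sd(t1$samples[, "start"]) / sqrt(100)
  expect_lt(abs(mean(t1$samples[, "start"]) - mean(t3$samples[, "start"])),
            4 * mc_se + 10)
})

test_that("the pass protocol converges on a unimodal model and flags frozen chains", {
  set.seed(27)
  m <- cal_sequence("m", cal_event("e1", det = determination(11000, 60,
                                                             curve_key = "ident")))
  cc <- check_convergence(m, curves1,
                          sampler_settings(initial_iterations = 3000))
  expect_true(cc$report$converged)
  expect_gt(cc$report$overall, 0.95)
  expect_lte(cc$report$iterations, 30000)   # well within the initial budget

  # metric unit checks: a frozen (non-moving) chain carries no evidence of
  # convergence; a chain that drifted between two modes scores low; a
  # well-mixed white chain scores high
  expect_equal(half_overlap(rep(12000, 1000)), 0)
  expect_lt(half_overlap(rep(c(12000, 15000), each = 500)), 0.05)
  set.seed(28)
  expect_gt(half_overlap(rnorm(4000)), 0.9)
})

test_that("posterior_pdf bins samples faithfully", {
  tr <- structure(list(samples = cbind(x = rep(12000, 500)),
                       settings = sampler_settings()),
                  class = "chron_trace")
  p <- posterior_pdf(tr, "x")
  expect_equal(length(p$grid), 1L)
  expect_equal(pdf_mode(p), 12002.5)   # the cell containing 12000

  set.seed(29)
  v <- rnorm(1e5, 12000, 100)
  tr$samples <- cbind(x = v)
  p5 <- posterior_pdf(tr, "x")
  expect_equal(pdf_mean(p5), 12000, tolerance = 2e-4)
  p10 <- posterior_pdf(tr, "x", resolution = 10)
  expect_lt(abs(pdf_mean(p10) - pdf_mean(p5)), 5)
  expect_error(posterior_pdf(tr, "nope"), "no parameter")
})

test_that("traces export to CSV with a JSON manifest", {
  set.seed(30)
  m <- phase_model(c(13900, 13100), c(40, 40))
  tr <- sample_posterior(m, curves1, fast_settings())
  dir <- withr::local_tempdir()
  paths <- export_trace(tr, dir)
  expect_true(all(file.exists(paths)))
  long <- read.csv(paths[1])
  expect_setequal(unique(long$parameter), colnames(tr$samples))
  man <- jsonlite::read_json(paths[2])
  expect_equal(man$n_samples, nrow(tr$samples))
})
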