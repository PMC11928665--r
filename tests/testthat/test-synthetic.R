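test_that("synthetic curves honour their parameters", {
  ident <- gen_calibration_curve(c(20000, 8000), 20, wiggle_sd = 0,
                                 error_level = 10, seed = 1)
  expect_equal(ident$mu, ident$theta)            # zero wiggle = identity

  a <- gen_calibration_curve(c(20000, 8000), 20, 15, 15, seed = 7)
  b <- gen_calibration_curve(c(20000, 8000), 20, 15, 15, seed = 7)
  expect_identical(a, b)
  c2 <- gen_calibration_curve(c(20000, 8000), 20, 15, 15, seed = 8)
  expect_false(identical(a$mu, c2$mu))

  # wiggle amplitude stays bounded over 100 seeds
  worst <- max(vapply(1:100, function(s) {
    cur <- gen_calibration_curve(c(28000, 8000), 20, wiggle_sd = 20,
                                 error_level = 10, seed = 1000 + s)
    max(abs(cur$mu - cur$theta))
  }, numeric(1)))
  expect_lt(worst, 6 * 20)

  expect_error(gen_calibration_curve(c(8000, 20000)), "old > young")
})

test_that("synthetic sites draw uniform ages and contaminate at the set rate", {
  ident <- gen_calibration_curve(c(20000, 8000), 20, 0, 0.001, seed = 1)

  # noiseless limit: CRAs equal true ages up to integer rounding
  gs <- gen_site(list(c(14000, 13000, 50)), ident, lab_error = 1e-3,
                 outlier_rate = 0, seed = 2)
  expect_lt(max(abs(gs$ages$cra - gs$truth$true_age)), 1)

  # uniform-phase event ages
  big <- gen_site(list(c(14000, 13000, 1000)), ident, lab_error = 10,
                  seed = 3)
  ks <- suppressWarnings(ks.test(big$truth$true_age, "punif", 13000, 14000))
  expect_gt(ks$p.value, 0.01)

  # contaminated fraction within the binomial 95% band around 0.1
  out <- gen_site(list(c(15000, 12000, 500)), ident, lab_error = 30,
                  outlier_rate = 0.1, seed = 4)
  frac <- mean(out$truth$outlier)
  expect_gt(frac, 0.1 - 1.96 * sqrt(0.09 / 500))
  expect_lt(frac, 0.1 + 1.96 * sqrt(0.09 / 500))

  expect_error(gen_site(list(c(13000, 14000, 5)), ident), "a > b")
  expect_error(gen_site(list(c(14000, 13500, 2), c(13800, 13000, 2)), ident),
               "non-overlapping")
})

test_that("generated databases load cleanly and are seed-stable", {
  db <- gen_database(n_sites = 25, seed = 50)
  ld <- load_database(db$ages)
  expect_equal(nrow(ld$rejects), 0L)
  expect_equal(length(unique(ld$ages$site)), 25L)
  expect_true(all(table(db$truth$sample_id) == 1))   # one truth row per event

  # byte-identical CSV under one seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_database(gen_database(n_sites = 8, seed = 60), d1)
  p2 <- write_database(gen_database(n_sites = 8, seed = 60), d2)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  # paper-shaped scale at the full default size
  full <- gen_database(seed = 42)
  expect_gte(length(unique(full$ages$site)), 145)
  expect_gt(nrow(full$ages), 1500)
  expect_gt(mean(full$ages$age_type == "14c"), 0.9)
})

test_that("configured missingness is recovered by the database summary", {
  db <- gen_database(n_sites = 100, seed = 51,
                     missingness = list(cn_ratio = 0.89))
  sm <- summarize_database(load_database(db$ages))
  expect_gt(sm$pct_cn_reported, 9)
  expect_lt(sm$pct_cn_reported, 13)
  expect_lte(sm$n_cn_in_range, sm$n_cn_reported)
  expect_gt(sm$pct_charcoal_species_unreported, 88)
})

test_that("every generated rule-1/2 site model validates (closure)", {
  db <- gen_database(n_sites = 30, seed = 52)
  ld <- assign_curves(load_database(db$ages))
  n_models <- 0L
  for (s in unique(ld$ages$site)) {
    sm <- site_model_from_record(ld$ages[ld$ages$site == s, ])
    if (!is.null(sm$model)) {
      expect_length(validate_model(sm$model), 0)
      n_models <- n_models + 1L
    }
  }
  expect_gt(n_models, 15L)
})
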