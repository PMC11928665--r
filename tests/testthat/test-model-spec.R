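test_that("r_combine pools replicates and flags inconsistency", {
  d <- function(x, s) determination(x, s, curve_key = "ident")

  same <- r_combine(list(d(10000, 50), d(10000, 50)))
  expect_equal(same$cra, 10000)
  expect_equal(same$sigma, 50 / sqrt(2), tolerance = 1e-9)
  expect_equal(same$t_stat, 0)
  expect_true(same$passed)

  pair <- r_combine(list(d(10000, 50), d(10100, 50)))
  expect_equal(pair$cra, 10050)
  expect_equal(pair$sigma, 50 / sqrt(2), tolerance = 1e-4)
  expect_equal(pair$t_stat, 2.0)        # below the 3.84 chi-square cut
  expect_true(pair$passed)

  far <- r_combine(list(d(10000, 30), d(10500, 30)))
  expect_equal(far$t_stat, 2 * (250 / 30)^2, tolerance = 1e-9)
  expect_false(far$passed)

  expect_error(r_combine(list(d(10000, 50))), "at least 2")
  expect_error(r_combine(list(
    d(10000, 50),
    determination(10000, 50, reservoir = "marine", delta_r = c(100, 20),
                  curve_key = "marine"))), "common curve")
})

test_that("r_combine is permutation-invariant and scales as sigma/sqrt(k)", {
  set.seed(9)
  dets <- lapply(1:5, function(i)
    determination(10000 + rnorm(1, 0, 40), runif(1, 30, 60),
                  curve_key = "ident"))
  a <- r_combine(dets)
  b <- r_combine(dets[c(3, 1, 5, 2, 4)])
  expect_equal(a$cra, b$cra)
  expect_equal(a$sigma, b$sigma)
  expect_equal(a$t_stat, b$t_stat)

  for (k in c(2, 4, 8)) {
    rc <- r_combine(replicate(k, determination(9000, 48, curve_key = "x"),
                              simplify = FALSE))
    expect_equal(rc$sigma, 48 / sqrt(k), tolerance = 1e-12)
  }
})

test_that("validate_model spots structural violations and passes valid trees", {
  ok <- cal_sequence("s", cal_boundary("a"),
                     cal_phase("p",
                               cal_event("e1", det = determination(1, 1)),
                               cal_event("e2", det = determination(2, 1)),
                               cal_event("e3", det = determination(3, 1))),
                     cal_boundary("b"))
  expect_length(validate_model(ok), 0)

  bare <- cal_sequence("s", cal_phase("p", cal_event("e1")))
  expect_match(validate_model(bare), "not delimited", all = FALSE)

  naked_phase <- cal_phase("p", cal_event("e1"))
  expect_match(validate_model(naked_phase), "no enclosing boundaries",
               all = FALSE)

  dup <- cal_sequence("s", cal_boundary("a"),
                      cal_phase("p", cal_event("e"), cal_event("e")),
                      cal_boundary("b"))
  expect_match(validate_model(dup), "twice", all = FALSE)

  empty <- cal_sequence("s", cal_boundary("a"), cal_phase("p"),
                        cal_boundary("b"))
  expect_match(validate_model(empty), "empty", all = FALSE)

  expect_error(cal_event("e", det = determination(1, 1),
                         pdf = normal_pdf(100, 10)), "exactly one")

  # generator-validator agreement over 100 random valid trees
  set.seed(4)
  for (i in 1:100) expect_length(validate_model(random_model_tree()), 0)
})

test_that("model serialisation mirrors the tree", {
  node <- cal_sequence("site", cal_boundary("start"),
                       cal_phase("layer",
                                 cal_event("AA-1",
                                           det = determination(10000, 50),
                                           outlier = outlier_spec()),
                                 cal_event("query")),
                       cal_boundary("end"))
  txt <- format_model(node)
  expect_match(txt, 'Sequence\\("site"\\)')
  expect_match(txt, 'R_Date\\("AA-1", 10000, 50\\) \\{ Outlier\\("general", 0.05\\) \\}')
  expect_match(txt, 'Date\\("query"\\)')
  expect_match(txt, 'Boundary\\("start"\\)')
})

site_rows <- function(n_layers, dates_per_layer, order_known = TRUE,
                      site = "S1") {
  rows <- expand.grid(l = seq_len(n_layers), d = seq_len(dates_per_layer))
  data.frame(site = site, layer = paste0("L", rows$l),
             layer_order = if (order_known) rows$l else NA_integer_,
             sample_id = paste0(site, "_", seq_len(nrow(rows))),
             lab_id = paste0("X-", seq_len(nrow(rows))),
             age_type = "14c",
             cra = 14000 - 400 * rows$l - 10 * rows$d, error = 40,
             material = "charcoal", reservoir = "atmospheric",
             delta_r = NA_real_, delta_r_sd = NA_real_,
             curve_key = "south", stringsAsFactors = FALSE)
}

test_that("site models follow the three construction rules", {
  # rule 1: 3 ordered dated layers -> sequence of 3 phases, 4 boundaries
  sm1 <- site_model_from_record(site_rows(3, 2))
  expect_equal(sm1$rule, 1L)
  kinds <- vapply(sm1$model$children, function(c) c$kind, character(1))
  expect_equal(sum(kinds == "boundary"), 4L)
  expect_equal(sum(kinds == "phase"), 3L)
  expect_length(validate_model(sm1$model), 0)
  expect_equal(nrow(sm1$components), 3L)

  # rule 2: 4 dates without stratigraphic order -> one uniform phase
  sm2 <- site_model_from_record(site_rows(2, 2, order_known = FALSE))
  expect_equal(sm2$rule, 2L)
  kinds2 <- vapply(sm2$model$children, function(c) c$kind, character(1))
  expect_equal(kinds2, c("boundary", "phase", "boundary"))
  expect_length(validate_model(sm2$model), 0)

  # a single dated layer falls to rule 2 as well when >= 2 measurements
  sm2b <- site_model_from_record(site_rows(1, 3))
  expect_equal(sm2b$rule, 2L)

  # rule 3: one measurement -> passthrough, no model
  sm3 <- site_model_from_record(site_rows(1, 1))
  expect_equal(sm3$rule, 3L)
  expect_null(sm3$model)
  expect_equal(nrow(sm3$passthrough_row), 1L)

  # sediment-only sites are skipped with a reason
  sed <- site_rows(1, 2)
  sed$material <- "sediment"
  sm0 <- site_model_from_record(sed)
  expect_equal(sm0$rule, 0L)
  expect_match(sm0$reason, "non-sediment")
})

test_that("site model construction is deterministic and rules are exclusive", {
  set.seed(11)
  db <- gen_database(n_sites = 12, seed = 77)
  ld <- assign_curves(load_database(db$ages))
  rules <- integer(0)
  for (s in unique(ld$ages$site)) {
    rows <- ld$ages[ld$ages$site == s, ]
    a <- site_model_from_record(rows)
    b <- site_model_from_record(rows)
    expect_equal(a$rule, b$rule)
    if (!is.null(a$model)) {
      expect_identical(format_model(a$model), format_model(b$model))
      expect_length(validate_model(a$model), 0)   # closure property
    }
    rules <- c(rules, a$rule)
  }
  expect_true(all(rules %in% 0:3))
})

test_that("replicates are pooled before modelling", {
  rows <- site_rows(1, 3)
  rows$sample_id <- "S1_same"          # all three on one sample
  sm <- site_model_from_record(rows)
  expect_equal(sm$rule, 3L)            # pooled to a single measurement
  expect_length(sm$combines, 1L)
  expect_equal(sm$combines[[1]]$df, 2L)
})
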