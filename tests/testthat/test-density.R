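test_that("sum_distribution averages cell-wise and renormalises", {
  p <- normal_pdf(12000, 100)
  expect_equal(sum_distribution(list(p, p))$mass, p$mass, tolerance = 1e-12)

  spike <- function(at) cal_pdf(seq(52.5, 352.5, by = 5),
                                as.numeric(seq(52.5, 352.5, by = 5) == at))
  two <- sum_distribution(list(spike(102.5), spike(302.5)))
  expect_equal(sum(two$mass[two$grid %in% c(102.5, 302.5)]), 1)
  expect_equal(two$mass[two$grid == 102.5], 0.5)

  # 50 random PDFs against the direct cell-wise mean
  set.seed(41)
  pdfs <- lapply(1:50, function(i) normal_pdf(runif(1, 11000, 13000),
                                              runif(1, 50, 300)))
  s <- sum_distribution(pdfs)
  grids <- lapply(pdfs, function(p) p$grid)
  lo <- min(unlist(grids)); hi <- max(unlist(grids))
  grid <- seq(lo, hi, by = 5)
  manual <- rowMeans(vapply(pdfs, function(p) {
    m <- numeric(length(grid))
    m[match(round(p$grid, 6), round(grid, 6))] <- p$mass
    m
  }, numeric(length(grid))))
  expect_lt(max(abs(s$mass - manual / sum(manual))), 1e-12)

  expect_error(sum_distribution(list()), "at least one")
})

test_that("Silverman bandwidth follows the rule of thumb", {
  set.seed(42)
  v <- rnorm(100)
  v <- (v - mean(v)) / sd(v) * 100 + 12000    # exact sd 100
  h <- silverman_bandwidth(v)
  expect_equal(h, 0.9 * min(100, IQR(v) / 1.34) * 100^(-1 / 5),
               tolerance = 1e-12)

  expect_equal(silverman_bandwidth(v * 2), 2 * silverman_bandwidth(v),
               tolerance = 1e-9)

  # n -> 32 n with the same spread halves h (32^(1/5) = 2)
  v32 <- rep(v, 32)
  expect_equal(silverman_bandwidth(v32), silverman_bandwidth(v) / 2,
               tolerance = 0.02)

  expect_error(silverman_bandwidth(rep(5, 10)), "zero spread")
  expect_error(silverman_bandwidth(1), "at least 2")
})

test_that("kde_plot recovers a sampling mean and normalises", {
  set.seed(43)
  v <- rnorm(1e4, 12060, 400)
  k <- kde_plot(v)
  expect_equal(pdf_mean(k), 12060, tolerance = 15 / 12060)
  expect_equal(sum(k$mass), 1, tolerance = 1e-9)

  pair <- kde_plot(c(11000, 11000, 13000, 13000))
  modes <- pair$grid[which(diff(sign(diff(pair$mass))) == -2) + 1]
  expect_equal(length(modes), 2L)
})

test_that("kde_model recovers the generating distribution without over-smoothing", {
  set.seed(44)
  vals <- rnorm(170, 12050, 350)
  pdfs <- lapply(vals, function(v) normal_pdf(v, 25))
  r <- kde_model(pdfs, n_burn = 150, n_iter = 600)
  expect_lt(abs(r$mean - 12050), 30)
  expect_equal(sum(r$point_estimate$mass), 1, tolerance = 1e-9)
  expect_true(all(r$snapshot_sd >= 0))
  expect_true(all(r$shaping_posterior > 0 & r$shaping_posterior < 1))

  # two tight separated clusters stay bimodal
  set.seed(45)
  biv <- c(rnorm(12, 12000, 30), rnorm(12, 14000, 30))
  bim <- kde_model(lapply(biv, function(v) normal_pdf(v, 20)),
                   n_burn = 100, n_iter = 400)
  m <- bim$point_estimate$mass
  modes <- which(diff(sign(diff(m))) == -2) + 1
  big <- modes[m[modes] > max(m) / 10]
  peaks <- bim$point_estimate$grid[big]
  expect_true(any(abs(peaks - 12000) < 300))
  expect_true(any(abs(peaks - 14000) < 300))

  # identical narrow inputs concentrate on the common median
  same <- kde_model(replicate(8, normal_pdf(13000, 10), simplify = FALSE),
                    n_burn = 100, n_iter = 300)
  expect_lt(abs(same$mean - 13000), 5)

  expect_error(kde_model(list(normal_pdf(12000, 50))), "at least 2")
})

test_that("kde_model point estimates stabilise as the input set grows", {
  set.seed(46)
  spread <- function(n, reps = 6) {
    vapply(seq_len(reps), function(r) {
      vals <- rnorm(n, 12500, 300)
      kde_model(lapply(vals, function(v) normal_pdf(v, 25)),
                n_burn = 60, n_iter = 240, snapshot_every = 12)$mean
    }, numeric(1))
  }
  sds <- c(sd(spread(20)), sd(spread(80)), sd(spread(320)))
  expect_lt(sds[3], sds[1])
})

test_that("difference distributions follow the cross-correlation identities", {
  spike <- function(at) {
    g <- seq(at - 50, at + 50, by = 5)
    cal_pdf(g, as.numeric(g == at))
  }
  d <- difference(spike(13002.5), spike(12002.5))
  expect_equal(d$mean, 1000)
  expect_equal(d$mass[d$delta == 1000], 1)
  expect_equal(d$p_older, 1)

  p <- normal_pdf(12500, 120)
  dd <- difference(p, p)
  expect_equal(dd$p_older, 0.5, tolerance = 1e-9)
  expect_equal(dd$mean, 0, tolerance = 1e-9)

  # mean identity holds for arbitrary PDFs
  set.seed(47)
  a <- normal_pdf(13000, 200); b <- normal_pdf(12400, 90)
  dab <- difference(a, b)
  expect_lt(abs(dab$mean - (pdf_mean(a) - pdf_mean(b))), 5)

  # Monte-Carlo oracle on two uniform PDFs
  ua <- cal_pdf(seq(12002.5, 12052.5, 5), rep(1, 11))
  ub <- cal_pdf(seq(11952.5, 11982.5, 5), rep(1, 7))
  duv <- difference(ua, ub)
  set.seed(48)
  draws <- sample(ua$grid, 1e7, TRUE) - sample(ub$grid, 1e7, TRUE)
  emp <- table(factor(draws, levels = duv$delta)) / 1e7
  expect_lt(0.5 * sum(abs(as.numeric(emp) - duv$mass)), 1e-3)
})

test_that("interval overlap probabilities partition the mass", {
  acr <- interval_definition("ACR")
  expect_equal(acr$older, 14500); expect_equal(acr$younger, 13000)
  yd <- interval_definition("YD")
  expect_equal(c(yd$older, yd$younger), c(13000, 11700))
  expect_error(interval_definition("custom", 100, 200), "older > younger")

  u <- cal_pdf(seq(13002.5, 14497.5, by = 5), rep(1, 300))
  expect_equal(unname(overlap_probability(u, acr)), c(0, 1, 0))

  pt <- cal_pdf(seq(11952.5, 12052.5, 5), as.numeric(seq(11952.5, 12052.5, 5) == 12002.5))
  expect_equal(unname(overlap_probability(pt, acr)), c(0, 0, 1))

  tn <- normal_pdf(13000, 200)
  tr <- overlap_probability(tn, acr)
  manual <- c(sum(tn$mass[tn$grid > 14500]),
              sum(tn$mass[tn$grid <= 14500 & tn$grid >= 13000]),
              sum(tn$mass[tn$grid < 13000]))
  expect_equal(unname(tr), manual, tolerance = 1e-12)
  expect_equal(sum(tr), 1, tolerance = 1e-12)
})

test_that("smoothing preserves mass and location", {
  p <- normal_pdf(12500, 80)
  s <- smooth_pdf(p, 15)
  expect_equal(sum(s$mass), 1, tolerance = 1e-9)
  expect_lt(abs(pdf_mean(s) - pdf_mean(p)), 1)
  expect_identical(smooth_pdf(p, 0), p)
})
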