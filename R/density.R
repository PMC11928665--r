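# Distribution-level summaries and comparisons of calendar-age PDFs:
# Sum, fixed-bandwidth KDE, the MCMC KDE model, Difference, and overlap
# against named climatic intervals.

# Conform a list of cal_pdfs onto one shared grid (the union of their
# ranges); relies on the global cell-centre convention.
conform_pdfs <- function(pdfs) {
  res <- unique(round(vapply(pdfs, function(p) p$resolution, numeric(1)), 9))
  if (length(res) != 1L)
    stop("PDFs must share one grid resolution (got: ",
         paste(res, collapse = ", "), ")")
  res <- res[1]
  k <- lapply(pdfs, function(p) round(p$grid / res - 0.5))
  if (any(vapply(seq_along(pdfs), function(i)
    max(abs(res * (k[[i]] + 0.5) - pdfs[[i]]$grid)) > 1e-6, logical(1))))
    stop("PDF grids are not aligned to the shared cell-centre convention")
  k_lo <- min(vapply(k, min, numeric(1)))
  k_hi <- max(vapply(k, max, numeric(1)))
  grid <- res * (seq(k_lo, k_hi) + 0.5)
  mass <- vapply(seq_along(pdfs), function(i) {
    m <- numeric(length(grid))
    m[k[[i]] - k_lo + 1] <- pdfs[[i]]$mass
    m
  }, numeric(length(grid)))
  list(grid = grid, mass = mass, resolution = res)
}

#' Sum (average) a set of calendar PDFs
#'
#' The cell-wise average of the input masses on their common grid,
#' renormalised — the usual noisy summary that stacks individual date
#' distributions without any model of their dependence.
#'
#' @param pdfs Non-empty list of \code{\link{cal_pdf}}s on one grid
#'   convention.
#' @return A \code{\link{cal_pdf}}.
#' @export
sum_distribution <- function(pdfs) {
  if (!is.list(pdfs) || length(pdfs) == 0L)
    stop("sum_distribution needs at least one PDF")
  cf <- conform_pdfs(pdfs)
  cal_pdf(cf$grid, rowMeans(cf$mass))
}

#' Silverman's rule-of-thumb bandwidth
#'
#' \eqn{h = 0.9 \min(\hat\sigma, IQR/1.34) n^{-1/5}} for a sample of
#' calendar ages.
#'
#' @param values Numeric sample, n >= 2, with nonzero spread.
#' @return Bandwidth in years.
#' @export
silverman_bandwidth <- function(values) {
  n <- length(values)
  if (n < 2L) stop("bandwidth needs at least 2 values")
  s <- stats::sd(values)
  iqr <- stats::IQR(values) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(spread) || spread <= 0)
    stop("degenerate sample: zero spread")
  0.9 * spread * n^(-1 / 5)
}

#' Fixed-bandwidth kernel density of calendar values
#'
#' Normal kernel at Silverman's bandwidth, evaluated on the standard
#' calendar grid and normalised. This is the plain (non-MCMC) density plot
#' used for, e.g., last-appearance dates.
#'
#' @param values Calendar ages (cal BP), n >= 2.
#' @param resolution Grid resolution in years.
#' @param bandwidth Kernel bandwidth; default Silverman.
#' @return A \code{\link{cal_pdf}}.
#' @export
kde_plot <- function(values, resolution = 5,
                     bandwidth = silverman_bandwidth(values)) {
  rng <- range(values) + c(-4, 4) * bandwidth
  grid <- calibration_grid(rng, resolution)
  dens <- vapply(grid, function(g)
    sum(stats::dnorm(g, mean = values, sd = bandwidth)), numeric(1))
  cal_pdf(grid, dens)
}

#' MCMC kernel density model of a set of related dates
#'
#' Estimates the underlying distribution of a set of events, each known only
#' through a calendar PDF, resisting the over-smoothing of a fixed-bandwidth
#' KDE. The sampler alternates (i) a Metropolis update of each true event
#' age, whose conditional combines the event's own PDF (likelihood) with the
#' leave-one-out normal-kernel density of the other current ages (the KDE
#' acting as a shared prior, making events dependent), and (ii) a Metropolis
#' update of a bandwidth shaping factor s ~ U(0,1) applied to Silverman's
#' rule, h = s * h_Silverman, with the bandwidth treated as a parameter via
#' the KDE pseudo-likelihood of the current ages. Snapshots of the KDE are
#' recorded every pass; the point estimate is the snapshot mean.
#'
#' @param event_pdfs List of >= 2 \code{\link{cal_pdf}}s.
#' @param n_burn,n_iter Burn-in and retained iterations.
#' @param snapshot_every Iterations between recorded KDE snapshots.
#' @param resolution Output grid resolution in years.
#' @return A list of class \code{kde_result}: \code{point_estimate}
#'   (\code{cal_pdf}), \code{snapshot_mean}, \code{snapshot_sd} (per-grid
#'   density across snapshots), \code{bandwidth_posterior},
#'   \code{shaping_posterior}, \code{mean}, \code{median}, \code{grid}.
#' @export
kde_model <- function(event_pdfs, n_burn = 200, n_iter = 1000,
                      snapshot_every = 10, resolution = 5) {
  if (!is.list(event_pdfs) || length(event_pdfs) < 2L)
    stop("kde_model needs at least 2 event PDFs")
  n <- length(event_pdfs)
  cf <- conform_pdfs(event_pdfs)
  grid <- cf$grid
  massmat <- cf$mass
  res <- cf$resolution

  loglik_at <- function(i, t) {
    pos <- (t - grid[1]) / res
    j <- floor(pos); w <- pos - j
    if (j < 0 || j >= length(grid) - 1) return(-Inf)
    d <- massmat[j + 1, i] * (1 - w) + massmat[j + 2, i] * w
    if (d > 0) log(d) else -Inf
  }

  t <- vapply(event_pdfs, pdf_median, numeric(1))
  prop_sd <- vapply(event_pdfs, function(p)
    max(sqrt(sum(p$grid^2 * p$mass) - pdf_mean(p)^2), res), numeric(1))
  s_shape <- 0.5
  # degenerate sets (all ages in one cell) fall back to the grid scale
  base_bw <- function(tv) tryCatch(silverman_bandwidth(tv),
                                   error = function(e) res)
  kde_loglik <- function(tv, h) {
    # leave-one-out pseudo-likelihood of the current ages under the KDE
    ll <- 0
    for (i in seq_len(n)) {
      d <- sum(stats::dnorm(tv[i], tv[-i], h)) / (n - 1)
      if (d <= 0) return(-Inf)
      ll <- ll + log(d)
    }
    ll
  }

  snap <- list(); bw <- numeric(0); sh <- numeric(0)
  total <- n_burn + n_iter
  for (it in seq_len(total)) {
    h <- max(s_shape * base_bw(t), res / 4)
    for (i in seq_len(n)) {
      prop <- t[i] + rnorm(1, 0, prop_sd[i])
      num <- loglik_at(i, prop) +
        log(max(sum(stats::dnorm(prop, t[-i], h)), 1e-300))
      den <- loglik_at(i, t[i]) +
        log(max(sum(stats::dnorm(t[i], t[-i], h)), 1e-300))
      if (is.finite(num) && (num - den >= 0 || runif(1) < exp(num - den)))
        t[i] <- prop
    }
    s_prop <- s_shape + rnorm(1, 0, 0.1)
    if (s_prop > 0 && s_prop < 1) {
      h_prop <- max(s_prop * base_bw(t), res / 4)
      d <- kde_loglik(t, h_prop) - kde_loglik(t, h)
      if (is.finite(d) && (d >= 0 || runif(1) < exp(d))) s_shape <- s_prop
    }
    if (it > n_burn && (it - n_burn) %% snapshot_every == 0) {
      h <- max(s_shape * base_bw(t), res / 4)
      dens <- vapply(grid, function(g)
        sum(stats::dnorm(g, t, h)) / n, numeric(1))
      snap[[length(snap) + 1L]] <- dens
      bw <- c(bw, h); sh <- c(sh, s_shape)
    }
  }
  sm <- do.call(rbind, snap)
  mean_dens <- colMeans(sm)
  point <- cal_pdf(grid, mean_dens)
  structure(list(point_estimate = point,
                 snapshot_mean = mean_dens / (sum(mean_dens) * res),
                 snapshot_sd = apply(sm, 2, stats::sd) /
                   (sum(mean_dens) * res),
                 bandwidth_posterior = bw,
                 shaping_posterior = sh,
                 mean = pdf_mean(point),
                 median = pdf_median(point),
                 grid = grid),
            class = "kde_result")
}

#' @export
print.kde_result <- function(x, ...) {
  cat(sprintf("<kde_result: mean %.0f, median %.0f cal BP, %d snapshots>\n",
              x$mean, x$median, length(x$bandwidth_posterior)))
  invisible(x)
}

#' Distribution of the difference between two calendar PDFs
#'
#' Discrete cross-correlation of the two mass vectors under independence:
#' the distribution of (a - b) in years, positive meaning the first argument
#' is older. Also reports P(a - b > 0).
#'
#' @param pdf_a,pdf_b \code{\link{cal_pdf}}s on one grid convention.
#' @return A list of class \code{difference_result}: \code{delta} (signed
#'   years), \code{mass}, \code{p_older} = P(a - b > 0), \code{mean}.
#' @export
difference <- function(pdf_a, pdf_b) {
  cf <- conform_pdfs(list(pdf_a, pdf_b))
  a <- cf$mass[, 1]; b <- cf$mass[, 2]
  keep <- which(a > 0 | b > 0)          # trim to the joint support
  a <- a[keep[1]:keep[length(keep)]]
  b <- b[keep[1]:keep[length(keep)]]
  n <- length(a)
  # delta = res * k for k in -(n-1) .. (n-1); mass[k] = sum_i a[i+k] b[i]
  mass <- numeric(2 * n - 1)
  for (k in seq(-(n - 1), n - 1)) {
    i <- max(1, 1 - k):min(n, n - k)
    mass[k + n] <- sum(a[i + k] * b[i])
  }
  delta <- cf$resolution * seq(-(n - 1), n - 1)
  # half the tie cell counts as "older", so identical symmetric inputs give
  # exactly 1/2 (the continuous-limit convention)
  structure(list(delta = delta, mass = mass,
                 p_older = sum(mass[delta > 0]) + 0.5 * mass[delta == 0],
                 p_tie = mass[delta == 0],
                 mean = sum(delta * mass)),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf("<difference: mean %+.0f yr, P(first older) = %.3f>\n",
              x$mean, x$p_older))
  invisible(x)
}

#' Named climatic interval
#'
#' Fixed uniform intervals on the calendar scale. Presets:
#' \code{"ACR"} (Antarctic Cold Reversal) = 14500-13000 cal BP and
#' \code{"YD"} (Younger Dryas) = 13000-11700 cal BP.
#'
#' @param label \code{"ACR"}, \code{"YD"} or \code{"custom"}.
#' @param older,younger Endpoints in cal BP for a custom interval.
#' @return A list of class \code{interval_definition}.
#' @export
interval_definition <- function(label = c("ACR", "YD", "custom"),
                                older = NULL, younger = NULL) {
  label <- match.arg(label)
  if (label == "ACR") { older <- 14500; younger <- 13000 }
  else if (label == "YD") { older <- 13000; younger <- 11700 }
  if (is.null(older) || is.null(younger) || older <= younger)
    stop("custom interval needs older > younger")
  structure(list(label = label, older = older, younger = younger,
                 form = "uniform"), class = "interval_definition")
}

#' Gaussian-smooth a calendar PDF
#'
#' Light kernel smoothing of the cell masses (used when turning raw MCMC
#' histograms into reported densities, where single-cell noise would
#' otherwise fragment HPD intervals).
#'
#' @param pdf A \code{\link{cal_pdf}}.
#' @param bandwidth Kernel sd in years; 0 returns the input unchanged.
#' @return A \code{\link{cal_pdf}}.
#' @export
smooth_pdf <- function(pdf, bandwidth = 3 * pdf$resolution) {
  if (bandwidth <= 0) return(pdf)
  res <- pdf$resolution
  pad <- ceiling(4 * bandwidth / res)
  k <- round(pdf$grid / res - 0.5)
  kk <- seq(min(k) - pad, max(k) + pad)
  grid <- res * (kk + 0.5)
  half <- stats::dnorm(res * (0:pad), 0, bandwidth)
  kern <- c(rev(half[-1]), half)
  m <- numeric(length(kk))
  m[k - min(kk) + 1] <- pdf$mass
  sm <- stats::convolve(m, kern, type = "open")
  sm <- sm[(pad + 1):(pad + length(kk))]
  cal_pdf(grid, pmax(sm, 0))
}

#' Normal calendar-age prior as a PDF
#'
#' Used for chronometric ages already on the calendar scale (e.g. OSL or
#' U-series), which enter models as normal likelihoods directly.
#'
#' @param mean,sd Calendar age and 1-sigma error (cal BP / years).
#' @param resolution Grid resolution in years.
#' @return A \code{\link{cal_pdf}} over mean +/- 5 sd.
#' @export
normal_pdf <- function(mean, sd, resolution = 5) {
  grid <- calibration_grid(c(mean - 5 * sd, mean + 5 * sd), resolution)
  cal_pdf(grid, stats::dnorm(grid, mean, sd))
}

#' Overlap of a calendar PDF with a climatic interval
#'
#' @param start_pdf A \code{\link{cal_pdf}} (typically a start-boundary
#'   posterior).
#' @param interval An \code{\link{interval_definition}}.
#' @return Named numeric \code{c(p_before, p_within, p_after)}: the PDF mass
#'   older than, inside, and younger than the interval. Sums to 1.
#' @export
overlap_probability <- function(start_pdf, interval) {
  g <- start_pdf$grid; m <- start_pdf$mass
  c(p_before = sum(m[g > interval$older]),
    p_within = sum(m[g <= interval$older & g >= interval$younger]),
    p_after = sum(m[g < interval$younger]))
}
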