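#' Construct a calibration curve
#'
#' A calibration curve maps calendar age theta (cal BP, years before AD 1950,
#' larger = older) to an expected conventional radiocarbon age \code{mu(theta)}
#' with 1-sigma uncertainty \code{sigma(theta)}. Lookups between knots use
#' linear interpolation of both \code{mu} and \code{sigma}; lookups outside
#' the knot range are an error (silent truncation would bias phase boundaries).
#'
#' @param theta Calendar ages of the knots (cal BP). Must be strictly
#'   increasing after sorting; duplicates are an error.
#' @param mu Radiocarbon age (14C yr BP) at each knot.
#' @param sigma 1-sigma curve uncertainty (14C yr) at each knot; all > 0.
#' @param label Curve name, e.g. \code{"SHCal20"} or \code{"synthetic"}.
#' @param hemisphere One of \code{"north"}, \code{"south"}, \code{"marine"},
#'   \code{"synthetic"}.
#' @return An object of class \code{cal_curve}.
#' @export
cal_curve <- function(theta, mu, sigma, label = "curve",
                      hemisphere = c("synthetic", "north", "south", "marine")) {
  hemisphere <- match.arg(hemisphere)
  if (length(theta) < 2L) stop("a calibration curve needs at least 2 knots")
  if (length(mu) != length(theta) || length(sigma) != length(theta))
    stop("theta, mu and sigma must have equal length")
  ord <- order(theta)
  theta <- theta[ord]; mu <- mu[ord]; sigma <- sigma[ord]
  if (anyDuplicated(theta)) stop("duplicate calendar ages in calibration curve")
  if (any(!is.finite(theta)) || any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("non-finite values in calibration curve")
  if (any(sigma <= 0)) stop("curve sigma must be > 0 at every knot")
  structure(list(theta = theta, mu = mu, sigma = sigma,
                 label = label, hemisphere = hemisphere),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve '%s' (%s): %d knots, %.0f-%.0f cal BP>\n",
              x$label, x$hemisphere, length(x$theta),
              min(x$theta), max(x$theta)))
  invisible(x)
}

#' Read a calibration curve from a `.14c`-style file
#'
#' Accepts the circulated dialects: one knot per line as
#' \code{cal BP, 14C age BP, 1 sigma}, separated by commas or tabs
#' (auto-detected per file), with \code{#} comment lines ignored.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param dialect \code{"auto"} (default), \code{"comma"} or \code{"tab"}.
#' @param label,hemisphere Passed to \code{\link{cal_curve}}.
#' @return A \code{cal_curve}.
#' @export
read_14c <- function(source, dialect = c("auto", "comma", "tab"),
                     label = NULL, hemisphere = "synthetic") {
  dialect <- match.arg(dialect)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(label)) label <- "curve"
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("calibration curve format error: no knot lines")
  sep <- if (dialect == "comma") "," else if (dialect == "tab") "\t" else {
    if (any(grepl("\t", lines[idx]))) "\t" else ","
  }
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), sep, fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (length(vals) < 3L || any(is.na(vals[1:3])))
      stop(sprintf("calibration curve parse error at line %d: '%s'",
                   idx[k], lines[idx[k]]))
    rows[[k]] <- vals[1:3]
  }
  m <- do.call(rbind, rows)
  if (nrow(m) < 2L) stop("calibration curve format error: fewer than 2 knots")
  cal_curve(m[, 1], m[, 2], m[, 3], label = label, hemisphere = hemisphere)
}

#' Write a calibration curve to a `.14c`-style file
#'
#' @param curve A \code{cal_curve}.
#' @param path Output path.
#' @param dialect \code{"comma"} or \code{"tab"}.
#' @export
write_14c <- function(curve, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  header <- sprintf("# %s (%s); columns: cal BP%s14C age BP%s1 sigma",
                    curve$label, curve$hemisphere, sep, sep)
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  body <- paste(num(curve$theta), num(curve$mu), num(curve$sigma), sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Interpolate a calibration curve at given calendar ages
#'
#' @param curve A \code{cal_curve}.
#' @param theta Calendar ages (cal BP); must all lie within the knot range.
#' @return A list with numeric vectors \code{mu} and \code{sigma}.
#' @export
curve_lookup <- function(curve, theta) {
  rng <- range(curve$theta)
  if (any(theta < rng[1] | theta > rng[2]))
    stop(sprintf("calendar age outside calibration curve range [%g, %g]",
                 rng[1], rng[2]))
  list(mu = stats::approx(curve$theta, curve$mu, xout = theta)$y,
       sigma = stats::approx(curve$theta, curve$sigma, xout = theta)$y)
}

#' Construct a radiocarbon determination
#'
#' One laboratory measurement: a conventional radiocarbon age (CRA) with its
#' 1-sigma error and calibration metadata. Marine determinations must carry a
#' local reservoir offset Delta-R; positive Delta-R means locally older water
#' and is subtracted from the CRA mean before calibration.
#'
#' @param cra Conventional radiocarbon age (14C yr BP).
#' @param sigma 1-sigma measurement error (14C yr), > 0.
#' @param lab_id Laboratory code.
#' @param material Dated material (free text).
#' @param reservoir One of \code{"atmospheric"}, \code{"marine"},
#'   \code{"mixed_hemispheric"}.
#' @param delta_r Length-2 numeric \code{c(mean, sd)}; required iff
#'   \code{reservoir = "marine"}.
#' @param curve_key Name of the calibration curve to use (registry key).
#' @return An object of class \code{determination}.
#' @export
determination <- function(cra, sigma, lab_id = "", material = "",
                          reservoir = c("atmospheric", "marine",
                                        "mixed_hemispheric"),
                          delta_r = NULL, curve_key = "") {
  reservoir <- match.arg(reservoir)
  if (!is.finite(cra) || !is.finite(sigma) || sigma <= 0)
    stop("determination needs finite cra and sigma > 0")
  if (reservoir == "marine") {
    if (is.null(delta_r) || length(delta_r) != 2L || any(!is.finite(delta_r)))
      stop("marine determination requires delta_r = c(mean, sd)")
  } else if (!is.null(delta_r)) {
    stop("delta_r is only meaningful for marine determinations")
  }
  structure(list(lab_id = lab_id, cra = cra, sigma = sigma,
                 material = material, reservoir = reservoir,
                 delta_r = delta_r, curve_key = curve_key),
            class = "determination")
}

#' @export
print.determination <- function(x, ...) {
  cat(sprintf("<determination %s: %.0f +/- %.0f 14C BP (%s)>\n",
              if (nzchar(x$lab_id)) x$lab_id else "?", x$cra, x$sigma,
              x$reservoir))
  invisible(x)
}

#' Apply a marine reservoir offset (Delta-R) to a determination
#'
#' Subtracts the Delta-R mean from the CRA and adds its uncertainty in
#' quadrature; returns a new determination, leaving the input unchanged.
#'
#' @param det A marine \code{determination}.
#' @param delta_r Length-2 numeric \code{c(mean, sd)}; defaults to the value
#'   stored on the determination.
#' @return A \code{determination} with the offset folded in (and
#'   \code{delta_r} cleared so it is not applied twice).
#' @export
apply_reservoir_offset <- function(det, delta_r = det$delta_r) {
  if (det$reservoir != "marine")
    stop("reservoir offset applies only to marine determinations")
  if (is.null(delta_r) || length(delta_r) != 2L)
    stop("delta_r = c(mean, sd) required")
  out <- det
  out$cra <- det$cra - delta_r[1]
  out$sigma <- sqrt(det$sigma^2 + delta_r[2]^2)
  out$delta_r <- NULL
  out$reservoir <- "atmospheric"   # now calibrates directly on the marine curve grid
  out$applied_delta_r <- delta_r
  out
}

# ---- calendar-age PDFs -----------------------------------------------------

#' Construct a calendar-age probability distribution
#'
#' A discrete PDF on a regular cal BP grid (cell-centre convention). Masses
#' are normalised to sum to one.
#'
#' @param grid Ascending cal BP cell centres at constant spacing.
#' @param mass Non-negative cell masses; normalised internally.
#' @return An object of class \code{cal_pdf}.
#' @export
cal_pdf <- function(grid, mass) {
  if (length(grid) != length(mass) || length(grid) < 1L)
    stop("grid and mass must be equal-length, non-empty")
  if (any(mass < 0)) stop("negative mass in cal_pdf")
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0) stop("cal_pdf has zero total mass")
  if (length(grid) > 1L) {
    steps <- diff(grid)
    if (any(steps <= 0)) stop("cal_pdf grid must be strictly ascending")
    if (max(steps) - min(steps) > 1e-6 * steps[1])
      stop("cal_pdf grid must have constant resolution")
  }
  structure(list(grid = as.numeric(grid), mass = as.numeric(mass / tot),
                 resolution = if (length(grid) > 1L) grid[2] - grid[1] else NA_real_),
            class = "cal_pdf")
}

#' @export
print.cal_pdf <- function(x, ...) {
  ci <- hpd_interval(x, 0.954)
  cat(sprintf("<cal_pdf: %d cells @ %g yr, mean %.0f cal BP, 95.4%% HPD %s>\n",
              length(x$grid), x$resolution, pdf_mean(x),
              paste(sprintf("[%.0f, %.0f]", ci[, 1], ci[, 2]), collapse = " ")))
  invisible(x)
}

#' @rdname cal_pdf
#' @param pdf A \code{cal_pdf}.
#' @export
pdf_mean <- function(pdf) sum(pdf$grid * pdf$mass)

#' @rdname cal_pdf
#' @export
pdf_median <- function(pdf) {
  cum <- cumsum(pdf$mass)
  pdf$grid[which(cum >= 0.5)[1]]
}

#' @rdname cal_pdf
#' @export
pdf_mode <- function(pdf) pdf$grid[which.max(pdf$mass)]

#' Write / read a calendar PDF as two-column CSV
#'
#' Column 1 is cal BP (cell centre), column 2 the cell probability. A
#' \code{#}-prefixed metadata header records the resolution.
#'
#' @param pdf A \code{cal_pdf}.
#' @param path File path.
#' @export
write_cal_pdf <- function(pdf, path) {
  writeLines(c(sprintf("# cal_pdf resolution=%g", pdf$resolution),
               "calBP,probability",
               paste(format(pdf$grid, scientific = FALSE, trim = TRUE),
                     format(pdf$mass, digits = 17, scientific = FALSE,
                            trim = TRUE), sep = ",")), path)
  invisible(path)
}

#' @rdname write_cal_pdf
#' @export
read_cal_pdf <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  cal_pdf(d[[1]], d[[2]])
}

#' Calibrate a radiocarbon determination
#'
#' Converts a CRA x +/- sigma into a calendar-age PDF on a regular grid using
#' the error-in-variables likelihood
#' \deqn{p(\theta) \propto \frac{\exp\{-(x-\mu(\theta))^2 / 2(\sigma^2+\sigma_c(\theta)^2)\}}
#'       {\sqrt{\sigma^2+\sigma_c(\theta)^2}}}
#' evaluated at grid-cell centres and normalised. Marine determinations have
#' their Delta-R folded in first.
#'
#' @param det A \code{determination}.
#' @param curve A \code{cal_curve}.
#' @param resolution Grid spacing in calendar years (default 5).
#' @param range Optional \code{c(young, old)} cal BP limits for the grid;
#'   defaults to the curve's span.
#' @return A \code{cal_pdf}.
#' @export
calibrate <- function(det, curve, resolution = 5, range = NULL) {
  if (det$reservoir == "marine") det <- apply_reservoir_offset(det)
  rng <- if (is.null(range)) base::range(curve$theta) else sort(range)
  grid <- calibration_grid(rng, resolution)
  lk <- curve_lookup(curve, grid)
  v <- det$sigma^2 + lk$sigma^2
  logd <- -0.5 * (det$cra - lk$mu)^2 / v - 0.5 * log(v)
  dens <- exp(logd - max(logd))
  tot <- sum(dens)
  if (!is.finite(tot) || tot <= 0 || !is.finite(max(logd)))
    stop("calibration error: determination has no support on this curve")
  # guard against a date far outside the curve: all log-densities astronomically low
  if (max(logd) < -0.5 * 40^2)  # > 40 sigma off everywhere
    stop("calibration error: determination lies far outside the curve range")
  cal_pdf(grid, dens)
}

# Cell centres at resolution * (k + 1/2), so PDFs built anywhere in the
# package share one global grid convention and can be conformed cell-wise.
calibration_grid <- function(rng, resolution) {
  k_lo <- ceiling(rng[1] / resolution - 0.5 + 1e-9)
  k_hi <- floor(rng[2] / resolution - 0.5 - 1e-9)
  if (k_hi < k_lo) stop("grid range too narrow for requested resolution")
  resolution * (seq(k_lo, k_hi) + 0.5)
}

#' Calibrate with a uniform mixture of two hemispheric curves
#'
#' Marginalises a mixing fraction m ~ U(0,1) between a northern and a
#' southern curve: the effective curve has mean
#' \code{m * mu_n + (1-m) * mu_s} and similarly interpolated sigma. The
#' integral over m is approximated by midpoint quadrature.
#'
#' @param det A \code{determination}.
#' @param curve_n,curve_s The two \code{cal_curve}s (conventionally northern
#'   and southern hemisphere).
#' @param resolution Grid spacing in years.
#' @param n_quad Number of quadrature nodes for the mixing fraction
#'   (default 101; at least 21).
#' @param range Optional grid limits as in \code{\link{calibrate}}.
#' @return A \code{cal_pdf}.
#' @export
mix_calibration <- function(det, curve_n, curve_s, resolution = 5,
                            n_quad = 101, range = NULL) {
  if (n_quad < 21) stop("n_quad must be at least 21")
  rng_n <- base::range(curve_n$theta); rng_s <- base::range(curve_s$theta)
  rng <- if (is.null(range)) c(max(rng_n[1], rng_s[1]), min(rng_n[2], rng_s[2]))
         else sort(range)
  grid <- calibration_grid(rng, resolution)
  ln <- curve_lookup(curve_n, grid); ls <- curve_lookup(curve_s, grid)
  ms <- (seq_len(n_quad) - 0.5) / n_quad   # midpoints of U(0,1)
  dens <- numeric(length(grid))
  for (m in ms) {
    mu <- m * ln$mu + (1 - m) * ls$mu
    sg <- m * ln$sigma + (1 - m) * ls$sigma
    v <- det$sigma^2 + sg^2
    dens <- dens + exp(-0.5 * (det$cra - mu)^2 / v) / sqrt(v)
  }
  if (sum(dens) <= 0) stop("calibration error: no support under mixed curves")
  cal_pdf(grid, dens)
}

#' Highest posterior density interval(s) of a calendar PDF
#'
#' Greedily accumulates grid cells in descending mass order until the
#' requested level is reached (ties broken toward older ages), then merges
#' contiguous runs into disjoint intervals reported older to younger.
#'
#' @param pdf A \code{cal_pdf}.
#' @param level Coverage level in (0,1); conventionally 0.682 or 0.954.
#' @return A numeric matrix with columns \code{older}, \code{younger}, one
#'   row per disjoint interval, ordered oldest first. Attribute
#'   \code{coverage} holds the achieved mass.
#' @export
hpd_interval <- function(pdf, level = 0.954) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  ord <- order(pdf$mass, pdf$grid, decreasing = TRUE)  # ties toward older
  cum <- cumsum(pdf$mass[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  cells <- sort(ord[seq_len(k)])
  runs <- split(cells, cumsum(c(1, diff(cells) != 1)))
  out <- t(vapply(runs, function(r) c(pdf$grid[max(r)], pdf$grid[min(r)]),
                  numeric(2)))
  colnames(out) <- c("older", "younger")
  out <- out[order(out[, "older"], decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage") <- cum[k]
  out
}

#' Round a calendar interval to a reporting step
#'
#' Endpoints are rounded to the nearest multiple of \code{step}; exact
#' half-way values round outward (away from the interval centre) so coverage
#' never shrinks.
#'
#' @param interval Numeric \code{c(older, younger)} in cal BP, or a matrix
#'   with columns older/younger.
#' @param step Rounding step in years (default 10).
#' @return Rounded interval(s), same shape as the input.
#' @export
round_interval <- function(interval, step = 10) {
  if (is.matrix(interval)) {
    out <- interval
    out[, 1] <- step * floor(interval[, 1] / step + 0.5)
    out[, 2] <- step * ceiling(interval[, 2] / step - 0.5)
    return(out)
  }
  if (length(interval) != 2L || interval[1] < interval[2])
    stop("interval must be c(older, younger) with older >= younger")
  c(step * floor(interval[1] / step + 0.5),
    step * ceiling(interval[2] / step - 0.5))
}
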