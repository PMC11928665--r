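# Posterior sampling of phase models: compilation of a model tree into the
# flat form the compiled Metropolis-within-Gibbs core consumes, the
# convergence protocol, and trace summaries.

#' Sampler settings
#'
#' @param initial_iterations Adaptive warm-up length (default 30000). Proposal
#'   scales are tuned here and frozen afterwards, so retained samples satisfy
#'   detailed balance.
#' @param iterations Retained iterations for \code{\link{sample_posterior}}
#'   (default 30000).
#' @param pass_length Iterations per convergence pass (default 3000).
#' @param pass_interval_growth Factor by which the pass interval grows while
#'   convergence is unsatisfactory (default 2).
#' @param convergence_threshold Required minimum overlap between
#'   interleaved-half marginal densities (default 0.95).
#' @param max_iterations Hard cap on accumulated retained iterations for
#'   \code{\link{check_convergence}} (default 2^20).
#' @param thinning Keep every \code{thinning}-th iteration (default 1).
#' @param grid_resolution Calendar grid resolution in years for posterior
#'   PDFs (default 5).
#' @param span_prior \code{"standard"} (joint prior per uniform-phase group
#'   proportional to span^-(n-1): events uniform given the boundaries with
#'   the group span itself near-uniform) or \code{"naive"} (span^-n: flat
#'   prior directly on the boundary pair).
#' @param outlier_prior Default prior outlier probability per dated event.
#' @param window Optional \code{c(young, old)} cal BP support limits for all
#'   model parameters; defaults to the union of the events' likelihood
#'   supports.
#' @return A list of class \code{sampler_settings}.
#' @export
sampler_settings <- function(initial_iterations = 30000, iterations = 30000,
                             pass_length = 3000, pass_interval_growth = 2,
                             convergence_threshold = 0.95,
                             max_iterations = 2^20, thinning = 1,
                             grid_resolution = 5,
                             span_prior = c("standard", "naive"),
                             outlier_prior = 0.05, window = NULL) {
  span_prior <- match.arg(span_prior)
  stopifnot(initial_iterations > 0, iterations > 0, pass_length > 0,
            pass_interval_growth > 1, thinning >= 1,
            convergence_threshold > 0, convergence_threshold < 1)
  structure(list(initial_iterations = as.integer(initial_iterations),
                 iterations = as.integer(iterations),
                 pass_length = as.integer(pass_length),
                 pass_interval_growth = pass_interval_growth,
                 convergence_threshold = convergence_threshold,
                 max_iterations = max_iterations,
                 thinning = as.integer(thinning),
                 grid_resolution = grid_resolution,
                 span_prior = span_prior,
                 outlier_prior = outlier_prior,
                 window = window),
            class = "sampler_settings")
}

curve_table <- function(curve, step = 1) {
  rng <- range(curve$theta)
  theta <- seq(rng[1], rng[2], by = step)
  if (theta[length(theta)] < rng[2]) theta <- c(theta, rng[2])
  lk <- curve_lookup(curve, theta)
  list(theta0 = theta[1], step = step, mu = lk$mu, sigma = lk$sigma)
}

resolve_event_curves <- function(det, curves) {
  key <- det$curve_key
  if (det$reservoir == "mixed_hemispheric") {
    if (length(key) != 2L)
      stop(sprintf("mixed-curve determination '%s' needs two curve keys",
                   det$lab_id))
    return(key)
  }
  if (length(key) != 1L || !nzchar(key))
    stop(sprintf("determination '%s' has no curve assignment", det$lab_id))
  key
}

# Flatten a validated model tree into the structure the compiled sampler
# consumes. Supports the shapes the pipeline emits: a single sequence whose
# children are boundaries, uniform phases and bare (ordered) dated events, or
# a lone event/phaseless model. Undated events inside phases become Date
# queries (recorded draws), not parameters.
compile_model <- function(model, curves, settings) {
  v <- validate_model(model)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  if (model$kind == "event") model <- cal_sequence(model$label, model)
  if (model$kind != "sequence")
    stop("the sampler takes a sequence (or a single event); got a ", model$kind)

  curve_keys <- character(0)
  ev <- list(phase = integer(0), lik = integer(0), x = numeric(0),
             sig = numeric(0), c1 = integer(0), c2 = integer(0),
             out = integer(0), q = numeric(0), chain_pos = integer(0),
             label = character(0))
  pdfs <- list()
  bounds <- character(0)
  b_chain_pos <- integer(0)
  chain_type <- integer(0); chain_id <- integer(0)
  phase_start <- integer(0); phase_end <- integer(0)
  phase_label <- character(0); date_label <- character(0)

  curve_index <- function(keyv) {
    for (k in keyv) {
      if (!k %in% names(curves))
        stop(sprintf("curve '%s' is not registered", k))
      if (!k %in% curve_keys) curve_keys <<- c(curve_keys, k)
    }
    match(keyv, curve_keys)
  }

  add_event <- function(node, phase_idx, chain_pos) {
    i <- length(ev$label) + 1L
    out_type <- 0L; out_q <- 0
    if (!is.null(node$outlier)) {
      out_type <- if (node$outlier$preset == "general") 1L else 2L
      out_q <- node$outlier$prior_prob
    }
    if (!is.null(node$det)) {
      det <- node$det
      if (det$reservoir == "marine") det <- apply_reservoir_offset(det)
      keys <- resolve_event_curves(det, curves)
      idx <- curve_index(keys)
      ev$phase[i] <<- phase_idx; ev$lik[i] <<- 1L
      ev$x[i] <<- det$cra; ev$sig[i] <<- det$sigma
      ev$c1[i] <<- idx[1]; ev$c2[i] <<- if (length(idx) > 1) idx[2] else 0L
      pdfs[[i]] <<- list(NULL)
    } else {
      ev$phase[i] <<- phase_idx; ev$lik[i] <<- 2L
      ev$x[i] <<- 0; ev$sig[i] <<- 1
      ev$c1[i] <<- 1L; ev$c2[i] <<- 0L
      p <- node$pdf
      pdfs[[i]] <<- list(list(grid0 = p$grid[1], step = p$resolution,
                              dens = p$mass / p$resolution))
    }
    ev$out[i] <<- out_type; ev$q[i] <<- out_q
    ev$chain_pos[i] <<- chain_pos
    ev$label[i] <<- node$label
    i
  }

  for (child in model$children) {
    if (child$kind == "boundary") {
      j <- length(bounds) + 1L
      bounds[j] <- child$label
      chain_type <- c(chain_type, 0L); chain_id <- c(chain_id, j - 1L)
      b_chain_pos[j] <- length(chain_type) - 1L
    } else if (child$kind == "event") {
      if (is.null(child$det) && is.null(child$pdf))
        stop("undated events are only supported inside phases (as Date queries)")
      i <- add_event(child, -1L, NA_integer_)
      chain_type <- c(chain_type, 1L); chain_id <- c(chain_id, i - 1L)
      ev$chain_pos[i] <- length(chain_type) - 1L
    } else if (child$kind == "phase") {
      p <- length(phase_start) + 1L
      phase_start[p] <- length(bounds) - 1L    # 0-based index of preceding boundary
      phase_end[p] <- length(bounds)           # the following boundary, added next
      phase_label[p] <- child$label
      date_label[p] <- paste0("date:", child$label)
      for (e in child$children) {
        if (e$kind != "event")
          stop("nested groups inside phases are not supported by this sampler")
        if (is.null(e$det) && is.null(e$pdf)) {
          date_label[p] <- e$label             # explicit Date query node
        } else {
          add_event(e, p - 1L, NA_integer_)
        }
      }
    } else {
      stop("nested sequences are not supported by this sampler")
    }
  }
  if (length(phase_start) > 0 && any(phase_end > length(bounds) - 1L))
    stop("invalid model: a phase lacks its following boundary")

  n_per_phase <- if (length(phase_start))
    vapply(seq_along(phase_start) - 1L,
           function(p) sum(ev$phase == p), integer(1)) else integer(0)
  span_exp <- if (settings$span_prior == "standard")
    -(pmax(n_per_phase, 1L) - 1) else -pmax(n_per_phase, 1L)

  tabs <- lapply(curve_keys, function(k) curve_table(curves[[k]]))
  pdfs <- lapply(pdfs, function(p) p[[1]])

  list(window = c(0, 0),   # filled by init_state
       phase_start = phase_start, phase_end = phase_end,
       span_exp = span_exp,
       chain_type = chain_type, chain_id = chain_id,
       b_chain_pos = b_chain_pos,
       ev_chain_pos = ifelse(is.na(ev$chain_pos), -1L, ev$chain_pos),
       ev_phase = ev$phase, lik_type = ev$lik,
       curve1 = ev$c1, curve2 = ev$c2,
       out_type = ev$out, out_q = ev$q,
       x = ev$x, sigma = ev$sig,
       curves = tabs, pdfs = pdfs,
       labels = list(bounds = bounds, events = ev$label,
                     phases = phase_label, dates = date_label),
       curve_keys = curve_keys)
}

# Per-event likelihood summaries used for the support window, initial values
# and proposal scales. lo/hi are the full support of the event's likelihood
# (the curve span for determinations, the grid span for PDF events), matching
# the convention that the calibration curve bounds the modelled time range.
event_marginals <- function(cm, curves, settings) {
  n <- length(cm$ev_phase)
  out <- data.frame(lo = numeric(n), hi = numeric(n), med = numeric(n),
                    sd = numeric(n))
  for (i in seq_len(n)) {
    if (cm$lik_type[i] == 2L) {
      p <- cm$pdfs[[i]]
      grid <- p$grid0 + p$step * (seq_along(p$dens) - 1)
      pdf <- cal_pdf(grid, pmax(p$dens, 0))
      out$lo[i] <- grid[1]; out$hi[i] <- grid[length(grid)]
    } else {
      key <- cm$curve_keys[cm$curve1[i]]
      det <- determination(cm$x[i], cm$sigma[i], curve_key = key)
      pdf <- if (cm$curve2[i] > 0) {
        key2 <- cm$curve_keys[cm$curve2[i]]
        mix_calibration(det, curves[[key]], curves[[key2]],
                        resolution = settings$grid_resolution)
      } else {
        calibrate(det, curves[[key]], resolution = settings$grid_resolution)
      }
      rng <- range(curves[[key]]$theta)
      if (cm$curve2[i] > 0) {
        rng2 <- range(curves[[cm$curve_keys[cm$curve2[i]]]]$theta)
        rng <- c(max(rng[1], rng2[1]), min(rng[2], rng2[2]))
      }
      out$lo[i] <- rng[1]; out$hi[i] <- rng[2]
    }
    out$med[i] <- pdf_median(pdf)
    out$sd[i] <- sqrt(max(sum(pdf$grid^2 * pdf$mass) - pdf_mean(pdf)^2,
                          settings$grid_resolution^2))
  }
  out
}

init_state <- function(cm, marg, settings) {
  res <- settings$grid_resolution
  n <- length(cm$ev_phase); B <- length(cm$labels$bounds)
  if (nrow(marg) == 0L && is.null(settings$window))
    stop("a model without dated events needs an explicit settings window")
  window <- if (!is.null(settings$window)) sort(settings$window) else
    c(min(marg$lo), max(marg$hi))

  t0 <- marg$med
  b0 <- numeric(B)
  for (p in seq_along(cm$phase_start)) {
    members <- which(cm$ev_phase == p - 1L)
    if (length(members)) {
      b0[cm$phase_start[p] + 1L] <- max(t0[members]) + res
      b0[cm$phase_end[p] + 1L] <- min(t0[members]) - res
    } else {
      mid <- mean(window)
      b0[cm$phase_start[p] + 1L] <- mid + res
      b0[cm$phase_end[p] + 1L] <- mid - res
    }
  }
  # enforce chain monotonicity (oldest -> youngest), then re-clamp events
  L <- length(cm$chain_type)
  age_of <- function(k) if (cm$chain_type[k] == 0L) b0[cm$chain_id[k] + 1L]
                        else t0[cm$chain_id[k] + 1L]
  set_age <- function(k, v) {
    if (cm$chain_type[k] == 0L) b0[cm$chain_id[k] + 1L] <<- v
    else t0[cm$chain_id[k] + 1L] <<- v
  }
  if (L > 1) for (k in 2:L) {
    if (age_of(k) > age_of(k - 1) - res / 10) {
      prev_id <- cm$chain_id[k - 1] + 1L
      cur_id <- cm$chain_id[k] + 1L
      new_v <- age_of(k - 1) - res / 10
      if (new_v < window[1])
        stop(sprintf(
          "empty support: cannot order '%s' after '%s' within the window",
          chain_label(cm, k), chain_label(cm, k - 1)))
      set_age(k, new_v)
    }
  }
  for (p in seq_along(cm$phase_start)) {
    a <- b0[cm$phase_start[p] + 1L]; b <- b0[cm$phase_end[p] + 1L]
    if (a <= b)
      stop(sprintf("empty support: boundaries '%s' and '%s' cannot bracket phase '%s'",
                   cm$labels$bounds[cm$phase_start[p] + 1L],
                   cm$labels$bounds[cm$phase_end[p] + 1L],
                   cm$labels$phases[p]))
    members <- which(cm$ev_phase == p - 1L)
    t0[members] <- pmin(pmax(t0[members], b + res / 20), a - res / 20)
  }
  b0 <- pmin(pmax(b0, window[1]), window[2])
  t0 <- pmin(pmax(t0, window[1]), window[2])

  bscale <- if (n > 0) max(mean(marg$sd), res) else diff(window) / 10
  list(window = window,
       init = list(bounds = b0, t = t0, z = rep(0L, n),
                   eps = rep(0, n), u = 1, m = rep(0.5, n)),
       scales = list(bounds = rep(bscale, B),
                     t = pmax(marg$sd, res),
                     eps = rep(1, n), m = rep(0.2, n), u = 0.3))
}

chain_label <- function(cm, k) {
  if (cm$chain_type[k] == 0L) cm$labels$bounds[cm$chain_id[k] + 1L]
  else cm$labels$events[cm$chain_id[k] + 1L]
}

assemble_trace <- function(cm, raw, settings, window) {
  samples <- cbind(raw$bounds, raw$t, raw$dates)
  colnames(samples) <- c(cm$labels$bounds, cm$labels$events, cm$labels$dates)
  z <- raw$z; colnames(z) <- cm$labels$events
  m <- raw$m; colnames(m) <- cm$labels$events
  mixed <- cm$curve2 > 0
  structure(list(samples = samples,
                 outlier_active = z[, cm$out_type > 0, drop = FALSE],
                 mixing = m[, mixed, drop = FALSE],
                 scale_exponent = if (any(cm$out_type == 1L)) raw$u else NULL,
                 accept = raw$accept,
                 model_info = list(labels = cm$labels,
                                   chain_type = cm$chain_type,
                                   chain_id = cm$chain_id,
                                   ev_phase = cm$ev_phase,
                                   phase_start = cm$phase_start,
                                   phase_end = cm$phase_end,
                                   window = window),
                 settings = settings),
            class = "chron_trace")
}

#' @export
print.chron_trace <- function(x, ...) {
  cat(sprintf("<chron_trace: %d retained samples, %d parameters>\n",
              nrow(x$samples), ncol(x$samples)))
  invisible(x)
}

#' Sample the posterior of a chronological model
#'
#' Runs the compiled Metropolis-within-Gibbs sampler: an adaptive warm-up of
#' \code{initial_iterations} (discarded), then \code{iterations} retained
#' draws with frozen proposal scales. Reproducible under \code{set.seed}.
#'
#' @param model A \code{chron_node} (see \code{\link{cal_sequence}}).
#' @param curves Named list of \code{\link{cal_curve}}s, keyed by the
#'   determinations' \code{curve_key}.
#' @param settings A \code{\link{sampler_settings}}.
#' @return A \code{chron_trace}: retained samples (boundary ages, event ages,
#'   per-phase Date queries), outlier activation indicators, curve-mixing
#'   fractions, and acceptance rates.
#' @export
sample_posterior <- function(model, curves, settings = sampler_settings()) {
  cm <- compile_model(model, curves, settings)
  marg <- event_marginals(cm, curves, settings)
  st <- init_state(cm, marg, settings)
  cm$window <- st$window
  raw <- cpp_phase_sampler(cm, st$init, st$scales,
                           settings$initial_iterations, settings$iterations,
                           settings$thinning, TRUE)
  assemble_trace(cm, raw, settings, st$window)
}

#' Per-parameter convergence metric
#'
#' The overlap integral \eqn{\int \min(\hat f_1, \hat f_2)} between kernel
#' density estimates of the first and second halves of a chain, evaluated on
#' a shared grid: 1 means the halves agree perfectly, 0 that they are
#' disjoint (drift, or a chain that jumped between modes). A chain with zero
#' variance (frozen: the sampler never moved) scores 0, since a non-moving
#' chain carries no evidence of convergence.
#'
#' @param v Numeric chain of one parameter's retained samples.
#' @return Overlap in [0, 1].
#' @export
half_overlap <- function(v) {
  n <- length(v)
  if (n < 8) return(0)
  a <- v[seq_len(n %/% 2)]; b <- v[(n %/% 2 + 1):n]
  rng <- range(v)
  if (diff(rng) == 0) return(0)
  bw <- stats::bw.nrd0(v)
  if (bw <= 0) return(0)
  da <- stats::density(a, bw = bw, n = 256, from = rng[1] - 3 * bw,
                       to = rng[2] + 3 * bw)
  db <- stats::density(b, bw = bw, n = 256, from = rng[1] - 3 * bw,
                       to = rng[2] + 3 * bw)
  dx <- da$x[2] - da$x[1]
  min(sum(pmin(da$y, db$y)) * dx, 1)
}

#' Run the pass-based convergence protocol
#'
#' An adaptive warm-up of \code{initial_iterations}, then passes of
#' \code{pass_length} retained iterations. After each pass, every continuous
#' parameter's marginal is estimated from the two interleaved halves of the
#' accumulated chain and their overlap integral computed; if the minimum
#' overlap exceeds \code{convergence_threshold} the run stops, otherwise the
#' pass interval grows by \code{pass_interval_growth} until the
#' \code{max_iterations} cap, which flags (not fails) the report.
#'
#' @inheritParams sample_posterior
#' @return A list with elements \code{trace} (a \code{chron_trace} over all
#'   retained iterations) and \code{report} (per-parameter overlap,
#'   \code{overall} minimum, \code{passes_run}, \code{iterations},
#'   \code{converged}).
#' @export
check_convergence <- function(model, curves, settings = sampler_settings()) {
  cm <- compile_model(model, curves, settings)
  marg <- event_marginals(cm, curves, settings)
  st <- init_state(cm, marg, settings)
  cm$window <- st$window

  warm <- cpp_phase_sampler(cm, st$init, st$scales,
                            settings$initial_iterations, 1L, 1L, TRUE)
  state <- warm$state; scales <- warm$scales
  acc <- NULL
  pass_len <- settings$pass_length
  total <- 0L; passes <- 0L; converged <- FALSE; per_par <- NULL
  repeat {
    chunk <- cpp_phase_sampler(cm, state, scales, 0L, as.integer(pass_len),
                               settings$thinning, FALSE)
    state <- chunk$state
    acc <- if (is.null(acc)) chunk else list(
      bounds = rbind(acc$bounds, chunk$bounds),
      t = rbind(acc$t, chunk$t),
      z = rbind(acc$z, chunk$z),
      u = c(acc$u, chunk$u),
      m = rbind(acc$m, chunk$m),
      dates = rbind(acc$dates, chunk$dates),
      accept = chunk$accept)
    total <- total + pass_len; passes <- passes + 1L
    cont <- cbind(acc$bounds, acc$t)
    colnames(cont) <- c(cm$labels$bounds, cm$labels$events)
    if (any(cm$out_type == 1L)) cont <- cbind(cont, scale_exponent = acc$u)
    per_par <- apply(cont, 2, half_overlap)
    if (min(per_par) > settings$convergence_threshold) { converged <- TRUE; break }
    if (total >= settings$max_iterations) break
    pass_len <- pass_len * settings$pass_interval_growth
  }
  trace <- assemble_trace(cm, acc, settings, st$window)
  list(trace = trace,
       report = list(per_parameter = per_par,
                     overall = min(per_par),
                     passes_run = passes,
                     iterations = total,
                     converged = converged))
}

#' Posterior calendar PDF of a model parameter
#'
#' Bins the retained samples of a boundary, event or Date-query parameter
#' onto the standard calendar grid.
#'
#' @param trace A \code{chron_trace}.
#' @param label Parameter label (a boundary/event label, or
#'   \code{"date:<phase label>"} for a phase's Date query).
#' @param resolution Grid resolution in years; defaults to the trace's
#'   setting.
#' @return A \code{\link{cal_pdf}}.
#' @export
posterior_pdf <- function(trace, label,
                          resolution = trace$settings$grid_resolution) {
  if (!label %in% colnames(trace$samples))
    stop(sprintf("no parameter '%s' in trace (have: %s)", label,
                 paste(colnames(trace$samples), collapse = ", ")))
  samples_to_pdf(trace$samples[, label], resolution)
}

samples_to_pdf <- function(v, resolution) {
  k <- round(v / resolution - 0.5)
  k_rng <- range(k)
  counts <- tabulate(k - k_rng[1] + 1L, nbins = k_rng[2] - k_rng[1] + 1L)
  grid <- resolution * (seq(k_rng[1], k_rng[2]) + 0.5)
  cal_pdf(grid, counts)
}

#' Check the hard order constraints in every retained sample
#'
#' Verifies, exhaustively over the trace, that the sequence chain is ordered
#' oldest to youngest and that every phase event lies between its boundaries.
#'
#' @param trace A \code{chron_trace}.
#' @return Number of violated sample/constraint pairs (0 for a healthy run).
#' @export
count_constraint_violations <- function(trace) {
  mi <- trace$model_info
  s <- trace$samples
  nb <- length(mi$labels$bounds)
  bad <- 0L
  chain_cols <- ifelse(mi$chain_type == 0L,
                       mi$chain_id + 1L,            # boundary columns
                       nb + mi$chain_id + 1L)       # event columns
  if (length(chain_cols) > 1) {
    for (k in 2:length(chain_cols)) {
      bad <- bad + sum(s[, chain_cols[k]] > s[, chain_cols[k - 1]] + 1e-9)
    }
  }
  for (p in seq_along(mi$phase_start)) {
    a <- s[, mi$phase_start[p] + 1L]; b <- s[, mi$phase_end[p] + 1L]
    bad <- bad + sum(a < b - 1e-9)
    members <- which(mi$ev_phase == p - 1L)
    for (i in members) {
      ti <- s[, nb + i]
      bad <- bad + sum(ti > a + 1e-9 | ti < b - 1e-9)
    }
  }
  bad
}

#' Export a trace to columnar CSV plus a JSON run manifest
#'
#' @param trace A \code{chron_trace}.
#' @param dir Output directory (created if needed).
#' @param name Stem for the two files.
#' @return Invisibly, the paths written.
#' @export
export_trace <- function(trace, dir, name = "trace") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  long <- data.frame(
    iteration = rep(seq_len(nrow(trace$samples)), ncol(trace$samples)),
    parameter = rep(colnames(trace$samples), each = nrow(trace$samples)),
    value = as.vector(trace$samples))
  utils::write.csv(long, csv, row.names = FALSE)
  manifest <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(settings = unclass(trace$settings),
                            accept = trace$accept,
                            n_samples = nrow(trace$samples),
                            parameters = colnames(trace$samples)),
                       manifest, auto_unbox = TRUE, null = "null")
  invisible(c(csv, manifest))
}
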