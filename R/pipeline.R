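# The end-to-end timeline pipeline: database ingest, curve assignment,
# site-level models, category-level single-phase integration, climatic
# overlap testing, and database-completeness statistics.

db_required_cols <- c("site", "country", "province", "latitude", "longitude",
                      "altitude_masl", "lithic", "megafauna", "layer",
                      "layer_order", "sample_id", "lab_id", "age_type",
                      "cra", "error", "material", "species", "pretreatment",
                      "d13c", "cn_ratio", "reservoir", "delta_r",
                      "delta_r_sd")

#' Load an archaeo-chronometric component database
#'
#' One CSV row per determination, keyed by site and stratigraphic layer
#' (cultural component). Nothing is filtered at load time; malformed rows
#' are collected into a rejects report, never silently dropped. Unknown
#' columns are preserved.
#'
#' @param source CSV path or a data.frame in the documented schema.
#' @return A list of class \code{chron_db}: \code{ages} (clean rows),
#'   \code{rejects} (data.frame of row numbers and reasons).
#' @export
load_database <- function(source) {
  d <- if (is.data.frame(source)) source
       else utils::read.csv(source, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(db_required_cols, names(d))
  if (length(missing_cols))
    stop("database schema error: missing columns ",
         paste(missing_cols, collapse = ", "))
  for (col in c("cra", "error", "latitude", "longitude", "altitude_masl",
                "d13c", "cn_ratio", "delta_r", "delta_r_sd")) {
    if (!is.numeric(d[[col]])) {
      suppressWarnings(d[[paste0(".", col)]] <- as.numeric(d[[col]]))
    } else d[[paste0(".", col)]] <- d[[col]]
  }
  reasons <- character(nrow(d))
  bad_cra <- is.na(d$.cra) & !is.na(d$cra) |
    (is.na(d$.cra) & d$age_type %in% c("14c", "calendar"))
  reasons[bad_cra] <- "non-numeric or missing age"
  bad_err <- (is.na(d$.error) | d$.error <= 0) & reasons == ""
  reasons[bad_err] <- "missing or non-positive error"
  bad_type <- !(d$age_type %in% c("14c", "calendar")) & reasons == ""
  reasons[bad_type] <- "unknown age_type"
  bad_dr <- d$reservoir %in% "marine" &
    (is.na(d$.delta_r) | is.na(d$.delta_r_sd)) & reasons == ""
  reasons[bad_dr] <- "marine determination without delta_r"
  keep <- reasons == ""
  rejects <- data.frame(row = which(!keep), reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  clean <- d[keep, , drop = FALSE]
  for (col in c("cra", "error", "latitude", "longitude", "altitude_masl",
                "d13c", "cn_ratio", "delta_r", "delta_r_sd")) {
    clean[[col]] <- clean[[paste0(".", col)]]
    clean[[paste0(".", col)]] <- NULL
    d[[paste0(".", col)]] <- NULL
  }
  rownames(clean) <- NULL
  for (col in c("species", "pretreatment", "material", "reservoir",
                "lithic", "megafauna", "sample_id"))
    clean[[col]][is.na(clean[[col]])] <- ""
  structure(list(ages = clean, rejects = rejects), class = "chron_db")
}

#' @export
print.chron_db <- function(x, ...) {
  cat(sprintf("<chron_db: %d ages, %d sites, %d rejects>\n",
              nrow(x$ages), length(unique(x$ages$site)), nrow(x$rejects)))
  invisible(x)
}

#' Assign calibration curves by latitude band
#'
#' Southern-hemisphere curve by default; the mixed hemispheric curve for
#' sites inside the configured mixing band (where northern air masses
#' influence the regional carbon signal); the northern curve poleward of the
#' band's northern edge; the marine curve wherever the record says so.
#'
#' @param db A \code{chron_db}.
#' @param mixing_band \code{c(south, north)} latitude limits in degrees of
#'   the mixed-curve band (default \code{c(-25, 15)}).
#' @param overrides Optional named character vector site -> curve key.
#' @return The \code{chron_db} with a \code{curve_key} column
#'   (\code{"south"}, \code{"north"}, \code{"mixed"}, \code{"marine"}).
#' @export
assign_curves <- function(db, mixing_band = c(-25, 15), overrides = NULL) {
  a <- db$ages
  key <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (identical(a$reservoir[i], "marine")) { key[i] <- "marine"; next }
    if (!is.null(overrides) && a$site[i] %in% names(overrides)) {
      key[i] <- overrides[[a$site[i]]]; next
    }
    lat <- a$latitude[i]
    if (is.na(lat))
      stop(sprintf("site '%s' has no coordinates and no curve override",
                   a$site[i]))
    key[i] <- if (lat < mixing_band[1]) "south"
              else if (lat > mixing_band[2]) "north"
              else "mixed"
  }
  a$curve_key <- key
  db$ages <- a
  db
}

# 95.4% hull of a pdf
hpd_hull <- function(pdf, level = 0.954) {
  h <- hpd_interval(pdf, level)
  c(max(h[, "older"]), min(h[, "younger"]))
}

#' Run the site-level modelling stage
#'
#' Builds and samples a model per site (rules 1-3) and extracts one calendar
#' PDF per cultural component: the phase Date-query posterior for modelled
#' sites, the plain calibrated PDF for single-measurement sites. Components
#' are tagged with their category labels and with whether their 95.4\% range
#' intersects the period of interest.
#'
#' @param db A curve-assigned \code{chron_db}.
#' @param curves Named list of \code{\link{cal_curve}}s with keys
#'   \code{south}, \code{north} (and \code{marine} if used).
#' @param settings A \code{\link{sampler_settings}}.
#' @param period \code{c(older, younger)} cal BP window defining membership
#'   of the analysis set (default the combined ACR-YD span 14500-11700).
#' @return A list of class \code{site_stage}: \code{components} (one element
#'   per cultural component: site, layer, categories, \code{pdf},
#'   \code{rule}, \code{included}), \code{manifest} (counts and skip/failure
#'   reasons).
#' @export
run_site_stage <- function(db, curves, settings = sampler_settings(),
                           period = c(14500, 11700)) {
  stopifnot(inherits(db, "chron_db"), "curve_key" %in% names(db$ages))
  sites <- unique(db$ages$site)
  components <- list()
  skips <- list()
  n_modelled <- 0L; n_passthrough <- 0L
  for (s in sites) {
    rows <- db$ages[db$ages$site == s, , drop = FALSE]
    sm <- try(site_model_from_record(rows, settings), silent = TRUE)
    if (inherits(sm, "try-error")) {
      skips[[length(skips) + 1L]] <- data.frame(
        site = s, reason = paste("model construction failed:",
                                 attr(sm, "condition")$message))
      next
    }
    if (sm$rule == 0L) {
      skips[[length(skips) + 1L]] <- data.frame(site = s, reason = sm$reason)
      next
    }
    meta <- rows[1, c("site", "country", "province", "latitude", "longitude",
                      "altitude_masl", "lithic")]
    if (sm$rule == 3L) {
      row <- sm$passthrough_row
      pdf <- try({
        if (row$age_type != "14c")
          normal_pdf(row$cra, row$error, settings$grid_resolution)
        else if (identical(row$curve_key, "mixed"))
          mix_calibration(row_determination(row), curves$north, curves$south,
                          resolution = settings$grid_resolution)
        else
          calibrate(row_determination(row), curves[[row$curve_key]],
                    resolution = settings$grid_resolution)
      }, silent = TRUE)
      if (inherits(pdf, "try-error")) {
        skips[[length(skips) + 1L]] <- data.frame(
          site = s, reason = "calibration failed for single measurement")
        next
      }
      n_passthrough <- n_passthrough + 1L
      components[[length(components) + 1L]] <- component_entry(
        meta, rows, sm$components$layer[1], pdf, 3L, period)
      next
    }
    tr <- try(sample_posterior(sm$model, curves, settings), silent = TRUE)
    if (inherits(tr, "try-error")) {
      skips[[length(skips) + 1L]] <- data.frame(
        site = s, reason = paste("sampling failed:",
                                 attr(tr, "condition")$message))
      next
    }
    n_modelled <- n_modelled + 1L
    for (k in seq_len(nrow(sm$components))) {
      pdf <- posterior_pdf(tr, sm$components$query[k])
      components[[length(components) + 1L]] <- component_entry(
        meta, rows, sm$components$layer[k], pdf, sm$rule, period)
    }
  }
  structure(list(
    components = components,
    manifest = list(n_sites = length(sites), n_modelled = n_modelled,
                    n_passthrough = n_passthrough,
                    n_components = length(components),
                    n_included = sum(vapply(components, function(c)
                      c$included, logical(1))),
                    skips = if (length(skips)) do.call(rbind, skips)
                            else data.frame(site = character(0),
                                            reason = character(0)))),
    class = "site_stage")
}

component_entry <- function(meta, rows, layer, pdf, rule, period) {
  hull <- hpd_hull(pdf)
  comp_rows <- rows[rows$layer == layer, , drop = FALSE]
  list(site = meta$site, country = meta$country, province = meta$province,
       latitude = meta$latitude, altitude = meta$altitude_masl,
       lithic = strsplit(meta$lithic, ";", fixed = TRUE)[[1]],
       megafauna = any(comp_rows$megafauna == "yes"),
       layer = layer, pdf = pdf, rule = rule,
       included = hull[1] >= period[2] && hull[2] <= period[1])
}

#' @export
print.site_stage <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<site_stage: %d sites -> %d components ",
                     "(%d in analysis window), %d skips>\n"),
              m$n_sites, m$n_components, m$n_included, nrow(m$skips)))
  invisible(x)
}

#' Estimate a category's start with a single uniform phase
#'
#' The component PDFs become the event likelihoods of one
#' Boundary--Phase--Boundary model; the start boundary's posterior dates the
#' onset of the category's activity (a terminus: the earliest dated evidence
#' is a minimum age for human presence). Intervals are rounded to 10 years
#' and overlap probabilities against the ACR and YD presets attached.
#'
#' @param pdfs List of >= 2 component \code{\link{cal_pdf}}s.
#' @param label Category name.
#' @param settings A \code{\link{sampler_settings}}.
#' @return A list of class \code{category_model_result}: \code{category},
#'   \code{n_components}, \code{start_pdf}, \code{end_pdf}, \code{ci_954},
#'   \code{ci_682} (rounded hulls), \code{hpd_954} (the possibly disjoint
#'   interval set), \code{acr}, \code{yd} (overlap triples), \code{low_n}.
#' @export
integrate_category <- function(pdfs, label, settings = sampler_settings()) {
  if (length(pdfs) < 2L)
    stop(sprintf("category '%s' has %d component(s); need >= 2 to model",
                 label, length(pdfs)))
  evs <- lapply(seq_along(pdfs), function(i)
    cal_event(sprintf("%s_%03d", label, i), pdf = pdfs[[i]]))
  model <- cal_sequence(label,
                        cal_boundary(sprintf("start %s", label)),
                        do.call(cal_phase, c(list(label), evs)),
                        cal_boundary(sprintf("end %s", label)))
  curves <- list()   # PDF likelihoods only; no curve registry needed
  tr <- sample_posterior(model, curves, settings)
  start_raw <- posterior_pdf(tr, sprintf("start %s", label))
  start_pdf <- smooth_pdf(start_raw)
  end_pdf <- smooth_pdf(posterior_pdf(tr, sprintf("end %s", label)))
  structure(list(category = label, n_components = length(pdfs),
                 start_pdf = start_pdf, end_pdf = end_pdf,
                 ci_954 = round_interval(hpd_hull(start_pdf, 0.954)),
                 ci_682 = round_interval(hpd_hull(start_pdf, 0.682)),
                 hpd_954 = round_interval(hpd_interval(start_pdf, 0.954)),
                 acr = overlap_probability(start_pdf,
                                           interval_definition("ACR")),
                 yd = overlap_probability(start_pdf,
                                          interval_definition("YD")),
                 low_n = length(pdfs) < 5L,
                 accept = tr$accept),
            class = "category_model_result")
}

#' @export
print.category_model_result <- function(x, ...) {
  cat(sprintf("%s (n = %d): %.0f-%.0f cal BP (95.4%%), %.0f-%.0f (68.2%%)%s\n",
              x$category, x$n_components, x$ci_954[1], x$ci_954[2],
              x$ci_682[1], x$ci_682[2],
              if (x$low_n) " [low n: widened uncertainty]" else ""))
  cat(sprintf("  P(before/within/after ACR) = %.2f/%.2f/%.2f; YD = %.2f/%.2f/%.2f\n",
              x$acr[1], x$acr[2], x$acr[3], x$yd[1], x$yd[2], x$yd[3]))
  invisible(x)
}

#' Start estimate for the southernmost components of a province
#'
#' Filters a site stage's components to those poleward of the cutoff
#' latitude (strictly south of it) and integrates them as one category.
#'
#' @param stage A \code{site_stage}.
#' @param cutoff Latitude in degrees (default -40; i.e. poleward of 40
#'   degrees south).
#' @param province Restrict to one province first (default
#'   \code{"Southern Andes"}); \code{NULL} for no restriction.
#' @param settings A \code{\link{sampler_settings}}.
#' @param only_included Use only components in the analysis window.
#' @return A \code{category_model_result}, or \code{NULL} (with a message)
#'   when the subset is empty or has a single component.
#' @export
southern_andes_subset <- function(stage, cutoff = -40,
                                  province = "Southern Andes",
                                  settings = sampler_settings(),
                                  only_included = TRUE) {
  comps <- Filter(function(c) {
    (!only_included || c$included) &&
      (is.null(province) || identical(c$province, province)) &&
      !is.na(c$latitude) && c$latitude < cutoff
  }, stage$components)
  if (length(comps) < 2L) {
    message(sprintf("poleward-%g subset: %d component(s); skipped",
                    abs(cutoff), length(comps)))
    return(NULL)
  }
  res <- integrate_category(lapply(comps, function(c) c$pdf),
                            sprintf("poleward %g S", abs(cutoff)), settings)
  res
}

#' Prior/settings sensitivity comparison
#'
#' Re-runs a category integration under named settings variants and
#' tabulates the shift of the start-boundary interval endpoints against the
#' base run.
#'
#' @param pdfs Component PDFs for the category.
#' @param label Category name.
#' @param base A \code{\link{sampler_settings}}.
#' @param variants Named list; each element is a list of settings fields to
#'   override (e.g. \code{list(span_prior = "naive")}).
#' @return A data.frame with one row per run (base first): CI endpoints and
#'   shifts in years.
#' @export
sensitivity_run <- function(pdfs, label, base = sampler_settings(),
                            variants = list()) {
  runs <- c(list(base = list()), variants)
  out <- NULL
  for (nm in names(runs)) {
    st <- base
    for (f in names(runs[[nm]])) st[[f]] <- runs[[nm]][[f]]
    r <- integrate_category(pdfs, label, st)
    out <- rbind(out, data.frame(
      variant = nm, older = r$ci_954[1], younger = r$ci_954[2],
      stringsAsFactors = FALSE))
  }
  out$shift_older <- out$older - out$older[1]
  out$shift_younger <- out$younger - out$younger[1]
  out
}

#' Database completeness statistics
#'
#' Tallies the reporting-quality picture of a determination-level database:
#' proportion of radiocarbon ages, the dominance of charcoal and how rarely
#' its species is identified, and carbon-to-nitrogen reporting for bone
#' collagen with the count inside the conventional acceptance window.
#'
#' @param db A \code{chron_db}.
#' @param cn_range Accepted C:N window for bone collagen (default 2.9-3.6).
#' @return A list of class \code{database_summary}.
#' @export
summarize_database <- function(db, cn_range = c(2.9, 3.6)) {
  a <- db$ages
  n <- nrow(a)
  pct <- function(x, of) if (of == 0) 0 else 100 * x / of
  is14 <- a$age_type == "14c"
  charcoal <- is14 & a$material == "charcoal"
  bone <- is14 & a$material == "bone"
  cn_rep <- bone & !is.na(a$cn_ratio)
  per_tab <- function(key) {
    if (n == 0) return(data.frame(key = character(0), sites = integer(0),
                                  ages = integer(0)))
    ag <- stats::aggregate(list(ages = seq_len(n)), by = list(key = a[[key]]),
                           FUN = length)
    st <- stats::aggregate(list(sites = a$site), by = list(key = a[[key]]),
                           FUN = function(s) length(unique(s)))
    merge(st, ag, by = "key")
  }
  structure(list(
    n_sites = length(unique(a$site)), n_ages = n,
    pct_radiocarbon = pct(sum(is14), n),
    pct_charcoal = pct(sum(charcoal), sum(is14)),
    pct_charcoal_species_unreported =
      pct(sum(charcoal & a$species == ""), sum(charcoal)),
    pct_cn_reported = pct(sum(cn_rep), sum(bone)),
    n_cn_reported = sum(cn_rep),
    n_cn_in_range = sum(cn_rep & a$cn_ratio >= cn_range[1] &
                          a$cn_ratio <= cn_range[2]),
    per_country = per_tab("country"),
    per_province = per_tab("province")),
    class = "database_summary")
}

#' @export
print.database_summary <- function(x, ...) {
  cat(sprintf("<database_summary: %d sites, %d ages (%.0f%% 14C)>\n",
              x$n_sites, x$n_ages, x$pct_radiocarbon))
  cat(sprintf("  charcoal %.0f%% of 14C (species unreported %.0f%%); C:N reported %.0f%% (%d, %d in range)\n",
              x$pct_charcoal, x$pct_charcoal_species_unreported,
              x$pct_cn_reported, x$n_cn_reported, x$n_cn_in_range))
  invisible(x)
}

#' Compare faunal last-appearance dates with an exploitation start
#'
#' A fixed-bandwidth KDE of the last-appearance dates (LADs) plus a
#' per-taxon gap distribution against the estimated start of human
#' exploitation. Deliberately descriptive: a LAD is a terminus post quem for
#' extinction while a start boundary is a modelled onset — fundamentally
#' different temporal markers, so no joint model is fitted.
#'
#' @param lads Named numeric vector of LADs (cal BP), or named list of
#'   \code{\link{cal_pdf}}s.
#' @param exploitation_start A \code{\link{cal_pdf}}.
#' @param resolution Grid resolution in years.
#' @return A list of class \code{lad_report}: \code{kde} (\code{cal_pdf}),
#'   \code{kde_mean}, \code{kde_median}, \code{gaps} (per-taxon
#'   \code{difference} results, positive = LAD older than the start),
#'   \code{descriptive_note}.
#' @export
lad_comparison <- function(lads, exploitation_start, resolution = 5) {
  if (length(lads) < 2L) stop("lad_comparison needs at least 2 LADs")
  vals <- if (is.list(lads)) vapply(lads, pdf_median, numeric(1))
          else as.numeric(lads)
  kde <- kde_plot(vals, resolution = resolution)
  pdf_of <- function(i) {
    if (is.list(lads)) lads[[i]]
    else normal_pdf(vals[i], resolution, resolution)  # near-point mass
  }
  gaps <- lapply(seq_along(vals), function(i)
    difference(pdf_of(i), exploitation_start))
  names(gaps) <- names(vals) %||% paste0("taxon", seq_along(vals))
  structure(list(kde = kde, kde_mean = pdf_mean(kde),
                 kde_median = pdf_median(kde), gaps = gaps,
                 descriptive_note = paste(
                   "LADs are unmodelled termini post quem for extinction;",
                   "the exploitation start is a modelled onset. The",
                   "comparison is descriptive, not causal.")),
            class = "lad_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full multi-site timeline analysis
#'
#' Curve assignment, site-level models, category-level start estimates
#' (province, lithic technology, high altitude, megafauna exploitation), the
#' poleward-of-40-degrees-south check, the pooled KDE/Sum summary of the
#' analysis set, and database-completeness statistics.
#'
#' @param db A \code{chron_db} (curves assigned here if absent).
#' @param curves Named curve registry (\code{south}, \code{north}, and
#'   \code{marine} when marine dates occur).
#' @param settings A \code{\link{sampler_settings}}.
#' @param altitude_cutoff High-altitude threshold in metres (default 2500,
#'   inclusive).
#' @param kde_settings Optional list overriding \code{\link{kde_model}}
#'   iteration counts.
#' @return A list of class \code{timeline_result}: \code{stage},
#'   \code{categories} (named list of \code{category_model_result}),
#'   \code{poleward40}, \code{summary_kde}, \code{summary_sum},
#'   \code{db_summary}, \code{manifest}.
#' @export
run_timeline <- function(db, curves, settings = sampler_settings(),
                         altitude_cutoff = 2500, kde_settings = list()) {
  if (!"curve_key" %in% names(db$ages)) db <- assign_curves(db)
  stage <- run_site_stage(db, curves, settings)
  comps <- Filter(function(c) c$included, stage$components)
  cat_pdfs <- function(sel) lapply(Filter(sel, comps), function(c) c$pdf)
  categories <- list()
  skipped <- character(0)
  add_cat <- function(categories, label, sel) {
    pdfs <- cat_pdfs(sel)
    if (length(pdfs) >= 2L)
      categories[[label]] <- integrate_category(pdfs, label, settings)
    else skipped <<- c(skipped, sprintf("%s (n = %d)", label, length(pdfs)))
    categories
  }
  for (p in unique(vapply(comps, function(c) c$province, character(1))))
    categories <- add_cat(categories, p,
                          function(c) identical(c$province, p))
  liths <- unique(unlist(lapply(comps, function(c) c$lithic)))
  for (l in setdiff(liths, c(NA, "")))
    categories <- add_cat(categories, paste0("lithic: ", l),
                          function(c) l %in% c$lithic)
  categories <- add_cat(categories, "high altitude",
                        function(c) !is.na(c$altitude) &&
                          c$altitude >= altitude_cutoff)
  categories <- add_cat(categories, "megafauna",
                        function(c) isTRUE(c$megafauna))
  poleward40 <- southern_andes_subset(stage, settings = settings)

  all_pdfs <- lapply(comps, function(c) c$pdf)
  kd_args <- utils::modifyList(list(event_pdfs = all_pdfs, n_burn = 200,
                                    n_iter = 1000, snapshot_every = 10,
                                    resolution = settings$grid_resolution),
                               kde_settings)
  summary_kde <- if (length(all_pdfs) >= 2L) do.call(kde_model, kd_args)
                 else NULL
  summary_sum <- if (length(all_pdfs) >= 1L) sum_distribution(all_pdfs)
                 else NULL
  structure(list(stage = stage, categories = categories,
                 poleward40 = poleward40,
                 summary_kde = summary_kde, summary_sum = summary_sum,
                 db_summary = summarize_database(db),
                 manifest = c(stage$manifest,
                              list(n_analysis_set = length(comps),
                                   categories_skipped = skipped))),
            class = "timeline_result")
}

#' @export
print.timeline_result <- function(x, ...) {
  cat(sprintf("<timeline_result: %d components (%d in analysis set), %d category models>\n",
              x$manifest$n_components, x$manifest$n_analysis_set,
              length(x$categories)))
  for (r in x$categories) print(r)
  if (!is.null(x$summary_kde))
    cat(sprintf("summary KDE: mean %.0f, median %.0f cal BP\n",
                x$summary_kde$mean, x$summary_kde$median))
  invisible(x)
}
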