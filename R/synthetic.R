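# Synthetic calibration curves and archaeo-chronometric databases with known
# ground truth, so every pipeline stage is testable without external files.

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic calibration curve
#'
#' A monotone-trend baseline \code{mu(theta) = theta} plus a smoothed (AR(1))
#' random walk of stationary sd \code{wiggle_sd}, with per-knot curve errors
#' near \code{error_level}. Deterministic given \code{seed}.
#'
#' @param range \code{c(old, young)} cal BP limits, old > young.
#' @param knot_step Knot spacing in years.
#' @param wiggle_sd Stationary sd of the wiggle process (14C yr); 0 gives the
#'   identity curve exactly.
#' @param error_level Typical 1-sigma curve error (14C yr).
#' @param seed Integer seed, or \code{NULL} to use the current RNG stream.
#' @param label,hemisphere Passed to \code{\link{cal_curve}}.
#' @return A \code{\link{cal_curve}}.
#' @export
gen_calibration_curve <- function(range = c(25000, 8000), knot_step = 20,
                                  wiggle_sd = 15, error_level = 15,
                                  seed = NULL, label = "synthetic",
                                  hemisphere = "synthetic") {
  if (length(range) != 2L || range[1] <= range[2])
    stop("range must be c(old, young) with old > young")
  if (knot_step <= 0 || wiggle_sd < 0 || error_level <= 0)
    stop("knot_step and error_level must be positive, wiggle_sd >= 0")
  with_seed(seed, {
    theta <- seq(range[2], range[1], by = knot_step)
    n <- length(theta)
    rho <- 0.95
    w <- numeric(n)
    if (wiggle_sd > 0) {
      innov_sd <- wiggle_sd * sqrt(1 - rho^2)
      w[1] <- rnorm(1, 0, wiggle_sd)
      for (k in 2:n) w[k] <- rho * w[k - 1] + rnorm(1, 0, innov_sd)
    }
    sigma <- error_level * runif(n, 0.8, 1.2)
    cal_curve(theta, theta + w, sigma, label = label, hemisphere = hemisphere)
  })
}

#' Generate one synthetic site
#'
#' Event ages are drawn i.i.d. uniform within each layer's true boundary
#' pair (the uniform-phase assumption); CRAs are the curve mean at the true
#' age plus measurement noise; a fraction of events is further contaminated
#' by a calendar-scale shift (the outliers a fitted model should
#' down-weight). Optionally emits replicate measurements on a shared sample.
#'
#' @param true_layers List of \code{c(a, b, n_events)} per layer, oldest
#'   first: boundaries a > b in cal BP, layers non-overlapping.
#' @param curve A \code{\link{cal_curve}} to push ages through.
#' @param lab_error Measurement 1-sigma in 14C yr.
#' @param outlier_rate Probability an event's CRA is contaminated.
#' @param outlier_shift_sd Sd (yr) of the contamination shift.
#' @param replicate_rate Probability an event gets a duplicate measurement.
#' @param site Site name used in lab ids.
#' @param seed Integer seed or \code{NULL}.
#' @return A list with \code{ages} (a determination-level data.frame in the
#'   database schema) and \code{truth} (one row per event: true age, outlier
#'   status and shift, layer boundaries).
#' @export
gen_site <- function(true_layers, curve, lab_error = 40, outlier_rate = 0,
                     outlier_shift_sd = 800, replicate_rate = 0,
                     site = "site", seed = NULL) {
  for (ly in true_layers)
    if (length(ly) < 3 || ly[1] <= ly[2]) stop("each layer needs a > b and n")
  if (length(true_layers) > 1)
    for (k in 2:length(true_layers))
      if (true_layers[[k]][1] > true_layers[[k - 1]][2])
        stop("layers must be ordered oldest first and non-overlapping")
  with_seed(seed, {
    ages <- list(); truth <- list()
    idx <- 0L
    for (li in seq_along(true_layers)) {
      ly <- true_layers[[li]]
      for (e in seq_len(ly[3])) {
        idx <- idx + 1L
        age <- runif(1, ly[2], ly[1])
        lk <- curve_lookup(curve, age)
        is_out <- runif(1) < outlier_rate
        shift <- if (is_out) rnorm(1, 0, outlier_shift_sd) else 0
        mu_obs <- if (is_out) {
          shifted <- min(max(age + shift, min(curve$theta)), max(curve$theta))
          curve_lookup(curve, shifted)$mu
        } else lk$mu
        n_meas <- 1L + (runif(1) < replicate_rate)
        for (r in seq_len(n_meas)) {
          cra <- rnorm(1, mu_obs, sqrt(lab_error^2 + lk$sigma^2))
          ages[[length(ages) + 1L]] <- data.frame(
            site = site, layer = sprintf("%s_L%d", site, li),
            layer_order = li,
            sample_id = sprintf("%s_S%d", site, idx),
            lab_id = sprintf("%s-%d%s", site, idx,
                             if (n_meas > 1) letters[r] else ""),
            age_type = "14c", cra = round(cra), error = lab_error,
            stringsAsFactors = FALSE)
        }
        truth[[idx]] <- data.frame(
          site = site, layer = sprintf("%s_L%d", site, li),
          sample_id = sprintf("%s_S%d", site, idx),
          true_age = age, outlier = is_out, shift = shift,
          layer_start = ly[1], layer_end = ly[2],
          stringsAsFactors = FALSE)
      }
    }
    list(ages = do.call(rbind, ages), truth = do.call(rbind, truth))
  })
}

provinces_table <- function() {
  data.frame(
    province = c("Southern Andes", "Central Andes", "Northern Andes",
                 "Patagonian Plateau", "Paraguay-Parana Lowlands",
                 "Brazilian Highlands", "Amazonian Lowlands",
                 "Orinoco Lowlands", "Guiana Highlands"),
    prop = c(0.18, 0.15, 0.08, 0.15, 0.12, 0.18, 0.06, 0.05, 0.03),
    country = c("Chile", "Peru", "Colombia", "Argentina", "Uruguay",
                "Brazil", "Brazil", "Venezuela", "Guyana"),
    lat_lo = c(-45, -17, -4, -50, -34, -25, -10, 4, 2),
    lat_hi = c(-28, -8, 8, -38, -25, -12, 0, 9, 6),
    lon_lo = c(-72, -76, -78, -70, -59, -52, -68, -68, -61),
    lon_hi = c(-68, -68, -72, -66, -55, -42, -55, -63, -58),
    andes = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

lithic_traditions <- function() {
  c("Fishtail", "Paijan", "Tigre", "El Jobo", "Huentelauquen", "Itaparica",
    "Pay Paso", "Abriense", "Tequendamiense", "uniface/biface",
    "projectile point")
}

#' Generate a synthetic archaeo-chronometric database
#'
#' Emulates the shape of a continental compilation: ~150 sites, >1700 ages
#' (>90\% radiocarbon), charcoal dominating the material mix with species
#' mostly unreported, and carbon-to-nitrogen ratios reported for only a
#' small fraction of bone dates. Ground truth (true event ages, outlier
#' shifts, true layer boundaries) is returned separately so recovery can be
#' tested without the pipeline ever seeing it.
#'
#' @param n_sites Number of sites (default 150).
#' @param curve A \code{\link{cal_curve}} used to produce CRAs (one curve
#'   suffices for generation; calibration-time assignment is a pipeline
#'   concern).
#' @param outlier_rate Contamination probability per event.
#' @param missingness Named list of reporting gaps:
#'   \code{charcoal_species} (fraction of charcoal dates without species,
#'   default 0.94), \code{cn_ratio} (fraction of bone dates without C:N,
#'   default 0.89), \code{pretreatment}, \code{d13c}.
#' @param stratigraphy_known_rate Fraction of multi-layer sites whose layer
#'   order is recorded (the rest fall to single-phase modelling).
#' @param seed Integer seed or \code{NULL}.
#' @return A list with \code{ages} (determination-level data.frame in the
#'   loader schema) and \code{truth} (event-level truth table).
#' @export
gen_database <- function(n_sites = 150, curve = NULL, outlier_rate = 0.05,
                         missingness = list(), stratigraphy_known_rate = 0.6,
                         seed = NULL) {
  miss <- utils::modifyList(list(charcoal_species = 0.94, cn_ratio = 0.89,
                                 pretreatment = 0.7, d13c = 0.6), missingness)
  if (is.null(curve))
    curve <- gen_calibration_curve(c(25000, 8000), 20, 15, 15, seed = 1234)
  pt <- provinces_table()
  liths <- lithic_traditions()
  with_seed(seed, {
    all_ages <- list(); all_truth <- list()
    prov_idx <- sample.int(nrow(pt), n_sites, replace = TRUE, prob = pt$prop)
    # earliest occupation tendencies per province (cal BP), oldest in the
    # south/west; the sd spreads site chronologies well beyond the ACR-YD
    # window so a realistic fraction of components falls outside it
    start_centre <- c(15600, 14200, 13800, 14100, 13500, 13600, 12500,
                      12300, 12200)
    mf_budget <- max(1L, round(21 * n_sites / 150))
    for (s in seq_len(n_sites)) {
      p <- prov_idx[s]
      site_name <- sprintf("SYN%03d", s)
      lat <- runif(1, pt$lat_lo[p], pt$lat_hi[p])
      lon <- runif(1, pt$lon_lo[p], pt$lon_hi[p])
      alt <- if (pt$andes[p]) runif(1, 400, 4400) else runif(1, 0, 1200)
      n_layers <- sample(1:5, 1, prob = c(0.30, 0.30, 0.20, 0.12, 0.08))
      site_start <- rnorm(1, start_centre[p], 2000)
      site_start <- min(max(site_start, 9500), 22000)
      span <- min(runif(1, 400, 2800), site_start - 8200)  # stay on the curve
      cuts <- sort(runif(n_layers - 1, 0, span))
      edges <- site_start - c(0, cuts, span)
      layers <- lapply(seq_len(n_layers), function(k)
        c(edges[k], edges[k + 1], 2 + stats::rpois(1, 3.2)))
      gs <- gen_site(layers, curve, lab_error = sample(30:80, 1),
                     outlier_rate = outlier_rate, outlier_shift_sd = 900,
                     replicate_rate = 0.04, site = site_name)
      a <- gs$ages
      # site metadata
      a$country <- pt$country[p]; a$province <- pt$province[p]
      a$latitude <- round(lat, 3); a$longitude <- round(lon, 3)
      a$altitude_masl <- round(alt)
      n_lith <- 1 + (runif(1) < 0.05)
      a$lithic <- paste(sample(liths, n_lith), collapse = ";")
      # megafauna exploitation on the oldest layer of a few sites whose
      # oldest occupation can enter the analysis window
      mf_eligible <- edges[1] >= 11700 && edges[2] <= 15500
      mf <- mf_eligible && mf_budget > 0 && runif(1) < 0.35
      if (mf) mf_budget <- mf_budget - 1L
      a$megafauna <- ifelse(mf & a$layer == a$layer[1], "yes", "no")
      # stratigraphic knowledge
      if (n_layers > 1 && runif(1) > stratigraphy_known_rate)
        a$layer_order <- NA_integer_
      # materials and quality metadata
      n <- nrow(a)
      a$material <- sample(c("charcoal", "bone", "shell", "wood", "seed"),
                           n, replace = TRUE,
                           prob = c(0.55, 0.25, 0.03, 0.12, 0.05))
      non14c <- runif(n) < 0.07
      a$age_type[non14c] <- "calendar"
      a$material[non14c] <- "sediment"
      a$species <- ifelse(
        a$material == "charcoal" & runif(n) >= miss$charcoal_species,
        "Prosopis sp.", "")
      a$pretreatment <- ifelse(runif(n) >= miss$pretreatment, "ABA", "")
      a$d13c <- ifelse(runif(n) >= miss$d13c, round(rnorm(n, -24, 2), 1),
                       NA_real_)
      a$cn_ratio <- ifelse(a$material == "bone" & runif(n) >= miss$cn_ratio,
                           round(runif(n, 2.9, 3.6), 2), NA_real_)
      a$reservoir <- ifelse(a$material == "shell", "marine", "atmospheric")
      a$delta_r <- ifelse(a$reservoir == "marine", round(rnorm(n, 150, 40)),
                          NA_real_)
      a$delta_r_sd <- ifelse(a$reservoir == "marine", 30, NA_real_)
      # replicate measurements describe one physical sample: make their
      # sample-level metadata identical to the first row of the sample
      dup <- duplicated(a$sample_id)
      if (any(dup)) {
        first <- match(a$sample_id, a$sample_id)
        for (col in c("age_type", "material", "species", "pretreatment",
                      "d13c", "cn_ratio", "reservoir", "delta_r",
                      "delta_r_sd"))
          a[[col]][dup] <- a[[col]][first[dup]]
      }
      gs$truth$province <- pt$province[p]
      gs$truth$megafauna <- mf & gs$truth$layer == gs$truth$layer[1]
      all_ages[[s]] <- a
      all_truth[[s]] <- gs$truth
    }
    ages <- do.call(rbind, all_ages)
    rownames(ages) <- NULL
    cols <- c("site", "country", "province", "latitude", "longitude",
              "altitude_masl", "lithic", "megafauna", "layer", "layer_order",
              "sample_id", "lab_id", "age_type", "cra", "error", "material",
              "species", "pretreatment", "d13c", "cn_ratio", "reservoir",
              "delta_r", "delta_r_sd")
    list(ages = ages[, cols], truth = do.call(rbind, all_truth))
  })
}

#' Write a synthetic database to CSV (byte-stable given a seed)
#'
#' @param db Result of \code{\link{gen_database}}.
#' @param dir Output directory.
#' @param stem File stem; writes \code{<stem>_ages.csv} and
#'   \code{<stem>_truth.csv} (truth kept separate so the pipeline cannot see
#'   it).
#' @return Invisibly, the paths written.
#' @export
write_database <- function(db, dir, stem = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pa <- file.path(dir, paste0(stem, "_ages.csv"))
  pt <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(db$ages, pa, row.names = FALSE, na = "")
  utils::write.csv(db$truth, pt, row.names = FALSE, na = "")
  invisible(c(pa, pt))
}
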