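# Automatic site-model construction. One site's determination-level rows are
# turned into (1) a multi-phase sequence when dated stratigraphic levels have
# a known order, (2) a single uniform phase when >= 2 dates lack usable
# stratigraphy, or (3) a plain calibrated PDF when a single cultural
# measurement stands alone.

row_determination <- function(row) {
  if (identical(row$curve_key, "mixed")) {
    determination(row$cra, row$error, lab_id = row$lab_id,
                  material = row$material, reservoir = "mixed_hemispheric",
                  curve_key = c("north", "south"))
  } else if (identical(row$reservoir, "marine")) {
    determination(row$cra, row$error, lab_id = row$lab_id,
                  material = row$material, reservoir = "marine",
                  delta_r = c(row$delta_r, row$delta_r_sd),
                  curve_key = "marine")
  } else {
    determination(row$cra, row$error, lab_id = row$lab_id,
                  material = row$material, curve_key = row$curve_key)
  }
}

# Pool replicate measurements (shared sample_id) before modelling, per the
# convention that measurement-scale (SSimple) outlier handling applies only
# to replicates; the pooled age then carries the usual consistency check.
pool_replicates <- function(rows) {
  rows$.group <- ifelse(is.na(rows$sample_id) | rows$sample_id == "",
                        paste0(".row", seq_len(nrow(rows))), rows$sample_id)
  pooled <- list(); combines <- list()
  for (g in unique(rows$.group)) {
    sub <- rows[rows$.group == g, , drop = FALSE]
    if (nrow(sub) == 1L || any(sub$age_type != "14c")) {
      pooled[[length(pooled) + 1L]] <- sub
    } else {
      dets <- lapply(seq_len(nrow(sub)), function(i)
        row_determination(sub[i, ]))
      rc <- r_combine(dets)
      one <- sub[1, , drop = FALSE]
      one$cra <- rc$cra; one$error <- rc$sigma
      one$lab_id <- rc$det$lab_id
      pooled[[length(pooled) + 1L]] <- one
      combines[[length(combines) + 1L]] <- rc
    }
  }
  out <- do.call(rbind, pooled)
  out$.group <- NULL
  list(rows = out, combines = combines)
}

site_event <- function(row, outlier_prior, resolution) {
  label <- row$lab_id
  if (row$age_type == "14c") {
    cal_event(label, det = row_determination(row),
              outlier = outlier_spec("general", outlier_prior))
  } else {
    # already on the calendar scale (OSL/U-series etc.): normal likelihood
    cal_event(label, pdf = normal_pdf(row$cra, row$error, resolution))
  }
}

#' Build a chronological model for one site
#'
#' Applies the three construction rules to the determination-level rows of a
#' single site (curve assignments already present):
#' rule 1 — dated stratigraphic levels with a known total order become a
#' sequence of boundary-delimited uniform phases, modelling the site in its
#' entirety (layers outside the period of interest included, since they
#' constrain their neighbours), with a General outlier attached to every
#' radiocarbon event and replicates pooled first;
#' rule 2 — two or more dates without usable stratigraphy become a single
#' uniform phase; rule 3 — one cultural measurement is passed through as its
#' calibrated PDF, unmodelled. Sediment/geological ages participate as
#' constraints but never count as cultural components.
#'
#' @param rows Data.frame of one site's rows (loader schema plus
#'   \code{curve_key}).
#' @param settings A \code{\link{sampler_settings}} (outlier prior and grid
#'   resolution are read from it).
#' @return A list of class \code{site_model}: \code{rule} (1, 2, 3 or 0 when
#'   skipped), \code{model} (a \code{chron_node} or NULL), \code{components}
#'   (data.frame mapping cultural layers to Date-query labels),
#'   \code{passthrough_row} (rule 3), \code{combines} (replicate poolings),
#'   \code{reason} (when skipped).
#' @export
site_model_from_record <- function(rows, settings = sampler_settings()) {
  stopifnot(length(unique(rows$site)) == 1L)
  site <- rows$site[1]
  pooled <- pool_replicates(rows)
  rows <- pooled$rows
  cultural <- rows[rows$material != "sediment", , drop = FALSE]
  if (nrow(cultural) == 0L)
    return(structure(list(rule = 0L, model = NULL, components = NULL,
                          combines = pooled$combines,
                          reason = "no non-sediment determinations"),
                     class = "site_model"))

  res <- settings$grid_resolution
  q <- settings$outlier_prior
  layers <- unique(rows$layer)
  dated_layers <- unique(cultural$layer)
  order_known <- !anyNA(rows$layer_order) &&
    length(unique(rows$layer_order[rows$layer %in% dated_layers])) >= 2L

  if (order_known && length(dated_layers) >= 2L) {
    ord <- order(vapply(layers, function(l)
      min(rows$layer_order[rows$layer == l]), numeric(1)))
    layers <- layers[ord]
    parts <- list(cal_boundary(sprintf("start %s", site)))
    comp <- list()
    for (k in seq_along(layers)) {
      l <- layers[k]
      sub <- rows[rows$layer == l, , drop = FALSE]
      evs <- lapply(seq_len(nrow(sub)), function(i)
        site_event(sub[i, ], q, res))
      parts[[length(parts) + 1L]] <- do.call(cal_phase, c(list(l), evs))
      if (l %in% dated_layers)
        comp[[length(comp) + 1L]] <- data.frame(
          layer = l, query = paste0("date:", l), stringsAsFactors = FALSE)
      parts[[length(parts) + 1L]] <- cal_boundary(
        if (k < length(layers)) sprintf("%s/%s", l, layers[k + 1])
        else sprintf("end %s", site))
    }
    model <- do.call(cal_sequence, c(list(site), parts))
    return(structure(list(rule = 1L, model = model,
                          components = do.call(rbind, comp),
                          combines = pooled$combines, reason = NULL),
                     class = "site_model"))
  }

  if (nrow(cultural) >= 2L) {
    # single uniform phase; its implicit Date query (an undated draw between
    # the boundaries) represents every cultural layer of the site
    evs <- lapply(seq_len(nrow(rows)), function(i) site_event(rows[i, ], q, res))
    ph <- do.call(cal_phase, c(list(site), evs))
    model <- cal_sequence(site, cal_boundary(sprintf("start %s", site)), ph,
                          cal_boundary(sprintf("end %s", site)))
    comp <- data.frame(layer = dated_layers,
                       query = paste0("date:", site),
                       stringsAsFactors = FALSE)
    return(structure(list(rule = 2L, model = model, components = comp,
                          combines = pooled$combines, reason = NULL),
                     class = "site_model"))
  }

  structure(list(rule = 3L, model = NULL,
                 components = data.frame(layer = cultural$layer[1],
                                         query = NA_character_,
                                         stringsAsFactors = FALSE),
                 passthrough_row = cultural[1, , drop = FALSE],
                 combines = pooled$combines, reason = NULL),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("<site_model rule %d: %s>\n", x$rule,
              if (x$rule == 0L) x$reason else
                sprintf("%d component(s)", nrow(x$components))))
  invisible(x)
}
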