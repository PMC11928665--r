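# Chronological model trees: Sequence / Phase / Boundary / Event nodes with
# outlier attachments, mirroring the usual CQL concepts without being
# byte-compatible with any particular platform.

#' Model tree nodes
#'
#' Chronological models are trees of nodes. A \code{cal_sequence} orders its
#' children oldest to youngest; a \code{cal_phase} groups unordered events;
#' \code{cal_boundary} marks the start or end of a phase group; a
#' \code{cal_event} is one dated (or undated, queried) occurrence. In a valid
#' model every phase is delimited by a preceding and a following boundary
#' within its parent sequence (the Boundary--Boundary pair that defines a
#' uniform phase: all events equally likely between the boundaries).
#'
#' @param label Node label (used to name posterior parameters).
#' @param ... Child nodes, oldest first (sequence/phase only).
#' @return A \code{chron_node}.
#' @name model_nodes
NULL

chron_node <- function(kind, label, children = NULL, ...) {
  structure(c(list(kind = kind, label = label, children = children),
              list(...)), class = "chron_node")
}

#' @rdname model_nodes
#' @export
cal_sequence <- function(label, ...) {
  ch <- flatten_nodes(list(...))
  chron_node("sequence", label, children = ch)
}

#' @rdname model_nodes
#' @export
cal_phase <- function(label, ...) {
  ch <- flatten_nodes(list(...))
  chron_node("phase", label, children = ch)
}

#' @rdname model_nodes
#' @export
cal_boundary <- function(label) chron_node("boundary", label)

#' @rdname model_nodes
#' @param det A \code{\link{determination}} giving the event's likelihood, or
#'   \code{NULL}.
#' @param pdf A \code{\link{cal_pdf}} used directly as the event's likelihood
#'   (site-level posteriors entering category models), or \code{NULL}.
#' @param outlier An \code{\link{outlier_spec}} or \code{NULL}. Events with
#'   neither \code{det} nor \code{pdf} are undated queries.
#' @export
cal_event <- function(label, det = NULL, pdf = NULL, outlier = NULL) {
  if (!is.null(det) && !is.null(pdf))
    stop("an event carries exactly one likelihood source")
  if (!is.null(det) && !inherits(det, "determination"))
    stop("det must be a determination")
  if (!is.null(pdf) && !inherits(pdf, "cal_pdf"))
    stop("pdf must be a cal_pdf")
  chron_node("event", label, det = det, pdf = pdf, outlier = outlier)
}

flatten_nodes <- function(x) {
  out <- list()
  for (el in x) {
    if (inherits(el, "chron_node")) out[[length(out) + 1L]] <- el
    else if (is.list(el)) out <- c(out, flatten_nodes(el))
    else stop("model children must be chron_node objects")
  }
  out
}

#' Outlier model attachment
#'
#' Describes how a dated event may be down-weighted. The \code{general}
#' preset shifts the event on the calendar scale by t-distributed noise with
#' 5 degrees of freedom and a scale of 10^u years, u ~ U(0, 4); the
#' \code{ssimple} preset (used for replicate measurements) shifts the
#' measurement itself by standard-normal noise in units of its quoted sigma.
#'
#' @param preset \code{"general"} or \code{"ssimple"}.
#' @param prior_prob Prior outlier probability in (0,1); default 0.05.
#' @return An \code{outlier_spec}.
#' @export
outlier_spec <- function(preset = c("general", "ssimple"), prior_prob = 0.05) {
  preset <- match.arg(preset)
  if (!is.finite(prior_prob) || prior_prob <= 0 || prior_prob >= 1)
    stop("prior_prob must be in (0, 1)")
  structure(list(preset = preset, prior_prob = prior_prob,
                 shift_distribution = if (preset == "general")
                   "student_t(df=5)" else "normal(0,1)",
                 scale_exponent_prior = if (preset == "general") c(0, 4) else NULL),
            class = "outlier_spec")
}

#' Pool replicate determinations with a consistency check
#'
#' Inverse-variance weighted combination of replicate radiocarbon ages on
#' the same sample, with the chi-square consistency statistic
#' \eqn{T = \sum_i (x_i - \bar{x})^2 / \sigma_i^2} compared against the upper
#' 5\% quantile of chi-square with n-1 degrees of freedom.
#'
#' @param dets List of \code{\link{determination}}s (>= 2) sharing a curve
#'   assignment.
#' @return A list of class \code{combined_determination} with fields
#'   \code{det} (the pooled \code{determination}), \code{cra}, \code{sigma},
#'   \code{t_stat}, \code{df}, \code{passed}.
#' @export
r_combine <- function(dets) {
  if (length(dets) < 2L) stop("r_combine needs at least 2 determinations")
  if (!all(vapply(dets, inherits, logical(1), "determination")))
    stop("r_combine takes a list of determinations")
  res <- unique(vapply(dets, function(d) d$reservoir, character(1)))
  keys <- unique(vapply(dets, function(d)
    paste(d$curve_key, collapse = "+"), character(1)))
  if (length(res) > 1L || length(keys) > 1L)
    stop("r_combine requires a common curve/reservoir assignment")
  x <- vapply(dets, function(d) d$cra, numeric(1))
  s <- vapply(dets, function(d) d$sigma, numeric(1))
  w <- 1 / s^2
  cra <- sum(x * w) / sum(w)
  sigma <- 1 / sqrt(sum(w))
  t_stat <- sum((x - cra)^2 / s^2)
  df <- length(x) - 1L
  passed <- t_stat <= stats::qchisq(0.95, df)
  pooled <- determination(cra, sigma,
                          lab_id = paste(vapply(dets, function(d) d$lab_id,
                                                character(1)), collapse = "+"),
                          material = dets[[1]]$material,
                          reservoir = res, delta_r = dets[[1]]$delta_r,
                          curve_key = dets[[1]]$curve_key)
  structure(list(det = pooled, cra = cra, sigma = sigma, t_stat = t_stat,
                 df = df, passed = passed),
            class = "combined_determination")
}

#' @export
print.combined_determination <- function(x, ...) {
  cat(sprintf("<r_combine: %.1f +/- %.2f 14C BP, T = %.2f (df %d, %s)>\n",
              x$cra, x$sigma, x$t_stat, x$df,
              if (x$passed) "consistent at 5%" else "FAILS 5% test"))
  invisible(x)
}

#' Validate a chronological model tree
#'
#' Checks the structural rules a sampler relies on: phases are delimited by a
#' preceding and following boundary within their parent sequence, sequences
#' and phases are non-empty, event labels are unique, and events carry at
#' most one likelihood source. Violations are returned as data, not thrown.
#'
#' @param root A \code{chron_node}.
#' @return Character vector of violations; empty if the model is valid.
#' @export
validate_model <- function(root) {
  v <- character(0)
  seen_events <- character(0)
  walk <- function(node, parent_kind) {
    if (!inherits(node, "chron_node")) {
      v <<- c(v, "non-node object in model tree"); return(invisible())
    }
    if (node$kind %in% c("sequence", "phase")) {
      if (length(node$children) == 0L)
        v <<- c(v, sprintf("%s '%s' is empty", node$kind, node$label))
      if (node$kind == "sequence") {
        kinds <- vapply(node$children, function(c) c$kind, character(1))
        for (i in which(kinds == "phase")) {
          ok_before <- i > 1L && kinds[i - 1L] == "boundary"
          ok_after <- i < length(kinds) && kinds[i + 1L] == "boundary"
          if (!ok_before || !ok_after)
            v <<- c(v, sprintf(
              "phase '%s' is not delimited by a boundary pair",
              node$children[[i]]$label))
        }
      } else {
        for (c in node$children) if (c$kind %in% c("phase", "boundary"))
          v <<- c(v, sprintf("%s '%s' nested directly inside phase '%s'",
                             c$kind, c$label, node$label))
      }
      for (c in node$children) walk(c, node$kind)
    } else if (node$kind == "event") {
      if (node$label %in% seen_events)
        v <<- c(v, sprintf("event '%s' appears twice", node$label))
      seen_events <<- c(seen_events, node$label)
    } else if (node$kind == "boundary") {
      if (parent_kind != "sequence")
        v <<- c(v, sprintf("boundary '%s' outside a sequence", node$label))
    }
    invisible()
  }
  if (inherits(root, "chron_node") && root$kind == "phase") {
    v <- c(v, sprintf("phase '%s' has no enclosing boundaries", root$label))
    for (c in root$children) walk(c, "phase")
    return(v)
  }
  walk(root, "root")
  v
}

#' Serialise / parse a model tree
#'
#' A small indented text grammar, one-to-one with the in-memory tree:
#' \preformatted{
#' Sequence("site") {
#'   Boundary("start")
#'   Phase("layer 1") {
#'     R_Date("AA-1", 10000, 50) { Outlier("general", 0.05) }
#'     Date("query")
#'   }
#'   Boundary("end")
#' }
#' }
#' Events with a \code{cal_pdf} likelihood serialise as
#' \code{Pdf_Date("label", <n cells>)} (the numeric table is not embedded).
#'
#' @param node A \code{chron_node}.
#' @param indent Starting indent level (internal recursion).
#' @return A single character string.
#' @export
format_model <- function(node, indent = 0) {
  pad <- strrep("  ", indent)
  if (node$kind == "boundary")
    return(sprintf('%sBoundary("%s")', pad, node$label))
  if (node$kind == "event") {
    inner <- if (!is.null(node$outlier))
      sprintf(' { Outlier("%s", %g) }', node$outlier$preset,
              node$outlier$prior_prob) else ""
    if (!is.null(node$det))
      return(sprintf('%sR_Date("%s", %g, %g)%s', pad, node$label,
                     node$det$cra, node$det$sigma, inner))
    if (!is.null(node$pdf))
      return(sprintf('%sPdf_Date("%s", %d)%s', pad, node$label,
                     length(node$pdf$grid), inner))
    return(sprintf('%sDate("%s")%s', pad, node$label, inner))
  }
  kw <- if (node$kind == "sequence") "Sequence" else "Phase"
  body <- vapply(node$children, format_model, character(1), indent = indent + 1)
  sprintf('%s%s("%s") {\n%s\n%s}', pad, kw, node$label,
          paste(body, collapse = "\n"), pad)
}

#' @export
print.chron_node <- function(x, ...) {
  cat(format_model(x), "\n")
  invisible(x)
}
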