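#' TD reference ranges: per-metabolite min-max over the reference group
#'
#' The screening system defines "normal" per metabolite as the full observed
#' range (0%-100%, i.e. minimum to maximum) of creatinine-normalized values
#' in the typically developing (TD) group. Censored TD values participate as
#' imputed under the normalization's LOD policy; missing values are dropped.
#'
#' @param norm An `mdm_norm`.
#' @param groups Group labels in row order; defaults to the labels stored in
#'   `norm`.
#' @param panel Panel; defaults to the panel stored in `norm`.
#' @return Object of class `mdm_ranges`: data frame with `metabolite_id`,
#'   `lower`, `upper`, `n_reference`, plus attributes `panel_hash` and
#'   `lod_policy`.
#' @export
build_reference_ranges <- function(norm, groups = NULL, panel = NULL) {
  stopifnot(inherits(norm, "mdm_norm"))
  if (is.null(groups)) groups <- norm$participants$group
  if (is.null(panel)) panel <- norm$panel
  stopifnot(length(groups) == nrow(norm$values))
  td <- norm$values[groups == "TD", , drop = FALSE]
  if (nrow(td) < 2) stop("need at least 2 TD participants", call. = FALSE)

  n_ref <- colSums(!is.na(td))
  empty <- colnames(td)[n_ref == 0]
  if (length(empty) > 0) {
    stop("all TD values missing for metabolite(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(n_ref < 2)) {
    stop("fewer than 2 non-missing TD values for metabolite(s): ",
         paste(colnames(td)[n_ref < 2], collapse = ", "), call. = FALSE)
  }
  ranges <- data.frame(
    metabolite_id = colnames(td),
    lower = apply(td, 2, min, na.rm = TRUE),
    upper = apply(td, 2, max, na.rm = TRUE),
    n_reference = as.integer(n_ref),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(ranges, class = c("mdm_ranges", "data.frame"),
            panel_hash = panel_hash(panel), lod_policy = norm$lod_policy)
}

#' Serialize / load reference ranges as JSON
#'
#' Frozen ranges are the deployment artifact of the screening system: built
#' once from a reference cohort, stamped with the panel hash, and applied to
#' new samples.
#'
#' @param ranges An `mdm_ranges`.
#' @param path JSON path.
#' @return `write_ranges` returns `path` invisibly; `read_ranges` returns an
#'   `mdm_ranges`.
#' @export
write_ranges <- function(ranges, path) {
  stopifnot(inherits(ranges, "mdm_ranges"))
  payload <- list(
    panel_hash = attr(ranges, "panel_hash"),
    lod_policy = attr(ranges, "lod_policy"),
    ranges = stats::setNames(
      lapply(seq_len(nrow(ranges)), function(i) {
        list(lower = ranges$lower[i], upper = ranges$upper[i],
             n_reference = ranges$n_reference[i])
      }),
      ranges$metabolite_id)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(path) {
  payload <- jsonlite::read_json(path)
  r <- payload$ranges
  out <- data.frame(
    metabolite_id = names(r),
    lower = vapply(r, function(e) as.numeric(e$lower), numeric(1)),
    upper = vapply(r, function(e) as.numeric(e$upper), numeric(1)),
    n_reference = vapply(r, function(e) as.integer(e$n_reference), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("mdm_ranges", "data.frame"),
            panel_hash = payload$panel_hash, lod_policy = payload$lod_policy)
}

#' Strict reference-range exceedance indicators
#'
#' For a high-direction metabolite the indicator is 1 when the participant's
#' creatinine-normalized value is strictly above the TD maximum; a value
#' exactly at the maximum scores 0 ("above any TD child" is read strictly;
#' ties are measure-zero for continuous data). Low-direction markers score 1
#' strictly below the TD minimum. Missing values score 0 and are counted in
#' a notice.
#'
#' @param norm An `mdm_norm`.
#' @param ranges An `mdm_ranges` covering every scored metabolite.
#' @param panel Panel; defaults to the panel stored in `norm`.
#' @return Integer 0/1 matrix, participants x metabolites.
#' @export
exceedance_indicators <- function(norm, ranges, panel = NULL) {
  stopifnot(inherits(norm, "mdm_norm"), inherits(ranges, "mdm_ranges"))
  if (is.null(panel)) panel <- norm$panel
  vals <- norm$values
  missing_ranges <- setdiff(colnames(vals), ranges$metabolite_id)
  if (length(missing_ranges) > 0) {
    stop("no reference range for metabolite(s): ",
         paste(missing_ranges, collapse = ", "), call. = FALSE)
  }
  idx <- match(colnames(vals), ranges$metabolite_id)
  upper <- matrix(ranges$upper[idx], nrow(vals), ncol(vals), byrow = TRUE)
  lower <- matrix(ranges$lower[idx], nrow(vals), ncol(vals), byrow = TRUE)
  dir_low <- panel$direction[match(colnames(vals), panel$metabolite_id)] == "low"
  dir_mat <- matrix(dir_low, nrow(vals), ncol(vals), byrow = TRUE)

  e <- ifelse(dir_mat, vals < lower, vals > upper)
  n_missing <- sum(is.na(e))
  if (n_missing > 0) {
    message(n_missing, " missing value(s) scored as non-exceeding")
    e[is.na(e)] <- FALSE
  }
  mode(e) <- "integer"
  dimnames(e) <- dimnames(vals)
  e
}

#' MDM Total Score: count of reference-range exceedances per participant
#'
#' @param indicators 0/1 matrix from [exceedance_indicators()].
#' @param cutoff Classification cut-off: a participant is screened positive
#'   when their total is at least `cutoff` (default 1, i.e. one or more
#'   metabolites outside the TD range).
#' @return Data frame of class `mdm_scores`: `participant_id`, `total`,
#'   `classified_positive`.
#' @export
mdm_total_score <- function(indicators, cutoff = 1L) {
  stopifnot(is.matrix(indicators), cutoff >= 1)
  total <- as.integer(rowSums(indicators))
  out <- data.frame(
    participant_id = rownames(indicators),
    total = total,
    classified_positive = total >= cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("mdm_scores", "data.frame"), cutoff = cutoff)
}

#' Confusion-matrix metrics of the exceedance classifier
#'
#' ASD is the positive class. Ratios with a zero denominator are reported as
#' `NA` (undefined), never as 0.
#'
#' @param scores An `mdm_scores` (or logical vector of positive calls).
#' @param groups Group labels (`"ASD"`/`"TD"`), aligned with `scores`.
#' @return List of class `mdm_classification`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` (proportions in
#'   `[0, 1]`).
#' @export
classify_cohort <- function(scores, groups) {
  positive <- if (inherits(scores, "mdm_scores")) {
    scores$classified_positive
  } else as.logical(scores)
  stopifnot(length(positive) == length(groups))
  is_asd <- groups == "ASD"
  tp <- sum(positive & is_asd); fn <- sum(!positive & is_asd)
  tn <- sum(!positive & !is_asd); fp <- sum(positive & !is_asd)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy = ratio(tp + tn, tp + tn + fp + fn)),
    class = "mdm_classification"
  )
}

#' @export
print.mdm_classification <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("<mdm_classification>\n")
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %s  specificity %s\n",
              pct(x$sensitivity), pct(x$specificity)))
  cat(sprintf("  PPV %s  NPV %s  accuracy %s\n",
              pct(x$ppv), pct(x$npv), pct(x$accuracy)))
  invisible(x)
}

#' Score a cohort end to end (in-sample or against frozen ranges)
#'
#' Convenience wrapper: normalize, build ranges (in-sample mode) or take
#' frozen ones (deploy mode), compute indicators, totals and classification.
#' In-sample mode reproduces the published evaluation design, in which the
#' TD group that defines the ranges is also scored — its specificity is
#' tautologically 100% and every TD total is 0 by construction.
#'
#' @param cohort An `mdm_cohort`.
#' @param ranges `NULL` for in-sample mode, or a frozen `mdm_ranges`.
#' @param cutoff Classification cut-off (minimum exceedance count).
#' @param lod_policy Passed to [normalize_by_creatinine()].
#' @return List with `norm`, `ranges`, `indicators`, `scores`,
#'   `classification`, `mode`.
#' @export
score_cohort <- function(cohort, ranges = NULL, cutoff = 1L,
                         lod_policy = "half_lod") {
  norm <- normalize_by_creatinine(cohort, lod_policy)
  mode <- if (is.null(ranges)) "insample" else "deploy"
  if (is.null(ranges)) ranges <- build_reference_ranges(norm)
  ind <- exceedance_indicators(norm, ranges)
  scores <- mdm_total_score(ind, cutoff = cutoff)
  list(norm = norm, ranges = ranges, indicators = ind, scores = scores,
       classification = classify_cohort(scores, cohort_groups(cohort)),
       mode = mode)
}
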