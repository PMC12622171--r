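#' Welch's unequal-variance t-test
#'
#' Thin, contract-checked wrapper around [stats::t.test()] with
#' `var.equal = FALSE` (Welch-Satterthwaite degrees of freedom, two-sided).
#' The degenerate case of two zero-variance samples with equal means is
#' reported as no evidence of difference (`t = 0`, `p = 1`) with a message,
#' rather than an error.
#'
#' @param x,y Numeric samples (NAs dropped); each needs at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs at least 2 non-missing values per sample",
         call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      message("both samples constant and equal; reporting t = 0, p = 1")
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("both samples constant with different means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch's t-test on square-root-transformed values
#'
#' Right-skewed concentration data are square-root transformed before
#' re-testing; the transform requires non-negative input.
#'
#' @inheritParams welch_t
#' @return List with `t`, `df`, `p` on the transformed scale.
#' @export
sqrt_transform_then_test <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    stop("sqrt transform requires non-negative values", call. = FALSE)
  }
  welch_t(sqrt(x), sqrt(y))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment via
#' [stats::p.adjust()]`(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' AUROC by the rank (Mann-Whitney) formula
#'
#' `P(X > Y) + P(X = Y)/2` for a random ASD value X and TD value Y,
#' computed from midranks so ties contribute one half. Oriented so values
#' above 0.5 mean the first sample is stochastically larger.
#'
#' @param x First (ASD) sample; NAs dropped.
#' @param y Second (TD) sample; NAs dropped.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("auroc needs non-empty samples", call. = FALSE)
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

#' Percent difference of group means
#'
#' `100 * (mean_asd - mean_td) / mean_td`; undefined (NA, with a warning)
#' when the reference mean is zero.
#'
#' @param mean_asd,mean_td Group means (same units).
#' @return Percent difference (not rounded; see [format_report()]).
#' @export
percent_difference <- function(mean_asd, mean_td) {
  if (is.na(mean_td) || mean_td == 0) {
    warning("percent difference undefined for zero reference mean")
    return(NA_real_)
  }
  100 * (mean_asd - mean_td) / mean_td
}

#' Percent of a sample outside a reference range
#'
#' High direction: strictly above `upper`. Low direction: strictly below
#' `lower`. Missing values count in the denominator as non-exceeding,
#' mirroring the scoring indicators.
#'
#' @param values Numeric sample (typically the ASD column values).
#' @param lower,upper Reference range bounds.
#' @param direction `"high"` or `"low"`.
#' @return Percentage in `[0, 100]`.
#' @export
pct_above_reference <- function(values, lower, upper, direction = "high") {
  if (length(values) == 0) return(NA_real_)
  exceed <- if (direction == "low") values < lower else values > upper
  100 * sum(exceed, na.rm = TRUE) / length(values)
}

#' Percent of censored (below-LOD) measurements
#' @param flags Logical vector of below-LOD flags (both groups pooled).
#' @return Percentage in `[0, 100]`.
#' @export
pct_below_lod <- function(flags) {
  if (length(flags) == 0) return(NA_real_)
  100 * mean(flags)
}

#' Metabolite-metabolite correlation matrix
#'
#' Pairwise-complete Pearson (default) or Spearman correlations of
#' creatinine-normalized values; constant columns yield `NA` with a warning
#' from [stats::cor()].
#'
#' @param norm An `mdm_norm` (or a plain numeric matrix).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(norm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- if (inherits(norm, "mdm_norm")) norm$values else norm
  n_complete <- crossprod(!is.na(vals))
  if (any(n_complete < 3)) {
    warning("fewer than 3 complete pairs for some metabolite pair(s)")
  }
  stats::cor(vals, use = "pairwise.complete.obs", method = method)
}

#' Per-metabolite univariate report
#'
#' One row per metabolite: group means of the creatinine-normalized values,
#' percent difference, Welch p on the raw and on the square-root scale, BH
#' q-value (over the raw p-values), AUROC oriented ASD-high, percent of ASD
#' participants outside the TD reference range, and percent of all
#' measurements below the LOD. Censored cells enter the means as imputed by
#' the normalization's LOD policy; missing cells are excluded pairwise.
#'
#' @param norm An `mdm_norm`.
#' @param groups Group labels; default from `norm`.
#' @param ranges Reference ranges; built in-sample from the TD rows when
#'   `NULL`.
#' @param include_q Emit the BH q column (`TRUE` for the screening report;
#'   set `FALSE` for a report whose p-values are left unadjusted).
#' @return Data frame of class `mdm_univariate`, one row per metabolite.
#' @export
univariate_table <- function(norm, groups = NULL, ranges = NULL,
                             include_q = TRUE) {
  stopifnot(inherits(norm, "mdm_norm"))
  if (is.null(groups)) groups <- norm$participants$group
  if (is.null(ranges)) ranges <- build_reference_ranges(norm, groups)
  vals <- norm$values
  panel <- norm$panel
  is_asd <- groups == "ASD"

  rows <- lapply(colnames(vals), function(m) {
    x <- vals[is_asd, m]; y <- vals[!is_asd, m]
    direction <- panel$direction[match(m, panel$metabolite_id)]
    ri <- match(m, ranges$metabolite_id)
    wt <- tryCatch(suppressMessages(welch_t(x, y)),
                   error = function(e) list(t = NA_real_, df = NA_real_,
                                            p = NA_real_))
    ws <- tryCatch(suppressMessages(sqrt_transform_then_test(x, y)),
                   error = function(e) list(p = NA_real_))
    data.frame(
      metabolite_id = m,
      family = panel$family[match(m, panel$metabolite_id)],
      mean_asd = mean(x, na.rm = TRUE),
      mean_td = mean(y, na.rm = TRUE),
      pct_difference = suppressWarnings(
        percent_difference(mean(x, na.rm = TRUE), mean(y, na.rm = TRUE))),
      p_raw = wt$p,
      p_sqrt = ws$p,
      auroc = auroc(x, y),
      pct_asd_above_td = pct_above_reference(
        x, ranges$lower[ri], ranges$upper[ri], direction),
      pct_below_lod = pct_below_lod(norm$lod_mask[, m]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (include_q) {
    ok <- !is.na(out$p_raw)
    out$q_value <- NA_real_
    out$q_value[ok] <- bh_fdr(out$p_raw[ok])
    out$significant_q05 <- !is.na(out$q_value) & out$q_value < 0.05
  }
  rownames(out) <- NULL
  structure(out, class = c("mdm_univariate", "data.frame"))
}

#' Round a univariate report to publication formatting
#'
#' Percent columns to the nearest integer, AUROC to two decimals, p and q
#' to two significant figures; means keep three significant figures.
#'
#' @param table An `mdm_univariate`.
#' @return A plain data frame formatted for display.
#' @export
format_report <- function(table) {
  out <- as.data.frame(table)
  for (col in c("pct_difference", "pct_asd_above_td", "pct_below_lod")) {
    out[[col]] <- round(out[[col]])
  }
  out$auroc <- round(out$auroc, 2)
  for (col in intersect(c("p_raw", "p_sqrt", "q_value"), names(out))) {
    out[[col]] <- signif(out[[col]], 2)
  }
  for (col in c("mean_asd", "mean_td")) out[[col]] <- signif(out[[col]], 3)
  out
}
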