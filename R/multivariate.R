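#' Feature matrix for discriminant analysis
#'
#' Variance-stabilising transform of the creatinine-normalized values before
#' linear discriminant fitting. Missing cells (including `exclude`-policy
#' censored cells) are not tolerated here: impute at normalization or drop
#' the metabolite.
#'
#' @param norm An `mdm_norm`.
#' @param transform `"sqrt"` (default, consistent with the univariate
#'   re-test), `"log1p"`, or `"none"`.
#' @param features Metabolite ids to keep; default all.
#' @return Numeric matrix participants x features.
#' @export
prepare_features <- function(norm, transform = c("sqrt", "log1p", "none"),
                             features = NULL) {
  transform <- match.arg(transform)
  vals <- if (inherits(norm, "mdm_norm")) norm$values else norm
  if (!is.null(features)) vals <- vals[, features, drop = FALSE]
  if (anyNA(vals)) {
    stop("feature matrix contains missing values; use an imputing LOD ",
         "policy or drop incomplete metabolites", call. = FALSE)
  }
  switch(transform,
         sqrt = sqrt(vals),
         log1p = log1p(vals),
         none = vals)
}

#' Fit a (ridge-regularised) Fisher linear discriminant
#'
#' Solves `(S_W + ridge * I) w = mu_ASD - mu_TD`, where `S_W` is the pooled
#' within-class scatter of the class-centred data. The projection is
#' oriented so the ASD training mean score exceeds the TD mean score. A
#' small ridge (default `1e-6 * trace(S_W)/p`) is added automatically when
#' the scatter is ill-conditioned; a singular scatter with `ridge = 0` is an
#' error advising regularisation.
#'
#' @param X Numeric matrix, participants x features.
#' @param labels Group labels (`"ASD"`/`"TD"` or any two-level factor; the
#'   level named `"ASD"`, else the second level, is the positive class).
#' @param ridge Non-negative ridge; `NULL` for automatic conditioning.
#' @return Object of class `mdm_fda`: `feature_ids`, `weights`, `ridge`,
#'   `class_means`, `scores` (training projections), `auroc_insample`.
#' @export
fit_fda <- function(X, labels, ridge = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), all(is.finite(X)))
  pos <- if ("ASD" %in% labels) "ASD" else levels(factor(labels))[2]
  is_pos <- labels == pos
  if (sum(is_pos) < 2 || sum(!is_pos) < 2) {
    stop("need at least 2 participants per class", call. = FALSE)
  }
  mu1 <- colMeans(X[is_pos, , drop = FALSE])
  mu0 <- colMeans(X[!is_pos, , drop = FALSE])
  c1 <- sweep(X[is_pos, , drop = FALSE], 2, mu1)
  c0 <- sweep(X[!is_pos, , drop = FALSE], 2, mu0)
  sw <- crossprod(c1) + crossprod(c0)
  p <- ncol(X)

  auto <- is.null(ridge)
  if (auto) {
    ridge <- 0
    cond <- tryCatch(kappa(sw, exact = TRUE), error = function(e) Inf)
    if (!is.finite(cond) || cond > 1e10) {
      ridge <- 1e-6 * sum(diag(sw)) / p
      message(sprintf("ill-conditioned within-class scatter; ridge = %.3g",
                      ridge))
    }
  }
  w <- tryCatch(
    solve(sw + diag(ridge, p), mu1 - mu0),
    error = function(e) {
      stop("singular within-class scatter with ridge = 0; supply a ",
           "positive ridge", call. = FALSE)
    })
  scores <- drop(X %*% w)
  if (mean(scores[is_pos]) < mean(scores[!is_pos])) {
    w <- -w
    scores <- -scores
  }
  structure(
    list(feature_ids = colnames(X), weights = stats::setNames(w, colnames(X)),
         ridge = ridge, class_means = list(ASD = mu1, TD = mu0),
         scores = scores,
         auroc_insample = auroc(scores[is_pos], scores[!is_pos])),
    class = "mdm_fda"
  )
}

#' Project new samples onto a fitted discriminant
#' @param object An `mdm_fda`.
#' @param newdata Matrix with the model's feature columns.
#' @param ... Unused.
#' @return Numeric projection scores.
#' @export
predict.mdm_fda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$feature_ids, drop = FALSE]
  drop(newdata %*% object$weights)
}

#' Leave-one-out cross-validated AUROC of the Fisher discriminant
#'
#' Each participant is scored by a discriminant fitted on the remaining
#' `n - 1`; the `n` held-out scores are pooled and a single AUROC computed
#' on them (per-fold AUROC is undefined for single held-out points). Each
#' fold's orientation is fixed by its own training-class means so sign flips
#' cannot corrupt the pooled ranking.
#'
#' @inheritParams fit_fda
#' @return LOOCV AUROC in `[0, 1]`.
#' @export
loocv_auroc <- function(X, labels, ridge = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("LOOCV needs at least 4 participants", call. = FALSE)
  pos <- if ("ASD" %in% labels) "ASD" else levels(factor(labels))[2]
  held_out <- vapply(seq_len(n), function(i) {
    train_labels <- labels[-i]
    if (length(unique(train_labels)) < 2) {
      stop("a LOOCV fold has a single-class training set", call. = FALSE)
    }
    fit <- suppressMessages(fit_fda(X[-i, , drop = FALSE], train_labels,
                                    ridge = ridge))
    predict(fit, X[i, , drop = FALSE])
  }, numeric(1))
  auroc(held_out[labels == pos], held_out[labels != pos])
}

#' Exhaustive k-subset discriminant search
#'
#' Enumerates all size-`k` subsets of the feature pool in lexicographic
#' order, fits a Fisher discriminant on each, and returns the subsets whose
#' AUROC exceeds `auroc_floor`, sorted by decreasing AUROC (LOOCV AUROC when
#' `loocv = TRUE`, else in-sample) with lexicographic tie-break. The
#' enumeration is deterministic: identical inputs give an identical ranked
#' list.
#'
#' @param X Feature matrix (see [prepare_features()]).
#' @param labels Group labels.
#' @param k Subset size.
#' @param feature_pool Columns to search over; default all columns of `X`.
#' @param auroc_floor Keep subsets with AUROC strictly above this value.
#' @param loocv Also compute (and rank by) LOOCV AUROC per subset —
#'   substantially more expensive.
#' @param ridge Passed to [fit_fda()].
#' @param max_combinations Enumeration budget; exceeding it is an error
#'   stating the subset count.
#' @return Data frame of class `mdm_combinations`: one row per retained
#'   subset with `features` (slash-separated ids), `auroc_insample` and, if
#'   requested, `auroc_loocv`.
#' @export
combination_search <- function(X, labels, k, feature_pool = NULL,
                               auroc_floor = 0.8, loocv = FALSE,
                               ridge = NULL, max_combinations = 250000) {
  X <- as.matrix(X)
  if (is.null(feature_pool)) feature_pool <- colnames(X)
  stopifnot(all(feature_pool %in% colnames(X)), k >= 1,
            k <= length(feature_pool))
  n_comb <- choose(length(feature_pool), k)
  if (n_comb > max_combinations) {
    stop(sprintf("C(%d, %d) = %.0f subsets exceeds the budget of %d",
                 length(feature_pool), k, n_comb, max_combinations),
         call. = FALSE)
  }
  subsets <- utils::combn(feature_pool, k, simplify = FALSE)
  rows <- lapply(subsets, function(fs) {
    Xs <- X[, fs, drop = FALSE]
    fit <- suppressMessages(fit_fda(Xs, labels, ridge = ridge))
    row <- data.frame(features = paste(fs, collapse = "/"),
                      auroc_insample = fit$auroc_insample,
                      stringsAsFactors = FALSE)
    if (loocv) row$auroc_loocv <- loocv_auroc(Xs, labels, ridge = ridge)
    row
  })
  out <- do.call(rbind, rows)
  rank_col <- if (loocv) out$auroc_loocv else out$auroc_insample
  keep <- rank_col > auroc_floor
  out <- out[keep, , drop = FALSE]
  rank_col <- rank_col[keep]
  out <- out[order(-rank_col, out$features), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mdm_combinations", "data.frame"),
            k = k, auroc_floor = auroc_floor,
            n_evaluated = length(subsets))
}
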