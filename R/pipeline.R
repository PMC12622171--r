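#' End-to-end screening pipeline
#'
#' Orchestrates load -> creatinine normalization -> reference ranges (built
#' in-sample or loaded frozen) -> exceedance scoring -> classification ->
#' univariate report -> optional discriminant subset search, and writes
#' every artifact into an output directory: `univariate.csv`, `scores.csv`,
#' `classification.json`, `ranges.json`, `correlations.csv`,
#' `scores_vs_age.png` (when ages are available), `fda_search.csv` (when
#' requested) and `run_config.json` (the resolved configuration, for
#' reproducibility).
#'
#' Two modes, labelled in every report: `"insample"` evaluates the cohort
#' against ranges built from its own TD rows (the published evaluation
#' design, whose TD specificity is 100% by construction), `"deploy"` applies
#' frozen ranges from `ranges_path` to new samples.
#'
#' @param cohort An `mdm_cohort`, or a path to a cohort CSV.
#' @param panel An `mdm_panel`, or a path to a panel file (required when
#'   `cohort` is a path).
#' @param output_dir Directory for the artifact bundle (created if absent).
#' @param mode `"insample"` or `"deploy"`.
#' @param ranges_path Frozen ranges JSON (deploy mode).
#' @param cutoff Minimum exceedance count for a positive screen.
#' @param lod_policy LOD imputation policy for normalization.
#' @param fda Optional list of discriminant-search settings:
#'   `k`, `floor`, `loocv`, `transform`, `feature_pool`, `max_combinations`.
#' @return Invisibly, a list with all in-memory results (`norm`, `ranges`,
#'   `indicators`, `scores`, `classification`, `univariate`, `correlations`,
#'   `fda`, `mode`, `output_dir`).
#' @export
run_pipeline <- function(cohort, panel = NULL, output_dir,
                         mode = c("insample", "deploy"), ranges_path = NULL,
                         cutoff = 1L, lod_policy = "half_lod", fda = NULL) {
  mode <- match.arg(mode)
  if (is.character(cohort)) {
    if (is.null(panel)) stop("panel required when cohort is a path",
                             call. = FALSE)
    cohort <- load_cohort(cohort, panel)
  }
  stopifnot(inherits(cohort, "mdm_cohort"))
  if (mode == "deploy" && is.null(ranges_path)) {
    stop("deploy mode needs ranges_path", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  ranges <- if (mode == "deploy") read_ranges(ranges_path) else NULL
  res <- score_cohort(cohort, ranges = ranges, cutoff = cutoff,
                      lod_policy = lod_policy)
  uni <- univariate_table(res$norm, ranges = res$ranges)
  cors <- suppressWarnings(correlation_matrix(res$norm))

  fda_res <- NULL
  if (!is.null(fda)) {
    Xf <- prepare_features(res$norm,
                           transform = fda$transform %||% "sqrt",
                           features = fda$feature_pool)
    fda_res <- combination_search(
      Xf, cohort_groups(cohort), k = fda$k %||% 2,
      auroc_floor = fda$floor %||% 0.8, loocv = isTRUE(fda$loocv),
      max_combinations = fda$max_combinations %||% 250000)
    utils::write.csv(as.data.frame(fda_res),
                     file.path(output_dir, "fda_search.csv"),
                     row.names = FALSE)
  }

  utils::write.csv(format_report(uni),
                   file.path(output_dir, "univariate.csv"), row.names = FALSE)
  scores_out <- cbind(res$scores,
                      group = cohort_groups(cohort),
                      mode = mode)
  utils::write.csv(scores_out, file.path(output_dir, "scores.csv"),
                   row.names = FALSE)
  write_ranges(res$ranges, file.path(output_dir, "ranges.json"))
  utils::write.csv(as.data.frame(cors),
                   file.path(output_dir, "correlations.csv"))
  cls <- res$classification
  jsonlite::write_json(
    list(mode = mode, cutoff = cutoff,
         tp = cls$tp, fp = cls$fp, tn = cls$tn, fn = cls$fn,
         sensitivity = cls$sensitivity, specificity = cls$specificity,
         ppv = cls$ppv, npv = cls$npv, accuracy = cls$accuracy),
    file.path(output_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    list(mode = mode, cutoff = cutoff, lod_policy = lod_policy,
         panel_hash = panel_hash(cohort$panel),
         n_participants = nrow(cohort$raw),
         package_version = as.character(utils::packageVersion("mdmscreen"))),
    file.path(output_dir, "run_config.json"), auto_unbox = TRUE)

  if ("age_years" %in% names(cohort$participants) &&
      any(!is.na(cohort$participants$age_years))) {
    p <- plot_scores_vs_age(res$scores, cohort$participants$age_years,
                            cohort_groups(cohort))
    ggplot2::ggsave(file.path(output_dir, "scores_vs_age.png"), p,
                    width = 6, height = 4, dpi = 150)
  }

  invisible(c(res, list(univariate = uni, correlations = cors,
                        fda = fda_res, output_dir = output_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scatter plot of MDM Total Score against age
#'
#' One point per participant, coloured and shaped by group. In in-sample
#' mode every TD point sits at zero by construction. Participants with
#' missing age are dropped with a notice.
#'
#' @param scores An `mdm_scores`.
#' @param ages Numeric ages (years), aligned with `scores`.
#' @param groups Group labels, aligned with `scores`.
#' @return A ggplot object.
#' @export
plot_scores_vs_age <- function(scores, ages, groups) {
  stopifnot(inherits(scores, "mdm_scores"),
            length(ages) == nrow(scores), length(groups) == nrow(scores))
  df <- data.frame(age = ages, total = scores$total, group = groups)
  if (anyNA(df$age)) {
    message(sum(is.na(df$age)), " participant(s) without age dropped")
    df <- df[!is.na(df$age), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$total,
                                   colour = .data$group,
                                   shape = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(ASD = "#d95f02", TD = "#1f78b4")) +
    ggplot2::scale_shape_manual(values = c(ASD = 16, TD = 15)) +
    ggplot2::labs(x = "Age (years)",
                  y = "MDM Total Score (metabolites outside TD range)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
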