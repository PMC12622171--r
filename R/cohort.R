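#' Two-group urinary metabolomics cohort
#'
#' A cohort couples participant metadata (identifier, group label, age, sex,
#' urinary creatinine) with a participants-by-metabolites matrix of raw
#' concentrations. Below-LOD measurements are censored: the stored value is
#' `NA` and the corresponding cell of `lod_flags` is `TRUE`. Cells that are
#' `NA` without the flag are missing (not measured), and are never imputed.
#'
#' @param participants Data frame with columns `participant_id`, `group`
#'   (`"ASD"` or `"TD"`), `creatinine` (strictly positive, mmol/L), and
#'   optionally `age_years` and `sex`.
#' @param raw Numeric matrix, participants x metabolites, row names matching
#'   `participant_id`, column names matching panel metabolite ids. `NA` marks
#'   censored or missing cells.
#' @param lod_flags Logical matrix of the same shape; `TRUE` marks a
#'   below-LOD censored cell.
#' @param panel The `mdm_panel` the columns belong to.
#' @return An object of class `mdm_cohort`.
#' @export
mdm_cohort <- function(participants, raw, lod_flags, panel) {
  stopifnot(is.data.frame(participants), is.matrix(raw),
            is.matrix(lod_flags), inherits(panel, "mdm_panel"))
  participants <- as.data.frame(participants)
  for (col in c("participant_id", "group", "creatinine")) {
    if (!col %in% names(participants)) {
      stop("participants is missing column: ", col, call. = FALSE)
    }
  }
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    dup <- unique(participants$participant_id[
      duplicated(participants$participant_id)])
    stop("duplicate participant_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(participants$group), c("ASD", "TD"))
  if (length(bad_group) > 0) {
    stop("group labels must be ASD or TD, found: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  bad_cr <- is.na(participants$creatinine) | participants$creatinine <= 0
  if (any(bad_cr)) {
    stop("non-positive or missing creatinine for participant(s): ",
         paste(participants$participant_id[bad_cr], collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(colnames(raw), panel$metabolite_id)
  if (length(extra) > 0) {
    stop("metabolite column(s) absent from panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  stopifnot(identical(dim(raw), dim(lod_flags)),
            identical(colnames(raw), colnames(lod_flags)),
            nrow(raw) == nrow(participants))
  if (any(raw < 0, na.rm = TRUE)) {
    stop("raw concentrations must be non-negative", call. = FALSE)
  }
  # censoring implies the numeric value is absent (or at most the LOD)
  lods <- panel$lod[match(colnames(raw), panel$metabolite_id)]
  lod_mat <- matrix(lods, nrow = nrow(raw), ncol = ncol(raw), byrow = TRUE)
  viol <- lod_flags & !is.na(raw) & !is.na(lod_mat) & raw > lod_mat
  if (any(viol)) {
    stop("below-LOD flagged cell(s) hold values above the LOD", call. = FALSE)
  }
  rownames(raw) <- rownames(lod_flags) <- participants$participant_id
  structure(
    list(participants = participants, raw = raw, lod_flags = lod_flags,
         panel = panel),
    class = "mdm_cohort"
  )
}

#' @export
print.mdm_cohort <- function(x, ...) {
  n <- table(factor(x$participants$group, levels = c("ASD", "TD")))
  cat(sprintf(
    "<mdm_cohort> %d participants (ASD %d / TD %d), %d metabolites, %d censored cells\n",
    nrow(x$raw), n[["ASD"]], n[["TD"]], ncol(x$raw), sum(x$lod_flags)))
  invisible(x)
}

#' Number of participants / group labels helpers
#' @param cohort An `mdm_cohort`.
#' @return `cohort_groups` returns the character vector of group labels in
#'   row order.
#' @export
cohort_groups <- function(cohort) cohort$participants$group

# token used for censored cells in the CSV dialect
LOD_TOKEN <- "<LOD"

#' Load a cohort from a wide CSV file
#'
#' Expected dialect: comma-separated, UTF-8, `.` decimal, one header row with
#' columns `participant_id`, `group`, optionally `age_years` and `sex`,
#' `creatinine`, then one column per panel metabolite id. `"<LOD"` marks a
#' censored cell and the empty string marks a missing cell; anything else
#' must parse as a non-negative number.
#'
#' @param cohort_path Path to the cohort CSV.
#' @param panel An `mdm_panel`, or a path to a panel file.
#' @return A validated `mdm_cohort`.
#' @export
load_cohort <- function(cohort_path, panel) {
  if (!file.exists(cohort_path)) {
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  }
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "mdm_panel"))
  tab <- utils::read.csv(cohort_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  meta_cols <- intersect(c("participant_id", "group", "age_years", "sex",
                           "creatinine"), names(tab))
  if (!all(c("participant_id", "group", "creatinine") %in% meta_cols)) {
    stop("cohort file must have participant_id, group and creatinine columns",
         call. = FALSE)
  }
  met_cols <- setdiff(names(tab), meta_cols)
  extra <- setdiff(met_cols, panel$metabolite_id)
  if (length(extra) > 0) {
    stop("metabolite column(s) absent from panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }

  parse_num <- function(v, col, allow_blank = FALSE) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & nzchar(trimws(v))
    if (allow_blank) bad <- bad & !is.na(v)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   v[which(bad)[1]], which(bad)[1], col), call. = FALSE)
    }
    out
  }

  participants <- data.frame(
    participant_id = tab$participant_id,
    group = tab$group,
    creatinine = parse_num(tab$creatinine, "creatinine"),
    stringsAsFactors = FALSE
  )
  if ("age_years" %in% names(tab)) {
    participants$age_years <- parse_num(tab$age_years, "age_years",
                                        allow_blank = TRUE)
  }
  if ("sex" %in% names(tab)) participants$sex <- tab$sex

  raw <- matrix(NA_real_, nrow = nrow(tab), ncol = length(met_cols),
                dimnames = list(tab$participant_id, met_cols))
  flags <- matrix(FALSE, nrow = nrow(tab), ncol = length(met_cols),
                  dimnames = list(tab$participant_id, met_cols))
  for (m in met_cols) {
    v <- trimws(tab[[m]])
    cens <- v == LOD_TOKEN
    miss <- !nzchar(v) | is.na(v)
    num <- v
    num[cens | miss] <- NA_character_
    raw[, m] <- parse_num(num, m, allow_blank = TRUE)
    flags[, m] <- cens
  }
  mdm_cohort(participants, raw, flags, panel)
}

#' Write a cohort to the wide CSV dialect
#'
#' Inverse of [load_cohort()]: censored cells are written as `"<LOD"` and
#' missing cells as the empty string, so a round trip preserves the LOD
#' flags.
#'
#' @param cohort An `mdm_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mdm_cohort"))
  vals <- matrix(
    ifelse(cohort$lod_flags, LOD_TOKEN,
           ifelse(is.na(cohort$raw), "", sprintf("%.17g", cohort$raw))),
    nrow = nrow(cohort$raw), dimnames = dimnames(cohort$raw)
  )
  out <- cbind(cohort$participants, as.data.frame(vals))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
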