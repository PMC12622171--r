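#' Metabolite panel definitions
#'
#' A metabolite panel describes the compounds scored by the screening system:
#' a stable identifier, a display name, the biochemical family
#' (phenylalanine-derived, tryptophan-derived, or yeast/other), the scoring
#' direction (`"high"` for markers elevated in dysbiosis, `"low"` for markers
#' that are depleted, e.g. N-formyl methionine), the limit of detection in raw
#' concentration units, and the measurement units.
#'
#' Ratio pseudo-metabolites (e.g. the phenylalanine/tyrosine ratio) carry
#' `units = "ratio"` and are exempt from creatinine normalization: the ratio
#' is computed upstream and already dimensionless.
#'
#' @param entries A data frame with columns `metabolite_id`, `display_name`,
#'   `family`, `direction`, `lod`, `units`. `lod` may be `NA` when no limit of
#'   detection is known.
#' @return An object of class `mdm_panel` (a validated data frame).
#' @examples
#' panel <- metabolite_panel(data.frame(
#'   metabolite_id = c("pcs", "arabinitol"),
#'   display_name  = c("p-Cresol sulfate", "Arabinitol"),
#'   family        = c("phenylalanine", "yeast_other"),
#'   direction     = c("high", "high"),
#'   lod           = c(NA, 0.5),
#'   units         = c("umol/L", "umol/L")
#' ))
#' @export
metabolite_panel <- function(entries) {
  stopifnot(is.data.frame(entries))
  required <- c("metabolite_id", "display_name", "family", "direction",
                "lod", "units")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries <- as.data.frame(entries)[, required]
  entries$metabolite_id <- as.character(entries$metabolite_id)
  entries$display_name <- as.character(entries$display_name)
  entries$family <- as.character(entries$family)
  entries$direction <- as.character(entries$direction)
  entries$lod <- as.numeric(entries$lod)
  entries$units <- as.character(entries$units)

  if (anyNA(entries$metabolite_id) || any(!nzchar(entries$metabolite_id))) {
    stop("metabolite_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(entries$metabolite_id)) {
    dup <- unique(entries$metabolite_id[duplicated(entries$metabolite_id)])
    stop("duplicate metabolite_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_family <- setdiff(entries$family, mdm_families())
  if (length(bad_family) > 0) {
    stop("unknown family: ", paste(bad_family, collapse = ", "),
         "; expected one of ", paste(mdm_families(), collapse = ", "),
         call. = FALSE)
  }
  bad_dir <- setdiff(entries$direction, c("high", "low"))
  if (length(bad_dir) > 0) {
    stop("direction must be 'high' or 'low', got: ",
         paste(bad_dir, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(entries$lod) & entries$lod < 0)) {
    stop("lod must be non-negative", call. = FALSE)
  }
  rownames(entries) <- NULL
  class(entries) <- c("mdm_panel", "data.frame")
  entries
}

#' The three metabolite family labels
#' @return Character vector of the recognised family identifiers.
#' @export
mdm_families <- function() c("phenylalanine", "tryptophan", "yeast_other")

#' Is a panel entry a ratio pseudo-metabolite (exempt from normalization)?
#' @param panel An `mdm_panel`.
#' @return Logical vector along the panel rows.
#' @export
is_ratio_metabolite <- function(panel) {
  panel$units == "ratio"
}

#' Read a metabolite panel from CSV or YAML
#'
#' CSV files need one row per metabolite with the panel columns; YAML files
#' hold a list of per-metabolite mappings under the top-level key
#' `metabolites` (or a bare list).
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return An `mdm_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$metabolites)) raw <- raw$metabolites
    entries <- do.call(rbind, lapply(raw, function(e) {
      data.frame(
        metabolite_id = e$metabolite_id,
        display_name = if (is.null(e$display_name)) e$metabolite_id else e$display_name,
        family = e$family,
        direction = if (is.null(e$direction)) "high" else e$direction,
        lod = if (is.null(e$lod)) NA_real_ else as.numeric(e$lod),
        units = if (is.null(e$units)) "umol/L" else e$units,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    entries <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"direction" %in% names(entries)) entries$direction <- "high"
    if (!"lod" %in% names(entries)) entries$lod <- NA_real_
    if (!"units" %in% names(entries)) entries$units <- "umol/L"
    if (!"display_name" %in% names(entries)) {
      entries$display_name <- entries$metabolite_id
    }
  }
  metabolite_panel(entries)
}

#' Write a metabolite panel to CSV
#' @param panel An `mdm_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mdm_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Stable hash of a panel definition
#'
#' Used to stamp serialized reference ranges so that ranges are never applied
#' to a cohort scored under a different panel. Plain FNV-1a over the
#' canonical CSV text; no cryptographic strength needed or implied.
#'
#' @param panel An `mdm_panel`.
#' @return Hex string.
#' @export
panel_hash <- function(panel) {
  txt <- paste(
    apply(as.data.frame(panel), 1L, paste, collapse = "\x1f"),
    collapse = "\n"
  )
  bytes <- utf8ToInt(txt)
  # 32-bit FNV-1a in double arithmetic (exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # keep the multiply in double space, reduce mod 2^32
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' The default quantitative urine MDM panel
#'
#' The 24-row targeted panel: eleven phenylalanine-related entries (including
#' the Phe/Tyr and benzoic/hippuric ratio pseudo-metabolites), nine
#' tryptophan-related entries, and four yeast/other entries. All entries are
#' scored in the high direction; concentrations are micromoles per litre of
#' urine prior to creatinine normalization, except the two dimensionless
#' ratios.
#'
#' @return An `mdm_panel` with 24 entries.
#' @export
default_panel <- function() {
  metabolite_panel(mdm_study_anchors()[, c(
    "metabolite_id", "display_name", "family", "direction", "lod", "units"
  )])
}

# Per-metabolite anchors used by the calibrated simulator: typical TD
# creatinine-normalized level (geometric-mean scale), the target fraction of
# ASD participants above the TD reference maximum, and the pooled censoring
# fraction. Levels are umol/mmol creatinine.
mdm_study_anchors <- function() {
  a <- function(id, name, fam, td, exc, lod_frac, units = "umol/L") {
    data.frame(metabolite_id = id, display_name = name, family = fam,
               direction = "high", lod = NA_real_, units = units,
               td_level = td, target_exceedance = exc,
               censor_frac = lod_frac, stringsAsFactors = FALSE)
  }
  rbind(
    a("p_cresol_sulfate",   "p-Cresol sulfate",          "phenylalanine", 1072,   0.21, 0.00),
    a("p_cresol",           "p-Cresol",                  "phenylalanine", 0.25,   0.19, 0.00),
    a("hydroxybenzoic_acid","Hydroxybenzoic acid",       "phenylalanine", 1.03,   0.17, 0.31),
    a("benzoic_acid",       "Benzoic acid",              "phenylalanine", 0.71,   0.13, 0.08),
    a("phenylacetylglutamine", "Phenylacetylglutamine",  "phenylalanine", 0.44,   0.13, 0.00),
    a("phe_tyr_ratio",      "Phe/Tyr ratio",             "phenylalanine", 1.22,   0.10, 0.00, units = "ratio"),
    a("benzoic_hippuric_ratio", "Benzoic/hippuric ratio","phenylalanine", 0.01,   0.08, 0.03, units = "ratio"),
    a("hippuric_acid",      "Hippuric acid",             "phenylalanine", 54,     0.08, 0.00),
    a("dhppa",              "Dihydroxyphenylpropionic acid", "phenylalanine", 0.56, 0.04, 0.08),
    a("phenylacetic_acid",  "Phenylacetic acid",         "phenylalanine", 1.17,   0.04, 0.15),
    a("phenylpropionic_acid", "Phenylpropionic acid",    "phenylalanine", 0.03,   0.00, 0.76),
    a("indole_3_acryloyl_glycine", "Indole-3-acryloyl glycine", "tryptophan", 3.77, 0.17, 0.00),
    a("indole_3_propionic_acid", "3-Indolepropionic acid", "tryptophan",   0.01,   0.15, 0.00),
    a("indole_4_carbaldehyde", "4-Indolecarbaldehyde",   "tryptophan",    0.01,   0.13, 0.00),
    a("methyldioxindole_3", "3-Methyldioxindole",        "tryptophan",    0.002,  0.12, 0.70),
    a("indoxyl_sulfate",    "Indoxyl sulfate",           "tryptophan",    16,     0.10, 0.00),
    a("oxindole_2",         "2-Oxindole",                "tryptophan",    0.001,  0.08, 0.94),
    a("indole_3_acetonitrile", "3-Indoleacetonitrile",   "tryptophan",    0.002,  0.06, 0.08),
    a("methyl_thbc",        "1-Methyl-tetrahydro-beta-carboline", "tryptophan", 0.008, 0.06, 0.00),
    a("methoxyindole_5",    "5-Methoxyindole",           "tryptophan",    0.0005, 0.00, 0.95),
    a("arabinitol",         "Arabinitol",                "yeast_other",   27,     0.10, 0.00),
    a("citramalic_acid",    "Citramalic acid",           "yeast_other",   0.06,   0.04, 0.00),
    a("tartaric_acid",      "Tartaric acid",             "yeast_other",   0.053,  0.02, 0.36),
    a("tricarballylic_acid","Tricarballylic acid",       "yeast_other",   0.001,  0.00, 0.30)
  )
}
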