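# Shared in-code fixtures: a small panel and cohort builders. All randomness
# is seeded by the caller.

tiny_panel <- function(n = 5, directions = rep("high", n), lod = NA_real_) {
  ids <- sprintf("met%02d", seq_len(n))
  fams <- rep(mdm_families(), length.out = n)
  metabolite_panel(data.frame(
    metabolite_id = ids, display_name = toupper(ids), family = fams,
    direction = directions, lod = lod, units = "umol/L",
    stringsAsFactors = FALSE
  ))
}

# cohort with explicit raw values (participants x metabolites matrix)
make_cohort <- function(raw, groups, creatinine = NULL, panel = NULL,
                        flags = NULL, ages = NULL) {
  n <- nrow(raw)
  if (is.null(panel)) panel <- tiny_panel(ncol(raw))
  colnames(raw) <- panel$metabolite_id[seq_len(ncol(raw))]
  if (is.null(creatinine)) creatinine <- rep(1, n)
  if (is.null(flags)) {
    flags <- matrix(FALSE, n, ncol(raw), dimnames = dimnames(raw))
  } else {
    dimnames(flags) <- dimnames(raw)
  }
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = groups, creatinine = creatinine, stringsAsFactors = FALSE)
  if (!is.null(ages)) participants$age_years <- ages
  rownames(raw) <- rownames(flags) <- participants$participant_id
  mdm_cohort(participants, raw, flags, panel)
}

# random two-group cohort on creatinine = 1 (raw == normalized)
random_cohort <- function(n_asd, n_td, n_met, seed) {
  set.seed(seed)
  raw <- matrix(rlnorm((n_asd + n_td) * n_met), n_asd + n_td, n_met)
  make_cohort(raw, rep(c("ASD", "TD"), c(n_asd, n_td)))
}

# small calibrated synthetic cohort for fast end-to-end tests
small_sim <- function(seed, n_asd = 15, n_td = 12, n_met = 6,
                      elevation_prob = 0.3, ...) {
  panel <- tiny_panel(n_met)
  cfg <- sim_config(n_asd = n_asd, n_td = n_td, panel = panel,
                    log_mean = 0, log_sd = 1,
                    elevation_prob = elevation_prob, seed = seed, ...)
  generate_cohort(cfg)
}
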