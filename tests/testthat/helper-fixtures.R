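# small in-memory observation tables used across tests

make_raw_rows <- function(n = 10, variable = "AGB",
                          recovery = "restoration") {
  data.frame(
    study_id = sprintf("S%02d", seq_len(n)),
    variable = variable,
    mean_t = seq(2, 2 + n - 1),
    mean_c = rep(2, n),
    sd_t = rep(0.5, n), sd_c = rep(0.4, n),
    se_t = NA_real_, se_c = NA_real_,
    n_t = rep(5L, n), n_c = rep(5L, n),
    recovery_type = recovery,
    ecosystem_raw = rep(c("forest", "grassland"), length.out = n),
    duration_years = seq_len(n),
    latitude = 30, longitude = 110, mat = 10, map = 600,
    stringsAsFactors = FALSE
  )
}

# a small simulator config that keeps tests quick and fully clean
quick_sim_config <- function(seed = 1L, n_studies = 20L, ...) {
  meta_sim_config(n_studies = n_studies, seed = seed, ...)
}
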