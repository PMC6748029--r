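# Small, fast cohort configurations used across tests.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_control = 10,
                   n_per_subgroup = c(high = 8, normal = 8, low = 8),
                   n_mirna = 60,
                   library_size_range = c(5e4, 6e4),
                   nb_dispersion = 0.1,
                   seed = seed)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

# Near-noise-free world: tiny log-scale noise (exact zero would make the
# control reference degenerate), planted-normal subjects pinned to the
# distribution center, shifts just beyond the rule boundaries.
noisefree_config <- function(seed = 1, ...) {
  sim_config(n_control = 12,
             n_per_subgroup = c(high = 6, normal = 6, low = 6),
             cytokine_logsd = 1e-6,
             normal_sd_shrink = 0,
             ratio_shift = c(high = 1.001, normal = 1, low = 0.999),
             n_mirna = 40,
             effect_table = data.frame(subgroup = "high",
                                       mirna_index = 1:3, log2fc = 2),
             correlation_plan = data.frame(mirna_index = integer(),
                                           target = character(),
                                           stratum = character(),
                                           condition = character(),
                                           rho = numeric()),
             library_size_range = c(2e4, 3e4),
             seed = seed, ...)
}

flat_reference <- function(mu = 10, sigma = 2,
                           conditions = c("medium", "LPS", "zymosan",
                                          "CL097")) {
  structure(data.frame(condition = conditions, mean = mu, sd = sigma,
                       n = 30, stringsAsFactors = FALSE),
            class = c("control_reference", "data.frame"))
}

make_trace <- function(phase_means = c(baseline = 100, oligomycin = 40,
                                       FCCP = 160, antimycin_rotenone = 10),
                       reps = 3, noise = 0) {
  phases <- names(phase_means)
  data.frame(subject_id = "S1",
             phase = rep(phases, each = reps),
             replicate = rep(seq_len(reps), times = length(phases)),
             minutes = seq_len(reps * length(phases)) * 6,
             ocr_pmol_min = rep(phase_means, each = reps) +
               stats::rnorm(reps * length(phases), 0, noise),
             stringsAsFactors = FALSE)
}
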