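test_that("generation is deterministic for a fixed config and seed", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mirna_counts$counts, b$mirna_counts$counts)
  expect_identical(a$cytokine_table$pg_ml, b$cytokine_table$pg_ml)
  expect_identical(a$ocr_traces$ocr_pmol_min, b$ocr_traces$ocr_pmol_min)
  expect_identical(a$subjects, b$subjects)
  c <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$mirna_counts$counts, c$mirna_counts$counts))
})

test_that("cohort structure matches the configured sizes and invariants", {
  cfg <- small_config(seed = 2)
  co <- generate_cohort(cfg)
  expect_s3_class(co, "cohort_dataset")
  tab <- table(co$truth$labels)
  expect_equal(unname(tab[c("control", "high", "normal", "low")]),
               c(10L, 8L, 8L, 8L), ignore_attr = TRUE)
  expect_true(all(co$cytokine_table$pg_ml >= 0))
  expect_true(all(co$mirna_counts$counts >= 0))
  expect_type(co$mirna_counts$counts[1], "integer")
  expect_true(all(co$mirna_counts$library_size >= 5e4 &
                    co$mirna_counts$library_size <= 6e4))
  # every referenced subject exists
  expect_true(all(co$cytokine_table$subject_id %in% co$subjects$subject_id))
  expect_true(all(co$ocr_traces$subject_id %in% co$subjects$subject_id))
  expect_true(all(colnames(co$mirna_counts$counts) %in%
                    co$subjects$subject_id))
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(sim_config(nb_dispersion = -1), class = "serumir_config_error")
  expect_error(sim_config(ratio_shift = c(high = -2, normal = 1, low = 0.2)),
               class = "serumir_config_error")
  expect_error(sim_config(library_size_range = c(10, 5)),
               class = "serumir_config_error")
  expect_error(
    sim_config(n_mirna = 50,
               effect_table = data.frame(subgroup = "high",
                                         mirna_index = 99, log2fc = 2)),
    class = "serumir_config_error")
  expect_error(
    sim_config(effect_table = data.frame(subgroup = "high",
                                         mirna_index = c(1, 1),
                                         log2fc = c(2, -2))),
    class = "serumir_config_error")
  bad_ocr <- small_config()
  bad_ocr$ocr_params$phase_means[["FCCP"]] <- -5
  expect_error(validate_sim_config(bad_ocr), class = "serumir_config_error")
})

test_that("zero-noise cytokines land exactly at exp(logmean) times shift", {
  cfg <- sim_config(n_control = 2,
                    n_per_subgroup = c(high = 1, normal = 1, low = 1),
                    cytokine_logsd = 0, n_mirna = 40, seed = 3)
  labels <- c(S1 = "control", S2 = "high", S3 = "low")
  cyt <- simulate_cytokine_profiles(labels, cfg)
  pick <- function(sid, cond, k) {
    cyt$pg_ml[cyt$subject_id == sid & cyt$condition == cond &
                cyt$cytokine == k]
  }
  expect_equal(pick("S1", "LPS", "IL-1b"),
               exp(cfg$cytokine_logmean["LPS", "IL-1b"]))
  expect_equal(pick("S2", "LPS", "IL-1b"),
               exp(cfg$cytokine_logmean["LPS", "IL-1b"]) * 6)
  expect_equal(pick("S3", "zymosan", "IL-1b"),
               exp(cfg$cytokine_logmean["zymosan", "IL-1b"]) * 0.15)
  # IL-10 and bystander cytokines are never shifted
  expect_equal(pick("S2", "LPS", "IL-10"),
               exp(cfg$cytokine_logmean["LPS", "IL-10"]))
  expect_equal(pick("S2", "LPS", "TNF-a"),
               exp(cfg$cytokine_logmean["LPS", "TNF-a"]))
  expect_error(simulate_cytokine_profiles(c(S1 = "mystery"), cfg),
               class = "serumir_config_error")
})

test_that("control ratio moments match the closed-form lognormal values", {
  cfg <- sim_config(n_control = 4000,
                    n_per_subgroup = c(high = 0, normal = 0, low = 0),
                    condition_corr = 0, n_mirna = 40, seed = 11)
  labels <- stats::setNames(rep("control", 4000), sprintf("S%04d", 1:4000))
  cyt <- simulate_cytokine_profiles(labels, cfg)
  rt <- compute_ratio_table(cyt)
  x <- rt$ratio[rt$condition == "LPS"]
  s2 <- cfg$cytokine_logsd["LPS", "IL-1b"]^2 +
    cfg$cytokine_logsd["LPS", "IL-10"]^2
  m_theory <- exp(cfg$cytokine_logmean["LPS", "IL-1b"] -
                    cfg$cytokine_logmean["LPS", "IL-10"] + s2 / 2)
  s_theory <- m_theory * sqrt(exp(s2) - 1)
  se <- s_theory / sqrt(length(x))
  expect_lt(abs(mean(x) - m_theory), 3 * se)
  expect_lt(abs(stats::sd(x) - s_theory), 0.05 * s_theory)
})

test_that("detection-limit censoring substitutes and flags", {
  cfg <- sim_config(n_control = 3,
                    n_per_subgroup = c(high = 0, normal = 0, low = 0),
                    n_mirna = 40, detection_limit = 1e9, seed = 4)
  labels <- c(S1 = "control", S2 = "control", S3 = "control")
  cyt <- simulate_cytokine_profiles(labels, cfg)
  expect_true(all(cyt$censored))
  expect_true(all(cyt$pg_ml == 1e9))
})

test_that("simulated counts match NB moment formulas", {
  # 60 miRNAs x 400 samples gives 24k standardized cells; their mean is
  # N(0, 1/sqrt(24k)) under a correct generator
  cfg <- sim_config(n_control = 400,
                    n_per_subgroup = c(high = 0, normal = 0, low = 0),
                    n_mirna = 60, nb_dispersion = 0.2,
                    library_size_range = c(5e4, 5e4),
                    correlation_plan = data.frame(
                      mirna_index = integer(), target = character(),
                      stratum = character(), condition = character(),
                      rho = numeric()),
                    effect_table = data.frame(subgroup = "high",
                                              mirna_index = 1L, log2fc = 2),
                    seed = 21)
  labels <- stats::setNames(rep("control", 400), sprintf("S%04d", 1:400))
  cm <- simulate_mirna_counts(labels, cfg)
  p0 <- attr(cm, "abundance")
  mu <- p0 %o% as.numeric(cm$library_size)
  v <- mu + 0.2 * mu^2
  zcell <- (cm$counts - mu) / sqrt(v)
  expect_lt(abs(mean(zcell)), 3 / sqrt(length(zcell)))
  # per-miRNA empirical variance tracks the NB formula on average
  ratio <- rowMeans((cm$counts - mu)^2) / rowMeans(v)
  expect_gt(mean(ratio), 0.85)
  expect_lt(mean(ratio), 1.15)
})

test_that("dispersion -> 0 approaches the Poisson mean-variance limit", {
  cfg <- sim_config(n_control = 300,
                    n_per_subgroup = c(high = 0, normal = 0, low = 0),
                    n_mirna = 50, nb_dispersion = 0,
                    library_size_range = c(2e4, 2e4), seed = 5)
  labels <- stats::setNames(rep("control", 300), sprintf("S%03d", 1:300))
  cm <- simulate_mirna_counts(labels, cfg)
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, stats::var)
  keep <- m > 5
  expect_lt(abs(stats::median(v[keep] / m[keep]) - 1), 0.2)
})

test_that("planted log2FC of 1 doubles the group mean CPM", {
  n <- 200
  cfg <- sim_config(n_control = n,
                    n_per_subgroup = c(high = n, normal = 0, low = 0),
                    n_mirna = 60, nb_dispersion = 0.2,
                    effect_table = data.frame(subgroup = "high",
                                              mirna_index = 5L, log2fc = 1),
                    correlation_plan = data.frame(
                      mirna_index = integer(), target = character(),
                      stratum = character(), condition = character(),
                      rho = numeric()),
                    seed = 6)
  labels <- stats::setNames(rep(c("control", "high"), each = n),
                            sprintf("S%03d", 1:(2 * n)))
  cm <- simulate_mirna_counts(labels, cfg)
  x <- cpm(cm$counts, cm$library_size)
  fold <- mean(x[5, labels == "high"]) / mean(x[5, labels == "control"])
  expect_gt(fold, 1.7)
  expect_lt(fold, 2.3)
})

test_that("planted copula correlation is realized in rank correlation", {
  n <- 100
  cfg <- sim_config(n_control = 0,
                    n_per_subgroup = c(high = 0, normal = 0, low = n),
                    n_mirna = 40, nb_dispersion = 0.2,
                    effect_table = data.frame(subgroup = "high",
                                              mirna_index = 1L, log2fc = 2),
                    correlation_plan = data.frame(
                      mirna_index = 7L, target = "TNF-a", stratum = "low",
                      condition = "LPS", rho = 0.6,
                      stringsAsFactors = FALSE),
                    seed = 12)
  co <- generate_cohort(cfg)
  tnf <- co$cytokine_table
  tnf <- tnf[tnf$cytokine == "TNF-a" & tnf$condition == "LPS", ]
  v <- stats::setNames(tnf$pg_ml, tnf$subject_id)
  y <- co$mirna_counts$counts[7, names(v)]
  rho <- stats::cor(rank(y), rank(v))
  expect_lt(abs(rho - 0.6), 0.15)
})

test_that("OCR traces have 12 rows per subject in protocol order", {
  cfg <- small_config(seed = 9)
  labels <- c(A = "control", B = "high")
  ocr <- simulate_ocr_traces(labels, cfg)
  expect_equal(nrow(ocr), 24L)
  one <- ocr[ocr$subject_id == "A", ]
  expect_equal(one$phase,
               rep(c("baseline", "oligomycin", "FCCP",
                     "antimycin_rotenone"), each = 3))
  expect_equal(one$replicate, rep(1:3, 4))
  expect_true(all(diff(one$minutes) > 0))
})

test_that("noise-free OCR traces reproduce the configured phase means", {
  cfg <- small_config(seed = 10)
  cfg$ocr_params$noise_sd <- 0
  cfg$ocr_params$subject_logsd <- 0
  ocr <- simulate_ocr_traces(c(A = "control"), cfg)
  pv <- phase_summaries(ocr)
  p <- derive_parameters(pv)
  expect_equal(p$basal, 90)
  expect_equal(p$ALR, 60)
  expect_equal(p$PLR, 30)
  expect_equal(p$MRC, 150)
  expect_equal(p$RC, 60)
})

test_that("write/read round-trips a cohort", {
  cfg <- small_config(seed = 13)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$mirna_counts$counts, co$mirna_counts$counts)
  expect_equal(back$mirna_counts$library_size, co$mirna_counts$library_size,
               ignore_attr = TRUE)
  expect_equal(back$cytokine_table$pg_ml, co$cytokine_table$pg_ml)
  expect_equal(back$ocr_traces$ocr_pmol_min, co$ocr_traces$ocr_pmol_min)
  expect_equal(back$truth$labels, co$truth$labels)
  expect_equal(back$subjects$age, co$subjects$age)
})

test_that("reader errors name the missing column and tolerates extras", {
  cfg <- small_config(seed = 14)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  # extra unknown column: preserved and ignored
  cy <- utils::read.delim(file.path(dir, "cytokines.tsv"))
  cy$operator <- "tech_A"
  utils::write.table(cy, file.path(dir, "cytokines.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_s3_class(read_cohort(dir), "cohort_dataset")
  # missing required column: error names it
  cy$pg_ml <- NULL
  utils::write.table(cy, file.path(dir, "cytokines.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), "pg_ml", class = "serumir_parse_error")
})
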