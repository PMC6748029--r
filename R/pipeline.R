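# Targets table for the correlation screen: IL-1b/IL-10 ratio and selected
# cytokines per culture condition, respiration parameters per subject.
build_screen_targets <- function(cohort, respiration,
                                 cytokine_targets = c("IL-10", "TNF-a",
                                                      "CCL2"),
                                 respiration_targets = c("PLR", "ALR",
                                                         "MRC", "RC")) {
  rt <- compute_ratio_table(cohort$cytokine_table)
  ratio <- data.frame(subject_id = rt$subject_id, target = "ratio",
                      condition = rt$condition,
                      value = ifelse(rt$valid, rt$ratio, NA_real_),
                      stringsAsFactors = FALSE)
  cyt <- cohort$cytokine_table
  cyt <- cyt[cyt$cytokine %in% cytokine_targets, , drop = FALSE]
  cy <- data.frame(subject_id = cyt$subject_id, target = cyt$cytokine,
                   condition = cyt$condition, value = cyt$pg_ml,
                   stringsAsFactors = FALSE)
  resp <- do.call(rbind, lapply(respiration_targets, function(pp) {
    data.frame(subject_id = respiration$subject_id, target = pp,
               condition = NA_character_, value = respiration[[pp]],
               stringsAsFactors = FALSE)
  }))
  rbind(ratio, cy, resp)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> classify subjects into IL-1b/IL-10 subgroups ->
#' derive respiration parameters -> differential expression of each
#' subgroup vs controls plus all-ASD vs controls -> stratified correlation
#' screens of miRNA levels against ratio, cytokine and respiration targets
#' -> covariate screens (age, gender). Exactly one of `config` /
#' `input_dir` must be given. When `outdir` is set, every stage's table is
#' written there along with a machine-readable `summary.json`.
#'
#' @param config a [sim_config()] (simulate mode).
#' @param input_dir directory holding a written cohort (read mode).
#' @param outdir output directory, or `NULL` to skip writing.
#' @param rules a [rule_config()].
#' @param alpha nominal screen significance level.
#' @param fc_threshold,fdr_threshold DE thresholds.
#' @param seed optional override of the simulation seed.
#' @param screen_features `"de_significant"` (default: screen the union of
#'   DE-significant miRNAs, falling back to all when none) or `"all"`.
#' @param verbose emit per-stage progress messages.
#' @return list of class `serumir_run`: `cohort`, `classification`,
#'   `respiration`, `de` (named list of `de_result`), `de_summary`,
#'   `correlations`, `covariates`, `group_tests`, `summary`.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, outdir = NULL,
                         rules = rule_config(), alpha = 0.05,
                         fc_threshold = 2, fdr_threshold = 0.05,
                         seed = NULL,
                         screen_features = c("de_significant", "all"),
                         verbose = FALSE) {
  screen_features <- match.arg(screen_features)
  if (is.null(config) == is.null(input_dir)) {
    stop_serumir("provide exactly one of `config` (simulate) or `input_dir`",
                 class = "serumir_config_error")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(config)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    say("simulating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config)
  } else {
    say("reading cohort from %s", input_dir)
    cohort <- read_cohort(input_dir)
  }
  say("classifying %d subjects", nrow(cohort$subjects))
  cls <- classify_cohort(cohort, rules)
  say("deriving respiration parameters")
  resp <- respiration_table(cohort$ocr_traces)
  cm <- cohort$mirna_counts
  controls <- cohort$subjects$subject_id[
    tolower(cohort$subjects$diagnosis) == "control"]
  controls <- intersect(controls, colnames(cm$counts))
  lab <- stats::setNames(cls$labels$label, cls$labels$subject_id)
  comparisons <- list(
    high = names(lab)[lab == "high"],
    normal = names(lab)[lab == "normal"],
    low = names(lab)[lab == "low"],
    ASD = names(lab))
  de <- list()
  for (nm in names(comparisons)) {
    case <- intersect(comparisons[[nm]], colnames(cm$counts))
    if (length(case) < 2L || length(controls) < 2L) {
      say("skipping DE '%s' (too few samples)", nm)
      next
    }
    ids <- c(controls, case)
    grp <- factor(c(rep("control", length(controls)),
                    rep(nm, length(case))), levels = c("control", nm))
    say("DE: %s (n = %d) vs control (n = %d)", nm, length(case),
        length(controls))
    de[[nm]] <- de_analysis(cm$counts[, ids, drop = FALSE],
                            cm$library_size[ids], grp,
                            fc_threshold = fc_threshold,
                            fdr_threshold = fdr_threshold)
  }
  des <- de_summary(de, fc_threshold, fdr_threshold)
  # normalized CPM over all samples for the screens
  tmm_all <- tmm_factors(cm$counts, cm$library_size)
  ncpm <- normalized_cpm(cm$counts, factors = tmm_all)
  feats <- if (screen_features == "de_significant") {
    unique(unlist(lapply(de, function(d) d$feature[d$direction != "ns"])))
  } else {
    rownames(ncpm)
  }
  if (!length(feats)) feats <- rownames(ncpm)
  strata <- c(stats::setNames(rep("control", length(controls)), controls),
              lab[lab %in% c("high", "normal", "low")])
  say("correlation screen: %d features x %d strata", length(feats),
      length(unique(strata)))
  targets <- build_screen_targets(cohort, resp)
  correlations <- correlation_screen(ncpm[feats, , drop = FALSE], targets,
                                     strata, alpha = alpha)
  # covariate screens on the screened features, age + gender
  meta <- cohort$subjects[match(names(strata), cohort$subjects$subject_id), ]
  grp4 <- factor(strata, levels = c("control", "high", "normal", "low"))
  grp4 <- droplevels(grp4)
  cov <- NULL
  if (length(feats) && nlevels(grp4) >= 2L) {
    X <- ncpm[feats, names(strata), drop = FALSE]
    cov <- rbind(
      covariate_screen(X, grp4, meta$age, "age", alpha = alpha),
      if (length(unique(meta$gender)) > 1L)
        covariate_screen(X, grp4, factor(meta$gender), "gender",
                         alpha = alpha))
  }
  group_tests <- cohort_group_tests(cohort, lab)
  summary <- list(
    mode = if (is.null(input_dir)) "simulate" else "read",
    seed = if (!is.null(config)) config$seed else NULL,
    n_subjects = nrow(cohort$subjects),
    subgroup_sizes = as.list(table(lab)),
    n_controls = length(controls),
    de_comparisons = stats::setNames(
      lapply(seq_len(nrow(des)), function(i)
        list(n_up = des$n_up[i], n_down = des$n_down[i],
             n_tested = des$n_tested[i])),
      des$comparison),
    n_significant_correlations = sum(correlations$significant),
    parameters = list(alpha = alpha, fc_threshold = fc_threshold,
                      fdr_threshold = fdr_threshold))
  res <- structure(list(cohort = cohort, classification = cls,
                        respiration = resp, de = de, de_summary = des,
                        correlations = correlations, covariates = cov,
                        group_tests = group_tests, summary = summary),
                   class = "serumir_run")
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

cohort_group_tests <- function(cohort, lab) {
  sub <- cohort$subjects
  asd <- tolower(sub$diagnosis) != "control"
  rows <- list()
  add <- function(name, res, groups) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = res$test, comparison = name, statistic = res$statistic,
      p = res$p, groups = groups, stringsAsFactors = FALSE)
  }
  if (any(asd) && any(!asd)) {
    add("age ASD vs control", mann_whitney(sub$age[asd], sub$age[!asd]),
        "ASD,control")
    gt <- table(factor(asd, c(FALSE, TRUE)), factor(sub$gender))
    if (all(dim(gt) == 2L) && all(rowSums(gt) > 0) && all(colSums(gt) > 0)) {
      add("gender ASD vs control", fisher_exact(gt), "ASD,control")
    }
  }
  sg <- lab[lab %in% c("high", "normal", "low")]
  if (length(unique(sg)) >= 2L) {
    ages <- split(sub$age[match(names(sg), sub$subject_id)], sg)
    add("age across subgroups", kruskal_wallis(ages),
        paste(names(ages), collapse = ","))
    if ("NFA" %in% names(sub)) {
      nfa <- sub$NFA[match(names(sg), sub$subject_id)]
      tb <- table(sg, factor(nfa, c(FALSE, TRUE)))
      if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) {
        add("NFA across subgroups", chi_square(tb),
            paste(rownames(tb), collapse = ","))
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

write_run <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$classification$labels, file.path(outdir, "subgroups.tsv"))
  audit_path <- file.path(outdir, "classification_audit.jsonl")
  con <- file(audit_path, "w")
  for (a in res$classification$audit) {
    writeLines(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  write_tsv(res$respiration, file.path(outdir, "respiration.tsv"))
  cm <- res$cohort$mirna_counts
  tmm <- tmm_factors(cm$counts, cm$library_size)
  write_tsv(data.frame(sample_id = names(tmm$factors),
                       tmm_factor = unname(tmm$factors),
                       effective_lib = unname(tmm$effective_lib)),
            file.path(outdir, "tmm_factors.tsv"))
  ncpm <- normalized_cpm(cm$counts, factors = tmm)
  write_tsv(data.frame(mirna_id = rownames(ncpm), round(ncpm, 4),
                       check.names = FALSE),
            file.path(outdir, "cpm.tsv"))
  for (nm in names(res$de)) {
    d <- res$de[[nm]]
    d$neg_log10_fdr <- -log10(pmax(d$fdr, 1e-300))
    write_tsv(d, file.path(outdir, sprintf("de_%s_vs_control.tsv", nm)))
  }
  write_tsv(res$de_summary, file.path(outdir, "de_summary.tsv"))
  write_tsv(res$correlations, file.path(outdir, "correlations.tsv"))
  write_tsv(res$correlations[res$correlations$significant, , drop = FALSE],
            file.path(outdir, "correlations_significant.tsv"))
  if (!is.null(res$covariates)) {
    write_tsv(res$covariates, file.path(outdir, "covariate_screen.tsv"))
  }
  if (!is.null(res$group_tests)) {
    write_tsv(res$group_tests, file.path(outdir, "group_tests.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}

#' Human-readable run report
#'
#' Renders subgroup sizes, DE up/down counts per comparison and the top
#' correlations per stratum. Missing stages produce warnings, not errors.
#'
#' @param results a `serumir_run` object from [run_pipeline()].
#' @param top number of top correlations shown per stratum.
#' @return character vector of report lines (also printed invisibly by
#'   `print.serumir_run`).
#' @export
make_report <- function(results, top = 3L) {
  lines <- c("== serumir run report ==")
  s <- results$summary
  lines <- c(lines, sprintf("subjects: %d (%d controls)", s$n_subjects,
                            s$n_controls))
  sg <- unlist(s$subgroup_sizes)
  lines <- c(lines, paste0("subgroups: ",
                           paste(sprintf("%s=%d", names(sg), sg),
                                 collapse = ", ")))
  if (!is.null(results$de_summary) && nrow(results$de_summary)) {
    lines <- c(lines, "differential expression (vs control):")
    d <- results$de_summary
    lines <- c(lines, sprintf("  %-8s up %3d  down %3d  (of %d tested)",
                              d$comparison, d$n_up, d$n_down, d$n_tested))
  } else {
    warning("DE stage output missing from report", call. = FALSE)
  }
  co <- results$correlations
  if (!is.null(co) && nrow(co)) {
    lines <- c(lines, "top correlations per stratum:")
    for (st in unique(co$stratum)) {
      cs <- co[co$stratum == st & !is.na(co$p), , drop = FALSE]
      cs <- cs[order(cs$p), , drop = FALSE]
      n <- min(top, nrow(cs))
      if (!n) next
      lines <- c(lines, sprintf("  [%s]", st))
      lines <- c(lines, sprintf("    %s ~ %s (%s): rho %.3f, %s",
                                cs$feature[seq_len(n)],
                                cs$target[seq_len(n)],
                                cs$condition[seq_len(n)],
                                cs$rho[seq_len(n)],
                                cs$tier[seq_len(n)]))
    }
  } else {
    warning("correlation stage output missing from report", call. = FALSE)
  }
  lines
}

#' @export
print.serumir_run <- function(x, ...) {
  cat(paste(make_report(x), collapse = "\n"), "\n")
  invisible(x)
}
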