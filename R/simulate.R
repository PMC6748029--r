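#' Simulation configuration for a synthetic cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' describe a cohort with the structure of the study the pipeline targets:
#' 35 typically-developing controls and ASD subjects split into high (48),
#' normal (43) and low (25) innate-immune subgroups defined by monocyte
#' IL-1b/IL-10 ratios; cytokine production measured under four TLR-agonist
#' culture conditions (medium, LPS, zymosan, CL097); 4-phase Seahorse-style
#' oxygen-consumption traces with 3 measurements per phase; and
#' negative-binomial serum miRNA counts carrying the subgroup-specific
#' differential-expression pattern (high: 8 up + 9 down; normal: 0 up +
#' 10 down; low: 0 up + 18 down).
#'
#' Cytokine concentrations are lognormal per condition x cytokine, with a
#' shared within-subject component across conditions (`condition_corr`).
#' Subgroup membership is planted by multiplicatively shifting the
#' IL-1b/IL-10 ratio (`ratio_shift`, applied to IL-1b). Planted-normal
#' subjects draw their IL-1b/IL-10 latents with standard deviation shrunk by
#' `normal_sd_shrink`; without this no generative model can place subjects
#' inside a mean +/- 1 SD band with high probability (about 32% of i.i.d.
#' draws from any distribution fall outside it per condition).
#'
#' @param n_control number of control subjects.
#' @param n_per_subgroup named counts for the high/normal/low ASD subgroups.
#' @param conditions ordered culture-condition names.
#' @param cytokines cytokine panel; must include `"IL-1b"` and `"IL-10"`.
#' @param cytokine_logmean,cytokine_logsd condition x cytokine matrices of
#'   log-scale means / standard deviations (pg/ml scale after exp). Scalars
#'   are recycled.
#' @param condition_corr within-subject correlation of a cytokine's latent
#'   across conditions, in `[0, 1)`.
#' @param ratio_shift named multiplicative IL-1b/IL-10 ratio shifts for the
#'   high/normal/low subgroups; must be positive.
#' @param shift_conditions conditions in which the shift is applied.
#' @param normal_sd_shrink factor in `(0, 1]` shrinking the IL-1b/IL-10
#'   latent SD of planted-normal subjects.
#' @param target_purity minimum probability that a planted subject satisfies
#'   its subgroup's classification rule against the theoretical control
#'   reference; enforced by rejection sampling (at most `max_tries` redraws).
#' @param max_tries redraw cap for the purity rejection sampler.
#' @param n_mirna number of simulated miRNAs.
#' @param library_size_range integer pair; per-sample library sizes are drawn
#'   uniformly in this range.
#' @param nb_dispersion common negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param effect_table data frame with columns `subgroup`, `mirna_index`,
#'   `log2fc` giving the planted differential-expression pattern, or `NULL`
#'   for the default pattern (see [default_effect_table()]).
#' @param correlation_plan data frame with columns `mirna_index`, `target`,
#'   `stratum`, `condition`, `rho` of planted miRNA-phenotype rank
#'   correlations (Gaussian copula), or `NULL` for the default plan.
#' @param ocr_params list with `phase_means` (named: baseline, oligomycin,
#'   FCCP, antimycin_rotenone; pMol/min), `noise_sd` (per-measurement
#'   Gaussian noise) and `subject_logsd` (log-scale SD of a per-subject
#'   multiplicative respiration scale).
#' @param detection_limit pg/ml left-censoring floor for cytokines, or `NULL`
#'   (default) for no censoring; censored values are substituted by the limit
#'   and flagged.
#' @param seed integer root seed; every stage derives its own substream.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_control = 8, n_per_subgroup = c(high = 4, normal = 4, low = 4),
#'                   n_mirna = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_control = 35,
                       n_per_subgroup = c(high = 48, normal = 43, low = 25),
                       conditions = c("medium", "LPS", "zymosan", "CL097"),
                       cytokines = c("IL-1b", "IL-10", "TNF-a", "IL-6",
                                     "IL-12p40", "CCL2", "TGF-b", "sTNFRII"),
                       cytokine_logmean = NULL,
                       cytokine_logsd = 0.3,
                       condition_corr = 0.6,
                       ratio_shift = c(high = 6, normal = 1, low = 0.15),
                       shift_conditions = conditions,
                       normal_sd_shrink = 0.5,
                       target_purity = 0.9,
                       max_tries = 200L,
                       n_mirna = 500L,
                       library_size_range = c(5e5, 1e6),
                       nb_dispersion = 0.2,
                       effect_table = NULL,
                       correlation_plan = NULL,
                       ocr_params = list(
                         phase_means = c(baseline = 100, oligomycin = 40,
                                         FCCP = 160, antimycin_rotenone = 10),
                         noise_sd = 5, subject_logsd = 0.25),
                       detection_limit = NULL,
                       seed = 1L) {
  if (is.null(cytokine_logmean)) {
    # medium = unstimulated floor; TLR agonists induce a response.
    base <- c("IL-1b" = log(200), "IL-10" = log(50), "TNF-a" = log(300),
              "IL-6" = log(500), "IL-12p40" = log(60), "CCL2" = log(800),
              "TGF-b" = log(150), "sTNFRII" = log(120))
    med <- c("IL-1b" = log(20), "IL-10" = log(10), "TNF-a" = log(30),
             "IL-6" = log(50), "IL-12p40" = log(15), "CCL2" = log(200),
             "TGF-b" = log(100), "sTNFRII" = log(80))
    cytokine_logmean <- t(vapply(conditions, function(cc) {
      v <- if (cc == "medium") med[cytokines] else base[cytokines]
      v[is.na(v)] <- log(50)
      v
    }, numeric(length(cytokines))))
    dimnames(cytokine_logmean) <- list(conditions, cytokines)
  }
  cytokine_logmean <- expand_ck(cytokine_logmean, conditions, cytokines)
  cytokine_logsd <- expand_ck(cytokine_logsd, conditions, cytokines)
  if (is.null(effect_table)) effect_table <- default_effect_table(n_mirna)
  if (is.null(correlation_plan)) {
    # planted on miRNAs inside the default effect sets so the pipeline's
    # default screen (DE-significant features) exercises them
    correlation_plan <- data.frame(
      mirna_index = c(30L, 20L),
      target = c("TNF-a", "PLR"),
      stratum = c("low", "control"),
      condition = c("LPS", NA_character_),
      rho = c(0.6, -0.6),
      stringsAsFactors = FALSE)
    correlation_plan <-
      correlation_plan[correlation_plan$mirna_index <= n_mirna, , drop = FALSE]
  }
  cfg <- structure(list(
    n_control = as.integer(n_control),
    n_per_subgroup = n_per_subgroup,
    conditions = conditions, cytokines = cytokines,
    cytokine_logmean = cytokine_logmean, cytokine_logsd = cytokine_logsd,
    condition_corr = condition_corr, ratio_shift = ratio_shift,
    shift_conditions = shift_conditions,
    normal_sd_shrink = normal_sd_shrink, target_purity = target_purity,
    max_tries = as.integer(max_tries),
    n_mirna = as.integer(n_mirna),
    library_size_range = library_size_range,
    nb_dispersion = nb_dispersion, effect_table = effect_table,
    correlation_plan = correlation_plan, ocr_params = ocr_params,
    detection_limit = detection_limit, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

expand_ck <- function(x, conditions, cytokines) {
  if (length(x) == 1L) {
    x <- matrix(x, length(conditions), length(cytokines),
                dimnames = list(conditions, cytokines))
  }
  stopifnot(is.matrix(x))
  x[conditions, cytokines, drop = FALSE]
}

#' Default planted differential-expression pattern
#'
#' High subgroup: miRNAs 1-8 up, 9-17 down; normal: 18-27 down; low: 9-17 and
#' 28-36 down (18 miRNAs, partly shared with the high subgroup's
#' down-regulated set). Planted log2 fold changes are +/- 2.
#'
#' @param n_mirna total number of simulated miRNAs (must be >= 36).
#' @param log2fc absolute planted log2 fold change.
#' @return data frame with columns `subgroup`, `mirna_index`, `log2fc`.
#' @export
default_effect_table <- function(n_mirna = 500L, log2fc = 2) {
  if (n_mirna < 36L) {
    stop_serumir("default effect pattern needs n_mirna >= 36 (got %d)",
                 n_mirna, class = "serumir_config_error")
  }
  rbind(
    data.frame(subgroup = "high", mirna_index = 1:8, log2fc = log2fc),
    data.frame(subgroup = "high", mirna_index = 9:17, log2fc = -log2fc),
    data.frame(subgroup = "normal", mirna_index = 18:27, log2fc = -log2fc),
    data.frame(subgroup = "low", mirna_index = c(9:17, 28:36),
               log2fc = -log2fc))
}

validate_sim_config <- function(cfg) {
  err <- function(...) stop_serumir(..., class = "serumir_config_error")
  if (cfg$n_control < 0 || any(cfg$n_per_subgroup < 0)) {
    err("subject counts must be non-negative")
  }
  if (!all(c("high", "normal", "low") %in% names(cfg$n_per_subgroup))) {
    err("n_per_subgroup must name high, normal and low")
  }
  if (!all(c("IL-1b", "IL-10") %in% cfg$cytokines)) {
    err("cytokine panel must include IL-1b and IL-10")
  }
  if (cfg$nb_dispersion < 0) err("nb_dispersion must be positive")
  if (any(cfg$library_size_range < 1) ||
      cfg$library_size_range[2] < cfg$library_size_range[1]) {
    err("library_size_range must be an increasing pair of counts >= 1")
  }
  if (any(!is.finite(cfg$ratio_shift)) || any(cfg$ratio_shift <= 0)) {
    err("infeasible ratio_shift: shifts must be finite and > 0")
  }
  if (cfg$condition_corr < 0 || cfg$condition_corr >= 1) {
    err("condition_corr must be in [0, 1)")
  }
  et <- cfg$effect_table
  assert_columns(et, c("subgroup", "mirna_index", "log2fc"))
  if (any(et$mirna_index < 1L | et$mirna_index > cfg$n_mirna)) {
    err("effect_table miRNA indices must lie in [1, n_mirna]")
  }
  for (g in unique(et$subgroup)) {
    up <- et$mirna_index[et$subgroup == g & et$log2fc > 0]
    dn <- et$mirna_index[et$subgroup == g & et$log2fc < 0]
    if (length(intersect(up, dn))) {
      err("effect_table up and down sets overlap within subgroup '%s'", g)
    }
  }
  pm <- cfg$ocr_params$phase_means
  if (!all(c("baseline", "oligomycin", "FCCP", "antimycin_rotenone")
           %in% names(pm))) {
    err("ocr_params$phase_means must name all four injection phases")
  }
  if (any(pm < 0)) err("negative OCR phase mean")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_control, "controls;",
      paste(sprintf("%s=%d", names(x$n_per_subgroup), x$n_per_subgroup),
            collapse = ", "), "\n")
  cat("  ", x$n_mirna, "miRNAs, dispersion", x$nb_dispersion,
      "| seed", x$seed, "\n")
  invisible(x)
}

# ---- subject roster -------------------------------------------------------

simulate_subjects <- function(cfg, seed) {
  with_seed(seed, {
    labels <- c(rep("control", cfg$n_control),
                rep("high", cfg$n_per_subgroup[["high"]]),
                rep("normal", cfg$n_per_subgroup[["normal"]]),
                rep("low", cfg$n_per_subgroup[["low"]]))
    n <- length(labels)
    id <- sprintf("S%03d", seq_len(n))
    asd <- labels != "control"
    age <- ifelse(asd, stats::rnorm(n, 11.3, 5.4), stats::rnorm(n, 15.5, 7.8))
    age <- round(pmax(age, 2.2), 1)
    gender <- ifelse(stats::runif(n) < ifelse(asd, 0.838, 0.771), "M", "F")
    severity <- ifelse(asd,
                       sample(c("severe", "moderate", "mild"), n, TRUE,
                              prob = c(68, 24, 24)),
                       "not_applicable")
    flag <- function(p_asd) asd & stats::runif(n) < p_asd
    subjects <- data.frame(
      subject_id = id, diagnosis = ifelse(asd, "ASD", "control"),
      age = age, gender = gender, severity = severity,
      neuroleptics = flag(0.20), ADHD_meds = flag(0.25),
      AED = flag(0.29), SSRI = flag(0.15),
      NFA = flag(0.61), seizure = flag(0.12), SAD = flag(0.19),
      AR = flag(0.20), asthma = flag(0.13), GI = flag(0.70),
      sleep = flag(0.34),
      timepoint = 1L, stringsAsFactors = FALSE)
    names(labels) <- id
    list(subjects = subjects, labels = labels)
  })
}

# Theoretical control-reference ratio moments implied by the config
# (closed-form lognormal: the log-ratio is N(mu1 - mu10, sd1^2 + sd10^2)).
theoretical_reference <- function(cfg) {
  mu <- cfg$cytokine_logmean[, "IL-1b"] - cfg$cytokine_logmean[, "IL-10"]
  s2 <- cfg$cytokine_logsd[, "IL-1b"]^2 + cfg$cytokine_logsd[, "IL-10"]^2
  m <- exp(mu + s2 / 2)
  s <- m * sqrt(pmax(exp(s2) - 1, 0))
  data.frame(condition = cfg$conditions, mean = m, sd = s,
             n = Inf, stringsAsFactors = FALSE)
}

# ---- cytokine profiles ----------------------------------------------------

#' Simulate monocyte cytokine production
#'
#' Draws lognormal cytokine concentrations per subject x condition x cytokine
#' with a shared within-subject component across conditions. Subgroup shifts
#' are applied to IL-1b only (so the IL-1b/IL-10 ratio scales by the shift);
#' planted-normal subjects use a shrunken IL-1b/IL-10 latent SD. ASD subjects
#' are rejection-sampled (up to `max_tries` redraws of the IL-1b/IL-10
#' latents) until their ratio pattern satisfies their subgroup's
#' classification rule against the theoretical control reference, which
#' enforces the configured target purity.
#'
#' @param labels named character vector (subject id -> control/high/normal/low).
#' @param config a [sim_config()] object.
#' @param seed integer seed (defaults to a substream of `config$seed`).
#' @return long data frame (`subject_id`, `condition`, `cytokine`, `pg_ml`,
#'   `censored`) with an attribute `latents` holding the standardized latent
#'   draws used for correlation planting.
#' @export
simulate_cytokine_profiles <- function(labels, config,
                                       seed = derive_seed(config$seed,
                                                          "cytokines")) {
  cfg <- config
  bad <- setdiff(unique(labels), c("control", "high", "normal", "low"))
  if (length(bad)) {
    stop_serumir("unknown subgroup label(s): %s", paste(bad, collapse = ", "),
                 class = "serumir_config_error")
  }
  conds <- cfg$conditions; cyts <- cfg$cytokines
  r <- cfg$condition_corr
  ref <- theoretical_reference(cfg)
  rules <- rule_config()
  with_seed(seed, {
    out <- vector("list", length(labels))
    lat <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      sid <- names(labels)[i]; lab <- labels[[i]]
      shrink <- if (lab == "normal") cfg$normal_sd_shrink else 1
      draw_pair <- function() {
        # latent z for IL-1b and IL-10 only
        u <- stats::rnorm(2L)
        e <- matrix(stats::rnorm(2L * length(conds)), length(conds), 2L)
        sqrt(r) * matrix(u, length(conds), 2L, byrow = TRUE) +
          sqrt(1 - r) * e
      }
      shift <- if (lab %in% c("high", "low")) cfg$ratio_shift[[lab]] else 1
      sd1 <- cfg$cytokine_logsd[, "IL-1b"] * shrink
      sd10 <- cfg$cytokine_logsd[, "IL-10"] * shrink
      in_shift <- conds %in% cfg$shift_conditions
      ratio_of <- function(z) {
        exp((cfg$cytokine_logmean[, "IL-1b"] + sd1 * z[, 1L]) -
            (cfg$cytokine_logmean[, "IL-10"] + sd10 * z[, 2L])) *
          ifelse(in_shift, shift, 1)
      }
      z <- draw_pair()
      if (lab != "control" && any(sd1 > 0 | sd10 > 0) && all(ref$sd > 0)) {
        want <- lab
        for (k in seq_len(cfg$max_tries)) {
          got <- categorize_ratios(ratio_of(z), ref$mean, ref$sd, rules)
          if (got == want) break
          z <- draw_pair()
        }
      }
      # remaining cytokines: independent latents
      zz <- matrix(NA_real_, length(conds), length(cyts),
                   dimnames = list(conds, cyts))
      zz[, "IL-1b"] <- z[, 1L]; zz[, "IL-10"] <- z[, 2L]
      others <- setdiff(cyts, c("IL-1b", "IL-10"))
      for (k in others) {
        u <- stats::rnorm(1L)
        zz[, k] <- sqrt(r) * u + sqrt(1 - r) * stats::rnorm(length(conds))
      }
      sdm <- cfg$cytokine_logsd
      sdm[, "IL-1b"] <- sd1; sdm[, "IL-10"] <- sd10
      val <- exp(cfg$cytokine_logmean + sdm * zz)
      val[, "IL-1b"] <- val[, "IL-1b"] * ifelse(in_shift, shift, 1)
      censored <- matrix(FALSE, nrow(val), ncol(val))
      if (!is.null(cfg$detection_limit)) {
        censored <- val < cfg$detection_limit
        val[censored] <- cfg$detection_limit
      }
      out[[i]] <- data.frame(
        subject_id = sid,
        condition = rep(conds, times = length(cyts)),
        cytokine = rep(cyts, each = length(conds)),
        pg_ml = as.vector(val), censored = as.vector(censored),
        stringsAsFactors = FALSE)
      lat[[i]] <- zz
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    names(lat) <- names(labels)
    attr(tab, "latents") <- lat
    tab
  })
}

# ---- OCR traces -----------------------------------------------------------

#' Simulate Seahorse-style OCR traces
#'
#' Each subject gets 4 injection phases (baseline, oligomycin, FCCP,
#' antimycin A + rotenone) with 3 repeated measurements per phase over an
#' 18-minute window, Gaussian measurement noise, and a per-subject lognormal
#' respiration scale (so bioenergetic parameters vary across subjects while
#' efficiency ratios stay stable).
#'
#' @inheritParams simulate_cytokine_profiles
#' @param subject_scale_latent optional named standard-normal vector driving
#'   the per-subject respiration scale (used to plant miRNA-respiration
#'   correlations); drawn internally when `NULL`.
#' @return long data frame (`subject_id`, `phase`, `replicate`, `minutes`,
#'   `ocr_pmol_min`) with the subject scale latents as attribute
#'   `ocr_latents`.
#' @export
simulate_ocr_traces <- function(labels, config,
                                subject_scale_latent = NULL,
                                seed = derive_seed(config$seed, "ocr")) {
  cfg <- config
  pm <- cfg$ocr_params$phase_means
  if (any(pm < 0)) {
    stop_serumir("negative OCR phase mean", class = "serumir_config_error")
  }
  phases <- c("baseline", "oligomycin", "FCCP", "antimycin_rotenone")
  with_seed(seed, {
    if (is.null(subject_scale_latent)) {
      subject_scale_latent <- stats::rnorm(length(labels))
      names(subject_scale_latent) <- names(labels)
    }
    scl <- exp((cfg$ocr_params$subject_logsd %||% 0) *
               subject_scale_latent[names(labels)])
    out <- lapply(seq_along(labels), function(i) {
      sid <- names(labels)[i]
      mu <- rep(pm[phases] * scl[[i]], each = 3L)
      data.frame(
        subject_id = sid,
        phase = rep(phases, each = 3L),
        replicate = rep(1:3, times = 4L),
        minutes = rep((seq_along(phases) - 1L) * 18, each = 3L) +
          rep(c(6, 12, 18), times = 4L),
        ocr_pmol_min = mu + stats::rnorm(12L, 0, cfg$ocr_params$noise_sd),
        stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    attr(tab, "ocr_latents") <- subject_scale_latent
    tab
  })
}

# ---- miRNA counts ---------------------------------------------------------

#' Simulate a serum miRNA count matrix
#'
#' Counts are negative-binomial with mean = relative abundance x library size
#' x 2^log2fc for miRNAs in a subject's planted effect set (abundances are
#' renormalized per sample, as in real compositional sequencing data).
#' Library sizes are uniform on the configured range. When `target_latents`
#' is supplied, the configured correlation plan is realized through a
#' Gaussian copula: the NB count is drawn by quantile transform of a latent
#' correlated with the phenotype latent.
#'
#' @inheritParams simulate_cytokine_profiles
#' @param target_latents optional matrix (subjects x plan rows) of
#'   standardized phenotype latents, as assembled by [generate_cohort()].
#' @return an object of class `mirna_counts`: list with `counts` (integer
#'   matrix, miRNAs x samples), `library_size` (named vector), `mirna_ids`,
#'   `sample_ids`.
#' @export
simulate_mirna_counts <- function(labels, config, target_latents = NULL,
                                  seed = derive_seed(config$seed, "mirna")) {
  cfg <- config
  with_seed(seed, {
    n <- length(labels); G <- cfg$n_mirna
    mirna_ids <- sprintf("mir-%03d", seq_len(G))
    # heavy-tailed relative abundances, fixed across the cohort
    p0 <- exp(stats::rnorm(G, 0, 1.5)); p0 <- p0 / sum(p0)
    lib <- as.integer(round(stats::runif(
      n, cfg$library_size_range[1], cfg$library_size_range[2])))
    names(lib) <- names(labels)
    et <- cfg$effect_table
    lfc <- matrix(0, G, n)
    for (g in c("high", "normal", "low")) {
      rows <- et$subgroup == g
      if (any(rows)) {
        lfc[et$mirna_index[rows], labels == g] <- et$log2fc[rows]
      }
    }
    size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf
    counts <- matrix(0L, G, n, dimnames = list(mirna_ids, names(labels)))
    plan <- cfg$correlation_plan
    for (s in seq_len(n)) {
      mu <- p0 * 2^lfc[, s]
      mu <- mu / sum(mu) * lib[s]
      if (is.finite(size)) {
        y <- stats::rnbinom(G, size = size, mu = mu)
      } else {
        y <- stats::rpois(G, mu)
      }
      # copula-coupled miRNAs: overwrite with a quantile-transformed draw
      if (!is.null(target_latents) && nrow(plan)) {
        for (k in seq_len(nrow(plan))) {
          if (labels[[s]] != plan$stratum[k]) next
          zt <- target_latents[names(labels)[s], k]
          if (is.na(zt)) next
          rho <- plan$rho[k]
          zlat <- rho * zt + sqrt(1 - rho^2) * stats::rnorm(1L)
          g <- plan$mirna_index[k]
          if (is.finite(size)) {
            y[g] <- stats::qnbinom(stats::pnorm(zlat), size = size,
                                   mu = mu[g])
          } else {
            y[g] <- stats::qpois(stats::pnorm(zlat), mu[g])
          }
        }
      }
      counts[, s] <- as.integer(y)
    }
    structure(list(counts = counts, library_size = lib,
                   mirna_ids = mirna_ids, sample_ids = names(labels)),
              class = "mirna_counts", abundance = p0)
  })
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat("mirna_counts:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "samples; library sizes", min(x$library_size), "-",
      max(x$library_size), "\n")
  invisible(x)
}

# ---- cohort assembly ------------------------------------------------------

#' Generate a complete synthetic cohort
#'
#' Runs the subject, cytokine, OCR and miRNA simulators under substreams of
#' the configured root seed and bundles their outputs with a ground-truth
#' record (planted labels, effect table, correlation plan, seed). The result
#' is deterministic for a fixed configuration.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort_dataset`: list with `subjects`,
#'   `cytokine_table`, `ocr_traces`, `mirna_counts`, `truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  sub <- simulate_subjects(cfg, derive_seed(cfg$seed, "subjects"))
  labels <- sub$labels
  cyt <- simulate_cytokine_profiles(labels, cfg)
  ocr <- simulate_ocr_traces(labels, cfg)
  # assemble phenotype latents for the correlation plan
  plan <- cfg$correlation_plan
  tl <- NULL
  if (nrow(plan)) {
    lat <- attr(cyt, "latents")
    zocr <- attr(ocr, "ocr_latents")
    tl <- matrix(NA_real_, length(labels), nrow(plan),
                 dimnames = list(names(labels), NULL))
    resp <- NULL
    for (k in seq_len(nrow(plan))) {
      tg <- plan$target[k]
      if (tg %in% c("PLR", "ALR", "MRC", "RC", "basal", "non_mito")) {
        # couple to the measured parameter (not the latent scale), so the
        # planted rank correlation targets the observable variable
        if (is.null(resp)) resp <- respiration_table(ocr)
        v <- resp[[tg]][match(names(labels), resp$subject_id)]
        tl[, k] <- stats::qnorm((rank(v) - 0.5) / length(v))
      } else if (tg == "ratio") {
        cc <- plan$condition[k]
        s1 <- cfg$cytokine_logsd[cc, "IL-1b"]
        s10 <- cfg$cytokine_logsd[cc, "IL-10"]
        z <- vapply(lat, function(m) {
          s1 * m[cc, "IL-1b"] - s10 * m[cc, "IL-10"]
        }, numeric(1))
        tl[, k] <- z / max(sqrt(s1^2 + s10^2), .Machine$double.eps)
      } else if (tg %in% cfg$cytokines) {
        cc <- plan$condition[k]
        tl[, k] <- vapply(lat, function(m) m[cc, tg], numeric(1))
      } else {
        stop_serumir("correlation_plan target '%s' not recognized", tg,
                     class = "serumir_config_error")
      }
    }
  }
  cnt <- simulate_mirna_counts(labels, cfg, target_latents = tl)
  truth <- list(labels = labels, effect_table = cfg$effect_table,
                correlation_plan = plan, seed = cfg$seed)
  structure(list(subjects = sub$subjects, cytokine_table = cyt,
                 ocr_traces = ocr, mirna_counts = cnt, truth = truth),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(factor(x$truth$labels %||% rep("?", nrow(x$subjects)),
                      levels = c("control", "high", "normal", "low")))
  cat("cohort_dataset:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  print(x$mirna_counts)
  invisible(x)
}

# ---- persistence ----------------------------------------------------------

#' Write / read a cohort to a directory of plain-text tables
#'
#' Layout: `subjects.tsv`, `cytokines.tsv` (long), `ocr.tsv`, `counts.tsv`
#' (miRNA rows, first column `mirna_id`), `library_sizes.tsv` and
#' `truth.json` (when ground truth is present). `read_cohort()` tolerates
#' unknown extra columns but errors, naming the file and column, when a
#' required column is missing.
#'
#' @param dataset a `cohort_dataset`.
#' @param directory target directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `cohort_dataset`.
#' @export
write_cohort <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dataset$subjects, file.path(directory, "subjects.tsv"))
  cyt <- dataset$cytokine_table
  attr(cyt, "latents") <- NULL
  write_tsv(cyt, file.path(directory, "cytokines.tsv"))
  ocr <- dataset$ocr_traces
  attr(ocr, "ocr_latents") <- NULL
  write_tsv(ocr, file.path(directory, "ocr.tsv"))
  cm <- dataset$mirna_counts
  write_tsv(data.frame(mirna_id = cm$mirna_ids, cm$counts,
                       check.names = FALSE),
            file.path(directory, "counts.tsv"))
  write_tsv(data.frame(sample_id = names(cm$library_size),
                       library_size = unname(cm$library_size)),
            file.path(directory, "library_sizes.tsv"))
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    tr$labels <- as.list(tr$labels)
    jsonlite::write_json(tr, file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  subjects <- read_tsv_checked(
    file.path(directory, "subjects.tsv"),
    required = c("subject_id", "diagnosis", "timepoint"))
  cyt <- read_tsv_checked(
    file.path(directory, "cytokines.tsv"),
    required = c("subject_id", "condition", "cytokine", "pg_ml"))
  if (is.null(cyt$censored)) cyt$censored <- FALSE
  ocr <- read_tsv_checked(
    file.path(directory, "ocr.tsv"),
    required = c("subject_id", "phase", "replicate", "minutes",
                 "ocr_pmol_min"))
  cn <- read_tsv_checked(file.path(directory, "counts.tsv"),
                         required = "mirna_id")
  counts <- as.matrix(cn[, setdiff(names(cn), "mirna_id"), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cn$mirna_id
  libf <- file.path(directory, "library_sizes.tsv")
  if (file.exists(libf)) {
    lt <- read_tsv_checked(libf, required = c("sample_id", "library_size"))
    lib <- stats::setNames(lt$library_size, lt$sample_id)[colnames(counts)]
  } else {
    lib <- colSums(counts)
  }
  ids <- unique(c(subjects$subject_id, cyt$subject_id, ocr$subject_id,
                  colnames(counts)))
  unknown <- setdiff(ids, subjects$subject_id)
  if (length(unknown)) {
    stop_serumir("subject id(s) %s referenced but absent from subjects.tsv",
                 paste(unknown, collapse = ", "),
                 class = "serumir_parse_error")
  }
  truthf <- file.path(directory, "truth.json")
  truth <- NULL
  if (file.exists(truthf)) {
    truth <- jsonlite::read_json(truthf, simplifyVector = TRUE)
    truth$labels <- unlist(truth$labels)
  }
  structure(list(
    subjects = subjects, cytokine_table = cyt, ocr_traces = ocr,
    mirna_counts = structure(list(counts = counts,
                                  library_size = lib,
                                  mirna_ids = rownames(counts),
                                  sample_ids = colnames(counts)),
                             class = "mirna_counts"),
    truth = truth), class = "cohort_dataset")
}
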