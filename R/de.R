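#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`. Library size is the
#' total number of mapped reads per sample, stored independently of the
#' column sums (mapped reads need not all be miRNA-assigned).
#'
#' @param counts non-negative count matrix (features x samples).
#' @param library_sizes per-sample totals (> 0).
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  if (length(library_sizes) != ncol(counts)) {
    stop_serumir("library_sizes length (%d) != number of samples (%d)",
                 length(library_sizes), ncol(counts),
                 class = "serumir_config_error")
  }
  if (any(library_sizes <= 0)) {
    stop_serumir("library sizes must be > 0", class = "serumir_config_error")
  }
  sweep(counts, 2L, library_sizes, "/") * 1e6
}

#' Low-expression filter anchored to the smallest library
#'
#' The CPM threshold corresponds to a minimum raw count of `min_raw` in the
#' smallest library: `threshold = min_raw / min(library_sizes) * 1e6`. A
#' feature is kept when its CPM reaches the threshold in at least
#' `ceiling(min_samples_frac * n_small)` samples, where `n_small` is the
#' size of the smaller comparison group (all samples when `groups` is
#' `NULL`).
#'
#' @inheritParams cpm
#' @param groups optional two-group factor defining the comparison.
#' @param min_raw minimum raw count anchoring the CPM threshold.
#' @param min_samples_frac fraction of the smaller group that must pass.
#' @return list with `counts`, `library_sizes`, `kept`, `dropped`
#'   (feature names) and `threshold_cpm`.
#' @export
filter_low_expression <- function(counts, library_sizes, groups = NULL,
                                  min_raw = 5, min_samples_frac = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) {
    stop_serumir("need >= 2 samples to filter", class = "serumir_config_error")
  }
  threshold <- min_raw / min(library_sizes) * 1e6
  n_small <- if (is.null(groups)) ncol(counts) else min(table(groups))
  n_req <- max(1L, ceiling(min_samples_frac * n_small))
  x <- cpm(counts, library_sizes)
  keep <- rowSums(x >= threshold) >= n_req
  list(counts = counts[keep, , drop = FALSE],
       library_sizes = library_sizes,
       kept = rownames(counts)[keep],
       dropped = rownames(counts)[!keep],
       threshold_cpm = threshold)
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors from doubly trimmed, precision-weighted
#' log-ratios against a reference sample. The reference is the sample whose
#' 75th-percentile CPM is closest to the mean 75th percentile. For each
#' sample, M (log2 ratio of library-normalized counts) and A (average log2
#' abundance) are computed over features positive in both sample and
#' reference; the upper and lower `trim_m` tails of M and `trim_a` tails of
#' A are removed; the factor is 2 to the power of the weighted mean of the
#' surviving M values, with weights the inverse asymptotic binomial
#' variances. Factors are rescaled to geometric mean 1, so effective library
#' size = library size x factor.
#'
#' @inheritParams cpm
#' @param trim_m,trim_a symmetric tail fractions trimmed from M and A.
#' @return list of class `tmm_factors`: `factors` (named, geometric mean 1),
#'   `ref_sample`, `effective_lib`.
#' @export
tmm_factors <- function(counts, library_sizes, trim_m = 0.30,
                        trim_a = 0.05) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  library_sizes <- stats::setNames(as.numeric(library_sizes),
                                   names(library_sizes))
  ns <- ncol(counts)
  if (ns < 2L) {
    stop_serumir("TMM needs >= 2 samples", class = "serumir_config_error")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ns))
  }
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(counts)
  q75 <- apply(cpm(counts, library_sizes), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  yr <- counts[, ref]; Lr <- library_sizes[ref]
  f <- vapply(seq_len(ns), function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; Ls <- library_sizes[s]
    pos <- ys > 0 & yr > 0
    if (!any(pos)) {
      stop_serumir("sample %s shares no positive-count feature with the reference",
                   colnames(counts)[s], class = "serumir_config_error")
    }
    m <- log2((ys[pos] / Ls) / (yr[pos] / Lr))
    a <- 0.5 * log2((ys[pos] / Ls) * (yr[pos] / Lr))
    v <- (Ls - ys[pos]) / (Ls * ys[pos]) + (Lr - yr[pos]) / (Lr * yr[pos])
    n <- length(m)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    # average-rank ties keep a tied block together across the trim boundary
    rM <- rank(m)
    rA <- rank(a)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || all(v[keep] == 0)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / geomean(f)
  names(f) <- colnames(counts)
  structure(list(factors = f, ref_sample = colnames(counts)[ref],
                 effective_lib = library_sizes * f),
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM factors (ref ", x$ref_sample, "): ",
      paste(sprintf("%.3f", x$factors), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' TMM-normalized CPM
#'
#' CPM computed against effective library sizes (library size x TMM factor).
#'
#' @inheritParams cpm
#' @param factors a [tmm_factors()] object, or a named numeric vector of
#'   factors.
#' @export
normalized_cpm <- function(counts, library_sizes = NULL, factors) {
  if (inherits(factors, "tmm_factors")) {
    eff <- factors$effective_lib
  } else {
    if (is.null(library_sizes)) {
      stop_serumir("library_sizes required with bare factors",
                   class = "serumir_config_error")
    }
    eff <- library_sizes * factors
  }
  cpm(counts, eff)
}

# ---- library-size equalization -------------------------------------------

# Map counts to a common library size (geometric mean of the input sizes).
# Proportional scaling with rounding when sizes are within 20% of each
# other; otherwise a mid-p NB quantile map per cell, feature means taken
# proportional to overall feature abundance. Route stored as attribute.
equalize_counts <- function(counts, library_sizes, phi = 0.1) {
  counts <- as.matrix(counts)
  common <- geomean(library_sizes)
  if (max(library_sizes) / min(library_sizes) <= 1.2) {
    out <- round(sweep(counts, 2L, common / library_sizes, "*"))
    attr(out, "route") <- "proportional"
    attr(out, "common_lib") <- common
    return(out)
  }
  p <- rowSums(counts) / sum(library_sizes)
  out <- counts
  for (s in seq_len(ncol(counts))) {
    mu_in <- p * library_sizes[s]
    mu_out <- p * common
    y <- counts[, s]
    pos <- mu_in > 0
    u <- rep(0.5, length(y))
    if (phi > 0) {
      size <- 1 / phi
      u[pos] <- stats::pnbinom(y[pos] - 1, size = size, mu = mu_in[pos]) +
        0.5 * stats::dnbinom(y[pos], size = size, mu = mu_in[pos])
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      out[pos, s] <- stats::qnbinom(u[pos], size = size, mu = mu_out[pos])
    } else {
      u[pos] <- stats::ppois(y[pos] - 1, mu_in[pos]) +
        0.5 * stats::dpois(y[pos], mu_in[pos])
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      out[pos, s] <- stats::qpois(u[pos], mu_out[pos])
    }
    out[!pos, s] <- 0
  }
  attr(out, "route") <- "quantile"
  attr(out, "common_lib") <- common
  out
}

# ---- common dispersion ----------------------------------------------------

# Conditional log-likelihood of equal-library NB counts given their group
# totals, summed over features and groups; terms constant in phi dropped.
cond_loglik <- function(counts, groups, phi) {
  if (phi <= 0) return(-Inf)
  r <- 1 / phi
  ll <- 0
  for (g in levels(groups)) {
    Y <- counts[, groups == g, drop = FALSE]
    n <- ncol(Y)
    if (n < 2L) next
    z <- rowSums(Y)
    ll <- ll + sum(rowSums(lgamma(Y + r)) + lgamma(n * r) -
                   lgamma(z + n * r) - n * lgamma(r))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the summed per-feature conditional log-likelihood of the counts
#' given their group totals under an NB model with a single dispersion
#' shared across features (variance = mu + phi mu^2), after mapping counts
#' to a common library size (see the estimate's `metadata$route`). The
#' search is a log-scale grid on `[1e-4, 4]` refined by golden-section;
#' `phi = 0` is returned when the likelihood is maximized at the lower
#' boundary (the Poisson limit).
#'
#' @inheritParams cpm
#' @param groups factor of group memberships; at least one group must have
#'   >= 2 samples.
#' @param grid_bounds lower/upper bounds of the dispersion grid.
#' @return list of class `dispersion_estimate`: `phi` and `metadata`
#'   (`route`, `grid_bounds`, `converged`, `boundary`).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       library_sizes = NULL,
                                       grid_bounds = c(1e-4, 4)) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (all(table(groups) < 2L)) {
    stop_serumir("dispersion estimation needs a group with >= 2 samples",
                 class = "serumir_config_error")
  }
  route <- "none"
  if (!is.null(library_sizes) &&
      diff(range(library_sizes)) > .Machine$double.eps) {
    eq <- equalize_counts(counts, library_sizes, phi = 0.1)
    route <- attr(eq, "route")
    counts <- eq
  }
  grid <- exp(seq(log(grid_bounds[1]), log(grid_bounds[2]), length.out = 25))
  ll <- vapply(grid, function(p) cond_loglik(counts, groups, p), numeric(1))
  best <- which.max(ll)
  boundary <- FALSE
  if (best == 1L) {
    # compare against the Poisson limit via an even smaller dispersion
    if (cond_loglik(counts, groups, grid[1] / 10) >= ll[1]) {
      return(structure(list(
        phi = 0,
        metadata = list(route = route, grid_bounds = grid_bounds,
                        converged = TRUE, boundary = TRUE)),
        class = "dispersion_estimate"))
    }
  }
  lo <- grid[max(best - 1L, 1L)]; hi <- grid[min(best + 1L, length(grid))]
  opt <- stats::optimize(function(lp) cond_loglik(counts, groups, exp(lp)),
                         interval = log(c(lo, hi)), maximum = TRUE,
                         tol = 1e-5)
  phi <- exp(opt$maximum)
  if (best == length(grid)) boundary <- TRUE
  structure(list(phi = phi,
                 metadata = list(route = route, grid_bounds = grid_bounds,
                                 converged = TRUE, boundary = boundary)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common NB dispersion phi = %.4g (equalization: %s)\n",
              x$phi, x$metadata$route))
  invisible(x)
}

# ---- exact test -----------------------------------------------------------

# Two-sided conditional exact p for one feature: condition on the total
# count; the two group sums are NB with size n_i / phi and mean
# proportional to group size (equal per-sample libraries). p sums the
# conditional probabilities of all splits at most as probable as the
# observed one ("small-p" rule). phi = 0 reduces to the conditional
# binomial test.
exact_nb_p <- function(s1, s2, n1, n2, phi, window_max = 4096L) {
  t <- s1 + s2
  if (t == 0) return(NA_real_)
  mt <- t / (n1 + n2)
  if (t <= window_max) {
    # exact: every split enumerated at unit steps
    y1 <- 0:t
  } else {
    # the conditional distribution is smooth at this scale; evaluate it on
    # a strided grid (relative quadrature error ~ (stride/sd)^2, < 1e-6
    # at 20k points) with the observed split included exactly
    y1 <- unique(round(seq(0, t, length.out = 20001)))
    y1 <- sort(unique(c(y1, s1)))
  }
  if (phi > 0) {
    lp <- stats::dnbinom(y1, size = n1 / phi, mu = n1 * mt, log = TRUE) +
      stats::dnbinom(t - y1, size = n2 / phi, mu = n2 * mt, log = TRUE)
  } else {
    lp <- stats::dpois(y1, n1 * mt, log = TRUE) +
      stats::dpois(t - y1, n2 * mt, log = TRUE)
  }
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p_obs <- pr[match(s1, y1)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Conditioned negative-binomial exact test
#'
#' Per-feature two-sided exact test of equal relative abundance between two
#' groups with equalized library sizes and a common dispersion. For each
#' feature the total count is fixed and the conditional distribution of the
#' first group's sum (the ratio of two NB sums with sizes `n_i / phi`) is
#' enumerated; the p-value accumulates all splits whose conditional
#' probability does not exceed the observed split's. A feature with total
#' count 0 gets p = 1 and a flag.
#'
#' @inheritParams cpm
#' @param groups two-level factor.
#' @param phi common dispersion (>= 0; 0 gives the conditional binomial
#'   exact test).
#' @param library_sizes optional; when given and unequal, counts are first
#'   equalized with [estimate_common_dispersion()]'s mapping.
#' @return data frame: `feature`, `sum1`, `sum2`, `p`, `zero_total`.
#' @export
exact_test_de <- function(counts, groups, phi, library_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) {
    stop_serumir("exact test needs exactly two groups (got %d)",
                 nlevels(groups), class = "serumir_config_error")
  }
  if (!is.null(library_sizes) &&
      diff(range(library_sizes)) > .Machine$double.eps) {
    counts <- equalize_counts(counts, library_sizes, phi = max(phi, 1e-4))
  }
  g1 <- groups == levels(groups)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  s1 <- rowSums(counts[, g1, drop = FALSE])
  s2 <- rowSums(counts[, !g1, drop = FALSE])
  p <- vapply(seq_along(s1), function(i) {
    exact_nb_p(s1[i], s2[i], n1, n2, phi)
  }, numeric(1))
  zero <- is.na(p)
  p[zero] <- 1
  data.frame(feature = rownames(counts) %||% as.character(seq_along(s1)),
             sum1 = s1, sum2 = s2, p = p, zero_total = zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_serumir("p-values must lie in [0, 1]", class = "serumir_config_error")
  }
  n <- length(pvalues)
  if (n <= 1L) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

# ---- full DE analysis & summary ------------------------------------------

#' Differential expression between one group and controls
#'
#' Full pipeline for one two-group comparison: low-expression filter
#' anchored to the smallest library, TMM normalization, common-dispersion
#' estimation, conditioned NB exact test, BH adjustment, and fold changes
#' from group-mean TMM-normalized CPM with a 0.5-count prior. Direction
#' calls use `fold change > fc_threshold` and `FDR < fdr_threshold`.
#'
#' @inheritParams cpm
#' @param groups two-level factor; the FIRST level is the reference
#'   (control) group, the second the case group.
#' @param fc_threshold fold-change threshold on the natural scale.
#' @param fdr_threshold BH FDR threshold.
#' @param min_raw,min_samples_frac see [filter_low_expression()].
#' @param phi optional fixed dispersion (estimated when `NULL`).
#' @return data frame of class `de_result`: `feature`, `mean_cpm_ref`,
#'   `mean_cpm_case`, `log2fc`, `p`, `fdr`, `direction` (up/down/ns), with
#'   attributes `phi`, `tmm`, `comparison`.
#' @export
de_analysis <- function(counts, library_sizes, groups, fc_threshold = 2,
                        fdr_threshold = 0.05, min_raw = 5,
                        min_samples_frac = 1, phi = NULL) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) {
    stop_serumir("de_analysis needs exactly two groups",
                 class = "serumir_config_error")
  }
  flt <- filter_low_expression(counts, library_sizes, groups,
                               min_raw = min_raw,
                               min_samples_frac = min_samples_frac)
  y <- flt$counts
  if (!nrow(y)) {
    out <- data.frame(feature = character(), mean_cpm_ref = numeric(),
                      mean_cpm_case = numeric(), log2fc = numeric(),
                      p = numeric(), fdr = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    class(out) <- c("de_result", "data.frame")
    return(out)
  }
  tmm <- tmm_factors(y, library_sizes)
  eff <- tmm$effective_lib
  if (is.null(phi)) {
    disp <- estimate_common_dispersion(y, groups, library_sizes = eff)
    phi <- disp$phi
  }
  eq <- equalize_counts(y, eff, phi = max(phi, 1e-4))
  et <- exact_test_de(eq, groups, phi)
  ncpm <- cpm(y, eff)
  ref <- groups == levels(groups)[1L]
  m_ref <- rowMeans(ncpm[, ref, drop = FALSE])
  m_case <- rowMeans(ncpm[, !ref, drop = FALSE])
  prior <- 0.5 / mean(eff) * 1e6
  log2fc <- log2((m_case + prior) / (m_ref + prior))
  fdr <- bh_adjust(et$p)
  direction <- rep("ns", nrow(y))
  sig <- fdr < fdr_threshold & abs(log2fc) > log2(fc_threshold)
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"
  out <- data.frame(feature = rownames(y), mean_cpm_ref = m_ref,
                    mean_cpm_case = m_case, log2fc = log2fc, p = et$p,
                    fdr = fdr, direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "phi") <- phi
  attr(out, "tmm") <- tmm
  attr(out, "comparison") <- paste(levels(groups)[2L], "vs",
                                   levels(groups)[1L])
  class(out) <- c("de_result", "data.frame")
  out
}

#' Summarize up/down-regulated feature counts per comparison
#'
#' @param de_results a single `de_result` or a named list of them.
#' @param fc_threshold,fdr_threshold thresholds re-applied to the stored
#'   fold changes and FDR values.
#' @return data frame: `comparison`, `n_up`, `n_down`, `n_tested`.
#' @export
de_summary <- function(de_results, fc_threshold = 2, fdr_threshold = 0.05) {
  if (inherits(de_results, "de_result")) {
    de_results <- list(de_results)
    names(de_results) <- attr(de_results[[1L]], "comparison") %||% "comparison"
  }
  out <- do.call(rbind, lapply(names(de_results), function(nm) {
    d <- de_results[[nm]]
    sig <- d$fdr < fdr_threshold & abs(d$log2fc) > log2(fc_threshold)
    data.frame(comparison = nm,
               n_up = sum(sig & d$log2fc > 0),
               n_down = sum(sig & d$log2fc < 0),
               n_tested = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
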