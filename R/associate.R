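# cache for the exact-permutation index matrices (n <= 9)
.perm_cache <- new.env(parent = emptyenv())

all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with a tie-corrected p-value
#'
#' Rho is the Pearson correlation of mid-ranks (tie-corrected by
#' construction). The p-value uses the t approximation with `n - 2` degrees
#' of freedom, or an exact two-sided permutation enumeration when
#' `n <= exact_n` (default 9). Pairs with a missing value in either vector
#' are dropped.
#'
#' @param x,y paired numeric vectors.
#' @param exact_n largest n for which the exact permutation p is used.
#' @return list: `rho`, `p`, `n`, `method`, `flag` (`"zero_variance"` when
#'   either vector is constant, in which case rho and p are `NA`).
#' @export
spearman_cor <- function(x, y, exact_n = 9L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    stop_serumir("spearman needs >= 4 paired observations (got %d)", n,
                 class = "serumir_config_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "none",
                flag = "zero_variance"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    P <- all_perms(n)
    ry_mat <- matrix(ry[P], nrow(P), n)
    rho_perm <- as.vector(
      (ry_mat %*% rx - n * mean(rx) * mean(ry)) /
        ((n - 1) * stats::sd(rx) * stats::sd(ry)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method, flag = NULL)
}

#' Significance tier string for a p-value
#'
#' The smallest tier among `<0.0001`, `<0.0005`, `<0.001`, `<0.005`,
#' `<0.01`, `<0.05` containing the p-value, or `"ns"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of tiers.
#' @export
tier_pvalue <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_serumir("p-values must lie in [0, 1]", class = "serumir_config_error")
  }
  cuts <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2)
  labs <- c("<0.0001", "<0.0005", "<0.001", "<0.005", "<0.01", "<0.05")
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    i <- which(pp < cuts)
    if (length(i)) labs[i[1L]] else "ns"
  }, character(1))
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-tailed p by enumeration of all rank allocations when the
#' combined sample size is at most `exact_max`; otherwise the normal
#' approximation with tie correction (no continuity correction, so that the
#' squared z statistic matches the two-group Kruskal-Wallis chi-square).
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined n for exact enumeration.
#' @return list of class `serumir_test`: `test`, `statistic` (U for the
#'   first sample), `p`, `n`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 10L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop_serumir("both groups must be non-empty",
                 class = "serumir_config_error")
  }
  if (n1 < 3L || n2 < 3L) {
    warning("Mann-Whitney with a group below n = 3", call. = FALSE)
  }
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    method <- "exact_enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  structure(list(test = "mann_whitney", statistic = U, p = p,
                 n = c(n1, n2), method = method),
            class = "serumir_test")
}

#' Kruskal-Wallis test with tie correction
#'
#' @param groups list of numeric samples (>= 2 groups, all non-empty).
#' @return list of class `serumir_test`: `test`, `statistic` (H), `p`,
#'   `n`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L || any(lengths(groups) == 0L)) {
    stop_serumir("kruskal_wallis needs >= 2 non-empty groups",
                 class = "serumir_config_error")
  }
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups))
  gi <- rep(seq_along(groups), n)
  Rj <- tapply(r, gi, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  ties <- table(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C > 0) H <- H / C
  df <- length(groups) - 1L
  structure(list(test = "kruskal_wallis", statistic = H,
                 p = stats::pchisq(H, df, lower.tail = FALSE),
                 n = unname(n), df = df),
            class = "serumir_test")
}

#' Fisher exact test (2x2, two-sided by probability summation)
#'
#' Enumerates the hypergeometric distribution of the top-left cell over its
#' support and sums the probabilities of all tables at most as probable as
#' the observed one.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts.
#' @return list of class `serumir_test`: `test`, `statistic` (sample odds
#'   ratio), `p`, `n`.
#' @export
fisher_exact <- function(table2x2) {
  tab <- as.matrix(table2x2)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab))) {
    stop_serumir("fisher_exact needs a 2x2 table of non-negative integers",
                 class = "serumir_config_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_serumir("degenerate margins: a row or column sums to zero",
                 class = "serumir_config_error")
  }
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - nn):min(k, m)
  pr <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(tab[1, 1], m, nn, k)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(test = "fisher_exact", statistic = or, p = p,
                 n = sum(tab)), class = "serumir_test")
}

#' Pearson chi-square test for an r x c frequency table
#'
#' No continuity correction.
#'
#' @param table r x c matrix of non-negative counts.
#' @return list of class `serumir_test`: `test`, `statistic` (X-squared),
#'   `p`, `df`, `n`.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) {
    stop_serumir("counts must be non-negative",
                 class = "serumir_config_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_serumir("degenerate margins: a row or column sums to zero",
                 class = "serumir_config_error")
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(test = "chi_square", statistic = X2,
                 p = stats::pchisq(X2, df, lower.tail = FALSE),
                 df = df, n = sum(tab)), class = "serumir_test")
}

#' @export
print.serumir_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}

#' Stratified Spearman correlation screen
#'
#' For every stratum x target (x condition) x feature, computes the Spearman
#' correlation between feature levels and the target variable across the
#' stratum's subjects. P-values are nominal (no multiplicity adjustment,
#' matching tiered reporting practice); a BH column over the full table is
#' emitted alongside for modern use. Strata with fewer than `min_n`
#' subjects are skipped with a warning.
#'
#' @param feature_matrix numeric matrix (features x subjects, subject ids as
#'   column names), e.g. TMM-normalized miRNA CPM.
#' @param targets long data frame with columns `subject_id`, `target`,
#'   `condition` (`NA` for per-subject targets such as respiration
#'   parameters) and `value`.
#' @param strata named character vector: subject id -> stratum.
#' @param alpha nominal significance level for the `significant` flag.
#' @param min_n minimum stratum size.
#' @return data frame: `stratum`, `condition`, `target`, `feature`, `n`,
#'   `rho`, `p`, `fdr`, `tier`, `direction`, `significant`.
#' @export
correlation_screen <- function(feature_matrix, targets, strata,
                               alpha = 0.05, min_n = 5L) {
  assert_columns(targets, c("subject_id", "target", "value"))
  if (is.null(targets$condition)) targets$condition <- NA_character_
  rows <- list()
  for (st in unique(strata)) {
    ids <- intersect(names(strata)[strata == st], colnames(feature_matrix))
    if (length(ids) < min_n) {
      warning(sprintf("stratum '%s' has n = %d < %d; skipped", st,
                      length(ids), min_n), call. = FALSE)
      next
    }
    tt <- targets[targets$subject_id %in% ids, , drop = FALSE]
    combos <- unique(tt[, c("target", "condition"), drop = FALSE])
    for (j in seq_len(nrow(combos))) {
      tg <- combos$target[j]; cc <- combos$condition[j]
      sel <- tt$target == tg &
        (if (is.na(cc)) is.na(tt$condition) else
           !is.na(tt$condition) & tt$condition == cc)
      v <- stats::setNames(tt$value[sel], tt$subject_id[sel])
      use <- intersect(ids, names(v)[is.finite(v)])
      if (length(use) < max(min_n, 4L)) next
      for (g in rownames(feature_matrix)) {
        sc <- spearman_cor(feature_matrix[g, use], v[use])
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, condition = if (is.na(cc)) "-" else cc,
          target = tg, feature = g, n = sc$n, rho = sc$rho, p = sc$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(stratum = character(), condition = character(),
                      target = character(), feature = character(),
                      n = integer(), rho = numeric(), p = numeric(),
                      fdr = numeric(), tier = character(),
                      direction = character(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_adjust(out$p[ok])
  out$tier <- tier_pvalue(out$p)
  out$direction <- ifelse(is.na(out$rho), NA_character_,
                          ifelse(out$rho >= 0, "positive", "negative"))
  out$significant <- !is.na(out$p) & out$p < alpha
  rownames(out) <- NULL
  out
}

#' Covariate (confounding) screen via a general linear model
#'
#' For each feature, fits `log2(level) ~ covariate + group` and tests the
#' group effect with the partial F test against the covariate-only model.
#' A group effect that stays significant after adjustment
#' (`p < alpha`) means the covariate does not explain the group difference
#' (`group_effect_retained`). A constant covariate reduces to the one-way
#' model; a covariate perfectly collinear with the grouping is an error.
#'
#' @param feature_matrix features x subjects matrix of (already
#'   log-transformed or raw) levels; raw values are log2(x + 1) transformed
#'   when `log_transform = TRUE`.
#' @param groups factor across the matrix columns.
#' @param covariate numeric vector or factor across the matrix columns.
#' @param covariate_name label used in the output.
#' @param alpha decision threshold.
#' @param log_transform apply log2(x + 1) before modeling.
#' @return data frame: `feature`, `covariate`, `p_group`, `verdict`.
#' @export
covariate_screen <- function(feature_matrix, groups, covariate,
                             covariate_name = "covariate", alpha = 0.05,
                             log_transform = TRUE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) {
    stop_serumir("need >= 2 groups", class = "serumir_config_error")
  }
  constant <- if (is.numeric(covariate)) {
    stats::sd(covariate) == 0
  } else {
    length(unique(covariate)) == 1L
  }
  if (!constant) {
    cov_num <- if (is.numeric(covariate)) covariate else
      as.numeric(as.factor(covariate))
    aux <- stats::lm(cov_num ~ groups)
    # a perfect fit here IS the condition being detected; silence lm's
    # "essentially perfect fit" warning and raise the diagnostic error
    r2 <- suppressWarnings(summary(aux)$r.squared)
    if (r2 > 1 - 1e-10) {
      stop_serumir(paste("covariate '%s' is collinear with the grouping",
                         "(confounded design): R^2 = 1 in covariate ~ group"),
                   covariate_name, class = "serumir_config_error")
    }
  }
  out <- do.call(rbind, lapply(rownames(feature_matrix), function(g) {
    y <- feature_matrix[g, ]
    if (log_transform) y <- log2(y + 1)
    if (constant) {
      full <- stats::lm(y ~ groups)
      red <- stats::lm(y ~ 1)
    } else {
      full <- stats::lm(y ~ covariate + groups)
      red <- stats::lm(y ~ covariate)
    }
    a <- stats::anova(red, full)
    pg <- a[["Pr(>F)"]][2L]
    data.frame(feature = g, covariate = covariate_name, p_group = pg,
               verdict = if (!is.na(pg) && pg < alpha)
                 "group_effect_retained" else "group_effect_lost",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
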