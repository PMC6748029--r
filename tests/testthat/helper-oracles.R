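# Independent brute-force oracles. These deliberately re-derive each result
# from the printed rule / definition with a different computation than the
# implementation under test.

# Literal transcription of the three classification rules plus the default
# gap and conflict policies, evaluated rule by rule.
oracle_classify <- function(ratios, mu, sigma,
                            high_2sd = 1, high_1sd = 3, low_1sd = 1) {
  keep <- is.finite(ratios)
  r <- ratios[keep]; m <- mu[keep]; s <- sigma[keep]
  z <- (r - m) / s
  fires_high <- sum(z > 2) >= high_2sd || sum(z > 1) >= high_1sd
  fires_low <- sum(z < -1) >= low_1sd
  if (fires_high && fires_low) return("ambiguous")
  if (fires_high) return("high")
  if (fires_low) return("low")
  # normal as printed: all inside (-1, +1), or exactly one in (+1, +2);
  # everything else (the two-in-band gap) also resolves to normal by policy
  "normal"
}

# Conditional NB exact p by direct probability enumeration on the raw scale
# (explicit pmf, no log-sum-exp machinery). Valid for small totals.
oracle_exact_p <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  mt <- t / (n1 + n2)
  pmf <- function(y, n) {
    if (phi == 0) return(exp(-n * mt) * (n * mt)^y / factorial(y))
    r <- n / phi
    mu <- n * mt
    prob <- r / (r + mu)
    exp(lgamma(y + r) - lgamma(r) - lfactorial(y)) * prob^r * (1 - prob)^y
  }
  pr <- vapply(0:t, function(y) pmf(y, n1) * pmf(t - y, n2), numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[s1 + 1] * (1 + 1e-9)])
}

# Spreadsheet-style TMM factor for one sample vs the reference: M, A and
# weights listed per feature, trimming done by sorting and slicing rather
# than rank filtering.
oracle_tmm_factor <- function(y_s, L_s, y_r, L_r, trim_m = 0.30,
                              trim_a = 0.05) {
  rows <- data.frame(ys = y_s, yr = y_r)
  rows <- rows[rows$ys > 0 & rows$yr > 0, ]
  rows$M <- log2((rows$ys / L_s) / (rows$yr / L_r))
  rows$A <- 0.5 * log2((rows$ys / L_s) * (rows$yr / L_r))
  rows$w <- (L_s - rows$ys) / (L_s * rows$ys) +
    (L_r - rows$yr) / (L_r * rows$yr)
  n <- nrow(rows)
  drop_m <- floor(n * trim_m)
  drop_a <- floor(n * trim_a)
  keepM <- order(rows$M)[(drop_m + 1):(n - drop_m)]
  keepA <- order(rows$A)[(drop_a + 1):(n - drop_a)]
  keep <- intersect(keepM, keepA)
  2^(sum(rows$M[keep] / rows$w[keep]) / sum(1 / rows$w[keep]))
}

# Exact two-tailed Mann-Whitney by enumerating group assignments and
# counting pairwise wins (the U definition), independent of rank sums.
oracle_mw_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  N <- length(pool)
  U_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- U_of(x, y)
  sel <- utils::combn(N, n1)
  Us <- apply(sel, 2, function(ix) U_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9)))
}

# Exact two-sided Spearman permutation p by full enumeration of y orderings
# (recursive permutation generation, rho via the explicit covariance sum).
oracle_spearman_exact_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  rho_obs <- rho_of(rx, ry)
  rhos <- vapply(perms(ry), function(p) rho_of(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
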