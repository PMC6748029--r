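test_that("cpm computes reads-per-million and guards zero libraries", {
  m <- matrix(c(5, 10, 0, 2), 2, 2, dimnames = list(c("a", "b"), NULL))
  x <- cpm(m, c(1e6, 2e6))
  expect_equal(unname(x["a", ]), c(5, 0))
  expect_equal(unname(x["b", 1]), 10)
  expect_equal(unname(x["b", 2]), 1)
  expect_error(cpm(m, c(1e6, 0)), class = "serumir_config_error")
})

test_that("low-expression filter anchors to the smallest library", {
  m <- rbind(all_ok = c(6, 12), half = c(6, 5), zero = c(0, 0))
  lib <- c(1e6, 2e6)
  # threshold = 5 / 1e6 * 1e6 = 5 CPM; CPM(half) = (6, 2.5)
  f1 <- filter_low_expression(m, lib, min_samples_frac = 1)
  expect_setequal(f1$kept, "all_ok")
  f2 <- filter_low_expression(m, lib, min_samples_frac = 0.5)
  expect_setequal(f2$kept, c("all_ok", "half"))
  expect_true("zero" %in% f2$dropped)
  expect_equal(f1$threshold_cpm, 5)
  # with equal libraries of 1e6 every count >= 5 passes
  f3 <- filter_low_expression(rbind(a = c(5, 5)), c(1e6, 1e6))
  expect_equal(f3$kept, "a")
})

test_that("TMM gives unit factors for identical and globally scaled samples", {
  set.seed(30)
  y <- matrix(rnbinom(400, size = 5, mu = 50), 100, 4)
  rownames(y) <- paste0("g", 1:100)
  same <- cbind(y[, 1], y[, 1], y[, 1])
  f <- tmm_factors(same, rep(sum(y[, 1]), 3))
  expect_equal(unname(f$factors), rep(1, 3))
  # doubling all counts of one sample while its library doubles: factor 1
  two <- cbind(a = y[, 1], b = 2 * y[, 1])
  f2 <- tmm_factors(two, c(sum(y[, 1]), 2 * sum(y[, 1])))
  expect_equal(unname(f2$factors), c(1, 1))
  expect_equal(geomean(tmm_factors(y, colSums(y))$factors), 1)
})

test_that("TMM equals the hand-enumerated trimmed weighted mean", {
  # toy matrix with one dominant feature in sample B
  y <- cbind(A = c(100, 200, 300, 400, 500, 600),
             B = c(100, 200, 300, 400, 500, 6000))
  rownames(y) <- paste0("g", 1:6)
  lib <- c(A = 2100, B = 7500)
  f <- tmm_factors(y, lib, trim_m = 0.2, trim_a = 0)
  ref <- f$ref_sample
  other <- setdiff(colnames(y), ref)
  raw <- oracle_tmm_factor(y[, other], lib[[other]], y[, ref], lib[[ref]],
                           trim_m = 0.2, trim_a = 0)
  # implementation rescales both factors to geometric mean 1
  expect_equal(unname(f$factors[other] / f$factors[ref]), raw,
               tolerance = 1e-10)
})

test_that("TMM matches the reference implementation on random matrices", {
  set.seed(41)
  for (i in 1:5) {
    G <- 200
    y <- matrix(rnbinom(G * 6, size = 2, mu = exp(rnorm(G, 4, 1))), G, 6)
    rownames(y) <- paste0("g", 1:G)
    keep <- rowSums(y > 0) == 6
    y <- y[keep, ]
    lib <- colSums(y)
    ours <- tmm_factors(y, lib)$factors
    theirs <- edgeR::calcNormFactors(y, lib.size = lib, method = "TMM")
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
  }
})

test_that("normalized CPM responds to factors as a column operation", {
  y <- matrix(c(10, 20, 30, 40), 2, 2, dimnames = list(c("a", "b"), NULL))
  lib <- c(1e5, 1e5)
  expect_equal(normalized_cpm(y, lib, c(1, 1)), cpm(y, lib))
  half <- normalized_cpm(y, lib, c(1, 2))
  expect_equal(half[, 2], cpm(y, lib)[, 2] / 2)
  expect_equal(half[, 1], cpm(y, lib)[, 1])
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(52)
  G <- 500
  mu <- exp(rnorm(G, log(40), 1))
  grp <- factor(rep(c("a", "b"), each = 10))
  # Poisson data: estimate collapses toward the boundary
  yp <- matrix(rpois(G * 20, rep(mu, 20)), G, 20)
  ep <- estimate_common_dispersion(yp, grp)
  expect_lte(ep$phi, 0.05)
  # NB with phi = 0.4
  yn <- matrix(rnbinom(G * 20, size = 1 / 0.4, mu = rep(mu, 20)), G, 20)
  en <- estimate_common_dispersion(yn, grp)
  expect_gte(en$phi, 0.25)
  expect_lte(en$phi, 0.6)
  # identical constant counts: boundary estimate 0
  yc <- matrix(7, 50, 4)
  e0 <- estimate_common_dispersion(yc, factor(c("a", "a", "b", "b")))
  expect_equal(e0$phi, 0)
  expect_true(e0$metadata$boundary)
  expect_error(estimate_common_dispersion(yc, factor(c("a", "b", "c", "d"))),
               class = "serumir_config_error")
})

test_that("library equalization records its route", {
  y <- matrix(rpois(200, 50), 50, 4)
  near <- serumir:::equalize_counts(y, c(100, 105, 110, 108) * 1e3)
  expect_equal(attr(near, "route"), "proportional")
  far <- serumir:::equalize_counts(y, c(50, 100, 200, 400) * 1e3, phi = 0.1)
  expect_equal(attr(far, "route"), "quantile")
  expect_true(all(far >= 0))
})

test_that("exact test reproduces the worked conditional-binomial examples", {
  g <- factor(c("a", "b"))
  # perfectly balanced split, one sample per group
  p1 <- exact_test_de(matrix(c(3, 3), 1), g, phi = 0)$p
  expect_equal(p1, 1.0)
  # (10, 0): p = 2 * 0.5^10
  p2 <- exact_test_de(matrix(c(10, 0), 1), g, phi = 0)$p
  expect_equal(p2, 2 * 0.5^10)
  # zero total: p = 1, flagged
  z <- exact_test_de(matrix(c(0, 0), 1), g, phi = 0)
  expect_equal(z$p, 1)
  expect_true(z$zero_total)
  expect_error(exact_test_de(matrix(1:3, 1), factor(c("a", "b", "c")), 0.1),
               class = "serumir_config_error")
})

test_that("exact test agrees with the split-enumeration oracle", {
  set.seed(63)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    phi <- sample(c(0, 0.05, 0.2, 0.8), 1)
    t <- sample(0:50, 1)
    s1 <- sample(0:t, 1)
    cnt <- matrix(c(s1, rep(0, n1 - 1), t - s1, rep(0, n2 - 1)), 1)
    grp <- factor(rep(c("a", "b"), c(n1, n2)), levels = c("a", "b"))
    got <- exact_test_de(cnt, grp, phi)$p
    if (t == 0) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, oracle_exact_p(s1, t - s1, n1, n2, phi),
                   tolerance = 1e-9)
    }
  }
})

test_that("exact test matches the reference implementation per gene", {
  set.seed(71)
  n1 <- 4; n2 <- 7
  grp <- factor(rep(c("a", "b"), c(n1, n2)), levels = c("a", "b"))
  for (i in 1:25) {
    y <- matrix(rnbinom(n1 + n2, size = 4, mu = 15), 1)
    ours <- exact_test_de(y, grp, phi = 0.25)$p
    theirs <- edgeR::exactTestBySmallP(y[, 1:n1, drop = FALSE],
                                       y[, -(1:n1), drop = FALSE],
                                       dispersion = 0.25)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand computation and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(82)
  p <- runif(200)^2
  adj <- bh_adjust(p)
  expect_equal(adj, stats::p.adjust(p, "BH"))
  # monotone in the ranked ordering
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "serumir_config_error")
})

test_that("de_analysis recovers a planted pattern on a small cohort", {
  cfg <- small_config(seed = 19, nb_dispersion = 0.05,
                      n_per_subgroup = c(high = 12, normal = 8, low = 8),
                      n_control = 12)
  co <- generate_cohort(cfg)
  lab <- co$truth$labels
  ids <- names(lab)[lab %in% c("control", "high")]
  grp <- factor(ifelse(lab[ids] == "control", "control", "high"),
                levels = c("control", "high"))
  d <- de_analysis(co$mirna_counts$counts[, ids],
                   co$mirna_counts$library_size[ids], grp)
  s <- de_summary(d)
  # planted: 8 up, 9 down in the high subgroup
  expect_gte(s$n_up, 6); expect_lte(s$n_up, 8)
  expect_gte(s$n_down, 7); expect_lte(s$n_down, 9)
  up_called <- d$feature[d$direction == "up"]
  expect_true(all(up_called %in% sprintf("mir-%03d", 1:8)))
  # summary of an empty result set renders zeros
  empty <- d[0, ]
  class(empty) <- class(d)
  attr(empty, "comparison") <- "none"
  expect_equal(de_summary(list(none = empty))$n_up, 0)
})
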