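exact_test_sums_wrap <- function(a, b, phi) {
  exact_test(matrix(c(a, 0, 0), 1), matrix(c(b, 0, 0), 1), phi)
}

test_that("TPM matches its definition and normalisation", {
  tpm <- compute_tpm(matrix(c(10, 10), ncol = 1), c(1000, 2000))
  expect_equal(drop(tpm), c(666666.67, 333333.33), tolerance = 1e-6)

  set.seed(2)
  cnt <- matrix(rpois(60, 50), 10, 6)
  tpm2 <- compute_tpm(cnt, sample(200:2000, 10))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 6), tolerance = 1e-6)
  # conserved under feature permutation
  perm <- sample(10)
  expect_equal(unname(colSums(compute_tpm(cnt[perm, ],
                                          (200:209)[perm]))),
               rep(1e6, 6), tolerance = 1e-6)

  expect_equal(drop(compute_tpm(matrix(7, 1, 1), 500)), 1e6)
  expect_error(compute_tpm(cnt, rep(0, 10)), "positive")
  expect_warning(compute_tpm(matrix(0, 2, 1), c(100, 100)), "all-zero")
})

test_that("library equalisation scales to the geometric mean and keeps zeros", {
  cnt <- matrix(c(5L, 0L, 7L, 5L, 0L, 7L), ncol = 2)
  eq <- equalize_libraries(cnt)
  expect_identical(eq$counts, cnt)  # equal libraries: no-op

  cnt2 <- matrix(c(600000L, 400000L, 1600000L, 2400000L), ncol = 2)
  eq2 <- equalize_libraries(cnt2)
  expect_equal(eq2$target, 2e6)
  expect_true(all(abs(colSums(eq2$counts) - 2e6) <= 1))
  expect_true(all(eq2$counts[cnt2 == 0] == 0))

  set.seed(4)
  cnt3 <- matrix(rpois(300, 40), 50, 6)
  cnt3[sample(300, 40)] <- 0L
  eq3 <- equalize_libraries(cnt3)
  expect_true(all(eq3$counts[cnt3 == 0] == 0))
  expect_error(equalize_libraries(matrix(0L, 3, 2)), "zero library")
})

test_that("common dispersion is recovered by conditional maximum likelihood", {
  set.seed(19)
  n <- 800
  mu <- 10^runif(n, 1, 2.5)
  grp <- factor(rep(c("A", "B"), each = 3))
  cnt <- sapply(1:6, function(j) rnbinom(n, size = 1 / 0.2, mu = mu))
  est <- estimate_common_dispersion(cnt, grp)
  expect_gt(est$phi, 0.15)
  expect_lt(est$phi, 0.25)

  # Poisson data drives the estimate to the lower boundary
  cntp <- sapply(1:6, function(j) rpois(n, mu))
  expect_lte(estimate_common_dispersion(cntp, grp)$phi, 0.01)

  # duplicating the feature set scales the likelihood, not the argmax
  est2 <- estimate_common_dispersion(rbind(cnt, cnt), grp)
  expect_equal(est2$phi, est$phi, tolerance = 1e-6)

  expect_error(estimate_common_dispersion(cnt, factor(rep("A", 6))),
               ">= 2 groups")
})

test_that("exact test has its symmetries and limits", {
  # balanced design with equal sums: the observed split is the mode -> p = 1
  y1 <- matrix(c(5, 6, 7), 1)
  y2 <- matrix(c(7, 6, 5), 1)
  expect_equal(exact_test(y1, y2, 0.1), 1)
  # swapping the groups leaves p unchanged
  a <- matrix(c(2, 3, 1), 1)
  b <- matrix(c(9, 14, 11), 1)
  expect_equal(exact_test(a, b, 0.15), exact_test(b, a, 0.15))
  # no information at t = 0
  expect_equal(exact_test(matrix(0, 1, 3), matrix(0, 1, 3), 0.1), 1)
  # phi -> 0 reduces to the conditional binomial test
  for (t in c(5, 17, 30)) {
    for (aa in c(0, 3, t %/% 2)) {
      f <- dbinom(0:t, t, 0.5)
      p_binom <- sum(f[f <= f[aa + 1] * (1 + 1e-12)])
      expect_equal(exact_test_sums_wrap(aa, t - aa, 1e-9), p_binom,
                   tolerance = 1e-6)
    }
  }
})

test_that("exact test equals enumeration and edgeR oracles on a grid", {
  set.seed(6)
  for (phi in c(0, 0.1, 1)) {
    for (t in 0:20) {
      for (a in 0:t) {
        p <- exact_test_sums_wrap(a, t - a, phi)
        expect_equal(p, oracle_exact_p(a, t - a, 3, 3, phi),
                     tolerance = 1e-10)
      }
    }
  }
  # independent implementation cross-check
  y1 <- matrix(rpois(30, 20), 10, 3)
  y2 <- matrix(rpois(30, 35), 10, 3)
  p_mine <- exact_test(y1, y2, 0.12)
  p_edger <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.12)
  expect_equal(p_mine, as.numeric(p_edger), tolerance = 1e-10)
})

test_that("null exact-test p-values are (near) uniform", {
  set.seed(29)
  n <- 2000
  mu <- 10^runif(n, 1, 2.5)
  cnt <- sapply(1:6, function(j) rnbinom(n, size = 1 / 0.2, mu = mu))
  eq <- equalize_libraries(cnt)
  grp <- factor(rep(c("A", "B"), each = 3))
  phi <- estimate_common_dispersion(eq$counts, grp)$phi
  p <- exact_test(eq$counts[, 1:3], eq$counts[, 4:6], phi)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches the closed form and a step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(37)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("run_de gates, counts and FC sign convention are coherent", {
  set.seed(41)
  n <- 300
  base <- 10^runif(n, 1.8, 2.5)
  lfc <- numeric(n)
  de_idx <- 1:30
  lfc[de_idx] <- sample(c(-1, 1), 30, replace = TRUE) * runif(30, 2, 4)
  cond <- factor(rep(c("control", "LPS", "polyIC", "betaglucan"), each = 3),
                 levels = c("control", "LPS", "polyIC", "betaglucan"))
  cnt <- sapply(seq_along(cond), function(s) {
    mu <- if (cond[s] == "LPS") base * 2^lfc else base
    rnbinom(n, size = 1 / 0.1, mu = mu)
  })
  rownames(cnt) <- sprintf("f%03d", 1:n)
  res <- run_de(cnt, rep(500, n), cond)

  s <- res$summary
  expect_identical(s$up + s$down, s$total)
  lps <- res$tables$LPS
  expect_true(all(lps$fdr >= lps$p))
  expect_true(all(abs(lps$fc) >= 1))
  # planted high-expression |log2FC| >= 2: recall at default gates
  expect_gte(mean(lps$de_flag[de_idx]), 0.8)
  # directions match planted signs among recovered features
  rec <- de_idx[lps$de_flag[de_idx]]
  expect_true(all(sign(lps$fc[rec]) == sign(lfc[rec])))

  # FC sign inverts exactly when stimulus and control labels swap
  cond_sw <- cond
  levels(cond_sw) <- c("LPS", "control", "polyIC", "betaglucan")
  res_sw <- run_de(cnt, rep(500, n), cond_sw)
  expect_equal(res_sw$tables$LPS$fc, -res$tables$LPS$fc, tolerance = 1e-12)

  expect_error(run_de(cnt, rep(500, n), factor(rep(c("a", "b"), 6))),
               "control")
})
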