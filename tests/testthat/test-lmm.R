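test_that("with identity kinship the null fit recovers the sample REML variance", {
  set.seed(1)
  ids <- sprintf("s%02d", 1:40)
  y <- setNames(rnorm(40, 2, 1.5), ids)
  fit <- fit_null(y, identity_kinship(ids))
  # rotated model is i.i.d.: total variance must equal var(y) (n-1 denominator)
  expect_equal(fit$sigma_u2 + fit$sigma_e2, var(y), tolerance = 1e-6)
  expect_equal(fit$mu, mean(y), tolerance = 1e-6)
})

test_that("the profile REML criterion matches a dense-solve oracle", {
  set.seed(4)
  panel <- random_panel(25, 60, seed = 4)
  K <- ibs_kinship(panel)
  y <- setNames(drop(chol(unclass(K) + 0.5 * diag(25)) %*% rnorm(25)), rownames(panel$dosage))
  fit <- fit_null(y, K)
  W <- matrix(1, 25, 1)
  for (delta in c(0.05, 0.3, 1, 5)) {
    ours <- strainqtl:::reml_profile(
      crossprod(fit$eigen$U, y)[, 1],
      crossprod(fit$eigen$U, W),
      fit$eigen$s, delta, log(25)
    )$ll
    expect_equal(ours, as.numeric(oracle_reml_ll(y, W, unclass(K), delta)), tolerance = 1e-6)
  }
  # optimum dominates every grid point
  expect_true(all(fit$loglik >= fit$grid$loglik - 1e-9))
})

test_that("null-model variance components are recovered in simulation", {
  deltas <- vapply(1:8, function(s) {
    set.seed(200 + s)
    n <- 200
    panel <- random_panel(n, 150, seed = 200 + s)
    K <- ibs_kinship(panel)
    eg <- eigen(unclass(K), symmetric = TRUE)
    u <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n))
    y <- setNames(drop(u) + rnorm(n), rownames(panel$dosage))
    fit_null(y, K)$delta
  }, numeric(1))
  # generative delta = 1; estimates should concentrate around it
  expect_gt(mean(deltas >= 0.5 & deltas <= 2), 0.7)
  expect_lt(abs(median(deltas) - 1), 0.5)
})

test_that("degenerate inputs are rejected", {
  ids <- sprintf("s%02d", 1:10)
  expect_error(fit_null(setNames(rep(1, 10), ids), identity_kinship(ids)), "zero variance")
  expect_error(fit_null(setNames(rnorm(5), ids[1:5]), identity_kinship(ids)), "at least 8")
  M <- diag(10) - 0.5
  dimnames(M) <- list(ids, ids)
  class(M) <- c("kinship_matrix", "matrix", "array")
  expect_error(fit_null(setNames(rnorm(10), ids), M), "positive semidefinite")
})

test_that("with identity kinship the scan reproduces ordinary regression F-tests", {
  set.seed(7)
  panel <- random_panel(30, 40, seed = 7)
  ids <- rownames(panel$dosage)
  y <- setNames(rnorm(30), ids)
  I <- identity_kinship(ids)
  fit <- fit_null(y, I)
  scan <- suppressMessages(assoc_scan(y, panel, I, fit))
  for (i in seq_len(nrow(scan))) {
    x <- panel$dosage[, scan$snp_id[i]]
    lm_p <- summary(lm(y ~ x))$coefficients[2, 4]
    expect_equal(scan$p[i], lm_p, tolerance = 1e-8)
  }
})

test_that("the scan matches a dense GLS oracle under a real kinship", {
  set.seed(12)
  panel <- random_panel(24, 30, seed = 12)
  K <- ibs_kinship(panel)
  u <- drop(chol(unclass(K) + 1e-4 * diag(24)) %*% rnorm(24))
  y <- setNames(u + rnorm(24, 0, 0.7), rownames(panel$dosage))
  fit <- fit_null(y, K)
  scan <- suppressMessages(assoc_scan(y, panel, K, fit))
  Ko <- precondition_kinship(K)
  for (i in seq_len(nrow(scan))) {
    x <- panel$dosage[rownames(panel$dosage), scan$snp_id[i]]
    o <- oracle_gls_test(unname(y), unname(x), Ko, fit$sigma_u2, fit$sigma_e2)
    expect_equal(scan$p[i], o$p, tolerance = 1e-8)
    expect_equal(scan$beta[i], o$beta, tolerance = 1e-8)
  }
})

test_that("missing genotypes are dropped pairwise per SNP", {
  set.seed(3)
  panel <- random_panel(20, 60, seed = 3)
  panel$dosage[1:4, 2] <- NA
  panel <- genotype_panel(panel$dosage, panel$snp_meta[1:7])
  K <- ibs_kinship(panel)
  y <- setNames(rnorm(20), rownames(panel$dosage))
  fit <- fit_null(y, K)
  scan <- suppressMessages(assoc_scan(y, panel, K, fit))
  r2 <- scan[scan$snp_id == panel$snp_meta$snp_id[2], ]
  expect_equal(r2$n, 16)
  # oracle on the reduced strain set at the same delta; the F-test is
  # invariant to the overall variance scale, only delta matters
  rows <- 5:20
  Ks <- precondition_kinship(unclass(K)[rows, rows])
  o <- oracle_gls_test(
    unname(y[rows]), unname(panel$dosage[rows, 2]), Ks,
    1, fit$delta
  )
  expect_equal(r2$p, o$p, tolerance = 1e-6)
})

test_that("exact per-SNP REML agrees with the fast path when delta is flat", {
  set.seed(9)
  panel <- random_panel(20, 12, seed = 9)
  ids <- rownames(panel$dosage)
  y <- setNames(rnorm(20), ids)
  I <- identity_kinship(ids)
  fit <- fit_null(y, I)
  fast <- suppressMessages(assoc_scan(y, panel, I, fit))
  exact <- suppressMessages(assoc_scan(y, panel, I, fit, exact_delta = TRUE))
  expect_equal(exact$p, fast$p, tolerance = 1e-6)
})

test_that("the F-test has power against a strong planted effect", {
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 75
    x <- 2 * rbinom(n, 1, 0.5)
    while (var(x) == 0) x <- 2 * rbinom(n, 1, 0.5)
    # 50% variance explained
    beta <- sqrt(1 * var(x)^-1)
    y <- x * beta + rnorm(n, 0, sqrt(beta^2 * var(x)))
    ids <- sprintf("s%03d", 1:n)
    names(y) <- ids
    D <- matrix(x, n, 1, dimnames = list(ids, "snp1"))
    meta <- tibble::tibble(
      snp_id = "snp1", chrom = "1", pos = 100,
      ref = "A", alt = "G", consequence = NA, host_gene = NA
    )
    panel <- genotype_panel(D, meta)
    fit <- fit_null(y, identity_kinship(ids))
    suppressMessages(assoc_scan(y, panel, identity_kinship(ids), fit))$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("q-values match brute-force step-up computation", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh"), rep(0.04, 4))
  expect_equal(qvalues(0.05, method = "bh"), 0.05)
  set.seed(6)
  for (i in 1:5) {
    p <- runif(50)^(1 + i / 2)
    expect_equal(qvalues(p, method = "bh"), oracle_qvalues(p, 1), tolerance = 1e-12)
    expect_equal(qvalues(p, method = "bh"), p.adjust(p, "BH"), tolerance = 1e-12)
    pi0 <- oracle_storey_pi0(p)
    if (pi0 > 0) {
      expect_equal(qvalues(p, method = "storey"), oracle_qvalues(p, pi0), tolerance = 1e-12)
    }
    # monotone in p and bounded by pi0
    q <- qvalues(p, method = "storey")
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q <= max(pi0, 1 / 50) + 1e-12))
  }
  expect_identical(qvalues(numeric(0)), numeric(0))
  expect_error(qvalues(c(0.5, 0)), "0, 1")
})

test_that("map_qtl applies the coverage floor and attaches per-feature q-values", {
  sim <- simulate_panel(small_sim(8, coverage = c(0.3, 1)))
  K <- ibs_kinship(sim$panel)
  res <- suppressMessages(map_qtl(sim$abundance, sim$panel, K,
    cfg = run_config(), min_strains = 30
  ))
  counts <- colSums(!is.na(strain_aggregate(sim$abundance, FALSE)))
  expect_setequal(unique(res$assoc$feature_id), names(counts)[counts >= 30])
  one <- res$assoc[res$assoc$feature_id == res$assoc$feature_id[1], ]
  expect_equal(one$q, qvalues(one$p, "storey"))
  expect_true(all(res$fits$h2 >= 0 & res$fits$h2 <= 1))
})
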