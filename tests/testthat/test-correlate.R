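make_ab <- function(values, strains) {
  abundance_matrix(values, tibble::tibble(
    sample_id = rownames(values), strain_id = strains
  ))
}

test_that("strain aggregation averages replicates and respects missingness", {
  v <- rbind(
    a1 = c(1, 4), a2 = c(1, 4), # identical replicates
    b1 = c(2, NA), b2 = c(4, NA)
  )
  colnames(v) <- c("p1", "p2")
  ab <- make_ab(v, c("A", "A", "B", "B"))
  m <- strain_aggregate(ab, quantile_normalize = FALSE)
  expect_equal(m["A", ], c(p1 = 1, p2 = 4))
  expect_equal(m["B", "p1"], 3)
  expect_true(is.na(m["B", "p2"]))
})

test_that("quantile normalization matches the rank-average oracle", {
  # frozen 3-protein x 2-sample grid: both samples map onto (1.5, 3.5, 6.5)
  v <- rbind(s1 = c(1, 3, 5), s2 = c(2, 4, 8))
  colnames(v) <- paste0("p", 1:3)
  ab <- make_ab(v, c("A", "B"))
  m <- strain_aggregate(ab, quantile_normalize = TRUE)
  expect_equal(unname(m["A", ]), c(1.5, 3.5, 6.5))
  expect_equal(unname(m["B", ]), c(1.5, 3.5, 6.5))

  # a monotone transform of another sample becomes identical to it
  v2 <- rbind(s1 = c(0.2, 1.0, -0.7, 2.0), s2 = c(0.4, 2.0, -1.4, 4.0))
  colnames(v2) <- paste0("p", 1:4)
  m2 <- strain_aggregate(make_ab(v2, c("A", "B")), quantile_normalize = TRUE)
  expect_equal(m2["A", ], m2["B", ])

  # random grids match the literal oracle
  set.seed(14)
  for (i in 1:3) {
    v3 <- matrix(rnorm(8 * 5), 8, 5,
      dimnames = list(paste0("s", 1:8), paste0("p", 1:5))
    )
    m3 <- strain_aggregate(make_ab(v3, paste0("st", 1:8)), quantile_normalize = TRUE)
    expect_equal(unname(t(m3)), unname(oracle_quantile_normalize(t(v3))), tolerance = 1e-12)
  }
})

test_that("coefficients of variation are computed on the linear scale", {
  # linear replicates (0.9, 1.0, 1.1): sd 0.1, mean 1 -> CV exactly 10%
  v <- matrix(log2(c(0.9, 1.0, 1.1)), 3, 1, dimnames = list(paste0("r", 1:3), "p1"))
  ab <- make_ab(v, rep("A", 3))
  cv <- cv_report(ab)
  expect_equal(cv$cv_intra, 10, tolerance = 1e-9)

  # identical replicates -> CV 0
  v0 <- matrix(0.3, 4, 1, dimnames = list(paste0("r", 1:4), "p1"))
  expect_equal(cv_report(make_ab(v0, rep(c("A", "B"), 2)))$cv_intra, 0)

  # intra-strain CV grows with replicate noise
  med_cv <- vapply(c(0.05, 0.13, 0.3), function(s) {
    sim <- simulate_panel(small_sim(6, replicate_sd = s))
    unname(attr(cv_report(sim$abundance), "medians")["cv_intra"])
  }, numeric(1))
  expect_true(all(diff(med_cv) > 0))

  # invariant to protein order
  sim <- simulate_panel(small_sim(6))
  cv1 <- cv_report(sim$abundance)
  perm <- sample(ncol(sim$abundance$values))
  ab_perm <- abundance_matrix(sim$abundance$values[, perm], sim$abundance$sample_to_strain)
  cv2 <- cv_report(ab_perm)
  expect_equal(
    attr(cv1, "medians"), attr(cv2, "medians")
  )
})

test_that("bicor satisfies its defining identities and matches the formula oracle", {
  set.seed(20)
  x <- rnorm(12)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)

  # 8-point fixture with one gross outlier
  xf <- c(0.1, 0.2, 0.35, 0.5, 0.55, 0.7, 0.8, 0.9)
  yf <- c(0.12, 0.25, 0.3, 0.55, 0.5, 0.72, 0.85, 8.0)
  expect_equal(bicor(xf, yf), oracle_bicor(xf, yf), tolerance = 1e-12)
  expect_gt(abs(bicor(xf, yf)), abs(cor(xf, yf)))

  # random fixtures against the oracle; affine invariance; antisymmetry
  for (i in 1:10) {
    a <- rnorm(15)
    b <- 0.6 * a + rnorm(15)
    expect_equal(bicor(a, b), oracle_bicor(a, b), tolerance = 1e-12)
    expect_equal(bicor(2.5 * a + 3, b), bicor(a, b), tolerance = 1e-12)
    expect_equal(bicor(a, -b), -bicor(a, b), tolerance = 1e-12)
  }

  # zero MAD falls back to Pearson with a message
  z <- c(rep(0, 9), 1)
  w <- rnorm(10)
  expect_message(r <- bicor(z, w), "Pearson")
  expect_equal(r, cor(z, w))
  expect_error(bicor(1:2, 1:2), "at least 3")
})

test_that("correlation tests follow the closed-form t transform and BH", {
  set.seed(30)
  n <- 20
  strains <- sprintf("st%02d", 1:n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(strains, paste0("p", 1:4)))
  traits <- tibble::tibble(
    strain_id = strains,
    t_copy = X[, 1],             # exact copy of p1
    t_noise = rnorm(n)
  )
  res <- correlate_features(X, traits)
  copy <- res[res$feature_a == "p1" & res$feature_b == "t_copy", ]
  expect_equal(copy$r, 1, tolerance = 1e-9)
  expect_lt(copy$p, 1e-12)
  expect_true(copy$selected)
  # t transform checked against direct recomputation
  ok <- !is.na(res$r) & abs(res$r) < 1
  expect_equal(
    res$t_stat[ok], res$r[ok] * sqrt(res$n[ok] - 2) / sqrt(1 - res$r[ok]^2),
    tolerance = 1e-12
  )
  ok_p <- !is.na(res$p)
  expect_equal(res$q[ok_p], p.adjust(res$p[ok_p], "BH"), tolerance = 1e-12)
  expect_error(correlate_features(X, traits, trait_ids = "absent"), "absent")
})

test_that("network edges are unique, thresholded and degree-annotated", {
  set.seed(40)
  n <- 25
  strains <- sprintf("st%02d", 1:n)
  base <- rnorm(n)
  X <- cbind(
    a = base + rnorm(n, 0, 0.2), b = base + rnorm(n, 0, 0.2),
    c = base + rnorm(n, 0, 0.2), d = rnorm(n), e = rnorm(n)
  )
  rownames(X) <- strains
  res <- correlate_features(X)
  edges <- network_edges(res, r_cutoff = 0.6, q_cutoff = 0.05)
  # the co-regulated block forms a connected component
  expect_true(all(c("a", "b", "c") %in% unlist(edges[c("feature_a", "feature_b")])))
  expect_false(any(duplicated(edges[c("feature_a", "feature_b")])))
  expect_true(all(abs(edges$r) >= 0.6))
  deg <- attr(edges, "degrees")
  expect_equal(sum(deg$degree), 2 * nrow(edges))
  # cutoff 1 keeps only exact duplicates
  X2 <- cbind(X, a_dup = X[, "a"])
  res2 <- correlate_features(X2)
  e2 <- network_edges(res2, r_cutoff = 1 - 1e-12, q_cutoff = 0.05)
  expect_equal(nrow(e2), 1)
  expect_setequal(unlist(e2[c("feature_a", "feature_b")]), c("a", "a_dup"))
})

test_that("repeatability matches the ANOVA oracle and its limits", {
  # zero within-strain variance -> R = 1
  d1 <- tibble::tibble(strain_id = rep(c("A", "B", "C"), each = 3), value = rep(c(1, 5, 9), each = 3))
  expect_equal(repeatability(d1)$R, 1)
  # equal strain means -> R = 0 (negative component clipped)
  d0 <- tibble::tibble(strain_id = rep(c("A", "B"), each = 4), value = c(1, 3, 2, 4, 2, 4, 1, 3))
  expect_equal(repeatability(d0)$R, 0)
  expect_error(repeatability(tibble::tibble(strain_id = "A", value = 1)), "2 strains")

  # unbalanced random data against the summary-statistic oracle
  set.seed(50)
  for (i in 1:5) {
    g <- rep(sprintf("s%d", 1:6), times = sample(2:5, 6, TRUE))
    d <- tibble::tibble(
      strain_id = g,
      value = rnorm(length(g)) + rnorm(6)[as.integer(factor(g))]
    )
    o <- oracle_repeatability(d$value, d$strain_id)
    r <- repeatability(d)
    expect_equal(r$R, o$R, tolerance = 1e-10)
    expect_equal(r$sigma2_between, o$s2b, tolerance = 1e-10)
    expect_equal(r$sigma2_within, o$s2w, tolerance = 1e-10)
  }

  # generative sigma2_b = sigma2_w -> R concentrates near 0.5
  Rs <- vapply(1:50, function(s) {
    set.seed(600 + s)
    strain_eff <- rnorm(20)
    d <- tibble::tibble(
      strain_id = rep(sprintf("s%02d", 1:20), each = 4),
      value = rep(strain_eff, each = 4) + rnorm(80)
    )
    repeatability(d)$R
  }, numeric(1))
  expect_lt(abs(mean(Rs) - 0.5), 0.1)
})

test_that("differential tests reproduce hand-computed t statistics", {
  d <- tibble::tibble(
    feature_id = "f1",
    value = c(1, 2, 3, 4, 5, 6),
    group = rep(c("ctrl", "kd"), each = 3)
  )
  res <- differential(d, ref = "ctrl")
  expect_equal(res$t_stat, 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-10)

  dp <- tibble::tibble(
    feature_id = "f1",
    pair_id = rep(1:3, 2),
    value = c(0, 0, 0, 0.5, 1.0, 1.5),
    group = rep(c("ctrl", "kd"), each = 3)
  )
  resp <- differential(dp, paired = TRUE, ref = "ctrl")
  expect_equal(resp$t_stat, 3.464, tolerance = 1e-3)
  expect_equal(resp$df, 2)
  expect_equal(resp$p, 0.0742, tolerance = 1e-3)

  # identical groups: t = 0, p = 1; zero-variance difference flagged
  di <- tibble::tibble(
    feature_id = rep(c("same", "degen"), each = 6),
    value = c(1, 2, 3, 1, 2, 3, 1, 1, 1, 2, 2, 2),
    group = rep(rep(c("ctrl", "kd"), each = 3), 2)
  )
  resi <- differential(di, ref = "ctrl")
  expect_equal(resi$t_stat[resi$feature_id == "same"], 0)
  expect_equal(resi$p[resi$feature_id == "same"], 1)
  expect_true(resi$degenerate[resi$feature_id == "degen"])
  expect_true(is.na(resi$p[resi$feature_id == "degen"]))
  # BH across features matches p.adjust
  ok <- !is.na(resi$p)
  expect_equal(resi$q[ok], p.adjust(resi$p[ok], "BH"), tolerance = 1e-12)
})
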