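# Independent brute-force oracles used across the suite. These deliberately
# take the slow, direct route (dense solves, explicit step-up loops) so they
# share no code path with the package implementation.

# dense restricted log-likelihood: V = sigma_u2 * (K + delta * I), sigma_u2
# profiled at the given delta via direct GLS
oracle_reml_ll <- function(y, W, K, delta) {
  n <- length(y)
  p <- ncol(W)
  V0 <- K + delta * diag(n)
  V0i <- solve(V0)
  A <- t(W) %*% V0i %*% W
  beta <- solve(A, t(W) %*% V0i %*% y)
  r <- y - W %*% beta
  rss <- as.numeric(t(r) %*% V0i %*% r)
  sigma_u2 <- rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * sigma_u2) + 1) +
    determinant(V0, logarithm = TRUE)$modulus +
    determinant(A, logarithm = TRUE)$modulus -
    determinant(t(W) %*% W, logarithm = TRUE)$modulus)
}

# dense GLS single-SNP F-test at fixed variance components
oracle_gls_test <- function(y, x, K, sigma_u2, sigma_e2) {
  n <- length(y)
  V <- sigma_u2 * K + sigma_e2 * diag(n)
  Vi <- solve(V)
  W <- cbind(1, x)
  A <- t(W) %*% Vi %*% W
  coef <- solve(A, t(W) %*% Vi %*% y)
  r <- y - W %*% coef
  # residual-rescaled covariance, matching the profile form of the scan
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
  cov_b <- s2 * solve(A)
  f_stat <- coef[2]^2 / cov_b[2, 2]
  list(
    beta = as.numeric(coef[2]), se = sqrt(cov_b[2, 2]), f = as.numeric(f_stat),
    p = pf(f_stat, 1, n - 2, lower.tail = FALSE)
  )
}

# literal step-up q-values
oracle_qvalues <- function(p, pi0 = 1) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, pi0 * m * p[j] / rank_j)
      }
    }
    q[i] <- min(cand, 1)
  }
  q
}

oracle_storey_pi0 <- function(p, lambda = 0.5) min(1, mean(p > lambda) / (1 - lambda))

# literal biweight midcorrelation formula
oracle_bicor <- function(x, y) {
  wdev <- function(v) {
    d <- v - median(v)
    u <- d / (9 * median(abs(d)))
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d * w
  }
  a <- wdev(x)
  b <- wdev(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# literal quantile normalization: rank-average reference, ties share the mean
# of their rank slots (columns = samples)
oracle_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average the reference values of the (possibly fractional) rank slots
    vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[c(lo, hi)])
    }, numeric(1))
  })
}

# per-SNP double-loop identity-by-state kinship
oracle_ibs <- function(D) {
  n <- nrow(D)
  K <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      ok <- !is.na(D[i, ]) & !is.na(D[j, ])
      K[i, j] <- mean(1 - abs(D[i, ok] - D[j, ok]) / 2)
    }
  }
  diag(K) <- 1
  K
}

# one-way ANOVA repeatability from group summaries (no aov)
oracle_repeatability <- function(values, groups) {
  groups <- as.character(groups)
  g <- split(values, groups)
  ni <- lengths(g)
  N <- sum(ni)
  k <- length(g)
  grand <- mean(values)
  ss_b <- sum(ni * (vapply(g, mean, numeric(1)) - grand)^2)
  ss_w <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (ms_b - ms_w) / n0)
  list(R = if (s2b + ms_w == 0) 0 else s2b / (s2b + ms_w), s2b = s2b, s2w = ms_w)
}

# hand-built 4-strain / 4-SNP panel used in several unit tests
tiny_panel <- function() {
  D <- rbind(
    strain_A = c(0, 2, 2, 0),
    strain_B = c(0, 2, 0, 2),
    strain_C = c(2, 0, 2, 0),
    strain_D = c(0, 2, 2, 0)
  )
  colnames(D) <- paste0("snp_", 1:4)
  meta <- tibble::tibble(
    snp_id = colnames(D), chrom = c("1", "1", "2", "2"),
    pos = c(100, 5000, 300, 9000),
    ref = "A", alt = "G",
    consequence = c("missense_variant", NA, NA, "intron_variant"),
    host_gene = NA_character_
  )
  genotype_panel(D, meta)
}

# random panel + identity-kinship helpers for LMM tests
random_panel <- function(n, m, seed, chrom = "1") {
  set.seed(seed)
  D <- matrix(2 * rbinom(n * m, 1, runif(m, 0.2, 0.8)[rep(1:m, each = n)]), n, m)
  rownames(D) <- sprintf("s%03d", 1:n)
  colnames(D) <- sprintf("snp%04d", 1:m)
  meta <- tibble::tibble(
    snp_id = colnames(D), chrom = chrom,
    pos = sort(sample.int(5e7, m)),
    ref = "A", alt = "G", consequence = NA_character_, host_gene = NA_character_
  )
  genotype_panel(D, meta)
}

identity_kinship <- function(ids) {
  I <- diag(length(ids))
  dimnames(I) <- list(ids, ids)
  structure(I, class = c("kinship_matrix", "matrix", "array"))
}

small_sim <- function(seed, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, n_strains = 40, n_chromosomes = 2, chrom_length_bp = 6e7,
      n_snps = 120, n_genes = 60, n_proteins = 30, ld_block_bp = 6e6,
      hotspot_targets = 8
    ),
    list(...)
  )
  do.call(sim_config, args)
}

# constructed OPLS fixture: X carries a single y-predictive latent direction
# (so a one-component predictive fit is exact up to tiny noise), plus optional
# structured y-orthogonal variation loaded on other proteins
make_opls_fixture <- function(seed, n = 40, p = 25, ortho_sd = 0, noise_sd = 0.01) {
  set.seed(seed)
  strains <- sprintf("st%02d", 1:n)
  t_sig <- rnorm(n)
  w_sig <- c(runif(5, 0.5, 1), rep(0, p - 5))
  X <- outer(t_sig, w_sig)
  if (ortho_sd > 0) {
    t_o <- stats::residuals(lm(rnorm(n) ~ t_sig))
    w_o <- c(rep(0, 10), runif(5, 0.5, 1), rep(0, p - 15))
    X <- X + ortho_sd * outer(t_o, w_o)
  }
  X <- X + matrix(rnorm(n * p, 0, noise_sd), n, p)
  dimnames(X) <- list(strains, sprintf("pr%02d", 1:p))
  list(X = X, y = setNames(t_sig, strains))
}

# mirror of the engine's declared kinship preconditioning: when any eigenvalue
# falls below 1e-8 the matrix is regularized by +1e-6 on the diagonal, so the
# dense oracle must see the same effective K
precondition_kinship <- function(K) {
  K <- unclass(K)
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values < 1e-8)) {
    K <- K + 1e-6 * diag(nrow(K))
  }
  K
}
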