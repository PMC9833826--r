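# REML linear mixed-model association engine.
#
# Model per feature and SNP:  y = 1*mu + x*beta + u + e,
# with var(u) = sigma_u^2 * K (identity-by-state kinship) and
# var(e) = sigma_e^2 * I. The variance ratio delta = sigma_e^2 / sigma_u^2 is
# profiled by REML on the no-SNP null model via the eigendecomposition
# K = U diag(s) U': rotating by U' makes the covariance diagonal
# (sigma_u^2 * (s + delta)), so each candidate delta costs O(n). The null
# delta is then reused for every SNP (the fast-lmm "null-reuse"
# approximation), where each SNP needs only a weighted 2x2 generalized
# least-squares solve; exact per-SNP REML is available behind a flag.

kinship_eigen <- function(K) {
  eg <- eigen(K, symmetric = TRUE)
  s <- eg$values
  if (min(s) < -1e-8 * max(abs(s), 1)) {
    abort("kinship matrix is not positive semidefinite")
  }
  if (any(s < 1e-8)) {
    # equivalent to K + 1e-6 * I (same eigenvectors), keeping the effective
    # kinship an explicit, oracle-reproducible matrix
    s <- s + 1e-6
    warn("kinship eigenvalues below 1e-8; regularized by +1e-6 on the diagonal")
  }
  list(U = eg$vectors, s = s)
}

# Profile REML criterion at a given delta for rotated response yt and rotated
# design Wt (n x p). Returns the restricted log-likelihood with sigma_u^2
# profiled out in closed form.
reml_profile <- function(yt, Wt, s, delta, logdet_WtW) {
  n <- length(yt)
  p <- ncol(Wt)
  w <- 1 / (s + delta)
  A <- crossprod(Wt, Wt * w)
  b <- crossprod(Wt, yt * w)
  coef <- solve(A, b)
  rss <- sum(w * yt^2) - sum(coef * b)
  sigma_u2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma_u2) + 1) + sum(log(s + delta)) +
    determinant(A, logarithm = TRUE)$modulus - logdet_WtW)
  list(ll = as.numeric(ll), sigma_u2 = sigma_u2, coef = coef, rss = rss)
}

#' Fit the null mixed model for one feature
#'
#' Maximizes the restricted likelihood of `y = 1*mu + u + e` over the variance
#' ratio `delta = sigma_e^2 / sigma_u^2` on a log-spaced grid followed by
#' bounded local refinement, with `sigma_u^2` profiled out in closed form at
#' each `delta`.
#'
#' @param y Named numeric vector of strain-level values (names = strain ids);
#'   missing values are dropped. At least 8 non-missing strains required.
#' @param K A [ibs_kinship()] matrix covering the strains of `y`.
#' @param n_grid Number of grid points for `delta` (>= 100 recommended).
#' @param delta_range Search range for `delta`.
#' @return An object of class `lmm_fit`: `delta`, `sigma_u2`, `sigma_e2`, `mu`,
#'   `loglik`, `n`, `h2` (`sigma_u2 / (sigma_u2 + sigma_e2)`), the strains
#'   used, the cached kinship eigendecomposition, and the grid of restricted
#'   log-likelihoods.
#' @export
fit_null <- function(y, K, n_grid = 100, delta_range = c(1e-5, 1e5)) {
  if (is.null(names(y))) {
    if (length(y) != nrow(K)) abort("unnamed y must match K dimensions")
    names(y) <- rownames(K)
  }
  keep <- names(y)[!is.na(y)]
  keep <- keep[keep %in% rownames(K)]
  if (length(keep) < 8) abort("fit_null needs at least 8 strains with observed values")
  y <- y[keep]
  if (sd(y) == 0) abort("zero variance feature")
  Ks <- unclass(K)[keep, keep]
  eg <- kinship_eigen(Ks)
  n <- length(y)
  yt <- crossprod(eg$U, y)[, 1]
  ot <- crossprod(eg$U, rep(1, n))
  logdet_WtW <- log(n)

  grid <- 10^seq(log10(delta_range[1]), log10(delta_range[2]), length.out = n_grid)
  ll <- vapply(grid, function(d) reml_profile(yt, ot, eg$s, d, logdet_WtW)$ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  opt <- optimize(
    function(ld) reml_profile(yt, ot, eg$s, 10^ld, logdet_WtW)$ll,
    interval = c(log10(lo), log10(hi)), maximum = TRUE, tol = 1e-8
  )
  delta <- 10^opt$maximum
  at <- reml_profile(yt, ot, eg$s, delta, logdet_WtW)
  structure(
    list(
      feature_id = NA_character_,
      delta = delta,
      sigma_u2 = at$sigma_u2,
      sigma_e2 = delta * at$sigma_u2,
      mu = as.numeric(at$coef[1]),
      loglik = at$ll,
      n = n,
      h2 = 1 / (1 + delta),
      strains = keep,
      eigen = eg,
      grid = tibble(delta = grid, loglik = ll)
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> n = %d, delta = %.4g, sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
    x$n, x$delta, x$sigma_u2, x$sigma_e2, x$h2
  ))
  invisible(x)
}

#' @rdname fit_null
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(
    feature_id = x$feature_id, n = x$n, delta = x$delta,
    sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2, h2 = x$h2,
    mu = x$mu, loglik = x$loglik
  )
}

#' @rdname fit_null
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma_u2", "sigma_e2", "delta", "h2"),
    estimate = c(x$mu, x$sigma_u2, x$sigma_e2, x$delta, x$h2)
  )
}

# Vectorized single-SNP GLS F-tests for one missingness pattern. Takes the
# rotated response/intercept and a rotated dosage block; returns beta, se, F, p.
scan_block <- function(yt, ot, Xt, s, delta) {
  n <- length(yt)
  w <- 1 / (s + delta)
  wo <- w * ot
  a11 <- sum(wo * ot)
  b1 <- sum(wo * yt)
  yy <- sum(w * yt^2)
  A12 <- colSums(Xt * wo)
  A22 <- colSums(Xt^2 * w)
  B2 <- colSums(Xt * (w * yt))
  det <- a11 * A22 - A12^2
  ok <- det > 1e-12 * pmax(a11 * A22, 1e-300)
  beta <- (a11 * B2 - A12 * b1) / det
  alpha <- (A22 * b1 - A12 * B2) / det
  rss <- yy - (alpha * b1 + beta * B2)
  sigma2 <- pmax(rss, 0) / (n - 2)
  var_beta <- sigma2 * a11 / det
  f_stat <- beta^2 / var_beta
  p <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin
  beta[!ok] <- NA_real_; var_beta[!ok] <- NA_real_; f_stat[!ok] <- NA_real_; p[!ok] <- NA_real_
  tibble(
    n = n, beta = unname(beta), se = unname(sqrt(var_beta)),
    f_stat = unname(f_stat), p = unname(p)
  )
}

#' Mixed-model association scan for one feature
#'
#' Tests every polymorphic SNP of the panel against `y` by generalized least
#' squares under the covariance `sigma_u^2 * (K + delta * I)` with `delta`
#' fixed from the null fit. The test is the standard F-test of `beta = 0`
#' with 1 and `n - 2` degrees of freedom (`F = (beta / se)^2`). Strains with a
#' missing genotype at a SNP are dropped pairwise for that SNP; SNPs below the
#' MAF floor or monomorphic among the used strains are skipped (count
#' reported via a message).
#'
#' @param y Named numeric vector of strain-level values.
#' @param panel A [genotype_panel()].
#' @param K A [ibs_kinship()] matrix.
#' @param fit Optional [fit_null()] result for `y` on the same strains;
#'   computed when `NULL`.
#' @param maf_min Minor-allele-frequency floor among the strains used.
#' @param exact_delta If `TRUE`, re-estimate `delta` by REML per SNP under the
#'   two-parameter design (slow; reference mode).
#' @return Tibble with one row per tested SNP: `snp_id, chrom, pos, n, beta,
#'   se, f_stat, p`.
#' @export
assoc_scan <- function(y, panel, K, fit = NULL, maf_min = 0.05, exact_delta = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(names(y))) abort("y must be named by strain id")
  used <- names(y)[!is.na(y)]
  used <- used[used %in% rownames(panel$dosage)]
  if (is.null(fit)) {
    fit <- fit_null(y, K)
  } else if (!setequal(fit$strains, used)) {
    abort("`fit` was computed on a different strain set than y")
  }
  used <- fit$strains
  yv <- y[used]
  X <- panel$dosage[used, , drop = FALSE]

  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  mono <- !is.na(maf) & maf == 0
  low <- !is.na(maf) & maf > 0 & maf < maf_min
  keep <- which(!is.na(maf) & maf >= maf_min)
  if (sum(mono) + sum(low) > 0) {
    inform(sprintf(
      "assoc_scan: skipped %d monomorphic and %d low-MAF SNPs", sum(mono), sum(low)
    ))
  }
  meta <- panel$snp_meta
  if (length(keep) == 0) {
    warn("all SNPs monomorphic or below the MAF floor; empty association table")
    return(tibble(
      snp_id = character(), chrom = character(), pos = numeric(),
      n = integer(), beta = numeric(), se = numeric(), f_stat = numeric(), p = numeric()
    ))
  }
  X <- X[, keep, drop = FALSE]
  meta <- meta[keep, ]

  if (exact_delta) {
    out <- purrr::map(seq_len(ncol(X)), function(j) {
      x <- X[, j]
      ok <- !is.na(x)
      scan_exact_one(yv[ok], x[ok], unclass(K)[used[ok], used[ok]])
    })
    res <- dplyr::bind_rows(out)
  } else {
    pat <- apply(is.na(X), 2, function(z) paste(which(z), collapse = ","))
    res <- vector("list", length(unique(pat)))
    names(res) <- unique(pat)
    for (pp in unique(pat)) {
      cols <- which(pat == pp)
      miss <- if (pp == "") integer(0) else as.integer(strsplit(pp, ",")[[1]])
      rows <- if (length(miss) == 0) seq_along(used) else setdiff(seq_along(used), miss)
      if (length(rows) < 8) {
        res[[pp]] <- tibble(
          n = length(rows), beta = NA_real_, se = NA_real_,
          f_stat = NA_real_, p = NA_real_
        )[rep(1, length(cols)), ]
        res[[pp]]$.col <- cols
        next
      }
      if (length(miss) == 0) {
        eg <- fit$eigen
        ys <- yv
      } else {
        eg <- kinship_eigen(unclass(K)[used[rows], used[rows]])
        ys <- yv[rows]
      }
      yt <- crossprod(eg$U, ys)[, 1]
      ot <- crossprod(eg$U, rep(1, length(rows)))[, 1]
      Xt <- crossprod(eg$U, X[rows, cols, drop = FALSE])
      blk <- scan_block(yt, ot, Xt, eg$s, fit$delta)
      blk$.col <- cols
      res[[pp]] <- blk
    }
    res <- dplyr::arrange(dplyr::bind_rows(res), .data$.col)
    res$.col <- NULL
  }
  dplyr::bind_cols(meta[c("snp_id", "chrom", "pos")], res)
}

# exact mode: re-profile delta per SNP under the [1, x] design
scan_exact_one <- function(y, x, Ks) {
  n <- length(y)
  if (n < 8 || var(x) == 0) {
    return(tibble(n = n, beta = NA_real_, se = NA_real_, f_stat = NA_real_, p = NA_real_))
  }
  eg <- kinship_eigen(Ks)
  W <- cbind(1, x)
  yt <- crossprod(eg$U, y)[, 1]
  Wt <- crossprod(eg$U, W)
  logdet_WtW <- determinant(crossprod(W), logarithm = TRUE)$modulus
  grid <- 10^seq(-5, 5, length.out = 100)
  ll <- vapply(grid, function(d) reml_profile(yt, Wt, eg$s, d, logdet_WtW)$ll, numeric(1))
  i <- which.max(ll)
  opt <- optimize(
    function(ld) reml_profile(yt, Wt, eg$s, 10^ld, logdet_WtW)$ll,
    interval = log10(c(grid[max(1, i - 1)], grid[min(100, i + 1)])),
    maximum = TRUE, tol = 1e-8
  )
  delta <- 10^opt$maximum
  blk <- scan_block(yt, crossprod(eg$U, rep(1, n))[, 1],
    crossprod(eg$U, matrix(x, ncol = 1)), eg$s, delta)
  blk$n <- n
  blk
}

#' q-values from a p-value distribution
#'
#' Step-up false-discovery-rate adjustment. `"bh"` is the Benjamini-Hochberg
#' procedure; `"storey"` additionally estimates the null proportion
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` at `lambda = 0.5` and
#' scales the q-values by it.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Tuning point for the Storey `pi0` estimate.
#' @return q-values in the input order.
#' @export
qvalues <- function(p, method = c("storey", "bh"), lambda = 0.5) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  m <- length(p)
  pi0 <- if (method == "storey") min(1, mean(p > lambda) / (1 - lambda)) else 1
  if (pi0 == 0) pi0 <- 1 / m # all p tiny; fall back to pure BH scaling floor
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Map QTLs for a set of features
#'
#' Runs [fit_null()] and [assoc_scan()] for every feature of a strain-level
#' matrix, an [abundance_matrix()] (collapsed to strain means first, since
#' genotype varies only at strain level), or a trait tibble. Per feature, a
#' q-value column is added over its genome-wide scan.
#'
#' @param x An [abundance_matrix()], a trait tibble (`strain_id` + numeric
#'   columns), or a strain-by-feature numeric matrix with strain rownames.
#' @param panel A [genotype_panel()].
#' @param K A kinship matrix; computed from `panel` when `NULL`.
#' @param cfg A [run_config()] (MAF floor, q-value method, coverage floor).
#' @param min_strains Coverage floor; defaults to the config rule for
#'   abundance input and 8 otherwise.
#' @param quantile_normalize Quantile-normalize abundance samples before
#'   strain aggregation.
#' @return List with `assoc` (tibble: `feature_id, snp_id, chrom, pos, n,
#'   beta, se, f_stat, p, q`) and `fits` (one [glance.lmm_fit()] row per
#'   mapped feature).
#' @export
map_qtl <- function(x, panel, K = NULL, cfg = run_config(), min_strains = NULL,
                    quantile_normalize = FALSE) {
  if (is.null(K)) K <- ibs_kinship(panel)
  if (inherits(x, "abundance_matrix")) {
    mat <- strain_aggregate(x, quantile_normalize = quantile_normalize)
    floor_n <- min_strains %||% min_strains_default(cfg, nrow(panel$dosage))
  } else if (is.data.frame(x)) {
    x <- validate_traits(x)
    mat <- as.matrix(x[setdiff(names(x), "strain_id")])
    rownames(mat) <- x$strain_id
    floor_n <- min_strains %||% 8L
  } else {
    mat <- as.matrix(x)
    floor_n <- min_strains %||% 8L
  }
  feats <- colnames(mat)
  assoc <- vector("list", length(feats))
  fits <- vector("list", length(feats))
  skipped <- 0L
  for (j in seq_along(feats)) {
    y <- mat[, j]
    names(y) <- rownames(mat)
    n_obs <- sum(!is.na(y))
    if (n_obs < floor_n || sd(y, na.rm = TRUE) == 0) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_null(y, K)
    fit$feature_id <- feats[j]
    sc <- withCallingHandlers(
      assoc_scan(y, panel, K, fit = fit, maf_min = cfg$maf_min),
      message = function(m) invokeRestart("muffleMessage")
    )
    if (nrow(sc) > 0) {
      ok <- !is.na(sc$p)
      sc$q <- NA_real_
      sc$q[ok] <- qvalues(sc$p[ok], method = cfg$qvalue_method)
      sc <- dplyr::bind_cols(tibble(feature_id = feats[j]), sc)
      assoc[[j]] <- sc
    }
    fits[[j]] <- glance(fit)
  }
  if (skipped > 0) {
    inform(sprintf("map_qtl: skipped %d features below the coverage floor (%d strains) or with zero variance", skipped, floor_n))
  }
  list(assoc = dplyr::bind_rows(assoc), fits = dplyr::bind_rows(fits))
}
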