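#' Identity-by-state kinship matrix
#'
#' For strains `i, j`, `K[i, j]` is the mean over pairwise-complete SNPs of
#' `1 - |g_i - g_j| / 2`, i.e. the average allelic identity-by-state across all
#' SNPs. The diagonal is exactly 1. This realized IBS matrix is the `K` of the
#' mixed model's polygenic covariance `var(u) = sigma_u^2 * K`.
#'
#' @param panel A [genotype_panel()] with at least 2 strains.
#' @return A `kinship_matrix`: numeric strain-by-strain matrix in `[0, 1]`.
#' @export
ibs_kinship <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  D <- panel$dosage
  if (nrow(D) < 2) abort("kinship needs at least 2 strains")
  obs <- !is.na(D)
  # |a-b| over dosages {0,1,2} via indicator cross-products
  A0 <- (D == 0) & obs; A1 <- (D == 1) & obs; A2 <- (D == 2) & obs
  A0[!obs] <- FALSE; A1[!obs] <- FALSE; A2[!obs] <- FALSE
  A0 <- A0 * 1; A1 <- A1 * 1; A2 <- A2 * 1
  S <- 2 * (A0 %*% t(A2)) + A0 %*% t(A1) + A1 %*% t(A0) +
    A1 %*% t(A2) + A2 %*% t(A1) + 2 * (A2 %*% t(A0))
  C <- (obs * 1) %*% t(obs * 1)
  if (any(C == 0)) {
    bad <- which(C == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "strains '%s' and '%s' share no jointly observed SNPs",
      rownames(D)[bad[1]], rownames(D)[bad[2]]
    ))
  }
  K <- 1 - S / (2 * C)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(D), rownames(D))
  structure(K, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf(
    "<kinship_matrix> %d strains; off-diagonal range [%.3f, %.3f]\n",
    nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])
  ))
  invisible(x)
}

#' Tidy a kinship matrix into long format
#' @param x A `kinship_matrix`.
#' @param ... Unused.
#' @return Tibble `strain_a, strain_b, kinship` (all ordered pairs).
#' @method tidy kinship_matrix
#' @export
tidy.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    strain_a = rep(rownames(m), times = ncol(m)),
    strain_b = rep(colnames(m), each = nrow(m)),
    kinship = as.vector(m)
  )
}
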