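# Single-component orthogonal partial least squares (OPLS): one predictive
# component capturing y-correlated variation and one orthogonal component
# absorbing structured y-orthogonal variation, the standard
# orthogonal-signal-correction formulation for a single response.

#' Fit a 1+1 component OPLS model of a trait on the proteome
#'
#' Columns (proteins) are centred and unit-variance scaled by default and `y`
#' is centred. The algorithm: compute the PLS weight `w` proportional to
#' `X'y`; extract one orthogonal component whose loading is the part of the
#' X-loading orthogonal to `w`; deflate `X`; fit the single predictive
#' component on the deflated matrix. The predictive score is oriented so that
#' `cor(t_p, y) >= 0`. `Q2` is estimated by leave-one-strain-out
#' cross-validation.
#'
#' @param X Strain-by-protein matrix (e.g. from [strain_aggregate()]).
#'   Proteins with missing strain values are dropped complete-case (a message
#'   reports the count), as are zero-variance proteins.
#' @param y Named numeric trait vector (names = strain ids) or a trait tibble
#'   column extracted by the caller; strains with missing `y` are dropped.
#' @param scale Unit-variance scale the columns (default `TRUE`).
#' @param cv Compute leave-one-out `Q2`.
#' @return An `opls_fit`: `scores` (tibble `strain_id, t_p, t_o`), `loadings`
#'   (tibble `feature_id, p1, o1, w`), `r2y`, `q2`, `r2x_pred`, `r2x_ortho`,
#'   plus centering/scaling vectors.
#' @export
fit_opls <- function(X, y, scale = TRUE, cv = TRUE) {
  X <- as.matrix(X)
  if (is.null(names(y))) {
    if (length(y) != nrow(X)) abort("unnamed y must match rows of X")
    names(y) <- rownames(X)
  }
  strains <- intersect(rownames(X), names(y)[!is.na(y)])
  X <- X[strains, , drop = FALSE]
  y <- y[strains]
  complete <- colSums(is.na(X)) == 0
  if (any(!complete)) {
    inform(sprintf("fit_opls: dropped %d protein(s) with missing strain values", sum(!complete)))
  }
  X <- X[, complete, drop = FALSE]
  keep_var <- apply(X, 2, sd) > 0
  if (any(!keep_var)) {
    inform(sprintf("fit_opls: dropped %d zero-variance protein(s)", sum(!keep_var)))
  }
  X <- X[, keep_var, drop = FALSE]
  if (nrow(X) < 10) abort("fit_opls needs at least 10 complete-case strains")
  if (ncol(X) < 2) abort("fit_opls needs at least 2 proteins")
  if (sd(y) == 0) abort("zero-variance response")

  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y_ctr <- mean(y)
  ys <- y - y_ctr

  core <- opls_core(Xs, ys)
  ssx <- sum(Xs^2)
  r2x_pred <- sum(core$t_p^2) * sum(core$p1^2) / ssx
  r2x_ortho <- sum(core$t_o^2) * sum(core$o1^2) / ssx
  r2y <- 1 - sum((ys - core$t_p * core$c)^2) / sum(ys^2)

  q2 <- NA_real_
  if (cv) {
    press <- 0
    for (i in seq_len(nrow(Xs))) {
      Xi <- Xs[-i, , drop = FALSE]
      yi <- ys[-i]
      # re-centre within the fold; scaling is kept from the full model
      ctr_i <- colMeans(Xi)
      mi <- opls_core(sweep(Xi, 2, ctr_i), yi - mean(yi))
      xnew <- Xs[i, ] - ctr_i
      t_o_new <- sum(xnew * mi$w_o)
      t_new <- sum((xnew - t_o_new * mi$o1) * mi$w_p)
      pred <- mean(yi) + t_new * mi$c
      press <- press + (ys[i] - pred)^2
    }
    q2 <- 1 - press / sum(ys^2)
  }

  structure(
    list(
      scores = tibble(strain_id = rownames(Xs), t_p = core$t_p, t_o = core$t_o),
      loadings = tibble(
        feature_id = colnames(Xs), p1 = core$p1, o1 = core$o1, w = core$w_p
      ),
      coef_c = core$c, r2y = r2y, q2 = q2,
      r2x_pred = r2x_pred, r2x_ortho = r2x_ortho,
      center = ctr, scale_ = scl, y_center = y_ctr,
      n = nrow(Xs), trait = attr(y, "trait_id") %||% NA_character_
    ),
    class = "opls_fit"
  )
}

# one orthogonal + one predictive component on centred/scaled data
opls_core <- function(Xs, ys) {
  w <- drop(crossprod(Xs, ys))
  w <- w / sqrt(sum(w^2))
  t1 <- drop(Xs %*% w)
  p <- drop(crossprod(Xs, t1)) / sum(t1^2)
  w_o <- p - sum(w * p) * w
  no_ortho <- sqrt(sum(w_o^2)) < 1e-12
  if (no_ortho) {
    t_o <- rep(0, nrow(Xs))
    o1 <- rep(0, ncol(Xs))
    w_o <- rep(0, ncol(Xs))
    Xd <- Xs
  } else {
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- drop(Xs %*% w_o)
    o1 <- drop(crossprod(Xs, t_o)) / sum(t_o^2)
    Xd <- Xs - tcrossprod(t_o, o1)
  }
  w_p <- drop(crossprod(Xd, ys))
  w_p <- w_p / sqrt(sum(w_p^2))
  t_p <- drop(Xd %*% w_p)
  p1 <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  c_coef <- sum(ys * t_p) / sum(t_p^2)
  if (c_coef < 0) { # orient the predictive score along y
    w_p <- -w_p; t_p <- -t_p; p1 <- -p1; c_coef <- -c_coef
  }
  list(t_p = t_p, t_o = t_o, p1 = p1, o1 = o1, w_p = w_p, w_o = w_o, c = c_coef)
}

#' @export
print.opls_fit <- function(x, ...) {
  cat(sprintf(
    "<opls_fit> n = %d strains, %d proteins; R2Y = %.3f, Q2 = %.3f, R2X(pred) = %.3f, R2X(ortho) = %.3f\n",
    x$n, nrow(x$loadings), x$r2y, x$q2, x$r2x_pred, x$r2x_ortho
  ))
  invisible(x)
}

#' @rdname fit_opls
#' @param x An `opls_fit`.
#' @param ... Unused.
#' @method tidy opls_fit
#' @export
tidy.opls_fit <- function(x, ...) x$loadings

#' @rdname fit_opls
#' @method glance opls_fit
#' @export
glance.opls_fit <- function(x, ...) {
  tibble(
    n = x$n, n_proteins = nrow(x$loadings), r2y = x$r2y, q2 = x$q2,
    r2x_pred = x$r2x_pred, r2x_ortho = x$r2x_ortho
  )
}

#' Loading-based prioritization table
#'
#' Joins the OPLS loadings with the corresponding protein-trait correlation
#' results so each protein carries `(p1, o1, r, p, selected)` — the loading
#' plot with correlation-filter highlighting.
#'
#' @param model An [fit_opls()] result.
#' @param corr_results Tibble from [correlate_features()] restricted to the
#'   modelled trait; must cover the model's retained proteins.
#' @return Tibble: `feature_id, p1, o1, r, p, q, selected`, one row per
#'   protein retained in the model.
#' @export
export_loadings <- function(model, corr_results) {
  stopifnot(inherits(model, "opls_fit"))
  idx <- match(model$loadings$feature_id, corr_results$feature_a)
  if (anyNA(idx)) {
    abort(sprintf(
      "correlation results missing %d protein(s) of the model",
      sum(is.na(idx))
    ))
  }
  dplyr::bind_cols(
    model$loadings[c("feature_id", "p1", "o1")],
    corr_results[idx, c("r", "p", "q", "selected")]
  )
}
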