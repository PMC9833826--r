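# Reproducibility metrics, normalization/aggregation, robust correlation
# statistics, repeatability, and the screen-style differential tests.

#' Aggregate replicate samples to strain level
#'
#' Optionally quantile-normalizes the samples (each sample's values are mapped
#' onto the rank-average reference distribution; ties share the mean of their
#' rank slots) and then averages the biological replicates within each strain
#' on the log2 scale, ignoring missing values. A strain with no non-missing
#' sample for a protein yields a missing cell.
#'
#' @param ab An [abundance_matrix()].
#' @param quantile_normalize Apply quantile normalization across samples
#'   before averaging.
#' @return Strain-by-feature numeric matrix (rownames = strain ids).
#' @export
strain_aggregate <- function(ab, quantile_normalize = TRUE) {
  stopifnot(inherits(ab, "abundance_matrix"))
  values <- ab$values
  if (quantile_normalize) {
    # samples are rows here; limma normalizes columns, so transpose
    values <- t(limma::normalizeQuantiles(t(values), ties = TRUE))
    dimnames(values) <- dimnames(ab$values)
  }
  strain <- ab$sample_to_strain$strain_id
  strains <- unique(strain)
  sums <- rowsum(ifelse(is.na(values), 0, values), strain, reorder = FALSE)
  ns <- rowsum((!is.na(values)) * 1, strain, reorder = FALSE)
  out <- sums / ns
  out[ns == 0] <- NA_real_
  out[strains, , drop = FALSE]
}

#' Intra- and inter-strain coefficients of variation
#'
#' Log2 values are delogged to linear ratios (`2^value`). Per protein, the
#' intra-strain CV is the median across strains (with >= 2 replicates) of
#' `100 * sd / mean` within strain, and the inter-strain CV is
#' `100 * sd / mean` across the strain means.
#'
#' @param ab An [abundance_matrix()].
#' @return Tibble with one row per protein: `feature_id, cv_intra, cv_inter`.
#'   Panel-level medians are attached as attribute `"medians"` (named vector).
#' @export
cv_report <- function(ab) {
  stopifnot(inherits(ab, "abundance_matrix"))
  lin <- 2^ab$values
  strain <- ab$sample_to_strain$strain_id
  reps <- table(strain)
  if (!any(reps >= 2)) abort("cv_report needs at least one strain with >= 2 replicates")
  strains <- unique(strain)
  cv_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    100 * sd(v) / mean(v)
  }
  per_strain_cv <- vapply(strains, function(s) {
    idx <- which(strain == s)
    apply(lin[idx, , drop = FALSE], 2, cv_one)
  }, numeric(ncol(lin)))
  if (is.null(dim(per_strain_cv))) per_strain_cv <- matrix(per_strain_cv, nrow = 1)
  cv_intra <- apply(per_strain_cv, 1, function(z) {
    if (all(is.na(z))) NA_real_ else median(z, na.rm = TRUE)
  })
  means <- rowsum(ifelse(is.na(lin), 0, lin), strain, reorder = FALSE) /
    rowsum((!is.na(lin)) * 1, strain, reorder = FALSE)
  means[is.nan(means)] <- NA_real_
  cv_inter <- apply(means, 2, cv_one)
  out <- tibble(feature_id = colnames(lin), cv_intra = cv_intra, cv_inter = cv_inter)
  attr(out, "medians") <- c(
    cv_intra = median(cv_intra, na.rm = TRUE),
    cv_inter = median(cv_inter, na.rm = TRUE)
  )
  out
}

#' Biweight midcorrelation
#'
#' Robust correlation weighting observations by their distance from the
#' median: with `d_i = x_i - median(x)` and `u_i = d_i / (9 * mad(x))`
#' (unscaled median absolute deviation), weights are
#' `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]` and the correlation is the normalized
#' cross-product of the weighted deviations. When either vector has zero MAD
#' the function falls back to Pearson correlation (a message flags this).
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped (>= 3 required).
#' @return Correlation in `[-1, 1]`, or `NA` if undefined (constant input).
#' @export
bicor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("bicor needs at least 3 complete pairs")
  wdev <- function(v) {
    d <- v - median(v)
    m <- mad(v, constant = 1)
    if (m == 0) return(NULL)
    u <- d / (9 * m)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d * w
  }
  xt <- wdev(x); yt <- wdev(y)
  if (is.null(xt) || is.null(yt)) {
    inform("bicor: zero median absolute deviation; falling back to Pearson")
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    return(cor(x, y))
  }
  denom <- sqrt(sum(xt^2) * sum(yt^2))
  if (denom == 0) return(NA_real_)
  sum(xt * yt) / denom
}

cor_test_p <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(-abs(t), n - 2)
  p[p == 0] <- .Machine$double.xmin
  list(t = t, p = p)
}

#' Pairwise biweight-midcorrelation statistics
#'
#' Correlates every feature of a strain-level matrix against every trait (or,
#' when `traits` is `NULL`, against every other feature) on pairwise-complete
#' strains. p-values come from the Student t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom and
#' are BH-adjusted across all pairs. A pair is `selected` when
#' `r <= r_low` or `r >= r_high` and `p < p_cut` (the magnitude-plus-p filter
#' used to shortlist trait-associated proteins).
#'
#' @param x Strain-by-feature matrix from [strain_aggregate()].
#' @param traits Trait tibble (`strain_id` + numeric columns), or `NULL` for
#'   all feature-feature pairs (each unordered pair once).
#' @param trait_ids Optional subset of trait columns; unknown ids error.
#' @param r_low,r_high,p_cut Selection filter.
#' @param min_n Minimum complete pairs per correlation.
#' @return Tibble: `feature_a, feature_b, n, r, t_stat, p, q, selected`
#'   (`feature_b` is the trait id when `traits` is given).
#' @export
correlate_features <- function(x, traits = NULL, trait_ids = NULL,
                               r_low = -0.3, r_high = 0.6, p_cut = 0.05,
                               min_n = 3) {
  x <- as.matrix(x)
  pairs <- NULL
  if (!is.null(traits)) {
    traits <- validate_traits(traits)
    tids <- setdiff(names(traits), "strain_id")
    if (!is.null(trait_ids)) {
      missing_t <- setdiff(trait_ids, tids)
      if (length(missing_t) > 0) {
        abort(paste("trait(s) absent from trait table:", paste(missing_t, collapse = ", ")))
      }
      tids <- trait_ids
    }
    shared <- intersect(rownames(x), traits$strain_id)
    if (length(shared) < min_n) abort("fewer than `min_n` shared strains")
    tm <- as.matrix(traits[match(shared, traits$strain_id), tids, drop = FALSE])
    rownames(tm) <- shared
    xm <- x[shared, , drop = FALSE]
    pairs <- tidyr::expand_grid(feature_a = colnames(xm), feature_b = tids)
    get_b <- function(b) tm[, b]
  } else {
    xm <- x
    f <- colnames(xm)
    pairs <- tidyr::expand_grid(feature_a = f, feature_b = f)
    pairs <- pairs[match(pairs$feature_a, f) < match(pairs$feature_b, f), ]
    get_b <- function(b) xm[, b]
  }
  res <- purrr::pmap(pairs, function(feature_a, feature_b) {
    xa <- xm[, feature_a]
    xb <- get_b(feature_b)
    ok <- complete.cases(xa, xb)
    n <- sum(ok)
    if (n < min_n) {
      return(tibble(n = n, r = NA_real_, t_stat = NA_real_, p = NA_real_))
    }
    r <- suppressMessages(bicor(xa[ok], xb[ok]))
    if (is.na(r)) {
      return(tibble(n = n, r = NA_real_, t_stat = NA_real_, p = NA_real_))
    }
    tp <- cor_test_p(r, n)
    tibble(n = n, r = r, t_stat = tp$t, p = tp$p)
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$selected <- !is.na(out$r) & (out$r <= r_low | out$r >= r_high) & !is.na(out$p) & out$p < p_cut
  out
}

#' Correlation network edges
#'
#' Keeps undirected edges for pairs passing an absolute-correlation cutoff and
#' a q cut; each unordered pair appears exactly once.
#'
#' @param results Correlation tibble from [correlate_features()].
#' @param r_cutoff Absolute correlation cutoff.
#' @param q_cutoff q-value cut.
#' @return Tibble of edges `feature_a, feature_b, r, q`; the per-node degree
#'   table is attached as attribute `"degrees"`.
#' @export
network_edges <- function(results, r_cutoff = 0.6, q_cutoff = 0.05) {
  keep <- !is.na(results$r) & abs(results$r) >= r_cutoff &
    !is.na(results$q) & results$q < q_cutoff
  edges <- results[keep, c("feature_a", "feature_b", "r", "q")]
  swap <- edges$feature_a > edges$feature_b
  tmp <- edges$feature_a[swap]
  edges$feature_a[swap] <- edges$feature_b[swap]
  edges$feature_b[swap] <- tmp
  edges <- dplyr::distinct(edges, .data$feature_a, .data$feature_b, .keep_all = TRUE)
  deg <- table(c(edges$feature_a, edges$feature_b))
  attr(edges, "degrees") <- tibble(
    feature_id = names(deg), degree = as.integer(deg)
  )
  edges
}

#' Genetic repeatability (intraclass correlation)
#'
#' One-way random-effects ANOVA estimator of the between-strain variance
#' fraction: `sigma2_within = MS_within`,
#' `sigma2_between = max(0, (MS_between - MS_within) / n0)` with `n0` the
#' unbalanced-design effective group size, and
#' `R = sigma2_between / (sigma2_between + sigma2_within)`. R estimates the
#' genetic ceiling of a trait measured with replicate animals.
#'
#' @param data Long tibble with columns `strain_id` and `value` (one trait).
#' @return One-row tibble: `R, sigma2_between, sigma2_within, n_strains`.
#' @export
repeatability <- function(data) {
  data <- as_tibble(data)
  if (!all(c("strain_id", "value") %in% names(data))) {
    abort("repeatability needs columns strain_id and value")
  }
  data <- data[!is.na(data$value), ]
  ni <- table(data$strain_id)
  if (length(ni) < 2) abort("repeatability needs at least 2 strains")
  if (sum(ni >= 2) < 2) abort("repeatability needs at least 2 strains with >= 2 replicates")
  fit <- stats::aov(value ~ strain_id, data = data)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_b <- ms[1]; ms_w <- ms[2]
  N <- sum(ni); k <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (ms_b - ms_w) / n0)
  tibble(
    R = if (s2b + ms_w == 0) 0 else s2b / (s2b + ms_w),
    sigma2_between = s2b, sigma2_within = ms_w, n_strains = k
  )
}

#' Differential abundance tests (screen / knockdown style)
#'
#' Classical Student t-tests per feature with BH adjustment across features:
#' unpaired uses the pooled-variance two-sample t, paired the one-sample t on
#' within-pair differences. Zero-variance degenerate features get a missing p
#' and a `degenerate` flag.
#'
#' @param data Long tibble with columns `feature_id`, `value`, `group` (two
#'   levels), and `pair_id` when `paired = TRUE`.
#' @param paired Paired test on within-pair differences.
#' @param ref Optional reference group level (differences are `other - ref`);
#'   defaults to the first level.
#' @return Tibble: `feature_id, mean_diff, t_stat, df, p, q, degenerate`.
#' @export
differential <- function(data, paired = FALSE, ref = NULL) {
  data <- as_tibble(data)
  need <- c("feature_id", "value", "group", if (paired) "pair_id")
  if (!all(need %in% names(data))) {
    abort(paste("differential needs columns:", paste(need, collapse = ", ")))
  }
  lev <- unique(as.character(data$group))
  if (length(lev) != 2) abort("group must have exactly two levels")
  ref <- ref %||% lev[1]
  other <- setdiff(lev, ref)
  out <- purrr::map(unique(data$feature_id), function(f) {
    d <- data[data$feature_id == f, ]
    if (paired) {
      wide <- tidyr::pivot_wider(d[c("pair_id", "group", "value")],
        names_from = "group", values_from = "value"
      )
      diffs <- wide[[other]] - wide[[ref]]
      diffs <- diffs[!is.na(diffs)]
      if (length(diffs) < 2) abort(sprintf("feature '%s': fewer than 2 pairs", f))
      md <- mean(diffs)
      if (sd(diffs) == 0) {
        return(tibble(feature_id = f, mean_diff = md, t_stat = NA_real_,
                      df = length(diffs) - 1, p = NA_real_, degenerate = TRUE))
      }
      tt <- stats::t.test(diffs)
      tibble(feature_id = f, mean_diff = md, t_stat = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
    } else {
      a <- d$value[d$group == other & !is.na(d$value)]
      b <- d$value[d$group == ref & !is.na(d$value)]
      if (length(a) < 2 || length(b) < 2) {
        abort(sprintf("feature '%s': fewer than 2 observations per group", f))
      }
      md <- mean(a) - mean(b)
      if (sd(a) == 0 && sd(b) == 0) {
        if (md == 0) {
          return(tibble(feature_id = f, mean_diff = 0, t_stat = 0,
                        df = length(a) + length(b) - 2, p = 1, degenerate = FALSE))
        }
        return(tibble(feature_id = f, mean_diff = md, t_stat = NA_real_,
                      df = length(a) + length(b) - 2, p = NA_real_, degenerate = TRUE))
      }
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tibble(feature_id = f, mean_diff = md, t_stat = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
    }
  })
  out <- dplyr::bind_rows(out)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out[c("feature_id", "mean_diff", "t_stat", "df", "p", "q", "degenerate")]
}
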