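# Label-free interaction-proteomics statistics: down-shifted Gaussian
# imputation of missing-not-at-random values, per-protein two-sample
# tests, and a SAM-style permutation false discovery rate.

#' Down-shifted Gaussian imputation of missing LFQ values
#'
#' Per sample column, missing values are drawn from
#' `Normal(mean_col - shift * sd_col, (width * sd_col)^2)`, the standard
#' treatment of proteins near the detection limit. Observed values are
#' never altered; draws are deterministic given `seed`.
#'
#' @param m an [lfq_matrix()] of log2 intensities.
#' @param width imputation width as a fraction of the column sd
#'   (default 0.3).
#' @param shift downshift in column sds (default 1.8).
#' @param seed integer seed.
#' @param min_obs columns with fewer observed values fall back to the
#'   global mean/sd (flagged in the result).
#' @return An [lfq_matrix()] without missing values; attribute
#'   `imputed_mask` marks imputed cells, `global_fallback_cols` names
#'   columns that used the global moments.
#' @export
impute_downshift <- function(m, width = 0.3, shift = 1.8, seed = 1L,
                             min_obs = 3L) {
  stopifnot(inherits(m, "lfq_matrix"))
  x <- m$intensity
  set.seed(as.integer(seed))
  fallback <- character(0)
  g_mean <- mean(x, na.rm = TRUE)
  g_sd <- sd(as.numeric(x), na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    obs <- x[!miss, j]
    if (length(obs) < min_obs) {
      mu_j <- g_mean; sd_j <- g_sd
      fallback <- c(fallback, colnames(x)[j])
    } else {
      mu_j <- mean(obs); sd_j <- sd(obs)
    }
    x[miss, j] <- rnorm(sum(miss), mean = mu_j - shift * sd_j,
                        sd = width * sd_j)
  }
  out <- lfq_matrix(x, m$groups)
  attr(out, "imputed_mask") <- is.na(m$intensity)
  attr(out, "global_fallback_cols") <- fallback
  out
}

# Vectorized per-protein two-sample t. Returns diff (g1 - g2), se, t, df.
row_t_stats <- function(x, groups, var_equal = TRUE) {
  g1 <- levels(groups)[1]
  x1 <- x[, groups == g1, drop = FALSE]
  x2 <- x[, groups != g1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  list(diff = m1 - m2, se = se, t = ifelse(se > 0, (m1 - m2) / se, 0),
       df = df)
}

#' Per-protein two-sample t-test
#'
#' Equal-variance (Student) t by default, Welch behind a flag; two-tailed
#' p-values. Zero-variance degenerate proteins get t = 0, p = 1 and a
#' flag.
#'
#' @param m a complete (post-imputation) [lfq_matrix()].
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame per protein: `mean_diff` (first group level minus
#'   second, log2), `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
two_sample_test <- function(m, var_equal = TRUE) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (any(is.na(m$intensity)))
    stop("two_sample_test: matrix contains missing values; impute first")
  st <- row_t_stats(m$intensity, m$groups, var_equal = var_equal)
  degen <- st$se <= 0
  p <- ifelse(degen, 1, 2 * pt(-abs(st$t), df = st$df))
  data.frame(protein_id = rownames(m$intensity), mean_diff = st$diff,
             t_statistic = st$t, df = st$df, p_value = p,
             degenerate = degen, stringsAsFactors = FALSE)
}

all_label_permutations <- function(groups) {
  n <- length(groups)
  g1 <- levels(groups)[1]
  k <- sum(groups == g1)
  idx <- combn(n, k)
  obs <- which(groups == g1)
  comp <- which(groups != g1)
  perms <- lapply(seq_len(ncol(idx)), function(i) {
    # skip the observed partition and its mirror: they reproduce the
    # observed |d| and carry no null information
    if (identical(idx[, i], obs) ||
        (length(comp) == k && identical(idx[, i], comp))) return(NULL)
    g <- factor(rep(levels(groups)[2], n), levels = levels(groups))
    g[idx[, i]] <- g1
    g
  })
  Filter(Negate(is.null), perms)
}

#' SAM-style permutation false discovery rate
#'
#' Computes the modified statistic `d = diff / (se + s0)` per protein,
#' permutes group labels to build the null, and finds the smallest
#' |d| threshold whose estimated FDR is at most `fdr_q`. The estimate is
#' the add-one-corrected mean count of permutation exceedances per
#' permutation, divided by the number of observed positives; the
#' correction counts the observed labeling as one more permutation, so
#' the estimate is never exactly zero. The observed partition and its
#' mirror are excluded from the null set. When the number of remaining
#' distinct label assignments is small, all are enumerated exactly;
#' otherwise `n_perm` random ones are drawn. If no informative
#' permutation exists the procedure falls back to Bonferroni on the
#' t-test p-values (flagged). Deterministic given `seed`.
#'
#' @param m a complete [lfq_matrix()].
#' @param s0 fudge factor stabilizing low-variance proteins (default
#'   0.1).
#' @param n_perm permutations (default 250; >= 100 recommended).
#' @param fdr_q target FDR (default 0.05).
#' @param seed integer seed.
#' @param var_equal pooled-variance statistic (default) or Welch.
#' @return An `enrichment_volcano` data.frame per protein: `mean_diff`,
#'   `t_statistic`, `d_statistic`, `p_value`, `significant`; attributes
#'   `threshold` (|d| cutoff, `Inf` if none attainable), `est_fdr`,
#'   `n_perm_used`, `exact`.
#' @export
permutation_fdr <- function(m, s0 = 0.1, n_perm = 250L, fdr_q = 0.05,
                            seed = 1L, var_equal = TRUE) {
  stopifnot(inherits(m, "lfq_matrix"))
  if (any(is.na(m$intensity)))
    stop("permutation_fdr: matrix contains missing values; impute first")
  x <- m$intensity
  groups <- m$groups
  st <- row_t_stats(x, groups, var_equal = var_equal)
  d_obs <- st$diff / (st$se + s0)
  tt <- two_sample_test(m, var_equal = var_equal)
  set.seed(as.integer(seed))
  perms <- all_label_permutations(groups)
  ad <- abs(d_obs)
  if (!length(perms)) {
    # degenerate design: no informative permutation; Bonferroni fallback
    sig <- tt$p_value <= fdr_q / nrow(x)
    out <- data.frame(protein_id = rownames(x), mean_diff = st$diff,
                      t_statistic = st$t, d_statistic = d_obs,
                      p_value = tt$p_value, significant = sig,
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- NA_real_
    attr(out, "est_fdr") <- NA_real_
    attr(out, "n_perm_used") <- 0L
    attr(out, "exact") <- TRUE
    attr(out, "bonferroni_fallback") <- TRUE
    class(out) <- c("enrichment_volcano", "data.frame")
    return(out)
  }
  exact <- length(perms) <= n_perm
  if (!exact) {
    pick <- sample.int(length(perms), n_perm)
    perms <- perms[pick]
  }
  d_perm <- vapply(perms, function(g) {
    s <- row_t_stats(x, g, var_equal = var_equal)
    abs(s$diff / (s$se + s0))
  }, numeric(nrow(x)))
  cand <- sort(unique(ad), decreasing = TRUE)
  eps <- 1e-9
  sorted_ad <- sort(ad)
  sorted_perm <- sort(as.numeric(d_perm))
  n_pos <- length(ad) - findInterval(cand - eps, sorted_ad)
  fp_tot <- length(sorted_perm) - findInterval(cand - eps, sorted_perm)
  # add-one conservative estimate: the observed labeling counts as one
  # more permutation, so the estimated FDR is never exactly zero; the
  # chosen cutoff is the lowest |d| whose estimate stays within fdr_q
  fdr_hat <- (1 + fp_tot) / ((length(perms) + 1) * n_pos)
  ok <- which(fdr_hat <= fdr_q)
  if (length(ok)) {
    threshold <- cand[max(ok)]
    est_fdr <- fdr_hat[max(ok)]
  } else {
    threshold <- Inf
    est_fdr <- NA_real_
  }
  sig <- is.finite(threshold) & ad >= threshold
  out <- data.frame(protein_id = rownames(x), mean_diff = st$diff,
                    t_statistic = st$t, d_statistic = d_obs,
                    p_value = tt$p_value, significant = sig,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "est_fdr") <- est_fdr
  attr(out, "n_perm_used") <- length(perms)
  attr(out, "exact") <- exact
  attr(out, "bonferroni_fallback") <- FALSE
  class(out) <- c("enrichment_volcano", "data.frame")
  out
}
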