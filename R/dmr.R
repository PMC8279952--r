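# Focal DMR calling between a near-zero baseline methylome and a rescue
# methylome, length-matched random control regions, and one-sided
# rank-sum enrichment of region sets over annotation classes.

#' DMR-calling parameters
#'
#' Defaults are this package's re-specification of a window-scan caller:
#' sliding windows of `min_cpgs_per_window` consecutive co-covered CpGs
#' (step 1 CpG), a two-proportion z-test on pooled window counts,
#' Benjamini-Hochberg correction across windows, merging of significant
#' windows separated by at most `merge_gap_bp`, and region-level filters.
#'
#' @param min_cpgs_per_window CpGs per sliding window.
#' @param min_cov minimum per-CpG coverage in both samples.
#' @param min_delta minimum region mean methylation gain (sample -
#'   baseline).
#' @param fdr_q BH q-value cutoff for window significance.
#' @param merge_gap_bp maximum gap between significant windows merged
#'   into one region.
#' @param min_region_cpgs minimum co-covered CpGs per reported region.
#' @return A validated `dmr_params` list.
#' @export
dmr_params <- function(min_cpgs_per_window = 5L, min_cov = 5L,
                       min_delta = 0.1, fdr_q = 0.05,
                       merge_gap_bp = 250L, min_region_cpgs = 10L) {
  p <- list(min_cpgs_per_window = as.integer(min_cpgs_per_window),
            min_cov = as.integer(min_cov), min_delta = min_delta,
            fdr_q = fdr_q, merge_gap_bp = as.integer(merge_gap_bp),
            min_region_cpgs = as.integer(min_region_cpgs))
  if (p$min_cpgs_per_window < 1 || p$min_cov < 1 ||
      p$min_region_cpgs < 1 || p$merge_gap_bp < 0)
    stop("dmr_params: window/coverage/region parameters must be positive")
  if (p$min_delta <= 0 || p$min_delta > 1)
    stop("dmr_params: min_delta must be in (0, 1]")
  if (p$fdr_q <= 0 || p$fdr_q >= 1)
    stop("dmr_params: fdr_q must be in (0, 1)")
  structure(p, class = "dmr_params")
}

#' Call gain DMRs between a baseline and a sample methylome
#'
#' Scans sliding windows of consecutive co-covered CpGs, tests pooled
#' window counts with a two-proportion z-test, BH-adjusts across all
#' windows, merges significant gain windows separated by at most
#' `merge_gap_bp`, trims each merged region to the outermost co-covered
#' CpG whose own gain reaches `min_delta`, and keeps regions with at least
#' `min_region_cpgs` co-covered CpGs and an unweighted mean beta gain of
#' at least `min_delta`.
#'
#' @param baseline,sample [methylome_table()]s on the same genome.
#' @param params a [dmr_params()].
#' @return A [region_set()] of disjoint, sorted DMRs with columns
#'   `mean_baseline`, `mean_sample`, `delta`, `n_cpgs`; `score` holds the
#'   delta.
#' @export
call_dmrs <- function(baseline, sample, params = dmr_params()) {
  stopifnot(inherits(params, "dmr_params"))
  key_b <- paste(baseline$contig, baseline$pos)
  key_s <- paste(sample$contig, sample$pos)
  common <- intersect(key_b, key_s)
  if (!length(common))
    stop("call_dmrs: methylomes share no covered CpGs")
  b <- baseline[match(common, key_b), , drop = FALSE]
  s <- sample[match(common, key_s), , drop = FALSE]
  cov_b <- b$count_M + b$count_U
  cov_s <- s$count_M + s$count_U
  keep <- cov_b >= params$min_cov & cov_s >= params$min_cov
  if (!any(keep)) stop("call_dmrs: no CpG co-covered at min_cov")
  b <- b[keep, , drop = FALSE]
  s <- s[keep, , drop = FALSE]
  o <- order(b$contig, b$pos)
  b <- b[o, , drop = FALSE]; s <- s[o, , drop = FALSE]
  w <- params$min_cpgs_per_window
  win <- NULL
  for (ct in unique(b$contig)) {
    idx <- which(b$contig == ct)
    if (length(idx) < w) next
    starts <- idx[seq_len(length(idx) - w + 1)]
    m_b <- cumsum(c(0, b$count_M[idx]))
    t_b <- cumsum(c(0, b$count_M[idx] + b$count_U[idx]))
    m_s <- cumsum(c(0, s$count_M[idx]))
    t_s <- cumsum(c(0, s$count_M[idx] + s$count_U[idx]))
    i <- seq_len(length(idx) - w + 1)
    M1 <- m_b[i + w] - m_b[i]; N1 <- t_b[i + w] - t_b[i]
    M2 <- m_s[i + w] - m_s[i]; N2 <- t_s[i + w] - t_s[i]
    p1 <- M1 / N1; p2 <- M2 / N2
    pp <- (M1 + M2) / (N1 + N2)
    se <- sqrt(pp * (1 - pp) * (1 / N1 + 1 / N2))
    z <- ifelse(se > 0, (p2 - p1) / se, 0)
    pv <- 2 * pnorm(-abs(z))
    win <- rbind(win, data.frame(
      contig = ct, start = b$pos[starts],
      end = b$pos[idx[i + w - 1]] + 1, delta = p2 - p1, p = pv,
      stringsAsFactors = FALSE))
  }
  empty <- region_set()
  empty$mean_baseline <- empty$mean_sample <- empty$delta <- numeric(0)
  empty$n_cpgs <- integer(0)
  if (is.null(win)) return(empty)
  win$q <- p.adjust(win$p, method = "BH")
  sig <- win[win$q < params$fdr_q & win$delta > 0, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(sig$contig, IRanges::IRanges(sig$start + 1, sig$end)),
    min.gapwidth = params$merge_gap_bp + 1)
  regions <- granges_to_region_set(gr)
  # boundary refinement: windows straddling a focal gain drag flanking CpGs
  # into the merged span, so trim each region to the outermost co-covered
  # CpG whose own delta reaches min_delta
  beta_b <- b$count_M / (b$count_M + b$count_U)
  beta_s <- s$count_M / (s$count_M + s$count_U)
  trimmed <- lapply(seq_len(nrow(regions)), function(i) {
    idx <- which(b$contig == regions$contig[i] & b$pos >= regions$start[i] &
                   b$pos < regions$end[i])
    hot <- idx[beta_s[idx] - beta_b[idx] >= params$min_delta]
    if (!length(hot)) return(NULL)
    c(i, b$pos[hot[1]], b$pos[hot[length(hot)]] + 1)
  })
  trimmed <- do.call(rbind, trimmed)
  if (is.null(trimmed)) return(empty)
  regions <- regions[trimmed[, 1], , drop = FALSE]
  regions$start <- trimmed[, 2]
  regions$end <- trimmed[, 3]
  regions <- validate_region_set(regions)
  co <- methylome_table(b$contig, b$pos, b$count_M, b$count_U)
  mb <- region_mean_methylation(co, regions, min_cov = 1L)
  cs <- methylome_table(s$contig, s$pos, s$count_M, s$count_U)
  ms <- region_mean_methylation(cs, regions, min_cov = 1L)
  regions$mean_baseline <- mb$mean_beta
  regions$mean_sample <- ms$mean_beta
  regions$delta <- ms$mean_beta - mb$mean_beta
  regions$n_cpgs <- mb$n_cpgs_used
  ok <- regions$n_cpgs >= params$min_region_cpgs &
    !is.na(regions$delta) & regions$delta >= params$min_delta
  regions <- regions[ok, , drop = FALSE]
  if (!nrow(regions)) return(empty)
  regions$label <- sprintf("dmr_%05d", seq_len(nrow(regions)))
  regions$score <- regions$delta
  rownames(regions) <- NULL
  class(regions) <- c("region_set", "data.frame")
  regions
}

#' Length-matched, randomly placed control regions
#'
#' For each DMR, draws `n_per_dmr` control regions (CRs) of identical
#' length, placed uniformly at random over the non-gap genome (sampling
#' with replacement; CRs may overlap each other). The CR label records the
#' source DMR so per-DMR groupings remain possible.
#'
#' @param dmrs a [region_set()] of source regions.
#' @param genome a [build_toy_genome()]-shaped genome (contig lengths and
#'   `gap_mask` are used), or a list with `contigs` and optional
#'   `gap_mask`.
#' @param n_per_dmr control regions per DMR (default 1000).
#' @param seed integer seed; placement is deterministic given it.
#' @return A [region_set()] of `nrow(dmrs) * n_per_dmr` regions, labelled
#'   by source DMR.
#' @export
generate_control_regions <- function(dmrs, genome, n_per_dmr = 1000L,
                                     seed = 1L) {
  dmrs <- validate_region_set(dmrs)
  if (!nrow(dmrs)) return(region_set())
  set.seed(as.integer(seed))
  gaps <- if (!is.null(genome$gap_mask) && nrow(genome$gap_mask))
    GenomicRanges::reduce(as_granges(genome$gap_mask)) else NULL
  allowed <- do.call(rbind, lapply(seq_len(nrow(genome$contigs)), function(i) {
    ct <- genome$contigs$name[i]
    full <- GenomicRanges::GRanges(ct, IRanges::IRanges(1, genome$contigs$length[i]))
    a <- if (is.null(gaps)) full else GenomicRanges::setdiff(full, gaps)
    data.frame(contig = as.character(GenomicRanges::seqnames(a)),
               start = GenomicRanges::start(a) - 1,
               end = GenomicRanges::end(a), stringsAsFactors = FALSE)
  }))
  int_len <- allowed$end - allowed$start
  K <- length(int_len)
  L_dmr <- dmrs$end - dmrs$start
  tot_dmr <- vapply(L_dmr, function(L) sum(pmax(0, int_len - L + 1)),
                    numeric(1))
  if (any(tot_dmr <= 0)) {
    i <- which(tot_dmr <= 0)[1]
    stop(sprintf("generate_control_regions: region '%s' (length %d) cannot be placed",
                 dmrs$label[i], as.integer(L_dmr[i])))
  }
  # vectorized placement over all (dmr, draw) pairs; K (number of allowed
  # intervals) is small, so cumulate availability column by column
  L <- rep(L_dmr, each = n_per_dmr)
  u <- floor(runif(length(L), 0, rep(tot_dmr, each = n_per_dmr)))
  iv <- rep(1L, length(L))
  prev_cum <- numeric(length(L))
  cum <- numeric(length(L))
  for (k in seq_len(K)) {
    cum <- cum + pmax(0, int_len[k] - L + 1)
    if (k < K) {
      beyond <- u >= cum
      iv[beyond] <- iv[beyond] + 1L
      prev_cum[beyond] <- cum[beyond]
    }
  }
  st <- allowed$start[iv] + (u - prev_cum)
  region_set(allowed$contig[iv], st, st + L,
             label = rep(dmrs$label, each = n_per_dmr))
}

#' Per-region fraction of length overlapping an annotation class
#'
#' @param regions a [region_set()].
#' @param features an annotation [region_set()] with class labels.
#' @param class_label the feature class to measure against (its intervals
#'   are merged first).
#' @return Numeric vector in `[0, 1]`, one entry per region: overlapped
#'   base pairs / region length.
#' @export
class_overlap_fractions <- function(regions, features, class_label) {
  regions <- validate_region_set(regions)
  feat <- features[features$label == class_label, , drop = FALSE]
  if (!nrow(regions)) return(numeric(0))
  if (!nrow(feat)) return(rep(0, nrow(regions)))
  ov <- intersect_length(regions, feat)
  ov$overlap_bp / (regions$end - regions$start)
}

#' One-sided rank-sum enrichment test (region fractions vs control)
#'
#' Mann-Whitney rank-sum test with midranks for ties, alternative "DMR
#' fractions stochastically greater than CR fractions". For small samples
#' (up to `exact_limit` distinct group assignments) the p-value is the
#' exact permutation tail of the midrank U statistic, which is also the
#' fallback for zero-variance input; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param dmr_fracs,cr_fracs non-empty numeric vectors of per-region
#'   overlap fractions.
#' @param exact_limit maximum number of enumerated assignments for the
#'   exact p-value.
#' @return list: `statistic` (U), `p_value`, `direction`, `effect_size`
#'   (common-language, `U / (n1 n2)`), `method`, group sizes and means.
#' @export
enrichment_test <- function(dmr_fracs, cr_fracs, exact_limit = 2e5) {
  if (!length(dmr_fracs) || !length(cr_fracs))
    stop("enrichment_test: both vectors must be non-empty")
  n1 <- length(dmr_fracs); n2 <- length(cr_fracs)
  pooled <- c(dmr_fracs, cr_fracs)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n_comb <- choose(n1 + n2, n1)
  zero_var <- length(unique(pooled)) == 1
  if (n_comb <= exact_limit || zero_var) {
    if (zero_var) {
      p <- 1
      method <- "exact permutation (degenerate)"
    } else {
      idx <- combn(n1 + n2, n1)
      u_perm <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
      p <- mean(u_perm >= U - 1e-9)
      method <- "exact permutation"
    }
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate"
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- pnorm(z, lower.tail = FALSE)
      method <- "normal approximation, tie-corrected"
    }
  }
  list(statistic = U, p_value = p, direction = "greater",
       effect_size = U / (n1 * n2), method = method,
       n_dmr = n1, n_cr = n2,
       mean_dmr = mean(dmr_fracs), mean_cr = mean(cr_fracs))
}
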