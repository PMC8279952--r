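# Long-read cross-validation of WGBS DMRs: deletion detection from
# alignment gaps, CpG masking, per-region long-read methylation with a
# minimum-CpG filter, the high-confidence delta filter, and DMR/CR
# coverage normalization.

#' Detect sample-specific deletions from long-read alignment gaps
#'
#' Reports maximal intervals where at least `min_span_support` reads have
#' an alignment gap (between two consecutive blocks of the same read)
#' covering the whole interval, and at most `max_internal_reads` reads
#' have any aligned block inside it.
#'
#' @param reads a [long_read_calls()] object.
#' @param genome a genome model (contig namespace; unused coordinates-wise).
#' @param min_span_support minimum gap-spanning reads (default 5).
#' @param max_internal_reads maximum reads allowed with aligned sequence
#'   inside a reported interval (default 0).
#' @return A [region_set()] of deletion calls; `score` holds the number
#'   of spanning reads.
#' @export
detect_deletions <- function(reads, genome, min_span_support = 5L,
                             max_internal_reads = 0L) {
  b <- reads$blocks
  if (!nrow(b)) return(region_set())
  b <- b[order(b$read_id, b$contig, b$start), , drop = FALSE]
  same <- b$read_id[-1] == b$read_id[-nrow(b)] &
    b$contig[-1] == b$contig[-nrow(b)]
  gi <- which(same & b$start[-1] > b$end[-nrow(b)])
  if (!length(gi)) return(region_set())
  gaps <- data.frame(contig = b$contig[gi], start = b$end[gi],
                     end = b$start[gi + 1], stringsAsFactors = FALSE)
  ggr <- GenomicRanges::GRanges(gaps$contig,
                                IRanges::IRanges(gaps$start + 1, gaps$end))
  cov <- GenomicRanges::coverage(ggr)
  sl <- IRanges::slice(cov, lower = min_span_support, rangesOnly = TRUE)
  cand <- methods::as(sl, "GRanges")
  if (!length(cand)) return(region_set())
  bgr <- GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start + 1, b$end))
  hits <- GenomicRanges::findOverlaps(cand, bgr)
  n_internal <- vapply(seq_along(cand), function(i)
    length(unique(b$read_id[subjectHits(hits)[queryHits(hits) == i]])),
    integer(1))
  # spanning support: reads whose gap contains the whole candidate
  hits_g <- GenomicRanges::findOverlaps(cand, ggr, type = "within")
  n_span <- vapply(seq_along(cand), function(i)
    length(unique(b$read_id[gi[subjectHits(hits_g)[queryHits(hits_g) == i]]])),
    integer(1))
  keep <- n_span >= min_span_support & n_internal <= max_internal_reads
  cand <- cand[keep]
  if (!length(cand)) return(region_set())
  region_set(as.character(GenomicRanges::seqnames(cand)),
             GenomicRanges::start(cand) - 1, GenomicRanges::end(cand),
             label = sprintf("del_%04d", seq_along(cand)),
             score = n_span[keep])
}

#' Remove CpGs inside deletions
#'
#' @param m a [methylome_table()] (or any data.frame with `contig`,
#'   `pos`).
#' @param deletions a [region_set()]; half-open, so a CpG exactly at a
#'   deletion start is removed.
#' @return list with `kept` (filtered table), `n_masked` CpGs,
#'   `n_regions` and `masked_bp` totals.
#' @export
mask_cpgs <- function(m, deletions) {
  deletions <- validate_region_set(deletions)
  if (!nrow(deletions) || !nrow(m))
    return(list(kept = m, n_masked = 0L, n_regions = nrow(deletions),
                masked_bp = sum(deletions$end - deletions$start)))
  del <- GenomicRanges::reduce(as_granges(deletions))
  gpos <- GenomicRanges::GRanges(m$contig, IRanges::IRanges(m$pos + 1, m$pos + 1))
  inside <- IRanges::overlapsAny(gpos, del)
  list(kept = m[!inside, , drop = FALSE], n_masked = sum(inside),
       n_regions = nrow(deletions),
       masked_bp = sum(GenomicRanges::width(del)))
}

#' Per-region methylation from long-read calls
#'
#' Per CpG, beta is the fraction of M calls over all calls at that
#' position; the region mean is the unweighted mean over CpGs with at
#' least one call inside the region, undefined (`NA`) when fewer than
#' `min_cpgs` such CpGs exist.
#'
#' @param reads a [long_read_calls()] object.
#' @param regions a [region_set()].
#' @param min_cpgs minimum covered CpGs for a defined mean (default 10).
#' @return data.frame: regions plus `n_cpgs_used` and `mean_beta`.
#' @export
nanopore_region_methylation <- function(reads, regions, min_cpgs = 10L) {
  stopifnot(min_cpgs >= 1)
  regions <- validate_region_set(regions)
  cl <- reads$calls
  out <- as.data.frame(regions)
  out$n_cpgs_used <- 0L
  out$mean_beta <- NA_real_
  if (!nrow(cl) || !nrow(regions)) return(out)
  key <- paste(cl$contig, cl$pos)
  nm <- tapply(cl$call == "M", key, sum)
  nt <- tapply(cl$call, key, length)
  uk <- names(nt)
  parts <- strsplit(uk, " ", fixed = TRUE)
  cpg <- data.frame(contig = vapply(parts, `[`, character(1), 1),
                    pos = as.numeric(vapply(parts, `[`, character(1), 2)),
                    beta = as.numeric(nm[uk]) / as.numeric(nt[uk]),
                    stringsAsFactors = FALSE)
  gpos <- GenomicRanges::GRanges(cpg$contig,
                                 IRanges::IRanges(cpg$pos + 1, cpg$pos + 1))
  hits <- GenomicRanges::findOverlaps(as_granges(regions), gpos)
  if (!length(hits)) return(out)
  q <- queryHits(hits)
  n <- tabulate(q, nbins = nrow(regions))
  mb <- tapply(cpg$beta[subjectHits(hits)], q, mean)
  out$n_cpgs_used <- n
  out$mean_beta[as.integer(names(mb))] <- as.numeric(mb)
  out$mean_beta[n < min_cpgs] <- NA_real_
  out
}

#' High-confidence DMR filter on long-read methylation deltas
#'
#' Partitions the input DMRs into `excluded_low_delta` (both long-read
#' means defined and sample - baseline < `min_delta`),
#' `excluded_uncovered` / retained-with-flag for DMRs whose long-read
#' mean is undefined (controlled by `keep_uncovered`: the default TRUE
#' retains them flagged, the "if covered" semantics; FALSE drops them to
#' `excluded_uncovered`), and `retained` otherwise. The partition is
#' exact: every input DMR lands in exactly one output set.
#'
#' @param dmrs a [region_set()].
#' @param baseline_means,sample_means outputs of
#'   [nanopore_region_methylation()] on `dmrs` (same row order).
#' @param min_delta exclusion threshold: delta strictly below it is
#'   excluded (default 0.05, so delta == 0.05 is retained).
#' @param keep_uncovered retain DMRs without defined long-read means
#'   (flagged) instead of excluding them.
#' @return A `filter_report`: list of the three [region_set()]s plus a
#'   per-DMR `detail` table and counts.
#' @export
high_confidence_filter <- function(dmrs, baseline_means, sample_means,
                                   min_delta = 0.05, keep_uncovered = TRUE) {
  dmrs <- validate_region_set(dmrs)
  if (nrow(baseline_means) != nrow(dmrs) ||
      nrow(sample_means) != nrow(dmrs))
    stop("high_confidence_filter: mean tables must cover all DMRs")
  mb <- baseline_means$mean_beta
  ms <- sample_means$mean_beta
  delta <- ms - mb
  covered <- !is.na(delta)
  low <- covered & delta < min_delta
  if (keep_uncovered) {
    retained <- !low
    uncovered <- rep(FALSE, nrow(dmrs))
  } else {
    retained <- covered & !low
    uncovered <- !covered
  }
  detail <- as.data.frame(dmrs)
  detail$nanopore_baseline <- mb
  detail$nanopore_sample <- ms
  detail$nanopore_delta <- delta
  detail$status <- ifelse(low, "excluded_low_delta",
                          ifelse(uncovered, "excluded_uncovered",
                                 ifelse(covered, "retained",
                                        "retained_uncovered_flagged")))
  structure(list(
    input = dmrs,
    excluded_low_delta = dmrs[low, , drop = FALSE],
    excluded_uncovered = dmrs[uncovered, , drop = FALSE],
    retained = dmrs[retained, , drop = FALSE],
    detail = detail,
    counts = c(input = nrow(dmrs), excluded_low_delta = sum(low),
               excluded_uncovered = sum(uncovered),
               retained = sum(retained))), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d DMRs -> %d retained, ",
                     "%d excluded (low delta), %d excluded (uncovered)\n"),
              x$counts["input"], x$counts["retained"],
              x$counts["excluded_low_delta"], x$counts["excluded_uncovered"]))
  invisible(x)
}

region_mean_depth <- function(reads, regions) {
  b <- reads$blocks
  regions <- validate_region_set(regions)
  if (!nrow(b) || !nrow(regions)) return(rep(0, nrow(regions)))
  cov <- GenomicRanges::coverage(
    GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start + 1, b$end)))
  gr <- as_granges(regions)
  depth <- rep(0, nrow(regions))
  for (ct in unique(regions$contig)) {
    idx <- which(regions$contig == ct)
    if (!ct %in% names(cov)) next
    v <- cov[[ct]]
    depth[idx] <- vapply(idx, function(i) {
      s <- regions$start[i] + 1
      e <- min(regions$end[i], length(v))
      if (s > length(v)) return(0)
      mean(as.numeric(IRanges::Views(v, s, e)[[1]])) *
        (e - s + 1) / (regions$end[i] - regions$start[i])
    }, numeric(1))
  }
  depth
}

#' Normalize DMR read depth by its own control regions
#'
#' Per DMR: mean aligned-block depth over the DMR divided by the mean
#' depth over that DMR's control regions (linked by CR label = DMR
#' label). A ratio near 1 indicates no mapping bias against the DMRs.
#'
#' @param reads a [long_read_calls()] object (depth from aligned blocks
#'   only).
#' @param dmrs a [region_set()].
#' @param crs control regions from [generate_control_regions()] (labels
#'   name the source DMR).
#' @return data.frame per DMR: `dmr_depth`, `cr_depth`, `ratio` (`NA`
#'   and reported when the CR depth is zero).
#' @export
coverage_normalization <- function(reads, dmrs, crs) {
  dmrs <- validate_region_set(dmrs)
  crs <- validate_region_set(crs)
  d_depth <- region_mean_depth(reads, dmrs)
  c_depth_all <- region_mean_depth(reads, crs)
  cr_mean <- tapply(c_depth_all, crs$label, mean)
  out <- data.frame(label = dmrs$label, dmr_depth = d_depth,
                    cr_depth = as.numeric(cr_mean[dmrs$label]),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(!is.na(out$cr_depth) & out$cr_depth > 0,
                      out$dmr_depth / out$cr_depth, NA_real_)
  out
}
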