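# Pairwise methylome comparison: fixed genomic windows, per-element
# deltas with gain/loss classification, and read-level methylation classes.

#' Mean methylation in fixed non-overlapping windows
#'
#' Tiles each contig from position 0 in `window_bp` steps and reports the
#' unweighted mean beta of covered CpGs per window; windows without a
#' covered CpG are undefined (`NA`) and excluded from downstream fractions.
#'
#' @param m a [methylome_table()].
#' @param window_bp window size in bp (default 5000).
#' @param contig_lengths optional named vector of contig lengths; defaults
#'   to the last CpG position + 1 per contig.
#' @param min_cov minimum per-CpG coverage.
#' @return A [region_set()]-shaped data.frame with `n_cpgs_used` and
#'   `mean_beta` per window.
#' @export
window_means <- function(m, window_bp = 5000L, contig_lengths = NULL,
                         min_cov = 1L) {
  stopifnot(window_bp >= 1)
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(m$pos, m$contig, function(p) max(p) + 1)
  }
  wins <- do.call(rbind, lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    s <- seq(0, len - 1, by = window_bp)
    data.frame(contig = ct, start = s, end = pmin(s + window_bp, len),
               stringsAsFactors = FALSE)
  }))
  wins <- region_set(wins$contig, wins$start, wins$end,
                     label = sprintf("win_%06d", seq_len(nrow(wins))))
  region_mean_methylation(m, wins, min_cov = min_cov, min_cpgs = 1L)
}

#' Classify per-unit methylation differences as gain / loss / unchanged
#'
#' Computes per-unit mean methylation in both samples, the delta
#' (`b - a`), and classifies each defined unit: gain when
#' `delta > threshold`, loss when `delta < -threshold`, else unchanged.
#' Units undefined in either sample are excluded from the summary
#' denominators (the number excluded is reported).
#'
#' @param a,b [methylome_table()]s on the same genome (a = reference).
#' @param units a [region_set()] of comparison units (elements or windows).
#' @param threshold absolute delta beyond which a unit is gain/loss
#'   (strict inequality; default 0.05, i.e. 5% methylation).
#' @param min_cov,min_cpgs per-unit coverage filters as in
#'   [region_mean_methylation()].
#' @return list with `units` (per-unit table: mean_a, mean_b, delta,
#'   class) and `summary` (fractions of defined units per class plus
#'   `n_defined`, `n_excluded`).
#' @export
classify_delta <- function(a, b, units, threshold = 0.05, min_cov = 1L,
                           min_cpgs = 1L) {
  if (!length(intersect(unique(a$contig), unique(b$contig))))
    stop("classify_delta: methylomes share no contigs")
  ma <- region_mean_methylation(a, units, min_cov = min_cov,
                                min_cpgs = min_cpgs)
  mb <- region_mean_methylation(b, units, min_cov = min_cov,
                                min_cpgs = min_cpgs)
  out <- as.data.frame(units)
  out$mean_a <- ma$mean_beta
  out$mean_b <- mb$mean_beta
  out$delta <- out$mean_b - out$mean_a
  out$class <- ifelse(is.na(out$delta), NA_character_,
                      ifelse(out$delta > threshold, "gain",
                             ifelse(out$delta < -threshold, "loss",
                                    "unchanged")))
  def <- !is.na(out$class)
  n_def <- sum(def)
  frac <- function(cl) if (n_def) sum(out$class[def] == cl) / n_def else NA_real_
  list(units = out,
       summary = list(frac_gain = frac("gain"), frac_loss = frac("loss"),
                      frac_unchanged = frac("unchanged"),
                      n_defined = n_def, n_excluded = sum(!def)))
}

#' Read-level methylation classes within a region
#'
#' A read is counted if it has at least `min_calls` methylation calls
#' inside the region; counted reads are classified as fully unmethylated
#' (zero M calls), fully methylated (zero U calls) or partially
#' methylated. Fractions sum to 1 over counted reads.
#'
#' @param reads a [long_read_calls()] object (or any per-read call table
#'   of the same shape).
#' @param region a single-row [region_set()].
#' @param min_calls minimum calls inside the region for a read to count.
#' @return list with `fractions` (fully_unmethylated,
#'   partially_methylated, fully_methylated), `n_reads` counted and
#'   `per_read` detail.
#' @export
read_level_classes <- function(reads, region, min_calls = 1L) {
  stopifnot(min_calls >= 1, nrow(region) == 1)
  cl <- reads$calls
  inside <- cl$contig == region$contig & cl$pos >= region$start &
    cl$pos < region$end
  cl <- cl[inside, , drop = FALSE]
  if (!nrow(cl))
    return(list(fractions = c(fully_unmethylated = NA_real_,
                              partially_methylated = NA_real_,
                              fully_methylated = NA_real_),
                n_reads = 0L, per_read = NULL))
  nm <- tapply(cl$call == "M", cl$read_id, sum)
  nt <- tapply(cl$call, cl$read_id, length)
  keep <- nt >= min_calls
  nm <- nm[keep]; nt <- nt[keep]
  if (!length(nm))
    return(list(fractions = c(fully_unmethylated = NA_real_,
                              partially_methylated = NA_real_,
                              fully_methylated = NA_real_),
                n_reads = 0L, per_read = NULL))
  cls <- ifelse(nm == 0, "fully_unmethylated",
                ifelse(nm == nt, "fully_methylated", "partially_methylated"))
  fr <- c(fully_unmethylated = mean(cls == "fully_unmethylated"),
          partially_methylated = mean(cls == "partially_methylated"),
          fully_methylated = mean(cls == "fully_methylated"))
  list(fractions = fr, n_reads = length(cls),
       per_read = data.frame(read_id = names(nm), n_calls = as.integer(nt),
                             n_m = as.integer(nm), class = cls,
                             stringsAsFactors = FALSE))
}
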