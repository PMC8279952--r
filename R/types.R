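#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom stats rpois rbinom rmultinom rnorm rlnorm runif sd setNames
#'   optim p.adjust pnorm pt dmultinom complete.cases median quantile
#' @importFrom utils head tail combn
#' @importFrom methods as
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# CpGs are keyed by the plus-strand C position.

DYAD_STATES <- c("UU", "MU", "UM", "MM")

#' Per-CpG methylation count table
#'
#' The central container for bisulfite (or bisulfite-like) methylation data:
#' one row per CpG with methylated and unmethylated read counts. Beta values
#' (`count_M / (count_M + count_U)`) are defined only where coverage is
#' positive.
#'
#' @param contig character vector of contig names.
#' @param pos 0-based position of the plus-strand C of each CpG.
#' @param count_M,count_U non-negative integer read counts.
#' @return A `methylome_table`: a data.frame with columns `contig`, `pos`,
#'   `count_M`, `count_U`, sorted by contig then position, rows unique.
#' @export
methylome_table <- function(contig = character(), pos = integer(),
                            count_M = integer(), count_U = integer()) {
  x <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                  count_M = as.integer(count_M), count_U = as.integer(count_U),
                  stringsAsFactors = FALSE)
  validate_methylome_table(x)
}

validate_methylome_table <- function(x) {
  stopifnot(all(c("contig", "pos", "count_M", "count_U") %in% names(x)))
  if (any(x$count_M < 0) || any(x$count_U < 0))
    stop("methylome_table: counts must be non-negative")
  if (any(x$pos < 0)) stop("methylome_table: positions must be >= 0")
  o <- order(x$contig, x$pos)
  x <- x[o, , drop = FALSE]
  if (anyDuplicated(paste(x$contig, x$pos)))
    stop("methylome_table: duplicate (contig, pos) records")
  rownames(x) <- NULL
  class(x) <- c("methylome_table", "data.frame")
  x
}

#' Beta values of a methylome table
#'
#' @param m a [methylome_table()].
#' @return Numeric vector, `NA` where coverage is zero.
#' @export
beta_values <- function(m) {
  cov <- m$count_M + m$count_U
  ifelse(cov > 0, m$count_M / cov, NA_real_)
}

#' Labeled genomic interval set
#'
#' Half-open 0-based intervals with a class label and optional score. Used
#' for DMRs, control regions, repeat/feature annotation, gaps and deletions.
#'
#' @param contig,start,end interval coordinates, 0-based half-open.
#' @param label character labels (feature class, region id, ...).
#' @param score optional numeric score.
#' @return A `region_set` data.frame with columns `contig`, `start`, `end`,
#'   `label`, `score`.
#' @export
region_set <- function(contig = character(), start = integer(),
                       end = integer(), label = ".", score = NA_real_) {
  n <- max(length(contig), length(start), length(end))
  x <- data.frame(contig = rep_len(as.character(contig), n),
                  start = as.numeric(start), end = as.numeric(end),
                  label = rep_len(as.character(label), n),
                  score = rep_len(as.numeric(score), n),
                  stringsAsFactors = FALSE)
  validate_region_set(x)
}

validate_region_set <- function(x) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  if (is.null(x$label)) x$label <- "."
  if (is.null(x$score)) x$score <- NA_real_
  if (any(x$start < 0)) stop("region_set: negative start")
  if (any(x$start >= x$end)) stop("region_set: start must be < end")
  rownames(x) <- NULL
  class(x) <- c("region_set", "data.frame")
  x
}

as_granges <- function(x) {
  GenomicRanges::GRanges(x$contig, IRanges::IRanges(x$start + 1, x$end))
}

granges_to_region_set <- function(gr, label = ".", score = NA_real_) {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             label = label, score = score)
}

#' Long-read methylation call set
#'
#' Per-read aligned blocks plus per-CpG hard methylation calls. Blocks of
#' one read are non-overlapping and ordered; every call lies inside one of
#' its read's blocks.
#'
#' @param blocks data.frame with columns `read_id`, `contig`, `start`,
#'   `end` (0-based half-open aligned segments).
#' @param calls data.frame with columns `read_id`, `contig`, `pos`,
#'   `call` (`"M"` or `"U"`).
#' @return A `long_read_calls` object (list of the two validated tables).
#' @export
long_read_calls <- function(blocks, calls) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "contig", "start", "end") %in% names(blocks)),
            all(c("read_id", "contig", "pos", "call") %in% names(calls)))
  if (nrow(blocks) && any(blocks$start >= blocks$end))
    stop("long_read_calls: block start must be < end")
  if (nrow(calls) && !all(calls$call %in% c("M", "U")))
    stop("long_read_calls: calls must be 'M' or 'U'")
  blocks <- blocks[order(blocks$read_id, blocks$contig, blocks$start), , drop = FALSE]
  # blocks of one read must not overlap
  if (nrow(blocks) > 1) {
    same <- blocks$read_id[-1] == blocks$read_id[-nrow(blocks)] &
      blocks$contig[-1] == blocks$contig[-nrow(blocks)]
    if (any(same & blocks$start[-1] < blocks$end[-nrow(blocks)]))
      stop("long_read_calls: overlapping blocks within a read")
  }
  if (nrow(calls)) {
    key <- paste(calls$read_id, calls$contig)
    bkey <- paste(blocks$read_id, blocks$contig)
    inside <- vapply(seq_len(nrow(calls)), function(i) {
      b <- blocks[bkey == key[i], , drop = FALSE]
      any(calls$pos[i] >= b$start & calls$pos[i] < b$end)
    }, logical(1))
    if (!all(inside)) stop("long_read_calls: call outside aligned blocks")
  }
  rownames(blocks) <- rownames(calls) <- NULL
  structure(list(blocks = blocks, calls = calls), class = "long_read_calls")
}

#' @export
print.long_read_calls <- function(x, ...) {
  cat(sprintf("long_read_calls: %d reads, %d blocks, %d calls\n",
              length(unique(x$blocks$read_id)), nrow(x$blocks), nrow(x$calls)))
  invisible(x)
}

#' CpG-dyad count table
#'
#' Counts of the four CpG-dyad states per (sample, locus class). State
#' letters are (plus strand, minus strand): `UU` unmethylated, `MU`/`UM`
#' hemimethylated, `MM` fully methylated.
#'
#' @param sample,class character identifiers.
#' @param n_UU,n_MU,n_UM,n_MM non-negative counts.
#' @return A `dyad_count_table` data.frame.
#' @export
dyad_count_table <- function(sample, class, n_UU, n_MU, n_UM, n_MM) {
  x <- data.frame(sample = as.character(sample), class = as.character(class),
                  n_UU = as.numeric(n_UU), n_MU = as.numeric(n_MU),
                  n_UM = as.numeric(n_UM), n_MM = as.numeric(n_MM),
                  stringsAsFactors = FALSE)
  if (any(unlist(x[, c("n_UU", "n_MU", "n_UM", "n_MM")]) < 0))
    stop("dyad_count_table: counts must be non-negative")
  class(x) <- c("dyad_count_table", "data.frame")
  x
}

dyad_freqs <- function(row) {
  n <- as.numeric(row[c("n_UU", "n_MU", "n_UM", "n_MM")])
  tot <- sum(n)
  if (tot <= 0) stop("dyad state total is zero")
  setNames(n / tot, DYAD_STATES)
}

#' Label-free quantification matrix
#'
#' log2 LFQ intensities, proteins in rows and samples in columns, with an
#' explicit missingness mask (`NA`) and a two-level group factor over
#' samples (bait vs control).
#'
#' @param intensity numeric matrix of log2 intensities (`NA` = missing),
#'   rownames protein ids, colnames sample names.
#' @param groups factor/character of length `ncol(intensity)` with exactly
#'   two levels.
#' @return An `lfq_matrix` object.
#' @export
lfq_matrix <- function(intensity, groups) {
  intensity <- as.matrix(intensity)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(intensity))
  if (nlevels(groups) != 2)
    stop("lfq_matrix: exactly two sample groups required")
  if (any(table(groups) < 2))
    stop("lfq_matrix: at least 2 samples per group required")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- paste0("P", seq_len(nrow(intensity)))
  structure(list(intensity = intensity, groups = groups),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("lfq_matrix: %d proteins x %d samples (%s), %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(levels(x$groups), collapse = " vs "),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Kinetic parameters of the dyad inheritance model
#'
#' @param mu maintenance efficiency: probability per division that the
#'   nascent C opposite a methylated parental C is methylated.
#' @param delta_n de novo efficiency on the nascent strand.
#' @param delta_p de novo efficiency on the parental strand (default 0).
#' @param lam per-division loss of an existing methyl mark (default 0).
#' @param e conversion-failure probability (U read as M).
#' @param c inappropriate-conversion probability (M read as U).
#' @param p0 initial dyad distribution over (UU, MU, UM, MM).
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(mu, delta_n, delta_p = 0, lam = 0,
                           e = 0, c = 0, p0 = c(1, 0, 0, 0)) {
  pr <- c(mu = mu, delta_n = delta_n, delta_p = delta_p, lam = lam,
          e = e, c = c)
  if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
    stop("kinetic_params: all rates must be probabilities in [0, 1]")
  p0 <- as.numeric(p0)
  if (length(p0) != 4 || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("kinetic_params: p0 must be a distribution over the 4 dyad states")
  structure(list(mu = mu, delta_n = delta_n, delta_p = delta_p, lam = lam,
                 e = e, c = c, p0 = setNames(p0 / sum(p0), DYAD_STATES)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "kinetic_params: mu=%.4g delta_n=%.4g delta_p=%.4g lam=%.4g e=%.4g c=%.4g\n",
    x$mu, x$delta_n, x$delta_p, x$lam, x$e, x$c))
  invisible(x)
}
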