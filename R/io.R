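# On-disk formats. External conventions are enforced at the boundary:
# Bismark coverage is 1-based inclusive, BED is 0-based half-open; the
# internal convention is uniformly 0-based half-open.

format_header <- function(what) {
  ver <- tryCatch(as.character(utils::packageVersion("dyadkin")),
                  error = function(e) "dev")
  sprintf("# dyadkin %s %s", ver, what)
}

read_lines_nocomment <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read a Bismark-coverage-style file
#'
#' Expects 6 tab-separated columns: chrom, start (1-based), end (1-based
#' inclusive), percent methylation, count methylated, count unmethylated.
#' The percent column is ignored in favor of the counts. Coordinates are
#' shifted to the internal 0-based convention. Unsorted input is sorted on
#' load with a message; rows with zero total coverage are retained.
#'
#' @param path file path.
#' @return A [methylome_table()].
#' @export
read_bismark_cov <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_lines_nocomment(path)
  if (!length(lines)) return(methylome_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6))
    stop(sprintf("malformed Bismark coverage line %d in %s: expected 6 fields, got %d",
                 which(nf != 6)[1], path, nf[nf != 6][1]))
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.integer(m[, 5]))
  cu <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos1) | is.na(cm) | is.na(cu))
  if (length(bad))
    stop(sprintf("malformed Bismark coverage line %d in %s: non-numeric field",
                 bad[1], path))
  o <- order(m[, 1], pos1)
  if (!identical(o, seq_along(o)))
    message("read_bismark_cov: input not sorted; sorted on load")
  methylome_table(contig = m[o, 1], pos = pos1[o] - 1L,
                  count_M = cm[o], count_U = cu[o])
}

#' Write a methylome as a Bismark-coverage-style file
#'
#' @param m a [methylome_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(m, path) {
  cov <- m$count_M + m$count_U
  pct <- ifelse(cov > 0, 100 * m$count_M / cov, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header("bismark-coverage"), con)
  if (nrow(m))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d", m$contig, m$pos + 1L,
                       m$pos + 1L, format(pct, trim = TRUE), m$count_M,
                       m$count_U), con)
  invisible(path)
}

#' Read / write BED6
#'
#' BED is 0-based half-open; `label` maps to the name column and `score`
#' to the score column (`.` when missing). Round-trips are identical.
#'
#' @param path file path.
#' @param regions a [region_set()].
#' @return `read_bed` returns a [region_set()]; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_lines_nocomment(path)
  if (!length(lines)) return(region_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3)[1], path))
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i) p[i] else default, character(1))
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinate", bad[1], path))
  score <- suppressWarnings(as.numeric(get(5, ".")))
  region_set(get(1, NA), start, end, label = get(4, "."), score = score)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  regions <- validate_region_set(regions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header("bed6"), con)
  if (nrow(regions)) {
    sc <- ifelse(is.na(regions$score), ".", format(regions$score, trim = TRUE))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", regions$contig,
                       as.integer(regions$start), as.integer(regions$end),
                       regions$label, sc), con)
  }
  invisible(path)
}

#' Read / write bedGraph methylation tracks
#'
#' 4-column bedGraph (chrom, start, end, value), 0-based half-open, one
#' CpG per row. `write_bedgraph` emits beta values; `read_bedgraph`
#' returns positions and values only (counts are not recoverable from a
#' bedGraph, so the result is a plain data.frame, not a methylome table).
#'
#' @param m a [methylome_table()].
#' @param path file path.
#' @return `read_bedgraph` returns a data.frame (contig, pos, value).
#' @export
read_bedgraph <- function(path) {
  lines <- read_lines_nocomment(path)
  lines <- lines[!startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(contig = character(), pos = integer(),
                      value = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4))
    stop(sprintf("malformed bedGraph line %d in %s: expected 4 fields",
                 which(nf != 4)[1], path))
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  out <- data.frame(contig = m[, 1], pos = as.integer(m[, 2]),
                    value = as.numeric(m[, 4]), stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(m, path) {
  b <- beta_values(m)
  keep <- !is.na(b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header("bedgraph"), con)
  if (any(keep))
    writeLines(sprintf("%s\t%d\t%d\t%.10g", m$contig[keep], m$pos[keep],
                       m$pos[keep] + 1L, b[keep]), con)
  invisible(path)
}

#' Collapse minus-strand rows onto plus-strand CpG positions
#'
#' CpGs are keyed internally by the plus-strand C. Count rows reported at
#' the minus-strand C (plus position + 1) are shifted by -1 and merged
#' with the plus-strand row; how many rows were merged is messaged.
#' Positions matching neither strand of a known CpG are kept untouched.
#'
#' @param m a [methylome_table()] with per-strand rows.
#' @param cpg_sites data.frame with `contig`, `pos` of plus-strand CpG Cs
#'   (e.g. `genome$cpg`).
#' @return A dyad-collapsed [methylome_table()].
#' @export
collapse_dyads <- function(m, cpg_sites) {
  plus_key <- paste(cpg_sites$contig, cpg_sites$pos)
  key <- paste(m$contig, m$pos)
  minus_key <- paste(m$contig, m$pos - 1)
  is_minus <- !(key %in% plus_key) & (minus_key %in% plus_key)
  if (any(is_minus)) {
    message(sprintf("collapse_dyads: merged %d minus-strand row(s)",
                    sum(is_minus)))
    m$pos[is_minus] <- m$pos[is_minus] - 1L
  }
  agg <- stats::aggregate(cbind(count_M, count_U) ~ contig + pos,
                          data = as.data.frame(m), FUN = sum)
  methylome_table(agg$contig, agg$pos, agg$count_M, agg$count_U)
}

#' Rename contigs with an explicit map
#'
#' Contig matching everywhere in the package is exact; cross-assembly
#' naming differences (e.g. "1" vs "chr1") must be resolved explicitly
#' with a rename map, never by silent aliasing.
#'
#' @param x a [methylome_table()] or [region_set()] (any data.frame with
#'   a `contig` column).
#' @param map named character vector, `old_name = "new_name"`.
#' @return `x` with contigs renamed.
#' @export
rename_contigs <- function(x, map) {
  hit <- x$contig %in% names(map)
  x$contig[hit] <- unname(map[x$contig[hit]])
  if (inherits(x, "methylome_table"))
    return(validate_methylome_table(as.data.frame(x)))
  if (inherits(x, "region_set"))
    return(validate_region_set(as.data.frame(x)))
  x
}

#' Read / write dyad count tables
#'
#' Tab-separated with columns sample, class, n_UU, n_MU, n_UM, n_MM.
#'
#' @param x a [dyad_count_table()].
#' @param path file path.
#' @return `read_dyad_tsv` returns a [dyad_count_table()].
#' @export
read_dyad_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample", "class", "n_UU", "n_MU", "n_UM", "n_MM")
  if (!all(need %in% names(d)))
    stop("dyad TSV must have columns: ", paste(need, collapse = ", "))
  dyad_count_table(d$sample, d$class, d$n_UU, d$n_MU, d$n_UM, d$n_MM)
}

#' @rdname read_dyad_tsv
#' @export
write_dyad_tsv <- function(x, path) {
  con <- file(path, "w")
  writeLines(format_header("dyad-counts"), con)
  close(con)
  suppressWarnings(data.table::fwrite(as.data.frame(x), path, sep = "\t",
                                      append = TRUE, col.names = TRUE))
  invisible(path)
}

#' Read / write long-read call tables
#'
#' Flat TSV: read_id, chrom, block_start, block_end, cpg_pos, call. One row
#' per methylation call; an aligned block without calls is kept as a row
#' with `cpg_pos = .` and `call = .`.
#'
#' @param reads a [long_read_calls()] object.
#' @param path file path.
#' @return `read_longread_tsv` returns a [long_read_calls()] object.
#' @export
read_longread_tsv <- function(path) {
  lines <- read_lines_nocomment(path)
  header <- strsplit(lines[1], "\t")[[1]]
  need <- c("read_id", "chrom", "block_start", "block_end", "cpg_pos", "call")
  if (!identical(header, need))
    stop("long-read TSV must have columns: ", paste(need, collapse = ", "))
  if (length(lines) == 1)
    return(long_read_calls(
      data.frame(read_id = character(), contig = character(),
                 start = numeric(), end = numeric()),
      data.frame(read_id = character(), contig = character(),
                 pos = numeric(), call = character())))
  m <- matrix(unlist(strsplit(lines[-1], "\t", fixed = TRUE)), ncol = 6,
              byrow = TRUE)
  blocks <- unique(data.frame(read_id = m[, 1], contig = m[, 2],
                              start = as.numeric(m[, 3]),
                              end = as.numeric(m[, 4]),
                              stringsAsFactors = FALSE))
  has_call <- m[, 6] != "."
  calls <- data.frame(read_id = m[has_call, 1], contig = m[has_call, 2],
                      pos = as.numeric(m[has_call, 5]),
                      call = m[has_call, 6], stringsAsFactors = FALSE)
  long_read_calls(blocks, calls)
}

#' @rdname read_longread_tsv
#' @export
write_longread_tsv <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header("long-read-calls"), con)
  writeLines("read_id\tchrom\tblock_start\tblock_end\tcpg_pos\tcall", con)
  b <- reads$blocks
  cl <- reads$calls
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      ci <- cl[cl$read_id == b$read_id[i] & cl$contig == b$contig[i] &
                 cl$pos >= b$start[i] & cl$pos < b$end[i], , drop = FALSE]
      if (nrow(ci)) {
        writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%s", b$read_id[i],
                           b$contig[i], as.integer(b$start[i]),
                           as.integer(b$end[i]), as.integer(ci$pos),
                           ci$call), con)
      } else {
        writeLines(sprintf("%s\t%s\t%d\t%d\t.\t.", b$read_id[i], b$contig[i],
                           as.integer(b$start[i]), as.integer(b$end[i])), con)
      }
    }
  }
  invisible(path)
}

#' Read / write LFQ matrices
#'
#' Intensity TSV: `protein_id` column plus one column per sample; `NA` for
#' missing. Groups TSV: columns `sample`, `group`.
#'
#' @param m an [lfq_matrix()].
#' @param path,groups_path file paths.
#' @return `read_lfq_tsv` returns an [lfq_matrix()].
#' @export
read_lfq_tsv <- function(path, groups_path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (names(d)[1] != "protein_id") stop("first LFQ column must be protein_id")
  g <- data.table::fread(groups_path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  if (!all(c("sample", "group") %in% names(g)))
    stop("groups TSV must have columns sample, group")
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$protein_id
  if (!setequal(colnames(mat), g$sample))
    stop("LFQ sample columns and group map disagree")
  lfq_matrix(mat, g$group[match(colnames(mat), g$sample)])
}

#' @rdname read_lfq_tsv
#' @export
write_lfq_tsv <- function(m, path, groups_path) {
  d <- data.frame(protein_id = rownames(m$intensity), m$intensity,
                  check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(data.frame(sample = colnames(m$intensity),
                                group = as.character(m$groups)),
                     groups_path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Total overlap length of each region in `a` with a merged region set `b`
#'
#' `b` is self-merged first so overlapping b-intervals are not double
#' counted; the result is the number of base pairs of each `a` region
#' covered by the union of `b`.
#'
#' @param a,b [region_set()]s on the same contig namespace.
#' @return data.frame with the regions of `a` plus an `overlap_bp` column.
#' @export
intersect_length <- function(a, b) {
  a <- validate_region_set(a)
  b <- validate_region_set(b)
  out <- as.data.frame(a)
  out$overlap_bp <- 0
  if (!nrow(a) || !nrow(b)) return(out)
  ga <- as_granges(a)
  gb <- GenomicRanges::reduce(as_granges(b))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(ga[queryHits(hits)], gb[subjectHits(hits)])
    w <- tapply(GenomicRanges::width(ov), queryHits(hits), sum)
    out$overlap_bp[as.integer(names(w))] <- as.numeric(w)
  }
  out
}

#' Mean methylation per region
#'
#' Per region, the unweighted mean of per-CpG beta values over CpGs with
#' coverage at least `min_cov`; `NA` (undefined) when fewer than `min_cpgs`
#' CpGs qualify. A pooled-count mode (`pooled = TRUE`) divides summed
#' methylated counts by summed coverage instead.
#'
#' @param m a [methylome_table()].
#' @param regions a [region_set()].
#' @param min_cov minimum per-CpG coverage for a CpG to count (>= 1).
#' @param min_cpgs minimum number of qualifying CpGs for a defined mean.
#' @param pooled use pooled counts instead of mean of betas.
#' @return data.frame: the regions plus `n_cpgs_used` and `mean_beta`.
#' @export
region_mean_methylation <- function(m, regions, min_cov = 1L, min_cpgs = 1L,
                                    pooled = FALSE) {
  stopifnot(min_cov >= 1)
  regions <- validate_region_set(regions)
  out <- as.data.frame(regions)
  out$n_cpgs_used <- 0L
  out$mean_beta <- NA_real_
  if (!nrow(regions) || !nrow(m)) return(out)
  cov <- m$count_M + m$count_U
  keep <- cov >= min_cov
  mm <- m[keep, , drop = FALSE]
  if (!nrow(mm)) return(out)
  gm <- GenomicRanges::GRanges(mm$contig, IRanges::IRanges(mm$pos + 1, mm$pos + 1))
  hits <- GenomicRanges::findOverlaps(as_granges(regions), gm)
  if (!length(hits)) return(out)
  b <- beta_values(mm)[subjectHits(hits)]
  cm <- mm$count_M[subjectHits(hits)]
  cu <- mm$count_U[subjectHits(hits)]
  q <- queryHits(hits)
  n <- tabulate(q, nbins = nrow(regions))
  out$n_cpgs_used <- n
  if (pooled) {
    sM <- tapply(cm, q, sum)
    sT <- tapply(cm + cu, q, sum)
    idx <- as.integer(names(sM))
    mean_b <- rep(NA_real_, nrow(regions))
    mean_b[idx] <- as.numeric(sM) / as.numeric(sT)
  } else {
    sb <- tapply(b, q, mean)
    mean_b <- rep(NA_real_, nrow(regions))
    mean_b[as.integer(names(sb))] <- as.numeric(sb)
  }
  mean_b[n < min_cpgs] <- NA_real_
  out$mean_beta <- mean_b
  out
}
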