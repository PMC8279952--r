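# Seeded generators emulating the study designs: a repeat-rich toy genome,
# WGBS count tables from a near-zero baseline and a rescue passage series,
# hairpin dyad counts drawn from the kinetic model itself, long reads with
# sample-specific deletions, and an LFQ matrix with spiked interactors and
# missing-not-at-random dropout.

FEATURE_CLASSES <- c("IAPEz_int", "IAP_LTR", "ERV1", "LINE", "SINE",
                     "CGI", "gene", "intergenic")

# per-class CpG density (CpGs per bp); CGI is 8x intergenic
CPG_DENSITY <- c(IAPEz_int = 0.012, IAP_LTR = 0.02, ERV1 = 0.015,
                 LINE = 0.012, SINE = 0.02, CGI = 0.08, gene = 0.012,
                 intergenic = 0.01)

#' Simulation configuration
#'
#' All knobs of the synthetic-data generators in one validated list.
#'
#' @param seed integer master seed.
#' @param coverage_mean mean short-read coverage per CpG (Poisson).
#' @param conversion_failure bisulfite error e: true U read as M.
#' @param inappropriate_conversion bisulfite error c: true M read as U.
#' @param n_iap number of IAPEz_int-like elements in the toy genome.
#' @param read_length_median median long-read length in bp (lognormal).
#' @param read_length_sdlog lognormal sd of the read-length law.
#' @param n_reads number of long reads to simulate.
#' @param call_error symmetric per-CpG long-read call error.
#' @param dyads_per_class hairpin dyads drawn per locus class and timepoint.
#' @param lfq_n_proteins,lfq_n_spiked,lfq_effect_log2 LFQ design: matrix
#'   size, number of spiked interactors, their log2 enrichment in the bait
#'   group.
#' @param lfq_n_reps replicates per group (default 3, as in triplicate
#'   co-IP designs).
#' @param lfq_dropout list(p_max, midpoint, width): logistic
#'   missing-not-at-random dropout on the true log2 intensity; `p_max = 0`
#'   disables dropout.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, coverage_mean = 30,
                       conversion_failure = 0.005,
                       inappropriate_conversion = 0.005,
                       n_iap = 24L,
                       read_length_median = 25000, read_length_sdlog = 0.4,
                       n_reads = 400L, call_error = 0.01,
                       dyads_per_class = 20000L,
                       lfq_n_proteins = 1000L, lfq_n_spiked = 20L,
                       lfq_effect_log2 = 4, lfq_n_reps = 3L,
                       lfq_dropout = list(p_max = 0.9, midpoint = 22,
                                          width = 1)) {
  cfg <- list(seed = as.integer(seed), coverage_mean = coverage_mean,
              conversion_failure = conversion_failure,
              inappropriate_conversion = inappropriate_conversion,
              n_iap = as.integer(n_iap),
              read_length_median = read_length_median,
              read_length_sdlog = read_length_sdlog,
              n_reads = as.integer(n_reads), call_error = call_error,
              dyads_per_class = as.integer(dyads_per_class),
              lfq_n_proteins = as.integer(lfq_n_proteins),
              lfq_n_spiked = as.integer(lfq_n_spiked),
              lfq_effect_log2 = lfq_effect_log2,
              lfq_n_reps = as.integer(lfq_n_reps),
              lfq_dropout = lfq_dropout)
  for (f in c("conversion_failure", "inappropriate_conversion", "call_error"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("sim_config: field '%s' must be a probability in [0, 1]", f))
  if (cfg$coverage_mean <= 0)
    stop("sim_config: field 'coverage_mean' must be > 0")
  if (cfg$lfq_n_spiked > cfg$lfq_n_proteins)
    stop("sim_config: field 'lfq_n_spiked' must be <= 'lfq_n_proteins'")
  if (cfg$n_iap < 1) stop("sim_config: field 'n_iap' must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Build a deterministic toy genome with a repeat landscape
#'
#' One contig tiled with labelled features (IAPEz_int elements of 5-7 kb
#' flanked by LTRs, ERV1, LINE, SINE, CpG islands, genes, intergenic
#' spacers and two assembly gaps) and per-class CpG densities; CpG islands
#' are 8x denser in CpGs than intergenic sequence.
#'
#' @param config a [sim_config()].
#' @return A `genome_model`: list with `contigs` (name, length), `cpg`
#'   (contig, pos, class), `features` ([region_set()], a partition of the
#'   contig) and `gap_mask` ([region_set()] of unplaceable sequence,
#'   CpG-free).
#' @export
build_toy_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  segs <- list()
  add <- function(label, len) segs[[length(segs) + 1]] <<- c(label, len)
  n_iap <- config$n_iap
  pool <- c(rep("IAP", n_iap), rep("ERV1", 12), rep("LINE", 20),
            rep("SINE", 40), rep("CGI", 30), rep("gene", 12))
  pool <- sample(pool)
  gap_at <- sort(sample(seq_along(pool), 2))
  for (i in seq_along(pool)) {
    add("intergenic", round(runif(1, 2000, 15000)))
    if (i %in% gap_at) add("gap", round(runif(1, 15000, 25000)))
    switch(pool[i],
      IAP = {
        add("IAP_LTR", round(runif(1, 300, 400)))
        add("IAPEz_int", round(runif(1, 5000, 7000)))
        add("IAP_LTR", round(runif(1, 300, 400)))
      },
      ERV1 = add("ERV1", round(runif(1, 2000, 4000))),
      LINE = add("LINE", round(runif(1, 3000, 6000))),
      SINE = add("SINE", round(runif(1, 150, 300))),
      CGI = add("CGI", round(runif(1, 600, 1500))),
      gene = add("gene", round(runif(1, 5000, 15000))))
  }
  add("intergenic", round(runif(1, 2000, 15000)))
  lab <- vapply(segs, `[`, character(1), 1)
  len <- as.numeric(vapply(segs, `[`, character(1), 2))
  end <- cumsum(len)
  start <- end - len
  contig <- "chrS"
  is_gap <- lab == "gap"
  features <- region_set(contig, start, end,
                         label = ifelse(is_gap, "intergenic", lab))
  gap_mask <- if (any(is_gap))
    region_set(contig, start[is_gap], end[is_gap], label = "gap")
  else region_set()
  # CpG placement: binomial count per segment at the class density, gaps 0
  cpg_pos <- integer(0)
  cpg_class <- character(0)
  for (i in seq_along(lab)) {
    if (is_gap[i]) next
    dens <- CPG_DENSITY[[lab[i]]]
    n <- rbinom(1, as.integer(len[i]), dens)
    if (n == 0) next
    pos <- start[i] + sort(sample.int(as.integer(len[i]), n)) - 1L
    cpg_pos <- c(cpg_pos, pos)
    cpg_class <- c(cpg_class, rep(lab[i], n))
  }
  structure(list(
    contigs = data.frame(name = contig, length = sum(len)),
    cpg = data.frame(contig = contig, pos = as.integer(cpg_pos),
                     class = cpg_class, stringsAsFactors = FALSE),
    features = features, gap_mask = gap_mask), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d contig(s), %.2f Mb, %d CpGs, %d features\n",
              nrow(x$contigs), sum(x$contigs$length) / 1e6, nrow(x$cpg),
              nrow(x$features)))
  invisible(x)
}

#' Per-class true methylation profile
#'
#' @param levels named numeric vector in `[0, 1]`, one entry per feature
#'   class (missing classes fall back to `background`).
#' @param background global background level in `[0, 1]`.
#' @param passage passage index label (0 = baseline).
#' @return A `methylation_profile` object.
#' @export
methylation_profile <- function(levels = numeric(), background = 0,
                                passage = 0) {
  levels <- unlist(levels)
  if (length(levels) && (any(levels < 0) || any(levels > 1)))
    stop("methylation_profile: levels must be in [0, 1]")
  if (background < 0 || background > 1)
    stop("methylation_profile: background must be in [0, 1]")
  structure(list(levels = levels, background = background, passage = passage),
            class = "methylation_profile")
}

profile_p_true <- function(profile, classes) {
  p <- rep(profile$background, length(classes))
  hit <- classes %in% names(profile$levels)
  p[hit] <- profile$levels[classes[hit]]
  p
}

#' Simulate a WGBS count table
#'
#' Coverage per CpG is Poisson with mean `coverage_mean`; the methylated
#' count is binomial with observed success probability
#' `p_obs = p_true (1 - c) + (1 - p_true) e` (bisulfite error algebra).
#'
#' @param genome a [build_toy_genome()] result.
#' @param profile a [methylation_profile()].
#' @param config a [sim_config()]; its `seed` drives the draw.
#' @param seed optional override of `config$seed`.
#' @return A [methylome_table()] over the genome's CpGs.
#' @export
simulate_wgbs <- function(genome, profile, config = sim_config(),
                          seed = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "methylation_profile"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  p_true <- profile_p_true(profile, genome$cpg$class)
  e <- config$conversion_failure
  cc <- config$inappropriate_conversion
  p_obs <- p_true * (1 - cc) + (1 - p_true) * e
  n <- nrow(genome$cpg)
  cov <- rpois(n, config$coverage_mean)
  cm <- rbinom(n, cov, p_obs)
  methylome_table(genome$cpg$contig, genome$cpg$pos, cm, cov - cm)
}

#' Simulate a rescue passage series with matched hairpin dyad counts
#'
#' The dyad kinetic model ([transition_step()]) is the single source of
#' truth: per class, the dyad distribution is advanced
#' `passage x divisions_per_passage` divisions from the class's `p0`;
#' hairpin tables are multinomial draws from the error-convolved dyad
#' distribution and WGBS tables are binomial draws at its per-strand
#' marginal.
#'
#' @param genome a [build_toy_genome()] result.
#' @param kinetics_by_class named list of [kinetic_params()], covering all
#'   feature classes present in the genome.
#' @param divisions_per_passage cell divisions per passage (>= 1).
#' @param config a [sim_config()].
#' @param passages integer passage indices; 0 = baseline is always
#'   prepended.
#' @return list with `methylomes` (named list of [methylome_table()]s,
#'   `P0`, `P1`, ...) and `dyads` (a [dyad_count_table()] with one row per
#'   sample x class).
#' @export
simulate_passage_series <- function(genome, kinetics_by_class,
                                    divisions_per_passage = 6L,
                                    config = sim_config(),
                                    passages = c(1L, 5L, 15L, 25L)) {
  stopifnot(inherits(genome, "genome_model"), divisions_per_passage >= 1)
  classes <- unique(genome$cpg$class)
  missing_cls <- setdiff(classes, names(kinetics_by_class))
  if (length(missing_cls))
    stop("simulate_passage_series: no kinetics for class(es): ",
         paste(missing_cls, collapse = ", "))
  set.seed(config$seed)
  samples <- c(0L, sort(unique(as.integer(passages))))
  meths <- list()
  dy <- NULL
  for (p_idx in samples) {
    nm <- paste0("P", p_idx)
    lv <- numeric(0)
    for (cls in classes) {
      par <- kinetics_by_class[[cls]]
      pdist <- iterate_transition(par$p0, par,
                                  p_idx * as.integer(divisions_per_passage))
      obs_dist <- as.numeric(t(observation_matrix(par$e, par$c)) %*% pdist)
      cnt <- as.numeric(rmultinom(1, config$dyads_per_class, obs_dist))
      dy <- rbind(dy, data.frame(sample = nm, class = cls,
                                 n_UU = cnt[1], n_MU = cnt[2],
                                 n_UM = cnt[3], n_MM = cnt[4],
                                 stringsAsFactors = FALSE))
      lv[cls] <- strand_marginal(pdist)
    }
    prof <- methylation_profile(lv, background = 0, passage = p_idx)
    meths[[nm]] <- simulate_wgbs(genome, prof, config,
                                 seed = config$seed + p_idx)
  }
  list(methylomes = meths,
       dyads = dyad_count_table(dy$sample, dy$class, dy$n_UU, dy$n_MU,
                                dy$n_UM, dy$n_MM))
}

#' Simulate long reads with sample-specific deletions
#'
#' Read lengths are lognormal (median `read_length_median`, truncated at
#' contig ends); aligned blocks jump over any overlapping deletion, per-CpG
#' calls are Bernoulli at the methylome's beta with a symmetric call error,
#' and no calls fall inside deletions.
#'
#' @param genome a [build_toy_genome()] result.
#' @param methylome a [methylome_table()] giving per-CpG betas.
#' @param deletions a [region_set()] of sequence absent from this sample.
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A [long_read_calls()] object.
#' @export
simulate_long_reads <- function(genome, methylome, deletions = region_set(),
                                config = sim_config(), seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  deletions <- validate_region_set(deletions)
  if (nrow(deletions)) {
    clen <- genome$contigs$length[match(deletions$contig, genome$contigs$name)]
    if (any(is.na(clen)) || any(deletions$end > clen))
      stop("simulate_long_reads: deletion outside contig bounds")
  }
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  contig <- genome$contigs$name[1]
  clen <- genome$contigs$length[1]
  n <- config$n_reads
  L <- rlnorm(n, meanlog = log(config$read_length_median),
              sdlog = config$read_length_sdlog)
  start <- floor(runif(n, 0, pmax(1, clen - L)))
  end <- pmin(clen, floor(start + L))
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  ids <- sprintf("read_%05d", seq_along(start))
  if (nrow(deletions)) {
    del <- GenomicRanges::reduce(as_granges(deletions))
    ds <- GenomicRanges::start(del) - 1
    de <- GenomicRanges::end(del)
    blocks <- do.call(rbind, lapply(seq_along(ids), function(i) {
      bs <- start[i]; parts <- NULL
      for (j in seq_along(ds)) {
        if (de[j] <= start[i] || ds[j] >= end[i]) next
        if (ds[j] > bs) parts <- rbind(parts, c(bs, ds[j]))
        bs <- max(bs, de[j])
      }
      if (bs < end[i]) parts <- rbind(parts, c(bs, end[i]))
      if (is.null(parts)) return(NULL)
      data.frame(read_id = ids[i], contig = contig, start = parts[, 1],
                 end = parts[, 2], stringsAsFactors = FALSE)
    }))
    if (is.null(blocks))
      blocks <- data.frame(read_id = character(), contig = character(),
                           start = numeric(), end = numeric())
  } else {
    blocks <- data.frame(read_id = ids, contig = contig, start = start,
                         end = end, stringsAsFactors = FALSE)
  }
  blocks <- blocks[blocks$end > blocks$start, , drop = FALSE]
  # per-CpG calls within blocks
  beta <- beta_values(methylome)
  ok <- !is.na(beta) & methylome$contig == contig
  cp <- methylome$pos[ok]
  cb <- beta[ok]
  calls <- NULL
  gb <- GenomicRanges::GRanges(blocks$contig,
                               IRanges::IRanges(blocks$start + 1, blocks$end))
  gc <- GenomicRanges::GRanges(contig, IRanges::IRanges(cp + 1, cp + 1))
  hits <- GenomicRanges::findOverlaps(gb, gc)
  if (length(hits)) {
    pos <- cp[subjectHits(hits)]
    p_m <- cb[subjectHits(hits)]
    err <- config$call_error
    p_call <- p_m * (1 - err) + (1 - p_m) * err
    call <- ifelse(runif(length(pos)) < p_call, "M", "U")
    calls <- data.frame(read_id = blocks$read_id[queryHits(hits)],
                        contig = contig, pos = pos, call = call,
                        stringsAsFactors = FALSE)
  } else {
    calls <- data.frame(read_id = character(), contig = character(),
                        pos = numeric(), call = character())
  }
  long_read_calls(blocks, calls)
}

#' Simulate a label-free proteomics matrix with spiked interactors
#'
#' Protein log2 abundances are Gaussian; the first `lfq_n_spiked` proteins
#' are enriched by `lfq_effect_log2` in the bait group; missingness is
#' missing-not-at-random: the dropout probability rises logistically as
#' the true intensity falls.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return An [lfq_matrix()] with attributes `spiked` (protein ids) and
#'   `truth` (the pre-noise, pre-dropout matrix).
#' @export
simulate_lfq <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  np <- config$lfq_n_proteins
  ns <- config$lfq_n_spiked
  nr <- config$lfq_n_reps
  groups <- factor(rep(c("bait", "control"), each = nr),
                   levels = c("bait", "control"))
  base <- rnorm(np, mean = 25, sd = 2)
  truth <- matrix(base, nrow = np, ncol = 2 * nr)
  if (ns > 0)
    truth[seq_len(ns), groups == "bait"] <-
      truth[seq_len(ns), groups == "bait"] + config$lfq_effect_log2
  noise <- matrix(rnorm(np * 2 * nr, sd = 0.4), nrow = np)
  obs <- truth + noise
  dr <- config$lfq_dropout
  if (dr$p_max > 0) {
    p_miss <- dr$p_max / (1 + exp((truth - dr$midpoint) / dr$width))
    obs[matrix(runif(np * 2 * nr), nrow = np) < p_miss] <- NA
  }
  rownames(obs) <- c(sprintf("SPIKE_%03d", seq_len(ns)),
                     sprintf("BG_%04d", seq_len(np - ns)))
  colnames(obs) <- paste0(rep(c("bait", "ctrl"), each = nr), "_", seq_len(nr))
  out <- lfq_matrix(obs, groups)
  attr(out, "spiked") <- rownames(obs)[seq_len(ns)]
  rownames(truth) <- rownames(obs)
  attr(out, "truth") <- truth
  out
}
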