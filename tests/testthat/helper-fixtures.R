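# Shared fixture builders. Everything is generated in code under a fixed
# seed; nothing is read from disk except files the tests themselves write.

random_methylome <- function(n = 1000, contigs = c("chr1", "chr2"),
                             seed = 42) {
  set.seed(seed)
  ct <- sample(contigs, n, replace = TRUE)
  pos <- unlist(lapply(unique(ct), function(x)
    sample.int(1e6, sum(ct == x))))
  cov <- rpois(n, 20)
  cm <- rbinom(n, cov, runif(n))
  methylome_table(ct, pos - 1L, cm, cov - cm)
}

random_regions <- function(n = 50, contigs = c("chr1", "chr2"), seed = 7,
                           max_pos = 1e5, max_len = 5000) {
  set.seed(seed)
  st <- sample.int(max_pos, n)
  region_set(sample(contigs, n, replace = TRUE), st,
             st + sample.int(max_len, n, replace = TRUE),
             label = sprintf("r%03d", seq_len(n)),
             score = round(runif(n), 3))
}

# per-bp brute-force overlap of one region with a region set
brute_overlap_bp <- function(contig, start, end, b) {
  bp <- start:(end - 1)
  covered <- rep(FALSE, length(bp))
  for (j in seq_len(nrow(b))) {
    if (b$contig[j] != contig) next
    covered <- covered | (bp >= b$start[j] & bp < b$end[j])
  }
  sum(covered)
}

# straight-line per-region mean of betas (independent of GRanges)
brute_region_mean <- function(m, region, min_cov = 1, min_cpgs = 1) {
  cov <- m$count_M + m$count_U
  sel <- m$contig == region$contig & m$pos >= region$start &
    m$pos < region$end & cov >= min_cov
  if (sum(sel) < min_cpgs) return(NA_real_)
  mean(m$count_M[sel] / cov[sel])
}

# kinetics used across tests: strong maintenance + de novo on IAPs only,
# near-inert background
study_kinetics <- function(genome, mu_iap = 0.95, dn_iap = 0.2,
                           e = 0.005, c = 0.005) {
  kin <- list()
  for (cl in unique(genome$cpg$class))
    kin[[cl]] <- kinetic_params(0.3, 0.001, e = e, c = c)
  kin$IAPEz_int <- kinetic_params(mu_iap, dn_iap, e = e, c = c)
  kin
}

# construct a long_read_calls object from read spans minus per-read gaps
make_reads <- function(spans, gaps = NULL, contig = "chr1") {
  blocks <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start[i]; e <- spans$end[i]
    g <- if (is.null(gaps)) NULL else
      gaps[gaps$read_id == spans$read_id[i], , drop = FALSE]
    if (is.null(g) || !nrow(g)) {
      return(data.frame(read_id = spans$read_id[i], contig = contig,
                        start = s, end = e))
    }
    g <- g[order(g$start), ]
    out <- NULL; cur <- s
    for (j in seq_len(nrow(g))) {
      if (g$start[j] > cur)
        out <- rbind(out, data.frame(read_id = spans$read_id[i],
                                     contig = contig, start = cur,
                                     end = g$start[j]))
      cur <- max(cur, g$end[j])
    }
    if (cur < e)
      out <- rbind(out, data.frame(read_id = spans$read_id[i],
                                   contig = contig, start = cur, end = e))
    out
  }))
  long_read_calls(blocks, data.frame(read_id = character(),
                                     contig = character(), pos = numeric(),
                                     call = character()))
}

toy_genome_stub <- list(contigs = data.frame(name = "chr1", length = 1e6))

# simulate a dyad time course at given total divisions per timepoint
simulate_time_course <- function(params, totals_divs, n_dyads = 50000,
                                 seed = 1) {
  set.seed(seed)
  O <- observation_matrix(params$e, params$c)
  cnt <- t(vapply(totals_divs, function(tot) {
    p <- params$p0
    for (i in seq_len(tot)) p <- transition_step(p, params)
    as.numeric(rmultinom(1, n_dyads, as.numeric(t(O) %*% p)))
  }, numeric(4)))
  labels <- paste0("t", seq_along(totals_divs))
  dyad_time_course(labels, c(0, diff(totals_divs)),
                   dyad_count_table(labels, "x", cnt[, 1], cnt[, 2],
                                    cnt[, 3], cnt[, 4]))
}
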