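test_that("deletion detection needs spanning gaps and no internal reads", {
  # no gapped reads: empty call set
  spans <- data.frame(read_id = sprintf("r%02d", 1:10),
                      start = seq(0, 90000, by = 10000),
                      end = seq(0, 90000, by = 10000) + 30000)
  expect_equal(nrow(detect_deletions(make_reads(spans), toy_genome_stub)), 0)

  # injected 10 kb deletion covered by 20 gap-spanning reads, 0 internal
  del <- data.frame(start = 50000, end = 60000)
  spans2 <- data.frame(read_id = sprintf("s%02d", 1:20),
                       start = seq(20000, 39000, by = 1000),
                       end = seq(80000, 99000, by = 1000))
  gaps2 <- data.frame(read_id = spans2$read_id, start = del$start,
                      end = del$end)
  calls <- detect_deletions(make_reads(spans2, gaps2), toy_genome_stub,
                            min_span_support = 5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 50000)
  expect_equal(calls$end, 60000)
  expect_equal(calls$score, 20)

  # only 3 supporting reads with min_span_support = 5: not called
  few <- detect_deletions(make_reads(spans2[1:3, ], gaps2[1:3, ]),
                          toy_genome_stub, min_span_support = 5)
  expect_equal(nrow(few), 0)

  # an internal read suppresses the call at max_internal_reads = 0
  spans3 <- rbind(spans2, data.frame(read_id = "internal", start = 52000,
                                     end = 58000))
  gaps3 <- gaps2
  sup <- detect_deletions(make_reads(spans3, gaps3), toy_genome_stub,
                          min_span_support = 5, max_internal_reads = 0)
  expect_equal(nrow(sup), 0)
  tol <- detect_deletions(make_reads(spans3, gaps3), toy_genome_stub,
                          min_span_support = 5, max_internal_reads = 1)
  expect_equal(nrow(tol), 1)
})

test_that("CpG masking is exact on the half-open convention", {
  m <- methylome_table(rep("chr1", 5), c(100, 200, 300, 400, 500),
                       rep(1L, 5), rep(1L, 5))
  expect_equal(nrow(mask_cpgs(m, region_set())$kept), 5)

  del <- region_set("chr1", 200, 400)
  r <- mask_cpgs(m, del)
  # 200 (start, inside half-open) and 300 removed; 400 (end, outside) kept
  expect_equal(r$kept$pos, c(100, 400, 500))
  expect_equal(r$n_masked, 2)
  expect_equal(r$masked_bp, 200)
})

test_that("masking matches brute-force membership on random data", {
  m <- random_methylome(600, seed = 91)
  dels <- random_regions(15, seed = 92, max_pos = 9e5, max_len = 3e4)
  r <- mask_cpgs(m, dels)
  in_del <- vapply(seq_len(nrow(m)), function(i)
    any(dels$contig == m$contig[i] & m$pos[i] >= dels$start &
          m$pos[i] < dels$end), logical(1))
  expect_equal(r$n_masked, sum(in_del))
  expect_equal(r$kept$pos, m$pos[!in_del])
})

test_that("masking removes all CpGs in injected deletions and none elsewhere", {
  g <- build_toy_genome(sim_config(seed = 13))
  m <- simulate_wgbs(g, methylation_profile(background = 0.3),
                     sim_config(seed = 13))
  del <- region_set("chrS", c(40000, 300000), c(55000, 312000),
                    label = c("d1", "d2"))
  r <- mask_cpgs(m, del)
  kept_in_del <- sum(vapply(seq_len(nrow(r$kept)), function(i)
    any(r$kept$pos[i] >= del$start & r$kept$pos[i] < del$end), logical(1)))
  expect_equal(kept_in_del, 0)
  expect_equal(r$n_masked + nrow(r$kept), nrow(m))
  expect_equal(r$n_masked,
               sum(m$pos >= 40000 & m$pos < 55000) +
                 sum(m$pos >= 300000 & m$pos < 312000))
})

test_that("long-read region methylation applies the minimum-CpG rule", {
  blocks <- data.frame(read_id = "r1", contig = "chr1", start = 0, end = 1e4)
  mk <- function(pos, call) long_read_calls(
    blocks, data.frame(read_id = "r1", contig = "chr1", pos = pos,
                       call = call))
  reg <- region_set("chr1", 0, 1e4)
  all_m <- mk(seq(100, 1000, by = 90), "M")
  expect_equal(nanopore_region_methylation(all_m, reg, 10)$mean_beta, 1)

  nine <- mk(seq(100, 900, by = 100), "M")
  expect_true(is.na(nanopore_region_methylation(nine, reg, 10)$mean_beta))
  expect_equal(nanopore_region_methylation(nine, reg, 9)$mean_beta, 1)
})

test_that("long-read region methylation equals a brute-force recount", {
  set.seed(95)
  pos <- sort(sample.int(5000, 40))
  calls <- do.call(rbind, lapply(1:8, function(i)
    data.frame(read_id = sprintf("r%d", i), contig = "chr1",
               pos = sample(pos, 25),
               call = sample(c("M", "U"), 25, replace = TRUE))))
  lr <- long_read_calls(data.frame(read_id = sprintf("r%d", 1:8),
                                   contig = "chr1", start = 0, end = 6000),
                        calls)
  reg <- region_set("chr1", 1000, 4000)
  got <- nanopore_region_methylation(lr, reg, min_cpgs = 1)
  sub <- calls[calls$pos >= 1000 & calls$pos < 4000, ]
  want <- mean(tapply(sub$call == "M", sub$pos, mean))
  expect_equal(got$mean_beta, want)
  expect_equal(got$n_cpgs_used, length(unique(sub$pos)))
})

test_that("high-confidence filter partitions exactly at the 0.05 boundary", {
  dmrs <- region_set("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                     label = paste0("d", 1:4))
  mk_means <- function(v) data.frame(mean_beta = v)
  base <- mk_means(c(0.0, 0.0, 0.0, NA))
  samp <- mk_means(c(0.049, 0.05, 0.30, NA))
  fr <- high_confidence_filter(dmrs, base, samp, min_delta = 0.05)
  expect_equal(fr$detail$status,
               c("excluded_low_delta", "retained", "retained",
                 "retained_uncovered_flagged"))
  expect_equal(unname(fr$counts["retained"]), 3)
  strict <- high_confidence_filter(dmrs, base, samp, min_delta = 0.05,
                                   keep_uncovered = FALSE)
  expect_equal(unname(strict$counts),
               c(4, 1, 1, 2))

  expect_error(high_confidence_filter(dmrs, base[1:2, , drop = FALSE], samp),
               "must cover all DMRs")
})

test_that("filter partition is exact and monotone in min_delta on random data", {
  set.seed(96)
  n <- 200
  dmrs <- region_set("chr1", seq(0, by = 1000, length.out = n),
                     seq(500, by = 1000, length.out = n),
                     label = sprintf("d%03d", 1:n))
  base <- data.frame(mean_beta = ifelse(runif(n) < 0.1, NA, runif(n, 0, 0.1)))
  samp <- data.frame(mean_beta = ifelse(runif(n) < 0.1, NA, runif(n, 0, 0.6)))
  prev_retained <- Inf
  for (md in c(0.02, 0.05, 0.2, 0.5)) {
    fr <- high_confidence_filter(dmrs, base, samp, min_delta = md,
                                 keep_uncovered = FALSE)
    expect_equal(unname(fr$counts["input"]),
                 unname(sum(fr$counts[c("excluded_low_delta",
                                        "excluded_uncovered", "retained")])))
    expect_lte(unname(fr$counts["retained"]), prev_retained)
    prev_retained <- fr$counts["retained"]
  }
})

test_that("coverage normalization reports depth ratios against own CRs", {
  # uniform depth: every ratio 1
  spans <- data.frame(read_id = sprintf("r%02d", 1:5), start = 0, end = 1e5)
  lr <- make_reads(spans)
  dmrs <- region_set("chr1", c(10000, 50000), c(12000, 53000),
                     label = c("d1", "d2"))
  crs <- region_set("chr1", rep(c(20000, 70000), each = 2),
                    rep(c(22000, 73000), each = 2) + c(0, 0, 0, 0),
                    label = c("d1", "d1", "d2", "d2"))
  crs$end <- crs$start + rep(dmrs$end - dmrs$start, each = 2)
  r <- coverage_normalization(lr, dmrs, crs)
  expect_equal(r$ratio, c(1, 1))

  # doubling depth over one DMR doubles its ratio
  extra <- data.frame(read_id = sprintf("x%02d", 1:5), start = 10000,
                      end = 12000)
  lr2 <- make_reads(rbind(spans, extra))
  r2 <- coverage_normalization(lr2, dmrs, crs)
  expect_equal(r2$ratio, c(2, 1))

  # zero CR depth: undefined ratio
  lr3 <- make_reads(data.frame(read_id = "only", start = 10000, end = 12000))
  r3 <- coverage_normalization(lr3, dmrs, crs)
  expect_true(is.na(r3$ratio[1]))
})
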