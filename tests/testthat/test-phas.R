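test_that("phasing p-value boundary cases follow the tail definition", {
  expect_equal(phasing_pvalue(420, 20, 5, 0), 1)      # k = 0: total mass
  expect_equal(phasing_pvalue(100, 100, 7, 7), 1)     # all positions phased
  expect_equal(phasing_pvalue(50, 50, 10, 10), 1)
  expect_error(phasing_pvalue(10, 20, 5, 1), "exceed")
  expect_error(phasing_pvalue(10, 5, 4, 5), "exceed")
  expect_error(phasing_pvalue(10, 5, 4, -1), "integer")
})

test_that("phasing p-value matches the exact big-integer oracle", {
  # frozen values computed with exact rational arithmetic
  expect_equal(phasing_pvalue(420, 20, 10, 4), 6.59747113285536683e-04,
               tolerance = 1e-12)
  expect_equal(phasing_pvalue(100, 40, 20, 12), 3.79813414703930180e-02,
               tolerance = 1e-12)
  expect_equal(phasing_pvalue(480, 20, 12, 4), 8.82447811108995144e-04,
               tolerance = 1e-12)
  expect_equal(phasing_pvalue(60, 10, 8, 3), 1.20305709070387873e-01,
               tolerance = 1e-12)
})

test_that("phasing p-value agrees with phyper across a random grid", {
  set.seed(601)
  for (i in 1:200) {
    N <- sample(20:1000, 1)
    m <- sample(seq_len(min(N, 100)), 1)
    n <- sample(seq_len(min(N, 60)), 1)
    k <- sample(0:min(n, m), 1)
    p <- phasing_pvalue(N, m, n, k)
    q <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    expect_equal(p, q, tolerance = 1e-9,
                 info = paste(N, m, n, k))
    expect_true(p > 0 && p <= 1)
  }
})

test_that("phasing score follows the decided closed form", {
  expect_equal(phasing_score(1, 0, 3), log(11))
  expect_equal(phasing_score(5, 2, 2), 0)   # k < 3
  expect_equal(phasing_score(0, 10, 7), 0)  # no phased abundance
  # strictly increasing in P at fixed U and k >= 3
  P <- seq(0.5, 50, by = 0.5)
  s <- phasing_score(P, 2, 5)
  expect_true(all(diff(s) > 0))
  # more occupied cycles score higher at the same abundance
  expect_gt(phasing_score(10, 1, 8), phasing_score(10, 1, 5))
})

# A perfectly phased cluster: D-spaced reads on both strands.
phased_alignments <- function(D = 21, cycles = 8, start = 1000,
                              count = 20, off = integer(0)) {
  pos <- start + D * (seq_len(cycles) - 1)
  plus <- data.frame(chrom = "chr1", start = pos, end = pos + D,
                     strand = "+", seq = paste0("P", seq_along(pos)),
                     length = D, count = count, n_hits = 1L,
                     weight = count, over_mapped = FALSE,
                     cluster_id = 1L, stringsAsFactors = FALSE)
  minus <- plus
  minus$start <- plus$start - 2L
  minus$end <- minus$start + D
  minus$strand <- "-"
  minus$seq <- paste0("M", seq_along(pos))
  extra <- NULL
  if (length(off) > 0) {
    extra <- plus[seq_along(off), ]
    extra$start <- off
    extra$end <- off + D
    extra$seq <- paste0("O", seq_along(off))
    extra$count <- extra$weight <- count / 4
  }
  rbind(plus, minus, extra)
}

test_that("a perfectly phased cluster yields a deeply significant window", {
  aln <- phased_alignments(D = 21, cycles = 8)
  w <- scan_registers(aln, 21)
  expect_gt(nrow(w), 0)
  best <- w[which.min(w$p_value), ]
  expect_equal(best$k, 16L)   # 8 cycles on both strands
  expect_lt(best$p_value, 1e-6)
  expect_equal(best$window_start %% 21, 1000 %% 21)
  expect_equal(best$N, 420L)
  expect_equal(best$m, 20L)
})

test_that("scanning a 24-nt cluster at D = 21 finds nothing", {
  aln <- phased_alignments(D = 24, cycles = 8)
  w <- scan_registers(aln, 21)
  expect_equal(nrow(w), 0L)
})

test_that("multi-mapping and off-length reads are excluded from phasing", {
  aln <- phased_alignments(D = 21, cycles = 8)
  aln$n_hits <- 20L  # everything above the cap
  expect_equal(nrow(scan_registers(aln, 21)), 0L)
  aln2 <- phased_alignments(D = 21, cycles = 8)
  aln2$length <- 22L
  expect_equal(nrow(scan_registers(aln2, 21)), 0L)
})

test_that("window merging respects register and gap and keeps extremes", {
  w <- data.frame(chrom = "chr1",
                  cluster_id = 1L,
                  window_start = c(1000L, 1021L, 6000L),
                  phase_len = 21L, N = 420L, m = 20L,
                  n = c(10L, 10L, 9L), k = c(6L, 7L, 5L),
                  p_value = c(1e-5, 1e-8, 1e-4),
                  phased_ab = 50, unphased_ab = 2,
                  phasing_score = c(10, 12, 8),
                  stringsAsFactors = FALSE)
  loci <- merge_windows_to_loci(w, 21, min_cycles = 4)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$best_p, c(1e-8, 1e-4))
  expect_equal(loci$max_phasing_score[1], 12)
  expect_equal(loci$start[1], 1000L)
  expect_equal(loci$end[1], 1021L + 21L * 10L)
  # different register at the same distance stays separate
  w2 <- w[1:2, ]
  w2$window_start <- c(1000L, 1010L)
  expect_equal(nrow(merge_windows_to_loci(w2, 21, min_cycles = 4)), 2L)
  # loci below min_cycles occupied positions are not reported
  w3 <- w[1, ]; w3$k <- 3L
  expect_equal(nrow(merge_windows_to_loci(w3, 21, min_cycles = 4)), 0L)
  expect_equal(nrow(merge_windows_to_loci(w[0, ], 21)), 0L)
})

test_that("the 24-PHAS repeat filter removes repeat-derived windows", {
  aln <- phased_alignments(D = 24, cycles = 8)
  w <- scan_registers(aln, 24)
  expect_gt(nrow(w), 0)
  # single-copy reads: retained
  expect_equal(nrow(filter_24phas_repeats(w, aln)), nrow(w))
  # same windows inside a 20-copy repeat: removed
  aln_rep <- aln
  aln_rep$n_hits <- 20L
  aln_rep$weight <- aln_rep$count / 20
  expect_equal(nrow(filter_24phas_repeats(w, aln_rep)), 0L)
  # weighted mean n_hits matches a manual recount on a mixed window
  aln_mix <- aln
  aln_mix$n_hits[1:8] <- 9L
  aln_mix$weight <- aln_mix$count / aln_mix$n_hits
  sub <- aln_mix[aln_mix$start < w$window_start[1] + 240 &
                   aln_mix$end > w$window_start[1], ]
  manual <- sum(sub$weight * sub$n_hits) / sum(sub$weight)
  kept <- nrow(filter_24phas_repeats(w[1, ], aln_mix, rep_cap = 5))
  expect_equal(kept, if (manual <= 5) 1L else 0L)
  expect_equal(nrow(filter_24phas_repeats(w[0, ], aln)), 0L)
})

test_that("locus calling is invariant to alignment row order", {
  aln <- phased_alignments(D = 21, cycles = 8,
                           off = c(1203L, 1010L))
  l1 <- annotate_phas(aln, 21)
  l2 <- annotate_phas(aln[rev(seq_len(nrow(aln))), ], 21)
  expect_equal(l1, l2)
  expect_equal(l1$register, 1000L %% 21L)
})

test_that("coarser window strides never invent loci", {
  aln <- phased_alignments(D = 21, cycles = 8, off = c(1203L))
  w1 <- scan_registers(aln, 21, step = 1)
  wD <- scan_registers(aln, 21, step = 21)
  expect_true(all(wD$window_start %in% w1$window_start))
  expect_true(nrow(wD) <= nrow(w1))
})
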