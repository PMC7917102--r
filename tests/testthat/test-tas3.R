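MIR390 <- load_tas3_defaults()$mir390

test_that("target-site scoring penalizes by position and pairing class", {
  # perfect complementarity scores 0
  s <- score_target_site(MIR390, srnaloci:::rc(MIR390))
  expect_equal(s$score, 0)
  expect_equal(s$gu_count, 0L)
  expect_false(s$has_central_mismatch)

  # one G:U wobble at small RNA position 15 (outside the doubled core): 0.5
  site <- srnaloci:::rc(MIR390)
  L <- nchar(MIR390)
  stopifnot(substr(MIR390, 15, 15) == "T")
  substr(site, L - 15 + 1, L - 15 + 1) <- "G"
  s <- score_target_site(MIR390, site)
  expect_equal(s$score, 0.5)
  expect_equal(s$gu_count, 1L)

  # core mismatch at position 10 plus core wobble at position 5:
  # 1 * 2 + 0.5 * 2 = 3, and the position-10 mismatch is central
  site <- srnaloci:::rc(MIR390)
  stopifnot(substr(MIR390, 10, 10) == "A")
  substr(site, L - 10 + 1, L - 10 + 1) <- "C"
  stopifnot(substr(MIR390, 5, 5) == "T")
  substr(site, L - 5 + 1, L - 5 + 1) <- "G"
  s <- score_target_site(MIR390, site)
  expect_equal(s$score, 3)
  expect_true(s$has_central_mismatch)
  expect_error(score_target_site(MIR390, "ACGT"), "equal length")
})

test_that("scores equal a brute-force per-position penalty sum", {
  set.seed(701)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:40) {
    srna <- random_seq(21)
    site <- random_seq(21)
    s <- score_target_site(srna, site)
    a <- strsplit(srna, "")[[1]]
    b <- rev(strsplit(site, "")[[1]])
    manual <- 0
    for (p in 1:21) {
      pen <- if (b[p] == comp[a[p]]) 0
      else if ((a[p] == "G" && b[p] == "T") ||
               (a[p] == "T" && b[p] == "G")) 0.5
      else 1
      manual <- manual + pen * (if (p >= 2 && p <= 13) 2 else 1)
    }
    expect_equal(s$score, manual)
  }
})

sim_tas3_bundle <- function(seed = 702) {
  spec <- default_plant_spec()
  spec$mirna <- 0; spec$mirna_decoy <- 0
  spec$phas21 <- 1; spec$phas24 <- 0; spec$repeat_copies <- 0
  spec$tas3 <- 1; spec$tas3_decoy <- 1
  sim <- make_genome(seed = seed, length = 6e4, plant_spec = spec)
  prm <- sim_read_params(); prm$noise_reads <- 30
  rr <- make_reads(sim, prm, seed = seed)
  cl <- cluster_alignments(map_reads(rr$reads, build_index(sim$genome)))
  phas21 <- annotate_phas(cl$alignments, 21)
  list(sim = sim, phas21 = phas21)
}

test_that("dual-site TAS3 loci are found; single-site decoys are not", {
  b <- sim_tas3_bundle()
  tru <- b$sim$truth
  res <- find_tas3(b$phas21, b$sim$genome)
  t_tas <- tru[tru$class == "TAS3", ]
  t_dec <- tru[tru$class == "TAS3_DECOY", ]
  expect_equal(nrow(res$loci), 1L)
  expect_true(res$loci$start >= t_tas$start - 200 &&
                res$loci$end <= t_tas$end + 200)
  expect_equal(res$loci$site5_start, t_tas$site5_start)
  expect_equal(res$loci$site3_start, t_tas$site3_start)
  expect_true(res$loci$site3_cleavable)
  expect_true(res$loci$site5_central_mismatch)
  # the planted tasiARF is reported in register with a motif match
  arf <- res$tasiarf[res$tasiarf$motif_match, ]
  expect_true(t_tas$tasiarf_phase %in% arf$phase_index)
  expect_true(t_tas$tasiarf_start %in% arf$start)
  # decoy region yields no TAS3 call
  expect_false(any(res$loci$start < t_dec$end & res$loci$end > t_dec$start))
  # every TAS3 is one of the 21-PHAS loci
  expect_true(all(res$loci$phas_id %in% b$phas21$locus_id))
})

test_that("two sites on opposite strands do not make a TAS3 pair", {
  set.seed(703)
  site_plus <- srnaloci:::rc(MIR390)   # targeted on + strand
  site_minus <- MIR390                 # its occurrence targets the - strand
  g_str <- paste0(random_seq(300), site_plus, random_seq(200), site_minus,
                  random_seq(300))
  g <- genome_from_string(g_str)
  phas <- data.frame(chrom = "chr1", start = 280L, end = 760L, strand = ".",
                     phase_len = 21L, best_p = 1e-6,
                     max_phasing_score = 20, register = 280L %% 21L,
                     k_max = 8L, n_windows = 5L, total_abundance = 100,
                     locus_class = "PHAS21", locus_id = "PHAS21_00001",
                     stringsAsFactors = FALSE)
  res <- find_tas3(phas, g, flank = 100)
  expect_equal(nrow(res$loci), 0L)
})

test_that("an explicit miR390 sequence is required", {
  phas <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                     locus_id = "x", stringsAsFactors = FALSE)
  g <- genome_from_string(strrep("A", 200))
  expect_error(
    find_tas3(phas, g, mir390 = character(0), tasiarf_motif = "A"),
    "miR390")
})
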