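# A canonical planted hairpin: mature + 15-nt loop + revcomp(mature[1:19])
# + 2-nt non-pairing tail (2-nt 3' overhangs on both arms).
MAT <- "TTGACAGAAGATAGAGAGCAC"
mk_hairpin <- function(mature = MAT) srnaloci:::mirna_construct(mature)

test_that("a perfect mature/star duplex scores clean", {
  hp <- mk_hairpin()
  f <- fold_hairpin(hp$seq)
  dx <- evaluate_duplex(f$pairs, hp$mature_off, hp$mature_len)
  expect_true(dx$ok)
  expect_equal(dx$n_mismatch, 0L)
  expect_equal(dx$n_asym_bulge, 0L)
  expect_equal(dx$overhang_3p_mature, 2L)
  expect_equal(dx$overhang_3p_star, 2L)
  expect_equal(dx$star_off, hp$star_off)
  expect_equal(dx$star_len, hp$star_len)
})

test_that("a symmetric 1x1 internal loop counts one mismatch, no bulge", {
  # canonical duplex pair table: mature 1..19 pairs 55..37, with the
  # position-10 pair opened into a symmetric 1x1 internal loop
  pairs <- integer(57)
  for (i in 1:19) {
    if (i == 10) next
    pairs[i] <- 56L - i
    pairs[56L - i] <- i
  }
  dx <- evaluate_duplex(pairs, 0, 21)
  expect_true(dx$ok)
  expect_equal(dx$n_mismatch, 1L)
  expect_equal(dx$n_asym_bulge, 0L)
  expect_equal(dx$overhang_3p_mature, 2L)
})

test_that("a 3-nt bulge on the star arm is counted as asymmetry", {
  hp <- mk_hairpin()
  star19 <- substr(hp$seq, 37, 55)
  # insert 3 non-pairing nt into the star arm between positions 9 and 10
  bulged <- paste0(substr(hp$seq, 1, 36),
                   substr(star19, 1, 9), "AAA", substr(star19, 10, 19),
                   substr(hp$seq, 56, 57))
  f <- fold_hairpin(bulged)
  dx <- evaluate_duplex(f$pairs, hp$mature_off, hp$mature_len)
  expect_true(dx$ok)
  # hand count: opposing unpaired runs are 0 (mature) vs 3 (star)
  expect_equal(dx$n_asym_bulge, 3L)
  expect_equal(dx$n_mismatch, 0L)
})

test_that("an unpairable mature has no assignable star", {
  f <- fold_hairpin(strrep("A", 60))
  dx <- evaluate_duplex(f$pairs, 10, 21)
  expect_false(dx$ok)
  expect_equal(dx$reason, "no_star")
})

# A minimal scored candidate built around the planted hairpin.
mk_candidate <- function(mature_count = 100, star_count = 10,
                         frag_count = 2, n_libs = 1, strict = TRUE,
                         mature_len = 21, n_hits = 1) {
  hp <- mk_hairpin()
  g0 <- 5000L
  cand <- data.frame(chrom = "chr1", win_start = g0 - 15L,
                     win_end = g0 + 57L + 15L, strand = "+",
                     mature_start = g0, mature_len = mature_len,
                     star_off = hp$star_off + 15L, star_len = hp$star_len,
                     n_mismatch = 0L, n_asym_bulge = 0L,
                     overhang_3p_mature = 2L, overhang_3p_star = 2L,
                     stringsAsFactors = FALSE)
  star_g <- g0 + 36L
  aln <- data.frame(
    chrom = "chr1",
    start = c(g0, star_g, g0 + 25L),
    end = c(g0 + 21L, star_g + 21L, g0 + 46L),
    strand = "+",
    seq = c(MAT, srnaloci:::rc(substr(MAT, 1, 19)), "FRAG"),
    length = 21L,
    count = c(mature_count, star_count, frag_count),
    n_hits = c(n_hits, 1L, 1L),
    weight = c(mature_count / n_hits, star_count, frag_count),
    over_mapped = FALSE, cluster_id = 1L, stringsAsFactors = FALSE)
  aln <- aln[aln$count > 0, ]
  reads <- data.frame(seq = aln$seq, length = aln$length,
                      total_count = aln$count,
                      n_libs = rep(n_libs, nrow(aln)),
                      lib.sim1 = aln$count, stringsAsFactors = FALSE)
  params <- srna_config()$mirna
  params$strict <- strict
  score_mirna(cand, aln, reads, n_libs = max(1, n_libs), params = params)
}

test_that("an ideal locus is accepted and thresholds reject flawed ones", {
  s <- mk_candidate()
  expect_equal(s$verdict, "accepted")
  expect_equal(s$precision, 110 / 112)

  # precision failure: the cluster is dominated by other reads
  s <- mk_candidate(mature_count = 10, star_count = 4, frag_count = 30)
  expect_equal(s$verdict, "rejected")
  expect_match(s$reject_reasons, "precision_ok")

  # 19-nt mature fails the length rule
  s <- mk_candidate(mature_len = 19)
  expect_match(s$reject_reasons, "length_ok")

  # absent star fails strict mode, multi-mapped matures are repeat-derived
  s <- mk_candidate(star_count = 0)
  expect_match(s$reject_reasons, "star")
  s <- mk_candidate(n_hits = 25)
  expect_match(s$reject_reasons, "multimap_ok")
})

test_that("star-less 21-22 nt loci pass only in lenient mode", {
  s <- mk_candidate(star_count = 0, strict = FALSE)
  expect_equal(s$verdict, "accepted")
  s <- mk_candidate(star_count = 0, strict = TRUE)
  expect_equal(s$verdict, "rejected")
})

test_that("duplicate hairpins merge and identical matures group", {
  row <- mk_candidate()
  row$cluster_id <- 1L
  row$structure <- strrep(".", 87)
  shifted <- row
  shifted$win_start <- row$win_start + 5L
  shifted$win_end <- row$win_end + 5L
  shifted$precision <- row$precision - 0.01
  far <- row
  far$win_start <- row$win_start + 10000L
  far$win_end <- row$win_end + 10000L
  far$mature_start <- row$mature_start + 10000L
  out <- deduplicate_mirna(rbind(row, shifted, far))
  expect_equal(nrow(out), 2L)             # overlap collapsed
  expect_equal(length(unique(out$family)), 1L)  # same mature sequence
  expect_equal(out$locus_id, c("MIRNA_0001", "MIRNA_0002"))
  expect_equal(nrow(deduplicate_mirna(NULL)), 0L)
})

test_that("planted hairpins are recovered exactly; shuffled decoys are not", {
  spec <- default_plant_spec()
  spec$mirna <- 2; spec$mirna_decoy <- 1
  spec$phas21 <- 0; spec$phas24 <- 0; spec$repeat_copies <- 0
  spec$tas3 <- 0; spec$tas3_decoy <- 0
  sim <- make_genome(seed = 301, length = 4e4, plant_spec = spec)
  prm <- sim_read_params(); prm$noise_reads <- 30
  rr <- make_reads(sim, prm, seed = 301)
  idx <- build_index(sim$genome)
  cl <- cluster_alignments(map_reads(rr$reads, idx))
  res <- call_mirna(cl, sim$genome, rr$reads)
  tru <- sim$truth[sim$truth$class == "MIRNA", ]
  dec <- sim$truth[sim$truth$class == "MIRNA_DECOY", ]
  expect_equal(sort(res$loci$mature_start), sort(tru$mature_start))
  expect_equal(sum(res$loci$start < dec$end & res$loci$end > dec$start), 0L)
  # accepted set is invariant to read input order
  rr2 <- rr$reads[rev(seq_len(nrow(rr$reads))), ]
  cl2 <- cluster_alignments(map_reads(rr2, idx))
  res2 <- call_mirna(cl2, sim$genome, rr2)
  expect_equal(res$loci, res2$loci)
})
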