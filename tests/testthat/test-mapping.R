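test_that("k-mer lookup finds occurrences on both strands, never across N", {
  g <- genome_from_string("ACGTACGT")
  idx <- build_index(g)
  h <- lookup_sequence(idx, "ACGT")
  # ACGT is its own reverse complement: + and - hits at starts 0 and 4
  expect_equal(sort(h$start[h$strand == "+"]), c(0, 4))
  expect_equal(sort(h$start[h$strand == "-"]), c(0, 4))
  h2 <- lookup_sequence(build_index(genome_from_string("AAAATTTT")), "AATT")
  expect_equal(h2$start[h2$strand == "+"], 4 - 2)
  expect_equal(nrow(lookup_sequence(idx, "ACNT")), 0L)
})

test_that("placements agree with a sliding-window oracle on random genomes", {
  set.seed(401)
  for (rep in 1:5) {
    g_str <- random_seq(400)
    g <- genome_from_string(g_str)
    reads <- unique(vapply(1:8, function(i) {
      s <- sample(380, 1)
      substr(g_str, s, s + sample(18:24, 1))
    }, ""))
    counts <- stats::setNames(rep(2, length(reads)), reads)
    rs <- read_set_from_counts(counts)
    aln <- map_reads(rs, g)
    for (rd in reads) {
      got <- aln[aln$seq == rd, c("start", "strand")]
      want <- oracle_place_read(g_str, rd)
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_true(all(aln$n_hits[aln$seq == rd] == nrow(want)))
    }
  }
})

test_that("repeat reads report their full genomic hit count", {
  unit <- "ACGGATTACCAGGATCCGATTACA"  # 24-mer, not self-complementary
  g <- genome_from_string(paste(rep(c(unit, strrep("T", 40)), 10),
                                collapse = ""))
  rs <- read_set_from_counts(stats::setNames(10, unit))
  aln <- map_reads(rs, g)
  expect_equal(unique(aln$n_hits), 10L)
  expect_equal(sum(aln$strand == "+"), 10L)
  expect_equal(unique(aln$weight), 1)  # 10 / 10 hits
})

test_that("multi-mapping weights conserve total mapped abundance", {
  set.seed(402)
  g_str <- paste(rep(random_seq(120), 3), collapse = "")
  g <- genome_from_string(g_str)
  reads <- unique(vapply(1:10, function(i) {
    s <- sample(100, 1)
    substr(g_str, s, s + 20)
  }, ""))
  rs <- read_set_from_counts(stats::setNames(seq_along(reads) + 1, reads))
  aln <- map_reads(rs, g)
  mapped <- rs$total_count[rs$seq %in% aln$seq]
  expect_equal(sum(aln$weight), sum(mapped))
})

test_that("unmappable reads are reported unmapped", {
  g <- genome_from_string(strrep("A", 100))
  rs <- read_set_from_counts(c(GGGGCCCCGGGGCCCCGGGG = 5))
  aln <- map_reads(rs, g)
  expect_equal(nrow(aln), 0L)
  expect_equal(attr(aln, "unmapped"), "GGGGCCCCGGGGCCCCGGGG")
})

test_that("clustering merges by start gap and filters by abundance", {
  set.seed(403)
  g_str <- random_seq(3000)
  g <- genome_from_string(g_str)
  r1 <- substr(g_str, 101, 121)    # starts at 100 (0-based)
  r2 <- substr(g_str, 251, 271)    # 150 bp downstream
  r3 <- substr(g_str, 1101, 1121)  # 1000 bp downstream
  rs <- read_set_from_counts(stats::setNames(c(20, 20, 20), c(r1, r2, r3)))
  cl <- cluster_alignments(map_reads(rs, g), max_gap = 200,
                           min_abundance = 10)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(cl$clusters$start, c(100L, 1100L))

  # below-abundance clusters are dropped but alignments retain NA ids
  cl2 <- cluster_alignments(map_reads(rs, g), max_gap = 200,
                            min_abundance = 50)
  expect_equal(nrow(cl2$clusters), 0L)
  expect_true(all(is.na(cl2$alignments$cluster_id)))
})

test_that("cluster abundance equals a hit-normalized brute-force recount", {
  set.seed(404)
  core <- random_seq(60)
  g_str <- paste0(random_seq(300), core, random_seq(200), core,
                  random_seq(300))
  g <- genome_from_string(g_str)
  reads <- c(substr(core, 1, 21), substr(core, 25, 45), substr(g_str, 51, 74))
  rs <- read_set_from_counts(stats::setNames(c(10, 6, 30), reads))
  aln <- map_reads(rs, g)
  cl <- cluster_alignments(aln, max_gap = 200, min_abundance = 1)
  for (cid in cl$clusters$cluster_id) {
    members <- cl$alignments[!is.na(cl$alignments$cluster_id) &
                               cl$alignments$cluster_id == cid, ]
    manual <- sum(vapply(seq_len(nrow(members)), function(i) {
      hits <- nrow(oracle_place_read(g_str, members$seq[i]))
      rs$total_count[rs$seq == members$seq[i]] / hits
    }, numeric(1)))
    expect_equal(cl$clusters$total_abundance[cl$clusters$cluster_id == cid],
                 manual)
  }
})

test_that("mapping output is invariant to read input order", {
  set.seed(405)
  g_str <- random_seq(500)
  g <- genome_from_string(g_str)
  reads <- vapply(1:6, function(i) {
    s <- sample(470, 1); substr(g_str, s, s + 20)
  }, "")
  counts <- stats::setNames(seq_along(reads), reads)
  a1 <- map_reads(read_set_from_counts(counts), g)
  a2 <- map_reads(read_set_from_counts(rev(counts)), g)
  attr(a1, "unmapped") <- attr(a2, "unmapped") <- NULL
  expect_equal(a1, a2)
})
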