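# Independent oracles used across the suite.

# Exhaustive Nussinov maximum-pair count, written as a leftmost-base
# recursion (a different formulation from the package's span DP).
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  can <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- rec(i + 1L, j)  # i unpaired
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (can(ch[i], ch[k])) {
        v2 <- 1L + rec(i + 1L, k - 1L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (v2 > best) best <- v2
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) return(0L)
  rec(1L, n)
}

# Big-integer hypergeometric upper-tail oracle (exact rational arithmetic
# through the bundled Python helper).
oracle_hyper_tail <- function(N, m, n, k) {
  script <- system.file("oracle", "hyper_tail_exact.py", package = "srnaloci")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(N, m, n, k), f)
  as.numeric(system2("python", c(script, f), stdout = TRUE))
}

# Brute-force exact placement of one read on a genome string, both strands.
oracle_place_read <- function(genome_str, read) {
  L <- nchar(read)
  G <- nchar(genome_str)
  out <- list()
  rcread <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (s in 0:(G - L)) {
    win <- substr(genome_str, s + 1, s + L)
    if (win == read)
      out[[length(out) + 1]] <- data.frame(start = s, strand = "+")
    if (win == rcread)
      out[[length(out) + 1]] <- data.frame(start = s, strand = "-")
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), strand = character(0)))
  do.call(rbind, out)
}

# Small collapsed read set from a named count vector (names = sequences).
read_set_from_counts <- function(counts, library_id = "lib1") {
  f <- tempfile(fileext = ".fa")
  on.exit(unlink(f))
  writeLines(as.vector(rbind(
    sprintf(">r%d_%d", seq_along(counts), unname(counts)),
    names(counts))), f)
  read_collapsed_fasta(f, library_id)
}

# One-chromosome genome from a string.
genome_from_string <- function(s, name = "chr1") {
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
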