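#' @useDynLib srnaloci, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Reverse complement for plain character vectors (DNA alphabet incl. N).
rc <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize sequence text: uppercase, RNA U -> DNA T, non-ACGT IUPAC -> N.
normalize_seq <- function(x) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Random DNA string(s) at a given GC content.
random_dna <- function(n_bases, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
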