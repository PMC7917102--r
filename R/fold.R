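#' Fold a candidate hairpin by maximum base pairing
#'
#' Computes the nested secondary structure with the maximum number of base
#' pairs under Watson-Crick plus G:U wobble pairing, with a minimum hairpin
#' loop of 3 unpaired nt. The traceback is deterministic: the outermost
#' compatible pair of an interval is preferred whenever optimal. This
#' max-pair screen is what the MIRNA duplex criteria are evaluated on; a
#' thermodynamic backend could substitute, as criteria evaluation only
#' consumes the dot-bracket string.
#'
#' @param sequence A DNA-encoded sequence (T, not U); `N` never pairs.
#' @param min_loop Minimum unpaired hairpin loop length (default 3).
#' @return List with `structure` (dot-bracket), `n_pairs`, and `pairs`
#'   (integer vector of 1-based partners, 0 = unpaired).
#' @export
fold_hairpin <- function(sequence, min_loop = 3) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  .nussinov_fold_cpp(normalize_seq(sequence), as.integer(min_loop))
}

# Remove helices shorter than `min_helix` from a partner table.
# Max-pair folding happily places isolated single pairs between a hairpin
# arm and its loop or flanks; these carry no structural signal and would
# distort duplex evaluation, so they are pruned before criteria are
# applied (thermodynamic folders suppress them via stacking energies).
prune_short_helices <- function(pairs, min_helix = 2) {
  n <- length(pairs)
  if (n == 0 || min_helix <= 1) return(pairs)
  run_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j == 0 || j < i) next
    if (i > 1 && pairs[i - 1] == j + 1) {
      run_id[i] <- run_id[i - 1]
    } else {
      cur <- cur + 1L
      run_id[i] <- cur
    }
  }
  keep_run <- tabulate(run_id[run_id > 0]) >= min_helix
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j > i && !keep_run[run_id[i]]) {
      pairs[i] <- 0L
      pairs[j] <- 0L
    }
  }
  pairs
}

# Parse a dot-bracket string into a 1-based partner table (0 = unpaired).
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  pt
}
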