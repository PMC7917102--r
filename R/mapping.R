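#' Build an exact-match genome index
#'
#' Prepares both strands of a normalized genome for exact k-mer placement.
#' Positions containing `N` can never match (reads containing non-ACGT
#' characters are reported as unmapped).
#'
#' @param genome A named `DNAStringSet` from [read_genome()].
#' @return An object of class `srna_index`.
#' @export
build_index <- function(genome) {
  stopifnot(inherits(genome, "DNAStringSet"), !is.null(names(genome)))
  structure(list(genome = genome,
                 chrom_len = stats::setNames(Biostrings::width(genome),
                                             names(genome))),
            class = "srna_index")
}

#' Look up all exact occurrences of one sequence on both strands
#'
#' @param index An `srna_index`.
#' @param seq A single DNA string.
#' @return Data frame of placements (`chrom`, `start` 0-based, `strand`).
#' @export
lookup_sequence <- function(index, seq) {
  seq <- normalize_seq(seq)
  out <- list()
  if (!grepl("N", seq, fixed = TRUE)) {
    pat <- Biostrings::DNAString(seq)
    rcp <- Biostrings::reverseComplement(pat)
    for (ch in names(index$genome)) {
      for (str in c("+", "-")) {
        m <- Biostrings::matchPattern(if (str == "+") pat else rcp,
                                      index$genome[[ch]])
        if (length(m) > 0)
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = BiocGenerics::start(m) - 1, strand = str,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Place collapsed reads on the genome by exact matching
#'
#' Every unique read is matched exactly on both strands; the total number of
#' genomic placements (`n_hits`) is the repetitiveness signal used by the
#' downstream annotators. Abundance is hit-normalized (`weight =
#' count / n_hits`) so multi-mapped reads do not inflate locus abundance,
#' while `n_hits` itself stays un-normalized. Reads with more than
#' `max_hits` placements keep all placements but are flagged `over_mapped`.
#'
#' @param reads An `srna_reads` data frame.
#' @param index An `srna_index` (or a genome `DNAStringSet`).
#' @param max_hits Placement count above which a read is flagged
#'   `over_mapped` (default 50).
#' @return An `srna_alignments` data frame with columns `chrom`, `start`
#'   (0-based), `end`, `strand`, `seq`, `length`, `count`, `n_hits`,
#'   `weight`, `over_mapped`, sorted by (chrom, start, strand, seq).
#'   Unmapped sequences are available as `attr(, "unmapped")`.
#' @export
map_reads <- function(reads, index, max_hits = 50) {
  if (inherits(index, "DNAStringSet")) index <- build_index(index)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), length = integer(0),
                      count = numeric(0), n_hits = integer(0),
                      weight = numeric(0), over_mapped = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    attr(empty, "unmapped") <- character(0)
    class(empty) <- c("srna_alignments", "data.frame")
    return(empty)
  }
  clean <- !grepl("N", reads$seq, fixed = TRUE)
  hits <- list()
  for (L in sort(unique(reads$length[clean]))) {
    idx <- which(clean & reads$length == L)
    ss <- Biostrings::DNAStringSet(reads$seq[idx])
    pd_fwd <- Biostrings::PDict(ss)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(ss))
    for (ch in names(index$genome)) {
      subj <- index$genome[[ch]]
      if (length(subj) < L) next
      for (str in c("+", "-")) {
        pd <- if (str == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, subj)
        starts <- BiocGenerics::start(m)
        nh <- lengths(starts)
        if (sum(nh) == 0) next
        which_read <- rep(idx, nh)
        hits[[length(hits) + 1]] <- data.frame(
          chrom = ch, start = unlist(starts, use.names = FALSE) - 1,
          strand = str, read_i = which_read, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    attr(empty, "unmapped") <- reads$seq
    class(empty) <- c("srna_alignments", "data.frame")
    return(empty)
  }
  aln <- do.call(rbind, hits)
  nh_by_read <- table(aln$read_i)
  n_hits <- as.integer(nh_by_read[as.character(aln$read_i)])
  out <- data.frame(
    chrom = aln$chrom,
    start = aln$start,
    end = aln$start + reads$length[aln$read_i],
    strand = aln$strand,
    seq = reads$seq[aln$read_i],
    length = reads$length[aln$read_i],
    count = reads$total_count[aln$read_i],
    n_hits = n_hits,
    weight = reads$total_count[aln$read_i] / n_hits,
    over_mapped = n_hits > max_hits,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <-
    sort(reads$seq[!(seq_len(nrow(reads)) %in% unique(aln$read_i))])
  class(out) <- c("srna_alignments", "data.frame")
  out
}

#' Cluster alignments by positional proximity
#'
#' Single-linkage merging of placements whose consecutive start positions on
#' a chromosome differ by at most `max_gap`, strand-agnostic. Clusters whose
#' hit-normalized abundance is below `min_abundance` are discarded (this is
#' the permissive pre-filter; each locus annotator applies stricter rules).
#'
#' @param aln An `srna_alignments` data frame.
#' @param max_gap Maximum inter-start gap within a cluster (bp).
#' @param min_abundance Minimum hit-normalized abundance to keep a cluster.
#' @return A list with `clusters` (one row per kept cluster: `cluster_id`,
#'   `chrom`, `start`, `end`, `total_abundance`, `n_reads`) and `alignments`
#'   (the input with a `cluster_id` column; NA for dropped clusters).
#' @export
cluster_alignments <- function(aln, max_gap = 200, min_abundance = 10) {
  if (nrow(aln) == 0) {
    return(list(clusters = data.frame(cluster_id = integer(0),
                                      chrom = character(0), start = integer(0),
                                      end = integer(0),
                                      total_abundance = numeric(0),
                                      n_reads = integer(0),
                                      stringsAsFactors = FALSE),
                alignments = aln))
  }
  o <- order(aln$chrom, aln$start)
  aln <- aln[o, , drop = FALSE]
  new_cluster <- c(TRUE, aln$chrom[-1] != aln$chrom[-nrow(aln)] |
                     diff(aln$start) > max_gap)
  cid <- cumsum(new_cluster)
  ab <- rowsum(aln$weight, cid)
  keep_ids <- as.integer(rownames(ab))[ab[, 1] >= min_abundance]
  aln$cluster_id <- ifelse(cid %in% keep_ids, match(cid, keep_ids),
                           NA_integer_)
  kept <- !is.na(aln$cluster_id)
  if (!any(kept)) {
    cl <- data.frame(cluster_id = integer(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     total_abundance = numeric(0), n_reads = integer(0),
                     stringsAsFactors = FALSE)
    return(list(clusters = cl, alignments = aln))
  }
  ka <- aln[kept, , drop = FALSE]
  cl <- data.frame(
    cluster_id = sort(unique(ka$cluster_id)),
    chrom = tapply(ka$chrom, ka$cluster_id, `[`, 1),
    start = as.integer(tapply(ka$start, ka$cluster_id, min)),
    end = as.integer(tapply(ka$end, ka$cluster_id, max)),
    total_abundance = as.numeric(tapply(ka$weight, ka$cluster_id, sum)),
    n_reads = as.integer(tapply(ka$seq, ka$cluster_id,
                                function(s) length(unique(s)))),
    stringsAsFactors = FALSE)
  rownames(cl) <- NULL
  list(clusters = cl, alignments = aln)
}

#' Dump alignments as TSV
#'
#' One placement per row (`chrom`, `start` 0-based, `strand`, `seq`,
#' `count`, `n_hits`), sorted; useful for debugging placement decisions.
#' @param aln An `srna_alignments` data frame.
#' @param path Output path.
#' @export
write_alignments_tsv <- function(aln, path) {
  cols <- c("chrom", "start", "strand", "seq", "count", "n_hits")
  df <- aln[order(aln$chrom, aln$start, aln$strand, aln$seq), cols,
            drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Length histogram (hit-normalized abundance per read length) of a cluster.
cluster_length_profile <- function(aln, cluster_id) {
  sub <- aln[!is.na(aln$cluster_id) & aln$cluster_id == cluster_id, ,
             drop = FALSE]
  tapply(sub$weight, sub$length, sum)
}
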