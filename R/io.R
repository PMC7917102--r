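#' Read and normalize a genome FASTA
#'
#' Sequences are uppercased, RNA `U` is converted to `T`, and any other
#' non-`ACGT` IUPAC code becomes `N`. Multi-line records are concatenated
#' and duplicate sequence identifiers are an error. Only the first
#' whitespace-delimited token of each header is kept as the chromosome id.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate chromosome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_seq(as.character(x))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- ids
  g
}

new_read_set <- function(seq, length, total_count, n_libs, lib_counts) {
  df <- data.frame(seq = seq, length = length, total_count = total_count,
                   n_libs = n_libs, stringsAsFactors = FALSE)
  df <- cbind(df, lib_counts)
  class(df) <- c("srna_reads", "data.frame")
  df
}

lib_cols <- function(reads) grep("^lib\\.", colnames(reads), value = TRUE)

#' Read a collapsed sRNA FASTA library
#'
#' Headers of the form `>name_count` (count = final underscore-delimited
#' integer) or bare `>count` are accepted; identical sequences are merged by
#' summing their counts. Sequences are normalized (U to T, uppercase).
#'
#' @param path Path to a collapsed FASTA file.
#' @param library_id Library name used for the per-library count column.
#' @return An `srna_reads` data frame with columns `seq`, `length`,
#'   `total_count`, `n_libs` and one `lib.<library_id>` count column.
#' @export
read_collapsed_fasta <- function(path, library_id = "lib1") {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) {
    lc <- data.frame(numeric(0)); colnames(lc) <- paste0("lib.", library_id)
    return(new_read_set(character(0), integer(0), numeric(0), integer(0), lc))
  }
  hdr <- sub("\\s.*$", "", names(x))
  cnt <- suppressWarnings(as.numeric(hdr))
  need <- is.na(cnt)
  if (any(need)) {
    last <- sub(".*_", "", hdr[need])
    parsed <- suppressWarnings(as.numeric(last))
    bad <- is.na(parsed) | parsed != floor(parsed) | !grepl("_", hdr[need])
    if (any(bad))
      stop("cannot parse abundance count from header(s): ",
           paste(utils::head(hdr[need][bad], 3), collapse = ", "))
    cnt[need] <- parsed
  }
  if (any(cnt < 1)) stop("non-positive read count in ", path)
  seqs <- normalize_seq(as.character(x))
  agg <- rowsum(cnt, seqs)
  seq <- rownames(agg)
  total <- as.numeric(agg[, 1])
  o <- order(seq)
  seq <- seq[o]; total <- total[o]
  lc <- data.frame(total); colnames(lc) <- paste0("lib.", library_id)
  new_read_set(seq, nchar(seq), total, as.integer(total > 0), lc)
}

#' Collapse an adapter-trimmed FASTQ library
#'
#' Identical sequences are merged with summed counts; reads outside the
#' length window are discarded (the number discarded is reported via
#' [message()]). Input reads are assumed adapter-trimmed.
#'
#' @inheritParams read_collapsed_fasta
#' @param min_len,max_len Retained read-length window in nt.
#' @return An `srna_reads` data frame (see [read_collapsed_fasta()]).
#' @export
collapse_fastq <- function(path, library_id = "lib1",
                           min_len = 18, max_len = 26) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  seqs <- normalize_seq(as.character(x))
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (sum(!keep) > 0)
    message(sum(!keep), " read(s) outside [", min_len, ", ", max_len,
            "] nt discarded")
  seqs <- seqs[keep]
  if (length(seqs) == 0) {
    lc <- data.frame(numeric(0)); colnames(lc) <- paste0("lib.", library_id)
    return(new_read_set(character(0), integer(0), numeric(0), integer(0), lc))
  }
  tab <- table(seqs)
  seq <- names(tab)
  total <- as.numeric(tab)
  lc <- data.frame(total); colnames(lc) <- paste0("lib.", library_id)
  new_read_set(seq, nchar(seq), total, as.integer(total > 0), lc)
}

#' Merge per-library read sets into one collapsed read set
#'
#' @param read_sets A list of `srna_reads` objects, one per library, each
#'   carrying a distinct `lib.<id>` column.
#' @return One `srna_reads` data frame whose `total_count` sums all library
#'   counts; `n_libs` counts the libraries each sequence was seen in.
#' @export
merge_read_sets <- function(read_sets) {
  stopifnot(length(read_sets) >= 1)
  if (length(read_sets) == 1) return(read_sets[[1]])
  libs <- unlist(lapply(read_sets, lib_cols))
  if (anyDuplicated(libs)) stop("duplicate library ids across read sets")
  seq <- sort(unique(unlist(lapply(read_sets, function(r) r$seq))))
  lc <- matrix(0, nrow = length(seq), ncol = length(libs),
               dimnames = list(NULL, libs))
  for (r in read_sets) {
    cn <- lib_cols(r)
    lc[match(r$seq, seq), cn] <- r[[cn]]
  }
  total <- rowSums(lc)
  new_read_set(seq, nchar(seq), total, as.integer(rowSums(lc > 0)),
               as.data.frame(lc))
}

#' Reads-per-million normalization per library
#'
#' @param reads An `srna_reads` data frame.
#' @return `reads` with an added `rpm.<id>` column per library, computed
#'   from each library's post-filter total count; raw counts are retained.
#' @export
add_rpm <- function(reads) {
  for (cn in lib_cols(reads)) {
    tot <- sum(reads[[cn]])
    reads[[sub("^lib\\.", "rpm.", cn)]] <-
      if (tot > 0) reads[[cn]] / tot * 1e6 else 0
  }
  reads
}

#' Write a collapsed read set as canonical collapsed FASTA
#'
#' Headers are `>s<i>_<total_count>`, sequences sorted lexicographically so
#' output bytes are deterministic.
#' @param reads An `srna_reads` data frame.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  o <- order(reads$seq)
  lines <- as.vector(rbind(
    sprintf(">s%d_%d", seq_len(nrow(reads)), round(reads$total_count[o])),
    reads$seq[o]))
  writeLines(lines, path)
  invisible(path)
}

# ---- locus serialization -------------------------------------------------

# Canonical locus table -> GRanges (internal coords are 0-based half-open).
loci_granges <- function(loci, genome = NULL) {
  if (nrow(loci) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- loci$strand
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1, end = loci$end),
    strand = strand)
  extra <- setdiff(colnames(loci), c("chrom", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- loci[, extra, drop = FALSE]
  if (!is.null(genome))
    GenomeInfoDb::seqlengths(gr) <-
      Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(gr),
                                      names(genome))]
  sort(gr, ignore.strand = TRUE)
}

bed_score <- function(loci) {
  sc <- rep(0, nrow(loci))
  if ("best_p" %in% colnames(loci)) {
    has <- !is.na(loci$best_p)
    sc[has] <- pmin(1000, round(-10 * log10(pmax(loci$best_p[has], 1e-300))))
  }
  as.integer(sc)
}

#' Write loci as GFF3
#'
#' Coordinates are converted to the 1-based inclusive GFF3 convention and
#' records are sorted by (chrom, start). Class-specific columns of the locus
#' table (mature/star sequences, p-values, phasing scores, repetitiveness,
#' ...) are carried as GFF3 attributes. Accepted MIRNA loci additionally get
#' nested `miRNA` / `miRNA_star` child features.
#'
#' @param loci Locus table (`chrom`, `start` 0-based, `end`, `strand`,
#'   `locus_class`, `locus_id`, plus class-specific columns).
#' @param path Output path.
#' @param genome Optional genome `DNAStringSet` for sequence lengths.
#' @export
write_gff3 <- function(loci, path, genome = NULL) {
  gr <- loci_granges(loci, genome)
  if (length(gr) > 0) {
    S4Vectors::mcols(gr)$type <- S4Vectors::mcols(gr)$locus_class
    S4Vectors::mcols(gr)$source <- "srnaloci"
    S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$locus_id
    kids <- NULL
    if (all(c("mature_start", "mature_len") %in% colnames(S4Vectors::mcols(gr)))) {
      mc <- S4Vectors::mcols(gr)
      ok <- !is.na(mc$mature_start)
      if (any(ok)) {
        mk <- GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(gr)[ok],
          IRanges::IRanges(mc$mature_start[ok] + 1,
                           mc$mature_start[ok] + mc$mature_len[ok]),
          strand = GenomicRanges::strand(gr)[ok],
          type = "miRNA", source = "srnaloci",
          ID = paste0(mc$locus_id[ok], ".mature"),
          Parent = mc$locus_id[ok])
        kids <- mk
        if ("star_start" %in% colnames(mc) && any(ok & !is.na(mc$star_start))) {
          ok2 <- ok & !is.na(mc$star_start)
          sk <- GenomicRanges::GRanges(
            GenomeInfoDb::seqnames(gr)[ok2],
            IRanges::IRanges(mc$star_start[ok2] + 1,
                             mc$star_start[ok2] + mc$star_len[ok2]),
            strand = GenomicRanges::strand(gr)[ok2],
            type = "miRNA_star", source = "srnaloci",
            ID = paste0(mc$locus_id[ok2], ".star"),
            Parent = mc$locus_id[ok2])
          kids <- c(kids, sk)
        }
      }
    }
    if (!is.null(kids)) {
      S4Vectors::mcols(gr)$Parent <- NA_character_
      shared <- intersect(colnames(S4Vectors::mcols(gr)),
                          colnames(S4Vectors::mcols(kids)))
      gr <- c(gr[, shared], kids[, shared])
      gr <- sort(gr, ignore.strand = TRUE)
    }
  }
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write loci as BED6
#'
#' 0-based half-open coordinates; the score column carries
#' `-10 * log10(best_p)` capped at 1000 for PHAS loci and 0 otherwise;
#' strand `.` is preserved.
#' @inheritParams write_gff3
#' @export
write_bed <- function(loci, path, genome = NULL) {
  gr <- loci_granges(loci, genome)
  if (length(gr) > 0) {
    ord <- loci[order(loci$chrom, loci$start), , drop = FALSE]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = paste0(ord$locus_class, ":", ord$locus_id),
      score = bed_score(ord))
  }
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Write a locus table as TSV
#'
#' One row per locus, sorted by (chrom, start), with a documented header
#' line. Numeric formatting is deterministic.
#' @inheritParams write_gff3
#' @export
write_locus_tsv <- function(loci, path) {
  keys <- intersect(c("chrom", "start", "locus_id", "phase_index"),
                    colnames(loci))
  o <- do.call(order, unname(loci[, keys, drop = FALSE]))
  df <- loci[o, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
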