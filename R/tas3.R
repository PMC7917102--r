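#' Score a plant small RNA target site
#'
#' Gap-free alignment of a small RNA against an equal-length target site:
#' each mismatch costs 1, each G:U wobble 0.5, and positions 2-13 of the
#' small RNA (the 5' core) are doubled. Small RNA position `i` (1-based
#' from its 5' end) is evaluated against site position `L - i + 1`, the
#' standard antiparallel pairing geometry. A mismatch (not a wobble) at
#' small RNA positions 9-11 flags the site as having a central mismatch,
#' i.e. likely non-cleavable.
#'
#' @param small_rna Small RNA sequence, 5' to 3' (DNA alphabet).
#' @param site Target site sequence, 5' to 3', same length.
#' @return List: `score`, `gu_count`, `mismatch_count`,
#'   `has_central_mismatch`, and the per-position `penalties` vector
#'   (indexed by small RNA position).
#' @export
score_target_site <- function(small_rna, site) {
  small_rna <- normalize_seq(small_rna)
  site <- normalize_seq(site)
  L <- nchar(small_rna)
  if (nchar(site) != L) stop("small RNA and site must have equal length")
  s <- strsplit(small_rna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])  # t[i] faces small RNA position i
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  match_wc <- t == comp[s]
  wobble <- (s == "G" & t == "T") | (s == "T" & t == "G")
  mism <- !match_wc & !wobble
  pen <- ifelse(match_wc, 0, ifelse(wobble, 0.5, 1))
  core <- seq_len(L) >= 2 & seq_len(L) <= 13
  pen <- pen * ifelse(core, 2, 1)
  list(score = sum(pen),
       gu_count = sum(wobble),
       mismatch_count = sum(mism),
       has_central_mismatch = any(mism[seq_len(L) >= 9 & seq_len(L) <= 11]),
       penalties = unname(pen))
}

# Scan one strand of a region for target sites with score <= cutoff.
# Returns 0-based site starts relative to region, with scores and flags.
scan_target_sites <- function(region_seq, small_rna, cutoff) {
  L <- nchar(small_rna)
  n <- nchar(region_seq) - L + 1
  out <- list()
  if (n < 1) return(data.frame(offset = integer(0), score = numeric(0),
                               central = logical(0), site = character(0)))
  for (o in 0:(n - 1)) {
    site <- substr(region_seq, o + 1, o + L)
    sc <- score_target_site(small_rna, site)
    if (sc$score <= cutoff)
      out[[length(out) + 1]] <- data.frame(
        offset = o, score = sc$score, central = sc$has_central_mismatch,
        site = site, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(offset = integer(0), score = numeric(0),
                      central = logical(0), site = character(0)))
  do.call(rbind, out)
}

#' Load the shipped miR390 / tasiARF defaults
#'
#' The default mature miR390 and tasiARF motif live in an editable
#' key=value data file, not in code; both can be overridden per call.
#' @return Named list with `mir390` and `tasiarf_motif`.
#' @export
load_tas3_defaults <- function() {
  path <- system.file("extdata", "tas3_defaults.txt", package = "srnaloci")
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=")
  out <- stats::setNames(lapply(kv, function(x) normalize_seq(trimws(x[2]))),
                         trimws(vapply(kv, `[`, "", 1)))
  list(mir390 = out[["mir390"]], tasiarf_motif = out[["tasiarf_motif"]])
}

#' Identify TAS3 genes among 21-PHAS loci
#'
#' A 21-PHAS locus (extended by `flank` bp) qualifies as a TAS3 gene when
#' it carries at least two same-strand miR390 target sites with score at
#' most `score_cutoff`. The downstream (3') site anchors the phasing
#' register at its cleavage position (between small RNA positions 10 and
#' 11); in-register 21-mers between the two sites are enumerated and
#' checked against the tasiARF motif with at most `mm_max` mismatches.
#' The cleavable-3'/non-cleavable-5' asymmetry is reported as attributes,
#' not enforced.
#'
#' @param phas_loci 21-PHAS locus table from [annotate_phas()].
#' @param genome Genome `DNAStringSet`.
#' @param mir390 Mature miR390 sequence (default from
#'   [load_tas3_defaults()]).
#' @param tasiarf_motif tasiARF motif sequence (same default mechanism).
#' @param score_cutoff Maximum target-site score (default 6).
#' @param flank Search flank around each locus in bp (default 200).
#' @param mm_max Maximum mismatches for a tasiARF motif match (default 3).
#' @return List with `loci` (TAS3 locus table: site coordinates,
#'   sequences, scores, cleavability flags) and `tasiarf` (one row per
#'   in-register 21-mer between the sites, with phase index from the 3'
#'   cleavage site and motif-match flag).
#' @export
find_tas3 <- function(phas_loci, genome, mir390 = NULL,
                      tasiarf_motif = NULL, score_cutoff = 6,
                      flank = 200, mm_max = 3) {
  if (is.null(mir390) || is.null(tasiarf_motif)) {
    defs <- load_tas3_defaults()
    mir390 <- mir390 %||% defs$mir390
    tasiarf_motif <- tasiarf_motif %||% defs$tasiarf_motif
  }
  if (is.null(mir390) || length(mir390) != 1 || is.na(mir390) ||
      !nzchar(mir390))
    stop("a mature miR390 sequence is required")
  mir390 <- normalize_seq(mir390)
  L <- nchar(mir390)
  empty_loci <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           locus_class = character(0),
                           locus_id = character(0),
                           phas_id = character(0),
                           site5_start = integer(0), site3_start = integer(0),
                           site5_seq = character(0), site3_seq = character(0),
                           site5_score = numeric(0), site3_score = numeric(0),
                           site3_cleavable = logical(0),
                           site5_central_mismatch = logical(0),
                           n_tasiarf = integer(0), stringsAsFactors = FALSE)
  empty_arf <- data.frame(locus_id = character(0), phase_index = integer(0),
                          start = integer(0), seq = character(0),
                          motif_match = logical(0), mismatches = integer(0),
                          stringsAsFactors = FALSE)
  if (nrow(phas_loci) == 0) return(list(loci = empty_loci,
                                        tasiarf = empty_arf))
  loci_out <- list()
  arf_out <- list()
  for (i in seq_len(nrow(phas_loci))) {
    lc <- phas_loci[i, ]
    chrom_len <- Biostrings::width(genome[names(genome) == lc$chrom])
    rs <- max(0, lc$start - flank)
    re <- min(chrom_len, lc$end + flank)
    fwd <- as.character(Biostrings::subseq(genome[[lc$chrom]], rs + 1, re))
    hits_by_strand <- list(
      "+" = scan_target_sites(fwd, mir390, score_cutoff),
      "-" = scan_target_sites(rc(fwd), mir390, score_cutoff))
    # genomic start of a minus-strand site at revcomp offset o:
    hits_by_strand[["-"]]$offset <-
      if (nrow(hits_by_strand[["-"]])) {
        (re - rs) - hits_by_strand[["-"]]$offset - L
      } else integer(0)
    strand <- if (nrow(hits_by_strand[["+"]]) >= 2) "+" else
      if (nrow(hits_by_strand[["-"]]) >= 2) "-" else NA
    if (is.na(strand)) next
    h <- hits_by_strand[[strand]]
    h$gstart <- rs + h$offset
    h <- h[order(h$gstart), , drop = FALSE]
    # transcript-orientation 5' and 3' sites: outermost pair
    if (strand == "+") {
      s5 <- h[1, ]; s3 <- h[nrow(h), ]
    } else {
      s5 <- h[nrow(h), ]; s3 <- h[1, ]
    }
    if (s5$gstart == s3$gstart) next
    # cleavage boundary of the 3' site (between sRNA positions 10 and 11)
    c3 <- if (strand == "+") s3$gstart + (L - 10) else s3$gstart + 10
    # enumerate in-register 21-mers between the sites, phase index counted
    # upstream (transcript 5' direction) from the 3' cleavage position
    arfs <- list()
    j <- 1
    repeat {
      a_start <- if (strand == "+") c3 - 21 * j else c3 + 21 * (j - 1)
      a_end <- a_start + 21
      inside <- if (strand == "+") a_start >= s5$gstart + L else
        a_end <= s5$gstart
      if (!inside || a_start < 0 || a_end > chrom_len) break
      sq <- as.character(Biostrings::subseq(genome[[lc$chrom]],
                                            a_start + 1, a_end))
      if (strand == "-") sq <- rc(sq)
      mm <- if (!is.null(tasiarf_motif) &&
                nchar(tasiarf_motif) == 21) hamming(sq, tasiarf_motif)
            else NA_integer_
      arfs[[j]] <- data.frame(phase_index = j, start = a_start, seq = sq,
                              motif_match = !is.na(mm) && mm <= mm_max,
                              mismatches = mm, stringsAsFactors = FALSE)
      j <- j + 1
    }
    arfs <- if (length(arfs)) do.call(rbind, arfs) else
      empty_arf[, -1, drop = FALSE]
    id <- sprintf("TAS3_%03d", length(loci_out) + 1)
    loci_out[[length(loci_out) + 1]] <- data.frame(
      chrom = lc$chrom, start = min(s5$gstart, s3$gstart),
      end = max(s5$gstart, s3$gstart) + L, strand = strand,
      locus_class = "TAS3", locus_id = id, phas_id = lc$locus_id,
      site5_start = s5$gstart, site3_start = s3$gstart,
      site5_seq = s5$site, site3_seq = s3$site,
      site5_score = s5$score, site3_score = s3$score,
      site3_cleavable = !s3$central,
      site5_central_mismatch = s5$central,
      n_tasiarf = sum(arfs$motif_match), stringsAsFactors = FALSE)
    if (nrow(arfs) > 0) {
      arfs <- cbind(data.frame(locus_id = id, stringsAsFactors = FALSE),
                    arfs)
      arf_out[[length(arf_out) + 1]] <- arfs
    }
  }
  list(loci = if (length(loci_out)) do.call(rbind, loci_out) else empty_loci,
       tasiarf = if (length(arf_out)) do.call(rbind, arf_out) else empty_arf)
}
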