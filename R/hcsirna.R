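#' Call heterochromatic siRNA loci
#'
#' A read cluster becomes an hc-siRNA locus when it is dominated by
#' 23-24 nt reads (`frac24 >= f_min`), derives from repetitive sequence
#' (abundance-weighted mean placement count `>= r_min`), carries at least
#' `a_min` hit-normalized counts, spans at least `min_locus_len` bp, and
#' does not overlap an accepted MIRNA or PHAS locus (class precedence
#' MIRNA > PHAS > hc-siRNA). Repetitiveness is measured from read
#' multi-mapping, so no external repeat annotation is needed.
#'
#' @param clust Result of [cluster_alignments()].
#' @param params Parameters; see [srna_config()] element `hcsirna`.
#' @param exclude Optional locus table (MIRNA/PHAS) whose intervals
#'   suppress overlapping candidates.
#' @return hc-siRNA locus table with `frac24`, `repetitiveness`,
#'   `total_abundance`, `n_distinct_reads`.
#' @export
call_hcsirna <- function(clust, params = srna_config()$hcsirna,
                         exclude = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      locus_class = character(0), locus_id = character(0),
                      total_abundance = numeric(0), frac24 = numeric(0),
                      repetitiveness = numeric(0),
                      n_distinct_reads = integer(0),
                      stringsAsFactors = FALSE)
  cl <- clust$clusters
  if (nrow(cl) == 0) return(empty)
  aln <- clust$alignments
  rows <- lapply(cl$cluster_id, function(cid) {
    sub <- aln[!is.na(aln$cluster_id) & aln$cluster_id == cid, ,
               drop = FALSE]
    tot <- sum(sub$weight)
    is24 <- sub$length %in% 23:24
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), strand = ".",
               locus_class = "HCSIRNA", locus_id = NA_character_,
               total_abundance = tot,
               frac24 = sum(sub$weight[is24]) / tot,
               repetitiveness = sum(sub$weight * sub$n_hits) / tot,
               n_distinct_reads = length(unique(sub$seq)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$frac24 >= params$f_min &
               out$repetitiveness >= params$r_min &
               out$total_abundance >= params$a_min &
               (out$end - out$start) >= params$min_locus_len, ,
             drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(out) > 0) {
    sup <- overlaps_any(out, exclude)
    out <- out[!sup, , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$locus_id <- sprintf("HCSIRNA_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# TRUE for rows of `a` overlapping any interval of `b` (strand-agnostic).
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  ga <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom,
                               IRanges::IRanges(b$start + 1, b$end))
  IRanges::overlapsAny(ga, gb)
}

#' Resolve class precedence across annotators
#'
#' Applies the deterministic one-class-per-interval rule: MIRNA loci are
#' kept as-is; PHAS loci overlapping a MIRNA locus are suppressed;
#' hc-siRNA candidates overlapping either surviving class are suppressed.
#'
#' @param mirna,phas21,phas24,hcsirna Locus tables (possibly empty).
#' @return List of the four tables after suppression, plus `combined`
#'   (all surviving loci, shared columns only, sorted).
#' @export
classify_overlaps <- function(mirna, phas21, phas24, hcsirna) {
  base_cols <- c("chrom", "start", "end", "strand", "locus_class",
                 "locus_id")
  drop_overlapping <- function(x, against) {
    if (is.null(x) || nrow(x) == 0) return(x)
    x[!overlaps_any(x, against), , drop = FALSE]
  }
  phas21 <- drop_overlapping(phas21, mirna)
  phas24 <- drop_overlapping(phas24, mirna)
  phas_all <- rbind(phas21[, base_cols, drop = FALSE],
                    phas24[, base_cols, drop = FALSE])
  hcsirna <- drop_overlapping(hcsirna,
                              rbind(if (nrow(mirna)) mirna[, base_cols],
                                    if (nrow(phas_all)) phas_all))
  combined <- rbind(if (nrow(mirna)) mirna[, base_cols],
                    if (nrow(phas21)) phas21[, base_cols],
                    if (nrow(phas24)) phas24[, base_cols],
                    if (nrow(hcsirna)) hcsirna[, base_cols])
  if (is.null(combined)) {
    combined <- mirna[, base_cols, drop = FALSE]
  }
  combined <- combined[order(combined$chrom, combined$start,
                             combined$locus_class), , drop = FALSE]
  rownames(combined) <- NULL
  list(mirna = mirna, phas21 = phas21, phas24 = phas24,
       hcsirna = hcsirna, combined = combined)
}
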