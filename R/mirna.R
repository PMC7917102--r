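#' Propose precursor fold windows for a read cluster
#'
#' The most abundant distinct read placements of a cluster (top `top_n`)
#' are treated as putative mature miRNAs; windows with a grid of flank
#' lengths around each anchor, capped at `max_precursor_len`, are emitted
#' as fold candidates and clipped to chromosome bounds. Clusters must be
#' dominated by 20-24 nt reads; in strict mode a cluster consisting solely
#' of 23-24 nt reads yields no candidates (such clusters are hc-siRNA
#' territory).
#'
#' @param cluster_aln Alignments of one cluster.
#' @param chrom_len Length of the cluster's chromosome.
#' @param max_precursor_len Precursor length cap in bp (default 300).
#' @param top_n Number of anchor read positions to consider (default 3).
#' @param strict Require 20-22 nt reads to be present (default TRUE).
#' @return Data frame of candidate windows (`chrom`, `win_start`,
#'   `win_end`, `strand`, `mature_start`, `mature_len`), possibly empty.
#' @export
propose_precursors <- function(cluster_aln, chrom_len,
                               max_precursor_len = 300, top_n = 3,
                               strict = TRUE) {
  empty <- data.frame(chrom = character(0), win_start = integer(0),
                      win_end = integer(0), strand = character(0),
                      mature_start = integer(0), mature_len = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(cluster_aln) == 0) return(empty)
  ab_ok <- sum(cluster_aln$weight[cluster_aln$length >= 20 &
                                    cluster_aln$length <= 24])
  if (ab_ok < 0.5 * sum(cluster_aln$weight)) return(empty)
  if (strict && !any(cluster_aln$length >= 20 & cluster_aln$length <= 22))
    return(empty)
  anc <- cluster_aln[cluster_aln$length >= 20 & cluster_aln$length <= 24, ,
                     drop = FALSE]
  if (nrow(anc) == 0) return(empty)
  key <- paste(anc$start, anc$strand, anc$length)
  agg <- rowsum(anc$count, key)
  ord <- order(-agg[, 1], rownames(agg))
  top <- rownames(agg)[ord][seq_len(min(top_n, nrow(agg)))]
  flanks <- c(12L, 30L, 60L, 100L, 160L, 240L)
  out <- list()
  for (t in top) {
    f <- strsplit(t, " ")[[1]]
    a <- as.integer(f[1]); str <- f[2]; l <- as.integer(f[3])
    for (fl in flanks) for (fr in flanks) {
      if (fl + fr + l > max_precursor_len) next
      ws <- max(0L, a - fl)
      we <- min(chrom_len, a + l + fr)
      out[[length(out) + 1]] <- data.frame(
        chrom = cluster_aln$chrom[1], win_start = ws, win_end = we,
        strand = str, mature_start = a, mature_len = l,
        stringsAsFactors = FALSE)
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Evaluate the mature/star duplex of a folded precursor
#'
#' The star is the segment pairing the mature strand, extended by the 2-nt
#' 3' overhang characteristic of DCL1 processing. Mismatches are mature
#' positions left unpaired within the duplex; asymmetric-bulge nucleotides
#' are the summed absolute length differences of opposing unpaired runs.
#' If the mature pairs on both sides of itself (spanning the loop) or has
#' fewer than two pairing partners outside itself, no star is assignable.
#'
#' @param pairs 1-based partner table from [fold_hairpin()].
#' @param mature_off 0-based offset of the mature within the folded
#'   sequence.
#' @param mature_len Mature length in nt.
#' @return List with `ok`; on success `star_off`, `star_len`,
#'   `n_mismatch`, `n_asym_bulge`, `overhang_3p_mature`,
#'   `overhang_3p_star`; on failure `reason = "no_star"`.
#' @export
evaluate_duplex <- function(pairs, mature_off, mature_len,
                            min_block = 4, block_gap = 5) {
  L <- length(pairs)
  pairs <- prune_short_helices(pairs)
  mi <- (mature_off + 1):(mature_off + mature_len)
  if (mature_off < 0 || max(mi) > L) stop("mature outside folded sequence")
  pt <- pairs[mi]
  ext <- which(pt > 0 & !(pt %in% mi))
  if (length(ext) < min_block) return(list(ok = FALSE, reason = "no_star"))
  # the star is the dominant contiguous partner block: mature positions
  # whose partners jump elsewhere (loop, flanks) are not duplex pairing
  # and will count as mismatches below
  ord <- order(mi[ext])
  mp <- mi[ext][ord]
  pp <- pt[ext][ord]
  side <- pp > max(mi)
  blk <- cumsum(c(1L, abs(diff(pp)) > block_gap | diff(side) != 0))
  sizes <- tabulate(blk)
  best_blk <- which.max(sizes)
  if (sizes[best_blk] < min_block)
    return(list(ok = FALSE, reason = "no_star"))
  sel <- which(blk == best_blk)
  # terminal pairs of the block may belong to adjacent structure (e.g. the
  # overhang nucleotides pairing into the loop) rather than to the duplex;
  # evaluate trimmed variants and keep the interpretation closest to the
  # canonical duplex geometry
  best <- NULL
  for (trim_lo in 0:2) for (trim_hi in 0:2) {
    n_sel <- length(sel)
    if (n_sel - trim_lo - trim_hi < min_block) next
    use <- sel[seq.int(1 + trim_lo, n_sel - trim_hi)]
    ev <- duplex_metrics(mp[use], pp[use], mi, L)
    ev$fit <- 100 * max(0, abs(ev$overhang_3p_mature - 2) - 1) +
      ev$n_mismatch + ev$n_asym_bulge + 0.1 * (trim_lo + trim_hi)
    if (is.null(best) || ev$fit < best$fit) best <- ev
  }
  best$fit <- NULL
  c(list(ok = TRUE), best)
}

# Duplex metrics for a fixed set of mature/star pairs (mp: mature
# positions, pp: their partners, mi: all mature positions, L: length).
# The star interval is extrapolated through terminal fraying: unpaired
# 5'-terminal mature bases still face star sequence, so the star end
# extends past the outermost observed pair by the frayed run before the
# 2-nt 3' overhang is added.
duplex_metrics <- function(mp, pp, mi, L) {
  i_last <- max(mp)
  fray5 <- min(mp) - min(mi)
  fray3 <- max(0L, (max(mi) - 2L) - i_last)
  considered <- mi[mi <= i_last]
  # frayed duplex positions at the 3' end (before the overhang) are
  # unpaired duplex positions, i.e. mismatches, not extra overhang
  n_mismatch <- sum(!(considered %in% mp)) + fray3
  over_m <- max(mi) - i_last - fray3
  star_lo <- max(1L, min(pp) - fray3)
  star_hi_pair <- max(pp) + fray5
  star_hi <- min(star_hi_pair + 2L, L)
  over_s <- star_hi - star_hi_pair
  asym <- 0L
  if (length(mp) > 1) {
    gm <- diff(mp) - 1L
    gs <- abs(diff(pp)) - 1L
    asym <- sum(abs(gm - gs))
  }
  list(star_off = star_lo - 1L,
       star_len = star_hi - star_lo + 1L,
       n_mismatch = as.integer(n_mismatch),
       n_asym_bulge = as.integer(asym),
       overhang_3p_mature = as.integer(over_m),
       overhang_3p_star = as.integer(over_s))
}

# Cheap upper bound on the attainable precision of a candidate window,
# computed before folding: whatever the star turns out to be, mature + star
# abundance cannot exceed the mature group plus the best other read-position
# group (each with +/- 1 nt variants), so windows failing the precision
# criterion under this bound need not be folded at all.
precision_attainable <- function(cd, cluster_aln, precision_min) {
  sub <- cluster_aln[cluster_aln$strand == cd$strand, , drop = FALSE]
  prec_ab <- sum(sub$count)
  if (prec_ab == 0) return(FALSE)
  near_mature <- abs(sub$start - cd$mature_start) <= 1 &
    abs(sub$end - (cd$mature_start + cd$mature_len)) <= 1
  mature_ab <- sum(sub$count[near_mature])
  others <- sub[!near_mature, , drop = FALSE]
  ub_star <- 0
  if (nrow(others) > 0) {
    grp <- unique(others[, c("start", "end")])
    ub_star <- max(vapply(seq_len(nrow(grp)), function(g)
      sum(others$count[abs(others$start - grp$start[g]) <= 1 &
                         abs(others$end - grp$end[g]) <= 1]),
      numeric(1)))
  }
  (mature_ab + ub_star) / prec_ab >= precision_min
}

# Map a [off, off+len) interval of a (possibly reverse-complemented)
# window sequence back to genomic coordinates.
window_to_genomic <- function(win_start, win_end, strand, off, len) {
  if (strand == "+") win_start + off else win_end - off - len
}

#' Score a precursor candidate against the MIRNA acceptance criteria
#'
#' Builds the criteria scorecard: mature length 20-24 nt; at most 5
#' mismatched duplex positions of which at most 3 nt in asymmetric bulges;
#' 2-nt 3' overhangs (+/- 1 nt tolerance); precision (mature + star
#' abundance over the locus cluster's same-strand abundance, counting
#' +/- 1 nt positional variants) at least `precision_min`; star evidence;
#' replication across
#' libraries when more than one is supplied; and a mature multi-mapping
#' cap guarding against repeat-derived candidates.
#'
#' @param cand One candidate row (window + duplex evaluation fields).
#' @param cluster_aln Alignments of the candidate's cluster.
#' @param reads The merged `srna_reads` set (for replication lookup).
#' @param n_libs Number of libraries supplied.
#' @param params MIRNA parameter list; see [srna_config()] element `mirna`.
#' @return The candidate row with flag columns, `precision`, `verdict`
#'   ("accepted"/"rejected") and `reject_reasons` appended.
#' @export
score_mirna <- function(cand, cluster_aln, reads, n_libs,
                        params = srna_config()$mirna) {
  # precision denominator is the whole cluster on the candidate strand:
  # a candidate window must account for its locus, not just a slice of it
  sub <- cluster_aln[cluster_aln$strand == cand$strand, , drop = FALSE]
  prec_ab <- sum(sub$count)
  near <- function(a_start, a_len) {
    sel <- abs(sub$start - a_start) <= 1 &
      abs(sub$end - (a_start + a_len)) <= 1
    sum(sub$count[sel])
  }
  mature_ab <- near(cand$mature_start, cand$mature_len)
  star_g <- window_to_genomic(cand$win_start, cand$win_end, cand$strand,
                              cand$star_off, cand$star_len)
  star_ab <- near(star_g, cand$star_len)
  precision <- if (prec_ab > 0) (mature_ab + star_ab) / prec_ab else 0
  mrow <- sub[sub$start == cand$mature_start &
                sub$length == cand$mature_len, , drop = FALSE]
  mature_hits <- if (nrow(mrow) > 0) mrow$n_hits[1] else Inf
  mseq <- if (nrow(mrow) > 0) mrow$seq[1] else NA_character_
  libs_seen <- if (!is.na(mseq)) reads$n_libs[match(mseq, reads$seq)] else 0
  flags <- list(
    length_ok = cand$mature_len >= 20 && cand$mature_len <= 24,
    duplex_ok = cand$n_mismatch <= params$max_mismatch &&
      cand$n_asym_bulge <= params$max_asym_bulge,
    overhang_ok =
      abs(cand$overhang_3p_mature - 2) <= params$overhang_tol &&
      abs(cand$overhang_3p_star - 2) <= params$overhang_tol,
    precision_ok = precision >= params$precision_min,
    star_expressed = star_ab > 0,
    multi_library = n_libs < 2 || (!is.na(libs_seen) && libs_seen >= 2),
    multimap_ok = mature_hits <= params$max_mature_hits)
  star_req <- if (params$strict) flags$star_expressed else
    flags$star_expressed ||
    (cand$mature_len %in% 21:22 && flags$precision_ok && flags$multi_library)
  required <- c(flags[c("length_ok", "duplex_ok", "overhang_ok",
                        "precision_ok", "multi_library", "multimap_ok")],
                star = star_req)
  verdict <- if (all(unlist(required))) "accepted" else "rejected"
  reasons <- names(required)[!unlist(required)]
  cbind(cand,
        data.frame(star_start = star_g,
                   mature_ab = mature_ab, star_ab = star_ab,
                   precursor_ab = prec_ab, precision = precision,
                   mature_seq = mseq, mature_hits = mature_hits,
                   length_ok = flags$length_ok, duplex_ok = flags$duplex_ok,
                   overhang_ok = flags$overhang_ok,
                   precision_ok = flags$precision_ok,
                   star_expressed = flags$star_expressed,
                   multi_library = flags$multi_library,
                   multimap_ok = flags$multimap_ok,
                   verdict = verdict,
                   reject_reasons = paste(reasons, collapse = ","),
                   stringsAsFactors = FALSE))
}

# Candidate ordering: most abundant mature arm first (the mature is by
# convention the more abundant duplex strand), then highest precision,
# fewest mismatches, shortest precursor, then coordinates for determinism.
mirna_order <- function(df) {
  order(-df$mature_ab, -df$precision, df$n_mismatch,
        df$win_end - df$win_start, df$chrom, df$win_start, df$strand)
}

#' Call MIRNA loci from read clusters
#'
#' For each cluster, fold candidate precursor windows around the most
#' abundant read placements, evaluate the mature/star duplex, score every
#' candidate against the acceptance criteria and retain the best accepted
#' candidate per cluster; overlapping accepted hairpins are then merged
#' keeping the best scorecard, and loci sharing an identical mature
#' sequence are grouped into one family.
#'
#' @param clust Result of [cluster_alignments()].
#' @param genome Genome `DNAStringSet`.
#' @param reads Merged `srna_reads` set.
#' @param params MIRNA parameters; see [srna_config()].
#' @return List with `loci` (accepted MIRNA locus table) and `scorecards`
#'   (best-scoring candidate per cluster, accepted or not).
#' @export
call_mirna <- function(clust, genome, reads, params = srna_config()$mirna) {
  aln <- clust$alignments
  n_libs <- length(lib_cols(reads))
  cards <- list()
  accepted <- list()
  for (cid in clust$clusters$cluster_id) {
    cl_aln <- aln[!is.na(aln$cluster_id) & aln$cluster_id == cid, ,
                  drop = FALSE]
    ch <- cl_aln$chrom[1]
    cands <- propose_precursors(cl_aln,
                                chrom_len = Biostrings::width(
                                  genome[names(genome) == ch]),
                                max_precursor_len = params$max_precursor_len,
                                top_n = params$top_anchors,
                                strict = params$strict)
    if (nrow(cands) == 0) next
    scored <- list()
    for (i in seq_len(nrow(cands))) {
      cd <- cands[i, , drop = FALSE]
      if (!precision_attainable(cd, cl_aln, params$precision_min)) next
      sq <- as.character(Biostrings::subseq(genome[[ch]],
                                            cd$win_start + 1, cd$win_end))
      if (cd$strand == "-") sq <- rc(sq)
      fold <- fold_hairpin(sq)
      m_off <- if (cd$strand == "+") cd$mature_start - cd$win_start else
        cd$win_end - (cd$mature_start + cd$mature_len)
      dx <- evaluate_duplex(fold$pairs, m_off, cd$mature_len)
      if (!dx$ok) next
      cd2 <- cbind(cd, as.data.frame(dx[-1]), structure = fold$structure,
                   precursor_seq = sq, stringsAsFactors = FALSE)
      scored[[length(scored) + 1]] <-
        score_mirna(cd2, cl_aln, reads, n_libs, params)
    }
    if (length(scored) == 0) next
    sc <- do.call(rbind, scored)
    sc$cluster_id <- cid
    acc <- sc[sc$verdict == "accepted", , drop = FALSE]
    if (nrow(acc) > 0) {
      best <- acc[mirna_order(acc)[1], , drop = FALSE]
      accepted[[length(accepted) + 1]] <- best
      cards[[length(cards) + 1]] <- best
    } else {
      cards[[length(cards) + 1]] <- sc[mirna_order(sc)[1], , drop = FALSE]
    }
  }
  cards <- if (length(cards)) do.call(rbind, cards) else NULL
  loci <- if (length(accepted)) do.call(rbind, accepted) else NULL
  loci <- deduplicate_mirna(loci)
  list(loci = loci, scorecards = cards)
}

#' Merge overlapping accepted hairpins and group mature families
#'
#' Accepted hairpins overlapping on the same strand are collapsed keeping
#' the best scorecard (highest precision, fewest mismatches, shortest
#' precursor); distinct loci sharing an identical mature sequence are
#' grouped under one mature family id.
#'
#' @param loci Accepted candidate rows from [call_mirna()] (or NULL).
#' @return The deduplicated MIRNA locus table (possibly empty) with
#'   columns renamed to the canonical locus layout plus `family`.
#' @export
deduplicate_mirna <- function(loci) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      locus_class = character(0), locus_id = character(0),
                      mature_start = integer(0), mature_len = integer(0),
                      mature_seq = character(0), star_start = integer(0),
                      star_len = integer(0), precision = numeric(0),
                      n_mismatch = integer(0), n_asym_bulge = integer(0),
                      mature_ab = numeric(0), star_ab = numeric(0),
                      structure = character(0), family = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(loci) || nrow(loci) == 0) return(empty)
  loci <- loci[mirna_order(loci), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (loci$chrom[i] == loci$chrom[j] &&
          loci$strand[i] == loci$strand[j] &&
          loci$win_start[i] < loci$win_end[j] &&
          loci$win_end[i] > loci$win_start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  out <- data.frame(
    chrom = loci$chrom, start = loci$win_start, end = loci$win_end,
    strand = loci$strand, locus_class = "MIRNA",
    locus_id = NA_character_,
    mature_start = loci$mature_start, mature_len = loci$mature_len,
    mature_seq = loci$mature_seq, star_start = loci$star_start,
    star_len = loci$star_len, precision = loci$precision,
    n_mismatch = loci$n_mismatch, n_asym_bulge = loci$n_asym_bulge,
    mature_ab = loci$mature_ab, star_ab = loci$star_ab,
    structure = loci$structure, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$locus_id <- sprintf("MIRNA_%04d", seq_len(nrow(out)))
  fam <- match(out$mature_seq, sort(unique(out$mature_seq)))
  out$family <- sprintf("mat_%04d", fam)
  rownames(out) <- NULL
  out
}
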