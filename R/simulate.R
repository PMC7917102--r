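#' Default planted-locus specification for the synthetic genome
#'
#' @return List giving the number of planted loci per class and the
#'   construct parameters (phase cycles, repeat copy number and unit
#'   length, per-copy divergence, planted duplex mismatches).
#' @export
default_plant_spec <- function() {
  list(mirna = 3, mirna_decoy = 1,
       phas21 = 3, phas24 = 2,
       repeat_copies = 10, repeat_unit_len = 300, repeat_divergence = 0,
       tas3 = 1, tas3_decoy = 1,
       phas_cycles = 8, tasiarf_phase = 2)
}

# Pick a base that cannot pair (WC or G:U) with any base in `avoid`.
nonpairing_base <- function(avoid) {
  partners <- list(A = "T", T = c("A", "G"), G = c("C", "T"), C = "G",
                   N = character(0))
  bad <- unique(unlist(partners[avoid]))
  cand <- setdiff(c("A", "C", "G", "T"), bad)
  if (length(cand) == 0) "A" else cand[1]
}

# Canonical planted hairpin: mature(21) + loop(15) + revcomp(mature[1:19])
# + 2-nt tail, so the mature/star duplex has 2-nt 3' overhangs on both
# arms under max-pair folding. Tail bases are chosen unable to pair the
# overhang (duplex extension) or the mature 5' end (register shift).
mirna_construct <- function(mature, loop_len = 15) {
  m <- strsplit(mature, "")[[1]]
  loop <- random_dna(loop_len)
  star19 <- rc(substr(mature, 1, 19))
  tail <- paste0(nonpairing_base(c(m[20], m[2])),
                 nonpairing_base(c(m[21], m[1])))
  list(seq = paste0(mature, loop, star19, tail),
       mature_off = 0L, mature_len = 21L,
       star_off = 36L, star_len = 21L)
}

# Dinucleotide-preserving randomization: first-order Markov chain fitted
# to the sequence's own dinucleotide transitions, same length and start.
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  trans <- table(factor(ch[-n], levels = c("A", "C", "G", "T")),
                 factor(ch[-1], levels = c("A", "C", "G", "T")))
  out <- character(n)
  out[1] <- ch[1]
  for (i in 2:n) {
    w <- trans[out[i - 1], ]
    if (sum(w) == 0) w <- rep(1, 4)
    out[i] <- sample(c("A", "C", "G", "T"), 1, prob = w)
  }
  paste(out, collapse = "")
}

#' Build a synthetic genome with planted, truth-tracked loci
#'
#' A random background sequence at the requested GC content carries
#' non-overlapping planted constructs: MIRNA hairpins (mature + 15-nt loop
#' + reverse-complement star with 2-nt 3' overhangs), PHAS intervals with
#' a recorded register and cycle count, a dispersed repeat family, TAS3
#' regions bracketed by two miR390 target sites (the 5' one carrying a
#' central mismatch), plus structure-destroyed decoys: a
#' dinucleotide-randomized hairpin and a single-site TAS3.
#'
#' @param seed Integer RNG seed; a fixed seed gives a byte-identical
#'   genome and truth.
#' @param length Genome length in bp.
#' @param gc Background GC fraction.
#' @param plant_spec See [default_plant_spec()].
#' @param mir390 miR390 sequence for TAS3 constructs (default shipped).
#' @param tasiarf_motif tasiARF sequence planted in-register.
#' @return List with `genome` (single-chromosome `DNAStringSet`), `truth`
#'   (one row per planted locus with class-specific payload columns), and
#'   `seed`.
#' @export
make_genome <- function(seed, length = 5e5, gc = 0.4,
                        plant_spec = default_plant_spec(),
                        mir390 = NULL, tasiarf_motif = NULL) {
  defs <- load_tas3_defaults()
  mir390 <- normalize_seq(mir390 %||% defs$mir390)
  tasiarf_motif <- normalize_seq(tasiarf_motif %||% defs$tasiarf_motif)
  L390 <- nchar(mir390)
  with_seed(seed, {
    bg <- random_dna(length, gc)
    cycles <- plant_spec$phas_cycles
    constructs <- list()
    add <- function(class, seq, payload) {
      constructs[[base::length(constructs) + 1]] <<-
        c(list(class = class, seq = seq), payload)
    }
    # matures are resampled until they carry no appreciable self-structure,
    # as real mature miRNAs do not fold onto themselves
    sample_mature <- function() {
      repeat {
        m <- random_dna(21, 0.5)
        if (fold_hairpin(m)$n_pairs <= 3) return(m)
      }
    }
    for (i in seq_len(plant_spec$mirna)) {
      mc <- mirna_construct(sample_mature())
      add("MIRNA", mc$seq, mc[-1])
    }
    for (i in seq_len(plant_spec$mirna_decoy)) {
      mc <- mirna_construct(sample_mature())
      add("MIRNA_DECOY", dinuc_shuffle(mc$seq), mc[-1])
    }
    for (D in c(rep(21L, plant_spec$phas21), rep(24L, plant_spec$phas24))) {
      add(paste0("PHAS", D), random_dna(D * (cycles + 1), gc),
          list(phase_len = D, cycles = cycles))
    }
    if (plant_spec$repeat_copies > 0) {
      unit <- random_dna(plant_spec$repeat_unit_len, gc)
      for (i in seq_len(plant_spec$repeat_copies)) {
        u <- unit
        nmut <- round(plant_spec$repeat_divergence *
                        plant_spec$repeat_unit_len)
        if (nmut > 0) {
          pos <- sample(nchar(u), nmut)
          for (p in pos) {
            cur <- substr(u, p, p)
            substr(u, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
        add("REPEAT", u, list(copy_number = plant_spec$repeat_copies,
                              copy_index = i))
      }
    }
    make_tas3_construct <- function(dual_site) {
      site3 <- rc(mir390)
      site5 <- site3
      p10 <- L390 - 9  # site position facing small RNA position 10
      substr(site5, p10, p10) <-
        nonpairing_base(chartr("ACGT", "TGCA",
                               substr(mir390, 10, 10)))
      site3_off <- L390 + 21 * cycles
      total <- site3_off + L390
      body <- random_dna(total, gc)
      if (dual_site) substr(body, 1, L390) <- site5
      substr(body, site3_off + 1, site3_off + L390) <- site3
      c3 <- site3_off + 11  # cleavage boundary within the construct
      arf_off <- c3 - 21 * plant_spec$tasiarf_phase
      substr(body, arf_off + 1, arf_off + 21) <- tasiarf_motif
      list(seq = body, phase_len = 21L, cycles = cycles,
           site5_off = if (dual_site) 0L else NA_integer_,
           site3_off = site3_off, cleavage3_off = c3,
           tasiarf_off = arf_off,
           tasiarf_phase = plant_spec$tasiarf_phase)
    }
    for (i in seq_len(plant_spec$tas3)) {
      tc <- make_tas3_construct(TRUE)
      add("TAS3", tc$seq, tc[-1])
    }
    for (i in seq_len(plant_spec$tas3_decoy)) {
      tc <- make_tas3_construct(FALSE)
      add("TAS3_DECOY", tc$seq, tc[-1])
    }
    n <- base::length(constructs)
    if (n == 0) stop("plant_spec plants nothing")
    block <- floor(length / n)
    if (block < 2 * max(vapply(constructs, function(x) nchar(x$seq), 1)))
      stop("planted constructs cannot fit in the requested genome length")
    slots <- sample(n)  # construct -> block assignment
    truth <- list()
    for (i in seq_len(n)) {
      co <- constructs[[i]]
      b0 <- (slots[i] - 1) * block
      off <- sample.int(max(1, block %/% 4), 1)
      s <- b0 + off
      e <- s + nchar(co$seq)
      substr(bg, s + 1, e) <- co$seq
      row <- data.frame(
        class = co$class, chrom = "chr1", start = s, end = e, strand = "+",
        truth_id = sprintf("T%03d", i),
        mature_start = if (!is.null(co$mature_off)) s + co$mature_off
                       else NA_integer_,
        mature_len = co$mature_len %||% NA_integer_,
        star_start = if (!is.null(co$star_off)) s + co$star_off
                     else NA_integer_,
        star_len = co$star_len %||% NA_integer_,
        phase_len = co$phase_len %||% NA_integer_,
        cycles = co$cycles %||% NA_integer_,
        register = if (!is.null(co$phase_len) && is.null(co$cleavage3_off))
          s %% co$phase_len else NA_integer_,
        copy_number = co$copy_number %||% NA_integer_,
        site5_start = if (!is.null(co$site5_off) && !is.na(co$site5_off))
          s + co$site5_off else NA_integer_,
        site3_start = if (!is.null(co$site3_off)) s + co$site3_off
                      else NA_integer_,
        cleavage3 = if (!is.null(co$cleavage3_off)) s + co$cleavage3_off
                    else NA_integer_,
        tasiarf_start = if (!is.null(co$tasiarf_off)) s + co$tasiarf_off
                        else NA_integer_,
        tasiarf_phase = co$tasiarf_phase %||% NA_integer_,
        stringsAsFactors = FALSE)
      truth[[i]] <- row
    }
    truth <- do.call(rbind, truth)
    # registers of TAS3-style loci are anchored at the 3' cleavage site
    tas <- !is.na(truth$cleavage3)
    truth$register[tas] <- truth$cleavage3[tas] %% 21
    genome <- Biostrings::DNAStringSet(bg)
    names(genome) <- "chr1"
    list(genome = genome, truth = truth, seed = seed)
  })
}

#' Default read-emission parameters for the synthetic libraries
#' @return Named list of per-class abundance settings.
#' @export
sim_read_params <- function() {
  list(mirna_mature_count = 100, star_ratio = 0.1, n_frags = 2,
       phas_count_range = c(5, 50), off_phase_fraction = 0.1,
       repeat_total = 600, repeat_positions = 15,
       noise_reads = 200, n_libraries = 2)
}

#' Emit collapsed synthetic sRNA libraries from a planted genome
#'
#' MIRNA loci emit their mature and star (at `star_ratio`) plus low-level
#' precursor fragments; PHAS and TAS3 loci emit phase-length reads at the
#' planted register on both strands (minus-strand starts offset -2 nt so
#' their effective phase positions coincide) with `off_phase_fraction` of
#' abundance off-register; the repeat family emits 24-nt reads from within
#' its units; background noise reads of 18-26 nt are drawn from random
#' genome positions. With `permute_phas = TRUE` the PHAS/TAS3 read starts
#' are instead drawn uniformly within each locus (counts and lengths
#' preserved), destroying the phasing structure.
#'
#' @param sim Result of [make_genome()].
#' @param params See [sim_read_params()].
#' @param seed RNG seed for read emission (independent of the genome
#'   seed).
#' @param permute_phas Destroy phasing by uniform start permutation.
#' @return List with `reads` (merged `srna_reads` across
#'   `params$n_libraries` libraries) and `read_truth` (sequence to
#'   truth-locus attribution; background noise is `"noise"`).
#' @export
make_reads <- function(sim, params = sim_read_params(), seed = 1,
                       permute_phas = FALSE) {
  genome <- sim$genome
  truth <- sim$truth
  gseq <- as.character(genome[["chr1"]])
  glen <- nchar(gseq)
  sub_fw <- function(s, l) substr(gseq, s + 1, s + l)
  with_seed(seed + 104729L, {
    rows <- list()
    emit <- function(seq, count, locus, strand = "+") {
      if (count >= 1 && !grepl("N", seq, fixed = TRUE))
        rows[[base::length(rows) + 1]] <<-
          data.frame(seq = seq, count = count, locus = locus,
                     strand = strand, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      if (tr$class %in% c("MIRNA", "MIRNA_DECOY")) {
        m <- params$mirna_mature_count
        emit(sub_fw(tr$mature_start, tr$mature_len), m, tr$truth_id)
        emit(sub_fw(tr$star_start, tr$star_len),
             round(params$star_ratio * m), tr$truth_id)
        for (f in seq_len(params$n_frags)) {
          fs <- tr$start + sample.int(tr$end - tr$start - 21, 1)
          emit(sub_fw(fs, 21), 1, tr$truth_id)
        }
      } else if (tr$class %in% c("PHAS21", "PHAS24", "TAS3", "TAS3_DECOY")) {
        D <- tr$phase_len
        phased <- if (!is.na(tr$cleavage3))
          tr$cleavage3 - D * seq_len(tr$cycles)
        else tr$start + D * (seq_len(tr$cycles) - 1)
        lo <- min(phased); hi <- max(phased)
        cnt <- function() sample(params$phas_count_range[1]:
                                   params$phas_count_range[2], 1)
        for (p in phased) {
          emit(sub_fw(p, D), cnt(), tr$truth_id, "+")
          emit(rc(sub_fw(p - 2, D)), cnt(), tr$truth_id, "-")
        }
        n_off <- round(params$off_phase_fraction * 2 * tr$cycles)
        if (n_off > 0) {
          cand <- setdiff(lo:hi, phased)
          offp <- sample(cand, min(n_off, base::length(cand)))
          for (p in offp) {
            emit(sub_fw(p, D), max(1, round(cnt() / 2)), tr$truth_id, "+")
          }
        }
      } else if (tr$class == "REPEAT") {
        if (tr$end - tr$start > 24) {
          offs <- sample.int(tr$end - tr$start - 24, params$repeat_positions)
          per <- max(1, round(params$repeat_total /
                                (params$repeat_positions *
                                   sum(truth$class == "REPEAT"))))
          for (o in offs) emit(sub_fw(tr$start + o, 24), per, tr$truth_id)
        }
      }
    }
    for (i in seq_len(params$noise_reads)) {
      l <- sample(18:26, 1)
      s <- sample.int(glen - l, 1)
      sq <- sub_fw(s, l)
      if (sample(c(TRUE, FALSE), 1)) sq <- rc(sq)
      emit(sq, 1, "noise")
    }
    all <- do.call(rbind, rows)
    if (permute_phas) {
      # post-pass: redraw the start positions of phased-class reads
      # uniformly within their locus; counts and lengths are untouched
      for (i in seq_len(nrow(truth))) {
        tr <- truth[i, ]
        if (!tr$class %in% c("PHAS21", "PHAS24", "TAS3", "TAS3_DECOY"))
          next
        D <- tr$phase_len
        phased <- if (!is.na(tr$cleavage3))
          tr$cleavage3 - D * seq_len(tr$cycles)
        else tr$start + D * (seq_len(tr$cycles) - 1)
        lo <- min(phased); hi <- max(phased)
        sel <- which(all$locus == tr$truth_id)
        for (j in sel) {
          s <- lo + sample.int(hi - lo + 1, 1) - 1
          all$seq[j] <- if (all$strand[j] == "+") sub_fw(s, D)
                        else rc(sub_fw(s - 2, D))
        }
      }
    }
    total <- rowsum(all$count, all$seq)
    seqs <- rownames(total)
    counts <- as.numeric(total[, 1])
    o <- order(seqs)
    seqs <- seqs[o]; counts <- counts[o]
    nl <- max(1, params$n_libraries)
    if (nl == 1) {
      lc <- data.frame(counts); colnames(lc) <- "lib.sim1"
    } else {
      l1 <- ceiling(counts * 0.6)
      lc <- data.frame(l1, counts - l1)
      colnames(lc) <- c("lib.sim1", "lib.sim2")
    }
    reads <- new_read_set(seqs, nchar(seqs), counts,
                          as.integer(rowSums(lc > 0)), lc)
    attribution <- tapply(all$locus, all$seq,
                          function(x) paste(sort(unique(x)), collapse = ","))
    list(reads = reads,
         read_truth = data.frame(seq = seqs,
                                 locus = as.character(attribution[seqs]),
                                 stringsAsFactors = FALSE))
  })
}

#' Write a simulation bundle to disk
#'
#' Emits `genome.fa`, `reads.fa` (canonical collapsed FASTA of total
#' counts), `truth.bed` and a `truth.json` sidecar carrying the full truth
#' table and seed, all byte-deterministic for a fixed seed.
#'
#' @param sim Result of [make_genome()].
#' @param reads Result of [make_reads()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_collapsed_fasta(reads$reads, file.path(dir, "reads.fa"))
  tb <- sim$truth
  tb$locus_class <- tb$class
  tb$locus_id <- tb$truth_id
  write_bed(tb[, c("chrom", "start", "end", "strand", "locus_class",
                   "locus_id")], file.path(dir, "truth.bed"))
  jsonlite::write_json(list(seed = sim$seed, truth = sim$truth),
                       file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(dir)
}
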