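#' Upper-tail hypergeometric phasing p-value
#'
#' Probability of observing at least `k` occupied phased start positions
#' when `n` occupied positions are placed among `N` eligible positions of
#' which `m` are phased: `Pr[X >= k]` for `X ~ Hypergeometric(N, m, n)`.
#' Terms are evaluated by overflow-free interleaved rational products plus a
#' term-to-term recurrence, so no intermediate binomial coefficient is
#' formed (no floating overflow for `N <= 1e4`).
#'
#' @param N Total eligible start positions in the window (both strands).
#' @param m Phased positions among them.
#' @param n Occupied distinct positions.
#' @param k Occupied phased positions.
#' @return The exact tail probability in (0, 1]; `k = 0` gives 1.
#' @export
phasing_pvalue <- function(N, m, n, k) {
  stopifnot(length(N) == 1, length(m) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, m, n, k) < 0) || any(c(N, m, n, k) != floor(c(N, m, n, k))))
    stop("N, m, n, k must be non-negative integers")
  if (m > N || n > N) stop("m and n must not exceed N")
  if (k > min(n, m)) stop("k must not exceed min(n, m)")
  if (k == 0) return(1)
  kmax <- min(n, m)
  x0 <- max(k, n - (N - m))  # smallest x with a non-zero pmf term
  t <- hyper_pmf_term(N, m, n, x0)
  if (t == 0) {  # deep underflow: fall back to log-space accumulation
    lt <- lchoose(m, x0:kmax) + lchoose(N - m, n - (x0:kmax)) - lchoose(N, n)
    mx <- max(lt)
    return(min(1, exp(mx) * sum(exp(lt - mx))))
  }
  p <- t
  if (kmax > x0) {
    for (x in x0:(kmax - 1)) {
      t <- t * (m - x) * (n - x) / ((x + 1) * (N - m - n + x + 1))
      p <- p + t
    }
  }
  min(1, p)
}

# pmf term C(m,x) C(N-m,n-x) / C(N,n) via interleaved ratio products.
hyper_pmf_term <- function(N, m, n, x) {
  r1 <- if (x > 0) (m - x + seq_len(x)) / seq_len(x) else numeric(0)
  y <- n - x
  r2 <- if (y > 0) (N - m - y + seq_len(y)) / seq_len(y) else numeric(0)
  r3 <- if (n > 0) (N - n + seq_len(n)) / seq_len(n) else numeric(0)
  num <- c(r1, r2)
  v <- 1
  L <- max(length(num), length(r3))
  for (i in seq_len(L)) {
    if (i <= length(num)) v <- v * num[i]
    if (i <= length(r3)) v <- v / r3[i]
  }
  v
}

#' Phasing score of a register window
#'
#' `ln((1 + 10 P / (1 + U))^(k - 2))` for `k >= 3` occupied cycles and 0
#' otherwise, where `P` is the phased and `U` the unphased hit-normalized
#' abundance in the window. Strictly increasing in `P` at fixed `U`.
#'
#' @param P Phased abundance (>= 0).
#' @param U Unphased abundance (>= 0).
#' @param k Occupied phased positions (cycles).
#' @return Non-negative score.
#' @export
phasing_score <- function(P, U, k) {
  stopifnot(all(P >= 0), all(U >= 0), all(k >= 0))
  ifelse(k >= 3, (k - 2) * log1p(10 * P / (1 + U)), 0)
}

# Effective phase position of an alignment start: minus-strand starts are
# shifted +2 nt so both strands share the register of the phased duplex.
effective_pos <- function(start, strand) start + ifelse(strand == "-", 2L, 0L)

# Counts (N, m, n, k, P, U) for one window placement.
window_counts <- function(epos, strand, weight, wstart, D, cycles) {
  N <- 2L * D * cycles
  m <- 2L * cycles
  inw <- epos >= wstart & epos < wstart + D * cycles
  if (!any(inw)) {
    return(list(N = N, m = m, n = 0L, k = 0L, P = 0, U = 0))
  }
  e <- epos[inw]; s <- strand[inw]; w <- weight[inw]
  phased <- (e - wstart) %% D == 0
  key <- paste(s, e)
  n <- length(unique(key))
  k <- length(unique(key[phased]))
  list(N = N, m = m, n = n, k = k,
       P = sum(w[phased]), U = sum(w[!phased]))
}

#' Scan register windows for phased siRNA production
#'
#' Slides a window of `cycles` phase cycles (span `D * cycles` bp) across
#' each read cluster at the given stride and evaluates the hypergeometric
#' phasing p-value and phasing score for the register implied by each
#' window start. Occupancy counts distinct start positions (per strand,
#' with minus-strand starts shifted +2 nt); abundance enters only the
#' phasing score. Only reads of length exactly `D` (optionally +/-
#' `len_tol`) with at most `max_hits_phase` genomic placements contribute.
#'
#' @param aln `srna_alignments` with `cluster_id` (from
#'   [cluster_alignments()]).
#' @param D Phase length, 21 or 24 nt.
#' @param cycles Window length in phase cycles (default 10).
#' @param step Window stride in bp (default 1).
#' @param max_hits_phase Multi-mapping cap for phasing input (default 10).
#' @param p_cutoff Retain windows with `p <= p_cutoff` (default 1e-3);
#'   `return_all = TRUE` returns every scanned window.
#' @param len_tol Read-length tolerance around `D` (default 0).
#' @param min_phased_frac Minimum fraction of window abundance on phase
#'   for a window to count as significant (default 0.5): a phased locus
#'   is expected to produce the majority of its reads in register, and
#'   this guards against windows that clip a cluster edge and reach the
#'   p cutoff on a handful of coincidentally spaced positions.
#' @param return_all Return all windows, not only significant ones.
#' @return Data frame of windows: `chrom`, `cluster_id`, `window_start`,
#'   `phase_len`, `N`, `m`, `n`, `k`, `p_value`, `phased_ab`,
#'   `unphased_ab`, `phasing_score`.
#' @export
scan_registers <- function(aln, D, cycles = 10, step = 1,
                           max_hits_phase = 10, p_cutoff = 1e-3,
                           len_tol = 0, min_phased_frac = 0.5,
                           return_all = FALSE) {
  keep <- !is.na(aln$cluster_id) &
    abs(aln$length - D) <= len_tol &
    aln$n_hits <= max_hits_phase
  sub <- aln[keep, , drop = FALSE]
  out <- list()
  empty <- data.frame(chrom = character(0), cluster_id = integer(0),
                      window_start = integer(0), phase_len = integer(0),
                      N = integer(0), m = integer(0), n = integer(0),
                      k = integer(0), p_value = numeric(0),
                      phased_ab = numeric(0), unphased_ab = numeric(0),
                      phasing_score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sub) == 0) return(empty)
  wlen <- D * cycles
  for (cid in sort(unique(sub$cluster_id))) {
    cl <- sub[sub$cluster_id == cid, , drop = FALSE]
    epos <- effective_pos(cl$start, cl$strand)
    lo <- min(epos) - wlen + D  # earliest window still anchoring a full cycle
    hi <- max(epos)
    pcache <- new.env(parent = emptyenv())
    for (ws in seq(lo, hi, by = step)) {
      wc <- window_counts(epos, cl$strand, cl$weight, ws, D, cycles)
      if (wc$k == 0 && !return_all) next
      key <- paste(wc$n, wc$k)
      p <- pcache[[key]]
      if (is.null(p)) {
        p <- phasing_pvalue(wc$N, wc$m, wc$n, wc$k)
        pcache[[key]] <- p
      }
      sig <- p <= p_cutoff &&
        wc$P >= min_phased_frac * (wc$P + wc$U)
      if (sig || return_all) {
        out[[length(out) + 1]] <- data.frame(
          chrom = cl$chrom[1], cluster_id = cid, window_start = ws,
          phase_len = D, N = wc$N, m = wc$m, n = wc$n, k = wc$k,
          p_value = p, phased_ab = wc$P, unphased_ab = wc$U,
          phasing_score = phasing_score(wc$P, wc$U, wc$k),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove repeat-derived 24-nt phasing windows
#'
#' Windows whose contributing 24-nt reads have an abundance-weighted mean
#' placement count above `rep_cap`, or where more than `over_frac` of the
#' abundance comes from reads with more than `multimap_cap` placements, are
#' discarded; such windows are hc-siRNA territory, not phased siRNA loci.
#' The full alignment set (no multi-mapping cap) is consulted.
#'
#' @param windows Window table from [scan_registers()] with `phase_len` 24.
#' @param aln The complete `srna_alignments` data frame.
#' @param rep_cap Maximum weighted mean `n_hits` (default 5).
#' @param over_frac Maximum abundance fraction from over-mapped reads.
#' @param multimap_cap `n_hits` above which a read counts as over-mapped.
#' @param cycles Window length in cycles (must match the scan).
#' @return The filtered window table.
#' @export
filter_24phas_repeats <- function(windows, aln, rep_cap = 5,
                                  over_frac = 0.5, multimap_cap = 10,
                                  cycles = 10) {
  if (nrow(windows) == 0) return(windows)
  stopifnot(all(windows$phase_len == 24))
  keep <- vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    span <- c(w$window_start, w$window_start + w$phase_len * cycles)
    sub <- aln[aln$chrom == w$chrom & aln$length == w$phase_len &
                 aln$start < span[2] & aln$end > span[1], , drop = FALSE]
    if (nrow(sub) == 0) return(TRUE)
    tot <- sum(sub$weight)
    wmean <- sum(sub$weight * sub$n_hits) / tot
    fover <- sum(sub$weight[sub$n_hits > multimap_cap]) / tot
    wmean <= rep_cap && fover <= over_frac
  }, logical(1))
  windows[keep, , drop = FALSE]
}

#' Merge significant phasing windows into PHAS loci
#'
#' Windows sharing a register (window start mod `D`, +/- 1 nt tolerance)
#' and lying within `merge_gap` of each other are merged. A locus requires
#' at least `min_cycles` occupied phased positions in its best window run.
#'
#' @param windows Significant windows from [scan_registers()].
#' @param D Phase length.
#' @param cycles Window length in cycles (must match the scan).
#' @param merge_gap Maximum gap between member window starts (default 2 D).
#' @param min_cycles Minimum occupied cycles for a reportable locus.
#' @return PHAS locus table: `chrom`, `start`, `end`, `strand` ("."),
#'   `phase_len`, `best_p`, `max_phasing_score`, `register`, `k_max`,
#'   `n_windows`.
#' @export
merge_windows_to_loci <- function(windows, D, cycles = 10,
                                  merge_gap = 2 * D, min_cycles = 4) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      phase_len = integer(0), best_p = numeric(0),
                      max_phasing_score = numeric(0), register = integer(0),
                      k_max = integer(0), n_windows = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  w <- windows[order(windows$chrom, windows$window_start), , drop = FALSE]
  reg_diff <- function(a, b) {
    d <- (a - b) %% D
    pmin(d, D - d)
  }
  grp <- integer(nrow(w))
  g <- 1L
  grp[1] <- g
  for (i in seq_len(nrow(w))[-1]) {
    same <- w$chrom[i] == w$chrom[i - 1] &&
      (w$window_start[i] - w$window_start[i - 1]) <= merge_gap &&
      reg_diff(w$window_start[i], w$window_start[i - 1]) <= 1
    if (!same) g <- g + 1L
    grp[i] <- g
  }
  loci <- lapply(split(seq_len(nrow(w)), grp), function(ix) {
    s <- w[ix, , drop = FALSE]
    best <- which.min(s$p_value)
    data.frame(chrom = s$chrom[1],
               start = min(s$window_start),
               end = max(s$window_start) + D * cycles,
               strand = ".",
               phase_len = D,
               best_p = min(s$p_value),
               max_phasing_score = max(s$phasing_score),
               register = s$window_start[best] %% D,
               k_max = max(s$k),
               n_windows = nrow(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, loci)
  res <- res[res$k_max >= min_cycles, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate PHAS loci of one phase length
#'
#' Runs the register scan, the 24-nt repetitiveness filter when applicable,
#' and window merging; adds hit-normalized locus abundance and locus ids.
#'
#' @param aln Clustered `srna_alignments`.
#' @param D Phase length (21 or 24).
#' @param params Parameter list; see [srna_config()] element `phas`.
#' @return Locus table with `locus_class` `PHAS21`/`PHAS24` and `locus_id`.
#' @export
annotate_phas <- function(aln, D, params = srna_config()$phas) {
  if (is.na(params$merge_gap)) params$merge_gap <- 2 * D
  wins <- scan_registers(aln, D, cycles = params$cycles, step = params$step,
                         max_hits_phase = params$max_hits_phase,
                         p_cutoff = params$p_cutoff,
                         len_tol = params$len_tol,
                         min_phased_frac = params$min_phased_frac)
  if (D == 24) {
    wins <- filter_24phas_repeats(wins, aln, rep_cap = params$rep_cap,
                                  over_frac = params$over_frac,
                                  multimap_cap = params$max_hits_phase,
                                  cycles = params$cycles)
  }
  loci <- merge_windows_to_loci(wins, D, cycles = params$cycles,
                                merge_gap = params$merge_gap,
                                min_cycles = params$min_cycles)
  if (nrow(loci) == 0) {
    loci$total_abundance <- numeric(0)
    loci$locus_class <- character(0)
    loci$locus_id <- character(0)
    return(loci)
  }
  loci$total_abundance <- vapply(seq_len(nrow(loci)), function(i) {
    sub <- aln[aln$chrom == loci$chrom[i] & aln$length == D &
                 aln$start < loci$end[i] & aln$end > loci$start[i], ,
               drop = FALSE]
    sum(sub$weight)
  }, numeric(1))
  loci$locus_class <- paste0("PHAS", D)
  loci$locus_id <- sprintf("%s_%05d", loci$locus_class, seq_len(nrow(loci)))
  loci
}
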