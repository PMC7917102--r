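#' Full default run configuration
#'
#' Central registry of every tunable threshold with its default. Pass a
#' nested list of overrides; unknown keys are an error. A run's resolved
#' configuration is always serialized next to its outputs.
#'
#' @param overrides Nested named list of values to override.
#' @return The resolved configuration list.
#' @export
srna_config <- function(overrides = list()) {
  cfg <- list(
    io = list(min_len = 18, max_len = 26),
    mapping = list(max_hits = 50, max_gap = 200, min_abundance = 10),
    mirna = list(strict = TRUE, top_anchors = 3, max_precursor_len = 300,
                 max_mismatch = 5, max_asym_bulge = 3, overhang_tol = 1,
                 precision_min = 0.75, max_mature_hits = 20),
    phas = list(cycles = 10, step = 1, p_cutoff = 1e-3, len_tol = 0,
                max_hits_phase = 10, min_cycles = 4, merge_gap = NA,
                min_phased_frac = 0.5, rep_cap = 5, over_frac = 0.5),
    hcsirna = list(f_min = 0.75, r_min = 2, a_min = 10, min_locus_len = 50),
    tas3 = list(score_cutoff = 6, flank = 200, mm_max = 3,
                mir390 = NULL, tasiarf_motif = NULL))
  merge_into <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", path, nm)
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]],
                                 paste0(path, nm, "$"))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_into(cfg, overrides)
}

phas_params_for <- function(cfg, D) {
  p <- cfg$phas
  if (is.na(p$merge_gap)) p$merge_gap <- 2 * D
  p
}

#' Run the complete annotation bundle
#'
#' Executes mapping, MIRNA calling, 21- and 24-nt PHAS calling (with the
#' repetitiveness filter for the 24-nt class), hc-siRNA calling, TAS3
#' identification among the 21-PHAS loci, and final class-precedence
#' resolution (MIRNA > PHAS > hc-siRNA); writes GFF3/BED/TSV per class, a
#' locus-count summary JSON, the resolved configuration, and a per-stage
#' log. Reruns on identical inputs produce byte-identical annotation
#' outputs.
#'
#' @param genome A genome `DNAStringSet` (from [read_genome()]) or a FASTA
#'   path.
#' @param reads A merged `srna_reads` set, a list of per-library collapsed
#'   FASTA paths, or a single path.
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output.
#' @param config Configuration from [srna_config()].
#' @return List with the per-class locus tables (`mirna`, `phas21`,
#'   `phas24`, `hcsirna`, `tas3`, `tasiarf`, `combined`), the `summary`
#'   counts, and the resolved `config`.
#' @export
run_annotation <- function(genome, reads, out_dir = NULL,
                           config = srna_config()) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome file not found: ", genome)
    genome <- read_genome(genome)
  }
  if (is.character(reads)) {
    paths <- reads
    if (!all(file.exists(paths)))
      stop("read library file not found: ",
           paste(paths[!file.exists(paths)], collapse = ", "))
    sets <- lapply(seq_along(paths), function(i)
      read_collapsed_fasta(paths[i], paste0("lib", i)))
    reads <- merge_read_sets(sets)
  }
  reads <- reads[reads$length >= config$io$min_len &
                   reads$length <= config$io$max_len, , drop = FALSE]
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note(name, ": done in ",
         format(round(as.numeric(Sys.time() - s, units = "secs"), 2)), " s")
    r
  }
  note("input: ", nrow(reads), " unique reads, ",
       sum(reads$total_count), " total counts, ",
       length(lib_cols(reads)), " libraries")
  idx <- build_index(genome)
  aln <- stage("mapping", map_reads(reads, idx,
                                    max_hits = config$mapping$max_hits))
  note("mapping: ", nrow(aln), " placements, ",
       length(attr(aln, "unmapped")), " unmapped reads")
  clust <- stage("clustering",
                 cluster_alignments(aln, max_gap = config$mapping$max_gap,
                                    min_abundance =
                                      config$mapping$min_abundance))
  note("clustering: ", nrow(clust$clusters), " clusters")
  mirna <- stage("mirna", call_mirna(clust, genome, reads, config$mirna))
  note("mirna: ", nrow(mirna$loci), " accepted loci")
  phas21 <- stage("phas21",
                  annotate_phas(clust$alignments, 21,
                                phas_params_for(config, 21)))
  phas24 <- stage("phas24",
                  annotate_phas(clust$alignments, 24,
                                phas_params_for(config, 24)))
  note("phas: ", nrow(phas21), " 21-PHAS, ", nrow(phas24), " 24-PHAS loci")
  hcs <- stage("hcsirna", call_hcsirna(clust, config$hcsirna))
  tas3 <- stage("tas3",
                find_tas3(phas21, genome,
                          mir390 = config$tas3$mir390,
                          tasiarf_motif = config$tas3$tasiarf_motif,
                          score_cutoff = config$tas3$score_cutoff,
                          flank = config$tas3$flank,
                          mm_max = config$tas3$mm_max))
  note("tas3: ", nrow(tas3$loci), " loci")
  final <- stage("classify",
                 classify_overlaps(mirna$loci, phas21, phas24, hcs))
  summary <- list(MIRNA = nrow(final$mirna),
                  PHAS21 = nrow(final$phas21),
                  PHAS24 = nrow(final$phas24),
                  HCSIRNA = nrow(final$hcsirna),
                  TAS3 = nrow(tas3$loci))
  note("total: ", format(round(as.numeric(Sys.time() - t0,
                                          units = "secs"), 2)), " s")
  res <- list(mirna = final$mirna, phas21 = final$phas21,
              phas24 = final$phas24, hcsirna = final$hcsirna,
              tas3 = tas3$loci, tasiarf = tas3$tasiarf,
              combined = final$combined, summary = summary,
              config = config, log = log)
  if (!is.null(out_dir)) write_annotation_bundle(res, out_dir, genome)
  invisible(res)
}

#' Write an annotation bundle to disk
#'
#' @param res Result of [run_annotation()].
#' @param out_dir Output directory.
#' @param genome Optional genome for sequence lengths in the track files.
#' @export
write_annotation_bundle <- function(res, out_dir, genome = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  mir_gff <- res$mirna
  mir_gff$structure <- NULL  # dot-bracket goes in the per-locus text file
  write_gff3(mir_gff, p("mirna.gff3"), genome)
  write_bed(res$mirna, p("mirna.bed"), genome)
  write_locus_tsv(res$mirna, p("mirna.tsv"))
  if (nrow(res$mirna) > 0) {
    lines <- unlist(lapply(seq_len(nrow(res$mirna)), function(i) {
      r <- res$mirna[i, ]
      c(paste0(">", r$locus_id, " ", r$chrom, ":", r$start, "-", r$end,
               r$strand), r$mature_seq, r$structure)
    }))
    writeLines(lines, p("mirna_structures.txt"))
  } else writeLines(character(0), p("mirna_structures.txt"))
  for (cls in c("phas21", "phas24", "hcsirna")) {
    write_gff3(res[[cls]], p(paste0(cls, ".gff3")), genome)
    write_bed(res[[cls]], p(paste0(cls, ".bed")), genome)
    write_locus_tsv(res[[cls]], p(paste0(cls, ".tsv")))
  }
  write_locus_tsv(res$tas3, p("tas3.tsv"))
  write_locus_tsv(res$tasiarf, p("tasiarf.tsv"))
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(res$config, p("config.yaml"))
  writeLines(res$log, p("run.log"))
  invisible(out_dir)
}
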