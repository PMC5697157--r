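#' Build and validate a discovery pipeline configuration
#'
#' Collects every input and threshold of the discovery workflow in one
#' validated list. Inputs may be file paths (FASTA/FASTQ/TSV) or the
#' corresponding in-memory objects. Unknown keys are rejected.
#'
#' @param reads small RNA reads: FASTQ/FASTA path or data.frame with
#'   `read_id`, `sequence`.
#' @param scaffolds genomic scaffolds/ESTs: FASTA path or named vector.
#' @param known known mature miRNA reference: FASTA path or named vector.
#' @param contaminants contaminant ncRNA reference: FASTA path or named
#'   vector (`NULL` skips the filter).
#' @param transcripts transcriptome for target prediction (optional).
#' @param annotation term annotation table for enrichment (optional).
#' @param adapter 3' adapter to trim (optional).
#' @param min_len minimum read length after trimming (default 15).
#' @param size_lo,size_hi tag size-selection window (default 17–25).
#' @param ncrna_max_mismatch contaminant match tolerance (default 0).
#' @param homology_max_mismatch homology mismatch bound (default 3).
#' @param homology_max_shift homology terminal shift bound (default 2).
#' @param flank,max_precursor_len precursor window parameters.
#' @param criteria hairpin criteria thresholds, see [criteria_config()].
#' @param target_cutoff duplex score cutoff (default 4.0).
#' @param alpha enrichment significance threshold (default 0.05).
#' @param min_tag_count smallest tag count entering discovery (default 1).
#' @param max_loci_per_tag genomic loci evaluated per tag (default 20).
#' @param backend folding backend, see [fold_rna()].
#' @param seed integer seed recorded in the report.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, scaffolds, known, contaminants = NULL,
                            transcripts = NULL, annotation = NULL,
                            adapter = NULL, min_len = 15L, size_lo = 17L,
                            size_hi = 25L, ncrna_max_mismatch = 0L,
                            homology_max_mismatch = 3L,
                            homology_max_shift = 2L, flank = 200L,
                            max_precursor_len = 300L,
                            criteria = criteria_config(),
                            target_cutoff = 4.0, alpha = 0.05,
                            min_tag_count = 1L, max_loci_per_tag = 20L,
                            backend = "auto", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_len >= 1L, cfg$size_lo <= cfg$size_hi,
            cfg$homology_max_mismatch >= 0L, cfg$flank >= 20L,
            cfg$target_cutoff >= 0, cfg$alpha > 0, cfg$alpha <= 1)
  extra <- setdiff(names(criteria), names(criteria_config()))
  if (length(extra)) {
    stop("pipeline_config: unknown criteria keys: ",
         paste(extra, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

load_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x)
  else x
}

load_reads <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.(fq|fastq)$", x, ignore.case = TRUE)) {
      read_fastq(x)
    } else {
      seqs <- read_fasta(x)
      data.frame(read_id = names(seqs), sequence = unname(seqs),
                 stringsAsFactors = FALSE)
    }
  } else x
}

#' Run the full miRNA discovery workflow
#'
#' Executes, in order: read cleaning, tag collapsing, length distribution,
#' contaminant removal, size selection, known-miRNA homology, genomic
#' hairpin evaluation under the twelve criteria, group classification
#' (1/2a/2b/3), family census, and — when the inputs are provided —
#' target prediction and term enrichment. Every stage records its
#' input/output counts in a conservation ledger.
#'
#' @param config `pipeline_config` object.
#' @return list of class `discovery_report`: `calls` (classified miRNA
#'   calls with hairpin columns), `census`, `length_dist`, `stage_counts`,
#'   `targets`, `enrichment`, `config_used`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reads <- load_reads(config$reads)
  if (is.null(reads) || nrow(reads) == 0L) {
    stop("run_discovery: preprocess: empty reads input")
  }
  scaffolds <- load_seqs(config$scaffolds)
  known <- load_seqs(config$known)
  contaminants <- load_seqs(config$contaminants)

  stage <- list()
  cleaned <- clean_reads(reads, adapter = config$adapter,
                         min_len = config$min_len)
  stage$raw_reads <- nrow(reads)
  stage$clean_reads <- nrow(cleaned)
  tags <- collapse_reads(cleaned)
  stage$unique_tags <- nrow(tags)
  ldist <- length_distribution(tags)
  if (!is.null(contaminants) && length(contaminants)) {
    flt <- filter_ncrna(tags, contaminants,
                        max_mismatch = config$ncrna_max_mismatch)
    tags <- flt$kept
    stage$ncrna_removed_tags <- nrow(flt$removed)
  } else {
    stage$ncrna_removed_tags <- 0L
  }
  stage$tags_after_ncrna <- nrow(tags)
  tags <- size_select(tags, lo = config$size_lo, hi = config$size_hi)
  stage$tags_after_size <- nrow(tags)
  tags <- tags[tags$count >= config$min_tag_count, , drop = FALSE]
  stage$tags_entering_discovery <- nrow(tags)

  calls <- discover_mirnas(tags, scaffolds, known, config)
  stage$calls_total <- nrow(calls)
  for (g in c("1", "2a", "2b", "3")) {
    stage[[paste0("calls_group_", g)]] <- sum(calls$group %in% g)
  }

  census <- family_census(calls[!is.na(calls$family), , drop = FALSE])
  stage$conserved_families <- nrow(census)

  targets <- NULL
  enrichment_res <- NULL
  if (!is.null(config$transcripts)) {
    transcripts <- load_seqs(config$transcripts)
    mat <- calls[!is.na(calls$group), , drop = FALSE]
    tg <- list()
    for (i in seq_len(nrow(mat))) {
      hit <- scan_transcriptome(mat$sequence[i], transcripts,
                                cutoff = config$target_cutoff)
      if (nrow(hit)) {
        hit$mirna <- mat$mirna_id[i]
        tg[[length(tg) + 1L]] <- hit
      }
    }
    targets <- if (length(tg)) do.call(rbind, tg) else NULL
    stage$predicted_targets <- if (is.null(targets)) 0L else nrow(targets)
    if (!is.null(config$annotation) && !is.null(targets)) {
      ann <- if (is.character(config$annotation)) read_tsv(config$annotation)
      else config$annotation
      enrichment_res <- enrich(unique(targets$transcript_id), ann,
                               alpha = config$alpha)
    }
  }

  out <- list(calls = calls, census = census, length_dist = ldist,
              stage_counts = stage, targets = targets,
              enrichment = enrichment_res,
              config_used = config)
  class(out) <- "discovery_report"
  out
}

# Core discovery: homology + hairpin evaluation + classification for a
# preprocessed tag set.  All candidate windows are folded in one batch.
discover_mirnas <- function(tags, scaffolds, known, config) {
  empty <- data.frame(
    mirna_id = character(), sequence = character(), count = integer(),
    group = character(), family = character(), best_known = character(),
    mismatches = integer(), sequence_id = character(), strand = character(),
    precursor_start = integer(), precursor_end = integer(),
    precursor_seq = character(), structure = character(), mfe = numeric(),
    amfe = numeric(), mfei = numeric(), mature_start = integer(),
    mature_end = integer(), arm = character(), mfei_high = logical(),
    stringsAsFactors = FALSE
  )
  if (nrow(tags) == 0L) return(empty)
  n <- nrow(tags)
  homology <- vector("list", n)
  loci <- vector("list", n)
  windows <- list()
  for (i in seq_len(n)) {
    hits <- match_known(tags$sequence[i], known,
                        max_mismatch = config$homology_max_mismatch,
                        max_shift = config$homology_max_shift)
    homology[i] <- list(assign_family(hits))  # keep NULL slots
    loc <- locate_tag(tags$sequence[i], scaffolds)
    if (nrow(loc) > config$max_loci_per_tag) {
      loc <- loc[seq_len(config$max_loci_per_tag), , drop = FALSE]
    }
    loci[[i]] <- loc
    for (li in seq_len(nrow(loc))) {
      win <- extract_windows(loc[li, , drop = FALSE], scaffolds,
                             flank = config$flank,
                             max_len = config$max_precursor_len)
      win$tag_index <- i
      windows[[length(windows) + 1L]] <- win
    }
  }
  wtab <- if (length(windows)) do.call(rbind, windows) else NULL
  ctab <- NULL
  if (!is.null(wtab)) {
    # round 1: fold each distinct window once, trim to stem-loop candidates
    uniq <- unique(wtab$seq)
    folded_u <- fold_rna(uniq, backend = config$backend)
    folded <- folded_u[match(wtab$seq, uniq), , drop = FALSE]
    cands <- trim_candidates(wtab, folded)
    if (nrow(cands)) {
      # round 2: fold each distinct trimmed candidate precursor
      uniq2 <- unique(cands$precursor_seq)
      refolded_u <- fold_rna(uniq2, backend = config$backend)
      ctab <- list(cands = cands,
                   refolded = refolded_u[match(cands$precursor_seq, uniq2),
                                         , drop = FALSE])
    }
  }
  calls <- list()
  novel_k <- 0L
  ord <- order(-tags$count, tags$sequence)
  for (i in ord) {
    has_locus <- nrow(loci[[i]]) > 0L
    best <- NULL
    if (!is.null(ctab)) {
      for (w in which(ctab$cands$tag_index == i)) {
        cand <- candidate_record(ctab$cands[w, , drop = FALSE],
                                 ctab$refolded[w, , drop = FALSE],
                                 config$criteria)
        if (!is.null(cand) && better_candidate(cand, best)) best <- cand
      }
    }
    cls <- classify_tag(tags[i, , drop = FALSE], homology[[i]], best,
                        has_locus)
    if (is.na(cls$group)) next
    if (cls$group == "3") {
      novel_k <- novel_k + 1L
      mirna_id <- sprintf("csn-miRn%d", novel_k)
    } else {
      mirna_id <- sprintf("csn-%s_%s", cls$family, substr(tags$sequence[i],
                                                          1L, 6L))
    }
    row <- data.frame(
      mirna_id = mirna_id, sequence = cls$sequence, count = cls$count,
      group = cls$group, family = cls$family, best_known = cls$best_known,
      mismatches = cls$mismatches,
      sequence_id = NA_character_, strand = NA_character_,
      precursor_start = NA_integer_, precursor_end = NA_integer_,
      precursor_seq = NA_character_, structure = NA_character_,
      mfe = NA_real_, amfe = NA_real_, mfei = NA_real_,
      mature_start = NA_integer_, mature_end = NA_integer_,
      arm = NA_character_, mfei_high = NA,
      stringsAsFactors = FALSE
    )
    if (!is.null(best)) {
      cd <- best$candidate
      row$sequence_id <- cd$sequence_id
      row$strand <- cd$strand
      row$precursor_start <- cd$precursor_start
      row$precursor_end <- cd$precursor_end
      row$precursor_seq <- cd$precursor_seq
      row$structure <- best$structure
      row$mfe <- best$mfe
      row$amfe <- best$metrics$amfe
      row$mfei <- best$metrics$mfei
      row$mature_start <- cd$mature_start
      row$mature_end <- cd$mature_end
      row$arm <- best$metrics$arm
      row$mfei_high <- best$criteria$mfei_high
    }
    calls[[length(calls) + 1L]] <- row
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Write a discovery report bundle to disk
#'
#' Emits calls TSV, family census TSV, length distribution TSV, precursor
#' FASTA, a GFF3 of precursor and mature loci, and a versioned JSON
#' summary carrying stage counts and every configuration value used.
#'
#' @param report `discovery_report` from [run_discovery()].
#' @param out_dir output directory (created if absent).
#' @return invisible named list of written file paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "discovery_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    calls = file.path(out_dir, "mirna_calls.tsv"),
    census = file.path(out_dir, "family_census.tsv"),
    length_dist = file.path(out_dir, "length_distribution.tsv"),
    precursors = file.path(out_dir, "precursors.fa"),
    gff = file.path(out_dir, "mirna_loci.gff3"),
    summary = file.path(out_dir, "summary.json")
  )
  write_tsv(report$calls, paths$calls)
  write_tsv(report$census, paths$census)
  write_tsv(report$length_dist, paths$length_dist)
  with_prec <- report$calls[!is.na(report$calls$precursor_seq), ,
                            drop = FALSE]
  prec <- setNames(as_rna(with_prec$precursor_seq), with_prec$mirna_id)
  write_fasta(prec, paths$precursors)
  write_gff3(with_prec, paths$gff)
  cfg <- report$config_used
  cfg_json <- lapply(unclass(cfg), function(x) {
    if (is.character(x) && length(x) == 1L) x
    else if (is.numeric(x) || is.logical(x) || is.list(x)) x
    else sprintf("<in-memory %s>", class(x)[1L])
  })
  summary <- list(
    schema_version = "1.0",
    stage_counts = report$stage_counts,
    config = cfg_json
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# GFF3 of precursor (miRNA_primary_transcript) and mature (miRNA) loci.
write_gff3 <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("##gff-version 3\n", file = con)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    cat(sprintf("%s\tmirforge\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s\n",
                r$sequence_id, r$precursor_start, r$precursor_end,
                r$strand, r$mirna_id), file = con)
    # mature coordinates back to forward-strand genomic space
    if (r$strand == "+") {
      ms <- r$precursor_start + r$mature_start - 1L
      me <- r$precursor_start + r$mature_end - 1L
    } else {
      ms <- r$precursor_end - r$mature_end + 1L
      me <- r$precursor_end - r$mature_start + 1L
    }
    cat(sprintf("%s\tmirforge\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_mature;Parent=%s\n",
                r$sequence_id, ms, me, r$strand, r$mirna_id, r$mirna_id),
        file = con)
  }
  invisible(path)
}

#' Compare a discovery report against a synthetic truth table
#'
#' A planted locus counts as recovered when some call's precursor interval
#' overlaps the planted precursor on the same scaffold and the call's
#' group matches expectation (group 1 for loci emitted into the known
#' reference, group 3 otherwise). Calls whose precursor overlaps no
#' planted locus are false calls; the scaffolds they fall on are reported
#' so background-only scaffolds can be audited.
#'
#' @param report `discovery_report` from [run_discovery()].
#' @param truth truth table from [make_genome()] / [make_known_reference()].
#' @return list: `n_loci`, `n_recovered`, `recovery_fraction`,
#'   `recovered` (per-locus logical data.frame), `false_calls` (calls not
#'   overlapping any planted locus), `false_call_scaffolds`.
#' @export
evaluate_recovery <- function(report, truth) {
  calls <- report$calls
  located <- calls[!is.na(calls$precursor_start), , drop = FALSE]
  hit_locus <- rep(NA_character_, nrow(located))
  for (i in seq_len(nrow(located))) {
    ov <- truth$scaffold_id == located$sequence_id[i] &
      truth$precursor_start <= located$precursor_end[i] &
      truth$precursor_end >= located$precursor_start[i]
    if (any(ov)) hit_locus[i] <- truth$locus_id[which(ov)[1L]]
  }
  rec <- vapply(seq_len(nrow(truth)), function(j) {
    expected <- if (truth$is_conserved[j]) "1" else "3"
    any(hit_locus == truth$locus_id[j] & located$group == expected,
        na.rm = TRUE)
  }, TRUE)
  false_calls <- located[is.na(hit_locus), , drop = FALSE]
  list(
    n_loci = nrow(truth), n_recovered = sum(rec),
    recovery_fraction = if (nrow(truth)) sum(rec) / nrow(truth) else NA_real_,
    recovered = data.frame(locus_id = truth$locus_id, recovered = rec,
                           stringsAsFactors = FALSE),
    false_calls = false_calls,
    false_call_scaffolds = unique(false_calls$sequence_id)
  )
}

#' @export
print.discovery_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("miRNA discovery report\n")
  cat(sprintf("  raw reads: %d; clean: %d; unique tags: %d\n",
              sc$raw_reads, sc$clean_reads, sc$unique_tags))
  cat(sprintf("  after ncRNA filter: %d tags; after size selection: %d\n",
              sc$tags_after_ncrna, sc$tags_after_size))
  cat(sprintf("  calls: %d (group 1: %d, 2a: %d, 2b: %d, 3: %d); families: %d\n",
              sc$calls_total, sc$calls_group_1, sc$calls_group_2a,
              sc$calls_group_2b, sc$calls_group_3, sc$conserved_families))
  invisible(x)
}
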