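#' Synthetic ground-truth data for miRNA discovery
#'
#' The generator plants hairpin precursors with known mature miRNAs into
#' random scaffolds, samples small RNA reads from the mature arms, emits a
#' "foreign species" known-miRNA reference, and builds expression tables
#' with planted fold changes — so every downstream stage of the discovery
#' workflow can be validated against a complete truth table without any
#' external download.
#'
#' @name synthetic
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Build one hairpin precursor: 5' arm + loop + modified reverse complement
# of the arm.  A fraction of opposite-strand positions is converted to G:U
# wobbles, and a smaller fraction to outright mismatches, while keeping the
# stem >= 85% Watson-Crick so any reasonable MFE folder recovers it.
make_hairpin_seq <- function(stem_len, loop_len, gu_frac = 0.08,
                             mismatch_frac = 0.04, gc = 0.5) {
  arm <- strsplit(random_dna(stem_len, gc), "")[[1]]
  opp <- rev(chartr("ACGT", "TGCA", arm))       # perfect complement, reversed
  opp <- strsplit(paste(opp, collapse = ""), "")[[1]]
  # opp[k] pairs with arm[stem_len - k + 1]
  n_mod <- min(floor(stem_len * (gu_frac + mismatch_frac)),
               floor(stem_len * 0.15))
  if (n_mod > 0) {
    pos <- sample(seq_len(stem_len), n_mod)
    n_gu <- round(n_mod * gu_frac / (gu_frac + mismatch_frac))
    for (idx in seq_along(pos)) {
      k <- pos[idx]
      a <- arm[stem_len - k + 1]
      if (idx <= n_gu) {
        # convert to wobble where chemistry allows (G·U or U·G)
        if (a == "G") opp[k] <- "T" else if (a == "T") opp[k] <- "G"
      } else {
        comp <- chartr("ACGT", "TGCA", a)
        choices <- setdiff(c("A", "C", "G", "T"),
                           c(comp, if (a == "G") "T", if (a == "T") "G"))
        opp[k] <- sample(choices, 1L)
      }
    }
  }
  loop <- random_dna(loop_len, gc = 0.3) # AU-rich loop folds as a loop
  list(arm = paste(arm, collapse = ""),
       loop = loop,
       seq = paste0(paste(arm, collapse = ""), loop,
                    paste(opp, collapse = "")))
}

#' Generate synthetic scaffolds with planted miRNA hairpins
#'
#' Background sequence is i.i.d. uniform ACGT, which at desk scale makes
#' accidental long hairpins vanishingly unlikely. Each planted precursor is
#' `mature_arm + loop + reverse_complement(mature_arm)` with a small
#' fraction of wobble/mismatch positions, embedded at a non-overlapping
#' random position. When `background_scaffolds > 0`, that many trailing
#' scaffolds receive no hairpins, providing negative controls.
#'
#' @param seed integer RNG seed.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold (nt).
#' @param n_hairpins number of precursors to plant.
#' @param stem_len stem arm length (nt, >= 20).
#' @param loop_len terminal loop length (nt, >= 3).
#' @param gu_frac fraction of stem positions converted to G:U wobbles.
#' @param mismatch_frac fraction converted to mismatches.
#' @param mature_len_probs named numeric vector of mature-length
#'   probabilities (lengths as names), emulating the 24-nt-dominant,
#'   21-nt-secondary size distribution of plant small RNA libraries.
#' @param background_scaffolds trailing scaffolds guaranteed hairpin-free.
#' @return list with `scaffolds` (named character vector) and `truth`
#'   (data.frame: locus_id, scaffold_id, precursor_start, precursor_end,
#'   precursor_seq, mature_start, mature_end, mature_seq, arm,
#'   is_conserved, planted_read_count).
#' @export
make_genome <- function(seed, n_scaffolds = 20L, scaffold_length = 50000L,
                        n_hairpins = 20L, stem_len = 24L, loop_len = 8L,
                        gu_frac = 0.08, mismatch_frac = 0.04,
                        mature_len_probs = c("24" = 0.55, "21" = 0.25,
                                             "22" = 0.10, "23" = 0.10),
                        background_scaffolds = min(2L, n_scaffolds - 1L)) {
  stopifnot(stem_len >= 20L, loop_len >= 3L,
            2L * stem_len + loop_len <= scaffold_length)
  with_seed(seed, {
    prec_len <- 2L * stem_len + loop_len
    host <- max(1L, n_scaffolds - max(0L, background_scaffolds))
    if (n_hairpins > 0) {
      assign_to <- sort(sample(seq_len(host), n_hairpins, replace = TRUE))
      per_scaffold <- tabulate(assign_to, nbins = n_scaffolds)
      if (any(per_scaffold * (prec_len + 20L) > scaffold_length)) {
        stop("make_genome: hairpins do not fit without overlap")
      }
    } else {
      per_scaffold <- integer(n_scaffolds)
    }
    scaffolds <- character(n_scaffolds)
    names(scaffolds) <- sprintf("scaffold%03d", seq_len(n_scaffolds))
    truth <- list()
    locus_k <- 0L
    for (s in seq_len(n_scaffolds)) {
      seq_s <- random_dna(scaffold_length)
      m <- per_scaffold[s]
      if (m > 0) {
        # non-overlapping placement with a 10-nt guard between precursors
        slack <- scaffold_length - m * prec_len - (m + 1L) * 10L
        if (slack < 0) stop("make_genome: hairpins do not fit without overlap")
        g <- runif(m + 1L)
        gaps <- floor(g / sum(g) * slack)
        starts <- integer(m)
        cur <- 1L
        for (i in seq_len(m)) {
          cur <- cur + 10L + gaps[i]
          starts[i] <- cur
          cur <- cur + prec_len
        }
        for (i in seq_len(m)) {
          locus_k <- locus_k + 1L
          hp <- make_hairpin_seq(stem_len, loop_len, gu_frac, mismatch_frac)
          st <- starts[i]
          en <- st + prec_len - 1L
          substr(seq_s, st, en) <- hp$seq
          mlen <- as.integer(sample(names(mature_len_probs), 1L,
                                    prob = mature_len_probs))
          mlen <- min(mlen, stem_len)
          arm <- sample(c("5p", "3p"), 1L)
          off <- sample.int(stem_len - mlen + 1L, 1L) - 1L
          if (arm == "5p") {
            ms <- 1L + off
          } else {
            ms <- stem_len + loop_len + 1L + off
          }
          me <- ms + mlen - 1L
          truth[[locus_k]] <- data.frame(
            locus_id = sprintf("locus%03d", locus_k),
            scaffold_id = names(scaffolds)[s],
            precursor_start = st, precursor_end = en,
            precursor_seq = hp$seq,
            mature_start = ms, mature_end = me,
            mature_seq = substr(hp$seq, ms, me),
            arm = arm, is_conserved = FALSE,
            planted_read_count = 0L,
            stringsAsFactors = FALSE
          )
        }
      }
      scaffolds[s] <- seq_s
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      locus_id = character(), scaffold_id = character(),
      precursor_start = integer(), precursor_end = integer(),
      precursor_seq = character(), mature_start = integer(),
      mature_end = integer(), mature_seq = character(), arm = character(),
      is_conserved = logical(), planted_read_count = integer(),
      stringsAsFactors = FALSE
    )
    list(scaffolds = scaffolds, truth = truth)
  })
}

#' Sample synthetic small RNA reads from planted loci
#'
#' Reads are drawn from the mature arm of each planted precursor with
#' 0–2 nt of end jitter (isomiR-style end variation), optional contaminant
#' reads drawn as substrings of a contaminant ncRNA reference, and i.i.d.
#' per-base substitution errors.
#'
#' @param truth truth table from [make_genome()] (needs `precursor_seq`,
#'   `mature_start`, `mature_end`).
#' @param depth_per_locus planted reads per locus.
#' @param contaminant_fraction fraction of the final library drawn from
#'   `contaminants`.
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed.
#' @param contaminants named character vector of contaminant ncRNA
#'   sequences (required when `contaminant_fraction > 0`).
#' @param jitter_probs probabilities of 0/1/2 nt jitter at each read end.
#' @return data.frame with `read_id`, `sequence`, `origin` (`locus_id` or
#'   `"contaminant"`).
#' @export
make_reads <- function(truth, depth_per_locus = 50L,
                       contaminant_fraction = 0, error_rate = 0,
                       seed = 1L, contaminants = NULL,
                       jitter_probs = c(0.7, 0.2, 0.1)) {
  stopifnot(contaminant_fraction >= 0, contaminant_fraction <= 1)
  if (contaminant_fraction > 0 && is.null(contaminants)) {
    stop("make_reads: contaminants required when contaminant_fraction > 0")
  }
  with_seed(seed, {
    n_loci <- nrow(truth)
    reads <- list()
    if (n_loci > 0 && depth_per_locus > 0 && contaminant_fraction < 1) {
      for (i in seq_len(n_loci)) {
        prec <- truth$precursor_seq[i]
        ms <- truth$mature_start[i]
        me <- truth$mature_end[i]
        j5 <- sample(0:2, depth_per_locus, replace = TRUE,
                     prob = jitter_probs) *
          sample(c(-1L, 1L), depth_per_locus, replace = TRUE)
        j3 <- sample(0:2, depth_per_locus, replace = TRUE,
                     prob = jitter_probs) *
          sample(c(-1L, 1L), depth_per_locus, replace = TRUE)
        st <- pmax(1L, ms + j5)
        en <- pmin(nchar(prec), me + j3)
        reads[[i]] <- data.frame(
          sequence = substr(rep(prec, depth_per_locus), st, en),
          origin = truth$locus_id[i],
          stringsAsFactors = FALSE
        )
      }
    }
    planted <- if (length(reads)) do.call(rbind, reads) else
      data.frame(sequence = character(), origin = character(),
                 stringsAsFactors = FALSE)
    n_planted <- nrow(planted)
    n_contam <- if (contaminant_fraction >= 1) {
      max(n_loci, 1L) * depth_per_locus
    } else if (contaminant_fraction > 0) {
      round(n_planted * contaminant_fraction / (1 - contaminant_fraction))
    } else 0L
    if (n_contam > 0) {
      src <- sample(seq_along(contaminants), n_contam, replace = TRUE)
      lens <- sample(18:26, n_contam, replace = TRUE)
      starts <- vapply(seq_len(n_contam), function(i) {
        L <- nchar(contaminants[[src[i]]])
        lens[i] <<- min(lens[i], L)
        sample.int(L - lens[i] + 1L, 1L)
      }, 1L)
      contam <- data.frame(
        sequence = substr(contaminants[src], starts, starts + lens - 1L),
        origin = "contaminant", stringsAsFactors = FALSE
      )
    } else {
      contam <- planted[0, ]
    }
    out <- rbind(planted, contam)
    if (nrow(out) == 0L) {
      warning("make_reads: no reads generated")
    } else {
      out <- out[sample.int(nrow(out)), , drop = FALSE]
      if (error_rate > 0) {
        out$sequence <- vapply(out$sequence, function(s) {
          b <- strsplit(s, "")[[1]]
          hit <- runif(length(b)) < error_rate
          if (any(hit)) {
            b[hit] <- vapply(b[hit], function(x) {
              sample(setdiff(c("A", "C", "G", "T"), x), 1L)
            }, "")
          }
          paste(b, collapse = "")
        }, "", USE.NAMES = FALSE)
      }
    }
    rownames(out) <- NULL
    data.frame(read_id = sprintf("read%07d", seq_len(nrow(out))),
               sequence = out$sequence, origin = out$origin,
               stringsAsFactors = FALSE)
  })
}

#' Build a synthetic "foreign species" known-miRNA reference
#'
#' Emits, for `n_conserved` planted loci, a mature sequence differing from
#' the planted mature by 0..`max_divergence` substitutions, with
#' miRBase-style headers carrying an invented family name. Loci included in
#' the reference are flagged `is_conserved` in the returned truth table.
#'
#' @param truth truth table from [make_genome()].
#' @param n_conserved number of loci to emit (<= nrow(truth)).
#' @param max_divergence maximum substitutions between planted mature and
#'   emitted foreign mature; > 3 triggers a warning because the homology
#'   stage tolerates at most 3 mismatches.
#' @param seed integer RNG seed.
#' @return list with `reference` (named character vector; names like
#'   `ath-miR9001a`) and `truth` (updated `is_conserved` flags).
#' @export
make_known_reference <- function(truth, n_conserved, max_divergence = 2L,
                                 seed = 1L) {
  stopifnot(n_conserved <= nrow(truth), n_conserved >= 0)
  if (max_divergence > 3) {
    warning("max_divergence > 3: homology stage will miss these by design")
  }
  with_seed(seed, {
    reference <- character(0)
    truth$is_conserved <- FALSE
    if (n_conserved > 0) {
      pick <- sample(seq_len(nrow(truth)), n_conserved)
      truth$is_conserved[pick] <- TRUE
      for (idx in seq_along(pick)) {
        i <- pick[idx]
        m <- strsplit(truth$mature_seq[i], "")[[1]]
        ndiv <- sample(0:max_divergence, 1L)
        if (ndiv > 0) {
          pos <- sample(seq_along(m), ndiv)
          m[pos] <- vapply(m[pos], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)
          }, "")
        }
        fam <- 9000L + idx
        nm <- sprintf("ath-miR%da", fam)
        reference[nm] <- paste(m, collapse = "")
      }
    }
    list(reference = reference, truth = truth)
  })
}

#' Build a synthetic contaminant ncRNA reference
#'
#' Random rRNA/tRNA-like sequences used both to draw contaminant reads from
#' and as the subject of the contaminant filter.
#'
#' @param seed integer RNG seed.
#' @param n number of contaminant records.
#' @param length length of each record.
#' @return named character vector.
#' @export
make_contaminants <- function(seed = 1L, n = 5L, length = 300L) {
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) random_dna(length), "")
    names(out) <- sprintf("rfam_ncrna%02d", seq_len(n))
    out
  })
}

#' Generate synthetic microarray and qRT-PCR Ct tables
#'
#' Microarray: triplicate spot signals per locus with configurable
#' background and replicate CV. Ct tables: a planted fold change `f` for a
#' locus shifts its Ct by `-log2(f)` in every non-reference tissue against
#' a constant internal control (U6). One planted miRNA–target pair with
#' anti-correlated profiles (target fold `1/f`, GAPDH control) is included.
#'
#' @param truth truth table from [make_genome()].
#' @param n_tissues number of tissues/samples.
#' @param fold_changes numeric vector (one fold per locus, applied in all
#'   non-reference tissues) or matrix (loci x tissues).
#' @param seed integer RNG seed.
#' @param cv replicate coefficient of variation (0 = noise-free).
#' @param base_ct baseline Ct of each miRNA in the reference tissue.
#' @param control_ct Ct of the internal controls (constant).
#' @param signal_base true microarray spot signal.
#' @param bg_mean,bg_sd microarray background mean and SD.
#' @param n_reps replicates per probe / Ct measurement.
#' @return list with `microarray` (data.frame: probe_id, rep1..repN,
#'   bg_mean, bg_sd) and `ct` (data.frame: sample, gene, replicate, ct).
#' @export
make_expression_tables <- function(truth, n_tissues = 4L, fold_changes = NULL,
                                   seed = 1L, cv = 0, base_ct = 26,
                                   control_ct = 20, signal_base = 500,
                                   bg_mean = 40, bg_sd = 8, n_reps = 3L) {
  n_loci <- nrow(truth)
  if (is.null(fold_changes)) fold_changes <- rep(1, n_loci)
  fc <- if (is.matrix(fold_changes)) {
    stopifnot(nrow(fold_changes) == n_loci, ncol(fold_changes) == n_tissues)
    fold_changes
  } else {
    stopifnot(length(fold_changes) == n_loci)
    cbind(1, matrix(rep(fold_changes, n_tissues - 1L), nrow = n_loci))
  }
  stopifnot(all(fc > 0))
  with_seed(seed, {
    noisy <- function(mu) {
      if (cv > 0) rnorm(length(mu), mu, cv * abs(mu)) else mu
    }
    ma <- data.frame(probe_id = truth$locus_id, stringsAsFactors = FALSE)
    for (r in seq_len(n_reps)) {
      ma[[paste0("rep", r)]] <- noisy(rep(signal_base, n_loci)) + bg_mean
    }
    ma$bg_mean <- bg_mean
    ma$bg_sd <- bg_sd

    tissues <- sprintf("tissue%d", seq_len(n_tissues))
    rows <- list()
    add <- function(sample, gene, ct_mu) {
      data.frame(sample = sample, gene = gene,
                 replicate = seq_len(n_reps),
                 ct = if (cv > 0) rnorm(n_reps, ct_mu, cv) else rep(ct_mu,
                                                                    n_reps),
                 stringsAsFactors = FALSE)
    }
    k <- 0L
    for (t in seq_len(n_tissues)) {
      k <- k + 1L; rows[[k]] <- add(tissues[t], "U6", control_ct)
      k <- k + 1L; rows[[k]] <- add(tissues[t], "GAPDH", control_ct)
      for (i in seq_len(n_loci)) {
        k <- k + 1L
        rows[[k]] <- add(tissues[t], truth$locus_id[i],
                         base_ct - log2(fc[i, t]))
      }
      if (n_loci > 0) {
        # anti-correlated planted target of the first locus
        k <- k + 1L
        rows[[k]] <- add(tissues[t], paste0("target_of_", truth$locus_id[1]),
                         base_ct + log2(fc[1, t]))
      }
    }
    list(microarray = ma, ct = do.call(rbind, rows))
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Convenience wrapper producing the on-disk artifacts of a study input set:
#' scaffold FASTA, read FASTQ, known-miRNA reference FASTA, contaminant
#' FASTA, truth TSV, and expression TSVs.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer RNG seed controlling every stochastic choice.
#' @param ... passed to [make_genome()].
#' @param depth_per_locus,contaminant_fraction,error_rate read simulation
#'   parameters, see [make_reads()].
#' @param n_conserved,max_divergence reference parameters, see
#'   [make_known_reference()].
#' @return invisible list of generated file paths plus the in-memory bundle.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, depth_per_locus = 50L,
                            contaminant_fraction = 0.1, error_rate = 0,
                            n_conserved = 10L, max_divergence = 2L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_genome(seed = seed, ...)
  contam <- make_contaminants(seed = seed + 1L)
  ref <- make_known_reference(gen$truth, n_conserved = n_conserved,
                              max_divergence = max_divergence,
                              seed = seed + 2L)
  truth <- ref$truth
  reads <- make_reads(truth, depth_per_locus = depth_per_locus,
                      contaminant_fraction = contaminant_fraction,
                      error_rate = error_rate, seed = seed + 3L,
                      contaminants = contam)
  expr <- make_expression_tables(truth, seed = seed + 4L,
                                 fold_changes = rep(2, nrow(truth)))
  paths <- list(
    scaffolds = file.path(out_dir, "scaffolds.fa"),
    reads = file.path(out_dir, "reads.fq"),
    known = file.path(out_dir, "known_mirnas.fa"),
    contaminants = file.path(out_dir, "contaminants.fa"),
    truth = file.path(out_dir, "truth.tsv"),
    microarray = file.path(out_dir, "microarray.tsv"),
    ct = file.path(out_dir, "ct.tsv")
  )
  write_fasta(gen$scaffolds, paths$scaffolds)
  write_fastq(reads[, c("read_id", "sequence")], paths$reads)
  write_fasta(ref$reference, paths$known)
  write_fasta(contam, paths$contaminants)
  write_tsv(truth, paths$truth)
  write_tsv(expr$microarray, paths$microarray)
  write_tsv(expr$ct, paths$ct)
  invisible(list(paths = paths, scaffolds = gen$scaffolds, truth = truth,
                 reads = reads, reference = ref$reference,
                 contaminants = contam, expression = expr))
}
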