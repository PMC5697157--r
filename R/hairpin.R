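#' Locate a tag on genomic sequences
#'
#' All exact occurrences on both strands, reported as 1-based inclusive
#' coordinates on the forward strand with a strand flag.
#'
#' @param tag tag sequence.
#' @param sequences named character vector of scaffolds/ESTs.
#' @return data.frame: `sequence_id`, `start`, `end`, `strand`.
#' @export
locate_tag <- function(tag, sequences) {
  tag <- as_dna(tag)
  subj <- Biostrings::DNAStringSet(sequences)
  rc <- revcomp(tag)
  pats <- c("+" = tag)
  if (rc != tag) pats <- c(pats, "-" = rc)  # palindromes reported once
  out <- list()
  k <- 0L
  for (strand in names(pats)) {
    m <- Biostrings::vmatchPattern(pats[[strand]], subj)
    for (si in seq_along(m)) {
      r <- m[[si]]
      if (length(r)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          sequence_id = names(sequences)[si],
          start = BiocGenerics::start(r),
          end = BiocGenerics::end(r),
          strand = strand, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!k) {
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract candidate precursor windows around a tag locus
#'
#' Two windows per locus — one placing the tag toward each end of the
#' candidate precursor: `[start - flank, end + 20]` and
#' `[start - 20, end + flank]`, clipped at sequence ends and to `max_len`
#' (clipping removes flank, never the tag). Minus-strand loci are
#' reverse-complemented so the tag reads 5' to 3' in the emitted sequence.
#'
#' @param locus one-row data.frame from [locate_tag()].
#' @param sequences named character vector of scaffolds.
#' @param flank flanking length in nt (>= 20).
#' @param max_len maximum window length.
#' @return data.frame: `window_id`, `sequence_id`, `start`, `end`,
#'   `strand`, `seq`, `tag_start`, `tag_end` (tag position local to `seq`).
#' @export
extract_windows <- function(locus, sequences, flank = 200L, max_len = 300L) {
  stopifnot(flank >= 20L)
  seq_s <- sequences[[locus$sequence_id]]
  L <- nchar(seq_s)
  tl <- locus$end - locus$start + 1L
  ivs <- list(
    c(max(1L, locus$start - flank), min(L, locus$end + 20L)),
    c(max(1L, locus$start - 20L), min(L, locus$end + flank))
  )
  # clip to max_len on the flank side
  ivs[[1]][1] <- max(ivs[[1]][1], ivs[[1]][2] - max_len + 1L)
  ivs[[2]][2] <- min(ivs[[2]][2], ivs[[2]][1] + max_len - 1L)
  out <- lapply(seq_along(ivs), function(i) {
    ws <- ivs[[i]][1]; we <- ivs[[i]][2]
    fwd <- substr(seq_s, ws, we)
    if (locus$strand == "+") {
      sq <- fwd
      ts <- locus$start - ws + 1L
    } else {
      sq <- revcomp(fwd)
      ts <- we - locus$end + 1L
    }
    data.frame(
      window_id = sprintf("%s:%d-%d(%s)w%d", locus$sequence_id, ws, we,
                          locus$strand, i),
      sequence_id = locus$sequence_id, start = ws, end = we,
      strand = locus$strand, seq = sq,
      tag_start = ts, tag_end = ts + tl - 1L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Structural metrics of a candidate miRNA precursor
#'
#' Computes every quantity tested by the twelve hairpin criteria from the
#' dot-bracket structure and its pair table: AMFE (= |MFE|/length x 100),
#' MFEI (= AMFE / GC%), stem pairing, internal loop/bulge tallies, and
#' mature-region statistics over `[mature_start, mature_end]`.
#'
#' A bulge/internal loop between consecutive stem pairs contributes its
#' larger side as its size; it is "biased" when one-sided. The stem region
#' is the span between the outermost and innermost pair on each arm.
#'
#' @param precursor_seq precursor sequence.
#' @param structure dot-bracket structure.
#' @param mfe minimum free energy (kcal/mol, <= 0).
#' @param mature_start,mature_end 1-based mature position on the precursor.
#' @return object of class `hairpin_metrics` (a named list); key fields:
#'   `length`, `gc_percent`, `amfe`, `mfei`, `stem_pairs`,
#'   `max_stem_bulge`, `loop_length`, `single_stem`, `mature_pairs`,
#'   `mature_max_bulge`, `mature_max_biased_bulge`, `mature_bulge_count`,
#'   `mature_mismatch_nt`, `mature_in_stem_fraction`, `arm`.
#' @export
compute_metrics <- function(precursor_seq, structure, mfe,
                            mature_start, mature_end) {
  precursor_seq <- as_dna(precursor_seq)
  n <- nchar(precursor_seq)
  stopifnot(nchar(structure) == n, mature_start >= 1, mature_end <= n,
            mature_start <= mature_end, mfe <= 0)
  pt <- parse_structure(structure)
  chars <- strsplit(precursor_seq, "")[[1]]
  gc <- 100 * sum(chars %in% c("G", "C")) / n
  amfe <- abs(mfe) / n * 100
  mfei <- if (gc > 0) amfe / gc else NA_real_
  stem_pairs <- sum(pt > 0) / 2

  brackets <- gsub(".", "", structure, fixed = TRUE)
  single_stem <- stem_pairs == 0 || grepl("^\\(+\\)+$", brackets)

  opens <- which(pt > seq_along(pt))  # 5' partners, ascending
  loop_length <- NA_integer_
  max_stem_bulge <- 0L
  loops <- list()
  if (length(opens)) {
    inner_i <- opens[length(opens)]
    inner_j <- pt[inner_i]
    loop_length <- inner_j - inner_i - 1L
    if (length(opens) > 1L && single_stem) {
      for (k in seq_len(length(opens) - 1L)) {
        i1 <- opens[k]; i2 <- opens[k + 1L]
        j1 <- pt[i1]; j2 <- pt[i2]
        g5 <- i2 - i1 - 1L
        g3 <- j1 - j2 - 1L
        if (g5 > 0L || g3 > 0L) {
          loops[[length(loops) + 1L]] <- list(
            g5 = g5, g3 = g3,
            pos5 = if (g5 > 0L) (i1 + 1L):(i2 - 1L) else integer(0),
            pos3 = if (g3 > 0L) (j2 + 1L):(j1 - 1L) else integer(0)
          )
          max_stem_bulge <- max(max_stem_bulge, g5, g3)
        }
      }
    }
  }

  mat <- mature_start:mature_end
  mature_len <- length(mat)
  mature_pairs <- sum(pt[mat] > 0)
  mature_mismatch_nt <- mature_len - mature_pairs

  mature_max_bulge <- 0L
  mature_max_biased_bulge <- 0L
  mature_bulge_count <- 0L
  for (lp in loops) {
    touch5 <- length(intersect(lp$pos5, mat)) > 0L
    touch3 <- length(intersect(lp$pos3, mat)) > 0L
    if (touch5 || touch3) {
      side <- max(if (touch5) lp$g5 else 0L, if (touch3) lp$g3 else 0L)
      mature_max_bulge <- max(mature_max_bulge, side)
      biased <- lp$g5 != lp$g3
      if (biased) {
        mature_bulge_count <- mature_bulge_count + 1L
        if (lp$g5 == 0L || lp$g3 == 0L) {
          mature_max_biased_bulge <- max(mature_max_biased_bulge,
                                         lp$g5, lp$g3)
        } else {
          mature_max_biased_bulge <- max(mature_max_biased_bulge,
                                         abs(lp$g5 - lp$g3))
        }
      }
    }
  }

  in_stem <- 0L
  arm <- NA_character_
  if (length(opens)) {
    outer_i <- opens[1L]; outer_j <- pt[outer_i]
    inner_i <- opens[length(opens)]; inner_j <- pt[inner_i]
    stem_pos <- c(outer_i:inner_i, inner_j:outer_j)
    in_stem <- sum(mat %in% stem_pos)
    mid <- (mature_start + mature_end) / 2
    arm <- if (mid <= inner_i) "5p" else if (mid >= inner_j) "3p" else "loop"
  }
  out <- list(
    length = n, gc_percent = gc, mfe = mfe, amfe = amfe, mfei = mfei,
    stem_pairs = stem_pairs, max_stem_bulge = max_stem_bulge,
    loop_length = loop_length, single_stem = single_stem,
    mature_pairs = mature_pairs, mature_max_bulge = mature_max_bulge,
    mature_max_biased_bulge = mature_max_biased_bulge,
    mature_bulge_count = mature_bulge_count,
    mature_mismatch_nt = mature_mismatch_nt,
    mature_in_stem_fraction = in_stem / mature_len,
    arm = arm
  )
  class(out) <- "hairpin_metrics"
  out
}

#' Default thresholds for the twelve hairpin criteria
#'
#' Thresholds follow the standard pre-miRNA screening rules: stem bulge
#' <= 12 nt; >= 16 stem pairs; hairpin length >= 50 nt; loop <= 200 nt;
#' mature-region bulge <= 4 nt; biased mature bulge <= 2 nt; <= 2 biased
#' bulges in the mature region; <= 4 unpaired nt in the mature region;
#' at least 12 mature base pairs; at least 80% of the mature region in
#' the stem;
#' MFE <= -12 kcal/mol; MFEI >= 0.7 (relaxed to >= 0.4 when a predicted
#' target supports the candidate), with 0.85 as a confidence reporting
#' threshold.
#'
#' @return named list of thresholds.
#' @export
criteria_config <- function() {
  list(
    max_stem_bulge = 12L, min_stem_pairs = 16L, min_length = 50L,
    max_loop = 200L, max_mature_bulge = 4L, max_mature_biased_bulge = 2L,
    max_mature_bulge_count = 2L, max_mature_mismatch = 4L,
    min_mature_pairs = 12L, min_mature_in_stem = 0.8,
    max_mfe = -12, min_mfei = 0.7, min_mfei_with_target = 0.4,
    mfei_high_confidence = 0.85
  )
}

#' Apply the twelve structural criteria to a candidate hairpin
#'
#' Each criterion is evaluated independently against [criteria_config()]
#' thresholds; the overall verdict is their conjunction. Multi-branched
#' structures fail a single-stem gate before the criteria are applied.
#'
#' @param metrics `hairpin_metrics` from [compute_metrics()] (a plain
#'   named list with the same fields also works).
#' @param config threshold list, see [criteria_config()].
#' @param has_target whether a predicted target exists (selects the
#'   relaxed MFEI threshold).
#' @return named list: `c1`..`c12` logicals, `single_stem`, `pass`
#'   (conjunction of all), and `mfei_high` (MFEI above the confidence
#'   reporting threshold).
#' @export
apply_criteria <- function(metrics, config = criteria_config(),
                           has_target = FALSE) {
  m <- metrics
  mfei_thr <- if (has_target) config$min_mfei_with_target else
    config$min_mfei
  rep <- list(
    c1 = m$max_stem_bulge <= config$max_stem_bulge,
    c2 = m$stem_pairs >= config$min_stem_pairs,
    c3 = m$length >= config$min_length,
    c4 = !is.na(m$loop_length) && m$loop_length <= config$max_loop,
    c5 = m$mature_max_bulge <= config$max_mature_bulge,
    c6 = m$mature_max_biased_bulge <= config$max_mature_biased_bulge,
    c7 = m$mature_bulge_count <= config$max_mature_bulge_count,
    c8 = m$mature_mismatch_nt <= config$max_mature_mismatch,
    c9 = m$mature_pairs >= config$min_mature_pairs,
    c10 = m$mature_in_stem_fraction >= config$min_mature_in_stem,
    c11 = m$mfe <= config$max_mfe,
    c12 = !is.na(m$mfei) && m$mfei >= mfei_thr,
    single_stem = isTRUE(m$single_stem)
  )
  rep$pass <- all(unlist(rep))
  rep$mfei_high <- !is.na(m$mfei) && m$mfei >= config$mfei_high_confidence
  rep
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Stem-loop component containing the mature region
#'
#' Given the pair table of a folded window, finds the maximal clean
#' stem-loop (no branching) whose stem involves the mature tag: starting
#' from a mature base pair, the stem is extended outward while enclosing
#' pairs are directly nested (pair-free gaps on both sides) and walked
#' inward to the terminal loop. Returns `NULL` when the mature region is
#' entirely unpaired or sits above a multi-branched loop — such windows
#' are not canonical precursor candidates.
#'
#' @param pt pair table from [parse_structure()].
#' @param mature_start,mature_end mature position in the window.
#' @return `c(start, end)` of the component in window coordinates, or
#'   `NULL`.
#' @export
mature_stem_component <- function(pt, mature_start, mature_end) {
  mat <- mature_start:mature_end
  paired <- mat[pt[mat] > 0]
  if (!length(paired)) return(NULL)
  p <- paired[which.min(abs(paired - (mature_start + mature_end) / 2))]
  a <- min(p, pt[p]); b <- max(p, pt[p])
  repeat {
    cc <- a - 1L
    while (cc >= 1L && pt[cc] == 0L) cc <- cc - 1L
    if (cc < 1L) break
    d <- pt[cc]
    if (d <= b) break                      # side branch at the same level
    if (any(pt[seq2(cc + 1L, a - 1L)] > 0L) ||
        any(pt[seq2(b + 1L, d - 1L)] > 0L)) break  # branch in the gap
    a <- cc; b <- d
  }
  ia <- min(p, pt[p]); ib <- max(p, pt[p])
  repeat {
    interior <- seq2(ia + 1L, ib - 1L)
    inner <- interior[pt[interior] > 0L]
    if (!length(inner)) break
    i <- inner[1L]
    j <- pt[i]
    if (j < i || j > ib - 1L) return(NULL)
    if (any(pt[seq2(j + 1L, ib - 1L)] > 0L)) return(NULL)  # multi-loop
    ia <- i; ib <- j
  }
  c(a, b)
}

#' Evaluate all candidate windows of a tag locus
#'
#' Folds every extracted window, trims each to the stem-loop component
#' containing the tag ([mature_stem_component()]), re-folds the trimmed
#' candidate precursor, computes metrics and criteria, and picks the best
#' passing hairpin: lowest MFE among passing candidates, ties broken by
#' shorter precursor.
#'
#' @param locus one-row data.frame from [locate_tag()].
#' @param sequences named character vector of scaffolds.
#' @param flank,max_len window parameters, see [extract_windows()].
#' @param config criteria thresholds.
#' @param has_target passed to [apply_criteria()].
#' @param backend folding backend, see [fold_rna()].
#' @return list with `best` (list: window, structure, mfe, metrics,
#'   criteria — or `NULL` when no window passes) and `any_folds` (TRUE when
#'   at least one window folds into a hairpin with pairing).
#' @export
evaluate_locus <- function(locus, sequences, flank = 200L, max_len = 300L,
                           config = criteria_config(), has_target = FALSE,
                           backend = "auto") {
  win <- extract_windows(locus, sequences, flank = flank, max_len = max_len)
  folded <- fold_rna(win$seq, backend = backend)
  cands <- trim_candidates(win, folded)
  any_folds <- nrow(cands) > 0L
  best <- NULL
  if (nrow(cands)) {
    refolded <- fold_rna(cands$precursor_seq, backend = backend)
    for (i in seq_len(nrow(cands))) {
      cand <- candidate_record(cands[i, , drop = FALSE],
                               refolded[i, , drop = FALSE], config,
                               has_target)
      if (!is.null(cand) && better_candidate(cand, best)) best <- cand
    }
  }
  list(best = best, any_folds = any_folds)
}

# Trim folded windows to mature-containing stem-loop candidates.
# Returns one row per window with a usable component: trimmed precursor
# sequence, local mature coordinates, and genomic precursor coordinates.
trim_candidates <- function(win, folded) {
  out <- list()
  for (i in seq_len(nrow(win))) {
    pt <- parse_structure(folded$structure[i])
    comp <- mature_stem_component(pt, win$tag_start[i], win$tag_end[i])
    if (is.null(comp)) next
    a <- comp[1L]; b <- comp[2L]
    # keep the mature inside even when it overhangs the stem ends
    a <- min(a, win$tag_start[i]); b <- max(b, win$tag_end[i])
    if (win$strand[i] == "+") {
      gs <- win$start[i] + a - 1L
      ge <- win$start[i] + b - 1L
    } else {
      gs <- win$end[i] - b + 1L
      ge <- win$end[i] - a + 1L
    }
    row <- data.frame(
      window_id = win$window_id[i], sequence_id = win$sequence_id[i],
      strand = win$strand[i], precursor_start = gs, precursor_end = ge,
      precursor_seq = substr(win$seq[i], a, b),
      mature_start = win$tag_start[i] - a + 1L,
      mature_end = win$tag_end[i] - a + 1L,
      stringsAsFactors = FALSE
    )
    if (!is.null(win$tag_index)) row$tag_index <- win$tag_index[i]
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) {
    return(data.frame(window_id = character(), sequence_id = character(),
                      strand = character(), precursor_start = integer(),
                      precursor_end = integer(), precursor_seq = character(),
                      mature_start = integer(), mature_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Metrics + criteria for one trimmed, refolded candidate; NULL unless the
# candidate passes all criteria.
candidate_record <- function(cand, refolded, config, has_target = FALSE) {
  met <- compute_metrics(cand$precursor_seq, refolded$structure,
                         refolded$mfe, cand$mature_start, cand$mature_end)
  cr <- apply_criteria(met, config, has_target = has_target)
  if (!cr$pass) return(NULL)
  list(candidate = cand, structure = refolded$structure,
       mfe = refolded$mfe, metrics = met, criteria = cr)
}

better_candidate <- function(cand, best) {
  is.null(best) || cand$mfe < best$mfe ||
    (cand$mfe == best$mfe && cand$metrics$length < best$metrics$length)
}

#' Classify a tag into miRNA discovery groups
#'
#' Group 1: matches a known mature miRNA and a criteria-passing hairpin at
#' a genomic locus contains it in an arm. Group 2a: known match with a
#' genomic locus whose windows fold but fail at least one criterion.
#' Group 2b: known match with no genomic locus (supported only by the
#' foreign precursor). Group 3: no known match but a criteria-passing
#' genomic hairpin (novel candidate). Tags with neither are discarded
#' (group `NA`).
#'
#' @param tag one-row tag data.frame (`sequence`, `count`).
#' @param homology result of [assign_family()] (or `NULL`).
#' @param best_hairpin best passing hairpin from [evaluate_locus()] (or
#'   `NULL`).
#' @param has_locus whether the tag maps anywhere on the genomic sequences.
#' @return one-row data.frame: `sequence`, `count`, `group` (`"1"`,
#'   `"2a"`, `"2b"`, `"3"` or `NA`), `family` (NA for group 3).
#' @export
classify_tag <- function(tag, homology, best_hairpin, has_locus) {
  conserved <- !is.null(homology)
  passing <- !is.null(best_hairpin)
  group <- if (conserved && passing) "1"
  else if (conserved && has_locus) "2a"
  else if (conserved) "2b"
  else if (passing) "3"
  else NA_character_
  data.frame(
    sequence = tag$sequence, count = tag$count, group = group,
    family = if (conserved) homology$family else NA_character_,
    best_known = if (conserved) homology$best$name else NA_character_,
    mismatches = if (conserved) homology$best$mismatches else NA_integer_,
    stringsAsFactors = FALSE
  )
}
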