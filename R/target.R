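#' Plant miRNA target duplex scoring
#'
#' Complementarity scoring of a miRNA against a candidate target site
#' (both given 5' to 3'; the duplex is antiparallel). Penalties: ordinary
#' mismatch 1.0, G:U wobble 0.5, each bulged nucleotide 1.0; every penalty
#' is doubled at miRNA positions 2–13 (the seed-proximal core). At most
#' one single-nucleotide bulge is allowed, so the site length must be
#' within 1 nt of the miRNA length. The returned alignment is the
#' minimum-score arrangement over all allowed bulge placements.
#'
#' @param mirna miRNA sequence (RNA or DNA text).
#' @param target_site target site sequence, transcript 5' to 3'.
#' @return list of class `target_alignment`: `mirna_seq`, `site_seq`,
#'   `states` (per-miRNA-position character vector over `match`, `GU`,
#'   `mismatch`, `target_bulge`, `mirna_bulge`; a target bulge is recorded
#'   at the miRNA position 3' of it), `score`, `bulge` (`"none"`,
#'   `"target"`, `"mirna"`).
#' @export
score_duplex <- function(mirna, target_site) {
  m <- as_dna(mirna)
  s <- as_dna(target_site)
  nm <- nchar(m)
  ns <- nchar(s)
  if (abs(ns - nm) > 1L) {
    stop("score_duplex: site length must be within 1 nt of miRNA length")
  }
  mc <- strsplit(m, "")[[1]]
  rt <- rev(strsplit(s, "")[[1]])   # reversed target: rt[i] faces mirna[i]

  weight <- function(i) if (i >= 2L && i <= 13L) 2 else 1
  pair_pen <- function(a, b) {
    # a = miRNA base, b = target base (DNA alphabet)
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(c(0, 1))
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(c(0.5, 2))
    c(1, 3)
  }
  state_names <- c("match", "GU", "mismatch")

  best <- NULL
  consider <- function(score, states, bulge) {
    if (is.null(best) || score < best$score) {
      best <<- list(score = score, states = states, bulge = bulge)
    }
  }
  if (ns == nm) {
    sc <- 0
    st <- character(nm)
    for (i in seq_len(nm)) {
      p <- pair_pen(mc[i], rt[i])
      sc <- sc + p[1] * weight(i)
      st[i] <- state_names[p[2]]
    }
    consider(sc, st, "none")
  } else if (ns == nm + 1L) {
    for (u in seq_len(ns)) {          # bulged reversed-target index
      sc <- 0
      st <- character(nm)
      charge_at <- min(u, nm)
      sc <- sc + 1 * weight(charge_at)
      for (i in seq_len(nm)) {
        j <- if (i < u) i else i + 1L
        p <- pair_pen(mc[i], rt[j])
        sc <- sc + p[1] * weight(i)
        st[i] <- state_names[p[2]]
      }
      st[charge_at] <- paste0(st[charge_at], "+target_bulge")
      consider(sc, st, "target")
    }
  } else {
    for (u in seq_len(nm)) {          # bulged miRNA position
      sc <- 1 * weight(u)
      st <- character(nm)
      st[u] <- "mirna_bulge"
      for (i in seq_len(nm)) {
        if (i == u) next
        j <- if (i < u) i else i - 1L
        p <- pair_pen(mc[i], rt[j])
        sc <- sc + p[1] * weight(i)
        st[i] <- state_names[p[2]]
      }
      consider(sc, st, "mirna")
    }
  }
  out <- list(mirna_seq = m, site_seq = s, states = best$states,
              score = best$score, bulge = best$bulge)
  class(out) <- "target_alignment"
  out
}

#' Scan transcripts for miRNA target sites
#'
#' Every window (the site read 5' to 3' on the transcript, paired
#' antiparallel to the miRNA) whose best duplex score is at or below
#' `cutoff` is reported; overlapping candidate windows are deduplicated to
#' the local-minimum site.
#'
#' @param mirna miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum duplex score (default 4.0).
#' @return data.frame sorted by (score, transcript_id, start):
#'   `transcript_id`, `site_start`, `site_end` (1-based inclusive),
#'   `score`, `site_seq`.
#' @export
scan_transcriptome <- function(mirna, transcripts, cutoff = 4.0) {
  stopifnot(length(transcripts) > 0L)
  m <- as_dna(mirna)
  nm <- nchar(m)
  hits <- list()
  k <- 0L
  for (ti in seq_along(transcripts)) {
    tx <- as_dna(transcripts[[ti]])
    L <- nchar(tx)
    cand <- list()
    for (w in (nm - 1L):(nm + 1L)) {
      if (w < 1L || w > L) next
      for (st in seq_len(L - w + 1L)) {
        site <- substr(tx, st, st + w - 1L)
        sc <- score_duplex(m, site)$score
        if (sc <= cutoff) {
          cand[[length(cand) + 1L]] <- data.frame(
            transcript_id = names(transcripts)[ti], site_start = st,
            site_end = st + w - 1L, score = sc, site_seq = site,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$score, cand$site_start), , drop = FALSE]
    # greedy local-minimum deduplication of overlapping windows
    chosen <- cand[0, ]
    for (i in seq_len(nrow(cand))) {
      ov <- nrow(chosen) > 0L &&
        any(cand$site_start[i] <= chosen$site_end &
              cand$site_end[i] >= chosen$site_start)
      if (!ov) chosen <- rbind(chosen, cand[i, , drop = FALSE])
    }
    k <- k + 1L
    hits[[k]] <- chosen
  }
  if (!k) {
    return(data.frame(transcript_id = character(), site_start = integer(),
                      site_end = integer(), score = numeric(),
                      site_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$score, out$transcript_id, out$site_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map 5'RACE-derived transcript 5' ends to miRNA cleavage boundaries
#'
#' Each cloned 5' end falling inside the target site is translated to the
#' boundary between the miRNA positions opposite the cleaved phosphate:
#' a 5' end at transcript position `p` (the first base of the 3' cleavage
#' fragment) abuts the boundary between miRNA positions
#' `site_end - p + 1` and `site_end - p + 2`. miRNA-guided slicing in
#' plants canonically cleaves between the bases pairing miRNA positions
#' 10 and 11.
#'
#' @param site one-row data.frame with `site_start`, `site_end` (from
#'   [scan_transcriptome()]), describing an ungapped duplex.
#' @param five_prime_ends data.frame with `position` (transcript
#'   coordinate) and `count` (clone count).
#' @return list: `boundaries` (data.frame `i`, `j` = i+1, `count`,
#'   `fraction`; fractions sum to 1 over in-site clones), `modal_boundary`
#'   (c(i, i+1)), `modal_fraction`, `in_site_clones`, `out_of_site_clones`,
#'   `canonical` (modal boundary is 10/11).
#' @export
map_cleavage <- function(site, five_prime_ends) {
  p <- five_prime_ends$position
  cnt <- five_prime_ends$count
  inside <- p >= site$site_start & p <= site$site_end
  out_clones <- sum(cnt[!inside])
  if (!any(inside)) {
    warning("map_cleavage: all 5' ends fall outside the target site")
    return(list(boundaries = data.frame(i = integer(), j = integer(),
                                        count = numeric(),
                                        fraction = numeric()),
                modal_boundary = NULL, modal_fraction = NA_real_,
                in_site_clones = 0, out_of_site_clones = out_clones,
                canonical = FALSE))
  }
  i_pos <- site$site_end - p[inside] + 1L
  agg <- tapply(cnt[inside], i_pos, sum)
  boundaries <- data.frame(
    i = as.integer(names(agg)), j = as.integer(names(agg)) + 1L,
    count = as.numeric(agg)
  )
  boundaries$fraction <- boundaries$count / sum(boundaries$count)
  boundaries <- boundaries[order(-boundaries$count, boundaries$i), ,
                           drop = FALSE]
  rownames(boundaries) <- NULL
  modal <- c(boundaries$i[1L], boundaries$j[1L])
  list(boundaries = boundaries, modal_boundary = modal,
       modal_fraction = boundaries$fraction[1L],
       in_site_clones = sum(boundaries$count),
       out_of_site_clones = out_clones,
       canonical = identical(modal, c(10L, 11L)))
}
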