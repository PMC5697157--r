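#' Parse a miRNA family from a miRBase-style name
#'
#' `ath-miR166a-5p` -> `miR166`; the family is the `miR` token plus its
#' number, ignoring species prefix and letter/arm variant suffixes.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family names (`NA` when unparseable).
#' @export
parse_family <- function(name) {
  m <- regexpr("miR[0-9]+", name)
  out <- rep(NA_character_, length(name))
  out[m > 0] <- regmatches(name, m)
  out
}

#' Match a unique tag against known mature miRNAs
#'
#' Whole-tag ungapped matching with up to `max_mismatch` substitutions and
#' up to `max_shift` nt of terminal shift (isomiR-style end tolerance). For
#' each reference mature the best alignment over allowed shifts is
#' reported iff the substitution count over the overlap is within
#' `max_mismatch` and the overlap covers at least `tag length - 2`
#' positions. U/T differences are ignored (both sides normalized to DNA).
#'
#' @param tag tag sequence (17–25 nt).
#' @param reference named character vector of known mature sequences
#'   (miRBase-style names).
#' @param max_mismatch maximum substitutions (default 3).
#' @param max_shift maximum terminal shift in nt (default 2).
#' @return data.frame of hits sorted by (mismatches, |offset|, name):
#'   columns `name`, `family`, `mismatches`, `offset` (tag start minus
#'   mature start). Zero rows when nothing matches.
#' @export
match_known <- function(tag, reference, max_mismatch = 3L, max_shift = 2L) {
  tag <- as_dna(tag)
  nt <- nchar(tag)
  tag_ch <- strsplit(tag, "")[[1]]
  hits <- list()
  k <- 0L
  ref_dna <- as_dna(reference)
  for (ri in seq_along(ref_dna)) {
    r <- ref_dna[[ri]]
    nr <- nchar(r)
    r_ch <- strsplit(r, "")[[1]]
    best <- NULL
    for (s in -max_shift:max_shift) {
      # tag position i aligns to mature position i + s
      i_lo <- max(1L, 1L - s)
      i_hi <- min(nt, nr - s)
      if (i_hi < i_lo) next
      overlap <- i_hi - i_lo + 1L
      if (overlap < nt - 2L) next
      mm <- sum(tag_ch[i_lo:i_hi] != r_ch[(i_lo + s):(i_hi + s)])
      if (mm <= max_mismatch &&
          (is.null(best) || mm < best$mismatches ||
           (mm == best$mismatches && abs(s) < abs(best$offset)))) {
        best <- list(mismatches = mm, offset = s)
      }
    }
    if (!is.null(best)) {
      k <- k + 1L
      hits[[k]] <- data.frame(
        name = names(ref_dna)[ri],
        family = parse_family(names(ref_dna)[ri]),
        mismatches = best$mismatches,
        offset = best$offset,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k) {
    return(data.frame(name = character(), family = character(),
                      mismatches = integer(), offset = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$mismatches, abs(out$offset), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a tag to a single miRNA family
#'
#' Takes the sorted hit list from [match_known()] and returns the family of
#' the first (best) hit; ties at equal mismatches and offset resolve to the
#' lexicographically smaller name, so every tag is assigned to exactly one
#' family and census memberships stay disjoint.
#'
#' @param hits data.frame from [match_known()].
#' @return list with `family` and `best` (one-row data.frame), or `NULL`
#'   when there are no hits (the tag proceeds to the novel pipeline).
#' @export
assign_family <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  list(family = hits$family[1L], best = hits[1L, , drop = FALSE])
}

#' Family membership and abundance census of conserved calls
#'
#' @param calls data.frame with `sequence`, `count`, `family` (one row per
#'   conserved tag call).
#' @return data.frame per family: `family`, `member_count` (distinct mature
#'   sequences), `read_total`, `read_fraction` (fractions sum to 1), sorted
#'   by descending read total.
#' @export
family_census <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(data.frame(family = character(), member_count = integer(),
                      read_total = integer(), read_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  fams <- unique(calls$family)
  out <- data.frame(
    family = fams,
    member_count = vapply(fams, function(f) {
      length(unique(calls$sequence[calls$family == f]))
    }, 1L),
    read_total = vapply(fams, function(f) {
      sum(calls$count[calls$family == f])
    }, 1),
    stringsAsFactors = FALSE
  )
  out$read_fraction <- out$read_total / sum(out$read_total)
  out <- out[order(-out$read_total, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
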