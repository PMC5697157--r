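#' Small RNA read cleaning
#'
#' Applies the standard small RNA filter cascade: 3' adapter trimming at
#' the leftmost exact match of at least 8 adapter bases, removal of reads
#' shorter than `min_len` after trimming, removal of reads with more than
#' `max_n` ambiguous bases, and (when per-base qualities are present)
#' removal of low-quality reads, operationalized as mean Phred < `min_mean_q`.
#' An optional low-complexity "dust" filter (Shannon entropy below
#' `dust_entropy` bits per nt) is off by default.
#'
#' @param reads data.frame with `read_id`, `sequence`, optional `quality`
#'   (Phred+33 strings).
#' @param adapter 3' adapter sequence (>= 8 nt) or `NULL` to skip trimming.
#' @param min_len minimum insert length retained.
#' @param max_n maximum number of N bases tolerated.
#' @param min_mean_q minimum mean Phred quality (ignored without qualities).
#' @param dust_entropy entropy threshold in bits/nt; `NULL` disables.
#' @return the surviving reads, input order preserved, with an attribute
#'   `removed` (data.frame of removed reads with a `reason` column).
#' @export
clean_reads <- function(reads, adapter = NULL, min_len = 15L, max_n = 0L,
                        min_mean_q = 20, dust_entropy = NULL) {
  stopifnot(min_len >= 1L)
  if (!is.null(adapter)) {
    adapter <- as_dna(adapter)
    if (nchar(adapter) < 8L) {
      stop("clean_reads: adapter must be at least 8 nt")
    }
    key <- substr(adapter, 1L, 8L)
    hit <- regexpr(key, reads$sequence, fixed = TRUE)
    trim <- hit > 0L
    reads$sequence[trim] <- substr(reads$sequence[trim], 1L, hit[trim] - 1L)
    if (!is.null(reads$quality)) {
      reads$quality[trim] <- substr(reads$quality[trim], 1L, hit[trim] - 1L)
    }
  }
  reason <- rep(NA_character_, nrow(reads))
  len <- nchar(reads$sequence)
  reason[is.na(reason) & len < min_len] <- "too_short"
  n_count <- nchar(reads$sequence) -
    nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  reason[is.na(reason) & n_count > max_n] <- "ambiguous"
  if (!is.null(reads$quality)) {
    meanq <- vapply(reads$quality, function(q) {
      if (!nchar(q)) return(0)
      mean(utf8ToInt(q) - 33L)
    }, 0, USE.NAMES = FALSE)
    reason[is.na(reason) & meanq < min_mean_q] <- "low_quality"
  }
  if (!is.null(dust_entropy)) {
    ent <- vapply(reads$sequence, seq_entropy, 0, USE.NAMES = FALSE)
    reason[is.na(reason) & ent < dust_entropy] <- "low_complexity"
  }
  keep <- is.na(reason)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- reads[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  attr(out, "removed") <- removed
  out
}

# Shannon entropy of the mononucleotide composition, bits per nt.
seq_entropy <- function(s) {
  if (!nchar(s)) return(0)
  p <- table(strsplit(s, "")[[1]])
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Collapse reads to unique tags
#'
#' @param reads data.frame with a `sequence` column (cleaned reads).
#' @return data.frame of unique tags with columns `tag_id`, `sequence`,
#'   `count`, `length`, ordered by descending count then sequence; tag ids
#'   follow the `tag{n}_x{count}` convention.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(tag_id = character(), sequence = character(),
                      count = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads$sequence)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out$length <- nchar(out$sequence)
  out$tag_id <- sprintf("tag%d_x%d", seq_len(nrow(out)), out$count)
  out[, c("tag_id", "sequence", "count", "length")]
}

#' Read-length distribution of a tag set
#'
#' Tabulates, per length, both the read-weighted total and the number of
#' distinct tags, with percentage columns — the standard small RNA library
#' size-distribution summary (run before size selection so the full
#' 15–30 nt picture is reported).
#'
#' @param tags tag data.frame from [collapse_reads()].
#' @return data.frame: `length`, `total_reads`, `unique_tags`,
#'   `total_pct`, `unique_pct`; attributes `total_reads`, `total_tags`,
#'   `mode_total`, `mode_unique` (ties broken toward the smaller length).
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0L) {
    out <- data.frame(length = integer(), total_reads = integer(),
                      unique_tags = integer(), total_pct = numeric(),
                      unique_pct = numeric())
    attr(out, "total_reads") <- 0L
    attr(out, "total_tags") <- 0L
    return(out)
  }
  lens <- sort(unique(tags$length))
  total_reads <- vapply(lens, function(L) sum(tags$count[tags$length == L]),
                        0)
  unique_tags <- vapply(lens, function(L) sum(tags$length == L), 0)
  out <- data.frame(
    length = lens,
    total_reads = as.integer(total_reads),
    unique_tags = as.integer(unique_tags),
    total_pct = 100 * total_reads / sum(total_reads),
    unique_pct = 100 * unique_tags / sum(unique_tags)
  )
  attr(out, "total_reads") <- sum(out$total_reads)
  attr(out, "total_tags") <- sum(out$unique_tags)
  attr(out, "mode_total") <- lens[which.max(total_reads)]
  attr(out, "mode_unique") <- lens[which.max(unique_tags)]
  out
}

#' Remove tags matching a contaminant ncRNA reference
#'
#' A tag is removed iff it occurs as a substring of any contaminant record
#' on either strand with at most `max_mismatch` substitutions (rRNA, tRNA,
#' snoRNA, snRNA and similar housekeeping ncRNAs). Reverse-complement
#' matching is included because strandedness of contaminant references is
#' unreliable.
#'
#' @param tags tag data.frame.
#' @param contaminants named character vector of contaminant sequences.
#' @param max_mismatch substitutions tolerated (default 0 = exact).
#' @return list with `kept` and `removed` tag data.frames
#'   (`kept` + `removed` = input).
#' @export
filter_ncrna <- function(tags, contaminants, max_mismatch = 0L) {
  stopifnot(length(contaminants) > 0L)
  if (nrow(tags) == 0L) return(list(kept = tags, removed = tags))
  subjects <- c(as_dna(contaminants), revcomp(contaminants))
  hit <- vapply(tags$sequence, function(tg) {
    for (sub in subjects) {
      if (max_mismatch == 0L) {
        if (grepl(tg, sub, fixed = TRUE)) return(TRUE)
      } else {
        d <- .hamming_scan(tg, sub)
        if (length(d) && min(d) <= max_mismatch) return(TRUE)
      }
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
  kept <- tags[!hit, , drop = FALSE]
  removed <- tags[hit, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Percentage of unique reads in a library
#'
#' The standard library-complexity summary: unique (distinct) reads as a
#' percentage of raw reads, rounded to two decimals.
#'
#' @param unique_reads number of distinct reads surviving cleanup.
#' @param raw_reads total raw reads.
#' @return percentage (0–100), rounded to two decimals.
#' @export
unique_read_percent <- function(unique_reads, raw_reads) {
  stopifnot(raw_reads > 0, unique_reads >= 0)
  round(100 * unique_reads / raw_reads, 2)
}

#' Size-select tags to the miRNA-plausible window
#'
#' @param tags tag data.frame.
#' @param lo,hi inclusive length bounds (default 17–25 nt).
#' @return tags with `lo <= length <= hi`.
#' @export
size_select <- function(tags, lo = 17L, hi = 25L) {
  stopifnot(lo <= hi)
  out <- tags[tags$length >= lo & tags$length <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}
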