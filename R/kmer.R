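#' Count k-mers and build the multiplicity histogram
#'
#' Every window of length `k` containing no N is counted on the given
#' strand (canonical strand-merged counting is available behind
#' `canonical = TRUE`; the genome-size formula used downstream is stated
#' strand-naively, so it is off by default).
#'
#' @param sequences character vector of DNA sequences.
#' @param k word size (default 17).
#' @param canonical merge each k-mer with its reverse complement.
#' @return object of class `kmer_histogram`: list with `k`,
#'   `total_kmer_count` (number of counted windows), and `freq` (named
#'   integer vector: multiplicity d -> number of distinct k-mers seen
#'   exactly d times). Invariant: `sum(d * freq[d]) == total_kmer_count`.
#' @export
count_kmers <- function(sequences, k = 17L, canonical = FALSE) {
  stopifnot(k >= 1L)
  sequences <- as_dna(sequences)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  total <- 0
  for (s in sequences) {
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    words <- substring(s, starts, starts + k - 1L)
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (canonical && length(words)) {
      rc <- revcomp(words)
      words <- ifelse(words <= rc, words, rc)
    }
    total <- total + length(words)
    if (length(words)) {
      tab <- table(words)
      for (w in names(tab)) {
        prev <- if (is.null(counts[[w]])) 0L else counts[[w]]
        counts[[w]] <- prev + as.integer(tab[[w]])
      }
    }
  }
  depths <- unlist(as.list(counts), use.names = FALSE)
  freq <- if (length(depths)) table(depths) else table(integer(0))
  freq_v <- as.integer(freq)
  names(freq_v) <- names(freq)
  out <- list(k = as.integer(k), total_kmer_count = total, freq = freq_v)
  class(out) <- "kmer_histogram"
  stopifnot(sum(as.numeric(names(freq_v)) * freq_v) == total)
  out
}

#' Construct a k-mer histogram from a depth table
#'
#' Used when the k-mer spectrum was produced elsewhere (e.g. a counting
#' tool's depth/frequency output) and only the histogram is available.
#'
#' @param freq named numeric vector: multiplicity -> distinct k-mer count.
#' @param k word size.
#' @return `kmer_histogram` object.
#' @export
kmer_histogram <- function(freq, k = 17L) {
  stopifnot(all(freq >= 0), all(as.numeric(names(freq)) >= 1))
  out <- list(k = as.integer(k),
              total_kmer_count = sum(as.numeric(names(freq)) * freq),
              freq = freq)
  class(out) <- "kmer_histogram"
  out
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %.0f k-mers, %d depth classes\n",
              x$k, x$total_kmer_count, length(x$freq)))
  invisible(x)
}

#' Locate the coverage peak of a k-mer histogram
#'
#' Returns the depth with the largest number of distinct k-mers, ignoring
#' depths below `min_depth` (the sequencing-error peak at depth 1–3); ties
#' are broken toward the smaller depth.
#'
#' @param hist `kmer_histogram`.
#' @param min_depth smallest depth considered (default 4).
#' @return integer peak depth.
#' @export
find_peak <- function(hist, min_depth = 4L) {
  d <- as.numeric(names(hist$freq))
  keep <- d >= min_depth
  if (!any(keep) || all(hist$freq[keep] == 0)) {
    stop("find_peak: no coverage peak at depth >= min_depth")
  }
  d <- d[keep]
  f <- hist$freq[keep]
  ord <- order(d)
  d <- d[ord]; f <- f[ord]
  as.integer(d[which.max(f)])
}

#' Estimate genome size from a k-mer histogram
#'
#' Genome size = total k-mer count / peak depth of the k-mer distribution.
#'
#' @param hist `kmer_histogram`.
#' @param peak_depth coverage peak from [find_peak()].
#' @return list with `genome_size_bp` (exact real) and `genome_size_gb`
#'   (truncated — not rounded — to two decimals in Gb).
#' @export
estimate_genome_size <- function(hist, peak_depth) {
  if (is.null(peak_depth) || peak_depth < 1) {
    stop("estimate_genome_size: peak_depth must be >= 1")
  }
  gs <- hist$total_kmer_count / peak_depth
  list(genome_size_bp = gs, genome_size_gb = trunc(gs / 1e9 * 100) / 100)
}

#' Sequencing coverage
#'
#' @param total_sequenced_bases total bases sequenced.
#' @param genome_size_bp genome size in bp.
#' @return coverage (x).
#' @export
coverage <- function(total_sequenced_bases, genome_size_bp) {
  stopifnot(genome_size_bp > 0)
  total_sequenced_bases / genome_size_bp
}
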