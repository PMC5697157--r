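#' @useDynLib mirforge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor lowess rbinom runif rnorm sd setNames phyper dhyper
#'   p.adjust approx
#' @importFrom utils write.table read.table head
NULL

# Sequences are handled as DNA (T, not U) internally; conversion to RNA
# happens only at user-facing boundaries (display, FASTA output of matures).

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T, so that mature miRNAs given as RNA and
#' genomic sequence given as DNA compare directly.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
as_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Convert DNA text to RNA text (T -> U)
#' @param x character vector of sequences.
#' @return character vector with U in place of T.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", x)
}

#' Reverse complement of DNA text
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", as_dna(x))
  vapply(strsplit(out, ""), function(s) paste(rev(s), collapse = ""), "")
}

# Watson-Crick or G:U wobble pairing on the DNA alphabet.
can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

is_watson_crick <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning plain
#' uppercase character sequences keyed by the first header token.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    for (st in starts) {
      cat(substr(s, st, min(st + width - 1L, nchar(s))), "\n",
          sep = "", file = con)
    }
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4")
  }
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(
    read_id = sub("^@", "", vapply(strsplit(lines[idx], "\\s+"), `[`, "", 1L)),
    sequence = toupper(lines[idx + 1L]),
    quality = lines[idx + 3L],
    stringsAsFactors = FALSE
  )
}

#' Write reads as FASTQ with constant quality
#' @param reads data.frame with `read_id` and `sequence` (and optionally
#'   `quality`; a constant high quality is used when absent).
#' @param path output path.
#' @param qual_char quality character used when no qualities present.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  qual <- reads$quality
  if (is.null(qual)) {
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep(qual_char, n), "")
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
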