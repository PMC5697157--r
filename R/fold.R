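#' RNA secondary-structure prediction
#'
#' Folds one or more sequences into a single minimum-free-energy secondary
#' structure in dot-bracket notation. Two interchangeable backends sit
#' behind the same interface:
#'
#' * `"rnafold"` — the ViennaRNA `RNAfold` program (nearest-neighbor
#'   thermodynamic model), used when the executable is on the `PATH`.
#' * `"nussinov"` — a built-in weighted base-pair-maximization dynamic
#'   program (G:C 3, A:U 2, G:U 1, minimum hairpin loop 3 nt) whose
#'   reported energy is minus the total pair weight.
#'
#' Both backends are deterministic: the same sequence always yields the
#' same structure and energy.
#'
#' @param sequences character vector of RNA/DNA sequences (U and T are
#'   equivalent); each of length >= 10.
#' @param backend `"auto"` (default: RNAfold when available), `"rnafold"`,
#'   or `"nussinov"`.
#' @return data.frame with columns `sequence`, `structure`, `mfe`
#'   (kcal/mol, <= 0).
#' @export
fold_rna <- function(sequences, backend = c("auto", "rnafold", "nussinov")) {
  backend <- match.arg(backend)
  if (backend == "auto") {
    backend <- if (rnafold_available()) "rnafold" else "nussinov"
  }
  sequences <- as_dna(sequences)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) {
    stop("fold_rna: sequences contain non-ACGU characters after normalization")
  }
  if (any(nchar(sequences) < 10L)) {
    stop("fold_rna: sequences must be at least 10 nt")
  }
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  if (backend == "rnafold") {
    fold_rnafold(sequences)
  } else {
    res <- lapply(sequences, .fold_nussinov)
    data.frame(
      sequence = sequences,
      structure = vapply(res, `[[`, "", "structure"),
      mfe = vapply(res, `[[`, 0, "mfe"),
      stringsAsFactors = FALSE
    )
  }
}

rnafold_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

# Batch all sequences through a single RNAfold process.
fold_rnafold <- function(sequences) {
  ids <- sprintf("s%06d", seq_along(sequences))
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp))
  writeLines(as.vector(rbind(paste0(">", ids), sequences)), inp)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", inp), stdout = TRUE)
  )
  hdr <- grep("^>", out)
  if (length(hdr) != length(sequences)) {
    stop("RNAfold returned unexpected output")
  }
  struct_line <- out[hdr + 2L]
  m <- regmatches(struct_line,
                  regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", struct_line))
  mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  structure <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", struct_line)
  data.frame(sequence = sequences, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Parse dot-bracket structure into a pair table
#'
#' @param structure dot-bracket string over `.`, `(`, `)`.
#' @return integer vector `pt` of length `nchar(structure)`;
#'   `pt[i] = j` when positions i and j pair, `0` when i is unpaired.
#'   Satisfies `pt[pt[i]] == i` for every paired i.
#' @export
parse_structure <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (length(chars) && any(!chars %in% c(".", "(", ")"))) {
    stop("parse_structure: invalid character in dot-bracket string")
  }
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("parse_structure: unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("parse_structure: unbalanced brackets")
  pt
}
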