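# Shared fixtures, all generated in code.

# A perfect hairpin: arm + loop + exact reverse complement of the arm.
perfect_hairpin <- function(arm = "GCAGCCGUAGGCUAGCUUACCG", loop = "GAAUUCCA") {
  arm <- as_dna(arm)
  paste0(arm, as_dna(loop), revcomp(arm))
}

# Small reusable synthetic bundle (memoized per session to keep the suite
# fast); 4 scaffolds x 10 kb, 6 hairpins, one background-only scaffold.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- make_genome(seed = 7, n_scaffolds = 4, scaffold_length = 10000,
                       n_hairpins = 6, background_scaffolds = 1)
      ref <- make_known_reference(g$truth, n_conserved = 3,
                                  max_divergence = 2, seed = 8)
      contam <- make_contaminants(seed = 9)
      reads <- make_reads(ref$truth, depth_per_locus = 30,
                          contaminant_fraction = 0.1, error_rate = 0,
                          seed = 10, contaminants = contam)
      cache <<- list(scaffolds = g$scaffolds, truth = ref$truth,
                     reference = ref$reference, contaminants = contam,
                     reads = reads)
    }
    cache
  }
})

# Independent oracle: exhaustive recursive enumeration of all <= 1-bulge
# antiparallel duplex alignments, scored with the same penalty rules the
# package states (mismatch 1, G:U 0.5, bulged nt 1, doubled at miRNA
# positions 2-13; target bulge charged at the miRNA position 3' of it).
oracle_duplex_score <- function(mirna, site) {
  m <- strsplit(as_dna(mirna), "")[[1]]
  s <- rev(strsplit(as_dna(site), "")[[1]])
  w <- function(i) if (i >= 2 && i <= 13) 2 else 1
  pen <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) 0
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 0.5
    else 1
  }
  best <- Inf
  rec <- function(i, j, sc, bulge_used) {
    if (sc >= best) return()
    if (i > length(m) && j > length(s)) { best <<- sc; return() }
    if (i <= length(m) && j <= length(s)) {
      rec(i + 1, j + 1, sc + pen(m[i], s[j]) * w(i), bulge_used)
    }
    if (!bulge_used) {
      if (j <= length(s) && length(s) == length(m) + 1) {
        rec(i, j + 1, sc + 1 * w(min(i, length(m))), TRUE) # target bulge
      }
      if (i <= length(m) && length(m) == length(s) + 1) {
        rec(i + 1, j, sc + 1 * w(i), TRUE)                 # miRNA bulge
      }
    }
  }
  rec(1, 1, 0, length(m) == length(s))
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Construct a hairpin_metrics-shaped list with all-passing defaults;
# individual fields are overridden to probe criterion boundaries.
passing_metrics <- function(...) {
  m <- list(
    length = 80L, gc_percent = 50, mfe = -40, amfe = 50, mfei = 1.0,
    stem_pairs = 30, max_stem_bulge = 2L, loop_length = 8L,
    single_stem = TRUE, mature_pairs = 19L, mature_max_bulge = 1L,
    mature_max_biased_bulge = 1L, mature_bulge_count = 1L,
    mature_mismatch_nt = 2L, mature_in_stem_fraction = 1.0, arm = "5p"
  )
  over <- list(...)
  m[names(over)] <- over
  m
}
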