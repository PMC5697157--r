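mk_reads <- function(seqs, qual = NULL) {
  out <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                    sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(qual)) out$quality <- qual
  out
}

test_that("clean_reads applies length, adapter, N and quality rules", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- paste0(strrep("ACGT", 5), "AC")   # 22 nt
  expect_error(clean_reads(mk_reads("ACGT"), adapter = "ACGTACG"), "8 nt")
  out <- clean_reads(mk_reads(c("ACGT", paste0(insert, adapter), insert)),
                     adapter = adapter)
  expect_equal(out$sequence, c(insert, insert))  # trimmed + untrimmed kept
  expect_equal(attr(out, "removed")$reason, "too_short")
  # N handling around the max_n boundary
  withN <- paste0(strrep("A", 10), "N", strrep("C", 10))
  expect_equal(nrow(clean_reads(mk_reads(withN), max_n = 0)), 0L)
  expect_equal(nrow(clean_reads(mk_reads(withN), max_n = 1)), 1L)
  # low-quality read dropped only when qualities are present
  lowq <- mk_reads(strrep("ACGT", 5), qual = strrep("#", 20)) # Phred 2
  expect_equal(nrow(clean_reads(lowq)), 0L)
  expect_equal(nrow(clean_reads(mk_reads(strrep("ACGT", 5)))), 1L)
})

test_that("clean_reads and size_select are idempotent", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  set.seed(1)
  seqs <- c(vapply(1:20, function(i) random_seq(sample(10:30, 1)), ""),
            paste0(random_seq(22), adapter))
  once <- clean_reads(mk_reads(seqs), adapter = adapter)
  twice <- clean_reads(once, adapter = adapter)
  expect_equal(twice$sequence, once$sequence)
  tags <- collapse_reads(once)
  expect_identical(size_select(size_select(tags)), size_select(tags))
})

test_that("collapse_reads counts multiplicities deterministically", {
  out <- collapse_reads(mk_reads(c("AAA", "AAA", "CCC")))
  expect_equal(out$sequence, c("AAA", "CCC"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(out$tag_id, c("tag1_x2", "tag2_x1"))
  expect_equal(nrow(collapse_reads(mk_reads(character(0)))), 0L)
  big <- collapse_reads(mk_reads(rep("ACGTACGTACGTACGTACGTA", 1000)))
  expect_equal(big$count, 1000L)
  # descending count then lexicographic order
  mix <- collapse_reads(mk_reads(c("TTT", "GGG", "TTT", "GGG", "AAA")))
  expect_equal(mix$sequence, c("GGG", "TTT", "AAA"))
})

test_that("length_distribution tallies reads and tags per length", {
  tags <- data.frame(sequence = c(strrep("A", 24), strrep("C", 24),
                                  strrep("G", 24), strrep("A", 21)),
                     count = c(1L, 1L, 1L, 1L))
  tags$length <- nchar(tags$sequence)
  ld <- length_distribution(tags)
  expect_equal(ld$total_pct[ld$length == 24], 75)
  expect_equal(sum(ld$total_pct), 100)
  expect_equal(sum(ld$unique_pct), 100)
  expect_equal(sum(ld$total_reads), attr(ld, "total_reads"))
  one <- length_distribution(data.frame(sequence = "ACGTACGTACGTACGTACGTA",
                                        count = 5L, length = 21L))
  expect_equal(one$total_pct, 100)
  # read-weighted mode differs from unique mode; unique ties -> smaller length
  tags2 <- data.frame(sequence = c(strrep("A", 24), strrep("C", 21),
                                   strrep("G", 22)),
                      count = c(43L, 11L, 46L))
  tags2$length <- nchar(tags2$sequence)
  ld2 <- length_distribution(tags2)
  expect_equal(attr(ld2, "mode_total"), 22)
  expect_equal(attr(ld2, "mode_unique"), 21)
})

test_that("filter_ncrna matches substrings on both strands with tolerance", {
  ref <- c(trna = paste0("GGGCCC", "ACGTACGTACGTACGTACGTACGT", "TTTAAA"))
  tags <- data.frame(
    sequence = c("ACGTACGTACGTACGTACGT",          # exact substring
                 revcomp("ACGTACGTACGTACGTACGT"), # minus strand
                 "ACGTACGTACTTACGTACGT",          # Hamming 1 from substring
                 "TTTTTTTTTTTTTTTTTTTT"),         # absent
    count = 1L, stringsAsFactors = FALSE
  )
  tags$length <- nchar(tags$sequence)
  f0 <- filter_ncrna(tags, ref, max_mismatch = 0)
  expect_setequal(f0$removed$sequence, tags$sequence[1:2])
  expect_setequal(f0$kept$sequence, tags$sequence[3:4])
  f1 <- filter_ncrna(tags, ref, max_mismatch = 1)
  expect_setequal(f1$removed$sequence, tags$sequence[1:3])
  expect_equal(nrow(f0$kept) + nrow(f0$removed), nrow(tags))
})

test_that("size_select keeps the inclusive 17-25 window", {
  tags <- data.frame(sequence = vapply(c(16, 17, 25, 26), strrep,
                                       "", x = "A"),
                     count = 1L, stringsAsFactors = FALSE)
  tags$length <- nchar(tags$sequence)
  expect_equal(size_select(tags)$length, c(17L, 25L))
  expect_equal(size_select(tags, lo = 21, hi = 21)$length, integer(0))
  all24 <- data.frame(sequence = strrep("A", 24), count = 3L, length = 24L)
  expect_equal(nrow(size_select(all24)), 1L)
})

test_that("the filter cascade conserves reads and removes the planted contaminant fraction", {
  b <- small_bundle()
  cleaned <- clean_reads(b$reads)
  expect_equal(nrow(cleaned) + nrow(attr(cleaned, "removed")),
               nrow(b$reads))
  tags <- collapse_reads(cleaned)
  expect_equal(sum(tags$count), nrow(cleaned))
  flt <- filter_ncrna(tags, b$contaminants)
  expect_equal(nrow(flt$kept) + nrow(flt$removed), nrow(tags))
  expect_equal(sum(flt$kept$count) + sum(flt$removed$count),
               sum(tags$count))
  removed_fraction <- sum(flt$removed$count) / sum(tags$count)
  planted_fraction <- mean(b$reads$origin == "contaminant")
  expect_lt(abs(removed_fraction - planted_fraction), 0.03)
  # error-free planted reads are never flagged as contaminants
  planted_seqs <- b$reads$sequence[b$reads$origin != "contaminant"]
  expect_false(any(flt$removed$sequence %in% planted_seqs))
})

test_that("unique_read_percent reports the two-decimal summary", {
  expect_equal(unique_read_percent(1, 4), 25)
  expect_equal(unique_read_percent(2, 3), 66.67)
})
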