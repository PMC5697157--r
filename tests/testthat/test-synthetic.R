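test_that("make_genome plants hairpins with the promised geometry", {
  g <- make_genome(seed = 1, n_scaffolds = 1, scaffold_length = 2000,
                   n_hairpins = 2, stem_len = 22, loop_len = 8,
                   background_scaffolds = 0)
  expect_length(g$scaffolds, 1L)
  expect_equal(nrow(g$truth), 2L)
  expect_true(all(nchar(g$truth$precursor_seq) == 2 * 22 + 8))
  expect_true(all(g$truth$precursor_end - g$truth$precursor_start + 1 == 52))
  # precursor really sits in the scaffold at the recorded coordinates
  for (i in 1:2) {
    expect_identical(
      substr(g$scaffolds[[g$truth$scaffold_id[i]]],
             g$truth$precursor_start[i], g$truth$precursor_end[i]),
      g$truth$precursor_seq[i]
    )
    expect_identical(
      substr(g$truth$precursor_seq[i], g$truth$mature_start[i],
             g$truth$mature_end[i]),
      g$truth$mature_seq[i]
    )
  }
  expect_true(all(nchar(g$truth$mature_seq) >= 20 &
                    nchar(g$truth$mature_seq) <= 25))
  expect_false(any(duplicated(g$truth$locus_id)))
})

test_that("make_genome handles the empty and infeasible cases", {
  g0 <- make_genome(seed = 1, n_scaffolds = 2, scaffold_length = 1000,
                    n_hairpins = 0, background_scaffolds = 0)
  expect_equal(nrow(g0$truth), 0L)
  expect_length(g0$scaffolds, 2L)
  expect_error(
    make_genome(seed = 1, n_scaffolds = 1, scaffold_length = 200,
                n_hairpins = 5, stem_len = 22, loop_len = 8,
                background_scaffolds = 0),
    "fit"
  )
})

test_that("generator output is byte-identical under the same seed", {
  a <- make_genome(seed = 42, n_scaffolds = 2, scaffold_length = 3000,
                   n_hairpins = 3, background_scaffolds = 0)
  b <- make_genome(seed = 42, n_scaffolds = 2, scaffold_length = 3000,
                   n_hairpins = 3, background_scaffolds = 0)
  expect_identical(a, b)
  ra <- make_reads(a$truth, depth_per_locus = 10, seed = 5)
  rb <- make_reads(b$truth, depth_per_locus = 10, seed = 5)
  expect_identical(ra, rb)
  # and on-disk artifacts too
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  simulate_bundle(d1, seed = 3, n_scaffolds = 2, scaffold_length = 3000,
                  n_hairpins = 2, background_scaffolds = 0,
                  depth_per_locus = 5, n_conserved = 1)
  simulate_bundle(d2, seed = 3, n_scaffolds = 2, scaffold_length = 3000,
                  n_hairpins = 2, background_scaffolds = 0,
                  depth_per_locus = 5, n_conserved = 1)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("noise-free reads reproduce the planted mature exactly", {
  g <- make_genome(seed = 2, n_scaffolds = 1, scaffold_length = 2000,
                   n_hairpins = 1, background_scaffolds = 0)
  r <- make_reads(g$truth, depth_per_locus = 100, error_rate = 0,
                  seed = 3, jitter_probs = c(1, 0, 0))
  expect_equal(nrow(r), 100L)
  expect_true(all(r$sequence == g$truth$mature_seq))
})

test_that("contaminant_fraction = 1 yields a pure contaminant library", {
  g <- make_genome(seed = 2, n_scaffolds = 1, scaffold_length = 2000,
                   n_hairpins = 1, background_scaffolds = 0)
  contam <- make_contaminants(seed = 4, n = 2, length = 200)
  r <- make_reads(g$truth, depth_per_locus = 50, contaminant_fraction = 1,
                  seed = 5, contaminants = contam)
  expect_true(all(r$origin == "contaminant"))
  hay <- c(contam, revcomp(contam))
  expect_true(all(vapply(r$sequence, function(s) {
    any(vapply(hay, function(h) grepl(s, h, fixed = TRUE), TRUE))
  }, TRUE)))
})

test_that("substitution errors occur at the configured binomial rate", {
  g <- make_genome(seed = 6, n_scaffolds = 1, scaffold_length = 3000,
                   n_hairpins = 1, mature_len_probs = c("24" = 1),
                   background_scaffolds = 0)
  clean <- make_reads(g$truth, depth_per_locus = 1000, error_rate = 0,
                      seed = 7)
  noisy <- make_reads(g$truth, depth_per_locus = 1000, error_rate = 0.01,
                      seed = 7)
  stopifnot(identical(nchar(clean$sequence), nchar(noisy$sequence)))
  subs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$sequence, noisy$sequence)
  is24 <- nchar(clean$sequence) == 24
  expect_gt(mean(subs[is24]), 0.15)  # binomial mean 24 x 0.01 = 0.24
  expect_lt(mean(subs[is24]), 0.35)
})

test_that("every non-contaminant read comes from a planted arm", {
  b <- small_bundle()
  planted <- b$reads[b$reads$origin != "contaminant", ]
  found <- vapply(seq_len(nrow(planted)), function(i) {
    prec <- b$truth$precursor_seq[b$truth$locus_id == planted$origin[i]]
    grepl(planted$sequence[i], prec, fixed = TRUE)
  }, TRUE)
  expect_true(all(found))
})

test_that("known reference respects the divergence bound", {
  g <- make_genome(seed = 3, n_scaffolds = 2, scaffold_length = 5000,
                   n_hairpins = 5, background_scaffolds = 0)
  r0 <- make_known_reference(g$truth, n_conserved = 5, max_divergence = 0,
                             seed = 4)
  expect_setequal(unname(r0$reference),
                  g$truth$mature_seq[r0$truth$is_conserved])
  r3 <- make_known_reference(g$truth, n_conserved = 5, max_divergence = 3,
                             seed = 4)
  cons <- r3$truth[r3$truth$is_conserved, ]
  for (nm in names(r3$reference)) {
    d <- vapply(cons$mature_seq, function(m) {
      if (nchar(m) != nchar(r3$reference[[nm]])) return(99L)
      sum(strsplit(m, "")[[1]] != strsplit(r3$reference[[nm]], "")[[1]])
    }, 1L)
    expect_lte(min(d), 3)
  }
  re <- make_known_reference(g$truth, n_conserved = 0, seed = 1)
  expect_length(re$reference, 0L)
  expect_warning(make_known_reference(g$truth, 2, max_divergence = 4,
                                      seed = 1), "divergence")
})

test_that("expression tables encode planted fold changes in Ct space", {
  g <- make_genome(seed = 5, n_scaffolds = 1, scaffold_length = 3000,
                   n_hairpins = 2, background_scaffolds = 0)
  ex <- make_expression_tables(g$truth, n_tissues = 2,
                               fold_changes = c(8, 1), seed = 6, cv = 0)
  ct <- ex$ct
  ct1 <- mean(ct$ct[ct$sample == "tissue1" & ct$gene == "locus001"])
  ct2 <- mean(ct$ct[ct$sample == "tissue2" & ct$gene == "locus001"])
  expect_equal(ct2 - ct1, -3)        # log2(8) = 3 cycles earlier
  # fold 1 locus is flat
  ctf1 <- mean(ct$ct[ct$sample == "tissue1" & ct$gene == "locus002"])
  ctf2 <- mean(ct$ct[ct$sample == "tissue2" & ct$gene == "locus002"])
  expect_equal(ctf2 - ctf1, 0)
  # planted anti-correlated pair is exactly inverse at zero noise
  fc <- vapply(c("tissue1", "tissue2"), function(s) {
    fold_change_ddct(ct, "locus001", s, "tissue1")
  }, 1)
  fct <- vapply(c("tissue1", "tissue2"), function(s) {
    fold_change_ddct(ct, "target_of_locus001", s, "tissue1")
  }, 1)
  expect_equal(unname(fct), 1 / unname(fc))
})
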