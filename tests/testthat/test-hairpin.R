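test_that("parse_structure builds a symmetric pair table", {
  pt <- parse_structure("(((...)))")
  expect_equal(pt[1:3], c(9L, 8L, 7L))
  expect_equal(pt[7:9], c(3L, 2L, 1L))
  expect_equal(pt[4:6], c(0L, 0L, 0L))
  expect_true(all(pt[pt[pt > 0]] == which(pt > 0)))
  expect_equal(parse_structure("........."), integer(9))
  expect_error(parse_structure("(()"), "unbalanced")
  expect_error(parse_structure("())"), "unbalanced")
  expect_error(parse_structure("(x)"), "invalid")
})

test_that("folding is deterministic and pairs a perfect stem on both backends", {
  hp <- perfect_hairpin()
  backends <- c("nussinov", if (nzchar(Sys.which("RNAfold"))) "rnafold")
  for (be in backends) {
    f1 <- fold_rna(hp, backend = be)
    f2 <- fold_rna(hp, backend = be)
    expect_identical(f1, f2)
    expect_lt(f1$mfe, 0)
    pt <- parse_structure(f1$structure)
    # the planted stem dominates: nearly all arm positions pair to their
    # mirror (terminal pairs may slide into the loop under simple models)
    arm_len <- 22L; n <- nchar(hp)
    mirror <- sum(pt[1:arm_len] == n + 1 - (1:arm_len))
    expect_gte(mirror, arm_len - 3L)
    poly <- fold_rna(strrep("A", 10), backend = be)
    expect_equal(poly$structure, "..........")
    expect_equal(poly$mfe, 0)
  }
  expect_error(fold_rna("ACGTNACGTT"), "non-ACGU")
})

test_that("locate_tag reports exact loci on both strands", {
  b <- small_bundle()
  tr <- b$truth[1, ]
  loc <- locate_tag(tr$mature_seq, b$scaffolds)
  fwd <- loc[loc$strand == "+", ]
  expect_true(any(fwd$sequence_id == tr$scaffold_id &
                    fwd$start == tr$precursor_start + tr$mature_start - 1))
  expect_equal(nrow(locate_tag(strrep("ACGT", 6), b$scaffolds)), 0L)
  seqs <- c(s1 = paste0("TTTT", "ACGGACGGACGGACGGACGG", "TTTT",
                        revcomp("ACGGACGGACGGACGGACGG"), "TTTT"))
  loc2 <- locate_tag("ACGGACGGACGGACGGACGG", seqs)
  expect_setequal(loc2$strand, c("+", "-"))
  expect_equal(nrow(loc2), 2L)
})

test_that("extract_windows applies the stated arithmetic and clipping", {
  seqs <- c(chr = random_seq(2000))
  locus <- data.frame(sequence_id = "chr", start = 1000L, end = 1021L,
                      strand = "+", stringsAsFactors = FALSE)
  w <- extract_windows(locus, seqs, flank = 100L, max_len = 300L)
  expect_equal(w$start, c(900L, 980L))
  expect_equal(w$end, c(1041L, 1121L))
  expect_equal(w$seq[1], substr(seqs[["chr"]], 900, 1041))
  expect_equal(substr(w$seq[1], w$tag_start[1], w$tag_end[1]),
               substr(seqs[["chr"]], 1000, 1021))
  # clipping at the sequence start
  locus2 <- data.frame(sequence_id = "chr", start = 5L, end = 26L,
                       strand = "+", stringsAsFactors = FALSE)
  w2 <- extract_windows(locus2, seqs, flank = 100L)
  expect_equal(w2$start[1], 1L)
  # minus strand: emitted sequence is the reverse complement of the slice
  locus3 <- data.frame(sequence_id = "chr", start = 1000L, end = 1021L,
                       strand = "-", stringsAsFactors = FALSE)
  w3 <- extract_windows(locus3, seqs, flank = 100L)
  expect_equal(w3$seq[1], revcomp(substr(seqs[["chr"]], 900, 1041)))
  expect_equal(substr(w3$seq[1], w3$tag_start[1], w3$tag_end[1]),
               revcomp(substr(seqs[["chr"]], 1000, 1021)))
})

test_that("metrics implement the AMFE and MFEI formulas", {
  # 100 nt, GC 50%, MFE -50 -> AMFE 50, MFEI 1.0
  seq100 <- paste0(strrep("G", 25), strrep("C", 25), strrep("A", 25),
                   strrep("T", 25))
  m <- compute_metrics(seq100, strrep(".", 100), -50, 1, 21)
  expect_equal(m$amfe, 50)
  expect_equal(m$mfei, 1.0)
  m0 <- compute_metrics(seq100, strrep(".", 100), 0, 1, 21)
  expect_equal(m0$amfe, 0)
  expect_equal(m0$mfei, 0)
  # 80 nt, GC 40%, MFE -40 -> MFEI 1.25
  seq80 <- paste0(strrep("G", 16), strrep("C", 16), strrep("A", 24),
                  strrep("T", 24))
  m2 <- compute_metrics(seq80, strrep(".", 80), -40, 1, 21)
  expect_equal(m2$mfei, 1.25)
  # GC 0 -> MFEI undefined, criterion 12 fails
  at <- paste0(strrep("A", 30), strrep("T", 30))
  mna <- compute_metrics(at, strrep(".", 60), -5, 1, 21)
  expect_true(is.na(mna$mfei))
  expect_false(apply_criteria(mna)$c12)
})

test_that("structural tallies read bulges, loops and mature placement", {
  # 10-pair stem, 1-nt 5' bulge after 4 pairs, 4-nt loop
  struct <- "((((.((((((....))))))))))"
  seq <- paste0(strrep("G", 4), "A", strrep("G", 6), "AAAA",
                strrep("C", 10))
  m <- compute_metrics(seq, struct, -20, 1, 11)
  expect_equal(m$stem_pairs, 10)
  expect_equal(m$loop_length, 4L)
  expect_equal(m$max_stem_bulge, 1L)
  expect_true(m$single_stem)
  expect_equal(m$mature_pairs, 10L)       # positions 1..11, the dot at 5
  expect_equal(m$mature_mismatch_nt, 1L)
  expect_equal(m$mature_bulge_count, 1L)  # the one-sided bulge
  expect_equal(m$mature_max_biased_bulge, 1L)
  expect_equal(m$arm, "5p")
  expect_equal(m$mature_in_stem_fraction, 1.0)
  # multi-branched structure is flagged
  multi <- "((..((...))..((...))..))"
  mm <- compute_metrics(random_seq(24), multi, -10, 3, 10)
  expect_false(mm$single_stem)
  expect_false(apply_criteria(mm)$pass)
})

test_that("each criterion flips exactly at its printed threshold", {
  flips <- list(
    list(field = "max_stem_bulge",  pass = 12L,  fail = 13L,  crit = "c1"),
    list(field = "stem_pairs",      pass = 16L,  fail = 15L,  crit = "c2"),
    list(field = "length",          pass = 50L,  fail = 49L,  crit = "c3"),
    list(field = "loop_length",     pass = 200L, fail = 201L, crit = "c4"),
    list(field = "mature_max_bulge", pass = 4L,  fail = 5L,   crit = "c5"),
    list(field = "mature_max_biased_bulge", pass = 2L, fail = 3L,
         crit = "c6"),
    list(field = "mature_bulge_count", pass = 2L, fail = 3L,  crit = "c7"),
    list(field = "mature_mismatch_nt", pass = 4L, fail = 5L,  crit = "c8"),
    list(field = "mature_pairs",    pass = 12L,  fail = 11L,  crit = "c9"),
    list(field = "mature_in_stem_fraction", pass = 0.8, fail = 0.79,
         crit = "c10"),
    list(field = "mfe",             pass = -12,  fail = -11.9, crit = "c11"),
    list(field = "mfei",            pass = 0.7,  fail = 0.69, crit = "c12")
  )
  for (fl in flips) {
    args_pass <- setNames(list(fl$pass), fl$field)
    args_fail <- setNames(list(fl$fail), fl$field)
    rp <- apply_criteria(do.call(passing_metrics, args_pass))
    rf <- apply_criteria(do.call(passing_metrics, args_fail))
    expect_true(rp[[fl$crit]], label = paste(fl$field, "at threshold"))
    expect_true(rp$pass, label = paste(fl$field, "overall at threshold"))
    expect_false(rf[[fl$crit]], label = paste(fl$field, "past threshold"))
    expect_false(rf$pass, label = paste(fl$field, "overall past threshold"))
  }
  # MFEI threshold relaxes to 0.4 when a target is predicted
  m04 <- passing_metrics(mfei = 0.4)
  expect_false(apply_criteria(m04)$c12)
  expect_true(apply_criteria(m04, has_target = TRUE)$c12)
  expect_false(apply_criteria(passing_metrics(mfei = 0.39),
                              has_target = TRUE)$c12)
  # the 0.85 reporting flag does not gate the verdict
  r <- apply_criteria(passing_metrics(mfei = 0.7))
  expect_true(r$pass)
  expect_false(r$mfei_high)
  expect_true(apply_criteria(passing_metrics(mfei = 0.9))$mfei_high)
})

test_that("relaxing any single threshold never turns a pass into a fail", {
  cfg <- criteria_config()
  relax <- function(cfg, key) {
    # move each threshold in its permissive direction
    lower <- c("min_stem_pairs", "min_length", "min_mature_pairs",
               "min_mature_in_stem", "min_mfei", "min_mfei_with_target")
    cfg[[key]] <- if (key %in% lower) cfg[[key]] * 0.5 else
      if (key == "max_mfe") cfg[[key]] + 5 else cfg[[key]] * 2
    cfg
  }
  set.seed(41)
  n_passing <- 0L
  for (trial in 1:60) {
    m <- passing_metrics(
      max_stem_bulge = sample(0:16, 1), stem_pairs = sample(12:40, 1),
      length = sample(45:300, 1), loop_length = sample(3:220, 1),
      mature_max_bulge = sample(0:6, 1),
      mature_max_biased_bulge = sample(0:3, 1),
      mature_bulge_count = sample(0:3, 1),
      mature_mismatch_nt = sample(0:6, 1), mature_pairs = sample(10:22, 1),
      mature_in_stem_fraction = runif(1, 0.6, 1),
      mfe = -runif(1, 5, 60), mfei = runif(1, 0.3, 2)
    )
    base <- apply_criteria(m, cfg)$pass
    if (!base) next
    n_passing <- n_passing + 1L
    for (key in setdiff(names(cfg), "mfei_high_confidence")) {
      expect_true(apply_criteria(m, relax(cfg, key))$pass,
                  label = paste("relaxed", key))
    }
  }
  expect_gt(n_passing, 0)
})

test_that("mature_stem_component isolates the tag's stem-loop", {
  # clean hairpin inside a window with unpaired flanks
  struct <- paste0("....", "((((((((((....))))))))))", "....")
  pt <- parse_structure(struct)
  comp <- mature_stem_component(pt, 5, 14)
  expect_equal(comp, c(5L, 28L))
  # unpaired mature -> no component
  expect_null(mature_stem_component(pt, 1, 4))
  # mature above a multi-branched loop -> rejected
  multi <- "((((..((...))..((...))..))))"
  ptm <- parse_structure(multi)
  expect_null(mature_stem_component(ptm, 1, 4))
})

test_that("classification follows the group decision table", {
  tag <- data.frame(sequence = "ACGT", count = 5L, stringsAsFactors = FALSE)
  hom <- list(family = "miR166",
              best = data.frame(name = "ath-miR166a", family = "miR166",
                                mismatches = 1L, offset = 0L,
                                stringsAsFactors = FALSE))
  hp <- list(candidate = data.frame(sequence_id = "s", stringsAsFactors
                                    = FALSE))
  expect_equal(classify_tag(tag, hom, hp, TRUE)$group, "1")
  expect_equal(classify_tag(tag, hom, NULL, TRUE)$group, "2a")
  expect_equal(classify_tag(tag, hom, NULL, FALSE)$group, "2b")
  g3 <- classify_tag(tag, NULL, hp, TRUE)
  expect_equal(g3$group, "3")
  expect_true(is.na(g3$family))
  expect_true(is.na(classify_tag(tag, NULL, NULL, TRUE)$group))
})

test_that("a stored call re-validates on refolding", {
  b <- small_bundle()
  tr <- b$truth[1, ]
  loc <- data.frame(sequence_id = tr$scaffold_id,
                    start = tr$precursor_start + tr$mature_start - 1L,
                    end = tr$precursor_start + tr$mature_end - 1L,
                    strand = "+", stringsAsFactors = FALSE)
  ev <- evaluate_locus(loc, b$scaffolds)
  expect_false(is.null(ev$best))
  refold <- fold_rna(ev$best$candidate$precursor_seq)
  expect_identical(refold$structure, ev$best$structure)
  expect_identical(refold$mfe, ev$best$mfe)
  expect_true(ev$best$criteria$pass)
  expect_gt(ev$best$metrics$mfei, 0)
  expect_lte(ev$best$metrics$mfei, 5)
})
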