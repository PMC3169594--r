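# Histone-hairpin scanning, internal inverted repeats, ORFs, reference
# coverage and the classification rules; nested-insertion detection.

test_that("a planted perfect stem-loop is found with zero mismatches", {
  set.seed(80)
  hp <- "GGCTCTTTTCAGAGCC"   # 6 bp stem, 4 nt loop
  seq <- paste0(random_dna(120), hp, random_dna(120))
  hits <- scan_histone_hairpin(seq, profile = histone_hairpin_consensus())
  expect_gte(nrow(hits), 1)
  # the planted fold is among the hits with a clean 6 bp stem and 4 nt
  # loop (a longer imperfect stem over the same window may also be
  # reported)
  expect_true(any(hits$start == 121 & hits$stem_mismatches == 0 &
                    hits$loop_length == 4))
})

test_that("structural hairpin count on random sequence equals the
           brute-force all-windows fold check", {
  set.seed(81)
  for (i in 1:5) {
    seq <- random_dna(300)
    hits <- scan_histone_hairpin(seq, profile = NULL)
    expect_equal(nrow(hits), oracle_hairpins(seq))
  }
})

test_that("hairpin detection mirrors under reverse complement", {
  set.seed(82)
  hp <- histone_hairpin_consensus()
  seq <- paste0(random_dna(100), hp, random_dna(100))
  h1 <- scan_histone_hairpin(seq, profile = NULL)
  h2 <- scan_histone_hairpin(reverse_complement(seq), profile = NULL)
  n <- nchar(seq)
  # a stem-loop is a stem-loop on both strands: mirrored positions
  expect_equal(sort(n - h1$end + 1), sort(h2$start))
})

test_that("an internal inverted repeat is detected and is
           strand-invariant; random payloads are clean", {
  set.seed(83)
  arm <- random_dna(60)
  payload <- paste0(random_dna(60), arm, random_dna(80),
                    reverse_complement(arm), random_dna(60))
  ir <- detect_internal_ir(payload)
  expect_false(is.null(ir))
  expect_gte(ir$score, 50)
  ir2 <- detect_internal_ir(reverse_complement(payload))
  expect_false(is.null(ir2))
  expect_equal(ir$score, ir2$score)
  # random payload: the exhaustive local optimum of seq vs its reverse
  # complement stays below the default floor
  r <- random_dna(300)
  expect_null(detect_internal_ir(r))
  sw <- smith_waterman(r, reverse_complement(r),
                       scoring_preset("tir-delineation"))
  expect_lt(sw$score, 25 + nchar(r) * 0)   # oracle confirms sub-threshold
})

test_that("ORF scanning matches its definition and a brute-force count", {
  # ATG + 30 sense codons + TGA = ORF of 31 aa including Met
  set.seed(84)
  sense <- c("GCT","GAA","TTC","CTG","AAA","ATG")  # no stops, no ATG issues
  body <- paste(sample(sense[1:5], 30, replace = TRUE), collapse = "")
  orf_seq <- paste0("CC", "ATG", body, "TGA", "CC")
  orfs <- scan_orfs(orf_seq, min_aa = 10)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length_aa, 31)
  expect_equal(orfs$strand, "+")
  # stop-free frame without ATG gives nothing: a start is required
  no_atg <- paste(rep("GAA", 100), collapse = "")
  expect_equal(nrow(scan_orfs(no_atg, min_aa = 10)), 0)
  # random kilobase against the oracle
  for (i in 1:3) {
    s <- random_dna(1000)
    expect_equal(nrow(scan_orfs(s, min_aa = 15)),
                 oracle_orf_count(s, 15))
  }
})

test_that("reference coverage reflects deletions and localises them", {
  ref <- synthetic_reference()
  full <- reference_similarity(ref$reference, ref$reference, ref$regions)
  expect_equal(full$total, 1, tolerance = 0.02)
  expect_true(full$mule_covered)
  # middle third deleted: total ~2/3 and the deleted region uncovered
  n <- nchar(ref$reference)
  third <- n %/% 3
  del <- paste0(substr(ref$reference, 1, third),
                substr(ref$reference, 2 * third + 1, n))
  cov <- reference_similarity(del, ref$reference,
                              data.frame(name = c("kept5", "deleted",
                                                  "MULE_domain"),
                                         start = c(1, third + 1, 1150),
                                         end = c(third, 2 * third, 1450)))
  expect_equal(cov$total, 2 / 3, tolerance = 0.05)
  expect_lt(cov$regions[["deleted"]], 0.1)
  expect_gt(cov$regions[["kept5"]], 0.9)
})

test_that("a 3'-only fragment leaves the MULE region uncovered", {
  ref <- synthetic_reference()
  n <- nchar(ref$reference)
  frag <- substr(ref$reference, n - 599, n)     # 600 bp 3' fragment
  cov <- reference_similarity(frag, ref$reference, ref$regions)
  expect_false(cov$mule_covered)
  expect_gte(cov$total, 0.2)
})

fake_element_with_payload <- function(payload, d_status = "present") {
  e <- list(contig = "c", start = 1L, end = nchar(payload) + 100L,
            internal_seq = payload,
            d_left = list(status = d_status),
            d_right = list(status = d_status))
  class(e) <- "tm1_element"
  e
}

test_that("classification rules fire in fixed order and always label", {
  set.seed(85)
  refs <- synthetic_reference()
  # rule 1: full reference interior -> Tm1-A
  eA <- classify_element(fake_element_with_payload(refs$reference), refs)
  expect_equal(eA$class, "Tm1-A")
  expect_gt(length(eA$evidence), 0)
  # rule 2: 3' fragment, MULE absent -> Tm1-D
  n <- nchar(refs$reference)
  eD <- classify_element(
    fake_element_with_payload(paste0(random_dna(200),
                                     substr(refs$reference, n - 599, n))),
    refs)
  expect_equal(eD$class, "Tm1-D")
  # rule 3: hairpin-bearing payload -> Tm1-HH
  eH <- classify_element(fake_element_with_payload(
    paste0(random_dna(600), histone_hairpin_consensus(),
           random_dna(250))), refs)
  expect_equal(eH$class, "Tm1-HH")
  # rule 4: internal inverted repeat in a short interior -> Tm1-ML
  arm <- random_dna(60)
  eM <- classify_element(fake_element_with_payload(
    paste0(random_dna(60), arm, random_dna(100),
           reverse_complement(arm), random_dna(60)), "absent"), refs)
  expect_equal(eM$class, "Tm1-ML")
  # rule 5: nothing -> other
  eO <- classify_element(fake_element_with_payload(random_dna(700)), refs)
  expect_equal(eO$class, "other")
  # every element receives exactly one label even without references
  eNR <- classify_element(fake_element_with_payload(random_dna(300),
                                                    "absent"))
  expect_true(eNR$class %in% c("Tm1-A", "Tm1-D", "Tm1-HH", "Tm1-ML",
                               "other"))
})

test_that("nested insertions are found as large exemplar gaps, with their
           own TSDs when present", {
  set.seed(86)
  exemplar <- random_dna(1200)
  at <- 600L
  site <- substr(exemplar, at - 6, at)         # 7 bp target
  arm <- random_dna(60)
  nested <- paste0(arm, random_dna(700), reverse_complement(arm))
  with_ins <- paste0(substr(exemplar, 1, at), nested, site,
                     substr(exemplar, at + 1, 1200))
  ins <- detect_nested_insertions(with_ins, exemplar)
  expect_length(ins, 1)
  expect_gte(ins[[1]]$interval[2] - ins[[1]]$interval[1] + 1, 700)
  expect_false(is.null(ins[[1]]$own_tsd))
  expect_equal(ins[[1]]$own_tsd$length, 7)
  expect_false(is.null(ins[[1]]$internal_ir))
  # unchanged element: no insertions
  expect_length(detect_nested_insertions(exemplar, exemplar), 0)
  # insertion without a TSD is still reported, TSD empty
  with_plain <- paste0(substr(exemplar, 1, at), random_dna(500),
                       substr(exemplar, at + 1, 1200))
  ins2 <- detect_nested_insertions(with_plain, exemplar)
  expect_length(ins2, 1)
  expect_true(is.null(ins2[[1]]$own_tsd) ||
                ins2[[1]]$own_tsd$status != "found")
})
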