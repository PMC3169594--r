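# TIR delineation, orientation normalisation, terminal motifs, and the
# Motif C segmentation DP.

prof <- motif_profile("incognita")

# a grammar-true element: A1 B C^nl D C payload rc(C D) rc(C^nr) rc(B) A2
grammar_element <- function(nl, nr, payload, profile = prof,
                            has_d = TRUE) {
  paste0(profile$a1, profile$b, strrep(profile$c, nl),
         if (has_d) paste0(profile$d, profile$c) else "",
         payload,
         if (has_d) reverse_complement(paste0(profile$c, profile$d)) else "",
         reverse_complement(strrep(profile$c, nr)),
         reverse_complement(profile$b), profile$a2)
}

test_that("a perfect inverted-repeat construct is delineated exactly at
           100% identity", {
  set.seed(60)
  tir <- paste0(prof$b, strrep(prof$c, 3))
  # flank/payload boundary bases chosen so the inverted repeat cannot
  # extend by chance into them (an outward A pairs with a T on the
  # mirrored strand)
  payload <- paste0("A", random_dna(298), "A")
  elem <- paste0(tir, payload, reverse_complement(tir))
  win <- paste0(random_dna(79), "A", elem, "A", random_dna(79))
  del <- delineate_tirs(win, 81, 80 + nchar(elem))
  expect_true(del$resolved)
  expect_equal(del$tir_identity_pct, 100)
  expect_equal(del$left_tir, c(81, 80 + nchar(tir)))
  expect_equal(del$right_tir,
               c(81 + nchar(tir) + 300, 80 + nchar(elem)))
})

test_that("5% substitutions in one TIR give identity near the oracle
           global alignment, boundaries within 3 bp", {
  set.seed(61)
  tir <- paste0(prof$b, strrep(prof$c, 4))
  mut <- strsplit(tir, "")[[1]]
  at <- sample(length(mut), round(0.05 * length(mut)))
  for (p in at) mut[p] <- sample(setdiff(c("A","C","G","T"), mut[p]), 1)
  tir_mut <- paste(mut, collapse = "")
  payload <- random_dna(250)
  elem <- paste0(tir, payload, reverse_complement(tir_mut))
  win <- paste0(random_dna(80), elem, random_dna(80))
  del <- delineate_tirs(win, 81, 80 + nchar(elem))
  expect_true(del$resolved)
  oracle_id <- percent_identity(
    global_align_free_end(tir, tir_mut, global_preset("element")))
  expect_lt(abs(del$tir_identity_pct - oracle_id), 6)
  expect_gte(del$tir_identity_pct, 90)
  expect_lte(del$tir_identity_pct, 97)
  expect_lte(abs(del$left_tir[1] - 81), 3)
  expect_lte(abs(del$right_tir[2] - (80 + nchar(elem))), 3)
})

test_that("terminal motifs orient the element so A1 is left", {
  set.seed(62)
  elem <- grammar_element(2, 3, random_dna(200))
  contig <- list(id = "c", residues = paste0(random_dna(400), elem,
                                             random_dna(400)))
  cand <- data.frame(contig = "c", start = 420L,
                     end = 400L + nchar(elem) - 20L,
                     nested = FALSE)
  e <- annotate_element(cand, contig)
  expect_equal(e$orientation, "+")
  expect_equal(e$a1$status, "present")
  expect_equal(e$a2$status, "present")
  expect_equal(c(e$start, e$end), c(401L, 400L + nchar(elem)))

  # same element planted in reverse orientation: output flipped so A1 left
  contig2 <- list(id = "c", residues = paste0(
    random_dna(400), reverse_complement(elem), random_dna(400)))
  e2 <- annotate_element(cand, contig2)
  expect_equal(e2$orientation, "-")
  expect_equal(e2$a1$status, "present")
  expect_equal(c(e2$start, e2$end), c(401L, 400L + nchar(elem)))
})

test_that("Motif A2 on both ends is reported without flipping", {
  set.seed(63)
  elem <- paste0(reverse_complement(prof$a2), prof$b, strrep(prof$c, 3),
                 random_dna(200),
                 reverse_complement(strrep(prof$c, 3)),
                 reverse_complement(prof$b), prof$a2)
  contig <- list(id = "c", residues = paste0(random_dna(300), elem,
                                             random_dna(300)))
  cand <- data.frame(contig = "c", start = 320L,
                     end = 300L + nchar(elem) - 20L, nested = FALSE)
  e <- annotate_element(cand, contig)
  expect_true(e$a2_both_ends)
  expect_false(e$flipped)
})

test_that("orientation normalisation is idempotent", {
  set.seed(64)
  elem <- grammar_element(3, 2, random_dna(150))
  contig <- list(id = "c", residues = paste0(
    random_dna(300), reverse_complement(elem), random_dna(300)))
  cand <- data.frame(contig = "c", start = 320L,
                     end = 300L + nchar(elem) - 20L, nested = FALSE)
  e1 <- annotate_element(cand, contig)
  # feeding the already-oriented element back in changes nothing
  contig2 <- list(id = "c", residues = paste0(random_dna(300), elem,
                                              random_dna(300)))
  e2 <- annotate_element(cand, contig2)
  expect_equal(e2$orientation, "+")
  expect_equal(e1$end - e1$start, e2$end - e2$start)
  expect_equal(e1$a1$seq, e2$a1$seq)
})

test_that("exact tandem Motif C copies decompose into exact units", {
  tir <- strrep(prof$c, 4)
  u <- decompose_motif_c(tir, prof$c)
  expect_equal(nrow(u), 4)
  expect_true(all(u$length == 14))
  expect_true(all(u$identity_to_consensus == 100))
  expect_equal(u$start, c(1, 15, 29, 43))
  # partition property: units tile the sequence they cover
  expect_true(all(u$start[-1] > u$end[-4]))
})

test_that("the 38 bp seed query decomposes as C unit / Motif D / C unit", {
  q <- tm1_seed_query()
  d <- find_motif_d(q, prof)
  expect_equal(d$status, "present")
  expect_equal(d$seq, "GGGAAAAGGGGA")
  left <- decompose_motif_c(substr(q, 1, d$start - 1), prof$c)
  right <- decompose_motif_c(substr(q, d$end + 1, nchar(q)), prof$c)
  expect_equal(nrow(left), 1)
  expect_equal(nrow(right), 1)
  # each remainder is consumed entirely by its single unit
  expect_equal(left$length, d$start - 1L)
  expect_equal(right$length, nchar(q) - d$end)
})

test_that("segmentation cost equals exhaustive partition enumeration on
           short TIRs", {
  set.seed(65)
  for (i in 1:12) {
    n_units <- sample(1:3, 1)
    seq <- paste0(random_dna(sample(0:3, 1)), strrep(prof$c, n_units),
                  random_dna(sample(0:3, 1)))
    if (nchar(seq) > 45) seq <- substr(seq, 1, 45)
    u <- decompose_motif_c(seq, prof$c)
    dp_cost <- sum(u$edit) +
      0.75 * (nchar(seq) - sum(u$length))
    oracle <- oracle_segmentation_cost(seq, prof$c, 8, 17, 3, 0.75)
    expect_equal(dp_cost, oracle, tolerance = 1e-9)
  }
})

test_that("segmentation plus skipped residues reconstructs the TIR
           exactly", {
  set.seed(66)
  for (i in 1:10) {
    seq <- paste0(random_dna(5), strrep(prof$c, sample(1:4, 1)),
                  random_dna(7))
    u <- decompose_motif_c(seq, prof$c)
    if (nrow(u) == 0) next
    covered <- unlist(lapply(seq_len(nrow(u)), function(k)
      u$start[k]:u$end[k]))
    expect_equal(anyDuplicated(covered), 0)
    recon <- vapply(seq_len(nrow(u)), function(k)
      substr(seq, u$start[k], u$end[k]), character(1))
    expect_equal(paste(recon, collapse = ""),
                 paste(u$sequence, collapse = ""))
  }
})

test_that("grammar-built elements carry Motif B and D; MITE-like lack D", {
  set.seed(67)
  elem <- grammar_element(2, 2, random_dna(150))
  contig <- list(id = "c", residues = paste0(random_dna(300), elem,
                                             random_dna(300)))
  cand <- data.frame(contig = "c", start = 320L,
                     end = 300L + nchar(elem) - 20L, nested = FALSE)
  e <- annotate_element(cand, contig)
  expect_equal(e$b_left$status, "present")
  expect_equal(e$b_right$status, "present")
  expect_equal(e$d_left$status, "present")
  expect_equal(e$d_right$status, "present")

  arm <- random_dna(60)
  ml <- grammar_element(2, 2, paste0(arm, random_dna(60),
                                     reverse_complement(arm)),
                        has_d = FALSE)
  contig_ml <- list(id = "c", residues = paste0(random_dna(300), ml,
                                                random_dna(300)))
  cand_ml <- data.frame(contig = "c", start = 320L,
                        end = 300L + nchar(ml) - 20L, nested = FALSE)
  e_ml <- annotate_element(cand_ml, contig_ml)
  expect_equal(e_ml$d_left$status, "absent")
  expect_equal(e_ml$d_right$status, "absent")
})

test_that("Motif D detection tolerates both species variants at <= 2
           mismatches to the shared core", {
  for (v in c("GGGGAAAAGGGGA", "GTGGAAAAGGGGA", "GCCAAAAGGGGA")) {
    hit <- find_motif_d(paste0("ACGTACGT", v, "ACGTACGT"), prof)
    expect_equal(hit$status, "present")
    expect_lte(hit$mismatches, 2)
  }
  expect_equal(find_motif_d("ACGTACGTACGTACGTACGT", prof)$status, "absent")
})

test_that("unmutated planted elements decompose into the planted unit
           counts", {
  g <- tm1_grammar()
  p <- plant_elements(60000, 12, g, seed = 68)
  res <- run_pipeline(tm1_config(p$genome,
                                 references = synthetic_reference(),
                                 tree = FALSE))
  m <- merge(p$truth, res$table, by = "start")
  expect_equal(nrow(m), 12)
  exact <- m$c_units_left.x == m$c_units_left.y &
    m$c_units_right.x == m$c_units_right.y
  # payload sequence can coincidentally contain one consensus-like unit;
  # the planted counts themselves must dominate
  expect_gte(mean(exact), 0.9)
  # unit counts may legitimately differ between the two ends
  expect_true(any(m$c_units_left.y != m$c_units_right.y))
})
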