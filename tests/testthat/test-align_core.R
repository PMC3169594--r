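# The two alignment engines against independent oracles, DUST masking, and
# the E-value statistics.

test_that("DUST masking flags simple repeats and spares random sequence", {
  # dinucleotide repeat: every window is saturated with two triplets
  m <- mask_low_complexity("ACACACACACACACACACAC")
  expect_true(all(m))
  # the triplet score of that window, computed by direct counting, is far
  # above the threshold
  expect_gt(oracle_dust_score("ACACACACACACACACACAC", 1, 20), 2)
  set.seed(101)
  r <- random_dna(50)
  expect_lt(mean(mask_low_complexity(r)), 0.10)
  expect_lt(oracle_dust_score(r, 1, 50), 2)
  # degenerate input
  expect_equal(mask_low_complexity("ACGTA"), rep(FALSE, 5))
})

test_that("a perfect 38-mer match is found with score 38 and 100% identity", {
  set.seed(5)
  subj <- random_dna(600)
  q <- substr(subj, 201, 238)
  h <- seeded_local_search(q, subj)
  top <- h[which.max(h$raw_score), ]
  expect_equal(top$raw_score, 38)
  expect_equal(top$identity_pct, 100)
  expect_equal(c(top$s_start, top$s_end), c(201, 238))
  expect_equal(top$strand, "+")
})

test_that("a reverse-complemented target is found on the minus strand", {
  set.seed(6)
  core <- random_dna(38)
  subj <- paste0(random_dna(150), reverse_complement(core), random_dna(150))
  h <- seeded_local_search(core, subj)
  top <- h[which.max(h$raw_score), ]
  expect_equal(top$strand, "-")
  expect_equal(c(top$s_start, top$s_end), c(151, 188))
})

test_that("strand symmetry: searching the reverse-complemented subject
           mirrors strands and coordinates", {
  set.seed(8)
  subj <- paste0(random_dna(100), "GATTCAGTATACGGGGAAAAGGGGACGATTCAGTATAC",
                 random_dna(100))
  q <- tm1_seed_query()
  h1 <- seeded_local_search(q, subj)
  h2 <- seeded_local_search(q, reverse_complement(subj))
  n <- nchar(subj)
  expect_equal(nrow(h1), nrow(h2))
  h2m <- data.frame(s_start = n - h2$s_end + 1, s_end = n - h2$s_start + 1,
                    strand = ifelse(h2$strand == "+", "-", "+"),
                    raw_score = h2$raw_score)
  h2m <- h2m[order(h2m$s_start), ]
  expect_equal(h1$s_start, h2m$s_start)
  expect_equal(h1$s_end, h2m$s_end)
  expect_equal(h1$strand, h2m$strand)
  expect_equal(h1$raw_score, h2m$raw_score)
})

test_that("seeded search reaches the exhaustive Smith-Waterman optimum on
           pairs sharing a seed word", {
  # 200 random pairs that share a planted, lightly substituted segment, so
  # at least one exact word exists; the heuristic's best raw score must
  # equal the full-DP local optimum
  set.seed(77)
  scheme <- scoring_preset("seed-search", e_max = 1e9)
  for (i in 1:200) {
    seg <- random_dna(25)
    seg2 <- strsplit(seg, "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(25, nmut)
      for (p in at) seg2[p] <- sample(setdiff(c("A","C","G","T"), seg2[p]), 1)
    }
    a <- paste0(random_dna(60), seg, random_dna(60))
    b <- paste0(random_dna(60), paste(seg2, collapse = ""), random_dna(60))
    sw <- smith_waterman(a, b, scheme)
    h <- seeded_local_search(a, b, scheme)
    expect_equal(max(h$raw_score), sw$score)
  }
})

test_that("free-end-gap global aligner matches a plain-DP oracle on random
           short pairs", {
  set.seed(13)
  params <- global_preset("element")
  for (i in 1:40) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    al <- global_align_free_end(a, b, params)
    expect_equal(al$score,
                 oracle_global_score(a, b, params$match, params$mismatch,
                                     params$gap_open, params$gap_extend),
                 tolerance = 1e-9)
    # ungapping the rows recovers the inputs
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }
})

test_that("ACGT vs ACGGT aligns with a single 1-column gap", {
  # enumeration under the free-end-gap cost model (oracle above) shows the
  # optimum parks the extra G against a terminal gap: score 11
  al <- global_align_free_end("ACGT", "ACGGT")
  expect_equal(al$score, 11)
  expect_equal(oracle_global_score("ACGT", "ACGGT", 5, -4, 12, 3), 11)
  expect_equal(nchar(al$aligned_a), 5)
  expect_equal(sum(strsplit(al$aligned_a, "")[[1]] == "-") +
                 sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1)
})

test_that("identical strings align gaplessly at 100% identity", {
  set.seed(21)
  x <- random_dna(30)
  al <- global_align_free_end(x, x)
  expect_equal(al$identity_pct, 100)
  expect_false(grepl("-", al$aligned_a))
  expect_error(global_align_free_end("", "ACGT"), "empty")
})

test_that("percent identity counts columns correctly and is symmetric", {
  expect_equal(percent_identity(list(a_aln = "ACGTACGTAC",
                                     b_aln = "ACGTACGTAC")), 100)
  expect_equal(percent_identity(list(a_aln = "ACGTACGTAC",
                                     b_aln = "ACGTACGTAT")), 90)
  # end gaps excluded by default, counted when asked
  al <- list(a_aln = "--ACGT", b_aln = "GGACGT")
  expect_equal(percent_identity(al), 100)
  expect_equal(percent_identity(al, exclude_end_gaps = FALSE), 4 / 6 * 100)
  set.seed(31)
  for (i in 1:10) {
    a <- random_dna(30); b <- random_dna(30)
    expect_equal(percent_identity(global_align_free_end(a, b)),
                 percent_identity(global_align_free_end(b, a)))
  }
})

test_that("E-values decrease strictly in score and set a sensible floor", {
  scheme <- scoring_preset("seed-search")
  e <- evalue(5:40, 38, 1e6, scheme)
  expect_true(all(diff(e) < 0))
  fl <- score_floor(38, 1e6, scheme)
  expect_lte(evalue(fl, 38, 1e6, scheme), scheme$e_max)
  expect_gt(evalue(fl - 1L, 38, 1e6, scheme), scheme$e_max)
})

test_that("Karlin-Altschul lambda solves the scheme's characteristic
           equation", {
  for (mm in c(-3, -2)) {
    l <- karlin_lambda(1, mm)
    expect_equal(0.25 * exp(l) + 0.75 * exp(l * mm), 1, tolerance = 1e-8)
  }
  # query shorter than the word size is an error
  expect_error(seeded_local_search("ACGT", random_dna(100)), "word size")
})
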