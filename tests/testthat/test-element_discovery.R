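# Seed search over genomes, hit clustering, and pairing of
# opposite-orientation clusters into candidate elements.

test_that("a planted composite TIR seeds at least one hit", {
  set.seed(50)
  prof <- motif_profile("incognita")
  tir <- paste0(strrep(prof$c, 3), prof$d, prof$c)   # C3 + D + C
  contig <- paste0(random_dna(500), tir, random_dna(500))
  hits <- find_tir_seeds(list(list(id = "c", residues = contig)))
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$s_start <= 501 + nchar(tir) &
                    hits$s_end >= 501))
})

test_that("chance hits on a random 100 kb genome respect the E-value
           cutoff and never become called elements", {
  # an E-value cutoff of 10 EXPECTS a handful of chance hits in 100 kb;
  # what matters is that each reported hit clears the score floor and that
  # none survives pairing and terminal-motif validation
  set.seed(51)
  genome <- list(r = list(id = "r", residues = random_dna(100000)))
  hits <- find_tir_seeds(genome)
  fl <- score_floor(38, 1e5, scoring_preset("seed-search"))
  expect_lt(nrow(hits), 60)
  if (nrow(hits)) {
    expect_true(all(hits$e_value <= 10))
    expect_true(all(hits$raw_score >= fl))
    # the exhaustive local optimum of each hit region confirms the score
    j <- which.max(hits$raw_score)
    win <- substr(genome$r$residues, max(1, hits$s_start[j] - 50),
                  min(1e5, hits$s_end[j] + 50))
    if (hits$strand[j] == "-") win <- reverse_complement(win)
    sw <- smith_waterman(tm1_seed_query(), win)
    expect_gte(sw$score, hits$raw_score[j])
  }
  res <- run_pipeline(tm1_config(genome, tree = FALSE))
  expect_equal(length(res$elements), 0)
  expect_error(find_tir_seeds(list()), "empty genome")
})

test_that("clustering merges same-strand hits within the window and equals
           single-linkage", {
  mk <- function(starts, strand = "+", score = 20)
    data.frame(q_start = 1, q_end = 10, s_start = starts, s_end = starts + 9,
               strand = strand, raw_score = score, e_value = 1e-5,
               identity_pct = 100, aligned_query = "x",
               aligned_subject = "x", contig = "c1",
               stringsAsFactors = FALSE)
  cl <- cluster_hits(mk(c(1, 21, 46)), merge_window = 100)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_hits, 3)
  expect_equal(c(cl$start, cl$end), c(1, 55))
  cl2 <- cluster_hits(mk(c(1, 5001)), merge_window = 200)
  expect_equal(nrow(cl2), 2)
  # random hit sets against a brute-force single-linkage oracle
  set.seed(52)
  for (rep in 1:20) {
    starts <- sort(sample(1:5000, 12))
    h <- mk(starts)
    w <- sample(c(30, 100, 300), 1)
    cl <- cluster_hits(h, merge_window = w)
    grp <- oracle_single_linkage(starts, starts + 9, w)
    expect_equal(nrow(cl), length(unique(grp)))
  }
})

make_clusters <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig = r$contig %||% "c1", strand = r$strand,
               start = r$start, end = r$end, n_hits = r$n %||% 2,
               best_score = r$score %||% 20, stringsAsFactors = FALSE)))
}

test_that("opposite-strand cluster pairs become candidates; same-strand
           pairs do not", {
  cl <- make_clusters(list(strand = "+", start = 100, end = 179),
                      list(strand = "-", start = 950, end = 1029))
  cand <- call_elements(cl)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(100, 1029))
  expect_equal(cand$orientation, "+")
  same <- make_clusters(list(strand = "+", start = 100, end = 179),
                        list(strand = "+", start = 950, end = 1029))
  expect_equal(nrow(call_elements(same)), 0)
  # span constraints
  far <- make_clusters(list(strand = "+", start = 100, end = 179),
                       list(strand = "-", start = 50000, end = 50079))
  expect_equal(nrow(call_elements(far)), 0)
  expect_equal(nrow(call_elements(cl[0, ])), 0)
})

test_that("two neighbouring planted elements are paired end-to-end, not
           chimerically", {
  # four clusters: L1+ R1- L2+ R2-; the cross pairing (R1, L2) is shorter
  # but the total-score matching must keep the two correct pairs
  cl <- make_clusters(list(strand = "+", start = 100, end = 160, score = 17),
                      list(strand = "-", start = 520, end = 580, score = 14),
                      list(strand = "+", start = 880, end = 940, score = 17),
                      list(strand = "-", start = 1300, end = 1360, score = 14))
  cand <- call_elements(cl)
  expect_equal(nrow(cand), 2)
  expect_equal(cand$start, c(100, 880))
  expect_equal(cand$end, c(580, 1360))
})

test_that("a nested cluster pair is emitted as a nested candidate", {
  cl <- make_clusters(list(strand = "+", start = 100, end = 160, score = 30),
                      list(strand = "+", start = 700, end = 760, score = 25),
                      list(strand = "-", start = 1100, end = 1160, score = 25),
                      list(strand = "-", start = 1900, end = 1960, score = 30))
  cand <- call_elements(cl)
  expect_equal(nrow(cand), 2)
  expect_true(cand$nested[cand$start == 700])
  expect_false(cand$nested[cand$start == 100])
})

test_that("candidate calling is invariant under reverse complement of the
           contig", {
  set.seed(53)
  g <- tm1_grammar()
  p <- plant_elements(20000, 3, g, seed = 530)
  rec <- p$genome$synth_contig_1
  fw <- discover_elements(p$genome)$candidates
  rcg <- list(rc = list(id = "rc",
                        residues = reverse_complement(rec$residues)))
  rv <- discover_elements(rcg)$candidates
  n <- nchar(rec$residues)
  expect_equal(nrow(fw), nrow(rv))
  mirrored <- data.frame(start = sort(n - rv$end + 1))
  expect_equal(sort(fw$start), mirrored$start)
})

test_that("every zero-divergence planted element yields exactly one
           covering candidate", {
  g <- tm1_grammar()
  p <- plant_elements(40000, 6, g, seed = 54)
  cand <- discover_elements(p$genome)$candidates
  tr <- p$truth
  covered <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmin(tr$end[i], cand$end) - pmax(tr$start[i], cand$start) + 1
    rec <- pmin(ov / (tr$end[i] - tr$start[i] + 1),
                ov / (cand$end - cand$start + 1))
    sum(rec >= 0.7)
  }, numeric(1))
  expect_true(all(covered == 1))
})
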