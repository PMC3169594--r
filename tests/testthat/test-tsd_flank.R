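# Target-site duplications, empty-site reconstruction, in-silico PCR.

test_that("a planted 9 bp duplication is called with zero mismatches", {
  tsd <- detect_tsd("AGCTGATTAGCCATC", "TTAGCCATCAGCTGA")
  expect_equal(tsd$status, "found")
  expect_equal(tsd$length, 9)
  expect_equal(tsd$left_seq, "TTAGCCATC")
  expect_equal(tsd$right_seq, "TTAGCCATC")
  expect_length(tsd$mismatch_positions, 0)
})

test_that("independent random flanks give n.f.", {
  set.seed(70)
  nf <- 0
  for (i in 1:30) {
    lf <- random_dna(15); rf <- random_dna(15)
    call <- detect_tsd(lf, rf)
    oracle <- oracle_tsd(lf, rf)
    if (is.null(oracle)) {
      expect_equal(call$status, "n.f.")
      nf <- nf + 1
    }
  }
  expect_gt(nf, 25)   # nearly all random pairs lack a >= 7 bp repeat
})

test_that("detect_tsd equals brute force over random flank pairs,
           including imperfect duplications", {
  set.seed(71)
  for (i in 1:500) {
    # half the pairs carry a planted duplication of length 7-12 with 0-1
    # mismatches, the rest are random
    if (i %% 2 == 0) {
      len <- sample(7:12, 1)
      core <- random_dna(len)
      core2 <- strsplit(core, "")[[1]]
      if (runif(1) < 0.5) {
        p <- sample(len, 1)
        core2[p] <- sample(setdiff(c("A","C","G","T"), core2[p]), 1)
      }
      lf <- paste0(random_dna(15 - len), core)
      rf <- paste0(paste(core2, collapse = ""), random_dna(15 - len))
    } else {
      lf <- random_dna(15); rf <- random_dna(15)
    }
    call <- detect_tsd(lf, rf)
    oracle <- oracle_tsd(lf, rf)
    if (is.null(oracle)) {
      expect_equal(call$status, "n.f.")
    } else {
      expect_equal(call$status, "found")
      expect_equal(call$length, oracle$length)
      expect_equal(length(call$mismatch_positions), oracle$mm)
    }
  }
})

test_that("empty-site excision has the right arithmetic and exact
           inverse", {
  set.seed(72)
  bg <- random_dna(2000 - 1080)
  elem <- random_dna(1080)
  site_at <- 400L
  tsd_len <- 9L
  contig <- insert_element(bg, site_at, elem, tsd_len)
  expect_equal(nchar(contig), 2000 + 9)   # element + duplicated site
  # the planted element spans site_at+1 .. site_at+1080
  tsd <- list(status = "found", length = tsd_len,
              left_seq = substr(bg, site_at - 8, site_at),
              right_seq = substr(bg, site_at - 8, site_at),
              mismatch_positions = integer())
  empty <- reconstruct_empty_site(list(id = "c", residues = contig),
                                  site_at + 1L, site_at + 1080L, tsd)
  expect_equal(empty$length, nchar(contig) - 1080 - 9)
  expect_equal(empty$residues, bg)        # exact inverse
  expect_error(reconstruct_empty_site(contig, 10, 20,
                                      list(status = "n.f.")),
               "without a TSD")
})

test_that("an occupied-vs-empty locus shows the expected PCR size shift", {
  # synthetic analog of an element-bearing clone: primers flank an
  # insertion of 1080 bp with a 9 bp TSD; the occupied product is 1493 bp,
  # so the empty-site product must be 1493 - 1080 - 9 = 404 bp
  set.seed(73)
  fwd <- random_dna(22); rev <- random_dna(22)
  spacer1 <- random_dna(180)
  site <- random_dna(9)
  spacer2 <- random_dna(1493 - 22 - 22 - 180 - 9 - 1080 - 9)
  elem <- random_dna(1080)
  occupied <- paste0(random_dna(50), fwd, spacer1, site, elem, site,
                     spacer2, reverse_complement(rev), random_dna(50))
  prod <- in_silico_pcr(occupied, fwd, rev)
  expect_equal(nrow(prod), 1)
  expect_equal(prod$product_length, 1493)
  empty <- reconstruct_empty_site(
    list(id = "x", residues = occupied), 50 + 22 + 180 + 9 + 1L,
    50 + 22 + 180 + 9 + 1080L,
    list(status = "found", length = 9L))
  prod2 <- in_silico_pcr(empty, fwd, rev)
  expect_equal(prod2$product_length, 1493 - 1080 - 9)
})

test_that("product length is 5'-to-5' inclusive", {
  set.seed(74)
  fwd <- random_dna(20); rev <- random_dna(20)
  template <- paste0(random_dna(100), fwd, random_dna(500 - 40),
                     reverse_complement(rev), random_dna(100))
  prod <- in_silico_pcr(template, fwd, rev)
  expect_equal(prod$product_length, 500)
})

test_that("in-silico PCR is strand symmetric and anchors the 3' end", {
  set.seed(75)
  fwd <- random_dna(20); rev <- random_dna(20)
  template <- paste0(random_dna(80), fwd, random_dna(300),
                     reverse_complement(rev), random_dna(80))
  p1 <- in_silico_pcr(template, fwd, rev)
  p2 <- in_silico_pcr(reverse_complement(template), rev, fwd)
  expect_equal(p1$product_length, p2$product_length)
  # a 3'-terminal mismatch kills the binding site
  fwd_bad <- paste0(substr(fwd, 1, 19),
                    setdiff(c("A","C","G","T"),
                            substr(fwd, 20, 20))[1])
  expect_equal(nrow(in_silico_pcr(template, fwd_bad, rev,
                                  max_mismatch = 1)), 0)
  # but an internal mismatch within budget still amplifies
  fwd_mid <- fwd
  substr(fwd_mid, 10, 10) <- setdiff(c("A","C","G","T"),
                                     substr(fwd, 10, 10))[1]
  expect_equal(nrow(in_silico_pcr(template, fwd_mid, rev,
                                  max_mismatch = 1)), 1)
  expect_error(in_silico_pcr(template, "ACGTACGT", rev), ">= 15")
})

test_that("the primer table is usable by name", {
  pt <- primer_table()
  expect_true(all(c("17-F", "17-R", "SG1", "SG6") %in% pt$name))
  expect_true(all(grepl("^[ACGT]+$", pt$sequence)))
  # a template built around the named primers amplifies
  set.seed(76)
  f <- pt$sequence[pt$name == "17-F"]
  r <- pt$sequence[pt$name == "17-R"]
  template <- paste0(random_dna(60), f, random_dna(200),
                     reverse_complement(r), random_dna(60))
  prod <- in_silico_pcr(template, "17-F", "17-R")
  expect_equal(prod$product_length, nchar(f) + 200 + nchar(r))
})
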