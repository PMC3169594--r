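# Independent oracle implementations used to check the compiled engines.
# These are deliberately plain, quadratic, unshared code paths.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plain full-matrix affine global DP (free end gaps) -- score only
oracle_global_score <- function(a, b, match, mismatch, gopen, gext,
                                free_ends = TRUE) {
  m <- nchar(a); n <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in 2:(m + 1)) E[i, 1] <- if (free_ends) 0 else -(gopen + (i - 1) * gext)
  for (j in 2:(n + 1)) F_[1, j] <- if (free_ends) 0 else -(gopen + (j - 1) * gext)
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    s <- if (A[i - 1] == B[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1]) + s
    eopen <- max(M[i - 1, j], F_[i - 1, j]) - (gopen + gext)
    E[i, j] <- max(eopen, E[i - 1, j] - gext)
    if (free_ends && j == n + 1)
      E[i, j] <- max(E[i, j], M[i - 1, j], E[i - 1, j], F_[i - 1, j])
    fopen <- max(M[i, j - 1], E[i, j - 1]) - (gopen + gext)
    F_[i, j] <- max(fopen, F_[i, j - 1] - gext)
    if (free_ends && i == m + 1)
      F_[i, j] <- max(F_[i, j], M[i, j - 1], E[i, j - 1], F_[i, j - 1])
  }
  max(M[m + 1, n + 1], E[m + 1, n + 1], F_[m + 1, n + 1])
}

# brute-force DUST: window triplet score by direct counting
oracle_dust_score <- function(seq, from, to) {
  w <- substr(seq, from, to)
  k <- nchar(w) - 2
  tri <- substring(w, 1:k, 3:(k + 2))
  cnt <- table(tri)
  sum(cnt * (cnt - 1) / 2) / (k - 1)
}

# brute-force single-linkage clustering of intervals with a gap threshold
oracle_single_linkage <- function(starts, ends, threshold) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (grp[i] == grp[j]) next
      gap <- max(max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1, 0)
      if (gap <= threshold) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# brute-force best direct repeat between flank suffix and flank prefix
oracle_tsd <- function(lf, rf, len_range = c(7L, 12L), max_mm = 1L) {
  best <- NULL
  for (len in len_range[1]:min(len_range[2], nchar(lf), nchar(rf))) {
    ls <- substr(lf, nchar(lf) - len + 1, nchar(lf))
    rs <- substr(rf, 1, len)
    mm <- sum(strsplit(ls, "")[[1]] != strsplit(rs, "")[[1]])
    if (mm > max_mm) next
    sc <- len - mm
    if (is.null(best) || sc > best$score ||
        (sc == best$score &&
         ((len == 9 && best$length != 9) ||
          (best$length != 9 && len > best$length))))
      best <- list(length = len, score = sc, mm = mm)
  }
  best
}

# brute-force stem-loop scan (structural only, no profile)
oracle_hairpins <- function(seq, min_stem = 6L, loop_range = c(3L, 6L),
                            max_mm = 1L, max_stem = 10L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  found <- 0L
  if (n < 2 * min_stem + loop_range[1]) return(found)
  for (start in 1:(n - 2 * min_stem - loop_range[1] + 1)) {
    for (loop in loop_range[1]:loop_range[2]) {
      any_s <- FALSE
      smax <- min(max_stem, (n - start + 1 - loop) %/% 2)
      if (smax < min_stem) next
      for (s in min_stem:smax) {
        mm <- 0
        for (t in 1:s) {
          l <- ch[start + t - 1]; r <- ch[start + 2 * s + loop - t]
          if (l == "N" || r == "N" || comp[[l]] != r) mm <- mm + 1
        }
        if (mm <= max_mm) any_s <- TRUE
      }
      if (any_s) found <- found + 1L
    }
  }
  found
}

# brute-force six-frame ORF count
oracle_orf_count <- function(seq, min_aa) {
  count <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in c(seq, reverse_complement(seq))) {
    n <- nchar(s)
    for (f in 1:3) {
      codons <- substring(s, seq(f, n - 2, 3), seq(f + 2, n, 3))
      open <- NA
      for (i in seq_along(codons)) {
        if (is.na(open) && codons[i] == "ATG") open <- i
        if (!is.na(open) && codons[i] %in% stops) {
          if (i - open >= min_aa) count <- count + 1L
          open <- NA
        }
      }
    }
  }
  count
}

# exhaustive optimal Motif C segmentation cost by enumerating all partitions
oracle_segmentation_cost <- function(seq, cons, min_u, max_u, max_edit,
                                     skip) {
  L <- nchar(seq)
  memo <- rep(NA_real_, L + 1)
  rec <- function(i) {   # cost of suffix starting at i (1-based); i = L+1 -> 0
    if (i > L) return(0)
    if (!is.na(memo[i])) return(memo[i])
    best <- skip + rec(i + 1)
    for (len in min_u:max_u) {
      if (i + len - 1 > L) break
      ed <- as.numeric(adist(substr(seq, i, i + len - 1), cons))
      if (ed <= max_edit) best <- min(best, ed + rec(i + len))
    }
    memo[i] <<- best
    best
  }
  rec(1)
}

# SP score of an MSA under linear gap costs (for center-star sanity checks)
msa_sp_score <- function(msa, match = 1, mismatch = -1, gap = -1) {
  mat <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(mat); total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    for (k in seq_len(ncol(mat))) {
      a <- mat[i, k]; b <- mat[j, k]
      if (a == "-" && b == "-") next
      total <- total + if (a == "-" || b == "-") gap else
        if (a == b) match else mismatch
    }
  }
  total
}
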