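# Element discovery: genome-wide seed search with the TIR query, clustering
# of same-strand hits, and pairing of opposite-orientation clusters into
# candidate elements (two or more hits on one contig in opposite orientation
# suggest an intact element).

#' Search a genome for TIR seed hits
#'
#' Runs [seeded_local_search()] with the TIR seed query against every
#' contig. E-values are computed against the summed genome length, as a
#' database search would.
#'
#' @param genome list of records from [read_fasta()] (or a named character
#'   vector of contig residues)
#' @param tir_query seed query string (default [tm1_seed_query()])
#' @param scheme a [scoring_scheme()] (default the seed-search preset)
#' @return data.frame of hits with a \code{contig} column, sorted by
#'   (contig, s_start); attributes \code{n_total} (post-cull) and
#'   \code{n_raw} (pre-cull) carry the genome-wide hit counts
#' @export
find_tir_seeds <- function(genome, tir_query = tm1_seed_query(),
                           scheme = scoring_preset("seed-search")) {
  if (is.character(genome))
    genome <- lapply(names(genome), function(n)
      list(id = n, residues = unname(genome[[n]])))
  if (length(genome) == 0L) stop("empty genome")
  if (grepl("[^ACGTN]", tir_query)) stop("invalid residue in query")
  n_db <- sum(vapply(genome, function(r) nchar(r$residues), numeric(1)))
  res <- lapply(genome, function(rec) {
    h <- seeded_local_search(tir_query, rec$residues, scheme,
                             n_database = n_db)
    if (nrow(h)) h$contig <- rec$id
    list(hits = h, n_raw = attr(h, "n_raw") %||% 0L)
  })
  hits <- do.call(rbind, lapply(res, function(x)
    if (nrow(x$hits)) x$hits else NULL))
  if (is.null(hits)) {
    hits <- .empty_hits(); hits$contig <- character(0)
  }
  hits <- hits[order(hits$contig, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_total") <- nrow(hits)
  attr(hits, "n_raw") <- sum(vapply(res, function(x) x$n_raw, numeric(1)))
  hits
}

#' Cluster same-strand hits within a merge window
#'
#' Single-linkage clustering of hit intervals per contig and strand: hits
#' whose intervals are within \code{merge_window} bp of each other (gap
#' between intervals, 0 if overlapping) are merged, so the several seed
#' hits a single composite TIR produces become one cluster.
#'
#' @param hits data.frame from [find_tir_seeds()]
#' @param merge_window maximum gap in bp (default 200)
#' @return data.frame of clusters: contig, strand, start, end, n_hits,
#'   best_score, and \code{members} (list column of row indices into
#'   \code{hits})
#' @export
cluster_hits <- function(hits, merge_window = 200) {
  if (nrow(hits) == 0L)
    return(data.frame(contig = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_hits = integer(), best_score = numeric()))
  hits$row <- seq_len(nrow(hits))
  out <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$s_start, sub$s_end), , drop = FALSE]
    cl_start <- sub$s_start[1]; cl_end <- sub$s_end[1]
    members <- sub$row[1]
    flush <- function(members, cl_start, cl_end) {
      data.frame(contig = sub$contig[1], strand = sub$strand[1],
                 start = cl_start, end = cl_end,
                 n_hits = length(members),
                 best_score = max(hits$raw_score[members]),
                 members = I(list(members)),
                 stringsAsFactors = FALSE)
    }
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      gap <- sub$s_start[i] - cl_end - 1
      if (gap <= merge_window) {
        cl_end <- max(cl_end, sub$s_end[i])
        members <- c(members, sub$row[i])
      } else {
        out[[length(out) + 1L]] <- flush(members, cl_start, cl_end)
        cl_start <- sub$s_start[i]; cl_end <- sub$s_end[i]
        members <- sub$row[i]
      }
    }
    out[[length(out) + 1L]] <- flush(members, cl_start, cl_end)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair opposite-orientation clusters into candidate elements
#'
#' Every opposite-strand cluster pair on a contig whose outer span is within
#' \code{[min_span, max_span]} is scored (sum of cluster best scores, plus a
#' bonus per terminal motif found outward of each cluster, minus a span
#' penalty). Selection maximises the total score over candidate sets in
#' which each cluster is used at most once and selected spans are pairwise
#' disjoint or strictly nested (a non-crossing matching), computed exactly
#' by interval dynamic programming over the ordered clusters of each
#' contig. Chimeric pairings between neighbouring elements thereby lose to
#' the two correct pairings on total score, while genuinely nested
#' configurations are kept and flagged. Pairs sharing a cluster with a
#' selected candidate are dropped (ambiguous, not emitted).
#'
#' @param clusters data.frame from [cluster_hits()] (one or more contigs)
#' @param min_span,max_span accepted outer-span range in bp
#' @param genome optional record list; when given, each pair is probed for
#'   orientation-consistent terminal motifs (A1 outward of the plus-strand
#'   cluster, A2 outward of the minus-strand cluster, or their reverse
#'   complements for minus-oriented pairs) and each motif found adds
#'   \code{motif_bonus} to the pairing score -- the evidence that separates
#'   genuine element pairs (and genuinely nested elements) from chimeric
#'   pairings between neighbouring elements
#' @param profile [motif_profile()] used for the probe
#' @param motif_bonus score bonus per terminal motif found (default 30)
#' @return data.frame of candidates: contig, start, end, orientation
#'   (\code{"+"} if the plus-strand cluster is leftmost), pairing_score,
#'   nested (logical), left_cluster/right_cluster (row indices into
#'   \code{clusters}), cluster spans, and the probe's motif count
#' @export
call_elements <- function(clusters, min_span = 100, max_span = 10000,
                          genome = NULL, profile = motif_profile(),
                          motif_bonus = 30) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), orientation = character(),
                      pairing_score = numeric(), terminal_motifs = integer(),
                      nested = logical(),
                      left_cluster = integer(), right_cluster = integer(),
                      lc_start = integer(), lc_end = integer(),
                      rc_start = integer(), rc_end = integer())
  if (nrow(clusters) == 0L) return(empty)
  if (is.character(genome))
    genome <- lapply(names(genome), function(n)
      list(id = n, residues = unname(genome[[n]])))
  if (!is.null(genome))
    names(genome) <- vapply(genome, function(r) r$id, character(1))
  clusters$row <- seq_len(nrow(clusters))

  # a real element carries A1 just outward of its left cluster and A2
  # outward of its right cluster (or, for a minus-strand element, rc(A2)
  # left and rc(A1) right). The hit strand pattern itself (plus-strand
  # hits left, minus right) is the same for both element orientations, so
  # both hypotheses are probed; only an orientation-CONSISTENT motif pair
  # earns the full bonus -- chance motif matches, and the A1...rc(A1)
  # pattern of a chimera joining two elements' like ends, do not.
  probe <- function(ctg, left, right) {
    if (is.null(genome)) return(0)
    res <- genome[[ctg]]$residues
    found <- function(m, lo, hi)
      !is.null(.scan_motif(res, m, lo, hi, profile$a_max_mismatch))
    # the terminal motif is probed together with its adjacent Motif B
    # (A1+B left, B'+A2 right); the 10 bp pattern keeps chance matches in
    # diverged sequence negligible
    b <- profile$b; brc <- reverse_complement(b)
    llo <- left$start - 170L; lhi <- left$start
    rlo <- right$end - 9L; rhi <- right$end + 170L
    a1_l <- found(paste0(profile$a1, b), llo, lhi)
    ra2_l <- found(paste0(reverse_complement(profile$a2), b), llo, lhi)
    a2_r <- found(paste0(brc, profile$a2), rlo, rhi)
    ra1_r <- found(paste0(brc, reverse_complement(profile$a1)), rlo, rhi)
    if ((a1_l && a2_r) || (ra2_l && ra1_r)) return(2)
    0.5 * ((a1_l || ra2_l) + (a2_r || ra1_r))
  }

  cands <- list()
  for (ctg in unique(clusters$contig)) {
    cc <- clusters[clusters$contig == ctg, , drop = FALSE]
    if (nrow(cc) < 2) next
    for (i in seq_len(nrow(cc) - 1)) for (j in (i + 1):nrow(cc)) {
      a <- cc[i, ]; b <- cc[j, ]
      if (a$strand == b$strand) next
      left <- if (a$start <= b$start) a else b
      right <- if (a$start <= b$start) b else a
      if (left$end > right$start) next  # interleaved clusters: ambiguous
      span <- right$end - left$start + 1
      if (span < min_span || span > max_span) next
      orientation <- if (left$strand == "+") "+" else "-"
      nm <- probe(ctg, left, right)
      cands[[length(cands) + 1L]] <- data.frame(
        contig = ctg, start = left$start, end = right$end,
        orientation = orientation,
        pairing_score = left$best_score + right$best_score +
          nm * motif_bonus - span / 100,
        terminal_motifs = nm,
        nested = FALSE, left_cluster = left$row, right_cluster = right$row,
        lc_start = left$start, lc_end = left$end,
        rc_start = right$start, rc_end = right$end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L) return(empty)
  cands <- do.call(rbind, cands)
  rownames(cands) <- NULL

  # exact maximum-weight non-crossing matching per contig: clusters are
  # ordered by position; best[i, j] is the optimal total over clusters
  # i..j, choosing for cluster i either nothing or a partner k, with the
  # inside (i+1 .. k-1) and outside (k+1 .. j) solved independently
  keep <- integer(0)
  for (ctg in unique(cands$contig)) {
    rows <- which(cands$contig == ctg)
    cids <- sort(unique(c(cands$left_cluster[rows],
                          cands$right_cluster[rows])))
    m <- length(cids)
    pos <- match(seq_len(max(cids)), cids)           # cluster id -> index
    w <- matrix(NA_real_, m, m)
    cidx <- matrix(NA_integer_, m, m)
    for (r in rows) {
      i <- pos[cands$left_cluster[r]]; j <- pos[cands$right_cluster[r]]
      if (is.na(w[i, j]) || cands$pairing_score[r] > w[i, j]) {
        w[i, j] <- cands$pairing_score[r]; cidx[i, j] <- r
      }
    }
    best <- matrix(0, m + 1L, m + 1L)   # best[i, j+1] over range i..j
    for (len in 1:m) for (i in 1:(m - len + 1L)) {
      j <- i + len - 1L
      b <- best[i + 1L, j + 1L]                       # cluster i unpaired
      if (len >= 2L) for (k in (i + 1L):j) {
        if (is.na(w[i, k]) || w[i, k] <= 0) next
        cand_v <- w[i, k] + best[i + 1L, k] +
          (if (k < j) best[k + 1L, j + 1L] else 0)
        if (cand_v > b + 1e-9) b <- cand_v
      }
      best[i, j + 1L] <- b
    }
    # traceback
    stack <- list(c(1L, m))
    while (length(stack)) {
      rg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- rg[1]; j <- rg[2]
      if (i > j || i > m) next
      b <- best[i, j + 1L]
      if (abs(b - best[i + 1L, j + 1L]) <= 1e-9) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
        next
      }
      done <- FALSE
      if (j >= i + 1L) for (k in (i + 1L):j) {
        if (is.na(w[i, k]) || w[i, k] <= 0) next
        cand_v <- w[i, k] + best[i + 1L, k] +
          (if (k < j) best[k + 1L, j + 1L] else 0)
        if (abs(cand_v - b) <= 1e-9) {
          keep <- c(keep, cidx[i, k])
          stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          done <- TRUE
          break
        }
      }
      if (!done) stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
  }
  selected <- cands[sort(keep), , drop = FALSE]
  # flag nested candidates
  if (nrow(selected) > 1) {
    selected$nested <- vapply(seq_len(nrow(selected)), function(i) {
      s <- selected[i, ]
      any(selected$contig == s$contig & selected$start < s$start &
            selected$end > s$end)
    }, logical(1))
  }
  selected <- selected[order(selected$contig, selected$start), , drop = FALSE]
  rownames(selected) <- NULL
  selected
}

#' Discover candidate elements in a genome
#'
#' Convenience wrapper: [find_tir_seeds()], [cluster_hits()],
#' [call_elements()].
#'
#' @inheritParams find_tir_seeds
#' @inheritParams cluster_hits
#' @inheritParams call_elements
#' @return list with \code{hits}, \code{clusters}, \code{candidates}
#' @export
discover_elements <- function(genome, tir_query = tm1_seed_query(),
                              scheme = scoring_preset("seed-search"),
                              merge_window = 200, min_span = 100,
                              max_span = 10000) {
  hits <- find_tir_seeds(genome, tir_query, scheme)
  clusters <- cluster_hits(hits, merge_window)
  candidates <- call_elements(clusters, min_span, max_span, genome = genome)
  list(hits = hits, clusters = clusters, candidates = candidates)
}
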