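# R surface over the compiled alignment engines: low-complexity masking,
# the seeded local search (word seeding, X-drop extension, Karlin-Altschul
# E-values, diagonal culling), the free-end-gap global aligner and identity
# metrics. Exhaustive Smith-Waterman is exported separately so tests can use
# it as an independent optimum.

#' DUST-style low-complexity mask
#'
#' Marks positions inside windows whose normalised triplet score
#' (sum of c(c-1)/2 over triplet counts c, divided by the number of triplets
#' minus one) exceeds \code{threshold}. Sequences shorter than the window
#' are scored as one clamped window; sequences shorter than 8 nt return an
#' all-FALSE mask. Masking suppresses seeding only, never extension.
#'
#' @param seq residue string
#' @param window window length (>= 8; default 64)
#' @param threshold score threshold (default 2, the classic DUST level)
#' @return logical vector along \code{seq}
#' @export
mask_low_complexity <- function(seq, window = 64, threshold = 2) {
  stopifnot(window >= 8)
  cpp_dust_mask(seq, as.integer(window), threshold)
}

#' Exhaustive local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment; quadratic time and memory.
#' Used as the exact optimum against which the seeded heuristic is checked.
#'
#' @param a,b residue strings
#' @param scheme a [scoring_scheme()] supplying match/mismatch/gap costs
#' @return list with \code{score}, 1-based \code{a_start}/\code{a_end}/
#'   \code{b_start}/\code{b_end} and the gapped \code{a_aln}/\code{b_aln}
#' @export
smith_waterman <- function(a, b, scheme = scoring_preset("seed-search")) {
  cpp_smith_waterman(a, b, scheme$match, scheme$mismatch,
                     scheme$gap_open, scheme$gap_extend)
}

# cull hits that overlap a better same-strand hit by >= 50% in the subject
.cull_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(-hits$raw_score, hits$s_start, hits$q_start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- hits[keep, , drop = FALSE]
      same <- kept$strand == hits$strand[i]
      if (any(same)) {
        ks <- kept[same, , drop = FALSE]
        ov <- pmin(ks$s_end, hits$s_end[i]) - pmax(ks$s_start, hits$s_start[i]) + 1
        len <- hits$s_end[i] - hits$s_start[i] + 1
        if (any(ov >= 0.5 * len)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(), raw_score = numeric(),
             e_value = numeric(), identity_pct = numeric(),
             aligned_query = character(), aligned_subject = character(),
             stringsAsFactors = FALSE)
}

#' Seeded local search (BLASTN-style)
#'
#' Finds local alignments of \code{query} in \code{subject} on both strands:
#' exact word-size seeds, ungapped X-drop extension along the diagonal, then
#' affine-gapped X-drop extension for segments reaching the trigger score.
#' The final alignment and raw score of each hit are obtained by bounded
#' global DP over the extended extents. E-values use ungapped
#' Karlin-Altschul statistics with BLAST's effective-length adjustment; hits
#' with E above \code{scheme$e_max} are discarded, and overlapping hits on
#' the same strand are culled keeping the best score. The pre-cull hit count
#' is returned as attribute \code{n_raw}.
#'
#' @param query,subject residue strings (a record list from [read_fasta()]
#'   is also accepted)
#' @param scheme a [scoring_scheme()]
#' @param n_database effective database length for E-values; defaults to
#'   \code{nchar(subject)} (set it to the summed contig length when
#'   searching a multi-contig genome)
#' @return data.frame of hits sorted by subject start: \code{q_start},
#'   \code{q_end}, \code{s_start}, \code{s_end} (1-based, subject
#'   coordinates always on the plus strand), \code{strand} (subject strand
#'   relative to query), \code{raw_score}, \code{e_value},
#'   \code{identity_pct}, \code{aligned_query}, \code{aligned_subject}
#' @export
seeded_local_search <- function(query, subject,
                                scheme = scoring_preset("seed-search"),
                                n_database = NULL) {
  if (is.list(query)) query <- query$residues
  if (is.list(subject)) subject <- subject$residues
  m <- nchar(query); n <- nchar(subject)
  if (m < scheme$word_size)
    stop("query shorter than word size (", scheme$word_size, ")")
  if (n == 0) stop("empty subject")
  n_db <- n_database %||% n

  qmask <- if (scheme$mask_low_complexity)
    mask_low_complexity(query) else logical(0)

  trigger <- min(scheme$word_size * scheme$match,
                 score_floor(m, n_db, scheme) * 0.6)

  run_strand <- function(subj, strand) {
    raw <- cpp_seeded_search(query, subj, scheme$match, scheme$mismatch,
                             scheme$gap_open, scheme$gap_extend,
                             scheme$word_size, scheme$x_dropoff,
                             scheme$gapped_x_dropoff, trigger, qmask)
    if (nrow(raw) == 0) return(.empty_hits())
    raw <- unique(raw)
    alns <- lapply(seq_len(nrow(raw)), function(i) {
      qs <- substr(query, raw$q1[i], raw$q2[i])
      ss <- substr(subj, raw$s1[i], raw$s2[i])
      if (as.numeric(nchar(qs)) * nchar(ss) > 2e7) {
        # very large extents arise only from (near-)identical segments,
        # e.g. the trivial self-match of a self-comparison; score them
        # gaplessly rather than running a quadratic DP
        w <- min(nchar(qs), nchar(ss))
        q1 <- substr(qs, 1, w); s1 <- substr(ss, 1, w)
        mm <- sum(charToRaw(q1) != charToRaw(s1))
        list(score = (w - mm) * scheme$match + mm * scheme$mismatch,
             a_aln = q1, b_aln = s1)
      } else cpp_global_align(qs, ss, scheme$match, scheme$mismatch,
                              scheme$gap_open, scheme$gap_extend, FALSE)
    })
    s1 <- raw$s1; s2 <- raw$s2
    if (strand == "-") { # map coordinates back to the plus strand
      s1 <- n - raw$s2 + 1L; s2 <- n - raw$s1 + 1L
    }
    data.frame(q_start = raw$q1, q_end = raw$q2,
               s_start = s1, s_end = s2, strand = strand,
               raw_score = vapply(alns, `[[`, numeric(1), "score"),
               e_value = NA_real_,
               identity_pct = vapply(alns, function(al)
                 percent_identity(al, exclude_end_gaps = FALSE),
                 numeric(1)),
               aligned_query = vapply(alns, `[[`, character(1), "a_aln"),
               aligned_subject = vapply(alns, `[[`, character(1), "b_aln"),
               stringsAsFactors = FALSE)
  }

  hits <- rbind(run_strand(subject, "+"),
                run_strand(reverse_complement(subject), "-"))
  if (nrow(hits) == 0) return(.empty_hits())
  hits$e_value <- evalue(hits$raw_score, m, n_db, scheme)
  hits <- hits[hits$e_value <= scheme$e_max, , drop = FALSE]
  n_raw <- nrow(hits)
  hits <- .cull_hits(hits)
  hits <- hits[order(hits$s_start, hits$s_end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_raw") <- n_raw
  hits
}

#' Global alignment with free end gaps
#'
#' Optimal Needleman-Wunsch alignment with affine gap costs and zero-cost
#' terminal gaps, deterministic tie-breaking (diagonal, then gap in
#' \code{b}, then gap in \code{a}).
#'
#' @param a,b non-empty residue strings
#' @param params list with match, mismatch, gap_open, gap_extend
#'   (see [global_preset()])
#' @return list with \code{score}, gapped \code{aligned_a}/\code{aligned_b},
#'   \code{identity_pct} (end gaps excluded) and \code{end_gap_spans}
#'   (lengths of the four terminal gap runs: a-left, a-right, b-left,
#'   b-right)
#' @export
global_align_free_end <- function(a, b, params = global_preset("element")) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input to global alignment")
  al <- cpp_global_align(a, b, params$match, params$mismatch,
                        params$gap_open, params$gap_extend, TRUE)
  res <- list(aligned_a = al$a_aln, aligned_b = al$b_aln, score = al$score)
  res$end_gap_spans <- .end_gap_spans(al$a_aln, al$b_aln)
  res$identity_pct <- percent_identity(list(a_aln = al$a_aln,
                                            b_aln = al$b_aln))
  res
}

.end_gap_spans <- function(aa, bb) {
  runlen <- function(x, pattern) {
    m <- regexpr(pattern, x)
    if (m[1] == -1L) 0L else attr(m, "match.length")
  }
  list(a = c(left = runlen(aa, "^-+"), right = runlen(aa, "-+$")),
       b = c(left = runlen(bb, "^-+"), right = runlen(bb, "-+$")))
}

#' Percent identity of an alignment
#'
#' Identical columns divided by counted columns, times 100. Terminal-gap
#' columns are excluded by default; internal gap columns count as
#' non-identical.
#'
#' @param alignment list with gapped strings \code{a_aln}/\code{b_aln} (or
#'   \code{aligned_a}/\code{aligned_b})
#' @param exclude_end_gaps drop terminal gap columns before counting?
#' @return identity in [0, 100]
#' @export
percent_identity <- function(alignment, exclude_end_gaps = TRUE) {
  aa <- alignment$a_aln %||% alignment$aligned_a
  bb <- alignment$b_aln %||% alignment$aligned_b
  stopifnot(nchar(aa) == nchar(bb))
  a <- charToRaw(aa)
  b <- charToRaw(bb)
  gapc <- charToRaw("-")
  use <- rep(TRUE, length(a))
  if (exclude_end_gaps && length(a)) {
    gap <- a == gapc | b == gapc
    first <- which(!gap)[1]
    if (is.na(first)) stop("alignment has no aligned columns")
    last <- max(which(!gap))
    use[seq_along(a) < first | seq_along(a) > last] <- FALSE
  }
  n <- sum(use)
  if (n == 0) stop("no counted columns in alignment")
  100 * sum(a[use] == b[use] & a[use] != gapc) / n
}
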