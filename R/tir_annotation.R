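# TIR delineation and motif-grammar annotation. A candidate's TIRs are
# delineated by aligning its sequence window against its own reverse
# complement (the pairwise-BLAST approach: the best inverted local hit with
# one end anchored near each terminus); the composite-TIR grammar -- the
# asymmetric terminal motifs A1/A2 exterior to the TIR, the 3 bp Motif B,
# tandem Motif C units and the purine-rich Motif D -- is then annotated on
# the oriented element.

#' Delineate the terminal inverted repeats of a candidate element
#'
#' Searches the window against its reverse complement with the
#' TIR-delineation preset (word size 11) and keeps the best hit whose two
#' intervals are non-overlapping, ordered, and anchored near the candidate
#' termini. If nothing seeds at word size 11 (short or diverged TIRs) the
#' search is retried at \code{fallback_word}.
#'
#' @param seq window sequence (candidate span plus >= 50 bp flanks)
#' @param cand_start,cand_end candidate bounds relative to \code{seq}
#'   (1-based); defaults to the whole window
#' @param preset TIR-delineation [scoring_scheme()]
#' @param left_anchor,right_anchor optional intervals (start, end) relative
#'   to \code{seq} that the self-hit must overlap on each side -- normally
#'   the seed-hit cluster spans, which by construction lie inside the true
#'   TIRs; defaults to \code{anchor_slack} around the candidate termini
#' @param anchor_slack terminus slack in bp used when no cluster anchors
#'   are given
#' @param min_score minimum self-hit raw score to call the TIRs resolved
#' @param fallback_word word size for the rescue pass (NULL disables)
#' @return list with \code{resolved}, \code{left_tir}/\code{right_tir}
#'   (start, end), \code{tir_identity_pct}, \code{score} and the aligned
#'   strings; unresolved candidates have \code{resolved = FALSE}
#' @export
delineate_tirs <- function(seq, cand_start = 1L, cand_end = nchar(seq),
                           preset = scoring_preset("tir-delineation"),
                           left_anchor = NULL, right_anchor = NULL,
                           anchor_slack = 80L, min_score = 14,
                           fallback_word = 7L) {
  la <- left_anchor %||% c(max(1L, cand_start - anchor_slack),
                           cand_start + anchor_slack)
  ra <- right_anchor %||% c(cand_end - anchor_slack,
                            min(nchar(seq), cand_end + anchor_slack))
  pick <- function(scheme) {
    hits <- seeded_local_search(seq, seq, scheme)
    hits <- hits[hits$strand == "-", , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    ok <- hits$q_end < hits$s_start &
      hits$q_start <= la[2] & hits$q_end >= la[1] &
      hits$s_start <= ra[2] & hits$s_end >= ra[1] &
      hits$raw_score >= min_score
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    hits[which.max(hits$raw_score), , drop = FALSE]
  }
  best <- pick(preset)
  if (is.null(best) && !is.null(fallback_word))
    best <- pick(scoring_preset("tir-delineation", word_size = fallback_word))
  if (is.null(best))
    return(list(resolved = FALSE, left_tir = NULL, right_tir = NULL,
                tir_identity_pct = NA_real_, score = NA_real_))
  list(resolved = TRUE,
       left_tir = c(best$q_start, best$q_end),
       right_tir = c(best$s_start, best$s_end),
       tir_identity_pct = best$identity_pct,
       score = best$raw_score,
       aligned_left = best$aligned_query,
       aligned_right = best$aligned_subject)
}

# scan `seq` for `motif` with <= k mismatches over a start-position range;
# returns best start (fewest mismatches; ties broken by `tie`)
.scan_motif <- function(seq, motif, from, to, k,
                        tie = c("largest", "smallest")) {
  tie <- match.arg(tie)
  w <- nchar(motif)
  from <- max(1L, from); to <- min(nchar(seq) - w + 1L, to)
  if (from > to) return(NULL)
  starts <- from:to
  subs <- substring(seq, starts, starts + w - 1L)
  mm <- vapply(subs, function(s)
    sum(strsplit(s, "")[[1]] != strsplit(motif, "")[[1]]), numeric(1),
    USE.NAMES = FALSE)
  hit <- which(mm <= k)
  if (length(hit) == 0L) return(NULL)
  best <- hit[mm[hit] == min(mm[hit])]
  i <- if (tie == "largest") max(best) else min(best)
  list(start = starts[i], end = starts[i] + w - 1L, seq = subs[i],
       mismatches = mm[i])
}

#' Locate the asymmetric terminal motifs A1/A2 and resolve orientation
#'
#' Scans just outside each TIR terminus for Motif A1 (left) and Motif A2
#' (right) in both orientations. When exactly one orientation places A1
#' left/A2 right, the element should be reverse-complemented accordingly
#' (\code{flip}); A2 at both ends is allowed and flagged; when neither motif
#' is found the orientation is kept as given and statuses are
#' \code{"absent"}.
#'
#' @param seq window sequence
#' @param left_edge,right_edge TIR outer bounds (or candidate bounds when
#'   the TIRs are unresolved), relative to \code{seq}
#' @param profile a [motif_profile()]
#' @param max_mismatch mismatch budget per 7 bp motif (default 1)
#' @param scan_window outward rescue-scan width in bp when the motif is not
#'   immediately adjacent (TIR edges from self-alignment can under-call the
#'   longer TIR by whole Motif C units)
#' @return list with \code{flip}, \code{a2_both_ends}, and motif calls
#'   \code{a1}, \code{a2} (status/seq/start/end/mismatches, in the
#'   coordinates of \code{seq} \emph{before} any flip)
#' @export
find_terminal_motifs <- function(seq, left_edge, right_edge, profile,
                                 max_mismatch = 1L, scan_window = 160L) {
  k <- max_mismatch
  slop_in <- 12L
  scan_left <- function(motif)
    .scan_motif(seq, motif, left_edge - nchar(motif) - scan_window,
                left_edge - nchar(motif) + slop_in, k, tie = "largest")
  scan_right <- function(motif)
    .scan_motif(seq, motif, right_edge + 1L - slop_in,
                right_edge + 1L + scan_window, k, tie = "smallest")

  a1_l <- scan_left(profile$a1)            # plus orientation
  a2_r <- scan_right(profile$a2)
  a1_r <- scan_right(reverse_complement(profile$a1))  # minus orientation
  a2_l <- scan_left(reverse_complement(profile$a2))

  # choose the best-scoring consistent interpretation: plus (A1 left, A2
  # right), minus (rc(A2) left, rc(A1) right -> flip), or the recombinant
  # A2-at-both-ends configuration; a perfect motif outscores a chance
  # 1-mismatch match
  sc <- function(x) if (is.null(x)) 0 else nchar(profile$a1) + 1 - x$mismatches
  p_sc <- sc(a1_l) + sc(a2_r)
  m_sc <- sc(a2_l) + sc(a1_r)
  b_sc <- if (!is.null(a2_l) && !is.null(a2_r)) sc(a2_l) + sc(a2_r) else 0
  a2_both <- b_sc > p_sc && b_sc >= m_sc
  flip <- !a2_both && m_sc > p_sc
  call_of <- function(x) {
    if (is.null(x)) list(status = "absent", seq = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         mismatches = NA_integer_)
    else c(list(status = "present"), x)
  }
  list(flip = flip, a2_both_ends = a2_both,
       a1 = call_of(if (flip) a1_r else a1_l),
       a2 = call_of(if (flip) a2_l else a2_r),
       a2_left = call_of(a2_l), a1_right = call_of(a1_r))
}

#' Decompose a TIR into tandem Motif C units
#'
#' Optimal segmentation of the TIR into consecutive units scored against the
#' Motif C consensus by edit distance, via dynamic programming: each
#' position is either part of a unit of length within
#' \code{[min_unit, max_unit]} and edit cost at most \code{max_edit}, or
#' skipped at \code{skip_cost} per residue. The objective minimises total
#' cost, preferring (on ties) segmentations covering more residues with
#' units. The segmentation is a partition: units plus skipped residues
#' reconstruct the input exactly.
#'
#' @param tir_seq TIR sequence
#' @param c_consensus Motif C consensus (12-16 bp core)
#' @param min_unit,max_unit accepted unit length range
#' @param max_edit maximum edit distance of a unit to the consensus
#' @param skip_cost per-residue cost of leaving a residue outside all units
#' @return data.frame of units: start, end, length, sequence, edit,
#'   identity_to_consensus; zero rows when nothing resembles the consensus
#' @export
decompose_motif_c <- function(tir_seq, c_consensus, min_unit = 8L,
                              max_unit = 17L, max_edit = 3,
                              skip_cost = 0.75) {
  L <- nchar(tir_seq)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      sequence = character(), edit = numeric(),
                      identity_to_consensus = numeric(),
                      stringsAsFactors = FALSE)
  if (L < min_unit) return(empty)
  # edit distance of every candidate unit to the consensus
  cost <- matrix(Inf, nrow = L, ncol = max_unit)  # [end, len]
  for (len in min_unit:max_unit) {
    if (len > L) next
    ends <- len:L
    subs <- substring(tir_seq, ends - len + 1L, ends)
    cost[ends, len] <- as.numeric(adist(subs, c_consensus))
  }
  best <- c(0, rep(Inf, L))        # best[i+1] = cost of prefix i
  cover <- c(0, rep(-Inf, L))      # covered residues (tie-break, maximised)
  from <- integer(L + 1)           # unit length used at i (0 = skip)
  for (i in 1:L) {
    b <- best[i] + skip_cost; cv <- cover[i]; f <- 0L
    for (len in min_unit:max_unit) {
      if (i - len < 0) break
      ed <- cost[i, len]
      if (ed > max_edit) next
      cand <- best[i - len + 1L] + ed
      ccov <- cover[i - len + 1L] + len
      if (cand < b - 1e-9 || (abs(cand - b) <= 1e-9 && ccov > cv)) {
        b <- cand; cv <- ccov; f <- len
      }
    }
    best[i + 1L] <- b; cover[i + 1L] <- cv; from[i + 1L] <- f
  }
  units <- list()
  i <- L
  while (i > 0) {
    len <- from[i + 1L]
    if (len == 0L) { i <- i - 1L; next }
    s <- i - len + 1L
    sq <- substr(tir_seq, s, i)
    ed <- cost[i, len]
    alen <- max(len, nchar(c_consensus))
    units[[length(units) + 1L]] <- data.frame(
      start = s, end = i, length = len, sequence = sq, edit = ed,
      identity_to_consensus = 100 * (alen - ed) / alen,
      stringsAsFactors = FALSE)
    i <- s - 1L
  }
  if (length(units) == 0L) return(empty)
  out <- do.call(rbind, rev(units))
  rownames(out) <- NULL
  out
}

#' Locate Motif B at the TIR termini
#'
#' Motif B is the 3 bp sequence immediately internal to A1/A2, i.e. at the
#' very start of the left TIR and (reverse-complemented) at the very end of
#' the right TIR. Being only 3 bp it is matched exactly.
#'
#' @param seq element (oriented) sequence
#' @param tir_left,tir_right TIR intervals (start, end) in \code{seq}
#' @param profile a [motif_profile()]
#' @return list with \code{left} and \code{right} calls (status, seq,
#'   start, end)
#' @export
find_motif_b <- function(seq, tir_left, tir_right, profile) {
  b <- profile$b; w <- nchar(b)
  left <- .scan_motif(seq, b, tir_left[1] - 2L, tir_left[1] + 2L, 0L,
                      tie = "smallest")
  right <- .scan_motif(seq, reverse_complement(b),
                       tir_right[2] - w + 1L - 2L, tir_right[2] - w + 1L + 2L,
                       0L, tie = "largest")
  stat <- function(x) if (is.null(x))
    list(status = "absent", seq = NA_character_, start = NA_integer_,
         end = NA_integer_) else c(list(status = "present"), x)
  list(left = stat(left), right = stat(right))
}

#' Locate Motif D near the inner end of a TIR
#'
#' Scans the TIR (plus a short inward margin) for the purine-rich Motif D
#' core with a mismatch budget of 2, which tolerates the species variants of
#' the motif. For the right TIR pass the reverse complement of its sequence
#' so the motif reads in TIR orientation.
#'
#' @param tir_seq TIR sequence read in left-TIR orientation
#' @param profile a [motif_profile()]
#' @param max_mismatch mismatch budget (default \code{profile$d_max_mismatch})
#' @return call list (status, seq, start, end, mismatches), coordinates
#'   relative to \code{tir_seq}
#' @export
find_motif_d <- function(tir_seq, profile = motif_profile(),
                         max_mismatch = profile$d_max_mismatch) {
  hit <- .scan_motif(tir_seq, profile$d_core, 1L, nchar(tir_seq),
                     max_mismatch, tie = "largest")
  if (is.null(hit))
    return(list(status = "absent", seq = NA_character_,
                start = NA_integer_, end = NA_integer_,
                mismatches = NA_integer_))
  c(list(status = "present"), hit)
}

# -- per-candidate annotation ------------------------------------------------

.mirror_interval <- function(iv, W) if (is.null(iv)) NULL else c(W - iv[2] + 1L, W - iv[1] + 1L)

#' Annotate a candidate element
#'
#' Runs TIR delineation, orientation normalisation (so Motif A1 is left),
#' terminal/B/C/D motif annotation and TSD detection on one candidate, and
#' assembles a \code{tm1_element} record with contig coordinates.
#'
#' @param candidate one row of the candidates data.frame from
#'   [call_elements()]
#' @param record the contig record (from [read_fasta()])
#' @param profile a [motif_profile()]
#' @param tir_preset TIR-delineation [scoring_scheme()]
#' @param flank window flank in bp around the candidate span
#' @param tsd_len_range,tsd_max_mismatch TSD search settings (see
#'   [detect_tsd()])
#' @return a \code{tm1_element} list; \code{$resolved} is TRUE when either
#'   the TIR self-hit or both terminal motifs support the element
#' @export
annotate_element <- function(candidate, record, profile = motif_profile(),
                             tir_preset = scoring_preset("tir-delineation"),
                             flank = 200L, tsd_len_range = c(7L, 12L),
                             tsd_max_mismatch = 1L) {
  clen <- nchar(record$residues)
  ws <- max(1L, candidate$start - flank)
  we <- min(clen, candidate$end + flank)
  win <- substr(record$residues, ws, we)
  W <- nchar(win)
  rel_s <- candidate$start - ws + 1L
  rel_e <- candidate$end - ws + 1L
  # seed-cluster anchor intervals (inside the true TIRs), window-relative
  lanch <- if (!is.null(candidate$lc_start))
    c(candidate$lc_start - ws + 1L, candidate$lc_end - ws + 1L) else NULL
  ranch <- if (!is.null(candidate$rc_start))
    c(candidate$rc_start - ws + 1L, candidate$rc_end - ws + 1L) else NULL

  analyse <- function(seq, cs, ce, la, ra) {
    del <- delineate_tirs(seq, cs, ce, preset = tir_preset,
                          left_anchor = la, right_anchor = ra)
    le <- if (del$resolved) del$left_tir[1] else cs
    re <- if (del$resolved) del$right_tir[2] else ce
    tm <- find_terminal_motifs(seq, le, re, profile)
    list(del = del, tm = tm, le = le, re = re)
  }

  mirror <- function(iv) if (is.null(iv)) NULL else c(W - iv[2] + 1L, W - iv[1] + 1L)
  a <- analyse(win, rel_s, rel_e, lanch, ranch)
  flipped <- isTRUE(a$tm$flip)
  if (flipped) {
    win <- reverse_complement(win)
    a <- analyse(win, W - rel_e + 1L, W - rel_s + 1L,
                 mirror(ranch), mirror(lanch))
  }
  del <- a$del; tm <- a$tm

  tir_l <- if (del$resolved) del$left_tir else c(a$le, a$le)
  tir_r <- if (del$resolved) del$right_tir else c(a$re, a$re)

  el_start <- if (tm$a1$status == "present") tm$a1$start else tir_l[1]
  el_end <- if (tm$a2$status == "present") tm$a2$end else tir_r[2]

  # TIR outer edges sit immediately internal to the terminal motifs
  lstart <- if (tm$a1$status == "present") tm$a1$end + 1L else tir_l[1]
  rend <- if (tm$a2$status == "present") tm$a2$start - 1L else tir_r[2]

  # Motif grammar is annotated over a terminal window per end (the
  # self-alignment extent can under-call the longer TIR by whole Motif C
  # units, or chain into an internal inverted repeat); the window is large
  # enough for B + 9 C units + D + C but never reaches the opposite end.
  el_len <- el_end - el_start + 1L
  w_dec <- min(180L, max(20L, (el_len - 20L) %/% 2L))
  lwin_end <- min(W, lstart + w_dec - 1L)
  rwin_start <- max(1L, rend - w_dec + 1L)
  lwin <- substr(win, lstart, lwin_end)
  rwin <- reverse_complement(substr(win, rwin_start, rend))

  cr <- profile$c_len_range
  # units must form a tandem block; a gap of up to ~Motif D (plus slack)
  # between consecutive units is allowed, anything further inward is
  # payload sequence that happens to resemble the consensus
  trim_chain <- function(u, max_gap = 16L) {
    if (nrow(u) <= 1L) return(u)
    gaps <- u$start[-1] - u$end[-nrow(u)] - 1L
    brk <- which(gaps > max_gap)
    if (length(brk)) u[seq_len(brk[1]), , drop = FALSE] else u
  }
  c_left <- trim_chain(decompose_motif_c(lwin, profile$c, cr[1], cr[2]))
  c_right <- trim_chain(decompose_motif_c(rwin, profile$c, cr[1], cr[2]))
  d_left <- find_motif_d(lwin, profile)
  d_right <- find_motif_d(rwin, profile)

  # reported TIRs trimmed to the grammar: outer edge to the innermost
  # annotated motif (C unit or D), at least the 3 bp of Motif B
  inner_l <- max(c(3L, c_left$end, if (d_left$status == "present") d_left$end))
  inner_r <- max(c(3L, c_right$end, if (d_right$status == "present") d_right$end))
  inner_l <- min(inner_l, nchar(lwin))
  inner_r <- min(inner_r, nchar(rwin))
  tir_l <- c(lstart, lstart + inner_l - 1L)
  tir_r <- c(rend - inner_r + 1L, rend)

  ltir_seq <- substr(win, tir_l[1], tir_l[2])
  rtir_seq <- substr(win, tir_r[1], tir_r[2])
  bcall <- find_motif_b(win, tir_l, tir_r, profile)

  both <- tm$a1$status == "present" && tm$a2$status == "present"
  none <- tm$a1$status == "absent" && tm$a2$status == "absent" &&
    !isTRUE(tm$a2_both_ends)
  if (both) {
    lf <- substr(win, max(1L, el_start - 15L), el_start - 1L)
    rf <- substr(win, el_end + 1L, min(W, el_end + 15L))
    tsd <- detect_tsd(lf, rf, len_range = tsd_len_range,
                      max_mismatch = tsd_max_mismatch)
  } else if (none) {
    tsd <- list(status = "n.f.", length = NA_integer_,
                left_seq = NA_character_, right_seq = NA_character_,
                mismatch_positions = integer())
  } else {
    tsd <- list(status = "n.a.", length = NA_integer_,
                left_seq = NA_character_, right_seq = NA_character_,
                mismatch_positions = integer())
  }

  internal <- c(tir_l[2] + 1L, tir_r[1] - 1L)
  internal_seq <- if (internal[1] <= internal[2])
    substr(win, internal[1], internal[2]) else ""

  # map window coordinates back to the contig plus strand
  map <- function(p) if (flipped) we - p + 1L else ws + p - 1L
  span <- sort(c(map(el_start), map(el_end)))

  # motif child features in contig coordinates (left-window motifs are
  # window-forward; right-window motifs were annotated on the reverse
  # complement of [rwin_start, rend] and map back through rend)
  mot <- list()
  add_mot <- function(name, s, e) {
    iv <- sort(c(map(s), map(e)))
    mot[[length(mot) + 1L]] <<- data.frame(name = name, start = iv[1],
                                           end = iv[2],
                                           stringsAsFactors = FALSE)
  }
  if (tm$a1$status == "present") add_mot("A1", tm$a1$start, tm$a1$end)
  if (tm$a2$status == "present") add_mot("A2", tm$a2$start, tm$a2$end)
  if (bcall$left$status == "present")
    add_mot("B", bcall$left$start, bcall$left$end)
  if (bcall$right$status == "present")
    add_mot("B", bcall$right$start, bcall$right$end)
  lmap <- function(p) lstart + p - 1L          # lwin -> win
  rmap <- function(p) rend - p + 1L            # rwin (rc) -> win
  if (nrow(c_left)) for (k in seq_len(nrow(c_left)))
    add_mot("C", lmap(c_left$start[k]), lmap(c_left$end[k]))
  if (nrow(c_right)) for (k in seq_len(nrow(c_right)))
    add_mot("C", rmap(c_right$end[k]), rmap(c_right$start[k]))
  if (d_left$status == "present")
    add_mot("D", lmap(d_left$start), lmap(d_left$end))
  if (d_right$status == "present")
    add_mot("D", rmap(d_right$end), rmap(d_right$start))
  motif_intervals <- if (length(mot)) do.call(rbind, mot) else
    data.frame(name = character(), start = integer(), end = integer())

  el <- list(
    contig = record$id,
    start = span[1], end = span[2],
    orientation = if (flipped) "-" else "+",
    flipped = flipped,
    # a supported element needs terminal-motif evidence: both motifs, or a
    # resolved TIR self-hit plus at least one motif (chance pairings and
    # chimeric inner-cluster pairings have resolved-looking inverted
    # repeats but no terminal motifs)
    resolved = both || isTRUE(tm$a2_both_ends) ||
      (del$resolved && (tm$a1$status == "present" ||
                          tm$a2$status == "present")),
    tir_resolved = del$resolved,
    tir_identity = del$tir_identity_pct,
    tir_left = sort(c(map(tir_l[1]), map(tir_l[2]))),
    tir_right = sort(c(map(tir_r[1]), map(tir_r[2]))),
    a1 = tm$a1, a2 = tm$a2, a2_both_ends = tm$a2_both_ends,
    b_left = bcall$left, b_right = bcall$right,
    c_units_left = c_left, c_units_right = c_right,
    d_left = d_left, d_right = d_right,
    motif_intervals = motif_intervals,
    tsd = tsd,
    internal_seq = internal_seq,
    element_seq = substr(win, el_start, el_end),
    nested = list(), notes = "")
  class(el) <- "tm1_element"
  el
}

#' Annotate all candidates of a discovery run
#'
#' @param candidates candidates data.frame from [call_elements()]
#' @param genome list of records from [read_fasta()]
#' @param ... passed to [annotate_element()]
#' @param keep_unresolved keep candidates whose TIRs could not be resolved
#'   and that lack both terminal motifs? Default FALSE (they are returned in
#'   the \code{unresolved} attribute instead)
#' @return list of \code{tm1_element}
#' @export
annotate_elements <- function(candidates, genome, ...,
                              keep_unresolved = FALSE) {
  if (is.character(genome))
    genome <- lapply(names(genome), function(n)
      list(id = n, residues = unname(genome[[n]])))
  names(genome) <- vapply(genome, function(r) r$id, character(1))
  els <- lapply(seq_len(nrow(candidates)), function(i)
    annotate_element(candidates[i, ], genome[[candidates$contig[i]]], ...))
  resolved <- vapply(els, function(e) isTRUE(e$resolved), logical(1))
  out <- if (keep_unresolved) els else els[resolved]
  out <- .dedupe_elements(out)
  attr(out, "unresolved") <- els[!resolved]
  out
}

# distinct candidate hypotheses (e.g. the two strand-split cluster pairs of
# one element) can converge on the same element bounds; keep one record
.dedupe_elements <- function(els, min_overlap = 0.95) {
  if (length(els) <= 1L) return(els)
  keep <- logical(length(els))
  score <- vapply(els, function(e)
    (e$end - e$start + 1) + 1e6 * isTRUE(e$tir_resolved), numeric(1))
  for (i in order(-score)) {
    dup <- FALSE
    for (j in which(keep)) {
      if (els[[i]]$contig != els[[j]]$contig) next
      ov <- min(els[[i]]$end, els[[j]]$end) -
        max(els[[i]]$start, els[[j]]$start) + 1
      if (ov <= 0) next
      rec <- min(ov / (els[[i]]$end - els[[i]]$start + 1),
                 ov / (els[[j]]$end - els[[j]]$start + 1))
      if (rec >= min_overlap) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  els[keep]
}
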