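# Element classification. Classes are assigned from internal-sequence
# features: coverage of a user-supplied autonomous-element reference (with a
# named MULE-domain region) separates putative autonomous elements (Tm1-A)
# from their deletion derivatives (Tm1-D); a histone-hairpin motif defines
# Tm1-HH; a short internal inverted repeat defines the MITE-like class
# (Tm1-ML); everything else is "other". Nested insertions are found as
# large alignment gaps against a class exemplar.

#' Scan for histone-hairpin stem-loops
#'
#' Reports every window folding into a stem-loop with stem length at least
#' \code{min_stem}, loop length within \code{loop_range} and at most
#' \code{max_mismatch} non-complementary stem pairs. The ~16 nt
#' replication-dependent histone hairpin (6 bp stem, 4 nt loop) is the
#' motif of interest; passing its consensus as \code{profile} additionally
#' requires a sequence match with at most \code{profile_max_mismatch}
#' mismatches, which suppresses the incidental stem-loops any random
#' sequence contains.
#'
#' @param seq residue string
#' @param min_stem minimum stem arm length (bp)
#' @param loop_range loop length range (nt)
#' @param max_mismatch allowed non-complementary stem pairs
#' @param max_stem longest stem arm reported
#' @param profile optional hairpin sequence consensus (default
#'   [histone_hairpin_consensus()]; NULL disables the sequence filter)
#' @param profile_max_mismatch mismatch budget for the profile match
#' @return data.frame of hits: start, end, stem_length, loop_length,
#'   stem_mismatches, ordered by score (stem length minus mismatches) then
#'   position
#' @export
scan_histone_hairpin <- function(seq, min_stem = 6L, loop_range = c(3L, 6L),
                                 max_mismatch = 1L, max_stem = 10L,
                                 profile = histone_hairpin_consensus(),
                                 profile_max_mismatch = 3L) {
  empty <- data.frame(start = integer(), end = integer(),
                      stem_length = integer(), loop_length = integer(),
                      stem_mismatches = integer())
  n <- nchar(seq)
  if (n < 2L * min_stem + loop_range[1]) return(empty)
  ch <- strsplit(seq, "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  hits <- list()
  for (start in 1L:(n - 2L * min_stem - loop_range[1] + 1L)) {
    for (loop in loop_range[1]:loop_range[2]) {
      # for stem length s the window is [start, start + 2s + loop - 1];
      # stem pair t (1..s) is position start + t - 1 against
      # position start + 2s + loop - t
      smax <- min(max_stem, (n - start + 1L - loop) %/% 2L)
      if (smax < min_stem) next
      best <- NULL
      for (s in min_stem:smax) {
        end <- start + 2L * s + loop - 1L
        if (end > n) break
        mm <- 0L
        for (t in 1:s) {
          lpos <- start + t - 1L
          rpos <- start + 2L * s + loop - t
          if (ch[lpos] == "N" || ch[rpos] == "N" ||
              comp[lpos] != ch[rpos]) mm <- mm + 1L
        }
        if (mm <= max_mismatch)
          best <- data.frame(start = start, end = end, stem_length = s,
                             loop_length = loop, stem_mismatches = mm)
      }
      if (!is.null(best)) hits[[length(hits) + 1L]] <- best
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  if (!is.null(profile)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      w <- nchar(profile)
      lo <- max(1L, out$start[i] - 3L); hi <- min(n - w + 1L, out$start[i] + 3L)
      if (lo > hi) return(FALSE)
      !is.null(.scan_motif(seq, profile, lo, hi, profile_max_mismatch))
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) return(empty)
  score <- out$stem_length - out$stem_mismatches
  out <- out[order(-score, out$start, out$loop_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus of the metazoan replication-dependent histone hairpin
#'
#' The 16 nt stem-loop (6 bp stem, 4 nt loop) found in histone mRNA 3'
#' ends, and carried by Tm1-HH elements.
#'
#' @return character scalar
#' @export
histone_hairpin_consensus <- function() "GGCTCTTTTCAGAGCC"

#' Detect an internal inverted repeat (MITE-like payload)
#'
#' Local search of the internal sequence against its reverse complement
#' (TIRs must already be excluded); reports the best non-overlapping
#' inverted-repeat pair above \code{min_score}.
#'
#' @param internal_seq internal (between-TIR) sequence
#' @param preset [scoring_scheme()] (default TIR-delineation preset)
#' @param min_score minimum raw score (default 25)
#' @return list with intervals \code{arm1}, \code{arm2} and \code{score},
#'   or NULL if none
#' @export
detect_internal_ir <- function(internal_seq,
                               preset = scoring_preset("tir-delineation"),
                               min_score = 25) {
  if (nchar(internal_seq) < 2L * preset$word_size) return(NULL)
  hits <- tryCatch(seeded_local_search(internal_seq, internal_seq, preset),
                   error = function(e) NULL)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[hits$strand == "-" & hits$raw_score >= min_score, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  b <- hits[which.max(hits$raw_score), ]
  if (b$q_end < b$s_start) {
    list(arm1 = c(b$q_start, b$q_end), arm2 = c(b$s_start, b$s_end),
         score = b$raw_score)
  } else {
    # a short spacer lets the extension run arm-spacer-arm into a single
    # self-palindromic hit; split it at its centre
    mid <- (b$q_start + b$s_end) %/% 2L
    list(arm1 = c(min(b$q_start, b$s_start), mid),
         arm2 = c(mid + 1L, max(b$q_end, b$s_end)),
         score = b$raw_score)
  }
}

#' Six-frame ORF scan
#'
#' All open reading frames from a start codon (ATG) to an in-frame stop, at
#' least \code{min_aa} amino acids (Met included, stop excluded), on both
#' strands of the standard genetic code.
#'
#' @param seq residue string
#' @param min_aa minimum ORF length in amino acids (default 50)
#' @return data.frame: start, end (1-based on the plus strand, inclusive of
#'   the stop codon), strand, frame (1-3), length_aa
#' @export
scan_orfs <- function(seq, min_aa = 50L) {
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_aa = integer())
  n <- nchar(seq)
  if (n < (min_aa + 1L) * 3L) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (frame in 1:3) {
      starts <- seq(frame, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      open_at <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open_at) && codons[i] == "ATG") open_at <- i
        if (!is.na(open_at) && codons[i] %in% stops) {
          aa <- i - open_at
          if (aa >= min_aa) {
            a <- starts[open_at]; b <- starts[i] + 2L
            if (strand == "-") { tmp <- a; a <- n - b + 1L; b <- n - tmp + 1L }
            out[[length(out) + 1L]] <- data.frame(
              start = a, end = b, strand = strand, frame = frame,
              length_aa = aa, stringsAsFactors = FALSE)
          }
          open_at <- NA_integer_
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$strand, res$frame), , drop = FALSE]
}

# union length of 1-based intervals, via IRanges
.interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
}

.region_coverage <- function(starts, ends, rs, re) {
  if (length(starts) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
  ov <- IRanges::restrict(ir, start = rs, end = re)
  sum(IRanges::width(ov)) / (re - rs + 1L)
}

#' Coverage of a reference internal sequence by an element's interior
#'
#' Local hits of the element interior against the reference are projected
#' onto the reference; per-region coverage fractions are reported, including
#' whether the MULE-domain region is covered.
#'
#' @param internal_seq element internal sequence
#' @param reference reference residues (e.g. the autonomous-element internal
#'   region / transposase CDS)
#' @param regions optional data.frame (name, start, end) of named reference
#'   regions; a region named \code{"MULE_domain"} drives the
#'   \code{mule_covered} flag
#' @param preset [scoring_scheme()] for the local search
#' @param min_identity per-hit identity floor in percent (default 70)
#' @return list: \code{total} coverage fraction of the reference,
#'   \code{regions} named vector of per-region fractions,
#'   \code{mule_fraction}, \code{mule_covered} (fraction >= 0.5)
#' @export
reference_similarity <- function(internal_seq, reference, regions = NULL,
                                 preset = scoring_preset("tir-delineation"),
                                 min_identity = 70) {
  if (is.list(reference)) reference <- reference$residues
  hits <- if (nchar(internal_seq) >= preset$word_size)
    seeded_local_search(internal_seq, reference, preset) else .empty_hits()
  hits <- hits[hits$identity_pct >= min_identity, , drop = FALSE]
  rl <- nchar(reference)
  total <- .interval_union_length(hits$s_start, hits$s_end) / rl
  regs <- numeric(0)
  mule <- NA_real_
  if (!is.null(regions) && nrow(regions)) {
    regs <- vapply(seq_len(nrow(regions)), function(i)
      .region_coverage(hits$s_start, hits$s_end, regions$start[i],
                       regions$end[i]), numeric(1))
    names(regs) <- regions$name
    if ("MULE_domain" %in% regions$name) mule <- regs[["MULE_domain"]]
  }
  list(total = total, regions = regs, mule_fraction = mule,
       mule_covered = !is.na(mule) && mule >= 0.5)
}

#' Classify an element
#'
#' Fixed-order rules over the computed features: (1) MULE-region coverage
#' >= 0.5 and total reference coverage >= 0.8 is the putative autonomous
#' class Tm1-A; (2) reference coverage >= 0.2 with the MULE region uncovered
#' is a deletion derivative, Tm1-D; (3) a histone-hairpin hit is Tm1-HH;
#' (4) an internal inverted repeat in a short interior (<= 600 bp) is the
#' MITE-like class Tm1-ML; (5) otherwise "other". Exactly one label is
#' always assigned, with the supporting evidence recorded.
#'
#' @param element a \code{tm1_element} (from [annotate_element()])
#' @param references optional list with \code{reference} (residues) and
#'   \code{regions} (data.frame name/start/end); without it the A/D classes
#'   are unreachable
#' @param hairpin_args,ir_args overrides for [scan_histone_hairpin()] and
#'   [detect_internal_ir()]
#' @param ml_max_internal Tm1-ML internal length ceiling (default 600)
#' @return the element with \code{$class}, \code{$evidence} and feature
#'   fields filled in
#' @export
classify_element <- function(element, references = NULL,
                             hairpin_args = list(), ir_args = list(),
                             ml_max_internal = 600L) {
  int <- element$internal_seq
  ev <- character(0)
  cov <- NULL
  if (!is.null(references)) {
    cov <- reference_similarity(int, references$reference,
                                references$regions)
  }
  hp <- do.call(scan_histone_hairpin, c(list(int), hairpin_args))
  ir <- do.call(detect_internal_ir, c(list(int), ir_args))
  orfs <- scan_orfs(int, min_aa = 50L)

  label <- "other"
  if (!is.null(cov) && cov$mule_covered && cov$total >= 0.8) {
    label <- "Tm1-A"
    ev <- c(ev, sprintf("reference coverage %.2f", cov$total),
            sprintf("MULE region coverage %.2f", cov$mule_fraction))
  } else if (!is.null(cov) && cov$total >= 0.2 &&
             (is.na(cov$mule_fraction) || cov$mule_fraction < 0.1)) {
    label <- "Tm1-D"
    ev <- c(ev, sprintf("reference patch coverage %.2f", cov$total),
            "MULE region uncovered")
  } else if (nrow(hp) > 0L) {
    label <- "Tm1-HH"
    ev <- c(ev, sprintf("histone hairpin at %d (stem %d, loop %d)",
                        hp$start[1], hp$stem_length[1], hp$loop_length[1]))
  } else if (!is.null(ir) && nchar(int) <= ml_max_internal) {
    label <- "Tm1-ML"
    ev <- c(ev, sprintf("internal inverted repeat score %.0f", ir$score))
  } else {
    ev <- c(ev, "no class feature detected")
  }
  if (nrow(orfs)) ev <- c(ev, sprintf("%d ORF(s) >= 50 aa", nrow(orfs)))
  if (identical(element$d_left$status, "absent") &&
      identical(element$d_right$status, "absent"))
    ev <- c(ev, "Motif D absent")

  element$class <- label
  element$evidence <- ev
  element$features <- list(coverage = cov, hairpins = hp, internal_ir = ir,
                           orfs = orfs)
  element
}

#' Detect nested insertions relative to a class exemplar
#'
#' Globally aligns the element to a same-class exemplar with free end gaps;
#' runs of >= \code{min_gap} element residues unmatched in the exemplar are
#' flagged as insertions, and each is re-analysed for an internal inverted
#' repeat and its own target site duplication (sought in the immediately
#' flanking element sequence).
#'
#' @param element_seq element residues (oriented)
#' @param exemplar exemplar residues
#' @param min_gap minimum insertion length (default 200)
#' @param params global-alignment parameters
#' @return list of insertions, each with \code{interval} (element
#'   coordinates), \code{own_tsd} (a TSD call or NULL) and
#'   \code{internal_ir}; empty when the element matches the exemplar
#' @export
detect_nested_insertions <- function(element_seq, exemplar, min_gap = 200L,
                                     params = global_preset("element")) {
  al <- global_align_free_end(element_seq, exemplar, params)
  a <- strsplit(al$aligned_a, "")[[1]]
  b <- strsplit(al$aligned_b, "")[[1]]
  # element positions per column
  epos <- cumsum(a != "-")
  gap_in_ex <- b == "-" & a != "-"
  # exclude terminal free-gap columns
  core <- which(!(a == "-" | b == "-"))
  if (length(core)) {
    gap_in_ex[seq_along(a) < min(core)] <- FALSE
    gap_in_ex[seq_along(a) > max(core)] <- FALSE
  }
  r <- rle(gap_in_ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_gap) next
    es <- epos[starts[i]]; ee <- epos[ends[i]]
    ins_seq <- substr(element_seq, es, ee)
    lf <- substr(element_seq, max(1L, es - 15L), es - 1L)
    tail15 <- substr(ins_seq, max(1L, nchar(ins_seq) - 14L), nchar(ins_seq))
    after15 <- substr(element_seq, ee + 1L, min(nchar(element_seq), ee + 15L))
    # the duplicated target can sit at either gap placement the aligner
    # chose: "T [nested T]" (copies: flank suffix / insertion tail or
    # following sequence) or "[T nested] T" (copies: insertion head /
    # following sequence)
    head15 <- substr(ins_seq, 1L, 15L)
    tsd_tail <- detect_tsd(lf, after15)
    tsd_suffix <- .detect_tsd_suffix(lf, tail15)
    tsd_head <- .detect_tsd_prefix(head15, after15)
    cand <- NULL
    for (t in list(tsd_suffix, tsd_tail, tsd_head)) {
      if (identical(t$status, "found") &&
          (is.null(cand) || t$length - length(t$mismatch_positions) >
             cand$length - length(cand$mismatch_positions)))
        cand <- t
    }
    ir <- detect_internal_ir(ins_seq)
    out[[length(out) + 1L]] <- list(interval = c(es, ee), own_tsd = cand,
                                    internal_ir = ir)
  }
  out
}

.rev_string <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# direct-repeat search where both copies are prefixes of their windows
.detect_tsd_prefix <- function(left_prefix_window, right_prefix_window,
                               len_range = c(7L, 12L), max_mismatch = 1L) {
  nf <- list(status = "n.f.", length = NA_integer_,
             left_seq = NA_character_, right_seq = NA_character_,
             mismatch_positions = integer())
  lmax <- min(len_range[2], nchar(left_prefix_window),
              nchar(right_prefix_window))
  if (lmax < len_range[1]) return(nf)
  best <- NULL
  for (len in len_range[1]:lmax) {
    ls <- substr(left_prefix_window, 1L, len)
    rs <- substr(right_prefix_window, 1L, len)
    mm <- which(strsplit(ls, "")[[1]] != strsplit(rs, "")[[1]])
    if (length(mm) > max_mismatch) next
    cand <- list(status = "found", length = len, left_seq = ls,
                 right_seq = rs, mismatch_positions = mm)
    if (is.null(best) || (len - length(mm)) >
        (best$length - length(best$mismatch_positions)) ||
        (len == 9L && best$length != 9L))
      best <- cand
  }
  best %||% nf
}

# direct-repeat search where BOTH copies are suffixes of their windows
.detect_tsd_suffix <- function(left_suffix_window, right_suffix_window,
                               len_range = c(7L, 12L), max_mismatch = 1L) {
  nf <- list(status = "n.f.", length = NA_integer_,
             left_seq = NA_character_, right_seq = NA_character_,
             mismatch_positions = integer())
  lmax <- min(len_range[2], nchar(left_suffix_window),
              nchar(right_suffix_window))
  if (lmax < len_range[1]) return(nf)
  best <- NULL
  for (len in len_range[1]:lmax) {
    ls <- substr(left_suffix_window, nchar(left_suffix_window) - len + 1L,
                 nchar(left_suffix_window))
    rs <- substr(right_suffix_window, nchar(right_suffix_window) - len + 1L,
                 nchar(right_suffix_window))
    mm <- which(strsplit(ls, "")[[1]] != strsplit(rs, "")[[1]])
    if (length(mm) > max_mismatch) next
    cand <- list(status = "found", length = len, left_seq = ls,
                 right_seq = rs, mismatch_positions = mm)
    if (is.null(best) || (len - length(mm)) >
        (best$length - length(best$mismatch_positions)) ||
        (len == 9L && best$length != 9L))
      best <- cand
  }
  best %||% nf
}
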