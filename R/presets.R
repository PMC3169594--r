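# Scoring schemes, Karlin-Altschul statistics, motif profiles and the
# primer table. The two local-search presets reproduce the BLASTN settings
# used to define the Tm1 family; the global presets reproduce the Geneious
# (65% cost matrix) and ClustalW tandem-repeat settings.

# Ungapped Karlin-Altschul K and H for the standard BLASTN reward/penalty
# pairs (NCBI precomputed tables); lambda is solved from the scheme itself.
.ka_table <- data.frame(
  match    = c(1, 1, 1, 2),
  mismatch = c(-3, -2, -1, -3),
  k_const  = c(0.711, 0.460, 0.200, 0.620),
  h_ent    = c(1.31, 0.850, 0.275, 1.12)
)

#' Solve the ungapped Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves \code{sum_ij p_i p_j exp(lambda * s_ij) = 1} under a uniform
#' nucleotide background (p = 1/4 each).
#'
#' @param match match reward (> 0)
#' @param mismatch mismatch score (< 0)
#' @return positive real lambda
#' @export
karlin_lambda <- function(match, mismatch) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

.ka_lookup <- function(match, mismatch) {
  i <- which(.ka_table$match == match & .ka_table$mismatch == mismatch)
  if (length(i) == 1L)
    list(k_const = .ka_table$k_const[i], h_ent = .ka_table$h_ent[i])
  else  # conservative fallback for non-tabulated schemes
    list(k_const = 0.35, h_ent = abs(mismatch) * 0.4)
}

#' Construct a local-search scoring scheme
#'
#' Bundles the match/mismatch rewards, affine gap costs (a gap of length k
#' costs \code{gap_open + k * gap_extend}), seeding word size, X-drop
#' thresholds and E-value statistics used by [seeded_local_search()].
#'
#' @param match,mismatch integer match reward (> 0) and mismatch score (< 0)
#' @param gap_open,gap_extend non-negative gap costs
#' @param word_size exact-word seed length (>= 4)
#' @param x_dropoff ungapped extension X-drop, raw score units
#' @param gapped_x_dropoff gapped extension X-drop, raw score units
#' @param e_max E-value cutoff; hits above it are discarded
#' @param mask_low_complexity mask the query with [mask_low_complexity()]
#'   before seeding?
#' @param lambda_,k_const optional Karlin-Altschul overrides; by default
#'   lambda is solved from the scheme and K taken from the standard tables
#' @return an object of class \code{tm1_scheme}
#' @export
scoring_scheme <- function(match = 1, mismatch = -3, gap_open = 4,
                           gap_extend = 2, word_size = 7,
                           x_dropoff = 20, gapped_x_dropoff = 50,
                           e_max = 10, mask_low_complexity = TRUE,
                           lambda_ = NULL, k_const = NULL) {
  stopifnot(match > 0, mismatch < 0, word_size >= 4, gap_open >= 0,
            gap_extend >= 0, x_dropoff > 0, gapped_x_dropoff > 0, e_max > 0)
  # expected score per aligned pair must be negative for the statistics
  if (0.25 * match + 0.75 * mismatch >= 0)
    stop("expected score per aligned pair is non-negative; ",
         "Karlin-Altschul statistics do not apply")
  ka <- .ka_lookup(match, mismatch)
  s <- list(match = match, mismatch = mismatch, gap_open = gap_open,
            gap_extend = gap_extend, word_size = as.integer(word_size),
            x_dropoff = x_dropoff, gapped_x_dropoff = gapped_x_dropoff,
            e_max = e_max, mask_low_complexity = mask_low_complexity,
            lambda_ = if (is.null(lambda_)) karlin_lambda(match, mismatch) else lambda_,
            k_const = if (is.null(k_const)) ka$k_const else k_const,
            h_ent = ka$h_ent)
  class(s) <- "tm1_scheme"
  s
}

#' Named local-search presets
#'
#' \code{"seed-search"}: word size 7, match/mismatch 1/-3, gap open/extend
#' 4/2, E-value cutoff 10, low-complexity filter on -- the setting used to
#' seed the family-wide TIR search. \code{"tir-delineation"}: word size 11,
#' match/mismatch 1/-2, gap open/extend 5/2, gapped X-drop 50 -- the pairwise
#' (BLAST2-style) setting used to delineate the full extent of the TIRs.
#'
#' @param name preset name
#' @param ... overrides passed to [scoring_scheme()]
#' @return a \code{tm1_scheme}
#' @export
scoring_preset <- function(name = c("seed-search", "tir-delineation"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "seed-search" = list(match = 1, mismatch = -3, gap_open = 4,
                         gap_extend = 2, word_size = 7, e_max = 10,
                         mask_low_complexity = TRUE),
    "tir-delineation" = list(match = 1, mismatch = -2, gap_open = 5,
                             gap_extend = 2, word_size = 11,
                             gapped_x_dropoff = 50, e_max = 10,
                             mask_low_complexity = TRUE))
  over <- list(...)
  args[names(over)] <- over
  do.call(scoring_scheme, args)
}

#' Global (free-end-gap) alignment parameter presets
#'
#' \code{"element"}: the 65% cost matrix used for element-vs-element global
#' alignments (match 5, mismatch -4, gap open 12, extend 3).
#' \code{"motif"}: the ClustalW-style costs used to align Motif C tandem
#' repeat units (gap open 15, extend 6.66; match 1.9, mismatch 0).
#'
#' @param name preset name
#' @return list of match, mismatch, gap_open, gap_extend
#' @export
global_preset <- function(name = c("element", "motif")) {
  name <- match.arg(name)
  switch(name,
    element = list(match = 5, mismatch = -4, gap_open = 12, gap_extend = 3),
    motif   = list(match = 1.9, mismatch = 0, gap_open = 15, gap_extend = 6.66))
}

#' TIR motif grammar profiles
#'
#' Consensus sequences of the composite-TIR motifs. The two species profiles
#' differ in Motif A1, the Motif C core and the Motif D 5' end; Motif A2 and
#' Motif B are shared. \code{d_core} is the species-independent purine-rich
#' core used for mismatch-tolerant Motif D detection. \code{c_len_range} is
#' the accepted Motif C unit-length envelope.
#'
#' @param name \code{"incognita"} (default, also used for unknown genomes)
#'   or \code{"hapla"}
#' @return a list with components a1, a2, b, c, d, d_core, c_len_range,
#'   a_max_mismatch, d_max_mismatch
#' @export
motif_profile <- function(name = c("incognita", "hapla")) {
  name <- match.arg(name)
  base <- list(a2 = "CCTACCC", b = "GGA", d_core = "GGGAAAAGGGGA",
               a_max_mismatch = 1L, d_max_mismatch = 2L)
  sp <- switch(name,
    incognita = list(a1 = "CGGTTAA", c = "CGATTCAGTATCGC",
                     d = "GGGGAAAAGGGGA", c_len_range = c(8L, 17L)),
    hapla     = list(a1 = "CGGATAA", c = "CGTTTCAGTATCGC",
                     d = "GCCAAAAGGGGA", c_len_range = c(12L, 21L)))
  out <- c(base, sp, list(name = name))
  class(out) <- "tm1_motif_profile"
  out
}

#' The 38 bp TIR seed query
#'
#' The composite-TIR fragment (one Motif C unit, Motif D, one Motif C unit)
#' used to seed the genome-wide search for Tm1 elements.
#'
#' @return a character scalar of 38 residues
#' @export
tm1_seed_query <- function() {
  "GATTCAGTATACGGGGAAAAGGGGACGATTCAGTATAC"
}

#' Named PCR primers for Tm1 loci
#'
#' The primer set used for empty-site and element-presence assays at Tm1
#' insertion loci, keyed by name (e.g. \code{"17-F"}, \code{"17-R"},
#' \code{"SG1"}, \code{"SG6"}).
#'
#' @return data.frame with columns \code{name} and \code{sequence}
#' @export
primer_table <- function() {
  data.frame(
    name = c("a5", "a6", "SG1", "SG2", "SG6", "M8-1F", "M8-3R", "M8-6R",
             "MjActin-RT-F", "MjActin-RT-R", "Mj-bActin-F", "Mj-bActin-R",
             "17-F", "17-R"),
    sequence = c("GAGCCGTCCATTTTAAACCA", "GGGTTAAGGTTGTTGTTGCC",
                 "CGAGAATTCTACACTGACAATG", "ACTGAATCGTCCCCTTTTCC",
                 "GATTCAGTATACGGGGAAAAGG", "TGGCTTTCTATATGTTTTTCATGC",
                 "GTAAGTTGCTGTCAGTGCAAGG", "TCAGAATCTGCCAAAAGAAACC",
                 "AAGCCGTTCTTTCTTTGTATGC", "AAGAATAACCACGTTCAGTGAGG",
                 "TAGGTATGTTGCCATCCAAGC", "CAAAGCAGTAATTTCCTTCTGC",
                 "AGAGCTCGGGACTGAAACGTCC", "TCTCCCTCGCCTCATCTCCACG"),
    stringsAsFactors = FALSE)
}

# BLAST-style effective length adjustment: l = ln(K m n) / H, clamped so the
# effective lengths stay positive.
.effective_lengths <- function(m, n, scheme) {
  l <- log(scheme$k_const * m * n) / scheme$h_ent
  m_eff <- max(m - l, 1 / scheme$k_const)
  n_eff <- max(n - l, 1)
  list(m = m_eff, n = n_eff)
}

#' E-value of a raw local alignment score
#'
#' Ungapped Karlin-Altschul E-value \code{E = K m' n' exp(-lambda S)} with
#' the standard effective-length adjustment \code{l = ln(K m n)/H}.
#'
#' @param score raw score(s)
#' @param m query length
#' @param n subject (database) length
#' @param scheme a [scoring_scheme()]
#' @return E-value(s)
#' @export
evalue <- function(score, m, n, scheme) {
  eff <- .effective_lengths(m, n, scheme)
  scheme$k_const * eff$m * eff$n * exp(-scheme$lambda_ * score)
}

#' Raw-score floor equivalent to an E-value cutoff
#'
#' The smallest integer score whose E-value is at most \code{e_max} for a
#' query of length \code{m} against a database of length \code{n}.
#'
#' @inheritParams evalue
#' @return integer score floor
#' @export
score_floor <- function(m, n, scheme) {
  eff <- .effective_lengths(m, n, scheme)
  s <- ceiling(log(scheme$k_const * eff$m * eff$n / scheme$e_max) /
                 scheme$lambda_)
  max(as.integer(s), 1L)
}
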