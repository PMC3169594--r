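# Target-site duplications, empty-site reconstruction and in-silico PCR.
# Tm1 elements are flanked by 8-10 bp (most commonly 9 bp) direct repeats of
# host sequence created at integration; the paralogous locus without the
# element carries a single copy (the empty site), which a primer pair
# flanking the insertion amplifies as a shorter product.

#' Detect a target site duplication in the element flanks
#'
#' Finds the best direct repeat with one copy ending immediately before the
#' element (Motif A1) and one beginning immediately after it (Motif A2).
#' Candidates over \code{len_range} are scored by length minus mismatches;
#' ties prefer length 9, then longer. Calls with more than
#' \code{max_mismatch} mismatches are rejected (\code{"n.f."}).
#'
#' @param left_flank sequence immediately left of the element (its last
#'   residue abuts Motif A1); nominally 15 bp
#' @param right_flank sequence immediately right of the element
#' @param len_range TSD lengths searched (default 7-12)
#' @param max_mismatch mismatch budget (default 1)
#' @return a TSD call: list with \code{status} (\code{"found"}/\code{"n.f."}),
#'   \code{length}, \code{left_seq}, \code{right_seq},
#'   \code{mismatch_positions}
#' @export
detect_tsd <- function(left_flank, right_flank, len_range = c(7L, 12L),
                       max_mismatch = 1L) {
  nf <- list(status = "n.f.", length = NA_integer_,
             left_seq = NA_character_, right_seq = NA_character_,
             mismatch_positions = integer())
  lmax <- min(len_range[2], nchar(left_flank), nchar(right_flank))
  if (lmax < len_range[1]) return(nf)
  best <- NULL
  for (len in len_range[1]:lmax) {
    ls <- substr(left_flank, nchar(left_flank) - len + 1L, nchar(left_flank))
    rs <- substr(right_flank, 1L, len)
    mm <- which(strsplit(ls, "")[[1]] != strsplit(rs, "")[[1]])
    if (length(mm) > max_mismatch) next
    cand <- list(status = "found", length = len, left_seq = ls,
                 right_seq = rs, mismatch_positions = mm,
                 score = len - length(mm))
    if (is.null(best)) { best <- cand; next }
    if (cand$score > best$score) best <- cand
    else if (cand$score == best$score) {
      # ties broken toward length 9, then longer
      better <- (cand$length == 9L && best$length != 9L) ||
        (best$length != 9L && cand$length > best$length)
      if (better) best <- cand
    }
  }
  if (is.null(best)) return(nf)
  best$score <- NULL
  best
}

#' Reconstruct the empty (pre-insertion) site of an element
#'
#' Removes the element and one TSD copy from its contig, modelling the
#' paralogous locus before integration duplicated the target site.
#'
#' @param record contig record (from [read_fasta()]) or residue string
#' @param element_start,element_end element bounds on the contig (1-based,
#'   inclusive; the TSD copies lie outside these bounds)
#' @param tsd a TSD call from [detect_tsd()] with status \code{"found"}
#' @return a record list (id suffixed \code{"_empty_site"}) with the excised
#'   sequence
#' @export
reconstruct_empty_site <- function(record, element_start, element_end, tsd) {
  if (is.character(record)) record <- list(id = "seq", residues = record)
  if (!identical(tsd$status, "found"))
    stop("cannot reconstruct an empty site without a TSD (status ",
         tsd$status %||% "missing", ")")
  res <- record$residues
  stopifnot(element_start > tsd$length, element_end <= nchar(res))
  # drop the element plus the right TSD copy; the left copy remains
  out <- paste0(substr(res, 1L, element_start - 1L),
                substr(res, element_end + tsd$length + 1L, nchar(res)))
  list(id = paste0(record$id, "_empty_site"), description = "",
       residues = out, length = nchar(out))
}

#' Re-insert an element at an empty site (inverse of excision)
#'
#' @param empty_site record or residue string of the empty locus
#' @param insert_after position of the last base of the (single) target-site
#'   copy after which the element integrates
#' @param element_seq element residues
#' @param tsd_length target-site length to duplicate
#' @return residue string with the element inserted and the target site
#'   duplicated
#' @export
insert_element <- function(empty_site, insert_after, element_seq,
                           tsd_length) {
  res <- if (is.list(empty_site)) empty_site$residues else empty_site
  tsd <- substr(res, insert_after - tsd_length + 1L, insert_after)
  paste0(substr(res, 1L, insert_after), element_seq, tsd,
         substr(res, insert_after + 1L, nchar(res)))
}

#' In-silico PCR
#'
#' Reports every convergent placement of the two primers with at most
#' \code{max_mismatch} mismatches per primer and an exact match over the
#' 3'-terminal \code{anchor_3prime} bases, for products up to
#' \code{max_product} bp. Product length is inclusive of both primer
#' footprints (5' end to 5' end), matching gel-size reporting.
#'
#' @param template record (from [read_fasta()]) or residue string
#' @param fwd_primer,rev_primer primer sequences, 5'->3', >= 15 nt; primer
#'   names from [primer_table()] are also accepted
#' @param max_mismatch mismatch budget per primer binding site (default 1)
#' @param anchor_3prime exact-match 3' anchor length (default 3)
#' @param max_product maximum product length (default 20 kb)
#' @return data.frame of products: fwd_start, fwd_end, rev_start, rev_end
#'   (1-based template coordinates of each primer footprint),
#'   product_length, strand (\code{"+"} when \code{fwd_primer} binds the
#'   plus strand)
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer,
                          max_mismatch = 1L, anchor_3prime = 3L,
                          max_product = 20000L) {
  if (is.list(template)) template <- template$residues
  lookup <- function(p) {
    if (p %in% primer_table()$name)
      primer_table()$sequence[match(p, primer_table()$name)] else p
  }
  fwd_primer <- lookup(fwd_primer); rev_primer <- lookup(rev_primer)
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L)
    stop("primers must be >= 15 nt")

  sites <- function(primer, strand) {
    # plus: primer as given; minus: primer binds the minus strand, i.e. its
    # reverse complement appears in the template
    pat <- if (strand == "+") primer else reverse_complement(primer)
    w <- nchar(pat)
    tl <- nchar(template)
    if (tl < w) return(data.frame(start = integer(), end = integer()))
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(template),
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L) return(data.frame(start = integer(), end = integer()))
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    ok <- vapply(seq_along(st), function(i) {
      hit <- substr(template, st[i], en[i])
      # 3' anchor: last bases of the primer = template end (plus strand) or
      # template start complemented (minus strand)
      if (strand == "+") {
        substr(hit, w - anchor_3prime + 1L, w) ==
          substr(pat, w - anchor_3prime + 1L, w)
      } else {
        substr(hit, 1L, anchor_3prime) == substr(pat, 1L, anchor_3prime)
      }
    }, logical(1))
    data.frame(start = st[ok], end = en[ok])
  }

  out <- list()
  combos <- list(list(f = fwd_primer, r = rev_primer, strand = "+"),
                 list(f = rev_primer, r = fwd_primer, strand = "-"))
  for (cb in combos) {
    fs <- sites(cb$f, "+")     # leftward primer on plus strand
    rs <- sites(cb$r, "-")     # rightward primer on minus strand
    if (nrow(fs) == 0L || nrow(rs) == 0L) next
    for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
      # convergent: plus primer 5' end left of minus primer 5' end
      if (rs$end[j] <= fs$end[i]) next
      len <- rs$end[j] - fs$start[i] + 1L
      if (len > max_product) next
      out[[length(out) + 1L]] <- data.frame(
        fwd_start = fs$start[i], fwd_end = fs$end[i],
        rev_start = rs$start[j], rev_end = rs$end[j],
        product_length = len, strand = cb$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      product_length = integer(), strand = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$product_length, res$fwd_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
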