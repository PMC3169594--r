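# Sequence and annotation I/O. Residues are plain uppercase character
# strings over {A,C,G,T,N}; coordinates are 1-based inclusive throughout
# (the R/Bioconductor convention), so GFF3 output is direct and BED output
# converts to 0-based half-open.

.norm_residues <- function(x, id = "?") {
  x <- toupper(x)
  x <- gsub("[ \t\r\n]", "", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0) {
    warning("record '", id, "': ", nchar(bad),
            " non-ACGTN residue(s) (IUPAC ambiguity or other) mapped to N",
            call. = FALSE)
    x <- chartr(paste(unique(strsplit(bad, "")[[1]]), collapse = ""),
                strrep("N", length(unique(strsplit(bad, "")[[1]]))), x)
  }
  x
}

#' Read a FASTA file into a list of sequence records
#'
#' Residues are uppercased; IUPAC ambiguity codes other than N are mapped to
#' N with a warning, so draft assemblies pass. Duplicate record ids and empty
#' files are errors.
#'
#' @param path FASTA file
#' @return named list of records; each record is a list with \code{id},
#'   \code{description}, \code{residues} and \code{length}
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty FASTA id")
  recs <- lapply(seq_along(set), function(i) {
    res <- .norm_residues(as.character(set[[i]]), ids[i])
    list(id = ids[i], description = desc[i], residues = res,
         length = nchar(res))
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records list of records as returned by [read_fasta()], or a named
#'   character vector of residues
#' @param path output file
#' @param width line width
#' @return \code{path}, invisibly
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records))
    records <- lapply(names(records), function(n)
      list(id = n, description = "", residues = unname(records[[n]])))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description %||% "")) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    res <- r$residues
    starts <- seq(1, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1, nchar(res))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a residue string
#'
#' Watson-Crick complement, reversed; N maps to N. Characters outside
#' {A,C,G,T,N} are an error.
#'
#' @param seq residue string (vectorised)
#' @return reverse-complemented string(s)
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) stop("invalid residue in reverse_complement")
  out <- vapply(seq, function(s) {
    if (nchar(s) == 0) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

# -- coordinate conversion ---------------------------------------------------

#' Convert internal (1-based inclusive) intervals to BED (0-based half-open)
#' @param start,end 1-based inclusive coordinates
#' @return data.frame with \code{start} and \code{end} in BED convention
#' @export
to_bed_coords <- function(start, end) data.frame(start = start - 1L, end = end)

#' Convert BED (0-based half-open) intervals to internal 1-based inclusive
#' @param start,end BED coordinates
#' @return data.frame with 1-based inclusive \code{start}, \code{end}
#' @export
from_bed_coords <- function(start, end) data.frame(start = start + 1L, end = end)

# short deterministic parameter fingerprint for output headers
.param_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.writer_header <- function(params = NULL) {
  c(sprintf("#! tm1annot %s", tm1_version()),
    sprintf("#! parameter-hash %s", .param_hash(params %||% list())))
}

# -- annotation writers ------------------------------------------------------

.gff3_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, character(1))),
        collapse = ";")
}

.check_coords <- function(elements, contig_lengths) {
  if (is.null(contig_lengths)) return(invisible())
  for (e in elements) {
    len <- contig_lengths[[e$contig]]
    if (!is.null(len) && (e$start < 1 || e$end > len))
      stop("element coordinates [", e$start, ",", e$end,
           "] outside contig ", e$contig, " (length ", len, ")")
  }
  invisible()
}

#' Write element annotations to GFF3, BED or TSV
#'
#' GFF3 output is 1-based inclusive with parent/child rows (element, then
#' its TIRs, motifs and TSD); BED is 0-based half-open; the TSV mirrors the
#' per-element supplementary-table layout, with the status vocabulary
#' \code{"n.a."} (not analyzed: a terminal motif is missing) and
#' \code{"n.f."} (not found).
#'
#' @param elements list of \code{tm1_element} objects (see
#'   [annotate_elements()]); may be empty
#' @param path output file
#' @param format one of \code{"gff3"}, \code{"bed"}, \code{"tsv"}
#' @param contig_lengths optional named vector for coordinate validation
#' @param params parameter list recorded in the header hash
#' @return \code{path}, invisibly
#' @export
write_annotations <- function(elements, path,
                              format = c("gff3", "bed", "tsv"),
                              contig_lengths = NULL, params = NULL) {
  format <- match.arg(format)
  .check_coords(elements, contig_lengths)
  switch(format,
         gff3 = .write_gff3(elements, path, params),
         bed  = .write_bed(elements, path, params),
         tsv  = .write_tsv(elements, path, params))
  invisible(path)
}

.write_gff3 <- function(elements, path, params) {
  lines <- c("##gff-version 3", .writer_header(params))
  src <- "tm1annot"
  for (k in seq_along(elements)) {
    e <- elements[[k]]
    eid <- sprintf("element%03d", k)
    strand <- e$orientation %||% "+"
    row <- function(type, start, end, id = NULL, parent = NULL, ...) {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              e$contig, src, type, start, end, strand,
              .gff3_attr(ID = id, Parent = parent, ...))
    }
    lines <- c(lines,
               row("transposable_element", e$start, e$end, id = eid,
                   Name = e$class %||% "unclassified",
                   tir_identity = if (!is.null(e$tir_identity) &&
                                        !is.na(e$tir_identity))
                     sprintf("%.2f", e$tir_identity) else NULL,
                   tsd_length = if (identical(e$tsd$status, "found"))
                     e$tsd$length else NULL))
    if (!is.null(e$tir_left))
      lines <- c(lines, row("terminal_inverted_repeat", e$tir_left[1],
                            e$tir_left[2], id = paste0(eid, ".tirL"),
                            parent = eid))
    if (!is.null(e$tir_right))
      lines <- c(lines, row("terminal_inverted_repeat", e$tir_right[1],
                            e$tir_right[2], id = paste0(eid, ".tirR"),
                            parent = eid))
    mot <- e$motif_intervals
    if (!is.null(mot) && nrow(mot))
      for (i in seq_len(nrow(mot)))
        lines <- c(lines, row("sequence_motif", mot$start[i], mot$end[i],
                              id = sprintf("%s.m%d", eid, i), parent = eid,
                              Name = mot$name[i]))
    if (!is.null(e$tsd) && identical(e$tsd$status, "found")) {
      lines <- c(lines,
                 row("target_site_duplication", e$start - e$tsd$length,
                     e$start - 1L, id = paste0(eid, ".tsdL"), parent = eid),
                 row("target_site_duplication", e$end + 1L,
                     e$end + e$tsd$length, id = paste0(eid, ".tsdR"),
                     parent = eid))
    }
  }
  writeLines(lines, path)
}

.write_bed <- function(elements, path, params) {
  lines <- .writer_header(params)
  for (k in seq_along(elements)) {
    e <- elements[[k]]
    bc <- to_bed_coords(e$start, e$end)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d\t%s", e$contig, bc$start,
                              bc$end, e$class %||% "unclassified",
                              0L, e$orientation %||% "+"))
  }
  writeLines(lines, path)
}

#' Tabulate annotated elements
#'
#' One row per element with the supplementary-table status vocabulary:
#' TSD status is \code{"n.a."} if either terminal motif is missing and
#' \code{"n.f."} if both terminal motifs are absent or no duplication was
#' found.
#'
#' @param elements list of \code{tm1_element} objects
#' @return data.frame
#' @export
elements_table <- function(elements) {
  if (length(elements) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer(),
                      orientation = character(), class = character(),
                      tir_identity = numeric(), c_units_left = integer(),
                      c_units_right = integer(), a1 = character(),
                      a2 = character(), d = character(), tsd = character(),
                      tsd_length = character(), tsd_seq = character(),
                      notes = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(elements, function(e) {
    stat <- function(m) if (is.null(m) || m$status != "present") "n.f." else m$seq
    tsd <- e$tsd
    tsd_status <- if (is.null(tsd)) "n.a." else tsd$status
    data.frame(
      contig = e$contig, start = e$start, end = e$end,
      length = e$end - e$start + 1L,
      orientation = e$orientation %||% "+",
      class = e$class %||% "unclassified",
      tir_identity = if (is.null(e$tir_identity)) NA_real_ else
        round(e$tir_identity, 2),
      c_units_left = length(e$c_units_left$length %||% integer()),
      c_units_right = length(e$c_units_right$length %||% integer()),
      a1 = stat(e$a1), a2 = stat(e$a2), d = stat(e$d_left),
      tsd = tsd_status,
      tsd_length = if (identical(tsd_status, "found"))
        as.character(tsd$length) else tsd_status,
      tsd_seq = if (identical(tsd_status, "found")) tsd$left_seq else "",
      notes = e$notes %||% "",
      stringsAsFactors = FALSE)
  }))
}

.write_tsv <- function(elements, path, params) {
  hdr <- .writer_header(params)
  tab <- elements_table(elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
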