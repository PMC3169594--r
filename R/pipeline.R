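# Pipeline orchestration: discover -> delineate/annotate -> TSD -> classify
# -> summarize, from a single validated config. All randomness flows from
# the config seed; identical configs give identical outputs.

.config_keys <- c("genome", "tir_query", "motif_profile", "seed_preset",
                  "tir_preset", "references", "min_span", "max_span",
                  "merge_window", "flank", "tsd_len_range",
                  "tsd_max_mismatch", "keep_unresolved", "out_prefix",
                  "seed", "bootstrap_replicates", "tree")

#' Build and validate a pipeline configuration
#'
#' Every pipeline parameter has a named key defaulting to the family's
#' published search settings, so the zero-override run reproduces them.
#' Unknown keys are rejected.
#'
#' @param genome path to a genome FASTA, or a record list from
#'   [read_fasta()]
#' @param ... overrides of: tir_query, motif_profile (name or object),
#'   seed_preset, tir_preset, references (list(reference, regions) or NULL),
#'   min_span, max_span, merge_window, flank, tsd_len_range,
#'   tsd_max_mismatch, keep_unresolved, out_prefix, seed,
#'   bootstrap_replicates, tree (build the ML-element tree?)
#' @return a validated \code{tm1_config}
#' @export
tm1_config <- function(genome, ...) {
  over <- list(...)
  unknown <- setdiff(names(over), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    genome = genome,
    tir_query = tm1_seed_query(),
    motif_profile = "incognita",
    seed_preset = scoring_preset("seed-search"),
    tir_preset = scoring_preset("tir-delineation"),
    references = NULL,
    min_span = 100L, max_span = 10000L, merge_window = 200L,
    flank = 200L,
    tsd_len_range = c(7L, 12L), tsd_max_mismatch = 1L,
    keep_unresolved = FALSE,
    out_prefix = NULL,
    seed = 1L,
    bootstrap_replicates = 100L,
    tree = TRUE)
  cfg[names(over)] <- over
  if (is.character(cfg$motif_profile))
    cfg$motif_profile <- motif_profile(cfg$motif_profile)
  if (is.character(cfg$genome)) {
    if (!file.exists(cfg$genome)) stop("genome file not found: ", cfg$genome)
    cfg$genome <- read_fasta(cfg$genome)
  }
  if (length(cfg$genome) == 0L) stop("empty genome")
  if (grepl("[^ACGTN]", cfg$tir_query)) stop("invalid TIR query")
  class(cfg) <- "tm1_config"
  cfg
}

#' Run the full annotation pipeline
#'
#' Seed search, hit clustering, candidate calling, TIR delineation and
#' motif annotation, TSD detection, classification, and family summaries.
#' Per-stage counts are logged; "no elements found" is a valid empty
#' result, not an error. When \code{config$out_prefix} is set, GFF3/TSV
#' outputs, the class summary, logo matrices and the Newick tree are
#' written.
#'
#' @param config a [tm1_config()]
#' @return list: \code{elements} (classified \code{tm1_element} list),
#'   \code{table} (per-element data.frame), \code{class_summary},
#'   \code{motif_c_histogram}, \code{logos}, \code{tree},
#'   \code{mean_tir_identity}, \code{hits}, \code{clusters},
#'   \code{candidates}, \code{log} (named stage counts)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tm1_config"))
  disc <- discover_elements(config$genome, config$tir_query,
                            config$seed_preset,
                            merge_window = config$merge_window,
                            min_span = config$min_span,
                            max_span = config$max_span)
  els <- annotate_elements(disc$candidates, config$genome,
                           profile = config$motif_profile,
                           tir_preset = config$tir_preset,
                           flank = config$flank,
                           tsd_len_range = config$tsd_len_range,
                           tsd_max_mismatch = config$tsd_max_mismatch,
                           keep_unresolved = config$keep_unresolved)
  n_unresolved <- length(attr(els, "unresolved") %||% list())
  els <- lapply(els, classify_element, references = config$references)

  tab <- elements_table(els)
  logs <- c(seed_hits = attr(disc$hits, "n_total") %||% 0L,
            seed_hits_precull = attr(disc$hits, "n_raw") %||% 0L,
            clusters = nrow(disc$clusters),
            candidates = nrow(disc$candidates),
            elements = length(els),
            unresolved = n_unresolved,
            tsd_found = sum(tab$tsd == "found"),
            tsd_nf = sum(tab$tsd == "n.f."),
            tsd_na = sum(tab$tsd == "n.a."))

  cls <- summarize_classes(els)
  hist <- motif_c_length_histogram(els)
  tir_ids <- vapply(els, function(e) e$tir_identity %||% NA_real_,
                    numeric(1))
  mean_tir_identity <- if (any(!is.na(tir_ids)))
    mean(tir_ids, na.rm = TRUE) else NA_real_

  logos <- NULL
  c_units <- unlist(lapply(els, function(e)
    c(e$c_units_left$sequence, e$c_units_right$sequence)))
  if (length(c_units) >= 2L) {
    msa <- align_motif_instances(c_units)
    logos <- list(motif_c = compute_logo(msa))
  }
  tree <- if (isTRUE(config$tree))
    ml_element_tree(els, config$bootstrap_replicates, config$seed) else NULL

  out <- list(elements = els, table = tab, class_summary = cls,
              motif_c_histogram = hist, logos = logos, tree = tree,
              mean_tir_identity = mean_tir_identity,
              hits = disc$hits, clusters = disc$clusters,
              candidates = disc$candidates, log = logs)

  if (!is.null(config$out_prefix)) {
    px <- config$out_prefix
    params <- config[c("min_span", "max_span", "merge_window", "flank",
                       "tsd_len_range", "tsd_max_mismatch", "seed")]
    contig_lengths <- setNames(
      vapply(config$genome, function(r) nchar(r$residues), numeric(1)),
      vapply(config$genome, function(r) r$id, character(1)))
    write_annotations(els, paste0(px, ".elements.gff3"), "gff3",
                      contig_lengths, params)
    write_annotations(els, paste0(px, ".elements.bed"), "bed",
                      contig_lengths, params)
    write_annotations(els, paste0(px, ".elements.tsv"), "tsv",
                      contig_lengths, params)
    write.table(cls, paste0(px, ".class_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(logos)) {
      lg <- logos$motif_c
      write.table(cbind(t(lg$counts), bits = round(lg$bits, 4)),
                  paste0(px, ".motif_c_logo.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    if (!is.null(tree)) writeLines(tree$newick, paste0(px, ".ml_tree.nwk"))
    writeLines(paste(names(logs), logs, sep = "\t"),
               paste0(px, ".log.tsv"))
  }
  out
}
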