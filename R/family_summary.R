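# Family-level summaries: center-star multiple alignment of motif
# instances, sequence logos with small-sample correction, Motif C length
# histograms, class summaries, group identities and the neighbor-joining
# tree of MITE-like elements (tree construction and Newick serialisation
# via ape).

#' Center-star multiple alignment
#'
#' Progressive multiple alignment around the center instance (the one
#' minimising summed pairwise distance, computed from free-end-gap pairwise
#' alignments); every other instance is aligned to the center and gap
#' columns merged. Deterministic; adequate for short motif units and small
#' element sets.
#'
#' @param instances character vector of sequences (>= 1)
#' @param params pairwise alignment parameters (default the ClustalW-style
#'   motif preset: gap open 15, extend 6.66)
#' @return character vector of gapped sequences, equal width
#' @export
align_motif_instances <- function(instances,
                                  params = global_preset("motif")) {
  n_all <- length(instances)
  if (n_all == 0L) stop("no instances")
  if (n_all == 1L) return(instances)
  # collapse duplicates: the weighted summed distance over unique
  # sequences selects the same center as the full pairwise sum, and
  # identical instances share one pairwise alignment
  uniq <- unique(instances)
  idx_of <- match(instances, uniq)
  weight <- tabulate(idx_of, nbins = length(uniq))
  if (length(uniq) == 1L)
    return(instances)
  n <- length(uniq)
  dist <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- global_align_free_end(uniq[i], uniq[j], params)
    dist[i, j] <- dist[j, i] <- 100 - al$identity_pct
  }
  center <- which.min(as.vector(dist %*% weight))
  others <- setdiff(seq_len(n), center)

  # merged center coordinates: a growing gapped master string for the
  # center; each pairwise alignment is re-projected onto it
  master <- strsplit(uniq[center], "")[[1]]    # center residues
  pair_alns <- lapply(others, function(j)
    global_align_free_end(uniq[center], uniq[j], params))
  # column map: for each center residue, how many gap columns precede it
  ins_before <- rep(0L, length(master) + 1L)  # insertions before residue k
  proj <- list()
  for (idx in seq_along(others)) {
    al <- pair_alns[[idx]]
    ca <- strsplit(al$aligned_a, "")[[1]]
    ot <- strsplit(al$aligned_b, "")[[1]]
    k <- 1L; run <- 0L
    cols <- list()  # per center-slot list of other-residues
    pre <- vector("list", length(master) + 1L)
    at <- vector("character", length(master))
    for (c in seq_along(ca)) {
      if (ca[c] == "-") {
        pre[[k]] <- c(pre[[k]], ot[c])
      } else {
        at[k] <- ot[c]
        k <- k + 1L
      }
    }
    npre <- vapply(pre, length, integer(1))
    ins_before <- pmax(ins_before, npre)
    proj[[idx]] <- list(pre = pre, at = at)
  }
  # build final columns
  width <- sum(ins_before) + length(master)
  build_row <- function(pre, at) {
    out <- character(0)
    for (k in seq_len(length(master) + 1L)) {
      gaps_here <- ins_before[k]
      have <- if (k <= length(pre)) pre[[k]] else character(0)
      pad <- gaps_here - length(have)
      out <- c(out, have, rep("-", pad))
      if (k <= length(master)) out <- c(out, at[k])
    }
    paste(out, collapse = "")
  }
  center_row <- build_row(vector("list", length(master) + 1L),
                          master)
  res <- character(n)
  res[center] <- center_row
  for (idx in seq_along(others)) {
    p <- proj[[idx]]
    at <- ifelse(p$at == "", "-", p$at)
    res[others[idx]] <- build_row(p$pre, at)
  }
  res[idx_of]
}

#' Per-column information content (sequence logo matrix)
#'
#' Counts bases per alignment column and computes information content
#' \code{bits = 2 - (H + e(n))} with Shannon entropy H over the base
#' frequencies and, optionally, the small-sample correction
#' \code{e(n) = 3 / (2 ln(2) n)}; floored at 0. The consensus reports only
#' positions with bits > 0 (others are masked with \code{"."}).
#'
#' @param msa character vector of equal-width gapped sequences
#' @param correction apply the small-sample correction? (default TRUE)
#' @return list with \code{counts} (4 x width matrix), \code{bits},
#'   \code{consensus}
#' @export
compute_logo <- function(msa, correction = TRUE) {
  if (length(msa) == 0L) stop("empty alignment")
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("alignment rows differ in width")
  mat <- do.call(rbind, strsplit(msa, ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(w), function(j)
    vapply(bases, function(b) sum(mat[, j] == b), numeric(1)),
    numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(bases, NULL))
  bits <- vapply(seq_len(w), function(j) {
    n <- sum(counts[, j])
    if (n == 0L) return(0)
    p <- counts[, j] / n
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    e <- if (correction) 3 / (2 * log(2) * n) else 0
    max(0, 2 - h - e)
  }, numeric(1))
  cons <- vapply(seq_len(w), function(j) {
    if (bits[j] <= 0) return(".")
    bases[which.max(counts[, j])]
  }, character(1))
  list(counts = counts, bits = bits, consensus = paste(cons, collapse = ""))
}

#' Motif C unit-length histogram
#'
#' Exact counts of annotated Motif C unit lengths over both TIRs of all
#' elements, with the modal length.
#'
#' @param elements list of \code{tm1_element}
#' @return list with \code{counts} (table over unit length), \code{total}
#'   and \code{mode}
#' @export
motif_c_length_histogram <- function(elements) {
  lens <- unlist(lapply(elements, function(e)
    c(e$c_units_left$length, e$c_units_right$length)))
  if (length(lens) == 0L)
    return(list(counts = table(integer()), total = 0L, mode = NA_integer_))
  tb <- table(lens)
  list(counts = tb, total = length(lens),
       mode = as.integer(names(tb)[which.max(tb)]))
}

#' Class summary table
#'
#' Per-class element counts and mean lengths (rounded to integer bp), with
#' a totals row; the class-table analog of a family summary.
#'
#' @param elements list of \code{tm1_element} with \code{$class} set
#' @return data.frame: class, count, mean_length
#' @export
summarize_classes <- function(elements) {
  classes <- c("Tm1-A", "Tm1-D", "Tm1-HH", "Tm1-ML", "other")
  lens <- vapply(elements, function(e) e$end - e$start + 1L, numeric(1))
  labs <- vapply(elements, function(e) e$class %||% "other", character(1))
  rows <- lapply(classes, function(cl) {
    sel <- labs == cl
    data.frame(class = cl, count = sum(sel),
               mean_length = if (any(sel)) round(mean(lens[sel])) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = "Total", count = length(elements),
                        mean_length = NA))
}

#' Mean pairwise identity of a sequence group
#'
#' Mean over all unordered pairs of the free-end-gap global alignment
#' identity (end gaps excluded).
#'
#' @param seqs character vector (>= 2)
#' @param params alignment parameters
#' @return mean identity in percent
#' @export
group_identity <- function(seqs, params = global_preset("element")) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    ids <- c(ids, global_align_free_end(seqs[i], seqs[j], params)$identity_pct)
  mean(ids)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) on distances
#' \code{d = 1 - identity}; Newick serialisation round-trips via
#' [ape::write.tree()].
#'
#' @param distances symmetric numeric matrix with labelled rows/columns
#' @return an [ape::nj()] \code{phylo} tree
#' @export
nj_tree <- function(distances) {
  if (any(!is.finite(as.matrix(distances)))) stop("non-finite distances")
  if (nrow(as.matrix(distances)) < 3L) stop("need >= 3 taxa")
  ape::nj(stats::as.dist(distances))
}

# pairwise distance from an MSA: 1 - identity over columns where neither
# sequence is gapped
msa_distances <- function(msa, labels = NULL) {
  n <- length(msa)
  mat <- do.call(rbind, strsplit(msa, ""))
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    use <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- d[j, i] <- if (sum(use) == 0) 1 else
      1 - sum(mat[i, use] == mat[j, use]) / sum(use)
  }
  rownames(d) <- colnames(d) <- labels %||% paste0("seq", seq_len(n))
  d
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Column resampling with replacement on the alignment, NJ per replicate,
#' and majority-rule support (percent of replicates containing each
#' bipartition of the original topology, via [ape::prop.clades()]).
#'
#' @param msa character vector of equal-width gapped sequences (>= 3)
#' @param labels tip labels
#' @param replicates bootstrap replicates (default 100)
#' @param seed RNG seed (required, for reproducibility)
#' @return list with \code{tree} (node labels carry supports in 0-100) and
#'   \code{support}
#' @export
bootstrap_support <- function(msa, labels = NULL, replicates = 100L, seed) {
  if (missing(seed)) stop("a seed is required")
  labels <- labels %||% paste0("seq", seq_along(msa))
  tree <- nj_tree(msa_distances(msa, labels))
  w <- unique(nchar(msa))
  mat <- do.call(rbind, strsplit(msa, ""))
  set.seed(seed)
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(w, w, replace = TRUE)
    sub <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    reps[[r]] <- tryCatch(nj_tree(msa_distances(sub, labels)),
                          error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  pc <- ape::prop.clades(tree, reps, rooted = FALSE)
  support <- round(100 * pc / length(reps))
  tree$node.label <- support
  list(tree = tree, support = support)
}

#' Build the MITE-like element tree
#'
#' Center-star MSA of the Tm1-ML element sequences, MSA distances, NJ tree
#' and bootstrap supports.
#'
#' @param elements list of classified \code{tm1_element}
#' @param replicates bootstrap replicates
#' @param seed RNG seed
#' @return list with \code{tree}, \code{support}, \code{newick}, or NULL
#'   when fewer than 3 ML elements exist
#' @export
ml_element_tree <- function(elements, replicates = 100L, seed = 1L) {
  ml <- Filter(function(e) identical(e$class, "Tm1-ML"), elements)
  if (length(ml) < 3L) return(NULL)
  seqs <- vapply(ml, function(e) e$element_seq, character(1))
  labels <- vapply(seq_along(ml), function(i)
    sprintf("%s_%d_%d", ml[[i]]$contig, ml[[i]]$start, ml[[i]]$end),
    character(1))
  msa <- align_motif_instances(seqs, global_preset("element"))
  bs <- bootstrap_support(msa, labels, replicates, seed)
  list(tree = bs$tree, support = bs$support,
       newick = ape::write.tree(bs$tree))
}
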