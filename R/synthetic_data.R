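# Synthetic genomes with planted elements and full ground truth. Elements
# are assembled from the composite-TIR grammar
#   TSD . A1 . B . C^n . D . C . payload . rc(C . D) . rc(C^m) . rc(B) . A2 . TSD
# (Motif D and its flanking C unit omitted for the MITE-like class), with
# class-specific payloads, 8-10 bp TSDs weighted toward 9 bp, optional
# nested insertions, and a tunable neutral-divergence model. Identical
# seeds give identical genomes.

#' Default grammar for planted elements
#'
#' Motif consensuses from the default species profile; Motif C run lengths
#' 1-9 per TIR; TSD lengths {8, 9, 10} weighted 2:6:2 (most commonly 9 bp);
#' class mix proportional to the observed family composition (A:D:HH:ML:
#' other = 1:8:8:42:2).
#'
#' @param profile a [motif_profile()]
#' @param reference optional reference interior for the A/D classes; default
#'   [synthetic_reference()]
#' @return a \code{tm1_grammar} list
#' @export
tm1_grammar <- function(profile = motif_profile("incognita"),
                        reference = synthetic_reference()) {
  g <- list(
    a1 = profile$a1, a2 = profile$a2, b = profile$b, c = profile$c,
    d = profile$d,
    c_units_range = c(1L, 9L),
    tsd_lengths = c(8L, 9L, 10L),
    tsd_weights = c(2, 6, 2),
    class_weights = c("Tm1-A" = 1, "Tm1-D" = 8, "Tm1-HH" = 8,
                      "Tm1-ML" = 42, other = 2),
    hairpin = histone_hairpin_consensus(),
    ml_arm = 60L, ml_spacer_range = c(30L, 200L),
    hh_payload_range = c(850L, 1000L),
    d_fragment_range = c(500L, 700L), d_pad_range = c(300L, 500L),
    other_payload_range = c(400L, 900L),
    reference = reference)
  class(g) <- "tm1_grammar"
  g
}

#' Deterministic synthetic reference interior for the autonomous class
#'
#' A fixed pseudo-random 2300 bp sequence standing in for an
#' autonomous-element internal region, with a designated MULE-domain
#' region at 1150-1450. It is synthetic: generated from a fixed seed, not
#' derived from any database record.
#'
#' @param length reference length (default 2300)
#' @param seed generation seed (default 104729, fixed)
#' @return list with \code{reference} residues and \code{regions}
#'   data.frame (the MULE domain plus 5'/3' regions)
#' @export
synthetic_reference <- function(length = 2300L, seed = 104729L) {
  rng <- .tm1_rng(seed)
  seq <- .random_dna(length, rng)
  list(reference = seq,
       regions = data.frame(
         name = c("five_prime", "MULE_domain", "three_prime"),
         start = c(1L, 1150L, 1451L),
         end = c(1149L, 1450L, length),
         stringsAsFactors = FALSE))
}

# local RNG stream so generator determinism is independent of the caller's
# RNG state
.tm1_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  env
}

.with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

.random_dna <- function(n, rng, weights = c(1, 1, 1, 1)) {
  if (n == 0L) return("")
  .with_rng(rng, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                              prob = weights), collapse = ""))
}

.rint <- function(rng, range) .with_rng(rng, sample(range[1]:range[2], 1L))

#' Build one planted element from the grammar
#'
#' @param grammar a [tm1_grammar()]
#' @param class one of \code{"Tm1-A"}, \code{"Tm1-D"}, \code{"Tm1-HH"},
#'   \code{"Tm1-ML"}, \code{"other"}
#' @param rng internal RNG stream (from \code{.tm1_rng}); tests can pass
#'   \code{make_rng(seed)}
#' @param has_d force Motif D on/off; forcing D on a MITE-like element is
#'   an error (its definition excludes it)
#' @return list with \code{sequence} and \code{truth} (class, per-end
#'   Motif C unit counts including the D-adjacent unit, TIR lengths,
#'   payload length)
#' @export
build_element <- function(grammar, class, rng, has_d = NULL) {
  if (is.null(has_d)) has_d <- class != "Tm1-ML"
  if (class == "Tm1-ML" && has_d)
    stop("a MITE-like element cannot carry Motif D")
  nL <- .rint(rng, grammar$c_units_range)
  nR <- .rint(rng, grammar$c_units_range)
  payload <- switch(class,
    "Tm1-A" = grammar$reference$reference,
    "Tm1-D" = {
      ref <- grammar$reference$reference
      fl <- .rint(rng, grammar$d_fragment_range)
      frag <- substr(ref, nchar(ref) - fl + 1L, nchar(ref))  # 3' fragment
      paste0(.random_dna(.rint(rng, grammar$d_pad_range), rng), frag)
    },
    "Tm1-HH" = {
      plen <- .rint(rng, grammar$hh_payload_range)
      hp <- grammar$hairpin
      at <- floor(plen * 0.7)   # hairpin near the 3' end
      paste0(.random_dna(at, rng), hp,
             .random_dna(plen - at - nchar(hp), rng))
    },
    "Tm1-ML" = {
      arm <- .random_dna(grammar$ml_arm, rng)
      paste0(arm, .random_dna(.rint(rng, grammar$ml_spacer_range), rng),
             reverse_complement(arm))
    },
    "other" = .random_dna(.rint(rng, grammar$other_payload_range), rng),
    stop("unknown class: ", class))

  cL <- strrep(grammar$c, nL)
  cR <- strrep(grammar$c, nR)
  inner_l <- if (has_d) paste0(grammar$d, grammar$c) else ""
  inner_r <- if (has_d) reverse_complement(paste0(grammar$c, grammar$d)) else ""
  seq <- paste0(grammar$a1, grammar$b, cL, inner_l,
                payload,
                inner_r, reverse_complement(cR),
                reverse_complement(grammar$b), grammar$a2)
  tir_left_len <- nchar(grammar$b) + nchar(cL) + nchar(inner_l)
  tir_right_len <- nchar(inner_r) + nchar(cR) + nchar(grammar$b)
  list(sequence = seq,
       truth = list(class = class,
                    c_units_left = nL + if (has_d) 1L else 0L,
                    c_units_right = nR + if (has_d) 1L else 0L,
                    has_d = has_d,
                    tir_left_len = tir_left_len,
                    tir_right_len = tir_right_len,
                    payload_length = nchar(payload),
                    length = nchar(seq)))
}

#' Expose an internal RNG stream for element construction
#' @param seed integer seed
#' @return RNG stream usable with [build_element()]
#' @export
make_rng <- function(seed) .tm1_rng(seed)

.mutate_seq <- function(seq, rng, substitution_rate, indel_rate = 0,
                        indel_max = 10L) {
  if (substitution_rate <= 0 && indel_rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  .with_rng(rng, {
    subs <- which(stats::runif(n) < substitution_rate)
    for (i in subs) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    if (indel_rate > 0) {
      pts <- which(stats::runif(n) < indel_rate)
      for (i in rev(pts)) {
        len <- sample.int(indel_max, 1L, prob = 0.5^(1:indel_max))
        if (stats::runif(1) < 0.5) {        # deletion
          ch <- ch[-(i:min(n, i + len - 1L))]
        } else {                            # insertion
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          ch <- append(ch, ins, after = i)
        }
        n <- length(ch)
      }
    }
  })
  paste(ch, collapse = "")
}

#' Plant elements into a synthetic genome
#'
#' Draws a uniform-composition background (composition adjustable), plants
#' \code{n_elements} non-overlapping grammar-built elements at random sites
#' with target-site duplication semantics (the TSD is drawn from the
#' background at the insertion point and duplicated), applies element-wise
#' divergence (substitutions and optional indels to the element and each
#' TSD copy independently), and records full ground truth. Deterministic
#' given the seed.
#'
#' @param genome_length background length before insertions
#' @param n_elements number of elements to plant
#' @param grammar a [tm1_grammar()]
#' @param substitution_rate per-site substitution rate in [0, 0.3]
#' @param indel_rate per-site indel rate (default 0)
#' @param seed integer seed (required)
#' @param classes optional named vector of class counts (e.g.
#'   \code{c("Tm1-HH" = 10, "Tm1-ML" = 30)}); default draws from the
#'   grammar's class weights
#' @param min_gap minimum distance between planted elements (default 300)
#' @param composition background base weights A,C,G,T (default uniform)
#' @param nested_in optional number of elements additionally given a nested
#'   insertion (default 0)
#' @return list with \code{genome} (record list, one contig), \code{truth}
#'   (data.frame: contig, start, end, orientation, class, tsd_length,
#'   tsd_seq, c_units_left, c_units_right, length), and \code{params}
#' @export
plant_elements <- function(genome_length, n_elements,
                           grammar = tm1_grammar(),
                           substitution_rate = 0, indel_rate = 0,
                           seed, classes = NULL, min_gap = 300L,
                           composition = c(1, 1, 1, 1),
                           nested_in = 0L) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.3)
  rng <- .tm1_rng(seed)

  cls <- if (!is.null(classes)) {
    rep(names(classes), times = classes)
  } else {
    .with_rng(rng, sample(names(grammar$class_weights), n_elements,
                          replace = TRUE, prob = grammar$class_weights))
  }
  if (length(cls) != n_elements)
    stop("class counts must sum to n_elements")

  built <- lapply(cls, function(cl) build_element(grammar, cl, rng))
  nest_idx <- if (nested_in > 0L)
    .with_rng(rng, sample.int(n_elements, min(nested_in, n_elements)))
  else integer(0)
  for (i in nest_idx) {
    host <- built[[i]]
    nested_el <- build_element(grammar, "Tm1-ML", rng)
    tlen <- 7L
    pay_mid <- nchar(host$sequence) %/% 2L
    site <- substr(host$sequence, pay_mid - tlen + 1L, pay_mid)
    host$sequence <- paste0(substr(host$sequence, 1L, pay_mid),
                            nested_el$sequence, site,
                            substr(host$sequence, pay_mid + 1L,
                                   nchar(host$sequence)))
    host$truth$nested <- nchar(nested_el$sequence)
    host$truth$length <- nchar(host$sequence)
    built[[i]] <- host
  }

  total_planted <- sum(vapply(built, function(b) nchar(b$sequence),
                              numeric(1)))
  if (total_planted >= genome_length / 2)
    stop("planted length (", total_planted,
         ") must be below half the genome length")

  bg <- .random_dna(genome_length, rng, weights = composition)

  # choose non-overlapping insertion points (positions in the background)
  max_tsd <- max(grammar$tsd_lengths)
  points <- integer(0)
  tries <- 0L
  while (length(points) < n_elements) {
    p <- .rint(rng, c(max_tsd + min_gap, genome_length - min_gap))
    if (all(abs(p - points) >= min_gap)) points <- c(points, p)
    tries <- tries + 1L
    if (tries > n_elements * 200L)
      stop("could not place ", n_elements, " elements without overlap")
  }
  points <- sort(points)

  orient <- .with_rng(rng, sample(c("+", "-"), n_elements, replace = TRUE))
  tsd_len <- .with_rng(rng, sample(grammar$tsd_lengths, n_elements,
                                   replace = TRUE,
                                   prob = grammar$tsd_weights))

  pieces <- character(0)
  truth <- list()
  cursor <- 1L   # next background position to copy
  out_len <- 0L  # emitted length so far
  for (i in seq_len(n_elements)) {
    p <- points[i]
    pre <- substr(bg, cursor, p)          # background through the site end
    tlen <- tsd_len[i]
    site <- substr(bg, p - tlen + 1L, p)
    el_seq <- built[[i]]$sequence
    if (orient[i] == "-") el_seq <- reverse_complement(el_seq)
    # divergence: element and each TSD copy mutated independently
    el_mut <- .mutate_seq(el_seq, rng, substitution_rate, indel_rate)
    tsd_a <- .mutate_seq(site, rng, substitution_rate, 0)
    tsd_b <- .mutate_seq(site, rng, substitution_rate, 0)
    # replace the site copy at the end of `pre` with its mutated version
    pre <- paste0(substr(pre, 1L, nchar(pre) - tlen), tsd_a)
    pieces <- c(pieces, pre, el_mut, tsd_b)
    start <- out_len + nchar(pre) + 1L
    end <- start + nchar(el_mut) - 1L
    out_len <- out_len + nchar(pre) + nchar(el_mut) + nchar(tsd_b)
    cursor <- p + 1L
    tr <- built[[i]]$truth
    truth[[i]] <- data.frame(
      contig = "synth_contig_1", start = start, end = end,
      orientation = orient[i], class = tr$class,
      tsd_length = tlen, tsd_seq = site,
      c_units_left = tr$c_units_left, c_units_right = tr$c_units_right,
      length = nchar(el_mut), nested = tr$nested %||% 0L,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, substr(bg, cursor, genome_length))
  genome_seq <- paste(pieces, collapse = "")

  list(genome = list(synth_contig_1 = list(
         id = "synth_contig_1", description = "synthetic genome",
         residues = genome_seq, length = nchar(genome_seq))),
       truth = do.call(rbind, truth),
       params = list(genome_length = genome_length,
                     n_elements = n_elements,
                     substitution_rate = substitution_rate,
                     indel_rate = indel_rate, seed = seed))
}

#' Write planted-truth annotations as GFF3
#'
#' @param truth truth data.frame from [plant_elements()]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_truth_gff3 <- function(truth, path) {
  lines <- c("##gff-version 3", .writer_header(list(what = "planted-truth")))
  for (i in seq_len(nrow(truth))) {
    lines <- c(lines, sprintf(
      "%s\ttm1annot\ttransposable_element\t%d\t%d\t.\t%s\t.\t%s",
      truth$contig[i], truth$start[i], truth$end[i], truth$orientation[i],
      .gff3_attr(ID = sprintf("truth%03d", i), Name = truth$class[i],
                 tsd_length = truth$tsd_length[i],
                 c_units_left = truth$c_units_left[i],
                 c_units_right = truth$c_units_right[i])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score recovery of planted elements
#'
#' A called element matches a truth element on the same contig when their
#' reciprocal overlap is at least \code{min_overlap}. Precision and recall
#' are computed over calls and truths; boundary mean absolute error, TSD
#' length accuracy and class accuracy over the matched pairs.
#'
#' @param truth truth data.frame from [plant_elements()]
#' @param called data.frame with contig, start, end and optionally class,
#'   tsd_length (e.g. from [elements_table()]; its \code{tsd_length} column
#'   may contain the status strings)
#' @param min_overlap reciprocal overlap threshold (default 0.8)
#' @return list: precision, recall, boundary_mae, tsd_accuracy,
#'   class_accuracy, n_truth, n_called, n_matched
#' @export
evaluate_recovery <- function(truth, called, min_overlap = 0.8) {
  n_t <- nrow(truth); n_c <- nrow(called)
  if (n_c == 0L)
    return(list(precision = NA_real_, recall = 0, boundary_mae = NA_real_,
                tsd_accuracy = NA_real_, class_accuracy = NA_real_,
                n_truth = n_t, n_called = 0L, n_matched = 0L))
  matched_t <- rep(NA_integer_, n_t)
  used_c <- logical(n_c)
  for (i in seq_len(n_t)) {
    best <- NA_integer_; best_ov <- 0
    for (j in seq_len(n_c)) {
      if (used_c[j] || called$contig[j] != truth$contig[i]) next
      ov <- min(truth$end[i], called$end[j]) -
        max(truth$start[i], called$start[j]) + 1
      if (ov <= 0) next
      rec <- min(ov / (truth$end[i] - truth$start[i] + 1),
                 ov / (called$end[j] - called$start[j] + 1))
      if (rec >= min_overlap && rec > best_ov) { best <- j; best_ov <- rec }
    }
    if (!is.na(best)) { matched_t[i] <- best; used_c[best] <- TRUE }
  }
  m <- which(!is.na(matched_t))
  n_m <- length(m)
  res <- list(precision = n_m / n_c, recall = n_m / n_t,
              boundary_mae = NA_real_, tsd_accuracy = NA_real_,
              class_accuracy = NA_real_, n_truth = n_t, n_called = n_c,
              n_matched = n_m)
  if (n_m > 0L) {
    j <- matched_t[m]
    res$boundary_mae <- mean((abs(truth$start[m] - called$start[j]) +
                                abs(truth$end[m] - called$end[j])) / 2)
    if (!is.null(called$tsd_length)) {
      tl <- suppressWarnings(as.integer(called$tsd_length[j]))
      res$tsd_accuracy <- mean(!is.na(tl) & tl == truth$tsd_length[m])
    }
    if (!is.null(called$class))
      res$class_accuracy <- mean(called$class[j] == truth$class[m])
  }
  res
}
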