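#' @title Planted-motif synthetic sequence datasets
#'
#' @description
#' Generates labelled variable-length nucleotide datasets with the
#' statistical structure of m6A peak-sequence data: lengths uniform on
#' 20-800 nt, a 1:2 positive:negative class ratio, negatives drawn from the
#' background composition, and positives distinguished by one or more
#' degenerate motif instances planted at random internal positions.  Ground
#' truth motif coordinates (0-based, half-open) are retained on each record
#' so that saliency-based motif recovery can be validated.
#'
#' @name synthetic_data
NULL

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1L]]
  paste0(vapply(chars, function(ch) {
    opts <- IUPAC[[ch]]
    if (is.null(opts)) stop("unknown IUPAC code: ", ch)
    if (length(opts) == 1L) opts else paste0("[", paste0(opts, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Specification of a synthetic dataset
#'
#' @param n_pos number of positive sequences.
#' @param n_neg number of negatives (default twice `n_pos`, the 1:2 class
#'   ratio of the benchmark data being emulated).
#' @param length_range inclusive sequence length range in nt.
#' @param motifs character vector of (possibly degenerate IUPAC) motifs;
#'   each planted instance picks one at random.  The default is the
#'   RRACH-style consensus "GGACT".
#' @param motif_copies integer vector of candidate per-positive motif copy
#'   counts, sampled uniformly.
#' @param background named base probabilities for A/C/G/T.
#' @param decoy_policy `"none"` resamples any negative that contains an
#'   exact match of a motif; `"allow"` keeps negatives as drawn.
#' @param seed integer seed.
#' @return list of class `m6a_synth_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg = 2L * n_pos,
                           length_range = c(20L, 800L),
                           motifs = "GGACT", motif_copies = 1:3,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           decoy_policy = c("none", "allow"),
                           seed = 1L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L,
            length_range[1L] >= 1L, length_range[2L] >= length_range[1L])
  if (max(nchar(motifs)) > length_range[1L])
    stop("motif longer than the minimum sequence length")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background probabilities must sum to 1")
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               length_range = as.integer(length_range),
               motifs = toupper(motifs),
               motif_copies = as.integer(motif_copies),
               background = background,
               decoy_policy = match.arg(decoy_policy),
               seed = as.integer(seed))
  class(spec) <- "m6a_synth_spec"
  spec
}

random_background <- function(len, background) {
  paste0(sample(names(background), len, replace = TRUE,
                prob = background), collapse = "")
}

#' Plant a motif instance into a sequence
#'
#' Degenerate IUPAC codes are resolved by a uniform random choice among the
#' bases they denote (using the current RNG state); the resolved motif is
#' written into the sequence at the given 0-based position.
#'
#' @param sequence host sequence string.
#' @param motif IUPAC motif string.
#' @param position 0-based start position; the motif must fit.
#' @return list with `sequence` (modified string) and `interval`
#'   (`c(start, end)`, 0-based half-open).
#' @export
plant_motif <- function(sequence, motif, position) {
  m <- nchar(motif)
  n <- nchar(sequence)
  if (position < 0L || position + m > n)
    stop("motif does not fit at position ", position,
         " (sequence length ", n, ")")
  resolved <- paste0(vapply(strsplit(toupper(motif), "")[[1L]], function(ch) {
    opts <- IUPAC[[ch]]
    if (is.null(opts)) stop("unknown IUPAC code: ", ch)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
  out <- paste0(substr(sequence, 1L, position), resolved,
                substr(sequence, position + m + 1L, n))
  list(sequence = out, interval = c(start = position, end = position + m))
}

#' Generate a labelled synthetic dataset
#'
#' Deterministic given `spec$seed`.  Positives carry at least one planted
#' motif (coordinates retained in `motif_intervals`); under
#' `decoy_policy = "none"` negatives are resampled until they contain no
#' exact motif match, so a motif scan separates the classes perfectly and
#' the learning task is solvable by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [sequence_record()]s (positives first).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "m6a_synth_spec"))
  regexes <- vapply(spec$motifs, iupac_regex, "")
  recs <- vector("list", spec$n_pos + spec$n_neg)
  with_preserved_seed(spec$seed, {
    for (i in seq_len(spec$n_pos)) {
      len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      s <- random_background(len, spec$background)
      ncopy <- if (length(spec$motif_copies) == 1L) spec$motif_copies
               else sample(spec$motif_copies, 1L)
      ivals <- matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
      placed <- 0L
      tries <- 0L
      while (placed < ncopy && tries < 50L) {
        tries <- tries + 1L
        motif <- if (length(spec$motifs) == 1L) spec$motifs
                 else sample(spec$motifs, 1L)
        m <- nchar(motif)
        pos <- sample.int(len - m + 1L, 1L) - 1L
        if (nrow(ivals) &&
            any(pos < ivals[, "end"] & pos + m > ivals[, "start"]))
          next                                  # overlap: re-draw position
        pl <- plant_motif(s, motif, pos)
        s <- pl$sequence
        ivals <- rbind(ivals, pl$interval)
        placed <- placed + 1L
      }
      recs[[i]] <- sequence_record(sprintf("pos_%05d", i), s, 1L,
                                   motif_intervals = ivals)
    }
    for (j in seq_len(spec$n_neg)) {
      len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      repeat {
        s <- random_background(len, spec$background)
        if (spec$decoy_policy == "allow" ||
            !any(vapply(regexes, function(rx) grepl(rx, s), logical(1))))
          break
      }
      recs[[spec$n_pos + j]] <- sequence_record(sprintf("neg_%05d", j), s, 0L)
    }
  })
  recs
}

#' Write a synthetic dataset to disk
#'
#' FASTA sequences (labels as `label=` header tokens), a TSV label sidecar,
#' and a BED file of the ground-truth motif intervals (0-based half-open).
#'
#' @param records output of [generate_dataset()].
#' @param prefix output path prefix.
#' @return paths written, invisibly.
#' @export
write_dataset <- function(records, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".labels.tsv")
  bed <- paste0(prefix, ".motifs.bed")
  write_fasta(records, fa)
  lab <- data.frame(id = vapply(records, `[[`, "", "id"),
                    label = vapply(records, `[[`, integer(1), "label"))
  write.table(lab, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rows <- do.call(rbind, lapply(records, function(r) {
    if (is.null(r$motif_intervals) || !nrow(r$motif_intervals)) return(NULL)
    data.frame(chrom = r$id, start = r$motif_intervals[, "start"],
               end = r$motif_intervals[, "end"])
  }))
  if (is.null(rows)) rows <- data.frame(chrom = character(0),
                                        start = integer(0), end = integer(0))
  write.table(rows, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(fa, tsv, bed))
}
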