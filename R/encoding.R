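#' @title Sequence I/O and max-length padded label encoding
#'
#' @description
#' Variable-length nucleotide sequences are mapped to a fixed-shape integer
#' representation: each base is label-encoded (P -> 0, A -> 1, T -> 2,
#' G -> 3, C -> 4, where P is the padding symbol) and every sequence is
#' left-padded with the code 0 to the maximum length `L_max`, so that e.g.
#' `"ATTCG"` with `L_max = 10` becomes the vector
#' `c(0,0,0,0,0,1,2,2,4,3)`.
#'
#' @name encoding
NULL

# fixed code map: names are the canonical alphabet after normalisation
BASE_CODES <- c(P = 0L, A = 1L, T = 2L, G = 3L, C = 4L)
CODE_BASES <- names(BASE_CODES)

#' Construct a sequence record
#'
#' @param id identifier string.
#' @param sequence nucleotide string over A/C/G/T (U accepted, mapped to T).
#' @param label optional binary class label (1 = contains an m6A site).
#' @param motif_intervals optional integer matrix of known motif intervals
#'   (columns `start`, `end`; 0-based, half-open) used by the synthetic
#'   generator to retain ground truth.
#' @return a list of class `m6a_record`.
#' @export
sequence_record <- function(id, sequence, label = NA_integer_,
                            motif_intervals = NULL) {
  rec <- list(id = as.character(id), sequence = as.character(sequence),
              label = if (is.na(label)) NA_integer_ else as.integer(label),
              motif_intervals = motif_intervals)
  class(rec) <- "m6a_record"
  rec
}

#' Normalise a nucleotide sequence
#'
#' Uppercases and maps U to T.  Under the default strict policy any symbol
#' outside A/C/G/T raises an error; under `"map_to_pad"` ambiguous symbols
#' are replaced by the padding symbol `P` (code 0) with a warning.
#'
#' @param sequence character string.
#' @param ambiguous_policy `"strict"` or `"map_to_pad"`.
#' @param id identifier used in error messages.
#' @return the normalised sequence string.
#' @export
normalize_sequence <- function(sequence, ambiguous_policy = "strict",
                               id = "<sequence>") {
  s <- toupper(sequence)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (!nzchar(s)) stop("sequence '", id, "' is empty")
  bad <- gregexpr("[^ACGT]", s)[[1L]]
  if (bad[1L] != -1L) {
    sym <- unique(substring(s, bad, bad))
    if (identical(ambiguous_policy, "map_to_pad")) {
      warning("sequence '", id, "': ambiguous symbol(s) ",
              paste(sym, collapse = ", "), " encoded as padding")
      for (ch in sym) s <- gsub(ch, "P", s, fixed = TRUE)
    } else {
      stop("sequence '", id, "' contains invalid symbol(s): ",
           paste(sym, collapse = ", "), " (first at position ", bad[1L], ")")
    }
  }
  s
}

#' Read sequences (and optional labels) from FASTA
#'
#' Labels may be carried in the FASTA header as a `label=0|1` token, or in a
#' two-column tab-separated sidecar file (`id<TAB>label`).  Sequences are
#' normalised on input (uppercase, U -> T).
#'
#' @param path FASTA file.
#' @param labels_path optional TSV sidecar with columns id and label.
#' @param ambiguous_policy see [normalize_sequence()].
#' @return list of [sequence_record()]s in file order.
#' @export
read_fasta <- function(path, labels_path = NULL, ambiguous_policy = "strict") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no sequences")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  labels <- rep(NA_integer_, length(set))
  m <- regmatches(headers, regexpr("label=([01])", headers))
  has <- lengths(regmatches(headers, gregexpr("label=([01])", headers))) > 0
  labels[has] <- as.integer(sub("label=", "", m))
  if (!is.null(labels_path)) {
    tab <- read.table(labels_path, sep = "\t", header = FALSE,
                      col.names = c("id", "label"),
                      colClasses = c("character", "integer"))
    idx <- match(ids, tab$id)
    labels[!is.na(idx)] <- tab$label[idx[!is.na(idx)]]
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- normalize_sequence(as.character(set[[i]]), ambiguous_policy,
                            id = ids[i])
    out[[i]] <- sequence_record(ids[i], s, labels[i])
  }
  out
}

#' Write sequence records to FASTA (labels as header tokens)
#'
#' @param records list of [sequence_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  hdr <- vapply(records, function(r) {
    if (is.na(r$label)) r$id else paste0(r$id, " label=", r$label)
  }, "")
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Encode one sequence as a padded integer vector
#'
#' @param sequence normalised sequence string (A/C/G/T, optionally P).
#' @param L_max padded length.
#' @param padding_side `"left"` (default) or `"right"`.
#' @param truncate `"error"` or `"center"` handling of over-length input.
#' @return integer vector of length `L_max` with entries in 0..4.
#' @examples
#' encode_pad("ATTCG", 10)  # 0 0 0 0 0 1 2 2 4 3
#' @export
encode_pad <- function(sequence, L_max, padding_side = "left",
                       truncate = "error") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n > L_max) {
    if (identical(truncate, "center")) {
      off <- (n - L_max) %/% 2L
      chars <- chars[(off + 1L):(off + L_max)]
      n <- L_max
    } else {
      stop("sequence of length ", n, " exceeds L_max = ", L_max,
           " and truncation is disabled")
    }
  }
  codes <- BASE_CODES[chars]
  if (anyNA(codes))
    stop("sequence contains symbols outside the P/A/T/G/C alphabet")
  pad <- integer(L_max - n)
  if (identical(padding_side, "right")) out <- c(codes, pad)
  else out <- c(pad, codes)
  names(out) <- NULL
  as.integer(out)
}

#' Decode a padded code vector back to a sequence
#'
#' Inverse of [encode_pad()]: strips the leading zero padding and maps codes
#' back to bases.  A zero appearing after a nonzero entry signals a corrupt
#' left-padded vector and raises an error.  An all-zero vector decodes to the
#' empty string.
#'
#' @param codes integer vector with entries in 0..4.
#' @return nucleotide string.
#' @export
decode_codes <- function(codes) {
  if (any(codes < 0L | codes > 4L)) stop("codes must lie in 0..4")
  nz <- which(codes != 0L)
  if (!length(nz)) return("")
  body <- codes[nz[1L]:length(codes)]
  if (any(body == 0L))
    stop("corrupt encoding: padding code 0 after the first base")
  paste0(CODE_BASES[body + 1L], collapse = "")
}

#' Encode a batch of records
#'
#' @param records list of [sequence_record()]s.
#' @param L_max padded length.
#' @param padding_side,truncate see [encode_pad()].
#' @return list of class `m6a_batch` with `codes` (n x L_max integer
#'   matrix), `lengths`, `labels` (or NULL) and `ids`.
#' @export
batch_encode <- function(records, L_max, padding_side = "left",
                         truncate = "error") {
  n <- length(records)
  codes <- matrix(0L, nrow = n, ncol = L_max)
  lengths <- integer(n)
  labels <- vapply(records, function(r)
    if (is.null(r$label)) NA_integer_ else r$label, integer(1))
  if (n > 0L && any(is.na(labels)) && !all(is.na(labels)))
    stop("labels must be present for all records or for none")
  for (i in seq_len(n)) {
    v <- encode_pad(records[[i]]$sequence, L_max, padding_side, truncate)
    codes[i, ] <- v
    lengths[i] <- min(nchar(records[[i]]$sequence), L_max)
  }
  out <- list(codes = codes, lengths = lengths,
              labels = if (n == 0L || all(is.na(labels))) NULL else labels,
              ids = vapply(records, `[[`, "", "id"))
  class(out) <- "m6a_batch"
  out
}
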