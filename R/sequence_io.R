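# Fixed channel order for one-hot encoding. Alphabetical; position j of a
# sequence maps to a length-4 indicator row in this order.
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Read a FASTA file of DNA sequences
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and attaches a
#' single binary class label to every record. Sequences are normalized to
#' uppercase. Alphabet validation is a separate step: see
#' [validate_alphabet()].
#'
#' @param path Path to a FASTA file.
#' @param label Class label attached to every record: `1` for nucleosome,
#'   `0` for linker, or `NA` for unlabeled sequences (e.g. prediction input).
#' @return A data frame with columns `id` (record identifier, the first
#'   whitespace-delimited token of the header), `seq` (uppercase sequence
#'   string) and `label`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ttttgggg"), fa)
#' read_fasta(fa, label = 1)
#' @seealso [read_dataset()] for the two-file positive/negative convention.
#' @export
read_fasta <- function(path, label = NA_integer_) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stopf("FASTA record(s) with no sequence: %s",
          paste(ids[widths == 0L], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stopf("duplicated FASTA ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stopf("label must be 0, 1 or NA, got %s", format(label))
  }
  data.frame(id = ids,
             seq = toupper(as.character(set)),
             label = rep(as.integer(label), length(set)),
             stringsAsFactors = FALSE)
}

#' Validate sequences against the A/C/G/T alphabet
#'
#' DNA one-hot encoding assumes the strict four-letter alphabet. IUPAC
#' ambiguity codes (including `N`) are either rejected (`policy = "strict"`,
#' the default) or the offending sequences are dropped with a message
#' (`policy = "drop"`). No fractional encoding of ambiguous bases is offered.
#'
#' @param seqs A data frame as returned by [read_fasta()], or a
#'   `nucnet_dataset`.
#' @param policy `"strict"` (error on the first offending base, naming the
#'   record and position) or `"drop"` (remove offending sequences).
#' @return The input with only valid sequences retained.
#' @export
validate_alphabet <- function(seqs, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  df <- if (inherits(seqs, "nucnet_dataset")) as.data.frame(seqs) else seqs
  bad_pos <- regexpr("[^ACGT]", df$seq)
  offenders <- which(bad_pos > 0L)
  if (length(offenders) == 0L) return(seqs)
  if (policy == "strict") {
    i <- offenders[1L]
    stopf("sequence '%s' contains non-ACGT character '%s' at position %d",
          df$id[i], substr(df$seq[i], bad_pos[i], bad_pos[i]), bad_pos[i])
  }
  message(sprintf("validate_alphabet: dropped %d of %d sequence(s) with non-ACGT characters",
                  length(offenders), nrow(df)))
  kept <- df[-offenders, , drop = FALSE]
  if (inherits(seqs, "nucnet_dataset")) {
    labeled_dataset(kept$id, kept$seq, kept$label)
  } else {
    kept
  }
}

#' Construct a labeled fixed-length sequence dataset
#'
#' The container used throughout the package: equal-length DNA sequences over
#' A/C/G/T with binary labels (1 = nucleosome, 0 = linker).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of equal-length uppercase DNA strings.
#' @param label Integer vector of 0/1 labels (no `NA`).
#' @return An object of class `nucnet_dataset`: a list with elements `id`,
#'   `seq`, `label`, `length` (common sequence length L) and `class_counts`
#'   (named vector, positives then negatives).
#' @export
labeled_dataset <- function(id, seq, label) {
  if (length(id) != length(seq) || length(seq) != length(label)) {
    stopf("id, seq and label must have equal lengths")
  }
  if (length(seq) == 0L) stopf("dataset must contain at least one sequence")
  if (anyDuplicated(id)) stopf("sequence ids must be unique")
  label <- as.integer(label)
  if (anyNA(label) || !all(label %in% c(0L, 1L))) {
    stopf("all labels must be 0 or 1")
  }
  lens <- nchar(seq)
  if (length(unique(lens)) != 1L) {
    off <- id[lens != lens[1L]]
    stopf("sequences must share one length; offending ids: %s",
          paste(utils::head(off, 5L), collapse = ", "))
  }
  structure(
    list(id = as.character(id), seq = toupper(seq), label = label,
         length = lens[1L],
         class_counts = c(n_positive = sum(label == 1L),
                          n_negative = sum(label == 0L))),
    class = "nucnet_dataset")
}

#' @export
as.data.frame.nucnet_dataset <- function(x, ...) {
  data.frame(id = x$id, seq = x$seq, label = x$label, stringsAsFactors = FALSE)
}

#' @export
length.nucnet_dataset <- function(x) length(x$seq)

#' @export
print.nucnet_dataset <- function(x, ...) {
  cat(sprintf("<nucnet_dataset> %d sequences of length %d bp (%d nucleosome, %d linker)\n",
              length(x$seq), x$length,
              x$class_counts[["n_positive"]], x$class_counts[["n_negative"]]))
  invisible(x)
}

#' Subset a dataset by index
#'
#' @param x A `nucnet_dataset`.
#' @param i Integer or logical index over sequences.
#' @param ... Ignored.
#' @return A `nucnet_dataset` with the selected sequences.
#' @export
`[.nucnet_dataset` <- function(x, i, ...) {
  labeled_dataset(x$id[i], x$seq[i], x$label[i])
}

#' Read a positive/negative FASTA pair into a labeled dataset
#'
#' The two-file convention: one FASTA of nucleosome (positive) sequences and
#' one of linker (negative) sequences.
#'
#' @param positive_fasta,negative_fasta FASTA paths.
#' @param policy Alphabet policy passed to [validate_alphabet()].
#' @return A `nucnet_dataset`.
#' @export
read_dataset <- function(positive_fasta, negative_fasta, policy = "strict") {
  pos <- validate_alphabet(read_fasta(positive_fasta, label = 1L), policy)
  neg <- validate_alphabet(read_fasta(negative_fasta, label = 0L), policy)
  both <- rbind(pos, neg)
  if (anyDuplicated(both$id)) {
    both$id <- c(paste0("pos_", pos$id), paste0("neg_", neg$id))
  }
  labeled_dataset(both$id, both$seq, both$label)
}

#' Write a labeled dataset as a positive/negative FASTA pair
#'
#' @param ds A `nucnet_dataset`.
#' @param positive_fasta,negative_fasta Output paths for the nucleosome and
#'   linker sequences.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_dataset_fasta <- function(ds, positive_fasta, negative_fasta) {
  stopifnot(inherits(ds, "nucnet_dataset"))
  for (side in list(list(lab = 1L, path = positive_fasta),
                    list(lab = 0L, path = negative_fasta))) {
    keep <- ds$label == side$lab
    set <- Biostrings::DNAStringSet(ds$seq[keep])
    names(set) <- ds$id[keep]
    Biostrings::writeXStringSet(set, side$path, width = 80L)
  }
  invisible(c(positive_fasta, negative_fasta))
}

#' One-hot encode DNA sequences
#'
#' Transforms each length-L sequence into an L x 4 binary indicator matrix
#' with fixed channel order A, C, G, T (position rows, symbol channels), the
#' standard input representation for sequence convolution. Batched output.
#'
#' @param x A `nucnet_dataset`, a data frame with a `seq` column, or a
#'   character vector of equal-length A/C/G/T strings.
#' @return A numeric array of dimension `(N, L, 4)` with entries in {0, 1};
#'   each position row sums to exactly 1. Channel dimnames are A, C, G, T.
#' @examples
#' one_hot_encode("ACGT")[1, , ]  # the 4 x 4 identity matrix
#' @export
one_hot_encode <- function(x) {
  seqs <- if (inherits(x, "nucnet_dataset")) x$seq
          else if (is.data.frame(x)) x$seq
          else as.character(x)
  if (length(seqs) == 0L) stopf("no sequences to encode")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    ids <- if (inherits(x, "nucnet_dataset")) x$id else as.character(seq_along(seqs))
    stopf("sequences must have equal lengths; offending ids: %s",
          paste(utils::head(ids[lens != lens[1L]], 5L), collapse = ", "))
  }
  L <- lens[1L]
  n <- length(seqs)
  # map characters to channel indices in one pass
  chan <- match(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]],
                DNA_ALPHABET)
  if (anyNA(chan)) stopf("non-ACGT character encountered; run validate_alphabet() first")
  arr <- array(0, dim = c(n, L, 4L),
               dimnames = list(NULL, NULL, DNA_ALPHABET))
  # chan is laid out sequence-major: positions of seq 1, then seq 2, ...
  pos <- rep(seq_len(L), times = n)
  sid <- rep(seq_len(n), each = L)
  arr[cbind(sid, pos, chan)] <- 1
  arr
}

#' Decode one-hot tensors back to sequence strings
#'
#' Exact inverse of [one_hot_encode()] for valid one-hot input.
#'
#' @param t Array of dimension `(N, L, 4)` (or a single `(L, 4)` matrix) with
#'   one 1 per position row.
#' @return Character vector of N sequences.
#' @export
one_hot_decode <- function(t) {
  if (is.matrix(t)) t <- array(t, dim = c(1L, nrow(t), ncol(t)))
  stopifnot(length(dim(t)) == 3L, dim(t)[3L] == 4L)
  n <- dim(t)[1L]; L <- dim(t)[2L]
  sums <- apply(t, c(1L, 2L), sum)
  binary <- all(t %in% c(0, 1))
  if (!binary || any(sums != 1)) {
    bad <- which(sums != 1, arr.ind = TRUE)
    if (nrow(bad) == 0L) bad <- matrix(c(1L, 1L), 1L)
    stopf("not a valid one-hot tensor: row (sequence %d, position %d) does not sum to 1",
          bad[1L, 1L], bad[1L, 2L])
  }
  out <- character(n)
  for (i in seq_len(n)) {
    idx <- max.col(matrix(t[i, , ], nrow = L), ties.method = "first")
    out[i] <- paste(DNA_ALPHABET[idx], collapse = "")
  }
  out
}
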