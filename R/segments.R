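# Canonical nucleotide and dinucleotide orders used throughout the package.
# Dinucleotides are lexicographic AA, AC, ..., UU; external tables that list
# another order are mapped by name on read.
RNA_BASES <- c("A", "C", "G", "U")
RNA_DINUCS <- as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))

#' Construct an RNA segment with a central uridine
#'
#' A segment is a fixed, odd-length window of `2*xi + 1` nucleotides over the
#' alphabet A/C/G/U whose central position is always U. Segments are the unit
#' every feature encoder consumes.
#'
#' @param sequence Character scalar over A/C/G/U (T is accepted and mapped to
#'   U; lower case is accepted).
#' @param xi Half-window size: the number of nucleotides flanking the central
#'   U on each side.
#' @param origin Optional list with `id` (source sequence identifier) and
#'   `position` (1-based position of the central U on the source sequence).
#' @return An object of class `rna_segment`.
#' @examples
#' rna_segment("ACGUUUGCA", xi = 4)
#' @export
rna_segment <- function(sequence, xi, origin = NULL) {
  sequence <- normalize_rna(sequence, what = "segment")
  validate_segment(sequence, xi)
  structure(
    list(sequence = sequence, xi = as.integer(xi), origin = origin),
    class = "rna_segment"
  )
}

#' @export
print.rna_segment <- function(x, ...) {
  cat(sprintf("<rna_segment> %s (xi = %d)\n", x$sequence, x$xi))
  if (!is.null(x$origin)) {
    cat(sprintf("  origin: %s position %d\n", x$origin$id, x$origin$position))
  }
  invisible(x)
}

# Uppercase, T->U, and reject anything outside the RNA alphabet.
normalize_rna <- function(sequence, what = "sequence", id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("tT", "uU", sequence)
  s <- toupper(s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L) {
    where <- if (is.null(id)) what else sprintf("%s '%s'", what, id)
    stop(sprintf("invalid character '%s' at position %d of %s",
                 substr(s, bad, bad), bad, where), call. = FALSE)
  }
  s
}

validate_segment <- function(sequence, xi) {
  xi <- as.integer(xi)
  if (is.na(xi) || xi < 1L) stop("xi must be a positive integer", call. = FALSE)
  L <- nchar(sequence)
  if (L != 2L * xi + 1L) {
    stop(sprintf("segment length %d != 2*xi + 1 = %d", L, 2L * xi + 1L),
         call. = FALSE)
  }
  if (substr(sequence, xi + 1L, xi + 1L) != "U") {
    stop(sprintf("central position %d of segment is '%s', not 'U'",
                 xi + 1L, substr(sequence, xi + 1L, xi + 1L)), call. = FALSE)
  }
  invisible(TRUE)
}

seg_string <- function(segment) {
  if (inherits(segment, "rna_segment")) segment$sequence else segment
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA-style T is converted to U; any other
#' symbol (including ambiguity codes) is an error naming the record and
#' position, rather than being skipped.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_rna(seqs[[i]], what = "record", id = ids[[i]])
  }, character(1))
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids Character vector of record identifiers.
#' @param sequences Character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Reflecting boundary index: maps any integer position onto 1..L by mirror
# reflection about the terminal nucleotide, terminus excluded from the
# reflection, repeating (ping-pong) when the deficit exceeds the sequence.
reflect_index <- function(i, L) {
  if (L == 1L) return(rep(1L, length(i)))
  period <- 2L * (L - 1L)
  j <- (i - 1L) %% period
  ifelse(j >= L, period - j, j) + 1L
}

#' Extract a centered window with mirror-image padding
#'
#' Returns the `2*xi + 1` window centered on a uridine. Where the sequence has
#' fewer than `xi` nucleotides on a side, the deficit is filled by reflecting
#' the sequence about its terminal nucleotide (the terminus itself is not
#' duplicated), repeating the reflection if the sequence is shorter than the
#' deficit.
#'
#' @param sequence Character scalar; T is mapped to U.
#' @param center 1-based position of the uridine to center on.
#' @param xi Half-window size.
#' @param id Optional source identifier stored in the segment's origin.
#' @return An [rna_segment].
#' @examples
#' mirror_pad("ACGU", center = 4, xi = 2)  # "CGUGC"
#' @export
mirror_pad <- function(sequence, center, xi, id = NULL) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > L) {
    stop(sprintf("center %d out of range 1..%d", center, L), call. = FALSE)
  }
  if (substr(sequence, center, center) != "U") {
    stop(sprintf("position %d is '%s', not 'U'",
                 center, substr(sequence, center, center)), call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- reflect_index(seq(center - xi, center + xi), L)
  rna_segment(paste(chars[idx], collapse = ""), xi,
              origin = list(id = id, position = center))
}

#' Extract one segment per uridine in a sequence
#'
#' Slides a `2*xi + 1` window over every U in the sequence, mirror-padding
#' windows that overhang either terminus. Mirrors the behavior of the web
#' scanner: the sequence must be at least `2*xi + 1` nucleotides long (21 for
#' xi = 10, 31 for xi = 15).
#'
#' @inheritParams mirror_pad
#' @return A list of [rna_segment] objects in positional order; empty if the
#'   sequence contains no U.
#' @export
extract_segments <- function(sequence, xi, id = NULL) {
  sequence <- normalize_rna(sequence, what = "query", id = id)
  L <- nchar(sequence)
  need <- 2L * as.integer(xi) + 1L
  if (L < need) {
    stop(sprintf("sequence length %d is below the minimum of %d (2*xi + 1 for xi = %d)",
                 L, need, xi), call. = FALSE)
  }
  centers <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == "U")
  lapply(centers, function(p) mirror_pad(sequence, p, xi, id = id))
}

#' Construct a labeled segment dataset
#'
#' @param segments Character vector of segment strings (or list of
#'   [rna_segment]), all sharing the same half-window size.
#' @param labels Character vector of `"pos"` / `"neg"` (or logical, TRUE =
#'   positive).
#' @param xi Half-window size shared by all segments.
#' @param name Dataset name used in reports and model provenance.
#' @return An object of class `psi_dataset`.
#' @export
psi_dataset <- function(segments, labels, xi, name = "dataset") {
  if (is.list(segments)) segments <- vapply(segments, seg_string, character(1))
  segments <- vapply(segments, normalize_rna, character(1), USE.NAMES = FALSE)
  if (is.logical(labels)) labels <- ifelse(labels, "pos", "neg")
  labels <- as.character(labels)
  if (!all(labels %in% c("pos", "neg"))) {
    stop("labels must be 'pos' or 'neg'", call. = FALSE)
  }
  if (length(labels) != length(segments)) {
    stop("segments and labels must have equal length", call. = FALSE)
  }
  for (s in segments) validate_segment(s, xi)
  structure(
    list(segments = segments, labels = labels, xi = as.integer(xi),
         name = name),
    class = "psi_dataset"
  )
}

#' @export
print.psi_dataset <- function(x, ...) {
  cat(sprintf("<psi_dataset> %s: %d segments of length %d (xi = %d), %d pos / %d neg\n",
              x$name, length(x$segments), 2L * x$xi + 1L, x$xi,
              sum(x$labels == "pos"), sum(x$labels == "neg")))
  invisible(x)
}

n_pos <- function(dataset) sum(dataset$labels == "pos")
n_neg <- function(dataset) sum(dataset$labels == "neg")

subset_dataset <- function(dataset, keep) {
  psi_dataset(dataset$segments[keep], dataset$labels[keep], dataset$xi,
              name = dataset$name)
}

#' Load a labeled benchmark FASTA
#'
#' The canonical benchmark format is plain FASTA of fixed-length segments with
#' the class encoded in the header (default: headers matching `^pos` are
#' positive, `^neg` negative). Every record must satisfy the segment
#' invariants: length `2*xi + 1` with the central nucleotide U.
#'
#' @param path Path to a benchmark FASTA file.
#' @param xi Half-window size the segments must match.
#' @param label_rule Named list of two regular expressions, `pos` and `neg`,
#'   applied to record headers.
#' @param name Dataset name; defaults to the file name without extension.
#' @return A [psi_dataset].
#' @export
load_benchmark <- function(path, xi,
                           label_rule = list(pos = "^pos", neg = "^neg"),
                           name = NULL) {
  recs <- read_fasta(path)
  is_pos <- grepl(label_rule$pos, recs$id)
  is_neg <- grepl(label_rule$neg, recs$id)
  unlabeled <- !is_pos & !is_neg
  if (any(unlabeled)) {
    stop(sprintf("header '%s' matches neither label pattern ('%s' / '%s')",
                 recs$id[which(unlabeled)[1]], label_rule$pos, label_rule$neg),
         call. = FALSE)
  }
  if (any(is_pos & is_neg)) {
    stop("label patterns are ambiguous: a header matches both", call. = FALSE)
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  psi_dataset(recs$sequence, ifelse(is_pos, "pos", "neg"), xi, name = name)
}

#' Write a labeled dataset as benchmark FASTA
#'
#' Headers follow the canonical `pos_<i>` / `neg_<i>` convention that
#' [load_benchmark()] reads back.
#'
#' @param dataset A [psi_dataset].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(dataset, path) {
  counter <- c(pos = 0L, neg = 0L)
  ids <- character(length(dataset$segments))
  for (i in seq_along(ids)) {
    lab <- dataset$labels[i]
    counter[lab] <- counter[lab] + 1L
    ids[i] <- sprintf("%s_%d", lab, counter[lab])
  }
  write_fasta(ids, dataset$segments, path)
}

# Integer encodings used by the fast encoder paths: one row per segment,
# values 1..4 (nucleotides) or 1..16 (overlapping dinucleotides).
seg_nuc_idx <- function(sequences) {
  L <- nchar(sequences[1])
  m <- matrix(match(unlist(strsplit(sequences, "", fixed = TRUE)), RNA_BASES),
              nrow = length(sequences), ncol = L, byrow = TRUE)
  m
}

seg_dinuc_idx <- function(nuc_idx) {
  L <- ncol(nuc_idx)
  (nuc_idx[, -L, drop = FALSE] - 1L) * 4L + nuc_idx[, -1L, drop = FALSE]
}
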