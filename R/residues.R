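#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order.
#' Integer residue codes used throughout the package are 0-based positions
#' in this vector (A = 0, ..., Y = 19). The ordering is a documented
#' convention only; nothing downstream relies on it numerically.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode an amino-acid sequence as integer residue codes
#'
#' Maps each canonical residue letter to its 0-based alphabetical code
#' (A = 0, ..., Y = 19). Non-canonical letters (wildcards such as X, B, Z,
#' U, O) are tolerated and encoded as `NA`, the unknown sentinel; they are
#' excluded from residue-type-guided contrastive sampling downstream.
#'
#' @param sequence Single non-empty character string of residue letters
#'   (case-insensitive).
#' @return Integer vector of per-position codes in 0..19, `NA` for unknowns.
#' @examples
#' encode_residues("ACDE")
#' encode_residues("AXA")
#' @export
encode_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  letters_vec <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(letters_vec, AA_ALPHABET) - 1L
  codes
}

#' Decode integer residue codes back to letters
#'
#' Left inverse of [encode_residues()] on canonical letters; unknown
#' sentinels decode to `"X"`.
#'
#' @param codes Integer vector of residue codes (0..19 or `NA`).
#' @return Character string of residue letters.
#' @export
decode_residues <- function(codes) {
  out <- ifelse(is.na(codes), "X", AA_ALPHABET[codes + 1L])
  paste(out, collapse = "")
}

#' Construct a protein record
#'
#' Bundles a protein's identifier, sequence, per-residue type codes, its
#' prediction target and its data split. Exactly one task mode applies per
#' record: a class index (0-based, among the thermostability categories or
#' hot/cold) for `task = "classification"`, or a melting temperature in
#' degrees Celsius for `task = "regression"`.
#'
#' @param id Protein identifier (unique within a data set).
#' @param sequence Residue letters; upper-cased on construction.
#' @param target Class index in 0..C-1, or melting temperature (numeric, degrees C).
#' @param task `"classification"` or `"regression"`.
#' @param split One of `"train"`, `"valid"`, `"test"`.
#' @param n_classes Number of classes C (classification only).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, target, task = c("classification", "regression"),
                           split = c("train", "valid", "test"), n_classes = NULL) {
  task <- match.arg(task)
  split <- match.arg(split)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  validate_sequence_letters(sequence, id)
  labels <- encode_residues(sequence)
  if (task == "classification") {
    stopifnot(!is.null(n_classes), n_classes >= 2)
    target <- as.integer(target)
    if (is.na(target) || target < 0L || target >= n_classes)
      stop(sprintf("record '%s': class index %s outside 0..%d", id, target, n_classes - 1L))
  } else {
    target <- as.numeric(target)
    if (!is.finite(target)) stop(sprintf("record '%s': missing or non-finite temperature", id))
  }
  structure(list(id = id, sequence = sequence, residue_labels = labels,
                 target = target, task = task, split = split,
                 n_classes = if (task == "classification") as.integer(n_classes) else NULL),
            class = "protein_record")
}

validate_sequence_letters <- function(sequence, id) {
  bad <- grepl("[^A-Za-z]", sequence)
  if (!nzchar(sequence)) stop(sprintf("record '%s': empty sequence", id))
  if (bad) stop(sprintf("record '%s': sequence contains non-letter characters", id))
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  tgt <- if (x$task == "classification") sprintf("class %d/%d", x$target, x$n_classes)
         else sprintf("Tm %.1f C", x$target)
  cat(sprintf("<protein_record> %s  L=%d  %s  split=%s\n",
              x$id, nchar(x$sequence), tgt, x$split))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses FASTA via Biostrings and returns bare records (sequence and
#' residue codes populated; targets must be attached separately, e.g. from
#' container metadata). Sequences are upper-cased; non-canonical letters
#' become the unknown sentinel in `residue_labels`.
#'
#' @param path Path to a FASTA file.
#' @param task,split,n_classes Passed through to [protein_record()]; records
#'   get a placeholder target (class 0 or 0 degrees C) pending real metadata.
#' @return List of `protein_record`.
#' @export
read_fasta <- function(path, task = "classification", split = "train",
                       n_classes = 5L) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("FASTA file '%s' contains no records", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    validate_sequence_letters(toupper(s), ids[i])
    out[[i]] <- protein_record(ids[i], s, target = 0,
                               task = task, split = split, n_classes = n_classes)
  }
  out
}
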