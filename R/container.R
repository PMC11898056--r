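#' Validate and symmetrize a residue contact map
#'
#' Contact maps are L x L matrices of residue-residue interaction strengths
#' in \[0, 1\] (e.g. contact probabilities emitted alongside protein
#' language-model embeddings). The matrix must be symmetric up to a small
#' numerical tolerance; tolerable asymmetry is removed by averaging with the
#' transpose, and values within 1e-9 of the \[0, 1\] boundary are clipped.
#' Weights are kept as-is (no binarization): downstream graph convolution
#' consumes them as a weighted adjacency.
#'
#' @param values Square numeric matrix.
#' @param tol Maximum permitted absolute asymmetry (default 1e-6).
#' @return The validated, exactly symmetric matrix (class `contact_map`).
#' @export
validate_contact_map <- function(values, tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("contact map must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("contact map must be square")
  if (any(!is.finite(values)))
    stop("contact map contains non-finite entries")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("contact map asymmetry %.3g exceeds tolerance %.1g", asym, tol))
  eps <- 1e-9
  if (any(values < -eps) || any(values > 1 + eps))
    stop("contact map entries outside [0, 1]")
  m <- (values + t(values)) / 2
  m[m < 0] <- 0
  m[m > 1] <- 1
  structure(m, class = c("contact_map", "matrix", "array"))
}

validate_embedding <- function(values, id = "?") {
  if (!is.matrix(values) || !is.numeric(values) || any(!is.finite(values)))
    stop(sprintf("protein '%s': embedding must be a finite numeric matrix", id))
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop(sprintf("protein '%s': embedding must be at least 1 x 1", id))
  values
}

#' Write a protein data set container
#'
#' Serializes records plus their embedding and contact arrays into the
#' package's native container: a single uncompressed RDS file holding, per
#' protein id, the float embedding (L x F) and contact (L x L) matrices, and
#' one metadata table with columns id, target, split, task. Writing is fully
#' deterministic: the same content yields a byte-identical file.
#'
#' @param triples List of `list(record, embedding, contact)` triples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_container()]
#' @export
write_container <- function(triples, path) {
  stopifnot(length(triples) >= 1L)
  ids <- vapply(triples, function(t) t$record$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate protein ids in container")
  meta <- data.frame(
    id = ids,
    target = vapply(triples, function(t) as.numeric(t$record$target), numeric(1)),
    split = vapply(triples, function(t) t$record$split, character(1)),
    task = vapply(triples, function(t) t$record$task, character(1)),
    stringsAsFactors = FALSE
  )
  proteins <- lapply(triples, function(t) {
    list(sequence = t$record$sequence,
         n_classes = t$record$n_classes,
         embedding = t$embedding,
         contact = unclass(t$contact))
  })
  names(proteins) <- ids
  obj <- list(format = "stabnet_container", version = 1L,
              meta = meta, proteins = proteins)
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' Load a protein data set container
#'
#' Reads a container written by [write_container()] (or
#' [generate_dataset()]), re-validating every triple: embedding and contact
#' dimensions must agree with the sequence length, contact maps must pass
#' [validate_contact_map()], targets must be present, and ids unique.
#'
#' @param path Container file path.
#' @return List of `list(record, embedding, contact)` triples.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("container not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "stabnet_container"))
    stop(sprintf("'%s' is not a stabnet container", path))
  meta <- obj$meta
  if (anyDuplicated(meta$id)) stop("container metadata has duplicate ids")
  triples <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]
    p <- obj$proteins[[id]]
    if (is.null(p)) stop(sprintf("protein '%s' listed in metadata but absent", id))
    task <- meta$task[i]
    if (is.na(meta$target[i])) stop(sprintf("protein '%s': missing target", id))
    rec <- protein_record(id, p$sequence, meta$target[i], task = task,
                          split = meta$split[i], n_classes = p$n_classes)
    L <- nchar(p$sequence)
    emb <- validate_embedding(p$embedding, id)
    if (nrow(emb) != L)
      stop(sprintf("protein '%s': embedding has %d rows but sequence length %d",
                   id, nrow(emb), L))
    if (!is.matrix(p$contact) || nrow(p$contact) != L || ncol(p$contact) != L)
      stop(sprintf("protein '%s': contact map shape does not match sequence length %d", id, L))
    cm <- validate_contact_map(p$contact)
    triples[[i]] <- list(record = rec, embedding = emb, contact = cm)
  }
  triples
}

#' Assemble padded batches of variable-length proteins
#'
#' Groups triples into batches of at most `batch_size`, zero-padding
#' embeddings and contact maps to the longest protein in each batch and
#' returning a boolean mask marking valid residue positions. Order is
#' preserved unless a shuffle seed is given, in which case the permutation
#' is reproducible from the seed.
#'
#' @param triples List of `list(record, embedding, contact)`.
#' @param batch_size Maximum proteins per batch.
#' @param shuffle_seed Optional integer; if given, triples are permuted
#'   reproducibly before batching.
#' @return List of batches, each a list with elements `records`,
#'   `embeddings` (B x L_max x F), `contacts` (B x L_max x L_max), `mask`
#'   (B x L_max logical), `targets` (length-B numeric), `lengths`.
#' @export
make_batches <- function(triples, batch_size, shuffle_seed = NULL) {
  stopifnot(length(triples) >= 1L, batch_size >= 1L)
  idx <- seq_along(triples)
  if (!is.null(shuffle_seed)) {
    rng <- local({ set.seed(as.integer(shuffle_seed)); sample.int(length(triples)) })
    idx <- rng
  }
  triples <- triples[idx]
  n <- length(triples)
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    chunk <- triples[s:min(s + batch_size - 1L, n)]
    B <- length(chunk)
    lens <- vapply(chunk, function(t) nrow(t$embedding), integer(1))
    Lmax <- max(lens)
    Fdim <- ncol(chunk[[1]]$embedding)
    emb <- array(0, dim = c(B, Lmax, Fdim))
    con <- array(0, dim = c(B, Lmax, Lmax))
    mask <- matrix(FALSE, B, Lmax)
    for (b in seq_len(B)) {
      L <- lens[b]
      emb[b, 1:L, ] <- chunk[[b]]$embedding
      con[b, 1:L, 1:L] <- chunk[[b]]$contact
      mask[b, 1:L] <- TRUE
    }
    list(records = lapply(chunk, `[[`, "record"),
         embeddings = emb, contacts = con, mask = mask,
         targets = vapply(chunk, function(t) as.numeric(t$record$target), numeric(1)),
         lengths = lens)
  })
}
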