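## Residue-type-guided triplet contrastive scheme. Anchors are sampled rows
## of the sequence representation X, positives the same residues' rows of
## the structure representation G, negatives are other sampled residues of
## a different amino-acid type. Similarity is an omega-scaled cosine; the
## positive loss pulls matching sequence/structure pairs together through a
## logistic log-loss, the negative loss pushes differently-typed anchors
## apart.

#' Contrastive learning configuration
#'
#' @param L_s Residues sampled per protein (default 64); undersized proteins
#'   contribute all their residues.
#' @param K Negatives sampled per anchor (default 5).
#' @param omega Scale factor in (0, 1) applied to cosine similarities
#'   (default 0.5); it bounds the similarity away from the logistic
#'   saturation region.
#' @param enabled If `FALSE`, [contrastive_loss()] returns exactly 0.
#' @param kernel Similarity kernel, `"cosine"` (default) or `"dot"`.
#' @return An object of class `contrastive_config`.
#' @export
contrastive_config <- function(L_s = 64L, K = 5L, omega = 0.5, enabled = TRUE,
                               kernel = c("cosine", "dot")) {
  kernel <- match.arg(kernel)
  stopifnot(L_s >= 1L, K >= 1L, omega > 0, omega < 1)
  structure(list(L_s = as.integer(L_s), K = as.integer(K), omega = omega,
                 enabled = isTRUE(enabled), kernel = kernel),
            class = "contrastive_config")
}

#' Sample residues for a contrastive pass
#'
#' Draws min(L, L_s) positions uniformly without replacement (all positions
#' in original order when the protein is shorter than L_s) and extracts the
#' anchor matrix X_s, positive matrix G_s and their residue-type labels.
#' Deterministic given the R random number state.
#'
#' @param X,G L x D sequence and structure representations.
#' @param labels Length-L integer residue codes (`NA` = unknown type).
#' @param cfg A [contrastive_config()].
#' @return An object of class `contrastive_sample` with fields `indices`,
#'   `X_s`, `G_s`, `labels`, `negatives` (unfilled).
#' @export
sample_residues <- function(X, G, labels, cfg) {
  if (!all(dim(X) == dim(G))) stop("X and G must have identical shape")
  L <- nrow(X)
  stopifnot(length(labels) == L)
  idx <- if (L <= cfg$L_s) seq_len(L) else sort(sample.int(L, cfg$L_s))
  structure(list(indices = idx,
                 X_s = X[idx, , drop = FALSE],
                 G_s = G[idx, , drop = FALSE],
                 labels = labels[idx],
                 negatives = NULL),
            class = "contrastive_sample")
}

#' Sample negative sets per anchor
#'
#' For each sampled anchor residue, draws `K` positions uniformly from the
#' sampled residues whose amino-acid type differs from the anchor's
#' (unknown-type residues are never negatives). When fewer than `K`
#' candidates exist but at least one, sampling is with replacement; anchors
#' with no candidates — or of unknown type themselves — get an empty
#' negative set and drop out of the negative loss.
#'
#' @param sample A `contrastive_sample` from [sample_residues()].
#' @param K Negatives per anchor.
#' @return The sample with `negatives` filled: a list of integer vectors of
#'   positions into the sample (possibly empty).
#' @export
build_negative_sets <- function(sample, K) {
  labs <- sample$labels
  n <- length(labs)
  sample$negatives <- lapply(seq_len(n), function(i) {
    if (is.na(labs[i])) return(integer(0))
    cand <- which(!is.na(labs) & labs != labs[i])
    if (length(cand) == 0L) return(integer(0))
    if (length(cand) >= K) cand[sample.int(length(cand), K)]
    else cand[sample.int(length(cand), K, replace = TRUE)]
  })
  sample
}

cosine_rows <- function(A, B) {
  # cosine between row i of A and row j of B for all pairs; zero rows -> 0
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  S <- tcrossprod(A, B)
  denom <- outer(na, nb)
  out <- ifelse(denom > 0, S / pmax(denom, .Machine$double.eps), 0)
  out
}

#' Pairwise anchor-positive similarity matrix
#'
#' Psi\[i, j\] = omega * cos(x_i, g_j), the omega-scaled cosine between
#' anchor row i and positive row j. Rows of all zeros get similarity 0 by
#' convention. With the `"dot"` kernel the raw inner product is scaled
#' instead.
#'
#' @param X_s,G_s L_s x D anchor and positive matrices.
#' @param omega Scale factor in (0, 1).
#' @param kernel `"cosine"` (default) or `"dot"`.
#' @return L_s x L_s similarity matrix with entries bounded by omega
#'   (cosine kernel).
#' @export
pairwise_similarity <- function(X_s, G_s, omega, kernel = "cosine") {
  stopifnot(all(dim(X_s) == dim(G_s)))
  if (kernel == "cosine") omega * cosine_rows(X_s, G_s)
  else omega * tcrossprod(X_s, G_s)
}

#' Positive-pair loss
#'
#' The diagonal of Psi pairs each sampled residue's sequence-branch vector
#' with its own structure-branch vector. The loss
#' L_pos = -(1/L_s) sum_i log sigmoid(Psi\[i, i\]) is strictly decreasing in
#' every diagonal similarity, so minimizing it pulls positive pairs
#' together. At zero similarity it equals log 2.
#'
#' @param Psi Square similarity matrix from [pairwise_similarity()].
#' @param anchor_mask Optional logical vector: which diagonal entries count
#'   (used to exclude unknown-type residues); default all.
#' @return Nonnegative scalar loss (0 if no anchors are counted).
#' @export
positive_loss <- function(Psi, anchor_mask = NULL) {
  stopifnot(nrow(Psi) == ncol(Psi))
  d <- diag(Psi)
  if (!is.null(anchor_mask)) d <- d[anchor_mask]
  if (length(d) == 0L) return(0)
  mean(softplus(-d))
}

#' Negative-pair loss
#'
#' Pushes each anchor away from its sampled negatives (residues of a
#' different amino-acid type):
#' L_neg = -(1/M) sum over anchor-negative pairs of
#' log sigmoid(-omega * cos(x_i, x_neg)), where M is the total number of
#' pairs. Anchors with empty negative sets are skipped; with no pairs at
#' all the loss is 0.
#'
#' @param sample A `contrastive_sample` with negatives filled.
#' @param omega Scale factor in (0, 1).
#' @param kernel `"cosine"` or `"dot"`.
#' @return Nonnegative scalar loss.
#' @export
negative_loss <- function(sample, omega, kernel = "cosine") {
  if (is.null(sample$negatives)) stop("negative sets not built")
  X_s <- sample$X_s
  total <- 0; M <- 0L
  for (i in seq_along(sample$negatives)) {
    negs <- sample$negatives[[i]]
    if (length(negs) == 0L) next
    sims <- if (kernel == "cosine")
      cosine_rows(X_s[i, , drop = FALSE], X_s[negs, , drop = FALSE])[1, ]
    else drop(X_s[negs, , drop = FALSE] %*% X_s[i, ])
    total <- total + sum(softplus(omega * sims))
    M <- M + length(negs)
  }
  if (M == 0L) return(0)
  total / M
}

#' Combined contrastive loss for one protein
#'
#' Draws a fresh residue sample and negative sets, then returns
#' L_cont = L_pos + L_neg. Unknown-type residues are excluded both as
#' anchors (from the positive and negative losses) and as negatives.
#' Returns 0 exactly when the configuration is disabled.
#'
#' @param X,G L x D sequence and structure representations.
#' @param labels Length-L residue codes (`NA` = unknown).
#' @param cfg A [contrastive_config()].
#' @return Scalar loss >= 0.
#' @export
contrastive_loss <- function(X, G, labels, cfg) {
  if (!cfg$enabled) return(0)
  sm <- sample_residues(X, G, labels, cfg)
  sm <- build_negative_sets(sm, cfg$K)
  Psi <- pairwise_similarity(sm$X_s, sm$G_s, cfg$omega, cfg$kernel)
  lp <- positive_loss(Psi, anchor_mask = !is.na(sm$labels))
  ln <- negative_loss(sm, cfg$omega, cfg$kernel)
  lp + ln
}

## ---- loss + gradients for training --------------------------------------

# Gradient of cos(a, b) wrt a (b fixed): b/(|a||b|) - cos * a/|a|^2.
# Returns value and both gradients; zero-norm rows give zero gradient.
cos_grad <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    return(list(value = 0, da = a * 0, db = b * 0))
  cv <- sum(a * b) / (na * nb)
  list(value = cv,
       da = b / (na * nb) - cv * a / na^2,
       db = a / (na * nb) - cv * b / nb^2)
}

# Per-protein contrastive loss with gradients wrt X and G, on a freshly
# drawn sample (consumes RNG). Cosine kernel only (training path).
contrastive_loss_grad <- function(X, G, labels, cfg) {
  zero <- list(loss = 0, pos = 0, neg = 0, dX = X * 0, dG = G * 0)
  if (!cfg$enabled) return(zero)
  sm <- sample_residues(X, G, labels, cfg)
  sm <- build_negative_sets(sm, cfg$K)
  idx <- sm$indices
  known <- which(!is.na(sm$labels))
  dX <- X * 0; dG <- G * 0
  pos <- 0
  if (length(known) > 0L) {
    for (i in known) {
      cg <- cos_grad(sm$X_s[i, ], sm$G_s[i, ])
      t <- cfg$omega * cg$value
      pos <- pos + softplus(-t)
      coef <- -logistic(-t) * cfg$omega / length(known)
      dX[idx[i], ] <- dX[idx[i], ] + coef * cg$da
      dG[idx[i], ] <- dG[idx[i], ] + coef * cg$db
    }
    pos <- pos / length(known)
  }
  M <- sum(lengths(sm$negatives))
  neg <- 0
  if (M > 0L) {
    for (i in seq_along(sm$negatives)) {
      for (j in sm$negatives[[i]]) {
        cg <- cos_grad(sm$X_s[i, ], sm$X_s[j, ])
        u <- cfg$omega * cg$value
        neg <- neg + softplus(u)
        coef <- logistic(u) * cfg$omega / M
        dX[idx[i], ] <- dX[idx[i], ] + coef * cg$da
        dX[idx[j], ] <- dX[idx[j], ] + coef * cg$db
      }
    }
    neg <- neg / M
  }
  list(loss = pos + neg, pos = pos, neg = neg, dX = dX, dG = dG)
}
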