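## Dense network core: MLP sequence encoder, GCN structure encoder with
## symmetric adjacency normalization, grouped self-attention pooling, fused
## prediction head. Forward passes cache intermediates; model_backward()
## implements the exact reverse-mode gradients (verified against finite
## differences in the test suite).

relu <- function(x) pmax(x, 0)

logistic <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Model configuration
#'
#' Dimensions and switches of the network. `D` is the shared width of the
#' learned sequence and structure representations; the MLP maps F -> D -> D
#' with ReLU, the GCN applies `gcn_depth` layers of D -> D propagation over
#' the normalized contact graph. Attention pooling uses `attn_groups`
#' independent attention vectors per branch (`attn_dim` hidden units in the
#' tanh layer); each branch (sequence, structure) has its own attention
#' parameters unless `share_attention` is set.
#'
#' @param D Representation width (default 128).
#' @param mlp_depth Number of MLP layers (>= 1, default 2).
#' @param gcn_depth Number of GCN layers (>= 1, default 2).
#' @param attn_dim Attention hidden width D_a (default `D`).
#' @param attn_groups Number of attention groups D'' (default 4).
#' @param share_attention Share attention parameters across branches?
#' @param gcn_bias Add bias terms in GCN layers? Default `FALSE` (classic
#'   formulation).
#' @param adjacency_c Degree-regularization constant c in the symmetric
#'   normalization (default 1e-6; with self-loops added, row sums are >= 1,
#'   so this is a pure safeguard against empty rows).
#' @return An object of class `stabnet_model_config`.
#' @export
model_config <- function(D = 128L, mlp_depth = 2L, gcn_depth = 2L,
                         attn_dim = D, attn_groups = 4L,
                         share_attention = FALSE, gcn_bias = FALSE,
                         adjacency_c = 1e-6) {
  stopifnot(D >= 1L, mlp_depth >= 1L, gcn_depth >= 1L, attn_dim >= 1L,
            attn_groups >= 1L, adjacency_c > 0)
  structure(list(D = as.integer(D), mlp_depth = as.integer(mlp_depth),
                 gcn_depth = as.integer(gcn_depth),
                 attn_dim = as.integer(attn_dim),
                 attn_groups = as.integer(attn_groups),
                 share_attention = isTRUE(share_attention),
                 gcn_bias = isTRUE(gcn_bias), adjacency_c = adjacency_c),
            class = "stabnet_model_config")
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

# Initializes all parameter tensors. Consumes the current RNG stream.
init_params <- function(cfg, n_features, n_out) {
  D <- cfg$D
  mlp <- vector("list", cfg$mlp_depth)
  d_in <- n_features
  for (l in seq_len(cfg$mlp_depth)) {
    mlp[[l]] <- list(W = glorot(d_in, D), b = numeric(D))
    d_in <- D
  }
  gcn <- vector("list", cfg$gcn_depth)
  for (l in seq_len(cfg$gcn_depth)) {
    gcn[[l]] <- list(W = glorot(D, D),
                     b = if (cfg$gcn_bias) numeric(D) else NULL)
  }
  make_attn <- function() list(W1 = glorot(cfg$attn_dim, D) * 1,
                               W2 = glorot(cfg$attn_groups, cfg$attn_dim))
  att_x <- make_attn()
  att_g <- if (cfg$share_attention) att_x else make_attn()
  head <- list(W = glorot(2L * D, n_out), b = numeric(n_out))
  list(mlp = mlp, gcn = gcn, att_x = att_x, att_g = att_g, head = head)
}

#' MLP sequence encoder forward pass
#'
#' Applies the per-residue multilayer perceptron X = sigma(... sigma(P W1 +
#' b1) ... Wl + bl) to a pretrained embedding matrix. Each row (residue) is
#' mapped independently; ReLU activation after every layer.
#'
#' @param P L x F numeric matrix of pretrained per-residue features.
#' @param layers List of `list(W, b)` with chained dimensions F -> ... -> D.
#' @return L x D matrix of sequence representations.
#' @export
mlp_forward <- function(P, layers) {
  stopifnot(is.matrix(P), all(is.finite(P)))
  H <- P
  for (l in layers) {
    if (ncol(H) != nrow(l$W))
      stop(sprintf("MLP dimension mismatch: input %d vs weight %d", ncol(H), nrow(l$W)))
    H <- relu(H %*% l$W + matrix(l$b, nrow(H), length(l$b), byrow = TRUE))
  }
  H
}

#' Symmetrically normalized adjacency
#'
#' Adds self-loops and normalizes the contact-map adjacency symmetrically:
#' A~ = A + I, D_ii = sum_j A~_ij + c, A^ = D^(-1/2) A~ D^(-1/2). The small
#' constant c guards against empty rows; with self-loops the row sums are
#' at least 1, so the default is a pure safeguard. Self-loops are added
#' unconditionally even if the input diagonal is nonzero.
#'
#' @param A L x L symmetric contact map (weights in \[0, 1\]).
#' @param c Positive degree-regularization constant (default 1e-6).
#' @return L x L symmetric normalized adjacency matrix.
#' @export
normalize_adjacency <- function(A, c = 1e-6) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be square")
  stopifnot(c > 0)
  At <- unclass(A) + diag(nrow(A))
  d <- rowSums(At) + c
  s <- 1 / sqrt(d)
  Ahat <- At * tcrossprod(s)
  (Ahat + t(Ahat)) / 2  # exact symmetry against rounding
}

#' GCN structure encoder forward pass
#'
#' Propagates residue representations over the normalized contact graph:
#' H^(l+1) = sigma(A^ H^(l) W^(l)), starting from H^(0) = X, with ReLU
#' after every layer. The output after the last layer is the structure
#' representation G.
#'
#' @param X L x D input representations (typically [mlp_forward()] output).
#' @param Ahat L x L normalized adjacency from [normalize_adjacency()].
#' @param layers List of `list(W)` (square D x D), optional `b`.
#' @return L x D structure representation G.
#' @export
gcn_forward <- function(X, Ahat, layers) {
  if (nrow(X) != nrow(Ahat)) stop("GCN: X and adjacency disagree on L")
  H <- X
  for (l in layers) {
    if (ncol(H) != nrow(l$W))
      stop(sprintf("GCN dimension mismatch: input %d vs weight %d", ncol(H), nrow(l$W)))
    Z <- Ahat %*% H %*% l$W
    if (!is.null(l$b)) Z <- Z + matrix(l$b, nrow(Z), length(l$b), byrow = TRUE)
    H <- relu(Z)
  }
  H
}

#' Grouped self-attention weights
#'
#' Computes the attention matrix A_g = softmax(W2 tanh(W1 H^T)) with the
#' softmax taken along the residue axis, so each of the D'' attention
#' groups distributes a unit of weight over the valid residues. Masked
#' (padded) positions receive exactly zero weight via -Inf logits.
#'
#' @param H L x D residue representation matrix.
#' @param W1 D_a x D first attention parameter.
#' @param W2 D'' x D_a second attention parameter.
#' @param mask Logical length-L vector of valid positions (default all).
#' @return D'' x L attention matrix; each row sums to 1 over valid positions.
#' @export
attention_weights <- function(H, W1, W2, mask = NULL) {
  L <- nrow(H)
  if (is.null(mask)) mask <- rep(TRUE, L)
  stopifnot(length(mask) == L)
  if (!any(mask)) stop("attention over an all-masked input is undefined")
  Tm <- tanh(W1 %*% t(H))          # D_a x L
  E <- W2 %*% Tm                   # D'' x L
  E[, !mask] <- -Inf
  M <- apply(E, 1, max)
  Z <- exp(E - M)                  # masked cols -> 0
  Z[, !mask] <- 0
  sweep(Z, 1, rowSums(Z), "/")
}

#' Attention pooling of residue representations
#'
#' Aggregates residues into one protein-level vector: G~ = A_g H stacks one
#' attention-weighted average per group, and the final representation is
#' the mean over the D'' group rows.
#'
#' @param H L x D residue representations.
#' @param Ag D'' x L attention matrix from [attention_weights()].
#' @return Length-D pooled vector.
#' @export
attention_pool <- function(H, Ag) {
  stopifnot(ncol(Ag) == nrow(H))
  Gt <- Ag %*% H
  colMeans(Gt)
}

#' Fuse pooled branch representations and predict
#'
#' Concatenates the pooled structure and sequence vectors and applies a
#' fully connected layer: output = \[g~ || x~\] W + b. Returns class logits
#' (length C) for classification or a scalar melting-temperature estimate
#' (degrees C) for regression.
#'
#' @param g_pool Length-D pooled structure vector.
#' @param x_pool Length-D pooled sequence vector.
#' @param W (2D) x out weight matrix.
#' @param b Length-out bias.
#' @return Numeric vector of length out.
#' @export
fuse_and_predict <- function(g_pool, x_pool, W, b) {
  z <- c(g_pool, x_pool)
  stopifnot(length(z) == nrow(W), length(b) == ncol(W))
  drop(z %*% W) + b
}

## ---- full forward with cache -------------------------------------------

# One protein. P: L x F, Ahat: L x L. Returns output plus every
# intermediate needed by model_backward().
model_forward <- function(P, Ahat, params, mask = NULL) {
  L <- nrow(P)
  if (is.null(mask)) mask <- rep(TRUE, L)
  # MLP
  mlp_in <- vector("list", length(params$mlp))
  mlp_pre <- vector("list", length(params$mlp))
  H <- P
  for (l in seq_along(params$mlp)) {
    mlp_in[[l]] <- H
    Z <- H %*% params$mlp[[l]]$W +
      matrix(params$mlp[[l]]$b, L, length(params$mlp[[l]]$b), byrow = TRUE)
    mlp_pre[[l]] <- Z
    H <- relu(Z)
  }
  X <- H
  # GCN
  gcn_in <- vector("list", length(params$gcn))
  gcn_ax <- vector("list", length(params$gcn))
  gcn_pre <- vector("list", length(params$gcn))
  H <- X
  for (l in seq_along(params$gcn)) {
    gcn_in[[l]] <- H
    AX <- Ahat %*% H
    gcn_ax[[l]] <- AX
    Z <- AX %*% params$gcn[[l]]$W
    if (!is.null(params$gcn[[l]]$b))
      Z <- Z + matrix(params$gcn[[l]]$b, L, ncol(Z), byrow = TRUE)
    gcn_pre[[l]] <- Z
    H <- relu(Z)
  }
  G <- H
  att_fwd <- function(H, ap) {
    Tm <- tanh(ap$W1 %*% t(H))
    E <- ap$W2 %*% Tm
    E[, !mask] <- -Inf
    M <- apply(E, 1, max)
    Z <- exp(E - M); Z[, !mask] <- 0
    Ag <- sweep(Z, 1, rowSums(Z), "/")
    list(Tm = Tm, Ag = Ag, pooled = colMeans(Ag %*% H))
  }
  ax <- att_fwd(X, params$att_x)
  ag <- att_fwd(G, params$att_g)
  z <- c(ag$pooled, ax$pooled)
  out <- drop(z %*% params$head$W) + params$head$b
  list(out = out, X = X, G = G, z = z, ax = ax, ag = ag,
       mlp_in = mlp_in, mlp_pre = mlp_pre,
       gcn_in = gcn_in, gcn_ax = gcn_ax, gcn_pre = gcn_pre,
       P = P, Ahat = Ahat, mask = mask)
}

## ---- full backward ------------------------------------------------------

zero_like_params <- function(params) {
  lapply(params, function(x) {
    if (is.null(x)) NULL
    else if (is.list(x)) zero_like_params(x)
    else x * 0
  })
}

# d_out: gradient of the loss wrt the head output (length out).
# dX_extra / dG_extra: L x D gradients flowing into X and G from the
# contrastive loss (or NULL). Returns list(grads, dP).
model_backward <- function(cache, params, d_out,
                           dX_extra = NULL, dG_extra = NULL) {
  g <- zero_like_params(params)
  z <- cache$z
  D <- length(cache$ax$pooled)
  g$head$W <- outer(z, d_out)
  g$head$b <- d_out
  dz <- drop(params$head$W %*% d_out)
  d_gpool <- dz[seq_len(D)]
  d_xpool <- dz[D + seq_len(D)]

  att_bwd <- function(H, att, ap, d_pool) {
    Dg <- nrow(att$Ag)
    dGt <- matrix(d_pool / Dg, Dg, length(d_pool), byrow = TRUE)
    dH <- t(att$Ag) %*% dGt
    dAg <- dGt %*% t(H)                       # Dg x L
    # softmax backward per row
    dE <- att$Ag * (dAg - rowSums(dAg * att$Ag))
    dW2 <- dE %*% t(att$Tm)
    dTm <- t(ap$W2) %*% dE
    dTpre <- dTm * (1 - att$Tm^2)
    dW1 <- dTpre %*% H
    dH <- dH + t(dTpre) %*% ap$W1
    list(dH = dH, dW1 = dW1, dW2 = dW2)
  }
  bx <- att_bwd(cache$X, cache$ax, params$att_x, d_xpool)
  bg <- att_bwd(cache$G, cache$ag, params$att_g, d_gpool)
  g$att_x$W1 <- bx$dW1; g$att_x$W2 <- bx$dW2
  g$att_g$W1 <- bg$dW1; g$att_g$W2 <- bg$dW2

  dG <- bg$dH
  if (!is.null(dG_extra)) dG <- dG + dG_extra
  # GCN backward
  for (l in rev(seq_along(params$gcn))) {
    dZ <- dG * (cache$gcn_pre[[l]] > 0)
    g$gcn[[l]]$W <- t(cache$gcn_ax[[l]]) %*% dZ
    if (!is.null(params$gcn[[l]]$b)) g$gcn[[l]]$b <- colSums(dZ)
    dG <- cache$Ahat %*% (dZ %*% t(params$gcn[[l]]$W))  # Ahat symmetric
  }
  dX <- bx$dH + dG
  if (!is.null(dX_extra)) dX <- dX + dX_extra
  # MLP backward
  for (l in rev(seq_along(params$mlp))) {
    dZ <- dX * (cache$mlp_pre[[l]] > 0)
    g$mlp[[l]]$W <- t(cache$mlp_in[[l]]) %*% dZ
    g$mlp[[l]]$b <- colSums(dZ)
    dX <- dZ %*% t(params$mlp[[l]]$W)
  }
  list(grads = g, dP = dX)
}

## ---- shared-attention gradient merge ------------------------------------

merge_shared_attention <- function(grads, cfg) {
  if (cfg$share_attention) {
    gW1 <- grads$att_x$W1 + grads$att_g$W1
    gW2 <- grads$att_x$W2 + grads$att_g$W2
    grads$att_x$W1 <- gW1; grads$att_g$W1 <- gW1
    grads$att_x$W2 <- gW2; grads$att_g$W2 <- gW2
  }
  grads
}
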