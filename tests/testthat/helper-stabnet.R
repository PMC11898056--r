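# Shared fixtures and independent oracles for the test suite. Everything
# here is built in code at test time; the oracle implementations stay
# deliberately naive (explicit loops, scalar arithmetic) and independent of
# the package's vectorized paths.

tiny_model_cfg <- function(D = 4L, attn_dim = 3L, attn_groups = 2L) {
  model_config(D = D, attn_dim = attn_dim, attn_groups = attn_groups)
}

# Random parameter set for given dims, seeded.
tiny_params <- function(cfg, n_features, n_out, seed = 1) {
  set.seed(seed)
  stabnet:::init_params(cfg, n_features, n_out)
}

# A small synthetic triple with known-length proteins.
tiny_triples <- function(n = 4, L = 6, F_dim = 3, C = 2, seed = 1,
                         task = "classification") {
  set.seed(seed)
  spec <- synthetic_spec(n_proteins = n, length_range = c(L, L),
                         n_features = F_dim, task = task, n_classes = C,
                         effect_size = 1, noise_sd = 0.3, seed = seed)
  latents <- stabnet:::synthetic_latents(spec)
  lapply(seq_len(n), function(i) {
    tgt <- if (task == "classification") (i - 1) %% C else 20 + 10 * i
    generate_protein(spec, tgt, latents = latents, id = paste0("t", i),
                     split = "train")
  })
}

# Flatten / restore parameter lists for finite-difference checks.
flatten_params <- function(p) unlist(p, use.names = FALSE)

restore_params <- function(p, flat) {
  i <- 0L
  walk <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- flat[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  }
  walk(p)
}

# Central-difference gradient of scalar fn(params).
numerical_gradient <- function(fn, params, eps = 1e-5) {
  flat <- flatten_params(params)
  g <- numeric(length(flat))
  for (i in seq_along(flat)) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    g[i] <- (fn(restore_params(params, up)) - fn(restore_params(params, dn))) / (2 * eps)
  }
  g
}

# Independent forward pass built only from the exported primitive ops
# (used as the loss evaluator the analytic gradients are checked against).
oracle_forward_out <- function(P, Ahat, params, mask = NULL) {
  X <- mlp_forward(P, params$mlp)
  G <- gcn_forward(X, Ahat, params$gcn)
  Ax <- attention_weights(X, params$att_x$W1, params$att_x$W2, mask)
  Ag <- attention_weights(G, params$att_g$W1, params$att_g$W2, mask)
  list(out = fuse_and_predict(attention_pool(G, Ag), attention_pool(X, Ax),
                              params$head$W, params$head$b),
       X = X, G = G)
}

expect_params_close <- function(a, b, tol = 1e-6) {
  fa <- flatten_params(a); fb <- flatten_params(b)
  expect_equal(length(fa), length(fb))
  expect_lt(max(abs(fa - fb)), tol)
}
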