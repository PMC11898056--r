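#' Thermostability class bands (degrees Celsius)
#'
#' Organism-level thermostability categories and their temperature bands:
#' Cryophilic \[-20, 5), Psychrophilic \[5, 25), Mesophilic \[25, 45),
#' Thermophilic \[45, 75), Hyperthermophilic above 75 (open band, capped at
#' 95 for sampling). The binary hot/cold split is at 45.
#'
#' @format Data frame with columns `class`, `lo`, `hi`.
#' @export
THERMO_BANDS <- data.frame(
  class = c("Cryophilic", "Psychrophilic", "Mesophilic", "Thermophilic", "Hyperthermophilic"),
  lo = c(-20, 5, 25, 45, 75),
  hi = c(5, 25, 45, 75, 95),
  stringsAsFactors = FALSE
)

#' Specify a synthetic protein data set
#'
#' Defines the generating process for protein-language-model-like inputs
#' with a controllable thermostability signal. Residue i of amino-acid type
#' a in a protein of class c receives embedding row tau_a + mu_c + eps_i
#' with eps_i ~ N(0, sigma^2 I): `tau_a` are fixed random unit vectors per
#' residue type scaled by `residue_scale` (the signal the contrastive
#' scheme exploits) and `mu_c` is a class prototype of norm `effect_size`
#' (the signal the prediction head exploits). For regression, the prototype
#' direction is fixed and scaled by (t_m - 45) / 50 * effect_size, so the
#' embedding signal is linear in centered melting temperature. Contact maps
#' have a band of 1s at |i - j| <= `contact_band` (chain locality) plus
#' sparse symmetric long-range contacts with Bernoulli(`long_range_density`)
#' occupancy and Uniform(0.5, 1) weights; the diagonal is 0.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer \[L_min, L_max\], L_min >= 3.
#' @param n_features Pretrained feature dimension F.
#' @param task `"classification"` or `"regression"`.
#' @param n_classes 2 (hot/cold) or 5 (the five thermostability bands).
#' @param effect_size Norm delta of the class prototype (0 = no class signal).
#' @param residue_scale Norm of the per-residue-type vectors.
#' @param noise_sd Per-coordinate embedding noise standard deviation sigma.
#' @param contact_band Band half-width w of guaranteed short-range contacts.
#' @param long_range_density Probability rho of each long-range contact.
#' @param seed Integer seed; the whole data set is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200L, length_range = c(30L, 60L),
                           n_features = 32L,
                           task = c("classification", "regression"),
                           n_classes = 5L, effect_size = 3, residue_scale = 1,
                           noise_sd = 0.5, contact_band = 2L,
                           long_range_density = 0.02, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1] >= 3L, length_range[1] <= length_range[2],
            n_features >= 1L, n_classes %in% c(2L, 5L),
            effect_size >= 0, residue_scale >= 0, noise_sd >= 0,
            contact_band >= 0L, long_range_density >= 0, long_range_density <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_features = as.integer(n_features), task = task,
                 n_classes = as.integer(n_classes), effect_size = effect_size,
                 residue_scale = residue_scale, noise_sd = noise_sd,
                 contact_band = as.integer(contact_band),
                 long_range_density = long_range_density,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_unit_vectors <- function(n, d) {
  v <- matrix(stats::rnorm(n * d), n, d)
  v / pmax(sqrt(rowSums(v^2)), .Machine$double.eps)
}

# Dataset-level latent structure shared by all proteins of one data set:
# per-type directions tau (20 x F), class prototypes mu (C x F) or the
# regression direction u (1 x F).
synthetic_latents <- function(spec) {
  tau <- random_unit_vectors(20L, spec$n_features) * spec$residue_scale
  if (spec$task == "classification") {
    mu <- random_unit_vectors(spec$n_classes, spec$n_features) * spec$effect_size
    list(tau = tau, mu = mu)
  } else {
    list(tau = tau, u = random_unit_vectors(1L, spec$n_features)[1, ])
  }
}

#' Generate one synthetic protein
#'
#' Draws a random sequence over the 20 canonical residues, its embedding
#' matrix and contact map under the model described in [synthetic_spec()].
#' Consumes the current R random number stream; seed externally (or through
#' [generate_dataset()]) for reproducibility.
#'
#' @param spec A `synthetic_spec`.
#' @param target Class index (0-based) or melting temperature, matching the
#'   spec's task.
#' @param latents Dataset-level latent vectors from the internal generator;
#'   if `NULL`, fresh ones are drawn (useful for one-off proteins).
#' @param id Protein identifier.
#' @param split Data split tag.
#' @return A `list(record, embedding, contact)` triple.
#' @export
generate_protein <- function(spec, target, latents = NULL, id = "p1", split = "train") {
  if (is.null(latents)) latents <- synthetic_latents(spec)
  L <- if (spec$length_range[1] == spec$length_range[2]) spec$length_range[1]
       else sample(spec$length_range[1]:spec$length_range[2], 1L)
  codes <- sample(0:19, L, replace = TRUE)
  sequence <- decode_residues(codes)
  mu <- if (spec$task == "classification") latents$mu[target + 1L, ]
        else latents$u * (target - 45) / 50 * spec$effect_size
  emb <- latents$tau[codes + 1L, , drop = FALSE] +
    matrix(mu, L, spec$n_features, byrow = TRUE) +
    matrix(stats::rnorm(L * spec$n_features, sd = spec$noise_sd), L, spec$n_features)
  con <- matrix(0, L, L)
  if (spec$contact_band > 0L) {
    d <- abs(outer(seq_len(L), seq_len(L), "-"))
    con[d >= 1 & d <= spec$contact_band] <- 1
  }
  if (spec$long_range_density > 0) {
    for (i in seq_len(L - 1L)) {
      js <- which(seq_len(L) > i + spec$contact_band)
      if (length(js)) {
        hit <- js[stats::runif(length(js)) < spec$long_range_density]
        if (length(hit)) {
          w <- stats::runif(length(hit), 0.5, 1)
          con[i, hit] <- w
          con[hit, i] <- w
        }
      }
    }
  }
  rec <- protein_record(id, sequence, target, task = spec$task, split = split,
                        n_classes = if (spec$task == "classification") spec$n_classes else NULL)
  list(record = rec, embedding = emb, contact = validate_contact_map(con))
}

#' Generate a synthetic data set container
#'
#' Draws `n_proteins` proteins under the spec's generating model and writes
#' them as a container. Classification targets are balanced across classes
#' to within one protein; regression melting temperatures are drawn
#' uniformly within each of the five thermostability bands (balanced across
#' bands, Hyperthermophilic capped at 95 degrees C). Proteins are assigned
#' to train/valid/test splits 70/15/15 by a seeded permutation. The whole
#' container is byte-reproducible from `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @param path Output container path (default: tempfile).
#' @return The container path, invisibly a character scalar.
#' @export
generate_dataset <- function(spec, path = tempfile(fileext = ".rds")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  latents <- synthetic_latents(spec)
  if (spec$task == "classification") {
    classes <- rep(0:(spec$n_classes - 1L), length.out = n)
    targets <- as.numeric(sample(classes))
  } else {
    bands <- rep(seq_len(nrow(THERMO_BANDS)), length.out = n)
    bands <- sample(bands)
    targets <- stats::runif(n, THERMO_BANDS$lo[bands], THERMO_BANDS$hi[bands])
  }
  n_train <- floor(0.70 * n)
  n_valid <- floor(0.15 * n)
  splits <- c(rep("train", n_train), rep("valid", n_valid),
              rep("test", n - n_train - n_valid))
  splits <- splits[sample.int(n)]
  triples <- vector("list", n)
  for (i in seq_len(n)) {
    triples[[i]] <- generate_protein(spec, targets[i], latents = latents,
                                     id = sprintf("syn%04d", i), split = splits[i])
  }
  write_container(triples, path)
  invisible(path)
}

#' Nearest-class-mean separability of raw embeddings
#'
#' Sanity floor for the synthetic generator: mean-pools each protein's raw
#' embedding matrix, fits a nearest-class-mean classifier on the train
#' split, and returns its test-split accuracy. Any trained model should
#' beat this baseline on data with class signal; at zero effect size it sits
#' at chance.
#'
#' @param container Path to a classification container.
#' @return Test accuracy in \[0, 1\].
#' @export
check_separability <- function(container) {
  triples <- read_container(container)
  task <- triples[[1]]$record$task
  if (task != "classification")
    stop("check_separability requires a classification container")
  pooled <- t(vapply(triples, function(t) colMeans(t$embedding),
                     numeric(ncol(triples[[1]]$embedding))))
  y <- vapply(triples, function(t) t$record$target, numeric(1))
  split <- vapply(triples, function(t) t$record$split, character(1))
  tr <- split == "train"; te <- split == "test"
  if (!any(tr) || !any(te)) stop("container must have train and test splits")
  cls <- sort(unique(y[tr]))
  centers <- t(vapply(cls, function(c) colMeans(pooled[tr & y == c, , drop = FALSE]),
                      numeric(ncol(pooled))))
  d2 <- outer(rowSums(pooled[te, , drop = FALSE]^2), rowSums(centers^2), "+") -
    2 * pooled[te, , drop = FALSE] %*% t(centers)
  pred <- cls[max.col(-d2, ties.method = "first")]
  mean(pred == y[te])
}
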