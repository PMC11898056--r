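small_container <- function(seed = 81, n = 40, C = 2, task = "classification") {
  path <- tempfile(fileext = ".rds")
  generate_dataset(synthetic_spec(n_proteins = n, length_range = c(8L, 12L),
                                  n_features = 8, task = task, n_classes = C,
                                  effect_size = 3, noise_sd = 0.5, seed = seed),
                   path)
  path
}

small_fit <- function(path, epochs = 2, lr = 3e-3, seed = 1, alpha = 0.1, ...) {
  suppressWarnings(stabnet(
    path, model = model_config(D = 8, attn_groups = 2),
    contrastive = contrastive_config(L_s = 16L, K = 3L),
    training = train_config(learning_rate = lr, epochs = epochs, seed = seed,
                            batch_size = 8, alpha = alpha, ...)))
}

test_that("training is bit-reproducible from the seed", {
  path <- small_container()
  f1 <- small_fit(path, epochs = 2, seed = 5)
  f2 <- small_fit(path, epochs = 2, seed = 5)
  expect_identical(f1$history, f2$history)           # incl. epoch-0 losses
  expect_identical(f1$params, f2$params)
  f3 <- small_fit(path, epochs = 2, seed = 6)
  expect_false(identical(f1$history$total_loss, f3$history$total_loss))
})

test_that("zero learning rate leaves parameters and losses unchanged", {
  path <- small_container()
  fit <- suppressWarnings(stabnet(
    path, model = model_config(D = 8, attn_groups = 2),
    contrastive = contrastive_config(enabled = FALSE),
    training = train_config(learning_rate = 0, epochs = 3, seed = 2,
                            batch_size = 8, alpha = 0)))
  expect_params_close(fit$params_final, fit$params, tol = 1e-12)
  expect_equal(diff(range(fit$history$pred_loss)), 0, tolerance = 1e-12)
})

test_that("the high-SNR two-class task is learned quickly", {
  path <- small_container(seed = 83, n = 60)
  fit <- small_fit(path, epochs = 4, lr = 3e-3, seed = 3)
  rep <- evaluate_model(fit, split = "test")
  expect_gte(rep$accuracy, 0.8)
  expect_gte(rep$accuracy, check_separability(path) - 0.3)
})

test_that("best-epoch selection maximizes the metric with earliest-epoch ties", {
  fake <- structure(list(history = data.frame(epoch = 1:3, accuracy = c(0.6, 0.9, 0.8)),
                         selection_metric = "accuracy"), class = "stabnet")
  expect_identical(select_best_epoch(fake), 2L)
  fake$history$accuracy <- c(0.7, 0.7, 0.7)
  expect_identical(select_best_epoch(fake), 1L)
  fake$history <- fake$history[1, ]
  expect_identical(select_best_epoch(fake), 1L)
})

test_that("a zeroed head predicts the first class everywhere", {
  path <- small_container(seed = 84)
  fit <- small_fit(path, epochs = 1, lr = 0)
  fit$params$head$W[] <- 0
  fit$params$head$b[] <- 0
  pred <- predict(fit, split = "test", type = "class")
  expect_true(all(pred$class == 0L))
  rep <- evaluate_model(fit, split = "test")
  truth <- vapply(read_container(path), function(t)
    if (t$record$split == "test") t$record$target else NA_real_, numeric(1))
  expect_equal(rep$accuracy, mean(truth == 0, na.rm = TRUE))
})

test_that("evaluation is deterministic and serializes identically", {
  path <- small_container(seed = 85)
  fit <- small_fit(path, epochs = 2)
  j1 <- metric_report_json(evaluate_model(fit, split = "test"))
  j2 <- metric_report_json(evaluate_model(fit, split = "test"))
  expect_identical(j1, j2)
})

test_that("checkpoints round-trip through save and load", {
  path <- small_container(seed = 86)
  fit <- small_fit(path, epochs = 1)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, ck)
  back <- load_model(ck)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, split = "test"), predict(fit, split = "test"))
  expect_error(load_model(path), "checkpoint")
})

test_that("regression fits recover a monotone melting-temperature signal", {
  path <- small_container(seed = 87, n = 60, task = "regression")
  fit <- suppressWarnings(stabnet(
    path, model = model_config(D = 8, attn_groups = 2),
    contrastive = contrastive_config(L_s = 16L, K = 3L),
    training = train_config(learning_rate = 3e-3, epochs = 5, seed = 4,
                            batch_size = 8, alpha = 0.1,
                            normalize_targets = TRUE)))
  rep <- evaluate_model(fit, split = "test")
  expect_gte(rep$pearson, 0.7)
  res <- residuals(fit, split = "test")
  expect_length(res, rep$n)
  expect_equal(sqrt(mean(res^2)), rep$rmse, tolerance = 1e-10)
})

test_that("epoch-0 batch loss equals the standalone loss operations on the same forward pass", {
  path <- small_container(seed = 88, n = 12)
  triples <- read_container(path)
  train_triples <- triples[vapply(triples, function(t) t$record$split, "") == "train"]
  cfg <- model_config(D = 8, attn_groups = 2)
  ccfg <- contrastive_config(L_s = 16L, K = 3L)
  tcfg <- train_config(learning_rate = 0, epochs = 1, seed = 9,
                       batch_size = length(train_triples), alpha = 0.25,
                       selection_split = "train")
  fit <- stabnet(path, model = cfg, contrastive = ccfg, training = tcfg)

  # replay the first (only) batch by hand with the same seeded RNG
  set.seed(tcfg$seed)
  params <- stabnet:::init_params(cfg, 8, 2)
  perm <- sample.int(length(train_triples))
  ordered <- train_triples[perm]
  logits <- NULL; conts <- numeric(0)
  for (tr in ordered) {
    Ahat <- normalize_adjacency(unclass(tr$contact), cfg$adjacency_c)
    fw <- oracle_forward_out(tr$embedding, Ahat, params)
    logits <- rbind(logits, fw$out)
    conts <- c(conts, contrastive_loss(fw$X, fw$G, tr$record$residue_labels, ccfg))
  }
  targets <- vapply(ordered, function(t) t$record$target, numeric(1))
  pl <- prediction_loss(logits, targets, "classification")
  expect_equal(fit$history$pred_loss[1], pl, tolerance = 1e-10)
  expect_equal(fit$history$total_loss[1],
               total_loss(pl, fit$history$cont_loss[1], tcfg$alpha),
               tolerance = 1e-12)
})

test_that("task and container mismatches are rejected", {
  path <- small_container(seed = 89, task = "regression")
  expect_error(suppressWarnings(
    stabnet(path, training = train_config(selection_metric = "accuracy"))),
    "classification")
  path2 <- small_container(seed = 90)
  expect_error(suppressWarnings(
    stabnet(path2, training = train_config(selection_metric = "pearson"))),
    "regression")
})
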