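#' Training configuration
#'
#' Optimization protocol: Adam with a fixed learning rate (no schedule),
#' a fixed number of epochs (default 10), and best-epoch selection by a
#' validation metric. All randomness — parameter initialization, epoch
#' shuffling, contrastive sampling — flows from the single `seed`, so two
#' runs with the same seed produce bit-identical loss trajectories.
#'
#' @param learning_rate Fixed Adam learning rate (default 1e-4).
#' @param epochs Number of epochs (default 10).
#' @param batch_size Proteins per batch (default 8).
#' @param seed Integer seed for the whole run.
#' @param alpha Weight of the contrastive term in the total loss
#'   (default 0.1; 0 ablates it).
#' @param selection_metric Metric maximized across epochs: `"accuracy"`
#'   (classification) or `"pearson"` (regression); `"auto"` picks by task.
#' @param selection_split Split the selection metric is computed on.
#'   Default `"valid"`. Selecting on `"test"` reproduces the protocol of
#'   reporting the test-set performance of the best epoch, but leaks the
#'   test set into model selection; a warning is emitted.
#' @param normalize_targets Regression only: z-score melting temperatures
#'   with train-split mean/sd during optimization (predictions are always
#'   returned in degrees C). Default `FALSE`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 10L, batch_size = 8L,
                         seed = 1L, alpha = 0.1,
                         selection_metric = c("auto", "accuracy", "pearson"),
                         selection_split = c("valid", "test", "train"),
                         normalize_targets = FALSE) {
  selection_metric <- match.arg(selection_metric)
  selection_split <- match.arg(selection_split)
  stopifnot(learning_rate >= 0, epochs >= 1L, batch_size >= 1L, alpha >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 alpha = alpha, selection_metric = selection_metric,
                 selection_split = selection_split,
                 normalize_targets = isTRUE(normalize_targets)),
            class = "train_config")
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_update_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (k in seq_along(p)) {
      r <- adam_update_rec(p[[k]], g[[k]], m[[k]], v[[k]], lr_t, beta1, beta2, eps)
      out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m2 <- beta1 * m + (1 - beta1) * g
  v2 <- beta2 * v + (1 - beta2) * g^2
  list(p = p - lr_t * m2 / (sqrt(v2) + eps), m = m2, v = v2)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- adam_update_rec(params, grads, state$m, state$v, lr_t, beta1, beta2, eps)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

## ---- forward over a split ------------------------------------------------

forward_split <- function(triples, params, cfg) {
  outs <- lapply(triples, function(tr) {
    Ahat <- normalize_adjacency(tr$contact, cfg$adjacency_c)
    model_forward(tr$embedding, Ahat, params)$out
  })
  do.call(rbind, outs)
}

split_metric <- function(outputs, targets, metric) {
  if (metric == "accuracy") {
    pred <- max.col(outputs, ties.method = "first") - 1L
    mean(pred == as.integer(targets))
  } else {
    if (stats::sd(outputs[, 1]) == 0 || stats::sd(targets) == 0) return(0)
    pearson(outputs[, 1], targets)
  }
}

#' Fit a sequence- and structure-aware thermostability model
#'
#' The package's fitting function. Reads a data set container (or a list of
#' triples), builds the two-branch network — MLP sequence encoder, GCN
#' structure encoder over the symmetrically normalized contact graph,
#' grouped self-attention pooling per branch, fused linear head — and
#' trains it with Adam at a fixed learning rate. Each step minimizes the
#' prediction loss (cross-entropy for thermostability classes, RMSE in
#' degrees C for melting temperature) plus `alpha` times the
#' residue-type-guided contrastive loss; gradients are exact reverse-mode
#' derivatives of this objective. The epoch whose selection metric is best
#' (ties to the earliest epoch) provides the parameters used by
#' [predict.stabnet()] and [evaluate_model()].
#'
#' @param data Container path (see [generate_dataset()], [write_container()])
#'   or a list of `list(record, embedding, contact)` triples.
#' @param model A [model_config()].
#' @param contrastive A [contrastive_config()]; disable or set `alpha = 0`
#'   in `training` to ablate the contrastive term.
#' @param training A [train_config()].
#' @param log_file Optional path; per-epoch records are appended as JSON
#'   lines.
#' @return An object of class `stabnet` with the fitted parameters
#'   (best epoch and final), per-epoch history, and configuration.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_proteins = 60, n_classes = 2, n_features = 8,
#'                        length_range = c(10, 16), seed = 42)
#' path <- generate_dataset(spec)
#' fit <- stabnet(path, model = model_config(D = 8, attn_groups = 2),
#'                training = train_config(epochs = 2, seed = 1))
#' print(fit)
#' }
#' @export
stabnet <- function(data, model = model_config(),
                    contrastive = contrastive_config(),
                    training = train_config(), log_file = NULL) {
  triples <- if (is.character(data)) read_container(data) else data
  stopifnot(length(triples) >= 1L)
  task <- triples[[1]]$record$task
  if (!all(vapply(triples, function(t) t$record$task, character(1)) == task))
    stop("container mixes tasks")
  metric <- if (training$selection_metric == "auto") {
    if (task == "classification") "accuracy" else "pearson"
  } else training$selection_metric
  if (task == "classification" && metric == "pearson")
    stop("pearson selection requires a regression container")
  if (task == "regression" && metric == "accuracy")
    stop("accuracy selection requires a classification container")
  if (training$selection_split == "test")
    warning("selecting the best epoch on the test split leaks the test set into model selection")

  splits <- vapply(triples, function(t) t$record$split, character(1))
  train_triples <- triples[splits == "train"]
  sel_triples <- triples[splits == training$selection_split]
  if (length(train_triples) == 0L) stop("no training proteins in container")
  if (length(sel_triples) == 0L)
    stop(sprintf("selection split '%s' is empty", training$selection_split))

  n_features <- ncol(train_triples[[1]]$embedding)
  if (task == "classification") {
    n_classes <- train_triples[[1]]$record$n_classes
    class_levels <- if (n_classes == 5L) THERMO_BANDS$class
                    else if (n_classes == 2L) c("cold", "hot")
                    else paste0("class", 0:(n_classes - 1L))
    n_out <- n_classes
  } else {
    n_classes <- NULL; class_levels <- NULL; n_out <- 1L
  }

  target_center <- 0; target_scale <- 1
  if (task == "regression" && training$normalize_targets) {
    tr_t <- vapply(train_triples, function(t) t$record$target, numeric(1))
    target_center <- mean(tr_t)
    target_scale <- stats::sd(tr_t)
    if (!is.finite(target_scale) || target_scale == 0) target_scale <- 1
  }
  scale_t <- function(t) (t - target_center) / target_scale

  set.seed(training$seed)
  params <- init_params(model, n_features, n_out)
  if (model$share_attention) params$att_g <- params$att_x
  opt <- adam_init(params)

  n_train <- length(train_triples)
  history <- data.frame(epoch = integer(0), pred_loss = numeric(0),
                        cont_loss = numeric(0), total_loss = numeric(0),
                        selection = numeric(0))
  best_metric <- -Inf; best_epoch <- NA_integer_; params_best <- params

  sel_targets <- vapply(sel_triples, function(t) t$record$target, numeric(1))
  eval_selection <- function(p) {
    outs <- forward_split(sel_triples, p, model)
    if (task == "regression")
      outs <- outs * target_scale + target_center
    split_metric(outs, sel_targets, metric)
  }

  for (epoch in seq_len(training$epochs)) {
    perm <- sample.int(n_train)
    batches <- make_batches(train_triples[perm], training$batch_size)
    ep_pred <- 0; ep_cont <- 0; n_seen <- 0L
    for (batch in batches) {
      B <- length(batch$records)
      caches <- vector("list", B)
      Ahats <- vector("list", B)
      for (b in seq_len(B)) {
        L <- batch$lengths[b]
        P <- matrix(batch$embeddings[b, 1:L, ], nrow = L)
        A <- matrix(batch$contacts[b, 1:L, 1:L], nrow = L)
        Ahats[[b]] <- normalize_adjacency(A, model$adjacency_c)
        caches[[b]] <- model_forward(P, Ahats[[b]], params)
      }
      targets <- batch$targets
      if (task == "classification") {
        logits <- do.call(rbind, lapply(caches, `[[`, "out"))
        pred_loss <- prediction_loss(logits, targets, "classification")
        d_outs <- lapply(seq_len(B), function(b) {
          p <- softmax_vec(logits[b, ])
          p[targets[b] + 1L] <- p[targets[b] + 1L] - 1
          p / B
        })
      } else {
        outs <- vapply(caches, `[[`, numeric(1), "out")
        st <- scale_t(targets)
        pred_loss <- prediction_loss(outs, st, "regression")
        d_outs <- if (pred_loss > 0)
          lapply(seq_len(B), function(b) (outs[b] - st[b]) / (B * pred_loss))
        else lapply(seq_len(B), function(b) 0)
      }
      cont_batch <- 0
      grads_total <- NULL
      for (b in seq_len(B)) {
        labels <- batch$records[[b]]$residue_labels
        dX_extra <- NULL; dG_extra <- NULL
        if (contrastive$enabled && training$alpha > 0) {
          cg <- contrastive_loss_grad(caches[[b]]$X, caches[[b]]$G, labels, contrastive)
          cont_batch <- cont_batch + cg$loss / B
          dX_extra <- training$alpha * cg$dX / B
          dG_extra <- training$alpha * cg$dG / B
        } else if (contrastive$enabled) {
          cont_batch <- cont_batch + contrastive_loss(
            caches[[b]]$X, caches[[b]]$G, labels, contrastive) / B
        }
        bk <- model_backward(caches[[b]], params, d_outs[[b]], dX_extra, dG_extra)
        grads_total <- if (is.null(grads_total)) bk$grads
                       else add_params(grads_total, bk$grads)
      }
      grads_total <- merge_shared_attention(grads_total, model)
      st <- adam_step(params, grads_total, opt, training$learning_rate)
      params <- st$params; opt <- st$state
      if (model$share_attention) params$att_g <- params$att_x
      ep_pred <- ep_pred + pred_loss * B
      ep_cont <- ep_cont + cont_batch * B
      n_seen <- n_seen + B
    }
    ep_pred <- ep_pred / n_seen
    ep_cont <- ep_cont / n_seen
    sel <- eval_selection(params)
    history <- rbind(history, data.frame(
      epoch = epoch, pred_loss = ep_pred, cont_loss = ep_cont,
      total_loss = ep_pred + training$alpha * ep_cont, selection = sel))
    if (!is.null(log_file)) {
      line <- jsonlite::toJSON(list(epoch = epoch, pred_loss = ep_pred,
                                    cont_loss = ep_cont,
                                    total_loss = ep_pred + training$alpha * ep_cont,
                                    selection_metric = metric, selection = sel),
                               auto_unbox = TRUE, digits = NA)
      cat(line, "\n", sep = "", file = log_file, append = TRUE)
    }
    if (sel > best_metric) {
      best_metric <- sel; best_epoch <- epoch; params_best <- params
    }
  }
  names(history)[names(history) == "selection"] <- metric

  structure(list(params = params_best, params_final = params,
                 best_epoch = best_epoch, best_metric = best_metric,
                 history = history, task = task, n_classes = n_classes,
                 class_levels = class_levels, n_features = n_features,
                 model = model, contrastive = contrastive, training = training,
                 selection_metric = metric,
                 target_center = target_center, target_scale = target_scale,
                 container = if (is.character(data)) data else NULL),
            class = "stabnet")
}

add_params <- function(a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- add_params(a[[k]], b[[k]])
    return(a)
  }
  a + b
}

#' Index of the best epoch
#'
#' The (1-based) epoch maximizing the selection metric on the selection
#' split; ties resolve to the earliest epoch.
#'
#' @param object A fitted `stabnet` model.
#' @return Integer epoch index.
#' @export
select_best_epoch <- function(object) {
  stopifnot(inherits(object, "stabnet"))
  m <- object$history[[object$selection_metric]]
  which.max(m)  # which.max takes the first maximum: earliest epoch on ties
}

## ---- prediction and evaluation ------------------------------------------

resolve_triples <- function(object, newdata, split = NULL) {
  triples <- if (is.null(newdata)) {
    if (is.null(object$container))
      stop("no container stored in the fit; pass newdata")
    read_container(object$container)
  } else if (is.character(newdata)) read_container(newdata) else newdata
  if (!is.null(split)) {
    sp <- vapply(triples, function(t) t$record$split, character(1))
    triples <- triples[sp == split]
    if (length(triples) == 0L) stop(sprintf("split '%s' is empty", split))
  }
  triples
}

#' Predict from a fitted thermostability model
#'
#' Deterministic forward pass with the best-epoch parameters (contrastive
#' sampling plays no role at prediction time).
#'
#' @param object A fitted `stabnet`.
#' @param newdata Container path or list of triples; defaults to the
#'   container the model was fitted on.
#' @param split Optional split filter (`"train"`, `"valid"`, `"test"`).
#' @param type `"prob"` (class probabilities), `"class"` (0-based index),
#'   or `"response"` (probabilities for classification, degrees C for
#'   regression).
#' @param ... Unused.
#' @return Data frame: `id` plus `prob_<class>` columns and `class`
#'   (classification) or `tm_pred` (regression).
#' @export
predict.stabnet <- function(object, newdata = NULL, split = NULL,
                            type = c("response", "prob", "class"), ...) {
  type <- match.arg(type)
  triples <- resolve_triples(object, newdata, split)
  outs <- forward_split(triples, object$params, object$model)
  ids <- vapply(triples, function(t) t$record$id, character(1))
  if (object$task == "classification") {
    probs <- t(apply(outs, 1, softmax_vec))
    cls <- max.col(probs, ties.method = "first") - 1L
    df <- data.frame(id = ids, probs, class = cls, stringsAsFactors = FALSE)
    names(df)[1 + seq_len(ncol(probs))] <- paste0("prob_", object$class_levels)
    if (type == "class") df[, c("id", "class")] else df
  } else {
    tm <- outs[, 1] * object$target_scale + object$target_center
    data.frame(id = ids, tm_pred = tm, stringsAsFactors = FALSE)
  }
}

#' Evaluate a fitted model on a data split
#'
#' Classification: overall accuracy, per-class one-vs-rest precision, and
#' macro one-vs-rest ROC/AUC. Regression: Pearson, Spearman, R-squared and
#' RMSE (degrees C). Evaluation is deterministic: the same checkpoint and
#' split always produce an identical report.
#'
#' @param object A fitted `stabnet` or a checkpoint path from
#'   [save_model()].
#' @param newdata Container path or triples; defaults to the fitted
#'   container.
#' @param split Split to evaluate (default `"test"`).
#' @return A `metric_report` list; serialize with
#'   [metric_report_json()].
#' @export
evaluate_model <- function(object, newdata = NULL, split = "test") {
  if (is.character(object)) object <- load_model(object)
  stopifnot(inherits(object, "stabnet"))
  triples <- resolve_triples(object, newdata, split)
  truth <- vapply(triples, function(t) t$record$target, numeric(1))
  outs <- forward_split(triples, object$params, object$model)
  if (object$task == "classification") {
    probs <- t(apply(outs, 1, softmax_vec))
    pred <- max.col(probs, ties.method = "first") - 1L
    acc <- mean(pred == as.integer(truth))
    C <- object$n_classes
    prec <- vapply(0:(C - 1L), function(k) {
      cc <- confusion_counts(as.integer(pred == k), as.integer(truth == k))
      if (cc$TP + cc$FP == 0L) NA_real_ else cc$TP / (cc$TP + cc$FP)
    }, numeric(1))
    names(prec) <- object$class_levels
    roc <- if (length(unique(truth)) == C) macro_roc_auc(probs, truth) else NULL
    rep <- list(task = "classification", split = split, n = length(truth),
                accuracy = acc, per_class_precision = prec,
                per_class_auc = roc$per_class_auc, macro_auc = roc$macro_auc,
                macro_curve = roc$macro_curve)
  } else {
    tm <- outs[, 1] * object$target_scale + object$target_center
    rep <- list(task = "regression", split = split, n = length(truth),
                pearson = pearson(truth, tm), spearman = spearman(truth, tm),
                r_squared = r_squared(truth, tm),
                rmse = sqrt(mean((truth - tm)^2)))
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s split=%s n=%d\n", x$task, x$split, x$n))
  if (x$task == "classification") {
    cat(sprintf("  accuracy: %.4f\n", x$accuracy))
    if (!is.null(x$macro_auc)) cat(sprintf("  macro AUC: %.4f\n", x$macro_auc))
    cat("  per-class precision:\n")
    print(round(x$per_class_precision, 4))
  } else {
    cat(sprintf("  Pearson %.4f  Spearman %.4f  R^2 %.4f  RMSE %.2f C\n",
                x$pearson, x$spearman, x$r_squared, x$rmse))
  }
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param report A `metric_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
metric_report_json <- function(report, path = NULL) {
  r <- unclass(report)
  r$macro_curve <- NULL
  js <- jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

## ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding every named parameter tensor,
#' the full configuration snapshot and the training seed.
#'
#' @param object A fitted `stabnet`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `stabnet` object (load).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "stabnet"))
  saveRDS(object, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "stabnet")) stop(sprintf("'%s' is not a stabnet checkpoint", path))
  obj
}

## ---- S3 methods ----------------------------------------------------------

#' @export
print.stabnet <- function(x, ...) {
  cat(sprintf("<stabnet> %s model  D=%d  F=%d%s\n",
              x$task, x$model$D, x$n_features,
              if (x$task == "classification") sprintf("  C=%d", x$n_classes) else ""))
  cat(sprintf("  epochs: %d  best epoch: %d (%s=%.4f on %s split)\n",
              nrow(x$history), x$best_epoch, x$selection_metric,
              x$best_metric, x$training$selection_split))
  cat(sprintf("  contrastive: %s (alpha=%g, L_s=%d, K=%d, omega=%g)\n",
              if (x$contrastive$enabled && x$training$alpha > 0) "on" else "off",
              x$training$alpha, x$contrastive$L_s, x$contrastive$K,
              x$contrastive$omega))
  invisible(x)
}

#' @export
summary.stabnet <- function(object, split = "test", newdata = NULL, ...) {
  rep <- evaluate_model(object, newdata = newdata, split = split)
  out <- list(fit = object, report = rep)
  class(out) <- "summary.stabnet"
  out
}

#' @export
print.summary.stabnet <- function(x, ...) {
  print(x$fit)
  cat("\nTraining history:\n")
  print(x$fit$history, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @export
coef.stabnet <- function(object, ...) object$params

#' @export
residuals.stabnet <- function(object, newdata = NULL, split = "test", ...) {
  if (object$task != "regression")
    stop("residuals are defined for regression fits only")
  triples <- resolve_triples(object, newdata, split)
  truth <- vapply(triples, function(t) t$record$target, numeric(1))
  pred <- predict(object, newdata = triples)$tm_pred
  truth - pred
}

#' @export
plot.stabnet <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$total_loss, type = "b", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::lines(h$epoch, h$pred_loss, type = "b", lty = 2, col = 2)
  graphics::legend("topright", legend = c("total", "prediction"),
                   lty = c(1, 2), col = c(1, 2), bty = "n")
  graphics::plot(h$epoch, h[[x$selection_metric]], type = "b", xlab = "epoch",
                 ylab = x$selection_metric,
                 main = sprintf("%s (%s split)", x$selection_metric,
                                x$training$selection_split), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
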