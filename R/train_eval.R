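# Training loop, evaluation metrics, ablation harness, and hierarchical
# (two-level) classification.

#' Training configuration
#'
#' Defaults follow the reference operating point: mini-batches of 16,
#' learning rate 1e-3 with the Adam optimizer, 25 epochs, categorical
#' cross-entropy loss. The ablation mode selects the model wiring:
#' \describe{
#'   \item{full}{GAT graph embedding + additive attention over self-report
#'     and dialogue encodings (the complete two-channel model).}
#'   \item{sre_only / de_only}{classify from the self-report / dialogue
#'     encoding alone.}
#'   \item{knowledge_only}{classify from the mean-pooled GAT embedding of
#'     the filtered joint graph alone.}
#'   \item{sre_linear / de_linear}{text encoding concatenated with the
#'     unweighted mean of the subgraph's entity-name feature vectors
#'     (knowledge as a flat vector, no message passing).}
#'   \item{sre_knowledge / de_knowledge}{text encoding concatenated with
#'     the GAT-pooled subgraph embedding (no additive attention).}
#' }
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training split.
#' @param learning_rate Adam step size.
#' @param seed Seed controlling initialization, shuffling, and dropout.
#' @param ablation_mode One of the modes above.
#' @param hierarchical Whether to train a two-level classifier (see
#'   [train_hierarchical()]).
#' @param group_map Named character vector mapping disease to group, for
#'   hierarchical mode.
#' @return A list of class `kiddi_train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 25L, learning_rate = 1e-3,
                         seed = 0L, ablation_mode = "full",
                         hierarchical = FALSE, group_map = NULL) {
  if (!is_count(batch_size) || !is_count(epochs))
    stopf("batch_size and epochs must be positive integers")
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stopf("learning_rate must be non-negative")
  ablation_mode <- match.arg(ablation_mode, MODEL_MODES)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 ablation_mode = ablation_mode,
                 hierarchical = isTRUE(hierarchical), group_map = group_map),
            class = "kiddi_train_config")
}

#' Train a diagnosis model
#'
#' Minimizes the categorical cross-entropy by mini-batch Adam over the
#' training split; per-epoch training and validation losses are logged and
#' the parameters with the best validation accuracy are retained. Fully
#' deterministic given `config$seed` (initialization, shuffling, and
#' dropout all draw from the seeded stream).
#'
#' @param splits Named list of corpora as returned by [split_corpus()]
#'   (`train`, `validation`, `test`; `test` is unused here).
#' @param kg A `kiddi_kg` built from the training data.
#' @param config A [train_config()].
#' @param model_config A [model_config()].
#' @param distill_config A [distillation_config()].
#' @param verbose Print per-epoch progress.
#' @return A list of class `kiddi_checkpoint`: `model` (a `kiddi_model`
#'   with the best-validation parameters), `history` (data frame of epoch,
#'   train_loss, val_loss, val_accuracy), `best_epoch`, `config`.
#' @export
train <- function(splits, kg, config = train_config(),
                  model_config = kiddi::model_config(),
                  distill_config = distillation_config(), verbose = FALSE) {
  train_corpus <- splits$train
  if (!length(train_corpus$dialogues)) stopf("training split is empty")
  val_corpus <- splits$validation

  unseen <- setdiff(
    vapply(val_corpus$dialogues %||% list(), function(d) d$disease, character(1)),
    vapply(train_corpus$dialogues, function(d) d$disease, character(1)))
  if (length(unseen))
    warning(sprintf("disease(s) in validation unseen in training: %s",
                    paste(sort_c(unseen), collapse = ", ")))

  set.seed(config$seed)
  token_vocab <- build_token_vocab(train_corpus)
  model <- init_model(model_config, token_vocab, train_corpus$disease_vocab,
                      mode = config$ablation_mode,
                      distill_config = distill_config,
                      seed = config$seed)

  prep <- function(corp) lapply(corp$dialogues, prepare_example, kg = kg,
                                model = model)
  train_ex <- prep(train_corpus)
  val_ex <- if (length(val_corpus$dialogues)) prep(val_corpus) else list()

  eval_split <- function(exs, params) {
    model$params <- params
    losses <- numeric(length(exs))
    correct <- logical(length(exs))
    for (i in seq_along(exs)) {
      fw <- forward_example(exs[[i]], model, training = FALSE)
      losses[i] <- fw$loss
      correct[i] <- which.max(fw$probs) == exs[[i]]$label
    }
    list(loss = mean(losses), accuracy = mean(correct))
  }

  state <- adam_init(model$params)
  n <- length(train_ex)
  best <- list(params = model$params, accuracy = -Inf, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      bg <- NULL
      bloss <- 0
      for (i in idx) {
        ex <- train_ex[[i]]
        fw <- forward_example(ex, model, training = TRUE)
        g <- backward_example(ex, fw, model)
        bg <- if (is.null(bg)) g else add_grads(bg, g)
        bloss <- bloss + fw$loss
      }
      bg <- scale_grads(bg, 1 / length(idx))
      stepped <- adam_step(model$params, bg, state, config$learning_rate)
      model$params <- stepped$params
      state <- stepped$state
      epoch_loss <- epoch_loss + bloss
    }
    val <- if (length(val_ex)) eval_split(val_ex, model$params)
           else list(loss = NA_real_, accuracy = NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n, val_loss = val$loss,
      val_accuracy = val$accuracy))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val acc %.3f",
                      epoch, epoch_loss / n, val$loss, val$accuracy))
    track <- if (is.na(val$accuracy)) -epoch_loss / n else val$accuracy
    if (track > best$accuracy) {
      best <- list(params = model$params, accuracy = track, epoch = epoch)
    }
  }

  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 config = config),
            class = "kiddi_checkpoint")
}

#' Predict the disease for one dialogue
#'
#' @param checkpoint A `kiddi_checkpoint` from [train()].
#' @param dialogue A `kiddi_dialogue`.
#' @param kg The knowledge graph used in training.
#' @return As [forward()]: `probs`, `prediction`, `alpha`,
#'   `graph_embedding`.
#' @export
predict_dialogue <- function(checkpoint, dialogue, kg) {
  stopifnot(inherits(checkpoint, "kiddi_checkpoint"))
  forward(dialogue, kg, checkpoint$model)
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics from predictions
#'
#' Accuracy (correct / total), macro-averaged F1 over classes with support
#' (per-class harmonic mean of precision and recall, 0 where undefined),
#' mean per-example Jaccard similarity between the singleton truth and
#' prediction label sets (equal to accuracy for single-label prediction),
#' and top-k coverage accuracy for k in {1, 3, 5} when a probability
#' matrix is supplied.
#'
#' @param true,predicted Character vectors of gold and predicted classes.
#' @param classes Full class vocabulary (confusion-matrix axes).
#' @param probs Optional example x class probability matrix for top-k.
#' @return A list of class `kiddi_eval_report`: `accuracy`, `macro_f1`,
#'   `mean_jaccard`, `top_k` (named vector), `per_class` (data frame with
#'   precision/recall/F1/support), `confusion` (matrix of counts).
#' @export
eval_metrics <- function(true, predicted, classes, probs = NULL) {
  stopifnot(length(true) == length(predicted))
  if (!length(true)) stopf("cannot evaluate an empty split")
  confusion <- table(factor(true, levels = classes),
                     factor(predicted, levels = classes))
  confusion <- unclass(confusion)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL, stringsAsFactors = FALSE)
  accuracy <- mean(true == predicted)
  jaccard <- mean(ifelse(true == predicted, 1, 0))  # singleton label sets

  top_k <- NULL
  if (!is.null(probs)) {
    ks <- pmin(c(1L, 3L, 5L), length(classes))
    top_k <- vapply(ks, function(k) {
      mean(vapply(seq_along(true), function(i) {
        ord <- order(-probs[i, ], seq_len(ncol(probs)))
        true[i] %in% classes[ord[seq_len(k)]]
      }, logical(1)))
    }, numeric(1))
    names(top_k) <- paste0("top", c(1L, 3L, 5L))
  }

  structure(list(accuracy = accuracy,
                 macro_f1 = mean(f1[support > 0]),
                 mean_jaccard = jaccard, top_k = top_k,
                 per_class = per_class, confusion = confusion,
                 n = length(true)),
            class = "kiddi_eval_report")
}

#' @export
print.kiddi_eval_report <- function(x, ...) {
  cat(sprintf("<kiddi_eval_report> n=%d accuracy=%.4f macro_f1=%.4f jaccard=%.4f\n",
              x$n, x$accuracy, x$macro_f1, x$mean_jaccard))
  if (!is.null(x$top_k))
    cat("  top-k coverage:",
        paste(sprintf("%s=%.4f", names(x$top_k), x$top_k), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a checkpoint on a corpus
#'
#' Runs the model over every dialogue (dropout off, deterministic) and
#' computes [eval_metrics()]; also returns per-example predictions with
#' attention weights for inspection.
#'
#' @param checkpoint A `kiddi_checkpoint`.
#' @param corpus Evaluation corpus (non-empty).
#' @param kg The knowledge graph used in training.
#' @return A `kiddi_eval_report` with an extra `predictions` data frame
#'   (id, true, predicted, top5, alpha1, alpha2).
#' @export
evaluate <- function(checkpoint, corpus, kg) {
  stopifnot(inherits(checkpoint, "kiddi_checkpoint"))
  if (!length(corpus$dialogues)) stopf("cannot evaluate an empty split")
  model <- checkpoint$model
  classes <- model$disease_vocab
  n <- length(corpus$dialogues)
  probs <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  true <- character(n)
  alpha <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    d <- corpus$dialogues[[i]]
    out <- forward(d, kg, model)
    probs[i, ] <- out$probs
    true[i] <- d$disease
    if (!is.null(out$alpha)) alpha[i, ] <- out$alpha
  }
  predicted <- classes[max.col(probs, ties.method = "first")]
  report <- eval_metrics(true, predicted, classes, probs)
  top5 <- vapply(seq_len(n), function(i) {
    ord <- order(-probs[i, ], seq_along(classes))
    paste(classes[ord[seq_len(min(5L, length(classes)))]], collapse = ",")
  }, character(1))
  report$predictions <- data.frame(
    id = vapply(corpus$dialogues, function(d) d$id, character(1)),
    true = true, predicted = predicted, top5 = top5,
    alpha1 = alpha[, 1], alpha2 = alpha[, 2],
    stringsAsFactors = FALSE)
  report
}

# ---- ablation ---------------------------------------------------------------

#' Train and evaluate several model wirings under shared splits and seeds
#'
#' Splits the corpus once (same fractions and seed for every mode), trains
#' one model per requested mode, and evaluates each on the shared test
#' split, so mode differences are attributable to the wiring alone.
#'
#' @param corpus A `kiddi_corpus`.
#' @param kg A `kiddi_kg`.
#' @param config A [train_config()] (its `ablation_mode` is overridden per
#'   mode).
#' @param modes Character vector of wiring modes to run.
#' @param fractions Split fractions.
#' @param model_config,distill_config Passed to [train()].
#' @return Named list mode -> `kiddi_eval_report`.
#' @export
run_ablation <- function(corpus, kg, config = train_config(),
                         modes = MODEL_MODES, fractions = c(0.7, 0.1, 0.2),
                         model_config = kiddi::model_config(),
                         distill_config = distillation_config()) {
  modes <- vapply(modes, match.arg, character(1), choices = MODEL_MODES)
  splits <- split_corpus(corpus, fractions, seed = config$seed)
  out <- lapply(modes, function(m) {
    cfg <- config
    cfg$ablation_mode <- m
    ck <- train(splits, kg, cfg, model_config = model_config,
                distill_config = distill_config)
    evaluate(ck, splits$test, kg)
  })
  names(out) <- modes
  out
}

# ---- hierarchical classification --------------------------------------------

relabel_corpus <- function(corpus, map) {
  dialogues <- lapply(corpus$dialogues, function(d) {
    d$disease <- unname(map[[d$disease]])
    d
  })
  corpus(dialogues, symptom_vocab = corpus$symptom_vocab,
         disease_vocab = sort_c(unname(map)))
}

subset_corpus <- function(corpus, diseases) {
  keep <- vapply(corpus$dialogues, function(d) d$disease %in% diseases,
                 logical(1))
  corpus(corpus$dialogues[keep], symptom_vocab = corpus$symptom_vocab,
         disease_vocab = diseases)
}

#' Train a two-level (group, then disease) classifier
#'
#' Mirrors the structure of medical departments: a first-layer model
#' predicts the disease group, and a per-group model predicts the disease
#' within that group. Every component model is trained with the same
#' configuration and seed discipline as [train()].
#'
#' @param splits Corpus splits from [split_corpus()].
#' @param kg A `kiddi_kg`.
#' @param group_map Named character vector mapping every disease in the
#'   vocabulary to a group name.
#' @param config,model_config,distill_config As in [train()].
#' @return A list of class `kiddi_hierarchical`: `group_checkpoint`,
#'   `group_models` (named list of per-group checkpoints), `group_map`.
#' @export
train_hierarchical <- function(splits, kg, group_map, config = train_config(),
                               model_config = kiddi::model_config(),
                               distill_config = distillation_config()) {
  diseases <- splits$train$disease_vocab
  missing <- setdiff(diseases, names(group_map))
  if (length(missing))
    stopf("group_map is missing disease(s): %s", paste(missing, collapse = ", "))
  gsplits <- lapply(splits, relabel_corpus, map = group_map)
  group_checkpoint <- train(gsplits, kg, config, model_config = model_config,
                            distill_config = distill_config)
  groups <- sort_c(unname(group_map))
  group_models <- lapply(groups, function(g) {
    members <- sort_c(names(group_map)[group_map == g])
    sub <- lapply(splits, subset_corpus, diseases = members)
    train(sub, kg, config, model_config = model_config,
          distill_config = distill_config)
  })
  names(group_models) <- groups
  structure(list(group_checkpoint = group_checkpoint,
                 group_models = group_models, group_map = group_map),
            class = "kiddi_hierarchical")
}

#' Two-stage prediction: group, then disease within the group
#'
#' @param hier A `kiddi_hierarchical` from [train_hierarchical()].
#' @param dialogue A `kiddi_dialogue`.
#' @param kg The knowledge graph used in training.
#' @return List with `group` and `disease`.
#' @export
hierarchical_classify <- function(hier, dialogue, kg) {
  stopifnot(inherits(hier, "kiddi_hierarchical"))
  g <- predict_dialogue(hier$group_checkpoint, dialogue, kg)$prediction
  gm <- hier$group_models[[g]]
  if (is.null(gm)) stopf("no disease model for group '%s'", g)
  list(group = g, disease = predict_dialogue(gm, dialogue, kg)$prediction)
}

#' Evaluate a hierarchical classifier
#'
#' Reports group-level accuracy (was the right department triggered?) and
#' final disease accuracy; correctness of the disease implies correctness
#' of the group, so group accuracy is never below disease accuracy.
#'
#' @inheritParams hierarchical_classify
#' @param corpus Evaluation corpus.
#' @return List with `group_accuracy`, `disease_accuracy`, and a
#'   `predictions` data frame.
#' @export
evaluate_hierarchical <- function(hier, corpus, kg) {
  if (!length(corpus$dialogues)) stopf("cannot evaluate an empty split")
  res <- lapply(corpus$dialogues, hierarchical_classify, hier = hier, kg = kg)
  true_dis <- vapply(corpus$dialogues, function(d) d$disease, character(1))
  true_grp <- unname(hier$group_map[true_dis])
  pred_grp <- vapply(res, `[[`, character(1), "group")
  pred_dis <- vapply(res, `[[`, character(1), "disease")
  list(group_accuracy = mean(pred_grp == true_grp),
       disease_accuracy = mean(pred_dis == true_dis),
       predictions = data.frame(
         id = vapply(corpus$dialogues, function(d) d$id, character(1)),
         true = true_dis, true_group = true_grp,
         predicted_group = pred_grp, predicted = pred_dis,
         stringsAsFactors = FALSE))
}
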