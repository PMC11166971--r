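test_that("training loss decreases over epochs on a small corpus", {
  gen <- quick_corpus(seed = 0, n_dialogues = 50, n_diseases = 5)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 0)
  ck <- train(splits, kg, small_train_config(epochs = 3),
              model_config = small_model_config())
  expect_true(all(diff(ck$history$train_loss) < 0))
  # gradients reach the token embeddings: they move away from initialization
  init <- init_model(small_model_config(), build_token_vocab(splits$train),
                     splits$train$disease_vocab, mode = "full",
                     distill_config = distillation_config(), seed = 0)
  expect_gt(max(abs(ck$model$params$E - init$params$E)), 0)
})

test_that("training is bit-identical under a fixed seed", {
  gen <- quick_corpus(seed = 0, n_dialogues = 40, n_diseases = 4)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 0)
  cfg <- small_train_config(epochs = 2)
  ck1 <- train(splits, kg, cfg, model_config = small_model_config())
  ck2 <- train(splits, kg, cfg, model_config = small_model_config())
  expect_identical(ck1$model$params, ck2$model$params)
  r1 <- evaluate(ck1, splits$test, kg)
  r2 <- evaluate(ck2, splits$test, kg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("a zero learning rate leaves parameters unchanged", {
  gen <- quick_corpus(seed = 0, n_dialogues = 20, n_diseases = 4)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 0)
  cfg <- train_config(epochs = 1, learning_rate = 0, seed = 0)
  ck <- train(splits, kg, cfg, model_config = small_model_config())
  init <- init_model(small_model_config(), build_token_vocab(splits$train),
                     splits$train$disease_vocab, mode = "full",
                     distill_config = distillation_config(), seed = 0)
  expect_equal(ck$model$params, init$params)
})

test_that("metrics reproduce a hand-worked confusion matrix", {
  # 3 classes; 10 examples written out by hand:
  #   true a: predicted a, a, b        (3 examples)
  #   true b: predicted b, b, b, c     (4)
  #   true c: predicted c, a, a        (3)
  true <- c("a", "a", "a", "b", "b", "b", "b", "c", "c", "c")
  pred <- c("a", "a", "b", "b", "b", "b", "c", "c", "a", "a")
  r <- eval_metrics(true, pred, classes = c("a", "b", "c"))
  expect_equal(r$accuracy, 6 / 10)
  # precision: a 2/4, b 3/4, c 1/2 ; recall: a 2/3, b 3/4, c 1/3
  expect_equal(r$per_class$precision, c(2 / 4, 3 / 4, 1 / 2))
  expect_equal(r$per_class$recall, c(2 / 3, 3 / 4, 1 / 3))
  f1 <- c(2 * (1 / 2) * (2 / 3) / (1 / 2 + 2 / 3), 3 / 4,
          2 * (1 / 2) * (1 / 3) / (1 / 2 + 1 / 3))
  expect_equal(r$per_class$f1, f1)
  expect_equal(r$macro_f1, mean(f1))
  expect_equal(r$mean_jaccard, r$accuracy)  # singleton label sets
  expect_equal(unname(r$confusion["b", "c"]), 1)
})

test_that("perfect predictions give accuracy = F1 = Jaccard = 1; disjoint give 0", {
  r <- eval_metrics(c("a", "b"), c("a", "b"), classes = c("a", "b"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_f1, 1)
  expect_equal(r$mean_jaccard, 1)
  r0 <- eval_metrics("a", "b", classes = c("a", "b"))
  expect_equal(r0$mean_jaccard, 0)
  expect_error(eval_metrics(character(), character(), classes = "a"), "empty")
})

test_that("top-k coverage is monotone in k and bounded by accuracy", {
  gen <- quick_corpus(seed = 4, n_dialogues = 50, n_diseases = 5)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 4)
  ck <- train(splits, kg, small_train_config(epochs = 2),
              model_config = small_model_config())
  r <- evaluate(ck, splits$test, kg)
  expect_lte(r$top_k[["top1"]], r$top_k[["top3"]])
  expect_lte(r$top_k[["top3"]], r$top_k[["top5"]])
  expect_equal(r$top_k[["top1"]], r$accuracy)
  expect_equal(r$mean_jaccard, r$accuracy)
  expect_true(all(!is.na(r$predictions$alpha1)))
  expect_equal(r$predictions$alpha1 + r$predictions$alpha2,
               rep(1, nrow(r$predictions)), tolerance = 1e-9)
})

test_that("trained models beat chance on a clean synthetic task", {
  gen <- quick_corpus(seed = 0, n_dialogues = 100, n_diseases = 5,
                      noise_rate = 0)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 0)
  ck <- train(splits, kg, small_train_config(epochs = 6),
              model_config = small_model_config())
  r <- evaluate(ck, splits$test, kg)
  expect_gt(r$accuracy, 1 / 5 + 0.2)
})

test_that("every ablation mode emits a complete evaluation report", {
  gen <- quick_corpus(seed = 2, n_dialogues = 40, n_diseases = 4)
  kg <- build_graph(gen$corpus)
  reports <- run_ablation(gen$corpus, kg, small_train_config(epochs = 2),
                          modes = c("full", "sre_only", "knowledge_only",
                                    "de_linear"),
                          model_config = small_model_config())
  expect_named(reports, c("full", "sre_only", "knowledge_only", "de_linear"))
  for (r in reports) {
    expect_s3_class(r, "kiddi_eval_report")
    expect_true(is.finite(r$accuracy))
    expect_true(is.finite(r$macro_f1))
    expect_length(r$top_k, 3)
  }
})

test_that("a single all-disease group makes hierarchical classification flat", {
  gen <- quick_corpus(seed = 1, n_dialogues = 40, n_diseases = 4)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 1)
  diseases <- gen$corpus$disease_vocab
  gmap <- stats::setNames(rep("all", length(diseases)), diseases)
  cfg <- small_train_config(epochs = 2)
  hier <- train_hierarchical(splits, kg, gmap, cfg,
                             model_config = small_model_config())
  flat <- train(splits, kg, cfg, model_config = small_model_config())
  he <- evaluate_hierarchical(hier, splits$test, kg)
  fe <- evaluate(flat, splits$test, kg)
  expect_equal(he$group_accuracy, 1)
  expect_equal(he$disease_accuracy, fe$accuracy)
  expect_identical(he$predictions$predicted, fe$predictions$predicted)
})

test_that("group accuracy is never below disease accuracy", {
  gen <- quick_corpus(seed = 3, n_dialogues = 60, n_diseases = 6,
                      n_symptoms = 24)
  kg <- build_graph(gen$corpus)
  splits <- split_corpus(gen$corpus, seed = 3)
  diseases <- gen$corpus$disease_vocab
  gmap <- stats::setNames(rep(c("g1", "g2"), each = 3), diseases)
  hier <- train_hierarchical(splits, kg, gmap, small_train_config(epochs = 3),
                             model_config = small_model_config())
  he <- evaluate_hierarchical(hier, splits$test, kg)
  expect_gte(he$group_accuracy, he$disease_accuracy)
  expect_error(train_hierarchical(splits, kg, gmap[-1],
                                  small_train_config(epochs = 1),
                                  model_config = small_model_config()),
               "missing disease")
})

test_that("validation diseases unseen in training trigger a warning, not an error", {
  mk <- function(id, dis, sym) dialogue(id, dis, list(
    utterance("patient", paste("I have", sym), intent = "Symptom",
              symptoms = sym)))
  train_c <- corpus(list(mk("t1", "da", "s1"), mk("t2", "da", "s1"),
                         mk("t3", "db", "s2")),
                    disease_vocab = c("da", "db", "dc"))
  val_c <- corpus(list(mk("v1", "dc", "s1")),
                  disease_vocab = c("da", "db", "dc"))
  kg <- build_graph(train_c)
  splits <- list(train = train_c, validation = val_c, test = val_c)
  expect_warning(
    ck <- train(splits, kg, train_config(epochs = 1, seed = 0),
                model_config = model_config(d2 = 8, d1 = 4, d3 = 2,
                                            n_heads = 2,
                                            max_sequence_length = 32)),
    "unseen in training")
  # the class space stays vocabulary-defined: dC is still a valid output
  expect_length(predict_dialogue(ck, val_c$dialogues[[1]], kg)$probs, 3)
})
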