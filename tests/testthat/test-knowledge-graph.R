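test_that("counts match hand expectations on a one-dialogue corpus", {
  corp <- corpus(list(dialogue("d1", "flu", list(
    utterance("patient", "fever and cough", intent = "Symptom",
              symptoms = c("fever", "cough"))))))
  counts <- count_cooccurrences(corp)
  expect_equal(counts$n_sd["fever", "flu"], 1)
  expect_equal(counts$n_sd["cough", "flu"], 1)
  expect_equal(counts$n_ss["fever", "cough"], 1)
  expect_equal(counts$n_ss["cough", "fever"], 1)
  expect_equal(diag(counts$n_ss), c(cough = 0, fever = 0))
})

test_that("empty corpus yields zero counts", {
  counts <- count_cooccurrences(corpus(list()))
  expect_equal(length(counts$n_sd), 0)
  expect_equal(counts$disease_count, 0)
})

test_that("sf, idf, and edge weights reproduce hand-computed values", {
  # disease d1 with counts {a: 2, b: 2}; a occurs with 1 of 3 diseases
  dialogues <- list(
    dialogue("x1", "d1", list(utterance("patient", "t", intent = "Symptom",
                                        symptoms = c("a", "b")))),
    dialogue("x2", "d1", list(utterance("patient", "t", intent = "Symptom",
                                        symptoms = c("a", "b")))),
    dialogue("x3", "d2", list(utterance("patient", "t", intent = "Symptom",
                                        symptoms = "b"))),
    dialogue("x4", "d3", list(utterance("patient", "t", intent = "Symptom",
                                        symptoms = "b")))
  )
  counts <- count_cooccurrences(corpus(dialogues))
  expect_equal(symptom_frequency(counts, "a", "d1"), 0.5)
  expect_equal(inverse_disease_frequency(counts, "a"), log(3))
  expect_equal(sd_edge_weight(counts, "a", "d1"), 0.5 * log(3))
  # b occurs with all diseases: idf = 0, so the weight vanishes at any sf
  expect_equal(inverse_disease_frequency(counts, "b"), 0)
  expect_equal(sd_edge_weight(counts, "b", "d1"), 0)
  # disease with a single symptom: sf = 1
  expect_equal(symptom_frequency(counts, "b", "d2"), 1)
  expect_error(inverse_disease_frequency(counts, "zzz"), "never occurs")
})

test_that("symptom-symptom weights are row-normalized co-occurrence shares", {
  # n(a,b) = 1, n(a,c) = 3
  mk <- function(id, syms) dialogue(id, "d1", list(
    utterance("patient", "t", intent = "Symptom", symptoms = syms)))
  dialogues <- list(mk("y1", c("a", "b")), mk("y2", c("a", "c")),
                    mk("y3", c("a", "c")), mk("y4", c("a", "c")))
  counts <- count_cooccurrences(corpus(dialogues))
  expect_equal(ss_edge_weight(counts, "a", "b"), 0.25)
  expect_equal(ss_edge_weight(counts, "a", "c"), 0.75)
  expect_equal(ss_edge_weight(counts, "b", "a"), 1)  # b co-occurs only with a
  expect_error(ss_edge_weight(counts, "zz", "a"), "no co-occurrences")
})

test_that("normalization identities hold on generated corpora", {
  gen <- quick_corpus(seed = 3, n_dialogues = 30)
  kg <- build_graph(gen$corpus)
  counts <- kg$counts
  for (d in kg$diseases) {
    tot <- sum(counts$n_sd[, d])
    if (tot > 0) {
      expect_equal(sum(vapply(kg$symptoms, symptom_frequency,
                              numeric(1), counts = counts, d = d)), 1)
    }
  }
  active <- rowSums(counts$n_ss) > 0
  expect_true(all(abs(rowSums(kg$ss_weights[active, , drop = FALSE]) - 1) < 1e-12))
  # idf zero iff the symptom occurs with every disease
  for (s in kg$symptoms[rowSums(counts$n_sd) > 0]) {
    idf <- inverse_disease_frequency(counts, s)
    if (sum(counts$n_sd[s, ] > 0) == counts$disease_count) {
      expect_equal(idf, 0)
    } else {
      expect_gt(idf, 0)
    }
  }
})

test_that("the graph agrees exactly with the nested-loop oracle on random corpora", {
  for (seed in c(0, 1, 2, 7, 13)) {
    gen <- quick_corpus(seed = seed, n_dialogues = 15, n_diseases = 4,
                        n_symptoms = 16, p_affirmative = 0.5, noise_rate = 0.1)
    kg <- build_graph(gen$corpus)
    oracle <- kg_oracle(gen$corpus)
    expect_equal(kg$counts$n_sd, oracle$n_sd)
    expect_equal(kg$counts$n_ss, oracle$n_ss)
    for (s in kg$symptoms) for (d in kg$diseases) {
      if (oracle$n_sd[s, d] > 0) {
        expect_equal(kg$sd_weights[s, d], oracle$sf(s, d) * oracle$idf(s),
                     tolerance = 1e-12)
      } else {
        expect_equal(unname(kg$sd_weights[s, d]), 0)
      }
    }
    active <- rownames(oracle$n_ss)[rowSums(oracle$n_ss) > 0]
    for (a in active) for (b in kg$symptoms) {
      expect_equal(kg$ss_weights[a, b], oracle$ss(a, b), tolerance = 1e-12)
    }
  }
})

test_that("edge count matches nonzero count cells and weights ignore dialogue order", {
  gen <- quick_corpus(seed = 4, n_dialogues = 20)
  kg <- build_graph(gen$corpus)
  edges <- kg_edges(kg)
  expect_equal(sum(edges$type == "sd"), sum(kg$counts$n_sd > 0))
  expect_equal(sum(edges$type == "ss"), sum(kg$ss_weights > 0))

  permuted <- corpus(rev(gen$corpus$dialogues),
                     symptom_vocab = gen$corpus$symptom_vocab,
                     disease_vocab = gen$corpus$disease_vocab)
  kg2 <- build_graph(permuted)
  expect_equal(kg2$sd_weights, kg$sd_weights)
  expect_equal(kg2$ss_weights, kg$ss_weights)
})

test_that("knowledge graphs survive JSON round-trips", {
  gen <- quick_corpus(seed = 5, n_dialogues = 25)
  kg <- build_graph(gen$corpus)
  path <- withr::local_tempfile(fileext = ".json")
  write_kg(kg, path)
  kg2 <- read_kg(path)
  expect_equal(kg2$sd_weights, kg$sd_weights)
  expect_equal(kg2$ss_weights, kg$ss_weights)
  expect_equal(kg2$counts$n_sd, kg$counts$n_sd)
})
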