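# Symptom-symptom-disease (S-S-D) knowledge graph weighted by sf-idf.
#
# Nodes are symptoms and diseases. A symptom-disease edge exists iff the
# two co-occur in at least one dialogue and is weighted by symptom
# frequency-inverse disease frequency:
#
#   e(s, d)  = sf(s, d) * idf(s)
#   sf(s, d) = n_sd / sum_k n_kd          (share of d's symptom mass on s)
#   idf(s)   = log(|D| / #{d : n_sd > 0}) (natural log)
#
# Symptom-symptom edges are the row-normalized co-occurrence counts
# e(s_i, s_j) = n(s_i, s_j) / sum_k n(s_i, s_k); they are directed because
# the normalization is per source symptom. Counting uses set semantics: one
# dialogue contributes each (symptom, disease) or symptom pair at most
# once, with the dialogue's symptom set resolved by the same rule as
# symptom extraction (Affirmative turns attribute the preceding doctor
# inquiry's symptom).

#' Count symptom-disease and symptom-symptom co-occurrences
#'
#' @param corpus A `kiddi_corpus`.
#' @return A list of class `kiddi_counts`: `n_sd` (symptom x disease count
#'   matrix), `n_ss` (symmetric symptom x symptom count matrix with zero
#'   diagonal), `disease_count` (size of the disease vocabulary).
#' @export
count_cooccurrences <- function(corpus) {
  stopifnot(inherits(corpus, "kiddi_corpus"))
  S <- corpus$symptom_vocab
  D <- corpus$disease_vocab
  n_sd <- matrix(0, length(S), length(D), dimnames = list(S, D))
  n_ss <- matrix(0, length(S), length(S), dimnames = list(S, S))
  for (d in corpus$dialogues) {
    syms <- extract_symptoms(d)
    if (!length(syms)) next
    n_sd[syms, d$disease] <- n_sd[syms, d$disease] + 1
    if (length(syms) > 1) {
      n_ss[syms, syms] <- n_ss[syms, syms] + 1
      diag(n_ss)[match(syms, S)] <- diag(n_ss)[match(syms, S)] - 1
    }
  }
  structure(list(n_sd = n_sd, n_ss = n_ss, disease_count = length(D)),
            class = "kiddi_counts")
}

#' Symptom frequency sf(s, d)
#'
#' The co-occurrence count of symptom `s` with disease `d` divided by the
#' total symptom co-occurrence mass of `d`; sums to 1 over symptoms for any
#' disease with at least one count. Defined as 0 for a disease with no
#' observed symptoms.
#'
#' @param counts A `kiddi_counts`.
#' @param s,d Symptom and disease names.
#' @return Proportion in `[0, 1]`.
#' @export
symptom_frequency <- function(counts, s, d) {
  stopifnot(inherits(counts, "kiddi_counts"))
  tot <- sum(counts$n_sd[, d])
  if (tot == 0) return(0)
  counts$n_sd[s, d] / tot
}

#' Inverse disease frequency idf(s)
#'
#' Natural logarithm of the total number of diseases divided by the number
#' of diseases the symptom co-occurs with. Zero iff the symptom occurs with
#' every disease; errors for a symptom never observed with any disease.
#'
#' @param counts A `kiddi_counts`.
#' @param s Symptom name.
#' @return Non-negative real.
#' @export
inverse_disease_frequency <- function(counts, s) {
  stopifnot(inherits(counts, "kiddi_counts"))
  if (!s %in% rownames(counts$n_sd))
    stopf("idf undefined: symptom '%s' never occurs with any disease", s)
  k <- sum(counts$n_sd[s, ] > 0)
  if (k == 0) stopf("idf undefined: symptom '%s' never occurs with any disease", s)
  log(counts$disease_count / k)
}

#' Symptom-disease edge weight e(s, d) = sf(s, d) * idf(s)
#'
#' @inheritParams symptom_frequency
#' @return Non-negative real; high when `s` concentrates on `d` and links
#'   few other diseases.
#' @export
sd_edge_weight <- function(counts, s, d) {
  symptom_frequency(counts, s, d) * inverse_disease_frequency(counts, s)
}

#' Symptom-symptom edge weight e(s_i, s_j)
#'
#' Co-occurrence count of the pair divided by the co-occurrence of `s_i`
#' with all symptoms; rows are stochastic, and the weight is generally
#' asymmetric. Errors for a symptom with no co-occurrences.
#'
#' @param counts A `kiddi_counts`.
#' @param s_i,s_j Symptom names (source, target).
#' @return Proportion in `[0, 1]`.
#' @export
ss_edge_weight <- function(counts, s_i, s_j) {
  stopifnot(inherits(counts, "kiddi_counts"))
  if (!s_i %in% rownames(counts$n_ss))
    stopf("symptom-symptom weight undefined: '%s' has no co-occurrences", s_i)
  tot <- sum(counts$n_ss[s_i, ])
  if (tot == 0)
    stopf("symptom-symptom weight undefined: '%s' has no co-occurrences", s_i)
  counts$n_ss[s_i, s_j] / tot
}

#' Build the S-S-D knowledge graph from a corpus
#'
#' Composes the counting and weighting steps into weight matrices:
#' `sd_weights[s, d]` is `e(s, d)` where `n_sd > 0` and 0 elsewhere;
#' `ss_weights[i, j]` is the row-normalized co-occurrence (rows of isolated
#' symptoms stay all-zero, i.e. no outgoing edges).
#'
#' @param corpus A `kiddi_corpus`.
#' @return A list of class `kiddi_kg`: `symptoms`, `diseases`, `sd_weights`,
#'   `ss_weights`, `counts`.
#' @export
build_graph <- function(corpus) {
  build_graph_from_counts(count_cooccurrences(corpus))
}

#' Edge list of a knowledge graph
#'
#' @param kg A `kiddi_kg`.
#' @return A data frame with columns `source`, `target`, `weight`, `type`
#'   (`"sd"` or `"ss"`); symptom-disease edges are those with a positive
#'   co-occurrence count, symptom-symptom edges the nonzero off-diagonal
#'   normalized co-occurrences.
#' @export
kg_edges <- function(kg) {
  stopifnot(inherits(kg, "kiddi_kg"))
  sd_idx <- which(kg$counts$n_sd > 0, arr.ind = TRUE)
  sd <- data.frame(
    source = kg$symptoms[sd_idx[, 1]],
    target = kg$diseases[sd_idx[, 2]],
    weight = kg$sd_weights[sd_idx],
    type = rep("sd", nrow(sd_idx)),
    stringsAsFactors = FALSE
  )
  ss_idx <- which(kg$ss_weights > 0, arr.ind = TRUE)
  ss <- data.frame(
    source = kg$symptoms[ss_idx[, 1]],
    target = kg$symptoms[ss_idx[, 2]],
    weight = kg$ss_weights[ss_idx],
    type = rep("ss", nrow(ss_idx)),
    stringsAsFactors = FALSE
  )
  out <- rbind(sd, ss)
  out[order(out$type, out$source, out$target, method = "radix"), , drop = FALSE]
}

#' Write a knowledge graph as JSON
#'
#' Serializes node lists and the edge list (source, target, weight, type).
#' @param kg A `kiddi_kg`.
#' @param path Output path.
#' @export
write_kg <- function(kg, path) {
  edges <- kg_edges(kg)
  counts_sd <- which(kg$counts$n_sd > 0, arr.ind = TRUE)
  body <- list(
    diseases = as.list(kg$diseases),
    edges = lapply(seq_len(nrow(edges)), function(i) list(
      source = edges$source[i], target = edges$target[i],
      type = edges$type[i], weight = edges$weight[i]
    )),
    sd_counts = lapply(seq_len(nrow(counts_sd)), function(i) list(
      count = kg$counts$n_sd[counts_sd[i, 1], counts_sd[i, 2]],
      disease = kg$diseases[counts_sd[i, 2]],
      symptom = kg$symptoms[counts_sd[i, 1]]
    )),
    ss_counts = {
      idx <- which(kg$counts$n_ss > 0, arr.ind = TRUE)
      lapply(seq_len(nrow(idx)), function(i) list(
        count = kg$counts$n_ss[idx[i, 1], idx[i, 2]],
        source = kg$symptoms[idx[i, 1]],
        target = kg$symptoms[idx[i, 2]]
      ))
    },
    symptoms = as.list(kg$symptoms)
  )
  json <- jsonlite::toJSON(body[sort_c(names(body))], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Read a knowledge graph written by [write_kg()]
#'
#' @param path Path to a knowledge-graph JSON file.
#' @return A `kiddi_kg`.
#' @export
read_kg <- function(path) {
  if (!file.exists(path)) stopf("knowledge graph file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  S <- unlist(raw$symptoms) %||% character()
  D <- unlist(raw$diseases) %||% character()
  n_sd <- matrix(0, length(S), length(D), dimnames = list(S, D))
  for (x in raw$sd_counts) n_sd[x$symptom, x$disease] <- x$count
  n_ss <- matrix(0, length(S), length(S), dimnames = list(S, S))
  for (x in raw$ss_counts) n_ss[x$source, x$target] <- x$count
  counts <- structure(list(n_sd = n_sd, n_ss = n_ss, disease_count = length(D)),
                      class = "kiddi_counts")
  build_graph_from_counts(counts)
}

# shared tail of build_graph, reused when counts come from deserialization
build_graph_from_counts <- function(counts) {
  n_sd <- counts$n_sd
  col_tot <- colSums(n_sd)
  sf <- sweep(n_sd, 2, ifelse(col_tot > 0, col_tot, 1), "/")
  linked <- rowSums(n_sd > 0)
  idf <- ifelse(linked > 0, log(counts$disease_count / pmax(linked, 1)), 0)
  sd_w <- sf * idf
  sd_w[n_sd == 0] <- 0
  row_tot <- rowSums(counts$n_ss)
  ss_w <- counts$n_ss / ifelse(row_tot > 0, row_tot, 1)
  structure(list(symptoms = rownames(n_sd), diseases = colnames(n_sd),
                 sd_weights = sd_w, ss_weights = ss_w, counts = counts),
            class = "kiddi_kg")
}
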