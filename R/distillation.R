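# Discourse-aware selective filtering (DSF): resolve the conversation's
# symptom set, keep each symptom's top-K associated diseases, and attach a
# dialog node connected to every symptom node. The resulting joint graph is
# what the graph-attention channel consumes.

#' Configuration for knowledge distillation
#'
#' @param K Number of top-ranked diseases retained per symptom (the
#'   knowledge width; values 1-3 are the usual operating range).
#' @param include_ss_edges Include symptom-symptom edges among the filtered
#'   symptoms (toggleable for ablation; on by default since the knowledge
#'   graph is S-S-D).
#' @param symptom_source `"gold_annotations"` uses the corpus intent/slot
#'   annotations; `"learned_tagger"` uses a lexicon-matching tagger over the
#'   utterance text at the same contract (a trained sequence tagger can be
#'   substituted behind it).
#' @return A list of class `kiddi_distillation_config`.
#' @export
distillation_config <- function(K = 2L, include_ss_edges = TRUE,
                                symptom_source = c("gold_annotations",
                                                   "learned_tagger")) {
  if (!is_count(K)) stopf("K must be a positive integer")
  symptom_source <- match.arg(symptom_source)
  structure(list(K = as.integer(K), include_ss_edges = isTRUE(include_ss_edges),
                 symptom_source = symptom_source),
            class = "kiddi_distillation_config")
}

#' Extract the symptom set of a dialogue
#'
#' Gold mode takes the union of patient-turn symptom annotations and, for
#' each "Affirmative" patient turn (a bare agreement), attributes the
#' symptom(s) named in the immediately preceding doctor inquiry. The result
#' is duplicate-free in order of first mention. Learned-tagger mode matches
#' the `lexicon` of symptom names against patient utterance text instead of
#' reading the slot annotations, resolving Affirmative turns against the
#' preceding doctor text.
#'
#' @param dialogue A `kiddi_dialogue`.
#' @param config A [distillation_config()].
#' @param lexicon Symptom-name vector for learned-tagger mode (usually the
#'   corpus `symptom_vocab`).
#' @return Character vector of symptom names in first-mention order.
#' @export
extract_symptoms <- function(dialogue, config = distillation_config(),
                             lexicon = NULL) {
  learned <- config$symptom_source == "learned_tagger"
  if (learned && is.null(lexicon))
    stopf("learned_tagger mode requires a symptom lexicon")
  found <- character()
  turns <- dialogue$turns
  turn_symptoms <- function(t) {
    if (!learned) return(t$symptoms)
    txt <- normalize_name(t$text)
    pos <- vapply(lexicon, function(s) {
      p <- regexpr(s, txt, fixed = TRUE)[[1]]
      if (p < 0) NA_real_ else p
    }, numeric(1))
    lexicon[order(pos, na.last = NA)]  # mention order within the utterance
  }
  for (i in seq_along(turns)) {
    t <- turns[[i]]
    if (t$speaker != "patient") next
    syms <- if (identical(t$intent, "Affirmative")) {
      if (i < 2L) {
        warning(sprintf(
          "dialogue '%s': Affirmative turn %d has no preceding doctor turn; nothing to resolve",
          dialogue$id, i))
        character()
      } else {
        turn_symptoms(turns[[i - 1L]])
      }
    } else {
      turn_symptoms(t)
    }
    found <- c(found, setdiff(syms, found))
  }
  found
}

#' Top-K diseases associated with a symptom
#'
#' Diseases linked to the symptom in the knowledge graph (positive
#' co-occurrence count), sorted by sf-idf edge weight descending with ties
#' broken lexicographically by disease name, truncated to `K`.
#'
#' @param kg A `kiddi_kg`.
#' @param s Symptom name.
#' @param K Number of diseases to keep.
#' @return Character vector of at most `K` disease names; empty (with a
#'   message) if the symptom is absent from the graph.
#' @export
top_k_diseases <- function(kg, s, K) {
  stopifnot(inherits(kg, "kiddi_kg"))
  if (!s %in% kg$symptoms || sum(kg$counts$n_sd[s, ]) == 0) {
    message(sprintf("symptom '%s' is not linked in the knowledge graph", s))
    return(character())
  }
  linked <- which(kg$counts$n_sd[s, ] > 0)
  w <- kg$sd_weights[s, linked]
  nm <- kg$diseases[linked]
  ord <- order(-w, nm, method = "radix")
  utils::head(nm[ord], K)
}

#' Build the joint graph for a conversation
#'
#' Nodes: one dialog node, the resolved symptoms present in the knowledge
#' graph, and the union of their per-symptom top-K diseases. Edges
#' (undirected): dialog-symptom for every symptom node, symptom-disease for
#' each retained top-K association, and (optionally) symptom-symptom edges
#' among included symptoms with positive co-occurrence. If no resolved
#' symptom is in the graph the result degenerates to the dialog node alone,
#' which the model handles via self-loops. Edge weights inform only the
#' top-K ranking; message passing consumes topology and node features.
#'
#' @param kg A `kiddi_kg`.
#' @param symptoms Character vector of resolved symptom names (ordered).
#' @param config A [distillation_config()].
#' @param dialog_feature Optional feature vector for the dialog node.
#' @param node_features Optional `function(name, type)` returning a feature
#'   vector for symptom/disease nodes; all widths must agree.
#' @return A list of class `kiddi_joint_graph`: `nodes` (data frame with
#'   `name`, `type`), `edges` (2-column integer matrix of undirected node
#'   index pairs), `features` (node x width matrix or `NULL`).
#' @export
build_joint_graph <- function(kg, symptoms, config = distillation_config(),
                              dialog_feature = NULL, node_features = NULL) {
  stopifnot(inherits(kg, "kiddi_kg"))
  observed <- rowSums(kg$counts$n_sd) > 0
  in_kg <- symptoms[symptoms %in% kg$symptoms[observed]]
  dis <- character()
  sd_pairs <- list()
  for (s in in_kg) {
    top <- top_k_diseases(kg, s, config$K)
    dis <- c(dis, setdiff(top, dis))
    for (d in top) sd_pairs[[length(sd_pairs) + 1L]] <- c(s, d)
  }
  node_names <- c("<dialog>", in_kg, dis)
  node_types <- c("dialog", rep("symptom", length(in_kg)),
                  rep("disease", length(dis)))
  idx <- function(nm) match(nm, node_names)

  edges <- matrix(integer(), ncol = 2)
  if (length(in_kg))
    edges <- rbind(edges, cbind(1L, idx(in_kg)))
  for (p in sd_pairs)
    edges <- rbind(edges, cbind(idx(p[1]), idx(p[2])))
  if (config$include_ss_edges && length(in_kg) > 1) {
    for (a in seq_along(in_kg)) for (b in seq_along(in_kg)) {
      if (a < b && kg$counts$n_ss[in_kg[a], in_kg[b]] > 0)
        edges <- rbind(edges, cbind(idx(in_kg[a]), idx(in_kg[b])))
    }
  }
  storage.mode(edges) <- "integer"

  features <- NULL
  if (!is.null(node_features) || !is.null(dialog_feature)) {
    if (is.null(dialog_feature) || is.null(node_features))
      stopf("dialog_feature and node_features must be supplied together")
    width <- length(dialog_feature)
    features <- matrix(0, length(node_names), width)
    features[1, ] <- dialog_feature
    for (k in seq_along(node_names)[-1]) {
      f <- node_features(node_names[k], node_types[k])
      if (length(f) != width)
        stopf("node feature width %d != dialog feature width %d", length(f), width)
      features[k, ] <- f
    }
  }

  structure(
    list(nodes = data.frame(name = node_names, type = node_types,
                            stringsAsFactors = FALSE),
         edges = edges, features = features),
    class = "kiddi_joint_graph"
  )
}

#' Adjacency matrix of a joint graph
#'
#' Undirected adjacency with self-loops on every node, the neighborhood
#' structure used by the graph-attention layers (a node's neighborhood is
#' every touching node plus itself, so even an isolated dialog node has a
#' defined update).
#'
#' @param jg A `kiddi_joint_graph`.
#' @return Logical node x node matrix.
#' @export
jg_adjacency <- function(jg) {
  n <- nrow(jg$nodes)
  A <- diag(n) > 0
  e <- jg$edges
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}
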