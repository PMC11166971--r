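# Synthetic dialogue corpora with planted symptom-disease structure.
#
# The generator emulates the structure of an annotated diagnosis
# conversation: the patient opens with a self-report naming a few chief
# complaints, the doctor inquires about further symptoms one per turn, and
# the patient confirms either by naming the symptom (intent "Symptom") or
# with a bare agreement (intent "Affirmative"). Disease profiles mix a
# shared pool of "common" symptoms (the cold/cough/fever confound: self
# reports built from them under-determine the disease) with
# disease-specific discriminative symptoms. The generator's bookkeeping
# (profiles and per-dialogue planted symptom sets) is the ground-truth
# oracle for the knowledge-graph and symptom-extraction stages.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the study conditions used throughout the package's
#' simulations: 10 diseases over an inventory of 40 symptoms, profiles of 5
#' symptoms of which 2 come from a 4-symptom common pool, self-reports of 2
#' symptoms drawn preferentially from the common pool, and 600 dialogues.
#'
#' @param n_diseases,n_symptoms Number of diseases and size of the symptom
#'   inventory.
#' @param symptoms_per_disease Profile size for each disease.
#' @param n_common_symptoms Size of the shared common-symptom pool; each
#'   profile includes `min(n_common_symptoms, floor(symptoms_per_disease/2),
#'   symptoms_per_disease - 1)` of them, so every disease keeps at least one
#'   discriminative symptom.
#' @param self_report_symptoms Number of symptoms named in the opening
#'   self-report, taken from the profile's common symptoms first.
#' @param p_affirmative Probability that a confirmed symptom is expressed as
#'   a bare agreement ("Affirmative") rather than named by the patient.
#' @param noise_rate Probability that a patient confirmation also volunteers
#'   one off-profile symptom.
#' @param n_dialogues Number of dialogues, balanced round-robin over
#'   diseases.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `kiddi_generator_config`.
#' @export
generator_config <- function(n_diseases = 10L, n_symptoms = 40L,
                             symptoms_per_disease = 5L,
                             n_common_symptoms = 4L,
                             self_report_symptoms = 2L,
                             p_affirmative = 0.3, noise_rate = 0.05,
                             n_dialogues = 600L, seed = 0L) {
  for (nm in c("n_diseases", "n_symptoms", "symptoms_per_disease",
               "n_common_symptoms", "self_report_symptoms", "n_dialogues")) {
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  }
  if (!is_prob(p_affirmative)) stopf("p_affirmative must be in [0, 1]")
  if (!is_prob(noise_rate)) stopf("noise_rate must be in [0, 1]")
  cfg <- structure(
    list(n_diseases = as.integer(n_diseases),
         n_symptoms = as.integer(n_symptoms),
         symptoms_per_disease = as.integer(symptoms_per_disease),
         n_common_symptoms = as.integer(n_common_symptoms),
         self_report_symptoms = as.integer(self_report_symptoms),
         p_affirmative = p_affirmative, noise_rate = noise_rate,
         n_dialogues = as.integer(n_dialogues), seed = as.integer(seed)),
    class = "kiddi_generator_config"
  )
  n_common_in_profile(cfg)  # errors on infeasible configs
  cfg
}

all_symptom_names <- function(config) sprintf("sym%03d", seq_len(config$n_symptoms))
all_disease_names <- function(config) sprintf("dis%02d", seq_len(config$n_diseases))

n_common_in_profile <- function(config) {
  cc <- min(config$n_common_symptoms,
            config$symptoms_per_disease %/% 2L,
            config$symptoms_per_disease - 1L)
  cc <- max(cc, 0L)
  specific <- config$symptoms_per_disease - cc
  demand <- config$n_common_symptoms + config$n_diseases * specific
  if (demand > config$n_symptoms)
    stopf(paste0("infeasible generator config: %d common + %d diseases x %d ",
                 "disease-specific symptoms exceed the %d-symptom inventory"),
          config$n_common_symptoms, config$n_diseases, specific,
          config$n_symptoms)
  cc
}

#' Sample disease profiles
#'
#' Draws the common-symptom pool, then assigns each disease a profile of
#' `symptoms_per_disease` symptoms: a subset of the common pool plus
#' disease-specific symptoms drawn without replacement across diseases, so
#' discriminative symptoms are disjoint between diseases.
#'
#' @param config A [generator_config()].
#' @return List of profiles, each a list with `disease`, `profile_symptoms`,
#'   `common_symptoms`.
#' @export
sample_profiles <- function(config) {
  stopifnot(inherits(config, "kiddi_generator_config"))
  set.seed(config$seed)
  symptoms <- all_symptom_names(config)
  diseases <- all_disease_names(config)
  cc <- n_common_in_profile(config)
  common_pool <- sample(symptoms, config$n_common_symptoms)
  specific_pool <- setdiff(symptoms, common_pool)
  lapply(seq_along(diseases), function(i) {
    common_d <- if (cc > 0) sample(common_pool, cc) else character()
    n_spec <- config$symptoms_per_disease - cc
    specific_d <- specific_pool[seq_len(n_spec)]
    specific_pool <<- specific_pool[-seq_len(n_spec)]
    list(disease = diseases[[i]],
         profile_symptoms = sort_c(c(common_d, specific_d)),
         common_symptoms = sort_c(common_d))
  })
}

phrase_list <- function(symptoms) paste(symptoms, collapse = " and ")

#' Generate one dialogue for a disease profile
#'
#' Draws from the current RNG stream (callers seed it; [generate_corpus()]
#' does so once per corpus). The first turn is the patient self-report
#' naming `self_report_symptoms` profile symptoms, preferring common ones;
#' each remaining profile symptom then becomes a doctor inquiry followed by
#' a patient confirmation, expressed as an "Affirmative" agreement with
#' probability `p_affirmative` and otherwise as a "Symptom" turn naming it.
#' With probability `noise_rate` a confirmation also volunteers one
#' off-profile symptom. The planted symptom set (profile plus injected
#' noise) is attached as attribute `"gold_symptoms"`.
#'
#' @param profile One element of [sample_profiles()].
#' @param config The [generator_config()].
#' @param id Dialogue identifier.
#' @return A `kiddi_dialogue`.
#' @export
generate_dialogue <- function(profile, config, id = "dlg0001") {
  stopifnot(inherits(config, "kiddi_generator_config"))
  prof <- profile$profile_symptoms
  off_profile <- setdiff(all_symptom_names(config), prof)

  n_sr <- min(config$self_report_symptoms, length(prof))
  common <- intersect(prof, profile$common_symptoms)
  specific <- setdiff(prof, common)
  pref <- c(common[sample.int(length(common))], specific[sample.int(length(specific))])
  sr <- pref[seq_len(n_sr)]

  turns <- list(utterance(
    "patient",
    sprintf("I have been having %s lately.", phrase_list(sr)),
    intent = "Symptom", symptoms = sr
  ))

  remaining <- setdiff(prof, sr)
  remaining <- remaining[sample.int(length(remaining))]
  gold <- prof
  for (s in remaining) {
    turns[[length(turns) + 1L]] <- utterance(
      "doctor", sprintf("Have you been experiencing %s?", s), symptoms = s)
    noisy <- length(off_profile) > 0 && stats::runif(1) < config$noise_rate
    affirm <- stats::runif(1) < config$p_affirmative
    if (noisy) {
      extra <- off_profile[sample.int(length(off_profile), 1L)]
      gold <- c(gold, extra)
      turns[[length(turns) + 1L]] <- utterance(
        "patient",
        sprintf("Yes, and I also noticed %s.", extra),
        intent = "Symptom", symptoms = c(s, extra))
    } else if (affirm) {
      turns[[length(turns) + 1L]] <- utterance(
        "patient", "Yes, exactly that.", intent = "Affirmative")
    } else {
      turns[[length(turns) + 1L]] <- utterance(
        "patient", sprintf("Yes, I do have %s.", s),
        intent = "Symptom", symptoms = s)
    }
  }
  out <- dialogue(id, profile$disease, turns)
  attr(out, "gold_symptoms") <- sort_c(gold)
  out
}

#' Generate a full synthetic corpus with ground truth
#'
#' Dialogues are assigned to diseases round-robin, so per-disease counts
#' differ by at most one. The returned corpus carries the full symptom and
#' disease inventories as vocabularies (not only the mentioned subset), and
#' the truth component records the sampled profiles and each dialogue's
#' planted symptom set for oracle checks.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a `kiddi_corpus`) and `truth` (list with
#'   `profiles` and `dialogue_symptoms`, a named list keyed by dialogue id).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "kiddi_generator_config"))
  profiles <- sample_profiles(config)  # seeds the stream
  dialogues <- vector("list", config$n_dialogues)
  gold <- vector("list", config$n_dialogues)
  ids <- sprintf("dlg%04d", seq_len(config$n_dialogues))
  for (i in seq_len(config$n_dialogues)) {
    p <- profiles[[((i - 1L) %% config$n_diseases) + 1L]]
    d <- generate_dialogue(p, config, id = ids[[i]])
    gold[[i]] <- attr(d, "gold_symptoms")
    attr(d, "gold_symptoms") <- NULL
    dialogues[[i]] <- d
  }
  names(gold) <- ids
  list(
    corpus = corpus(dialogues,
                    symptom_vocab = all_symptom_names(config),
                    disease_vocab = all_disease_names(config)),
    truth = list(profiles = profiles, dialogue_symptoms = gold)
  )
}
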