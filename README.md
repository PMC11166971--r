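# kiddi — knowledge-infused disease diagnosis from doctor–patient dialogues

`kiddi` identifies a patient's disease from an annotated diagnosis
conversation. Diagnosis dialogues have a fixed shape — a patient
*self-report* stating chief complaints, then doctor inquiries eliciting
further symptoms — and the self-report alone under-determines the disease
because patients volunteer common symptoms (cold, cough, fever) shared by
many conditions. The package therefore fuses two evidence channels:

1. **Text channel** — encodings *S* (self-report) and *C* (full dialogue)
   from a pluggable utterance encoder behind a serialization contract with
   sentinel tokens (`[sr_start]`/`[sr_end]`, `[pat]`/`[doc]`).
2. **Knowledge channel** — a symptom–symptom–disease graph whose
   symptom–disease edges are weighted by *symptom frequency–inverse disease
   frequency*:

   e(s, d) = sf(s, d) · idf(s),  sf(s, d) = n_sd / Σₖ n_kd,
   idf(s) = log( |D| / #{d : n_sd > 0} ),

   with row-normalized symptom–symptom co-occurrence edges. Per
   conversation, discourse-aware selective filtering resolves the mentioned
   symptom set (attributing bare "Affirmative" agreements to the preceding
   doctor inquiry), keeps each symptom's top-K diseases by edge weight, and
   attaches a dialog node connected to all symptom nodes. A graph attention
   network (2 layers, 3 concatenated heads) embeds this joint graph and
   mean-pools it to a graph embedding *s*.

Additive attention with *s* as query weighs *S* against *C*
(eᵢ = vᵀ tanh(W₁hᵢ + W₂s)), and a softmax layer over [s; context] predicts
the disease, trained with categorical cross-entropy and Adam. Forward and
backward passes are written out explicitly (no autodiff framework) and the
gradients are verified against finite differences in the test suite.

A synthetic corpus generator plants recoverable symptom–disease structure
(disease profiles mixing a shared common-symptom pool with disease-specific
symptoms, templated turns, Affirmative confirmations, off-profile noise), so
every stage — counting, filtering, message passing, training — is testable
against ground truth without any downloads.

## Worked example

```r
library(kiddi)

gen <- generate_corpus(generator_config(n_diseases = 5, n_symptoms = 20,
                                        n_dialogues = 100, seed = 0))
kg <- build_graph(gen$corpus)
splits <- split_corpus(gen$corpus, seed = 0)

cfg <- model_config(d2 = 32, d1 = 24, d3 = 8, max_sequence_length = 256)
ck <- train(splits, kg, train_config(epochs = 6, learning_rate = 3e-3, seed = 0),
            model_config = cfg)

report <- evaluate(ck, splits$test, kg)
print(report)

d <- splits$test$dialogues[[1]]
out <- predict_dialogue(ck, d, kg)
cat(sprintf("dialogue %s: true %s, predicted %s (p = %.3f)\n",
            d$id, d$disease, out$prediction, max(out$probs)))
cat(sprintf("attention: self-report %.2f, dialogue %.2f\n",
            out$alpha[1], out$alpha[2]))
```

prints

```
<kiddi_eval_report> n=20 accuracy=1.0000 macro_f1=1.0000 jaccard=1.0000
  top-k coverage: top1=1.0000 top3=1.0000 top5=1.0000
dialogue dlg0009: true dis04, predicted dis04 (p = 0.592)
attention: self-report 0.51, dialogue 0.49
```

The report carries accuracy, macro-F1, mean Jaccard similarity, top-k
coverage (k = 1, 3, 5), per-class precision/recall, the confusion matrix,
and per-example predictions with the attention weights, so one can see
per case whether the model leaned on the self-report or on the doctor's
investigation. `run_ablation()` retrains the same parts in eight wirings
(self-report only, dialogue only, knowledge only, text + flat knowledge
mean, text + graph knowledge, full model) under shared splits and seeds;
`train_hierarchical()` adds a two-level department-then-disease classifier.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/kiddi.R synth    --config cfg.json --out corpus.json
Rscript inst/cli/kiddi.R build-kg --corpus corpus.json --out kg.json
Rscript inst/cli/kiddi.R train    --corpus corpus.json --kg kg.json --out ckpt.rds
Rscript inst/cli/kiddi.R eval     --checkpoint ckpt.rds --corpus corpus.json \
                                  --kg kg.json --out report.json
```

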