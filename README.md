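# medkgqa

Knowledge-graph-augmented, multi-task medical question answering in R.

Online health platforms hold large repositories of patient questions and
physician answers. Answering a new question well means three things at once:
picking the best of several retrieved candidate answers, recommending the
physician best placed to answer, and generating a response grounded in
domain knowledge. `medkgqa` implements a hybrid retrieve-rank-generate
architecture for this problem, aimed at researchers studying clinical QA
systems who want a fully inspectable, dependency-light reference
implementation that runs end to end on a single CPU.

## The model

For a question *q* with K retrieved candidate answers and their doctors:

* **Retrieval** classifies *q* into a disease category by surface-form
  pattern matching against a typed knowledge graph, falling back to an
  embedding soft match `C = argmax_j max_i cos(e^q_i, e^v_j)`, then returns
  the answers of the K most cosine-similar same-category questions.
* **KRGAT** encodes the question's one-hop knowledge subgraph with
  relation-aware graph attention,
  `β_ij = LeakyReLU(aᵀ[W_k v_i ‖ W_k v_j ‖ W_r e^r_ij])`,
  `v_i' = ELU(Σ_j α_ij (v_j + W_r e^r_ij))` — attention that sees the edge
  *type*, not just the endpoints.
* **Knowledge-aware attention** re-encodes question, answers and doctor
  profiles with self- and interaction attention whose scores carry a
  relation term from a token-pair knowledge association matrix,
  `s_ij = vᵀ tanh(q_i + k_j + W^r m_ij)`; a learned gate fuses the two
  views per position: `H = g ⊙ H_self + (1−g) ⊙ H_inter`.
* **Output heads**: a copy-gated decoder
  `p_final = g_gen · p_gen + (1−g_gen) · p_copy` mixing free generation
  (conditioned on the question and subgraph context) with copying from the
  top-ranked candidate; softmax ranking heads for candidate answers and
  doctors.
* **Multi-task loss** with trainable homoscedastic-uncertainty weights:
  `L = L_gen/(2α²) + L_rank/(2β²) + L_doc/(2γ²) + log α + log β + log γ`.

Real clinical corpora are private, so the package ships a seeded synthetic
generator producing a knowledge graph, doctor profiles and QA records with
the statistical structure the architecture assumes (entity-marked
questions, expert gold answers discussing graph-linked concepts,
off-category distractors), plus the standard automatic metrics: embedding
average, DISTINCT-n, medical entity density and mean reciprocal rank. See
`vignettes/medkgqa-methods.Rmd` for the full methods account.

## Worked example

```r
library(medkgqa)

kg <- generate_knowledge_graph(n_categories = 4, entities_per_category = 5, seed = 7)
kg
#> <med_kg> 20 entities, 26 relations, 4 categories, 9 relation types

corpus <- generate_corpus(kg, n_records = 200, k = 4, seed = 7)
r <- corpus$records[[1]]
paste(r$question, collapse = " ")
#> "brain_tumor_t02 brain_tumor_t03 is recover advice recently brain_tumor_t03 brain_tumor_t02 is"
classify_by_pattern(r$question, kg)
#> [1] "brain_tumor"

cfg <- toy_profile()   # dimension-32 single-CPU profile
cfg$seed <- 1
res <- run_pipeline(cfg, out_dir = file.path(tempdir(), "demo_run"))
str(res$metrics)
#> List of 9
#>  $ embedding_average        : num 0.404
#>  $ distinct_1               : num 0.152
#>  $ distinct_2               : num 0.676
#>  $ entity_density           : num 0.23
#>  $ distractor_entity_density: num 0.0837
#>  $ answer_mrr               : num 0.894
#>  $ doctor_mrr               : num 0.933
#>  $ retrieval_accuracy       : num 1
#>  $ n_test                   : int 40
```

Reading the numbers: on the held-out test split the ranking head places the
gold answer at mean reciprocal rank 0.89 and the gold doctor at 0.93
(1.0 would be "always first"); generated answers cover knowledge-graph
entities at density 0.23, almost three times the 0.08 baseline of the
off-category distractor answers, i.e. generation stays on medical topic;
retrieval classifies every test question into the right disease category.
`run_pipeline()` also writes the corpus, graph tables, embeddings, training
history, generations and a deterministic manifest under `out_dir`, and
reruns with the same config and seed reproduce the manifest byte for byte.

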