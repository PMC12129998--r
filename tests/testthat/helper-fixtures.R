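# Hand-built toy knowledge graph: two categories, one multi-token surface
# form, a clinical-symptom edge between "headache" and the brain-tumor hub.
toy_kg <- function() {
  entities <- data.frame(
    entity_id = c("brain_tumor", "headache", "ct_scan", "craniotomy", "stroke", "aphasia"),
    category = c(
      "brain_tumor", "brain_tumor", "brain_tumor", "brain_tumor",
      "stroke", "stroke"
    ),
    stringsAsFactors = FALSE
  )
  entities$surface_forms <- list(
    c("brain_tumor", "persistent headache tumor"),
    "headache", "ct_scan", "craniotomy", "stroke", "aphasia"
  )
  relations <- data.frame(
    head = c("brain_tumor", "brain_tumor", "brain_tumor", "stroke"),
    rtype = c("clinical_symptom", "examination", "treatment", "clinical_symptom"),
    tail = c("headache", "ct_scan", "craniotomy", "aphasia"),
    stringsAsFactors = FALSE
  )
  med_kg(entities, relations, c("brain_tumor", "stroke"), default_relation_vocab())
}

# Small deterministic random encoding matrix
rand_mat <- function(n, d, seed) {
  withr::with_seed(seed, matrix(rnorm(n * d), n, d))
}

tiny_corpus <- function(n = 24, seed = 5) {
  kg <- generate_knowledge_graph(4, 5, seed = seed)
  corpus <- generate_corpus(kg, n, 4, seed = seed)
  list(kg = kg, records = corpus$records, profiles = corpus$profiles)
}
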