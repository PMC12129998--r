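#' Typed medical knowledge graph
#'
#' A `med_kg` object holds entity nodes labelled with a disease category,
#' typed edges drawn from a closed relation vocabulary, and the category set.
#' Entities carry one or more surface forms (token strings, possibly
#' multi-token); the surface-form lexicon is the authority for entity
#' matching throughout the package (question classification, subgraph
#' extraction, association matrices, entity density).
#'
#' @param entities data.frame with columns `entity_id`, `category` and a
#'   list-column `surface_forms` of character vectors.
#' @param relations data.frame with columns `head`, `rtype`, `tail`.
#' @param categories character vector of disease-category labels.
#' @param relation_vocab closed vocabulary of relation labels.
#' @return An object of class `med_kg`.
#' @export
med_kg <- function(entities, relations, categories, relation_vocab) {
  stopifnot(is.data.frame(entities), is.data.frame(relations))
  if (nrow(entities) > 0 && anyDuplicated(entities$entity_id)) {
    stop_arg("duplicate entity ids in knowledge graph")
  }
  if (any(lengths(entities$surface_forms) == 0L)) {
    stop_arg("every entity needs at least one surface form")
  }
  if (!all(entities$category %in% categories)) {
    stop_arg("entity category outside the declared category set")
  }
  if (nrow(relations) > 0) {
    missing <- setdiff(c(relations$head, relations$tail), entities$entity_id)
    if (length(missing)) {
      stop_arg("dangling relation endpoint(s): %s", paste(missing, collapse = ", "))
    }
    bad <- setdiff(relations$rtype, relation_vocab)
    if (length(bad)) {
      stop_arg("relation type(s) outside vocabulary: %s", paste(bad, collapse = ", "))
    }
  }
  for (cat in categories) {
    if (!any(entities$category == cat)) {
      stop_arg("category '%s' has no entity", cat)
    }
  }
  structure(
    list(
      entities = entities, relations = relations,
      categories = categories, relation_vocab = relation_vocab
    ),
    class = "med_kg"
  )
}

#' @export
print.med_kg <- function(x, ...) {
  cat(sprintf(
    "<med_kg> %d entities, %d relations, %d categories, %d relation types\n",
    nrow(x$entities), nrow(x$relations), length(x$categories),
    length(x$relation_vocab)
  ))
  invisible(x)
}

#' Default relation vocabulary
#'
#' Nine relation categories mirroring the closed vocabulary of a clinical
#' knowledge graph (terminology links, symptomatology, anatomy, work-up and
#' therapy).
#'
#' @return Character vector of nine relation labels.
#' @export
default_relation_vocab <- function() {
  c(
    "umls", "icd10", "clinical_symptom", "site_of_onset", "examination",
    "english_name", "department", "cause_of_disease", "treatment"
  )
}

default_category_names <- function(n) {
  base <- c(
    "brain_tumor", "cerebral_hemorrhage", "epilepsy", "spinal_injury",
    "hydrocephalus", "aneurysm", "trigeminal_neuralgia", "parkinsonism"
  )
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("condition_%02d", seq_len(n - length(base))))
}

#' Generate a synthetic typed knowledge graph
#'
#' Each disease category gets one hub entity carrying the category's
#' canonical surface form plus `entities_per_category - 1` member entities,
#' all joined to the hub by typed edges (a star), with occasional extra
#' member-member edges. Every entity is therefore reachable from its
#' category hub within one hop. Deterministic for a fixed seed.
#'
#' @param n_categories number of disease categories (>= 1).
#' @param entities_per_category entities per category (>= 1), hub included.
#' @param relation_vocab closed relation vocabulary; defaults to the nine
#'   standard clinical relation types.
#' @param seed integer seed.
#' @return A [med_kg] object.
#' @export
generate_knowledge_graph <- function(n_categories, entities_per_category,
                                     relation_vocab = default_relation_vocab(),
                                     seed = 1) {
  if (n_categories < 1 || entities_per_category < 1) {
    stop_arg("n_categories and entities_per_category must be >= 1")
  }
  if (length(relation_vocab) == 0L) stop_arg("relation vocabulary is empty")
  cats <- default_category_names(n_categories)
  with_seed(derive_seed(seed, "kg"), {
    ids <- character(0); cat_of <- character(0); forms <- list()
    heads <- character(0); tails <- character(0); rtypes <- character(0)
    for (cat in cats) {
      hub <- cat
      ids <- c(ids, hub); cat_of <- c(cat_of, cat)
      forms <- c(forms, list(c(cat, paste(cat, "disease"))))
      if (entities_per_category > 1) {
        for (j in seq_len(entities_per_category - 1)) {
          eid <- sprintf("%s_e%02d", cat, j)
          ids <- c(ids, eid); cat_of <- c(cat_of, cat)
          forms <- c(forms, list(sprintf("%s_t%02d", cat, j)))
          heads <- c(heads, hub); tails <- c(tails, eid)
          rtypes <- c(rtypes, sample(relation_vocab, 1))
        }
        # extra intra-category edges (kept within the category so the
        # one-hop-from-hub property is preserved) give every condition a
        # distinctive neighbourhood of related concepts
        members <- sprintf("%s_e%02d", cat, seq_len(entities_per_category - 1))
        if (length(members) >= 2) {
          for (m in members) {
            if (stats::runif(1) < 0.6) {
              other <- sample(setdiff(members, m), 1)
              heads <- c(heads, m); tails <- c(tails, other)
              rtypes <- c(rtypes, sample(relation_vocab, 1))
            }
          }
        }
      }
    }
    entities <- data.frame(
      entity_id = ids, category = cat_of, stringsAsFactors = FALSE
    )
    entities$surface_forms <- forms
    relations <- data.frame(
      head = heads, rtype = rtypes, tail = tails, stringsAsFactors = FALSE
    )
    med_kg(entities, relations, cats, relation_vocab)
  })
}

# ---- Surface-form matching -------------------------------------------------

# Table of (entity_id, category, form, n_tokens) over all declared forms.
kg_form_table <- function(kg) {
  n <- lengths(kg$entities$surface_forms)
  data.frame(
    entity_id = rep(kg$entities$entity_id, n),
    category = rep(kg$entities$category, n),
    form = unlist(kg$entities$surface_forms),
    stringsAsFactors = FALSE
  )
}

# All matches of entity surface forms inside a token sequence.
# Returns data.frame(entity_id, category, form, start, len).
kg_match_forms <- function(tokens, kg) {
  ft <- kg_form_table(kg)
  ft$len <- vapply(strsplit(ft$form, " ", fixed = TRUE), length, integer(1))
  out <- list()
  for (r in seq_len(nrow(ft))) {
    ftoks <- strsplit(ft$form[r], " ", fixed = TRUE)[[1]]
    L <- length(ftoks)
    if (L > length(tokens)) next
    for (s in seq_len(length(tokens) - L + 1L)) {
      if (all(tokens[s:(s + L - 1L)] == ftoks)) {
        out[[length(out) + 1L]] <- data.frame(
          entity_id = ft$entity_id[r], category = ft$category[r],
          form = ft$form[r], start = s, len = L, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      entity_id = character(0), category = character(0), form = character(0),
      start = integer(0), len = integer(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}

# token -> entity_id lookup restricted to single-token surface forms
# (used by association matrices, which are defined per token pair).
kg_token_entity <- function(kg) {
  ft <- kg_form_table(kg)
  ft <- ft[!grepl(" ", ft$form, fixed = TRUE), , drop = FALSE]
  stats::setNames(ft$entity_id, ft$form)
}

# Undirected edge lookup: returns rtype of the first stored edge joining
# two entities (either direction), or NA.
kg_edge_between <- function(kg, a, b) {
  rel <- kg$relations
  hit <- which((rel$head == a & rel$tail == b) | (rel$head == b & rel$tail == a))
  if (length(hit)) rel$rtype[hit[1]] else NA_character_
}

# ---- Node/edge table I/O ---------------------------------------------------

#' Write / read a knowledge graph as tab-separated node and edge tables
#'
#' `path` is a file prefix: `<path>.nodes.tsv` holds
#' `entity_id  category  surface_forms` (forms pipe-delimited) and
#' `<path>.edges.tsv` holds `head  rtype  tail`. UTF-8, one record per line.
#'
#' @param kg a [med_kg].
#' @param path file prefix.
#' @return `write_kg` returns `path` invisibly; `read_kg` returns a [med_kg].
#' @export
write_kg <- function(kg, path) {
  nodes <- data.frame(
    entity_id = kg$entities$entity_id,
    category = kg$entities$category,
    surface_forms = vapply(kg$entities$surface_forms, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, paste0(path, ".nodes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.table(kg$relations, paste0(path, ".edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  writeLines(c(kg$categories), paste0(path, ".categories.txt"), useBytes = TRUE)
  writeLines(c(kg$relation_vocab), paste0(path, ".relations.txt"), useBytes = TRUE)
  invisible(path)
}

#' @rdname write_kg
#' @export
read_kg <- function(path) {
  nodes_file <- paste0(path, ".nodes.tsv")
  edges_file <- paste0(path, ".edges.tsv")
  if (!file.exists(nodes_file)) stop_arg("missing node table: %s", nodes_file)
  nodes <- utils::read.table(nodes_file,
    sep = "\t", header = TRUE,
    colClasses = "character", quote = "", fileEncoding = "UTF-8"
  )
  need <- c("entity_id", "category", "surface_forms")
  if (!all(need %in% names(nodes))) {
    stop_arg("node table must have columns %s", paste(need, collapse = ", "))
  }
  edges <- if (file.exists(edges_file)) {
    utils::read.table(edges_file,
      sep = "\t", header = TRUE,
      colClasses = "character", quote = "", fileEncoding = "UTF-8"
    )
  } else {
    data.frame(head = character(0), rtype = character(0), tail = character(0))
  }
  miss <- setdiff(c(edges$head, edges$tail), nodes$entity_id)
  if (length(miss)) {
    stop_arg("edge references missing node(s): %s", paste(unique(miss), collapse = ", "))
  }
  cats_file <- paste0(path, ".categories.txt")
  rels_file <- paste0(path, ".relations.txt")
  categories <- if (file.exists(cats_file)) readLines(cats_file, encoding = "UTF-8") else unique(nodes$category)
  relation_vocab <- if (file.exists(rels_file)) readLines(rels_file, encoding = "UTF-8") else unique(edges$rtype)
  entities <- data.frame(
    entity_id = nodes$entity_id, category = nodes$category,
    stringsAsFactors = FALSE
  )
  entities$surface_forms <- strsplit(nodes$surface_forms, "|", fixed = TRUE)
  med_kg(entities, edges, categories, relation_vocab)
}
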