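#' Default run configuration
#'
#' Every documented default of the architecture in one nested list. The
#' production-scale values are `encoder$dim = 768`, learning rate `1e-5`
#' with 3000 warmup steps, beam 5 and top-k 64, `K = 4` candidates and a
#' 2-layer KRGAT; [toy_profile()] overrides the scale-sensitive ones for
#' single-CPU runs.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    corpus = list(
      n_categories = 4L, entities_per_category = 5L, n_records = 200L,
      k = 4L, seed = 1L
    ),
    encoder = list(name = "toy", dim = 768L),
    krgat = list(layers = 2L, leaky_slope = 0.2),
    attention = list(score_form = "additive"),
    gate = list(per_channel = FALSE),
    model = list(use_kg = TRUE, use_doctor = TRUE),
    embeddings = list(dim = 50L),
    train = list(
      epochs = 30L, batch_size = 20L, lr = 1e-5, warmup = 3000L,
      weight_decay = 0.1, graph_dropout = 0.25, loss_scale = c(1, 1, 1)
    ),
    decode = list(
      beam = 5L, topk = 64L, max_len = 30L, min_len = 8L, rep_penalty = 3,
      sample = TRUE
    ),
    seed = 1L
  )
}

#' Single-CPU test profile
#'
#' The shipped demo configuration: toy encoder at dimension 32 and a
#' learning-rate/warmup pair suited to the tiny trainable head (the
#' production rate of 1e-5 is tuned for full-scale pretrained stacks and
#' barely moves a head this small within the demo budget).
#'
#' @return Nested configuration list.
#' @export
toy_profile <- function() {
  cfg <- default_config()
  cfg$encoder$dim <- 32L
  cfg$train$lr <- 0.1
  cfg$train$warmup <- 30L
  cfg$train$epochs <- 40L
  cfg
}

config_schema <- function() {
  # leaf -> checker
  list(
    corpus = list(
      n_categories = function(x) is.numeric(x) && x >= 1,
      entities_per_category = function(x) is.numeric(x) && x >= 1,
      n_records = function(x) is.numeric(x) && x >= 1,
      k = function(x) is.numeric(x) && x >= 1,
      seed = is.numeric
    ),
    encoder = list(
      name = function(x) x %in% c("toy", "pretrained"),
      dim = function(x) is.numeric(x) && x >= 2
    ),
    krgat = list(
      layers = function(x) is.numeric(x) && x >= 1,
      leaky_slope = function(x) is.numeric(x) && x >= 0
    ),
    attention = list(
      score_form = function(x) x %in% c("additive", "concat_dot")
    ),
    gate = list(per_channel = is.logical),
    model = list(use_kg = is.logical, use_doctor = is.logical),
    embeddings = list(dim = function(x) is.numeric(x) && x >= 2),
    train = list(
      epochs = function(x) is.numeric(x) && x >= 1,
      batch_size = function(x) is.numeric(x) && x >= 1,
      lr = function(x) is.numeric(x) && x > 0,
      warmup = function(x) is.numeric(x) && x >= 0,
      weight_decay = function(x) is.numeric(x) && x >= 0,
      graph_dropout = function(x) is.numeric(x) && x >= 0 && x < 1,
      loss_scale = function(x) is.numeric(x) && length(x) == 3 && all(x > 0)
    ),
    decode = list(
      beam = function(x) is.numeric(x) && x >= 1,
      topk = function(x) is.numeric(x) && x >= 1,
      max_len = function(x) is.numeric(x) && x >= 1,
      min_len = function(x) is.numeric(x) && x >= 0,
      rep_penalty = function(x) is.numeric(x) && x >= 1,
      sample = is.logical
    ),
    seed = is.numeric
  )
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, type-checks
#' every known key and fills defaults for absent ones.
#'
#' @param x path to a YAML configuration file, or a nested list.
#' @param base defaults used to fill missing keys ([toy_profile()] by
#'   default, the shipped demo profile).
#' @return Normalized configuration list.
#' @export
validate_config <- function(x = list(), base = toy_profile()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop_arg("configuration must be a mapping")
  schema <- config_schema()
  bad <- character(0)
  out <- base
  for (top in names(cfg)) {
    if (!top %in% names(schema)) {
      bad <- c(bad, top)
      next
    }
    if (is.function(schema[[top]])) {
      if (!isTRUE(schema[[top]](cfg[[top]]))) bad <- c(bad, top)
      out[[top]] <- cfg[[top]]
    } else {
      for (leaf in names(cfg[[top]])) {
        if (!leaf %in% names(schema[[top]])) {
          bad <- c(bad, paste(top, leaf, sep = "."))
          next
        }
        if (!isTRUE(schema[[top]][[leaf]](cfg[[top]][[leaf]]))) {
          bad <- c(bad, paste0(top, ".", leaf, " (invalid value)"))
        } else {
          out[[top]][[leaf]] <- cfg[[top]][[leaf]]
        }
      }
    }
  }
  if (length(bad)) {
    stop_arg("invalid configuration key(s): %s", paste(bad, collapse = ", "))
  }
  for (nm in c("n_categories", "entities_per_category", "n_records", "k")) {
    out$corpus[[nm]] <- as.integer(out$corpus[[nm]])
  }
  if (out$corpus$k > out$corpus$n_categories) {
    stop_arg("corpus.k (%d) exceeds corpus.n_categories (%d)", out$corpus$k, out$corpus$n_categories)
  }
  out
}
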