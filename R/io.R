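# Model file format (JSON), the seeded random-network fixture generator,
# and a small content hash for provenance logging.

MODEL_SCHEMA_VERSION <- "1.0"

#' Write a model to the JSON model document format
#'
#' Canonical serialization: nodes in declaration order, edges sorted by
#' (target, source), full-precision numbers. A write -> read -> write round
#' trip is byte-identical and preserves all weights and thresholds exactly.
#'
#' @param model A `bn_model`.
#' @param path Output file path.
#' @param metadata Optional named list of free-form provenance fields.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, metadata = NULL) {
  stopifnot(inherits(model, "bn_model"))
  e <- model$edges
  if (nrow(e) > 0L) e <- e[order(e$target, e$source), , drop = FALSE]
  rownames(e) <- NULL
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    variant = model$variant,
    nodes = model$nodes,
    edges = e,
    clamped_off = as.list(model$clamped_off)
  )
  if (!is.null(metadata)) doc$metadata <- metadata
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a model from the JSON model document format
#'
#' @param path File path of a document written by [write_model()].
#' @return A `bn_model`.
#' @export
read_model <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop(sprintf("cannot parse model document '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  for (field in c("schema_version", "variant", "nodes")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("model document '%s': missing field '%s'", path, field),
           call. = FALSE)
    }
  }
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("unsupported schema_version '%s' (supported: %s)",
                 doc$schema_version, MODEL_SCHEMA_VERSION), call. = FALSE)
  }
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  edges <- if (!is.null(doc$edges) && length(doc$edges)) {
    as.data.frame(doc$edges, stringsAsFactors = FALSE)
  } else NULL
  model <- bn_model(nodes, edges, variant = doc$variant,
                    clamped_off = unlist(doc$clamped_off))
  issues <- validate_model(model)
  if (length(issues)) {
    stop(sprintf("model document '%s' is invalid:\n  %s", path,
                 paste(issues, collapse = "\n  ")), call. = FALSE)
  }
  model
}

#' Generate a seeded random Boolean threshold network
#'
#' Fixture generator for property-based testing: every ordered pair of
#' distinct nodes receives an edge with probability `edge_density`, with a
#' weight drawn uniformly from `weight_set`; thresholds are drawn uniformly
#' from `threshold_set`; self-couplings from `self_coupling_set`. The RNG
#' state of the caller is left untouched, and a given parameter set with the
#' same seed always produces the identical network.
#'
#' @param n_nodes Number of nodes (1..16).
#' @param edge_density Probability of each directed edge.
#' @param weight_set Candidate edge weights.
#' @param threshold_set Candidate thresholds.
#' @param self_coupling_set Candidate self-couplings.
#' @param seed Integer seed (required, for reproducibility).
#' @param variant Update-rule variant of the generated model.
#' @return A `bn_model` whose nodes are named `n01`, `n02`, ... with
#'   `initial_on` drawn at random (at least one node ON).
#' @export
generate_random_network <- function(n_nodes, edge_density = 0.3,
                                    weight_set = c(-1, 1),
                                    threshold_set = c(-0.5, 0, 0.5),
                                    self_coupling_set = c(-1, 0, 1),
                                    seed,
                                    variant = c("simplified",
                                                "threshold_memory")) {
  variant <- match.arg(variant)
  if (n_nodes < 1 || n_nodes > 16) stop("n_nodes must be in 1..16")
  if (missing(seed)) stop("a seed is required for reproducible fixtures")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  nm <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(
    name = nm,
    threshold = sample(threshold_set, n_nodes, replace = TRUE),
    self_coupling = sample(self_coupling_set, n_nodes, replace = TRUE),
    initial_on = stats::runif(n_nodes) < 0.5,
    stringsAsFactors = FALSE
  )
  if (!any(nodes$initial_on)) nodes$initial_on[1L] <- TRUE
  pairs <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < edge_density
  edges <- if (any(keep)) {
    data.frame(source = pairs$source[keep], target = pairs$target[keep],
               weight = sample(weight_set, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  bn_model(nodes, edges, variant = variant)
}

#' Content hash of a model (polynomial hash of its canonical serialization)
#'
#' Stable across sessions and platforms; used by the CLI to log which model
#' produced an output file.
#'
#' @param model A `bn_model`.
#' @return Hex string.
#' @export
model_hash <- function(model) {
  e <- model$edges
  if (nrow(e) > 0L) e <- e[order(e$target, e$source), , drop = FALSE]
  canon <- paste(
    model$variant,
    paste(sprintf("%s|%.17g|%.17g|%d", model$nodes$name,
                  model$nodes$threshold, model$nodes$self_coupling,
                  as.integer(model$nodes$initial_on)), collapse = ";"),
    paste(sprintf("%s>%s|%.17g", e$source, e$target, e$weight),
          collapse = ";"),
    paste(sort(model$clamped_off), collapse = ";"),
    sep = "\n"
  )
  bytes <- utf8ToInt(canon)
  # Polynomial rolling hash mod the Mersenne prime 2^31-1; exact in doubles.
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
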