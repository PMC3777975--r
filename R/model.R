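# Canonical node order of the fission yeast cell cycle network.
POMBE_NODES <- c(
  "Start",
  "Cdc2/Cig1", "Cdc2/Cig2", "Cdc2/Puc1",
  "Cdc2/Cdc13", "Cdc2_Tyr15",
  "Ste9", "Rum1", "Slp1", "Wee1/Mik1", "Cdc25", "PP"
)

# Short aliases accepted wherever a node name is expected (strain encodings,
# the CLI, perturbation targets).
POMBE_ALIASES <- c(
  Cig1 = "Cdc2/Cig1", Cig2 = "Cdc2/Cig2", Puc1 = "Cdc2/Puc1",
  Cdc13 = "Cdc2/Cdc13", Tyr15 = "Cdc2_Tyr15", Wee1 = "Wee1/Mik1",
  Mik1 = "Wee1/Mik1"
)

#' Construct a Boolean threshold-network model
#'
#' A model couples a node table (name, activation threshold, self-coupling,
#' membership in the standard initial condition) with a signed, weighted
#' interaction matrix and an update-rule variant. Node `i` receives the input
#' `sum_j a_ij * S_j(t)` which is compared against its threshold `theta_i`;
#' see [successor()] for the two update rules.
#'
#' @param nodes Either a character vector of node names or a data frame with
#'   columns `name` and optionally `threshold` (default 0), `self_coupling`
#'   (default 0) and `initial_on` (default `FALSE`).
#' @param edges `NULL` or a data frame with columns `source`, `target`,
#'   `weight` describing the off-diagonal interactions (absent pair = weight
#'   0). Self-couplings belong in the node table, not here.
#' @param variant `"simplified"` (next state is 1 iff input exceeds the
#'   threshold) or `"threshold_memory"` (ties retain the current state;
#'   self-degradation enters the input sum as `a_ii = -1`).
#' @param clamped_off Character vector of node names forced to 0 from the
#'   first update onward (knocked-out nodes).
#' @return An object of class `bn_model`.
#' @seealso [build_pombe_model()], [validate_model()], [successor()]
#' @export
bn_model <- function(nodes, edges = NULL,
                     variant = c("simplified", "threshold_memory"),
                     clamped_off = character()) {
  variant <- match.arg(variant)
  if (is.character(nodes)) {
    nodes <- data.frame(name = nodes, stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) stop("a model needs at least one node")
  if (is.null(nodes$name)) stop("node table needs a 'name' column")
  nodes$name <- as.character(nodes$name)
  if (is.null(nodes$threshold)) nodes$threshold <- 0
  if (is.null(nodes$self_coupling)) nodes$self_coupling <- 0
  if (is.null(nodes$initial_on)) nodes$initial_on <- FALSE
  nodes$threshold <- as.numeric(nodes$threshold)
  nodes$self_coupling <- as.numeric(nodes$self_coupling)
  nodes$initial_on <- as.logical(nodes$initial_on)
  nodes <- nodes[, c("name", "threshold", "self_coupling", "initial_on")]

  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L &&
      !all(c("source", "target", "weight") %in% names(edges))) {
    stop("edge table needs columns source, target, weight")
  }
  edges <- edges[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)

  model <- structure(
    list(nodes = nodes, edges = edges, variant = variant,
         clamped_off = unique(as.character(clamped_off))),
    class = "bn_model"
  )
  model <- rebuild_matrix(model)
  model
}

# Rebuild the dense interaction matrix W (rows = targets, cols = sources)
# from the node/edge tables. Tolerates invalid edges (validate_model reports
# them) by dropping them from W.
rebuild_matrix <- function(model) {
  nm <- model$nodes$name
  n <- length(nm)
  W <- matrix(0, n, n, dimnames = list(nm, nm))
  diag(W) <- model$nodes$self_coupling
  e <- model$edges
  if (nrow(e) > 0L) {
    ok <- e$source %in% nm & e$target %in% nm
    for (k in which(ok)) W[e$target[k], e$source[k]] <- e$weight[k]
  }
  model$W <- W
  model$threshold <- stats::setNames(model$nodes$threshold, nm)
  model
}

#' @export
print.bn_model <- function(x, ...) {
  cat(sprintf("Boolean threshold network: %d nodes, %d edges, variant '%s'\n",
              nrow(x$nodes), nrow(x$edges), x$variant))
  if (length(x$clamped_off)) {
    cat("  clamped OFF:", paste(x$clamped_off, collapse = ", "), "\n")
  }
  special <- x$nodes$threshold != 0
  if (any(special)) {
    cat("  non-zero thresholds:",
        paste(sprintf("%s=%g", x$nodes$name[special],
                      x$nodes$threshold[special]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resolve a (possibly abbreviated) node name against a model
#'
#' Accepts the full node name or a common short alias (`Cig1`, `Cig2`,
#' `Puc1`, `Cdc13`, `Tyr15`, `Wee1`, `Mik1`).
#'
#' @param model A `bn_model`.
#' @param name Node name or alias.
#' @return The resolved full node name.
#' @export
resolve_node <- function(model, name) {
  nm <- model$nodes$name
  out <- vapply(name, function(x) {
    if (x %in% nm) return(x)
    if (x %in% names(POMBE_ALIASES) && POMBE_ALIASES[[x]] %in% nm) {
      return(POMBE_ALIASES[[x]])
    }
    stop(sprintf("unknown node '%s' (available: %s)", x,
                 paste(nm, collapse = ", ")), call. = FALSE)
  }, character(1))
  unname(out)
}

#' Build the fission yeast cell cycle network
#'
#' Constructs the 12-node wild-type model: the cell-mass indicator Start;
#' the three start-kinase complexes Cdc2/Cig1, Cdc2/Cig2, Cdc2/Puc1; the
#' M-phase promoting factor Cdc2/Cdc13 and its Tyr15 dephosphorylation state
#' Cdc2_Tyr15; the Cdc2/Cdc13 antagonists Ste9, Rum1 and Slp1; the inhibitory
#' kinase pair Wee1/Mik1 (one combined node); the activating phosphatase
#' Cdc25; and the resetting phosphatase PP.
#'
#' Thresholds are 0 except Cdc2/Cdc13 (-0.5, constitutive synthesis),
#' Cdc2_Tyr15 (+0.5, phosphorylated unless actively dephosphorylated) and
#' Slp1 (+1.5, requiring simultaneous Cdc2/Cdc13 and Cdc2_Tyr15 activity as
#' the mitosis barrier). The two update-rule variants share the identical
#' off-diagonal interaction matrix and differ only in the self-coupling
#' bookkeeping:
#'
#' * `"threshold_memory"`: ties at the threshold retain the node state, and
#'   inhibitory self-degradation loops (`a_ii = -1`) sit on the nodes that
#'   are not negatively regulated by others and not already offset from the
#'   decay regime by a non-zero threshold: Start, the three start kinases,
#'   and PP.
#' * `"simplified"`: nodes decay by default (next state 1 only if input
#'   exceeds threshold); the formerly non-self-degrading zero-threshold
#'   nodes Rum1, Ste9, Cdc25 and Wee1/Mik1 instead carry a self-activating
#'   coupling `a_ii = +1`.
#'
#' Both variants yield the same dynamics on this network (the test suite
#' verifies this state-by-state).
#'
#' @param variant `"simplified"` or `"threshold_memory"`.
#' @param slp1_threshold Activation threshold of Slp1. Any value strictly
#'   between 1 and 2 implements the same AND gate; default 1.5.
#' @return A `bn_model` with the standard initial condition flagged on
#'   Start, Ste9, Rum1 and Wee1/Mik1.
#' @examples
#' m <- build_pombe_model("simplified")
#' simulate_trajectory(m)
#' @export
build_pombe_model <- function(variant = c("simplified", "threshold_memory"),
                              slp1_threshold = 1.5) {
  variant <- match.arg(variant)
  if (!is.finite(slp1_threshold) || slp1_threshold <= 1 ||
      slp1_threshold >= 2) {
    stop("slp1_threshold must lie strictly between 1 and 2")
  }
  sk <- c("Cdc2/Cig1", "Cdc2/Cig2", "Cdc2/Puc1")

  nodes <- data.frame(
    name = POMBE_NODES,
    threshold = 0,
    self_coupling = 0,
    initial_on = POMBE_NODES %in% c("Start", "Ste9", "Rum1", "Wee1/Mik1"),
    stringsAsFactors = FALSE
  )
  nodes$threshold[nodes$name == "Cdc2/Cdc13"] <- -0.5
  nodes$threshold[nodes$name == "Cdc2_Tyr15"] <- 0.5
  nodes$threshold[nodes$name == "Slp1"] <- slp1_threshold

  if (variant == "threshold_memory") {
    # Degradation loops on the nodes with no negative regulator whose
    # threshold does not already place them in the default-decay regime.
    loops <- c("Start", sk, "PP")
    nodes$self_coupling[nodes$name %in% loops] <- -1
  } else {
    nodes$self_coupling[nodes$name %in%
                          c("Rum1", "Ste9", "Cdc25", "Wee1/Mik1")] <- 1
  }

  edge <- function(source, target, weight = 1) {
    data.frame(source = source, target = target, weight = weight,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    edge("Start", sk),
    edge(sk, "Ste9", -1),
    edge(sk, "Rum1", -1),
    edge("Cdc2/Cdc13", "Cdc25"),
    edge("Cdc2/Cdc13", "Ste9", -1),
    edge("Cdc2/Cdc13", "Rum1", -1),
    edge("Cdc2/Cdc13", "Wee1/Mik1", -1),
    edge("Wee1/Mik1", "Cdc2_Tyr15", -1),
    edge("Cdc25", "Cdc2_Tyr15"),
    edge("Rum1", "Cdc2/Cdc13", -1),
    edge("Ste9", "Cdc2/Cdc13", -1),
    edge("Slp1", "Cdc2/Cdc13", -1),
    edge("Slp1", "PP"),
    edge("Cdc2/Cdc13", "Slp1"),
    edge("Cdc2_Tyr15", "Slp1"),
    edge("PP", "Ste9"),
    edge("PP", "Rum1"),
    edge("PP", "Wee1/Mik1"),
    edge("PP", "Cdc25", -1)
  )

  bn_model(nodes, edges, variant = variant)
}

#' Network state at one discrete time step
#'
#' @param values Binary (0/1) vector aligned to the model's node order.
#' @param time Positive integer step index; the initial condition is step 1.
#' @return An object of class `bn_state`.
#' @export
bn_state <- function(values, time = 1L) {
  values <- as.integer(values)
  if (!all(values %in% c(0L, 1L))) stop("state entries must be 0 or 1")
  time <- as.integer(time)
  if (length(time) != 1L || is.na(time) || time < 1L) {
    stop("time must be a positive integer")
  }
  structure(list(values = values, time = time), class = "bn_state")
}

#' @export
print.bn_state <- function(x, ...) {
  cat(sprintf("step %d: %s\n", x$time, paste(x$values, collapse = "")))
  invisible(x)
}

#' Standard initial condition of the cell cycle model
#'
#' All nodes OFF except those flagged `initial_on` in the node table (for the
#' yeast model: Start, Ste9, Rum1, Wee1/Mik1), at time step 1. Knocked-out
#' (clamped) nodes are deliberately *not* zeroed here: a deletion takes
#' effect from the first update (step 2) onward, so step 1 is the unmodified
#' biological start condition.
#'
#' @param model A `bn_model`.
#' @return A `bn_state` with `time = 1`.
#' @export
standard_initial_state <- function(model) {
  stopifnot(inherits(model, "bn_model"))
  if (!any(model$nodes$initial_on)) {
    stop("model declares no initial_on nodes; cannot form the standard ",
         "initial condition")
  }
  bn_state(as.integer(model$nodes$initial_on), time = 1L)
}

#' Validate a model's structural invariants
#'
#' Checks for duplicate node names, edges referencing undeclared nodes,
#' non-finite thresholds or weights, non-binary state conventions in the
#' node table, self-couplings smuggled into the edge list, and clamping of
#' unknown nodes. Diagnostics are returned, never raised.
#'
#' @param model A `bn_model`.
#' @return Character vector of diagnostics; empty if the model is valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "bn_model"))
  out <- character()
  nm <- model$nodes$name
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) out <- c(out, sprintf("duplicate node name '%s'", d))
  bad <- !is.finite(model$nodes$threshold)
  for (b in nm[bad]) out <- c(out, sprintf("non-finite threshold on '%s'", b))
  bad <- !is.finite(model$nodes$self_coupling)
  for (b in nm[bad]) {
    out <- c(out, sprintf("non-finite self-coupling on '%s'", b))
  }
  if (!is.logical(model$nodes$initial_on)) {
    out <- c(out, "initial_on column is not logical")
  }
  e <- model$edges
  if (nrow(e) > 0L) {
    for (k in seq_len(nrow(e))) {
      if (!e$source[k] %in% nm) {
        out <- c(out, sprintf("edge %s -> %s: undeclared source node",
                              e$source[k], e$target[k]))
      }
      if (!e$target[k] %in% nm) {
        out <- c(out, sprintf("edge %s -> %s: undeclared target node",
                              e$source[k], e$target[k]))
      }
      if (!is.finite(e$weight[k])) {
        out <- c(out, sprintf("edge %s -> %s: non-finite weight",
                              e$source[k], e$target[k]))
      }
      if (identical(e$source[k], e$target[k])) {
        out <- c(out, sprintf(
          "self-loop on '%s' declared as an edge; put self-couplings in the node table",
          e$source[k]))
      }
    }
    key <- paste(e$source, e$target, sep = "\r")
    for (d in unique(key[duplicated(key)])) {
      out <- c(out, sprintf("duplicate edge %s",
                            gsub("\r", " -> ", d, fixed = TRUE)))
    }
  }
  for (cl in model$clamped_off) {
    if (!cl %in% nm) out <- c(out, sprintf("clamp of unknown node '%s'", cl))
  }
  out
}

# Indices of nodes not clamped OFF.
free_node_idx <- function(model) {
  which(!(model$nodes$name %in% model$clamped_off))
}
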