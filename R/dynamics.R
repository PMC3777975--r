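# Synchronous update engine, trajectory simulation with attractor detection,
# and exhaustive state-space / basin-of-attraction analysis.

#' Synchronous update: compute the successor of a network state
#'
#' Each node receives the input `sum_j a_ij * S_j(t)` (self-couplings on the
#' matrix diagonal participate). Under the `"threshold_memory"` rule the next
#' state is 1 if the input exceeds the node threshold, 0 if it falls below,
#' and unchanged on a tie. Under the `"simplified"` rule the next state is 1
#' iff the input strictly exceeds the threshold. Clamped (knocked-out) nodes
#' are forced to 0 in the returned state, which carries `time + 1`.
#'
#' @param model A `bn_model`.
#' @param state A `bn_state` or bare 0/1 vector aligned to the model.
#' @return The successor `bn_state`.
#' @export
successor <- function(model, state) {
  stopifnot(inherits(model, "bn_model"))
  if (inherits(state, "bn_state")) {
    v <- state$values
    t0 <- state$time
  } else {
    v <- as.integer(state)
    t0 <- 1L
  }
  if (length(v) != nrow(model$nodes)) {
    stop(sprintf("state has %d entries but the model has %d nodes",
                 length(v), nrow(model$nodes)))
  }
  bn_state(step_values(model, v), time = t0 + 1L)
}

# Bare-vector core of the update rule (no class bookkeeping).
step_values <- function(model, v) {
  input <- as.numeric(model$W %*% v)
  th <- unname(model$threshold)
  if (model$variant == "simplified") {
    new <- as.integer(input > th)
  } else {
    new <- ifelse(input > th, 1L, ifelse(input < th, 0L, as.integer(v)))
  }
  if (length(model$clamped_off)) {
    new[model$nodes$name %in% model$clamped_off] <- 0L
  }
  as.integer(new)
}

# Encode binary vectors as integers (bit 1 = first node). Works for up to
# 52 nodes (double mantissa), far above the enumeration cap.
encode_states <- function(mat) {
  pw <- 2^(seq_len(ncol(mat)) - 1)
  as.numeric(mat %*% pw)
}

decode_state <- function(code, n) {
  v <- integer(n)
  for (i in seq_len(n)) {
    v[i] <- as.integer(code %% 2)
    code <- code %/% 2
  }
  v
}

#' Simulate a trajectory until a state revisit
#'
#' Iterates the synchronous update from `start`, recording every state, and
#' stops at the first step whose state equals an earlier recorded state.
#' Because the update is deterministic over a finite state space, a revisit
#' is guaranteed within `2^n + 1` steps; the default `max_steps` of
#' `4 * 2^n` (capped at `4e6`) therefore always detects the attractor.
#'
#' The initial condition is step 1 (so "reaches its fixed point at step t"
#' means the state at `t + 1` equals the state at `t`, with `t` minimal).
#'
#' @param model A `bn_model`.
#' @param start Starting `bn_state`; default [standard_initial_state()].
#' @param max_steps Maximum number of recorded steps.
#' @return An object of class `bn_trajectory`: a list with `states` (matrix,
#'   one row per time step, one column per node), `attractor_kind`
#'   (`"FIXED_POINT"`, `"LIMIT_CYCLE"` or `"NONE"`), `attractor_entry_step`,
#'   `first_revisit_step`, `cycle_period`, and `phase` labels when the model
#'   carries the cell-cycle marker nodes.
#' @export
simulate_trajectory <- function(model, start = standard_initial_state(model),
                                max_steps = NULL) {
  stopifnot(inherits(model, "bn_model"))
  if (!inherits(start, "bn_state")) start <- bn_state(start)
  n <- nrow(model$nodes)
  nfree <- length(free_node_idx(model))
  if (is.null(max_steps)) max_steps <- min(4 * 2^nfree + 4, 4e6)
  if (max_steps < 1) stop("max_steps must be >= 1")

  states <- matrix(NA_integer_, nrow = min(max_steps, 1024L), ncol = n,
                   dimnames = list(NULL, model$nodes$name))
  codes <- numeric(nrow(states))
  v <- start$values
  states[1L, ] <- v
  codes[1L] <- encode_states(matrix(v, 1L))
  revisit <- NA_integer_
  repeat_of <- NA_integer_
  k <- 1L
  while (k < max_steps) {
    v <- step_values(model, v)
    k <- k + 1L
    if (k > nrow(states)) {
      states <- rbind(states, matrix(NA_integer_, nrow(states), n))
      codes <- c(codes, numeric(length(codes)))
    }
    states[k, ] <- v
    code <- encode_states(matrix(v, 1L))
    codes[k] <- code
    hit <- match(code, codes[seq_len(k - 1L)])
    if (!is.na(hit)) {
      revisit <- k
      repeat_of <- hit
      break
    }
  }
  states <- states[seq_len(k), , drop = FALSE]

  if (is.na(revisit)) {
    warning("max_steps exhausted without a state revisit; no attractor ",
            "detected")
    kind <- "NONE"
    entry <- NA_integer_
    period <- NA_integer_
  } else {
    period <- revisit - repeat_of
    kind <- if (period == 1L) "FIXED_POINT" else "LIMIT_CYCLE"
    entry <- repeat_of
  }
  structure(
    list(states = states, start_time = start$time,
         attractor_kind = kind, attractor_entry_step = entry,
         first_revisit_step = revisit, cycle_period = period,
         model_variant = model$variant, clamped_off = model$clamped_off),
    class = "bn_trajectory"
  )
}

#' @export
print.bn_trajectory <- function(x, ...) {
  k <- nrow(x$states)
  cat(sprintf("Trajectory of %d recorded steps (%s", k, x$attractor_kind))
  if (x$attractor_kind == "FIXED_POINT") {
    cat(sprintf(" reached at step %d", x$attractor_entry_step))
  } else if (x$attractor_kind == "LIMIT_CYCLE") {
    cat(sprintf(", period %d, entered at step %d", x$cycle_period,
                x$attractor_entry_step))
  }
  cat(")\n")
  print(utils::head(as.data.frame(x), 12L))
  invisible(x)
}

#' @export
as.data.frame.bn_trajectory <- function(x, ...) {
  # One row per unique time step (the duplicated revisit row is dropped so
  # the wild-type table has exactly its 10 printed rows).
  keep <- seq_len(if (is.na(x$first_revisit_step)) nrow(x$states) else
    x$first_revisit_step - 1L)
  df <- as.data.frame(x$states[keep, , drop = FALSE])
  data.frame(time = keep, df, check.names = FALSE)
}

#' Unique states of a trajectory (revisit row dropped)
#' @param trajectory A `bn_trajectory`.
#' @return Integer matrix, one row per step.
#' @export
trajectory_states <- function(trajectory) {
  keep <- seq_len(if (is.na(trajectory$first_revisit_step))
    nrow(trajectory$states) else trajectory$first_revisit_step - 1L)
  trajectory$states[keep, , drop = FALSE]
}

#' States belonging to the detected attractor
#' @param trajectory A `bn_trajectory`.
#' @return Integer matrix of the attractor's states in visit order (one row
#'   for a fixed point).
#' @export
attractor_states <- function(trajectory) {
  if (trajectory$attractor_kind == "NONE") {
    stop("trajectory has no detected attractor")
  }
  idx <- seq(trajectory$attractor_entry_step,
             trajectory$first_revisit_step - 1L)
  trajectory$states[idx, , drop = FALSE]
}

# Full successor table over the non-clamped state space: entry i is the
# 1-based encoded successor of the state with code i-1 (bits in free-node
# order, clamped nodes held at 0). Vectorized and chunked to bound memory.
successor_table <- function(model) {
  free <- free_node_idx(model)
  f <- length(free)
  n <- nrow(model$nodes)
  N <- 2^f
  succ <- integer(N)
  chunk <- as.integer(min(N, 2^16))
  th <- unname(model$threshold)
  clamped <- which(model$nodes$name %in% model$clamped_off)
  for (lo in seq(0, N - 1, by = chunk)) {
    idx <- lo:min(lo + chunk - 1, N - 1)
    S <- matrix(0L, length(idx), n)
    bits <- idx
    for (j in seq_len(f)) {
      S[, free[j]] <- bits %% 2
      bits <- bits %/% 2
    }
    input <- S %*% t(model$W)
    if (model$variant == "simplified") {
      newS <- matrix(0L, length(idx), n)
      newS[sweep(input, 2, th, ">")] <- 1L
    } else {
      up <- sweep(input, 2, th, ">")
      down <- sweep(input, 2, th, "<")
      newS <- S
      newS[up] <- 1L
      newS[down] <- 0L
    }
    if (length(clamped)) newS[, clamped] <- 0L
    code <- as.numeric(newS[, free, drop = FALSE] %*% 2^(seq_len(f) - 1))
    succ[idx + 1] <- as.integer(code + 1)
  }
  succ
}

#' First later step at which a given step's state recurs
#'
#' For a trajectory ending in a limit cycle, a state on the cycle recurs
#' every `cycle_period` steps; for a reference state off the attractor there
#' is no recurrence (`NA`).
#'
#' @param trajectory A `bn_trajectory`.
#' @param step Reference step index (1-based).
#' @return The smallest step `t > step` with `state(t) == state(step)`, or
#'   `NA` if the reference state never recurs.
#' @export
first_recurrence_of_step <- function(trajectory, step) {
  st <- trajectory$states
  stopifnot(step >= 1L, step <= nrow(st))
  ref <- st[step, ]
  later <- which(apply(st, 1L, function(r) all(r == ref)))
  later <- later[later > step]
  if (length(later)) return(min(later))
  if (!is.na(trajectory$attractor_entry_step) &&
      step >= trajectory$attractor_entry_step) {
    return(step + trajectory$cycle_period)
  }
  NA_integer_
}

#' Exhaustive attractor and basin-of-attraction analysis
#'
#' Visits every state of the non-clamped state space exactly once via a
#' memoized successor table, identifies all attractors (fixed points and
#' limit cycles) and their exact basin sizes. Clamped nodes are held at 0
#' throughout and excluded from enumeration, so `total_states = 2^f` with
#' `f` free nodes.
#'
#' Basins are reported over two initial-state ensembles: all `2^f` states
#' (`basin_size`, `basin_percent`), and — when the model carries a
#' non-clamped trigger node (default `"Start"`, the cell-size signal, which
#' is an externally set input rather than a regulatory protein) — the
#' `2^(f-1)` *resting* states with the trigger OFF (`resting_basin_size`,
#' `resting_basin_percent`).
#'
#' @param model A `bn_model`.
#' @param max_nodes Refuse models with more free nodes than this (default
#'   24); the state space grows as `2^f`.
#' @param trigger Name of the trigger node for the resting ensemble, or
#'   `NULL` to skip it.
#' @return An object of class `bn_attractors`: list with `attractors` (each
#'   holding `states`, `basin_size`, `basin_percent`, resting counterparts,
#'   and `kind`), sorted by descending basin size, plus `total_states`,
#'   `n_stationary_states` (total number of distinct recurrent states over
#'   all attractors) and `node_names`.
#' @export
enumerate_attractors <- function(model, max_nodes = 24L, trigger = "Start") {
  stopifnot(inherits(model, "bn_model"))
  free <- free_node_idx(model)
  f <- length(free)
  if (f > max_nodes) {
    stop(sprintf(paste0(
      "model has %d non-clamped nodes; exhaustive enumeration over 2^%d ",
      "states exceeds the cap of %d nodes. Raise max_nodes only if you ",
      "can afford the memory."), f, f, max_nodes))
  }
  n <- nrow(model$nodes)
  N <- 2^f
  succ <- successor_table(model)

  # Identify attractors on the functional graph succ (1-based indices).
  attr_id <- integer(N)                 # 0 = unassigned
  mark <- integer(N)                    # walk id during path construction
  att_states <- list()                  # attractor -> state codes (cycle order)
  n_att <- 0L
  for (s in seq_len(N)) {
    if (attr_id[s] != 0L) next
    path <- integer(64L)
    plen <- 0L
    v <- s
    while (attr_id[v] == 0L && mark[v] != s) {
      mark[v] <- s
      plen <- plen + 1L
      if (plen > length(path)) path <- c(path, integer(length(path)))
      path[plen] <- v
      v <- succ[v]
    }
    if (attr_id[v] != 0L) {
      id <- attr_id[v]
    } else {
      # v is on the current path: the segment from v onward is a new cycle.
      pos <- match(v, path[seq_len(plen)])
      n_att <- n_att + 1L
      id <- n_att
      att_states[[id]] <- path[pos:plen]
    }
    attr_id[path[seq_len(plen)]] <- id
  }
  basin <- tabulate(attr_id, nbins = n_att)

  resting_basin <- NULL
  trig_pos <- if (!is.null(trigger)) match(trigger, model$nodes$name[free])
  else NA_integer_
  if (!is.na(trig_pos)) {
    # Initial states with the trigger bit OFF: codes whose trig_pos bit is 0.
    codes0 <- seq_len(N) - 1L
    off <- (codes0 %/% 2^(trig_pos - 1)) %% 2 == 0
    resting_basin <- tabulate(attr_id[off], nbins = n_att)
  }

  decode_full <- function(codes) {
    m <- matrix(0L, length(codes), n, dimnames = list(NULL, model$nodes$name))
    bits <- codes - 1
    for (j in seq_len(f)) {
      m[, free[j]] <- as.integer(bits %% 2)
      bits <- bits %/% 2
    }
    m
  }
  attractors <- lapply(seq_len(n_att), function(id) {
    st <- decode_full(att_states[[id]])
    out <- list(states = st,
                kind = if (nrow(st) == 1L) "FIXED_POINT" else "LIMIT_CYCLE",
                basin_size = basin[id],
                basin_percent = round(100 * basin[id] / N))
    if (!is.null(resting_basin)) {
      out$resting_basin_size <- resting_basin[id]
      out$resting_basin_percent <- round(100 * resting_basin[id] / (N / 2))
    }
    out
  })
  ord <- order(vapply(attractors, `[[`, numeric(1), "basin_size"),
               decreasing = TRUE)
  structure(
    list(attractors = attractors[ord], total_states = N,
         n_stationary_states = sum(vapply(attractors, function(a)
           nrow(a$states), integer(1))),
         trigger = if (!is.na(trig_pos)) trigger else NULL,
         node_names = model$nodes$name, free_nodes = model$nodes$name[free]),
    class = "bn_attractors"
  )
}

#' @export
print.bn_attractors <- function(x, ...) {
  cat(sprintf(
    "%d attractor(s), %d stationary state(s), over %d states (%d free nodes)\n",
    length(x$attractors), x$n_stationary_states, x$total_states,
    length(x$free_nodes)))
  df <- as.data.frame(x)
  print(df)
  invisible(x)
}

#' @export
as.data.frame.bn_attractors <- function(x, ...) {
  rows <- lapply(seq_along(x$attractors), function(i) {
    a <- x$attractors[[i]]
    df <- data.frame(
      attractor = i,
      kind = a$kind,
      state = paste(apply(a$states, 1L, paste, collapse = ""),
                    collapse = "|"),
      basin_size = a$basin_size,
      basin_percent = a$basin_percent,
      stringsAsFactors = FALSE
    )
    if (!is.null(a$resting_basin_size)) {
      df$resting_basin_size <- a$resting_basin_size
      df$resting_basin_percent <- a$resting_basin_percent
    }
    df
  })
  do.call(rbind, rows)
}

#' Brute-force state-space analysis (independent oracle)
#'
#' Recomputes the attractor report by naive per-state simulation with no
#' memoization: every initial state is iterated with [successor()] until it
#' revisits one of its own previously visited states. Intended for tests
#' (oracle-equivalence with [enumerate_attractors()]); quadratic-ish and
#' limited to 16 free nodes.
#'
#' @param model A `bn_model`.
#' @param trigger Trigger node for the resting ensemble (as in
#'   [enumerate_attractors()]).
#' @return A `bn_attractors` object.
#' @export
state_space_oracle <- function(model, trigger = "Start") {
  stopifnot(inherits(model, "bn_model"))
  free <- free_node_idx(model)
  f <- length(free)
  if (f > 16L) stop("state_space_oracle is limited to 16 non-clamped nodes")
  n <- nrow(model$nodes)
  N <- 2^f
  trig_idx <- if (!is.null(trigger)) {
    i <- match(trigger, model$nodes$name)
    if (!is.na(i) && i %in% free) i else NA_integer_
  } else NA_integer_

  basin_of <- new.env(parent = emptyenv())   # canonical cycle key -> count
  rest_of <- new.env(parent = emptyenv())    # same, trigger-OFF initials
  states_of <- new.env(parent = emptyenv())  # canonical cycle key -> matrix
  for (code in seq(0, N - 1)) {
    v <- integer(n)
    v[free] <- decode_state(code, f)
    resting <- is.na(trig_idx) || v[trig_idx] == 0L
    seen <- character(0)
    repeat {
      key <- paste(v, collapse = "")
      pos <- match(key, seen)
      if (!is.na(pos)) {
        cyc <- seen[pos:length(seen)]
        canon_i <- which(cyc == min(cyc))[1L]
        canon <- paste(cyc[c(canon_i:length(cyc),
                             seq_len(canon_i - 1L))], collapse = "|")
        if (is.null(basin_of[[canon]])) {
          basin_of[[canon]] <- 0L
          rest_of[[canon]] <- 0L
          states_of[[canon]] <- do.call(rbind, lapply(
            strsplit(canon, "|", fixed = TRUE)[[1]],
            function(s) as.integer(strsplit(s, "")[[1]])))
        }
        basin_of[[canon]] <- basin_of[[canon]] + 1L
        if (resting) rest_of[[canon]] <- rest_of[[canon]] + 1L
        break
      }
      seen <- c(seen, key)
      v <- step_values(model, v)
    }
  }
  keys <- ls(basin_of)
  attractors <- lapply(keys, function(k) {
    st <- states_of[[k]]
    colnames(st) <- model$nodes$name
    out <- list(states = st,
                kind = if (nrow(st) == 1L) "FIXED_POINT" else "LIMIT_CYCLE",
                basin_size = basin_of[[k]],
                basin_percent = round(100 * basin_of[[k]] / N))
    if (!is.na(trig_idx)) {
      out$resting_basin_size <- rest_of[[k]]
      out$resting_basin_percent <- round(100 * rest_of[[k]] / (N / 2))
    }
    out
  })
  ord <- order(vapply(attractors, `[[`, numeric(1), "basin_size"),
               decreasing = TRUE)
  structure(
    list(attractors = attractors[ord], total_states = N,
         n_stationary_states = sum(vapply(attractors, function(a)
           nrow(a$states), integer(1))),
         trigger = if (!is.na(trig_idx)) trigger else NULL,
         node_names = model$nodes$name, free_nodes = model$nodes$name[free]),
    class = "bn_attractors"
  )
}

# Canonical comparable form of an attractor report: set of (cycle key,
# basin size) pairs, insensitive to ordering and cycle rotation.
canonical_attractor_set <- function(report) {
  keys <- vapply(report$attractors, function(a) {
    rows <- apply(a$states, 1L, paste, collapse = "")
    i <- which.min(rows)
    paste(paste(rows[c(i:length(rows), seq_len(i - 1L))], collapse = "|"),
          a$basin_size, sep = "#")
  }, character(1))
  sort(keys)
}

#' Export a trajectory as TSV
#'
#' One row per time step, one column per node, values 0/1, time running down
#' the rows; a `time` column leads.
#'
#' @param trajectory A `bn_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an attractor report as TSV
#'
#' One row per attractor (state bits, basin size, basin percent), sorted by
#' descending basin size.
#'
#' @param report A `bn_attractors` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attractors_tsv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
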