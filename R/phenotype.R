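# Cell-cycle phase labelling and viability classification, plus the
# concordance evaluation of the whole strain catalog.

PHASE_MARKERS <- c("Cdc2/Cdc13", "Cdc2_Tyr15", "Ste9", "Rum1", "Slp1")

#' Label a network state with a cell-cycle phase
#'
#' Marker-based labels, in precedence order:
#' * `M`: Slp1 (the mitotic APC activator) ON;
#' * `G2-M`: Cdc2/Cdc13 ON and Cdc2_Tyr15 ON (fully active MPF);
#' * `G2`: Cdc2/Cdc13 ON, Cdc2_Tyr15 OFF (moderate MPF activity);
#' * `G1`: Cdc2/Cdc13 OFF with at least one of the antagonists Ste9/Rum1 ON;
#' * `G1-S`: everything else (antagonists and MPF all OFF).
#'
#' Knocked-out (clamped) nodes count as OFF regardless of the state vector.
#'
#' @param state A `bn_state` or bare 0/1 vector.
#' @param model A `bn_model` containing the marker nodes.
#' @return One of `"G1"`, `"G1-S"`, `"G2"`, `"G2-M"`, `"M"`.
#' @export
label_phase <- function(state, model) {
  stopifnot(inherits(model, "bn_model"))
  v <- if (inherits(state, "bn_state")) state$values else as.integer(state)
  nm <- model$nodes$name
  if (!all(PHASE_MARKERS %in% nm)) {
    stop("model lacks the cell-cycle marker nodes (",
         paste(setdiff(PHASE_MARKERS, nm), collapse = ", "), ")")
  }
  v[nm %in% model$clamped_off] <- 0L
  on <- function(x) v[match(x, nm)] == 1L
  if (on("Slp1")) return("M")
  if (on("Cdc2/Cdc13")) {
    return(if (on("Cdc2_Tyr15")) "G2-M" else "G2")
  }
  if (on("Ste9") || on("Rum1")) return("G1")
  "G1-S"
}

# Phase label for every recorded step of a trajectory.
trajectory_phases <- function(trajectory, model) {
  st <- trajectory_states(trajectory)
  vapply(seq_len(nrow(st)), function(i) label_phase(st[i, ], model),
         character(1))
}

# The biological G1 fixed point of the unperturbed network.
pombe_g1_values <- function(model) {
  as.integer(model$nodes$name %in% c("Ste9", "Rum1", "Wee1/Mik1"))
}

#' Classify viability from a simulated trajectory
#'
#' A strain is called `VIABLE` iff
#' 1. its attractor is a fixed point whose restriction to surviving
#'    (non-clamped) nodes equals the wild-type G1 stationary state restricted
#'    likewise (Ste9, Rum1, Wee1/Mik1 ON; everything else, including Start,
#'    OFF); and
#' 2. the trajectory visited a G2-labelled state before its first M-labelled
#'    state (an orderly gap phase precedes mitosis); and
#' 3. the trajectory visited an M-labelled state at all (mitosis happened).
#'
#' Limit cycles are `LETHAL` (the cell runs through division states
#' periodically without a mass checkpoint: dividing ever faster and smaller).
#' Fixed points other than G1 are arrests; the arrest phase is the label of
#' the fixed point.
#'
#' @param trajectory A `bn_trajectory` with a detected attractor.
#' @param model The (perturbed) `bn_model` that produced the trajectory.
#' @param strain_name Optional name to carry into the call record.
#' @return An object of class `bn_phenotype`: list with `strain_name`,
#'   `attractor_kind`, `arrest_phase`, `visited_G2`, `visited_M`,
#'   `reached_G1_fixed_point`, `viability`.
#' @export
classify_viability <- function(trajectory, model, strain_name = "") {
  stopifnot(inherits(trajectory, "bn_trajectory"))
  if (trajectory$attractor_kind == "NONE") {
    stop("trajectory has no detected attractor; increase max_steps")
  }
  phases <- trajectory_phases(trajectory, model)
  first_M <- match("M", phases)
  visited_M <- !is.na(first_M)
  visited_G2 <- if (visited_M) {
    any(phases[seq_len(first_M - 1L)] == "G2")
  } else {
    any(phases == "G2")
  }
  g2_before_M <- visited_M && any(phases[seq_len(first_M - 1L)] == "G2")

  keep <- !(model$nodes$name %in% model$clamped_off)
  reached_G1 <- FALSE
  arrest <- "NONE"
  if (trajectory$attractor_kind == "FIXED_POINT") {
    fp <- attractor_states(trajectory)[1L, ]
    reached_G1 <- all(fp[keep] == pombe_g1_values(model)[keep])
    arrest <- label_phase(fp, model)
  }
  viable <- trajectory$attractor_kind == "FIXED_POINT" && reached_G1 &&
    g2_before_M && visited_M
  structure(
    list(strain_name = strain_name,
         attractor_kind = trajectory$attractor_kind,
         arrest_phase = if (viable) "NONE" else arrest,
         visited_G2 = visited_G2, visited_M = visited_M,
         reached_G1_fixed_point = reached_G1,
         viability = if (viable) "VIABLE" else "LETHAL"),
    class = "bn_phenotype"
  )
}

#' @export
print.bn_phenotype <- function(x, ...) {
  cat(sprintf("%s: %s (%s%s)\n",
              if (nzchar(x$strain_name)) x$strain_name else "strain",
              x$viability,
              if (x$attractor_kind == "LIMIT_CYCLE") "oscillation"
              else if (x$viability == "VIABLE") "completed cycle, G1"
              else paste("arrest in", x$arrest_phase),
              ""))
  invisible(x)
}

#' Evaluate the strain catalog against experimental viability
#'
#' Simulates every representable catalog strain from the standard initial
#' condition, classifies viability, and compares with the experimental
#' viability/lethality call. Benchmark-panel strains (`in_table3`) make up
#' the headline agreement count; documented model failures are reported in
#' the table but never counted as agreements; non-representable strains are
#' listed with `NA` model calls.
#'
#' @param variant Update-rule variant for the base model.
#' @param strains Catalog to evaluate; default [strain_catalog()].
#' @param include_wild_type Prepend the unperturbed wild type row.
#' @return A data frame (class `bn_concordance`) with one row per strain:
#'   name, encoding, attractor kind, arrest phase, model call, experimental
#'   call, concordance and bookkeeping flags. Attributes `n_panel` and
#'   `n_concordant` hold the benchmark counts.
#' @export
evaluate_catalog <- function(variant = c("simplified", "threshold_memory"),
                             strains = strain_catalog(),
                             include_wild_type = TRUE) {
  variant <- match.arg(variant)
  base <- build_pombe_model(variant)

  rows <- list()
  if (include_wild_type) {
    traj <- simulate_trajectory(base)
    ph <- classify_viability(traj, base, "WT")
    rows[[1]] <- data.frame(
      strain = "WT", encoding = "none", attractor = ph$attractor_kind,
      arrest_phase = ph$arrest_phase, model_viability = ph$viability,
      experimental_viability = "VIABLE", match = ph$viability == "VIABLE",
      in_table3 = FALSE, known_model_failure = FALSE, representable = TRUE,
      stringsAsFactors = FALSE
    )
  }
  for (s in strains) {
    enc <- paste(vapply(s$perturbations, perturbation_token, character(1)),
                 collapse = ",")
    if (!isTRUE(s$representable)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s$name, encoding = "(not representable)",
        attractor = NA_character_, arrest_phase = NA_character_,
        model_viability = NA_character_,
        experimental_viability = s$experimental_viability,
        match = NA, in_table3 = s$in_table3,
        known_model_failure = s$known_model_failure, representable = FALSE,
        stringsAsFactors = FALSE
      )
      next
    }
    m <- apply_perturbations(base, s)
    traj <- simulate_trajectory(m)
    ph <- classify_viability(traj, m, s$name)
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s$name, encoding = enc, attractor = ph$attractor_kind,
      arrest_phase = ph$arrest_phase, model_viability = ph$viability,
      experimental_viability = s$experimental_viability,
      match = if (is.na(s$experimental_viability)) NA
      else ph$viability == s$experimental_viability,
      in_table3 = s$in_table3, known_model_failure = s$known_model_failure,
      representable = TRUE, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  panel <- out$in_table3 & !out$known_model_failure
  attr(out, "n_panel") <- sum(panel)
  attr(out, "n_concordant") <- sum(out$match[panel], na.rm = TRUE)
  class(out) <- c("bn_concordance", class(out))
  out
}

#' @export
print.bn_concordance <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  print(df, right = FALSE)
  cat(sprintf("\nBenchmark panel: %d/%d strains concordant\n",
              attr(x, "n_concordant"), attr(x, "n_panel")))
  invisible(x)
}

#' Export a concordance report as TSV
#'
#' Per-strain rows plus a trailing comment line with the benchmark agreement
#' count.
#'
#' @param concordance Result of [evaluate_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(concordance, path) {
  df <- concordance
  class(df) <- "data.frame"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# panel_concordant\t%d/%d",
                     attr(concordance, "n_concordant"),
                     attr(concordance, "n_panel")), con)
  invisible(path)
}
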