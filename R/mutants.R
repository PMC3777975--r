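# Mutation semantics (knockout, overexpression, link reweighting) and the
# curated strain catalog with experimental viability calls.

DELTA <- "Δ"

#' Define a single perturbation
#'
#' @param kind One of `"knockout"` (node clamped OFF from the first update),
#'   `"moderate_op"` (activation threshold lowered to -0.5 or `value`),
#'   `"high_op"` (threshold lowered and a self-activating coupling
#'   `a_ii = +1` added), `"link_reweight"` (one edge weight replaced;
#'   `value` must lie in (0, 1]), or `"threshold_set"` (direct threshold
#'   override).
#' @param target Node name (or alias), or for `"link_reweight"` an edge
#'   written `"source->target"`.
#' @param value Numeric value where applicable; `NULL` for knockouts and for
#'   the default overexpression threshold of -0.5.
#' @return An object of class `bn_perturbation`.
#' @export
perturbation <- function(kind = c("knockout", "moderate_op", "high_op",
                                  "link_reweight", "threshold_set"),
                         target, value = NULL) {
  kind <- match.arg(kind)
  if (kind == "knockout" && !is.null(value)) {
    stop("a knockout carries no value")
  }
  if (kind == "link_reweight") {
    if (is.null(value) || !is.finite(value) || value <= 0 || value > 1) {
      stop("link_reweight needs a weight in (0, 1]")
    }
    if (!grepl("->", target, fixed = TRUE)) {
      stop("link_reweight target must be written 'source->target'")
    }
  }
  if (kind == "threshold_set" && (is.null(value) || !is.finite(value))) {
    stop("threshold_set needs a finite value")
  }
  structure(list(kind = kind, target = target, value = value),
            class = "bn_perturbation")
}

#' @export
print.bn_perturbation <- function(x, ...) {
  cat(perturbation_token(x), "\n")
  invisible(x)
}

perturbation_token <- function(p) {
  if (is.null(p$value)) paste(p$kind, p$target, sep = ":")
  else paste(p$kind, p$target, format(p$value), sep = ":")
}

parse_perturbation_token <- function(token) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop(sprintf("malformed perturbation '%s'", token))
  perturbation(parts[1], parts[2],
               value = if (length(parts) >= 3L) as.numeric(parts[3]))
}

#' Define a strain (named set of perturbations)
#'
#' @param name Strain name.
#' @param perturbations List of [perturbation()] objects (empty for the wild
#'   type and for strains the model cannot represent).
#' @param experimental_viability `"VIABLE"`, `"LETHAL"`, or `NA` when
#'   unknown.
#' @param experimental_note Free-text phenotype note (e.g. `"G2, L"`).
#' @param in_table3 Whether the strain belongs to the curated 32-strain
#'   benchmark panel.
#' @param known_model_failure Whether the model is documented *not* to
#'   reproduce this strain (reported separately, never counted as an
#'   agreement).
#' @param representable Whether the strain can be encoded at all in the
#'   Boolean framework (graded temperature-sensitive alleles cannot).
#' @return An object of class `bn_strain`.
#' @export
strain <- function(name, perturbations = list(),
                   experimental_viability = NA_character_,
                   experimental_note = "", in_table3 = FALSE,
                   known_model_failure = FALSE, representable = TRUE) {
  if (!is.na(experimental_viability)) {
    experimental_viability <- match.arg(experimental_viability,
                                        c("VIABLE", "LETHAL"))
  }
  stopifnot(all(vapply(perturbations, inherits, logical(1),
                       "bn_perturbation")))
  structure(
    list(name = name, perturbations = perturbations,
         experimental_viability = experimental_viability,
         experimental_note = experimental_note, in_table3 = in_table3,
         known_model_failure = known_model_failure,
         representable = representable),
    class = "bn_strain"
  )
}

#' @export
print.bn_strain <- function(x, ...) {
  cat(sprintf("Strain %s [%s]%s\n", x$name,
              paste(vapply(x$perturbations, perturbation_token,
                           character(1)), collapse = ", "),
              if (isTRUE(x$known_model_failure)) " (known model failure)"
              else ""))
  invisible(x)
}

#' Apply a strain's perturbations to a model
#'
#' Returns a new model; the input is never modified. Knockouts add the node
#' to `clamped_off`: the node is forced to 0 at every step with time >= 2,
#' while the standard initial state at step 1 is left untouched (a deletion
#' takes effect from the first update). Moderate overexpression lowers the
#' activation threshold to -0.5 (or the supplied override); under the
#' simplified variant it also clears any default self-activating coupling,
#' which is the bookkeeping device standing in for the memory rule's tie
#' branch and is no longer meaningful once the threshold leaves the integer
#' input lattice. High overexpression lowers the threshold *and* sets a
#' self-activating `a_ii = +1` under both variants. Link reweighting
#' replaces one existing edge weight (the Pyp3 backup-phosphatase semantics:
#' `Cdc25->Cdc2_Tyr15` at weight 0.75).
#'
#' @param model A `bn_model`.
#' @param strain A `bn_strain`, a list of [perturbation()]s, or a single
#'   perturbation.
#' @return The perturbed `bn_model`.
#' @export
apply_perturbations <- function(model, strain) {
  stopifnot(inherits(model, "bn_model"))
  perts <- if (inherits(strain, "bn_strain")) strain$perturbations
  else if (inherits(strain, "bn_perturbation")) list(strain)
  else strain
  stopifnot(all(vapply(perts, inherits, logical(1), "bn_perturbation")))
  if (inherits(strain, "bn_strain") && !isTRUE(strain$representable)) {
    stop(sprintf(paste0(
      "strain '%s' is not representable in the Boolean framework ",
      "(graded temperature-sensitive/overexpression allele); refusing to ",
      "simulate it silently"), strain$name))
  }

  # Conflict detection: at most one non-knockout perturbation per target,
  # and no op/threshold change on a knocked-out node.
  tgt <- vapply(perts, function(p) p$target, character(1))
  kinds <- vapply(perts, function(p) p$kind, character(1))
  non_ko <- tgt[kinds != "knockout"]
  if (anyDuplicated(non_ko)) {
    stop(sprintf("conflicting perturbations on target '%s'",
                 non_ko[duplicated(non_ko)][1]))
  }
  ko_nodes <- tgt[kinds == "knockout"]
  clash <- intersect(ko_nodes, tgt[kinds %in% c("moderate_op", "high_op",
                                                "threshold_set")])
  if (length(clash)) {
    stop(sprintf("target '%s' is both knocked out and re-parameterized",
                 clash[1]))
  }

  m <- model
  for (p in perts) {
    if (p$kind == "knockout") {
      node <- resolve_node(m, p$target)
      m$clamped_off <- unique(c(m$clamped_off, node))
    } else if (p$kind %in% c("moderate_op", "high_op")) {
      node <- resolve_node(m, p$target)
      th <- if (is.null(p$value)) -0.5 else p$value
      i <- match(node, m$nodes$name)
      m$nodes$threshold[i] <- th
      if (p$kind == "high_op") {
        m$nodes$self_coupling[i] <- 1
      } else if (m$variant == "simplified" && m$nodes$self_coupling[i] > 0) {
        m$nodes$self_coupling[i] <- 0
      }
    } else if (p$kind == "threshold_set") {
      node <- resolve_node(m, p$target)
      m$nodes$threshold[match(node, m$nodes$name)] <- p$value
    } else if (p$kind == "link_reweight") {
      ends <- strsplit(p$target, "->", fixed = TRUE)[[1]]
      src <- resolve_node(m, ends[1])
      dst <- resolve_node(m, ends[2])
      hit <- which(m$edges$source == src & m$edges$target == dst)
      if (length(hit) == 0L) {
        stop(sprintf("no edge %s -> %s to reweight", src, dst))
      }
      m$edges$weight[hit] <- p$value * sign(m$edges$weight[hit])
    }
  }
  rebuild_matrix(m)
}

# Internal shorthand constructors for the catalog.
ko <- function(...) lapply(c(...), function(x) perturbation("knockout", x))
pyp3_reweight <- function(weight) {
  list(perturbation("link_reweight", "Cdc25->Cdc2_Tyr15", weight))
}
high_op <- function(node) list(perturbation("high_op", node))

#' The curated mutant strain catalog
#'
#' Returns the benchmark panel of 32 mutant strains (flag `in_table3`) with
#' their published model encodings and experimental viability/lethality
#' calls, plus model-prediction strains and the documented model failures
#' (flag `known_model_failure`). Special encodings:
#'
#' * `Wee1ts` in a combined strain is encoded as a knockout of Wee1/Mik1
#'   (Boolean states cannot express graded, reduced activity).
#' * `Cdc25del` defaults to a knockout of the Cdc25 node
#'   (`cdc25_encoding = "knockout"`); the alternative reading — Cdc25's
#'   weak backup phosphatase Pyp3 taking over via the `Cdc25->Cdc2_Tyr15`
#'   link reweighted to `pyp3_weight` — is available as
#'   `cdc25_encoding = "reweight"` and yields the same G2 arrest.
#' * `Pyp3del` is the link reweighted to `pyp3_weight` with everything else
#'   intact (Cdc25 still present, Pyp3's weak contribution gone is
#'   equivalent to the strong link alone, still above threshold).
#' * `Cdc2del` knocks out every Cdc2-containing complex node (all three
#'   start kinases, Cdc2/Cdc13) plus Cdc2_Tyr15.
#' * `Cdc13op` is moderate overexpression with threshold override -0.75
#'   (any value strictly between -1 and -0.5 below the default -0.5 is
#'   equivalent on the integer input lattice).
#'
#' Graded temperature-sensitive / overexpression alleles that the Boolean
#' framework cannot express (`Wee1ts` alone, `Cdc25ts`, `Pyp3op`, ...) are
#' included with `representable = FALSE` and no perturbations; they are
#' never simulated.
#'
#' @param pyp3_weight Weight of the `Cdc25->Cdc2_Tyr15` link standing in for
#'   the Pyp3 backup phosphatase; the dynamics are insensitive to the exact
#'   value in (0.5, 1). Default 0.75.
#' @param cdc25_encoding `"knockout"` or `"reweight"` (see above).
#' @return List of `bn_strain` objects.
#' @export
strain_catalog <- function(pyp3_weight = 0.75,
                           cdc25_encoding = c("knockout", "reweight")) {
  cdc25_encoding <- match.arg(cdc25_encoding)
  if (!is.finite(pyp3_weight) || pyp3_weight <= 0.5 || pyp3_weight >= 1) {
    stop("pyp3_weight must lie strictly between 0.5 and 1")
  }
  d <- function(...) paste0(c(...), DELTA, collapse = "")
  cdc25_del <- if (cdc25_encoding == "knockout") ko("Cdc25")
  else pyp3_reweight(pyp3_weight)

  t3 <- function(name, perts, real, note) {
    strain(name, perts, real, note, in_table3 = TRUE)
  }
  panel <- list(
    t3(d("Wee1"), ko("Wee1"), "VIABLE", "V"),
    t3(paste(d("Rum1"), d("Ste9"), d("Wee1")), ko("Ste9", "Rum1", "Wee1"),
       "LETHAL", "OSC, L"),
    t3(paste(d("Wee1"), d("Cdc25")),
       c(ko("Wee1"), pyp3_reweight(pyp3_weight)), "VIABLE", "V"),
    t3(d("Wee1", "Cdc25", "Pyp3"), ko("Wee1", "Cdc25"), "LETHAL", "G2, L"),
    t3("Wee1op", high_op("Wee1"), "LETHAL", "G2, L"),
    t3(d("Cdc25"), cdc25_del, "LETHAL", "G2, L"),
    t3(d("Pyp3"), pyp3_reweight(pyp3_weight), "VIABLE", "V"),
    t3("Wee1tsCdc25op", c(ko("Wee1"), high_op("Cdc25")), "LETHAL", "L"),
    t3(d("Ste9"), ko("Ste9"), "VIABLE", "V"),
    t3(d("Rum1"), ko("Rum1"), "VIABLE", "V"),
    t3("Rum1op", high_op("Rum1"), "LETHAL", "G2, L"),
    t3("Ste9op", high_op("Ste9"), "LETHAL", "ER, L"),
    t3(d("Slp1"), ko("Slp1"), "LETHAL", "M, L"),
    t3(d("Cdc13"), ko("Cdc13"), "LETHAL", "ER, L"),
    t3(d("Cig1"), ko("Cig1"), "VIABLE", "V"),
    t3(d("Cig2"), ko("Cig2"), "VIABLE", "V"),
    t3(d("Puc1"), ko("Puc1"), "VIABLE", "V"),
    t3(d("Cig1", "Cig2"), ko("Cig1", "Cig2"), "VIABLE", "V"),
    t3(d("Cig1", "Puc1"), ko("Cig1", "Puc1"), "VIABLE", "V"),
    t3(d("Cig2", "Puc1"), ko("Cig2", "Puc1"), "VIABLE", "V"),
    t3(paste0(d("Cig1"), "Wee1ts"), ko("Cig1", "Wee1"), "VIABLE", "V"),
    t3(paste0(d("Cig1", "Cig2"), "Wee1ts"), ko("Cig1", "Cig2", "Wee1"),
       "VIABLE", "V"),
    t3(paste0(d("Cig2"), "Wee1ts"), ko("Cig2", "Wee1"), "VIABLE", "V"),
    t3(paste0(d("Puc1"), "Wee1ts"), ko("Puc1", "Wee1"), "VIABLE", "V"),
    t3(d("Cig2", "Rum1"), ko("Cig2", "Rum1"), "VIABLE", "V"),
    t3(d("Ste9", "Cig2"), ko("Ste9", "Cig2"), "VIABLE", "V"),
    t3(d("Cdc2"), ko("Cig1", "Cig2", "Puc1", "Cdc13", "Tyr15"),
       "LETHAL", "L"),
    t3(d("Cdc13", "Cig1"), ko("Cdc13", "Cig1"), "LETHAL", "ER, L"),
    t3(d("Cdc13", "Cig2"), ko("Cdc13", "Cig2"), "LETHAL", "G1, L"),
    t3(d("Cdc13", "Cig1", "Puc1"), ko("Cdc13", "Cig1", "Puc1"),
       "LETHAL", "ER, L"),
    t3("Cdc13op", list(perturbation("moderate_op", "Cdc13", -0.75)),
       "VIABLE", "V"),
    t3(d("Cdc13", "Cig2", "Cig1"), ko("Cdc13", "Cig2", "Cig1"),
       "LETHAL", "L")
  )

  predictions <- list(
    strain(d("Cig1", "Rum1"), ko("Cig1", "Rum1"), "VIABLE",
           "model prediction; triple with Cig2 known viable"),
    strain(d("Puc1", "Rum1"), ko("Puc1", "Rum1"), "VIABLE",
           "model prediction"),
    strain(d("Cdc2", "Cdc13"),
           ko("Cig1", "Cig2", "Puc1", "Cdc13", "Tyr15"), "LETHAL",
           "model prediction")
  )

  failures <- list(
    strain(d("Rum1", "Wee1"), ko("Rum1", "Wee1"), "LETHAL",
           "divides too fast; cell-size effect outside the model",
           known_model_failure = TRUE),
    strain(d("Ste9", "Wee1"), ko("Ste9", "Wee1"), "LETHAL",
           "divides too fast; cell-size effect outside the model",
           known_model_failure = TRUE),
    strain(d("Ste9", "Rum1"), ko("Ste9", "Rum1"), "VIABLE",
           "start-kinase simplification breaks this strain",
           known_model_failure = TRUE),
    strain(d("Cig1", "Cig2", "Puc1"), ko("Cig1", "Cig2", "Puc1"), "VIABLE",
           "start-kinase simplification breaks this strain",
           known_model_failure = TRUE)
  )
  graded <- c("Wee1ts", "Cdc25ts", "Wee1tsCdc25ts",
              paste0(d("Ste9", "Rum1"), "Wee1ts"), "Slp1ts", "Pyp3op",
              "Cig2op", "Cdc25op")
  not_representable <- lapply(graded, function(nm) {
    strain(nm, list(), NA_character_,
           "graded ts/op allele; no Boolean encoding",
           known_model_failure = TRUE, representable = FALSE)
  })

  c(panel, predictions, failures, not_representable)
}

#' Write a strain table as TSV
#'
#' Columns: name, perturbation tokens (`kind:target[:value]`, comma
#' separated), experimental viability, note, flags.
#'
#' @param strains List of `bn_strain` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(strains, path) {
  df <- data.frame(
    name = vapply(strains, `[[`, character(1), "name"),
    perturbations = vapply(strains, function(s) {
      paste(vapply(s$perturbations, perturbation_token, character(1)),
            collapse = ",")
    }, character(1)),
    experimental_viability = vapply(strains, `[[`, character(1),
                                    "experimental_viability"),
    experimental_note = vapply(strains, `[[`, character(1),
                               "experimental_note"),
    in_table3 = vapply(strains, `[[`, logical(1), "in_table3"),
    known_model_failure = vapply(strains, `[[`, logical(1),
                                 "known_model_failure"),
    representable = vapply(strains, `[[`, logical(1), "representable"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a strain table written by [write_strain_table()]
#'
#' @param path TSV file path.
#' @return List of `bn_strain` objects.
#' @export
read_strain_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          na.strings = "NA", quote = "")
  lapply(seq_len(nrow(df)), function(i) {
    toks <- df$perturbations[i]
    perts <- if (is.na(toks) || !nzchar(toks)) list()
    else lapply(strsplit(toks, ",", fixed = TRUE)[[1]],
                parse_perturbation_token)
    strain(df$name[i], perts,
           experimental_viability = df$experimental_viability[i],
           experimental_note = if (is.na(df$experimental_note[i])) ""
           else df$experimental_note[i],
           in_table3 = df$in_table3[i],
           known_model_failure = df$known_model_failure[i],
           representable = df$representable[i])
  })
}

#' Look up a strain by name
#'
#' Matching ignores case and treats `"d"`/`"del"` as the deletion symbol, so
#' `"wee1d"` or `"Wee1del"` find the Wee1 deletion strain.
#'
#' @param name Strain name (exact or ASCII-normalized).
#' @param strains Catalog to search; default [strain_catalog()].
#' @return A `bn_strain`.
#' @export
find_strain <- function(name, strains = strain_catalog()) {
  norm <- function(x) {
    x <- gsub(DELTA, "d", x, fixed = TRUE)
    x <- gsub("del", "d", x, fixed = TRUE)
    tolower(gsub("[ _]", "", x))
  }
  nms <- vapply(strains, `[[`, character(1), "name")
  hit <- which(norm(nms) == norm(name))
  if (length(hit) != 1L) {
    stop(sprintf("unknown strain '%s'; available: %s", name,
                 paste(nms, collapse = ", ")), call. = FALSE)
  }
  strains[[hit]]
}
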