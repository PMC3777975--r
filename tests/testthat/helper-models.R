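# Shared fixtures for the test suite. Everything is built in code; no data
# files.

# Node order of the yeast model, used to spell states compactly.
pombe_nodes <- function() {
  c("Start", "Cdc2/Cig1", "Cdc2/Cig2", "Cdc2/Puc1", "Cdc2/Cdc13",
    "Cdc2_Tyr15", "Ste9", "Rum1", "Slp1", "Wee1/Mik1", "Cdc25", "PP")
}

# Build a 0/1 state vector over the yeast model from the ON-node names.
pombe_state <- function(...) {
  on <- c(...)
  as.integer(pombe_nodes() %in% on)
}

# The biological G1 stationary state (Ste9, Rum1, Wee1/Mik1 ON).
pombe_g1 <- function() pombe_state("Ste9", "Rum1", "Wee1/Mik1")

# Knockout perturbation list from short node aliases.
kos <- function(...) {
  lapply(c(...), function(x) perturbation("knockout", x))
}

# Two-node cross-inhibition toggle switch with self-activation: the
# classic bistable motif, small enough to enumerate by hand.
toggle_switch <- function() {
  nodes <- data.frame(name = c("A", "B"), threshold = 0, self_coupling = 1,
                      initial_on = c(TRUE, FALSE))
  edges <- data.frame(source = c("A", "B"), target = c("B", "A"),
                      weight = -1)
  bn_model(nodes, edges, variant = "simplified")
}
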