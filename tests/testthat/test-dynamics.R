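# The wild-type trajectory expected below was derived by hand application of
# the threshold update rule to the interaction matrix, step by step, and is
# frozen here as the reference sequence (it also matches the published
# narrative: start kinases at step 2, antagonists off at 3, moderate MPF at
# 4, Cdc25 at 5, Tyr15 at 6, mitosis trigger at 7, reset at 8-9, G1 at 10).
wt_expected_states <- function() {
  rbind(
    pombe_state("Start", "Ste9", "Rum1", "Wee1/Mik1"),
    pombe_state("Cdc2/Cig1", "Cdc2/Cig2", "Cdc2/Puc1", "Ste9", "Rum1",
                "Wee1/Mik1"),
    pombe_state("Wee1/Mik1"),
    pombe_state("Cdc2/Cdc13", "Wee1/Mik1"),
    pombe_state("Cdc2/Cdc13", "Cdc25"),
    pombe_state("Cdc2/Cdc13", "Cdc2_Tyr15", "Cdc25"),
    pombe_state("Cdc2/Cdc13", "Cdc2_Tyr15", "Slp1", "Cdc25"),
    pombe_state("Cdc2_Tyr15", "Slp1", "Cdc25", "PP"),
    pombe_state("Cdc2_Tyr15", "Ste9", "Rum1", "Wee1/Mik1", "PP"),
    pombe_state("Ste9", "Rum1", "Wee1/Mik1")
  )
}

test_that("successor implements the threshold rule on hand-checked states", {
  for (v in c("simplified", "threshold_memory")) {
    m <- build_pombe_model(v)
    # the G1 stationary state maps to itself
    expect_identical(successor(m, bn_state(pombe_g1()))$values, pombe_g1())
    # start kinases come on at step 2
    s2 <- successor(m, standard_initial_state(m))
    expect_identical(s2$values[2:4], c(1L, 1L, 1L))
    expect_identical(s2$time, 2L)
    # from the all-OFF state only Cdc2/Cdc13 activates (no inhibitor
    # contributes and 0 > -0.5)
    s <- successor(m, bn_state(rep(0, 12)))
    expect_identical(s$values, pombe_state("Cdc2/Cdc13"))
  }
})

test_that("successor is pure and rejects misaligned states", {
  m <- build_pombe_model("simplified")
  s <- bn_state(pombe_state("Start"))
  expect_identical(successor(m, s)$values, successor(m, s)$values)
  expect_identical(s$values, pombe_state("Start"))  # argument untouched
  expect_error(successor(m, bn_state(c(0, 1))), "12 nodes")
})

test_that("wild-type simulation reproduces the 10-step sequence", {
  for (v in c("simplified", "threshold_memory")) {
    tr <- simulate_trajectory(build_pombe_model(v))
    expect_identical(tr$attractor_kind, "FIXED_POINT")
    expect_identical(tr$attractor_entry_step, 10L)
    expect_identical(tr$first_revisit_step, 11L)
    expect_identical(tr$cycle_period, 1L)
    expect_identical(unname(trajectory_states(tr)), wt_expected_states())
    expect_identical(unname(attractor_states(tr)[1, ]), pombe_g1())
  }
})

test_that("Slp1 deletion freezes the trajectory at step 6", {
  m <- apply_perturbations(build_pombe_model("simplified"), kos("Slp1"))
  tr <- simulate_trajectory(m)
  expect_identical(tr$attractor_kind, "FIXED_POINT")
  expect_identical(tr$attractor_entry_step, 6L)
  # coincides with the wild type until the mitosis trigger fails
  expect_identical(unname(trajectory_states(tr)), wt_expected_states()[1:6, ])
})

test_that("the antagonist triple knockout oscillates with period 6", {
  m <- apply_perturbations(build_pombe_model("simplified"),
                           kos("Ste9", "Rum1", "Wee1"))
  tr <- simulate_trajectory(m)
  expect_identical(tr$attractor_kind, "LIMIT_CYCLE")
  expect_identical(tr$cycle_period, 6L)
  # earliest revisit: step 9 repeats step 3 ...
  expect_identical(tr$first_revisit_step, 9L)
  expect_identical(tr$first_revisit_step - tr$cycle_period, 3L)
  expect_identical(tr$states[9L, ], tr$states[3L, ])
  # ... and, one step later, step 10 repeats step 4 (the published pair)
  expect_identical(first_recurrence_of_step(tr, 4L), 10L)
})

test_that("trajectories always revisit within 2^n + 1 steps", {
  for (seed in 1:12) {
    m <- generate_random_network(n_nodes = 3 + seed %% 6, edge_density = 0.4,
                                 seed = seed)
    tr <- simulate_trajectory(m, bn_state(rep(0, nrow(m$nodes))))
    expect_lte(tr$first_revisit_step, 2^nrow(m$nodes) + 1)
    expect_false(tr$attractor_kind == "NONE")
  }
})

test_that("exhausting max_steps yields attractor_kind NONE with a warning", {
  m <- build_pombe_model("simplified")
  expect_warning(tr <- simulate_trajectory(m, max_steps = 3), "max_steps")
  expect_identical(tr$attractor_kind, "NONE")
})

test_that("trivial state spaces enumerate exactly", {
  # single isolated node, theta = 0, simplified: 0 > 0 is false from both
  # start states, so all-OFF is the unique fixed point with basin 2
  m1 <- bn_model(data.frame(name = "a", threshold = 0, self_coupling = 0,
                            initial_on = TRUE), variant = "simplified")
  rep1 <- enumerate_attractors(m1, trigger = NULL)
  expect_length(rep1$attractors, 1L)
  expect_identical(rep1$attractors[[1]]$kind, "FIXED_POINT")
  expect_identical(unname(rep1$attractors[[1]]$states[1, ]), 0L)
  expect_identical(rep1$attractors[[1]]$basin_size, 2L)

  # the self-activating toggle switch is bistable: fixed points 10 and 01,
  # plus the decayed 00 state collecting 00 and 11 (enumerated by hand)
  rep2 <- enumerate_attractors(toggle_switch(), trigger = NULL)
  expect_length(rep2$attractors, 3L)
  states <- sort(vapply(rep2$attractors,
                        function(a) paste(a$states[1, ], collapse = ""),
                        character(1)))
  expect_identical(states, c("00", "01", "10"))
  basins <- vapply(rep2$attractors, `[[`, integer(1), "basin_size")
  expect_identical(sort(basins), c(1L, 1L, 2L))
})

test_that("wild-type landscape: 13 attractors, 15 stationary states, G1 dominant", {
  for (v in c("simplified", "threshold_memory")) {
    rep <- enumerate_attractors(build_pombe_model(v))
    expect_identical(rep$total_states, 4096)
    expect_length(rep$attractors, 13L)
    expect_identical(rep$n_stationary_states, 15L)
    kinds <- vapply(rep$attractors, `[[`, character(1), "kind")
    expect_identical(sum(kinds == "LIMIT_CYCLE"), 1L)
    top <- rep$attractors[[1]]
    expect_identical(unname(top$states[1, ]), pombe_g1())
    expect_identical(top$basin_size, 3220L)
    expect_identical(top$resting_basin_size, 1571L)
    expect_identical(top$resting_basin_percent, 77)
  }
})

test_that("basins partition the state space and attractors self-map", {
  models <- list(build_pombe_model("simplified"), toggle_switch())
  for (seed in 1:5) {
    models[[length(models) + 1]] <-
      generate_random_network(n_nodes = 6, edge_density = 0.35, seed = seed)
  }
  for (m in models) {
    rep <- enumerate_attractors(m)
    basins <- vapply(rep$attractors, `[[`, integer(1), "basin_size")
    expect_identical(sum(basins), as.integer(rep$total_states))
    # attractor state sets are pairwise disjoint
    keys <- unlist(lapply(rep$attractors, function(a)
      apply(a$states, 1, paste, collapse = "")))
    expect_false(anyDuplicated(keys) > 0)
    # every attractor state maps to the next state of its cycle
    for (a in rep$attractors) {
      k <- nrow(a$states)
      for (i in seq_len(k)) {
        nxt <- successor(m, bn_state(a$states[i, ]))$values
        expect_identical(unname(nxt), unname(a$states[i %% k + 1L, ]))
      }
    }
  }
})

test_that("enumeration agrees with the brute-force oracle", {
  m <- build_pombe_model("simplified")
  expect_identical(pombeBN:::canonical_attractor_set(enumerate_attractors(m)),
                   pombeBN:::canonical_attractor_set(state_space_oracle(m)))
  o <- state_space_oracle(m)
  expect_identical(o$n_stationary_states, 15L)
  expect_identical(o$attractors[[1]]$resting_basin_percent, 77)
})

test_that("enumeration refuses oversized state spaces with guidance", {
  big <- bn_model(sprintf("n%02d", 1:26))
  expect_error(enumerate_attractors(big), "cap")
  expect_error(state_space_oracle(big), "16")
})

test_that("trajectory export has one row per step and drops the revisit row", {
  tr <- simulate_trajectory(build_pombe_model("simplified"))
  df <- as.data.frame(tr)
  expect_identical(nrow(df), 10L)
  expect_identical(names(df)[1], "time")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
  expect_identical(nrow(back), 10L)
  expect_identical(as.integer(back[10, -1]), pombe_g1())
  # stable under re-run (no timestamps)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path2)
  expect_identical(readLines(path), readLines(path2))
})
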