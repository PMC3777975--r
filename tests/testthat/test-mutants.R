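test_that("perturbation constructors enforce their contracts", {
  expect_error(perturbation("knockout", "Slp1", value = 1), "no value")
  expect_error(perturbation("link_reweight", "Cdc25->Cdc2_Tyr15", 1.5),
               "in \\(0, 1\\]")
  expect_error(perturbation("link_reweight", "Cdc25", 0.75), "source->target")
  expect_error(perturbation("threshold_set", "Slp1"), "finite")
  expect_s3_class(perturbation("knockout", "Slp1"), "bn_perturbation")
})

test_that("apply_perturbations never mutates its input", {
  m <- build_pombe_model("simplified")
  W0 <- m$W
  th0 <- m$threshold
  m2 <- apply_perturbations(m, kos("Wee1", "Slp1"))
  expect_identical(m$W, W0)
  expect_identical(m$threshold, th0)
  expect_length(m$clamped_off, 0L)
  expect_setequal(m2$clamped_off, c("Wee1/Mik1", "Slp1"))
  # empty strain returns an equivalent model
  m3 <- apply_perturbations(m, list())
  expect_identical(m3$W, m$W)
  expect_identical(m3$nodes, m$nodes)
})

test_that("knockouts are idempotent and commute", {
  m <- build_pombe_model("simplified")
  once <- apply_perturbations(m, kos("Slp1"))
  twice <- apply_perturbations(once, kos("Slp1"))
  expect_identical(model_hash(once), model_hash(twice))

  perms <- list(c("Ste9", "Rum1", "Wee1"), c("Wee1", "Ste9", "Rum1"),
                c("Rum1", "Wee1", "Ste9"))
  hashes <- vapply(perms, function(p) model_hash(apply_perturbations(m, kos(p))),
                   character(1))
  expect_length(unique(hashes), 1L)
})

test_that("overexpression encodings follow the published scheme", {
  for (v in c("simplified", "threshold_memory")) {
    m <- build_pombe_model(v)
    hi <- apply_perturbations(m, list(perturbation("high_op", "Wee1")))
    i <- match("Wee1/Mik1", hi$nodes$name)
    expect_equal(hi$nodes$threshold[i], -0.5)
    expect_equal(hi$nodes$self_coupling[i], 1)
    expect_equal(hi$W[i, i], 1)

    mo <- apply_perturbations(m, list(perturbation("moderate_op", "Rum1")))
    j <- match("Rum1", mo$nodes$name)
    expect_equal(mo$nodes$threshold[j], -0.5)
    # under the simplified variant the default +1 bookkeeping coupling is
    # cleared so that moderate overexpression stays moderate
    expect_equal(mo$nodes$self_coupling[j], 0)
  }
  # threshold override, e.g. the moderate Cdc13 overexpression at -0.75
  m <- build_pombe_model("simplified")
  op <- apply_perturbations(m, list(perturbation("moderate_op", "Cdc13",
                                                 -0.75)))
  expect_equal(unname(op$threshold[["Cdc2/Cdc13"]]), -0.75)
})

test_that("link reweighting replaces exactly one edge weight", {
  m <- build_pombe_model("simplified")
  rw <- apply_perturbations(
    m, list(perturbation("link_reweight", "Cdc25->Cdc2_Tyr15", 0.75)))
  expect_equal(rw$W["Cdc2_Tyr15", "Cdc25"], 0.75)
  expect_identical(rw$W[-match("Cdc2_Tyr15", rownames(rw$W)), ],
                   m$W[-match("Cdc2_Tyr15", rownames(m$W)), ])
  expect_error(
    apply_perturbations(m, list(perturbation("link_reweight", "PP->Slp1",
                                             0.75))),
    "no edge")
})

test_that("conflicting or invalid perturbation sets are rejected", {
  m <- build_pombe_model("simplified")
  expect_error(apply_perturbations(m, kos("NoSuchNode")), "unknown node")
  expect_error(
    apply_perturbations(m, list(perturbation("moderate_op", "Rum1"),
                                perturbation("high_op", "Rum1"))),
    "conflicting")
  expect_error(
    apply_perturbations(m, list(perturbation("knockout", "Rum1"),
                                perturbation("high_op", "Rum1"))),
    "knocked out")
})

test_that("clamped nodes are OFF at every step from the first update on", {
  base <- build_pombe_model("simplified")
  for (target in c("Wee1", "Ste9", "Slp1", "Cdc13")) {
    m <- apply_perturbations(base, kos(target))
    tr <- simulate_trajectory(m)
    i <- match(resolve_node(m, target), m$nodes$name)
    expect_true(all(tr$states[-1L, i] == 0L))
  }
})

test_that("the catalog ships 32 benchmark strains with exact encodings", {
  cat <- strain_catalog()
  panel <- Filter(function(s) s$in_table3, cat)
  expect_length(panel, 32L)
  expect_true(all(!vapply(panel, `[[`, logical(1), "known_model_failure")))

  nm <- vapply(cat, `[[`, character(1), "name")
  triple <- cat[[grep("Rum1.*Ste9.*Wee1", nm)[1]]]
  expect_length(triple$perturbations, 3L)
  expect_true(all(vapply(triple$perturbations, `[[`, character(1), "kind") ==
                    "knockout"))
  expect_identical(triple$experimental_viability, "LETHAL")

  cdc13op <- find_strain("Cdc13op", cat)
  expect_identical(cdc13op$perturbations[[1]]$kind, "moderate_op")
  expect_equal(cdc13op$perturbations[[1]]$value, -0.75)
  expect_gt(cdc13op$perturbations[[1]]$value, -1)
  expect_lt(cdc13op$perturbations[[1]]$value, -0.5)

  # every representable catalog strain yields a structurally valid model
  base <- build_pombe_model("simplified")
  for (s in cat) {
    if (!s$representable) next
    expect_length(validate_model(apply_perturbations(base, s)), 0L)
  }
})

test_that("non-representable graded alleles refuse to simulate silently", {
  cat <- strain_catalog()
  wee1ts <- find_strain("Wee1ts", cat)
  expect_false(wee1ts$representable)
  expect_error(apply_perturbations(build_pombe_model("simplified"), wee1ts),
               "not representable")
})

test_that("strain tables round-trip through TSV", {
  cat <- strain_catalog()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_strain_table(cat, path)
  back <- read_strain_table(path)
  expect_length(back, length(cat))
  for (i in seq_along(cat)) {
    expect_identical(back[[i]]$name, cat[[i]]$name)
    expect_identical(back[[i]]$experimental_viability,
                     cat[[i]]$experimental_viability)
    expect_identical(back[[i]]$in_table3, cat[[i]]$in_table3)
    expect_identical(
      vapply(back[[i]]$perturbations, pombeBN:::perturbation_token,
             character(1)),
      vapply(cat[[i]]$perturbations, pombeBN:::perturbation_token,
             character(1)))
  }
})

test_that("find_strain accepts ASCII-normalized names", {
  s <- find_strain("wee1d cdc25d")
  expect_length(s$perturbations, 2L)
  expect_error(find_strain("not-a-strain"), "unknown strain")
})
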