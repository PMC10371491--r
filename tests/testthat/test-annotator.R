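test_that("a one-reaction-per-class model yields six assignments with six distinct rules", {
  doc <- six_class_doc()
  ann <- annotate_model(doc, tcfg)
  rx <- ann$assignments[ann$assignments$entity_kind == "reaction", ]
  expect_equal(nrow(rx), 6L)
  expect_equal(length(unique(rx$rule)), 6L)
  expect_equal(sort(unname(ann$classes)),
               sort(c("EXCHANGE", "DEMAND", "SINK", "BIOMASS", "TRANSPORT",
                      "BIOCHEMICAL")))
})

test_that("a ligase-annotated reaction receives the covalent-bond-formation term", {
  doc <- model_doc(
    compartments = "c",
    species = data.frame(id = c("a_c", "b_c"), compartment = "c"),
    reactions = list(list(id = "LIG", reactants = c(a_c = 1),
                          products = c(b_c = 1), ec = "6.3.2.4")))
  ann <- annotate_model(doc, tcfg)
  expect_equal(
    ann$assignments$sbo_id[ann$assignments$entity_id == "LIG"], 695L)
})

test_that("a model whose reactions all end generic reports fraction 1", {
  doc <- model_doc(
    compartments = "c",
    species = data.frame(id = c("a_c", "b_c"), compartment = "c"),
    reactions = list(
      list(id = "R1", reactants = c(a_c = 1), products = c(b_c = 1)),
      list(id = "R2", reactants = c(b_c = 1), products = c(a_c = 1))))
  ann <- annotate_model(doc, tcfg)
  expect_equal(ann$report$generic_reaction_fraction, 1.0)
})

test_that("modifiers are enzymatic catalysts only on EC-backed reactions", {
  mk <- function(ec, mods) {
    model_doc(compartments = "c",
              species = data.frame(id = c("a_c", "b_c", "enz_c"),
                                   compartment = "c"),
              reactions = list(list(id = "R1", reactants = c(a_c = 1),
                                    products = c(b_c = 1), ec = ec,
                                    modifiers = mods)))$reactions$R1
  }
  with_ec <- annotate_modifiers(mk("2.6.1.1", "enz_c"), tcfg)
  expect_equal(nrow(with_ec), 1L)
  expect_equal(with_ec$entity_id, "R1:enz_c")
  expect_equal(with_ec$sbo_id, tcfg$ids[["modifier_enzymatic"]])
  expect_equal(with_ec$rule, "modifier-enzymatic-catalyst")
  expect_equal(nrow(annotate_modifiers(mk(character(0), "enz_c"), tcfg)), 0L)
  expect_equal(nrow(annotate_modifiers(mk("2.6.1.1", character(0)), tcfg)), 0L)
})

test_that("species and genes receive their configured entity terms", {
  p <- build_fixture(fixture_spec("ent", c("BIOCHEMICAL")), dir = tempfile())
  ann <- annotate_model(load_model(p), tcfg)
  spa <- ann$assignments[ann$assignments$entity_kind == "species", ]
  expect_true(all(spa$sbo_id == tcfg$ids[["species"]]))
  ga <- ann$assignments[ann$assignments$entity_kind == "gene", ]
  expect_equal(nrow(ga), 2L)
  expect_true(all(ga$sbo_id == tcfg$ids[["gene"]]))
})

test_that("more specific pre-existing terms are preserved, unless forced", {
  doc <- model_doc(
    compartments = "c",
    species = data.frame(id = c("a_c", "b_c"), compartment = "c"),
    reactions = list(list(id = "R1", reactants = c(a_c = 1),
                          products = c(b_c = 1), existing_sbo = 214L)))
  kept <- annotate_model(doc, tcfg, preserve_existing = TRUE)
  expect_equal(kept$assignments$sbo_id[kept$assignments$entity_id == "R1"],
               214L)
  expect_equal(kept$assignments$rule[kept$assignments$entity_id == "R1"],
               "preserved-existing")
  forced <- annotate_model(doc, tcfg, preserve_existing = FALSE)
  expect_equal(forced$assignments$sbo_id[forced$assignments$entity_id == "R1"],
               176L)
  # an existing *less* specific term is always replaced
  doc$reactions$R1$existing_sbo <- 375L
  up <- annotate_model(doc, tcfg, preserve_existing = TRUE)
  expect_equal(up$assignments$sbo_id[up$assignments$entity_id == "R1"], 176L)
})

test_that("assigned reaction terms sit under their class top-level terms", {
  doc <- load_model(full_fixture())
  ann <- annotate_model(doc, tcfg)
  tops <- c(EXCHANGE = 627L, DEMAND = 628L, SINK = 632L, BIOMASS = 629L,
            TRANSPORT = 655L, BIOCHEMICAL = 176L)
  rx <- ann$assignments[ann$assignments$entity_kind == "reaction", ]
  for (i in seq_len(nrow(rx))) {
    cls <- ann$classes[[rx$entity_id[i]]]
    expect_true(sbo_is_a(tcfg$graph, rx$sbo_id[i], tops[[cls]]),
                info = rx$entity_id[i])
  }
})

test_that("annotation is deterministic and idempotent end to end", {
  p <- full_fixture()
  doc <- load_model(p)
  a1 <- annotate_model(doc, tcfg)
  a2 <- annotate_model(doc, tcfg)
  expect_identical(a1$assignments, a2$assignments)
  out <- apply_and_save(doc, a1$assignments, out_dir = tempfile())
  again <- annotate_model(load_model(out), tcfg)
  expect_identical(a1$assignments, again$assignments)
})

test_that("after saving, no reaction, species or gene lacks an sboTerm", {
  doc <- load_model(full_fixture())
  out <- apply_and_save(doc, annotate_model(doc, tcfg)$assignments,
                        out_dir = tempfile())
  re <- load_model(out)
  expect_false(anyNA(vapply(re$reactions, function(r) r$existing_sbo,
                            integer(1))))
  expect_false(anyNA(re$species$existing_sbo))
  expect_false(anyNA(re$genes$existing_sbo))
})

test_that("coverage comparison reports the generic fraction pair", {
  mk <- function(sbos) model_doc(
    compartments = "c",
    species = data.frame(id = "a_c", compartment = "c"),
    reactions = lapply(seq_along(sbos), function(i)
      list(id = sprintf("R%02d", i), reactants = c(a_c = 1),
           existing_sbo = sbos[i])))
  before <- mk(rep(176L, 10))
  after <- mk(c(rep(214L, 8), rep(176L, 2)))
  cr <- coverage_report(before, after)
  expect_equal(cr$generic_fraction_before, 1.0)
  expect_equal(cr$generic_fraction_after, 0.2)
  expect_equal(sort(cr$histogram$sbo_id), c(176L, 214L))

  same <- coverage_report(before, before)
  expect_equal(same$generic_fraction_before, same$generic_fraction_after)

  other <- mk(rep(176L, 9))
  expect_error(coverage_report(before, other), "entity sets")
})
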