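triage_of <- function(doc, id) as.character(triage_reaction(doc$reactions[[id]], doc))

test_that("the canonical examples triage to their classes", {
  doc <- model_doc(
    compartments = c("c", "e"),
    species = data.frame(
      id = c("o2_e", "glc__D_e", "pep_c", "g6p_c", "pyr_c", "f6p_c",
             "amob_c", "bm_c"),
      compartment = c("e", "e", "c", "c", "c", "c", "c", "c"),
      stringsAsFactors = FALSE),
    reactions = list(
      list(id = "EX_o2_e", reactants = c(o2_e = 1), reversible = TRUE),
      list(id = "R_BIOMASS", reactants = c(pyr_c = 1), products = c(bm_c = 1),
           objective = TRUE),
      list(id = "GLCpts", reactants = c(glc__D_e = 1, pep_c = 1),
           products = c(g6p_c = 1, pyr_c = 1)),
      list(id = "PGI", reactants = c(g6p_c = 1), products = c(f6p_c = 1),
           reversible = TRUE),
      list(id = "DM_amob_c", reactants = c(amob_c = 1))))
  expect_equal(triage_of(doc, "EX_o2_e"), "EXCHANGE")
  expect_equal(triage_of(doc, "R_BIOMASS"), "BIOMASS")
  expect_equal(triage_of(doc, "GLCpts"), "TRANSPORT")
  expect_equal(triage_of(doc, "PGI"), "BIOCHEMICAL")
  expect_equal(triage_of(doc, "DM_amob_c"), "DEMAND")
})

test_that("a reaction with no participants on either side is a classification error", {
  doc <- model_doc(compartments = "c",
                   species = data.frame(id = "x_c", compartment = "c"),
                   reactions = list(list(id = "NOTHING")))
  expect_error(triage_reaction(doc$reactions$NOTHING, doc), "degenerate")
})

test_that("biomass precedence beats one-sidedness and compartment span", {
  doc <- model_doc(
    compartments = c("c", "e"),
    species = data.frame(id = c("a_c", "b_e"), compartment = c("c", "e"),
                         stringsAsFactors = FALSE),
    reactions = list(
      list(id = "BIOMASS_span", reactants = c(a_c = 1), products = c(b_e = 1)),
      list(id = "Growth_drain", name = "Biomass drain",
           reactants = c(a_c = 1))))
  expect_equal(triage_of(doc, "BIOMASS_span"), "BIOMASS")
  expect_equal(triage_of(doc, "Growth_drain"), "BIOMASS")
})

test_that("an exchange reaction is recognized without the EX_ prefix", {
  # structural twin of an EX_ reaction: sole species in the extracellular
  # compartment (identified from the prefixed sibling)
  doc <- model_doc(
    compartments = c("c", "e"),
    species = data.frame(id = c("o2_e", "co2_e"), compartment = c("e", "e"),
                         stringsAsFactors = FALSE),
    reactions = list(
      list(id = "EX_o2_e", reactants = c(o2_e = 1), reversible = TRUE),
      list(id = "CO2out", reactants = c(co2_e = 1), reversible = TRUE)))
  expect_equal(triage_of(doc, "EX_o2_e"), "EXCHANGE")
  expect_equal(triage_of(doc, "CO2out"), "EXCHANGE")
})

test_that("sink and demand split on prefixes first, then reversibility", {
  doc <- model_doc(
    compartments = "c",
    species = data.frame(id = c("a_c", "b_c", "d_c", "e_c"),
                         compartment = "c", stringsAsFactors = FALSE),
    reactions = list(
      list(id = "SK_a_c", reactants = c(a_c = 1)),            # prefix wins
      list(id = "DM_b_c", reactants = c(b_c = 1), reversible = TRUE),
      list(id = "DRAIN1", reactants = c(d_c = 1), reversible = TRUE),
      list(id = "DRAIN2", reactants = c(e_c = 1))))
  expect_equal(triage_of(doc, "SK_a_c"), "SINK")
  expect_equal(triage_of(doc, "DM_b_c"), "DEMAND")
  expect_equal(triage_of(doc, "DRAIN1"), "SINK")
  expect_equal(triage_of(doc, "DRAIN2"), "DEMAND")
})

test_that("reversing the sides of a transport reaction never changes its class", {
  doc <- model_doc(
    compartments = c("c", "e"),
    species = data.frame(id = c("x_e", "x_c"), compartment = c("e", "c"),
                         stringsAsFactors = FALSE),
    reactions = list(
      list(id = "Xt", reactants = c(x_e = 1), products = c(x_c = 1)),
      list(id = "Xt_rev", reactants = c(x_c = 1), products = c(x_e = 1))))
  expect_equal(triage_of(doc, "Xt"), "TRANSPORT")
  expect_equal(triage_of(doc, "Xt_rev"), "TRANSPORT")
})

test_that("partition is total and disjoint on randomized models", {
  for (seed in 1:40) {
    doc <- random_model_doc(seed, n_reactions = 3L + seed %% 10L)
    buckets <- partition_model(doc)
    all_ids <- unlist(buckets, use.names = FALSE)
    expect_setequal(all_ids, names(doc$reactions))
    expect_equal(anyDuplicated(all_ids), 0L, info = paste("seed", seed))
  }
})

test_that("an empty model partitions into empty buckets", {
  doc <- model_doc(compartments = "c",
                   species = data.frame(id = character(0),
                                        compartment = character(0)),
                   reactions = list())
  buckets <- partition_model(doc)
  expect_named(buckets, sbotagger:::REACTION_CLASSES)
  expect_true(all(lengths(buckets) == 0L))
})
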