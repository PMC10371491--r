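# builds a two-compartment doc around a single reaction
tdoc <- function(reaction, species_df) {
  model_doc(compartments = unique(c("c", "e", species_df$compartment)),
            species = species_df, reactions = list(reaction))
}

sp <- function(...) {
  ids <- c(...)
  data.frame(id = ids,
             compartment = sub("^.*_", "", ids),
             stringsAsFactors = FALSE)
}

type_of <- function(doc) {
  as.character(classify_transport(doc$reactions[[1L]], doc, tcfg))
}

test_that("translocation events pair base species across compartments", {
  doc <- tdoc(list(id = "O2t", reactants = c(o2_e = 1),
                   products = c(o2_c = 1)), sp("o2_e", "o2_c"))
  ev <- translocation_events(doc$reactions$O2t, doc)
  expect_equal(ev$base_id, "o2")
  expect_equal(ev$from_compartment, "e")
  expect_equal(ev$to_compartment, "c")

  # PTS: phosphorylation changes identity, so nothing crosses intact
  doc <- tdoc(list(id = "GLCpts", reactants = c(glc__D_e = 1, pep_c = 1),
                   products = c(g6p_c = 1, pyr_c = 1)),
              sp("glc__D_e", "pep_c", "g6p_c", "pyr_c"))
  expect_equal(nrow(translocation_events(doc$reactions$GLCpts, doc)), 0L)

  doc <- tdoc(list(id = "PROt4", reactants = c(na1_e = 1, pro__L_e = 1),
                   products = c(na1_c = 1, pro__L_c = 1)),
              sp("na1_e", "pro__L_e", "na1_c", "pro__L_c"))
  ev <- translocation_events(doc$reactions$PROt4, doc)
  expect_equal(ev$base_id, c("na1", "pro__L"))
  expect_equal(ev$to_compartment, c("c", "c"))
})

test_that("the five mechanism archetypes classify as expected", {
  expect_equal(type_of(tdoc(list(id = "O2t", reactants = c(o2_e = 1),
                                 products = c(o2_c = 1), reversible = TRUE),
                            sp("o2_e", "o2_c"))), "PASSIVE")
  expect_equal(type_of(tdoc(
    list(id = "GLCabc", reactants = c(atp_c = 1, h2o_c = 1, glc__D_e = 1),
         products = c(adp_c = 1, pi_c = 1, h_c = 1, glc__D_c = 1)),
    sp("atp_c", "h2o_c", "glc__D_e", "adp_c", "pi_c", "h_c", "glc__D_c"))),
    "ACTIVE_ATP")
  expect_equal(type_of(tdoc(
    list(id = "GLCpts", reactants = c(glc__D_e = 1, pep_c = 1),
         products = c(g6p_c = 1, pyr_c = 1)),
    sp("glc__D_e", "pep_c", "g6p_c", "pyr_c"))), "ACTIVE_PEP")
  expect_equal(type_of(tdoc(
    list(id = "PROt4", reactants = c(na1_e = 1, pro__L_e = 1),
         products = c(na1_c = 1, pro__L_c = 1)),
    sp("na1_e", "pro__L_e", "na1_c", "pro__L_c"))), "SYMPORT")
  expect_equal(type_of(tdoc(
    list(id = "CAt6", reactants = c(ca2_c = 1, h_e = 1),
         products = c(ca2_e = 1, h_c = 1)),
    sp("ca2_c", "h_e", "ca2_e", "h_c"))), "ANTIPORT")
})

test_that("energy coupling takes precedence over co-transport patterns", {
  # ATP hydrolysis plus antiport-shaped events: the ATP signal wins
  doc <- tdoc(list(
    id = "PUMP", reactants = c(atp_c = 1, na1_e = 1, k_c = 1),
    products = c(adp_c = 1, pi_c = 1, na1_c = 1, k_e = 1)),
    sp("atp_c", "na1_e", "k_c", "adp_c", "pi_c", "na1_c", "k_e"))
  expect_equal(type_of(doc), "ACTIVE_ATP")
})

test_that("a kinase spanning compartments is not mistaken for ATP transport", {
  # consumes atp, but no pi product: not the hydrolysis couple
  doc <- tdoc(list(id = "HEXK", reactants = c(atp_c = 1, glcx_e = 1),
                   products = c(adp_c = 1, g6px_c = 1)),
              sp("atp_c", "glcx_e", "adp_c", "g6px_c"))
  expect_false(type_of(doc) == "ACTIVE_ATP")
})

test_that("protons count as translocation events", {
  # proton uniport with nothing else: passive
  doc <- tdoc(list(id = "Ht", reactants = c(h_e = 1), products = c(h_c = 1),
                   reversible = TRUE), sp("h_e", "h_c"))
  expect_equal(type_of(doc), "PASSIVE")
  # substrate plus co-transported proton: symport
  doc <- tdoc(list(id = "LACt2", reactants = c(lac__D_e = 1, h_e = 1),
                   products = c(lac__D_c = 1, h_c = 1)),
              sp("lac__D_e", "h_e", "lac__D_c", "h_c"))
  expect_equal(type_of(doc), "SYMPORT")
})

test_that("spanning reactions with no crossing species are generic", {
  doc <- tdoc(list(id = "ALAGLYt", reactants = c(ala__L_e = 1),
                   products = c(gly_c = 1)), sp("ala__L_e", "gly_c"))
  expect_equal(type_of(doc), "GENERIC")
})

test_that("swapping sides preserves passive, symport and antiport types", {
  cases <- list(
    list(r = c(o2_e = 1), p = c(o2_c = 1), ids = c("o2_e", "o2_c"),
         type = "PASSIVE"),
    list(r = c(na1_e = 1, pro__L_e = 1), p = c(na1_c = 1, pro__L_c = 1),
         ids = c("na1_e", "pro__L_e", "na1_c", "pro__L_c"),
         type = "SYMPORT"),
    list(r = c(ca2_c = 1, h_e = 1), p = c(ca2_e = 1, h_c = 1),
         ids = c("ca2_c", "h_e", "ca2_e", "h_c"), type = "ANTIPORT"))
  for (cs in cases) {
    fwd <- tdoc(list(id = "T", reactants = cs$r, products = cs$p),
                sp(cs$ids))
    rev <- tdoc(list(id = "T", reactants = cs$p, products = cs$r),
                sp(cs$ids))
    expect_equal(type_of(fwd), cs$type)
    expect_equal(type_of(rev), cs$type)
  }
})

test_that("classifying a non-transport reaction is a contract violation", {
  doc <- model_doc(compartments = "c",
                   species = data.frame(id = c("a_c", "b_c"),
                                        compartment = "c"),
                   reactions = list(list(id = "R1", reactants = c(a_c = 1),
                                         products = c(b_c = 1))))
  expect_error(classify_transport(doc$reactions$R1, doc, tcfg),
               "non-transport")
})
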