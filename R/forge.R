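## Fixture forge: deterministic miniature BiGG-style SBML models covering
## every classification branch, plus in-memory random model/ontology
## generators for property testing. Everything is generated from code; no
## binary or downloaded fixtures exist anywhere in the package.

#' Build an in-memory model document
#'
#' Programmatic constructor for the same record structure [load_model()]
#' produces, without touching disk. Used by the random-model generator and
#' handy for constructing single-reaction examples. Documents built this way
#' cannot be serialized (no backing file).
#'
#' @param model_id Model identifier.
#' @param compartments Character vector of compartment ids, or data.frame
#'   `(id, name)`.
#' @param species data.frame with columns `id`, `compartment` and optionally
#'   `is_boundary`, `name`, `existing_sbo`.
#' @param reactions List of lists with elements `id`, `reactants` /
#'   `products` (named numeric vectors, species id -> stoichiometry; may be
#'   empty), and optionally `reversible`, `modifiers`, `ec`, `objective`,
#'   `name`, `existing_sbo`.
#' @return An `sbml_model` (with `path = NULL`).
#' @export
model_doc <- function(model_id = "model", compartments, species, reactions) {
  if (is.character(compartments))
    compartments <- data.frame(id = compartments, name = NA_character_,
                               stringsAsFactors = FALSE)
  n_sp <- nrow(species)
  species$name <- if (is.null(species$name)) rep(NA_character_, n_sp) else
    species$name
  species$is_boundary <- if (is.null(species$is_boundary))
    rep(FALSE, n_sp) else species$is_boundary
  species$existing_sbo <- if (is.null(species$existing_sbo))
    rep(NA_integer_, n_sp) else as.integer(species$existing_sbo)
  species$base_id <- strip_compartment_suffix(species$id, species$compartment)
  stopifnot(all(species$compartment %in% compartments$id))
  rxns <- list()
  obj <- character(0)
  for (r in reactions) {
    side <- function(v) data.frame(
      species = names(v) %||% character(0),
      stoichiometry = as.numeric(v), stringsAsFactors = FALSE)
    rec <- structure(list(
      id = r$id,
      name = r$name %||% NA_character_,
      reversible = isTRUE(r$reversible),
      reactants = side(r$reactants %||% numeric(0)),
      products = side(r$products %||% numeric(0)),
      modifiers = r$modifiers %||% character(0),
      ec_numbers = ec_normalize_chr(r$ec %||% character(0)),
      existing_sbo = as.integer(r$existing_sbo %||% NA_integer_),
      is_objective = isTRUE(r$objective)
    ), class = "reaction_record")
    miss <- setdiff(c(rec$reactants$species, rec$products$species,
                      rec$modifiers), species$id)
    if (length(miss))
      stop("reaction ", r$id, " references unknown species: ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (rec$is_objective) obj <- c(obj, r$id)
    rxns[[r$id]] <- rec
  }
  structure(list(
    model_id = model_id, path = NULL,
    compartments = compartments,
    species = species[, c("id", "name", "base_id", "compartment",
                          "is_boundary", "existing_sbo")],
    reactions = rxns,
    genes = data.frame(id = character(0), label = character(0),
                       existing_sbo = integer(0), stringsAsFactors = FALSE),
    objective_reaction_ids = obj
  ), class = "sbml_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- branch templates ------------------------------------------------------

# each template: species (id -> compartment [+boundary]), one reaction, and
# the expectation row recorded in the sidecar
fixture_templates <- function() {
  rx <- function(id, reactants = numeric(0), products = numeric(0),
                 reversible = FALSE, ec = character(0),
                 modifiers = character(0), objective = FALSE)
    list(id = id, reactants = reactants, products = products,
         reversible = reversible, ec = ec, modifiers = modifiers,
         objective = objective)
  list(
    EXCHANGE = list(
      species = c(o2_e = "e"),
      reaction = rx("EX_o2_e", reactants = c(o2_e = 1), reversible = TRUE),
      class = "EXCHANGE", term = "exchange reaction"),
    DEMAND = list(
      species = c(amob_c = "c"),
      reaction = rx("DM_amob_c", reactants = c(amob_c = 1)),
      class = "DEMAND", term = "demand reaction"),
    SINK = list(
      species = c(ppi_c = "c"),
      reaction = rx("SK_ppi_c", reactants = c(ppi_c = 1), reversible = TRUE),
      class = "SINK", term = "sink reaction"),
    BIOMASS = list(
      species = c(ala__L_c = "c", atp_c = "c", adp_c = "c", pi_c = "c"),
      reaction = rx("BIOMASS_mini", reactants = c(ala__L_c = 0.5, atp_c = 2),
                    products = c(adp_c = 2, pi_c = 2), objective = TRUE),
      class = "BIOMASS", term = "biomass production"),
    TRANSPORT = list(
      species = c(o2_e = "e", o2_c = "c"),
      reaction = rx("O2t", reactants = c(o2_e = 1), products = c(o2_c = 1),
                    reversible = TRUE),
      class = "TRANSPORT", term = "passive transport"),
    BIOCHEMICAL = list(
      species = c(g6p_c = "c", f6p_c = "c"),
      reaction = rx("PGI", reactants = c(g6p_c = 1), products = c(f6p_c = 1),
                    reversible = TRUE, ec = "5.3.1.9"),
      class = "BIOCHEMICAL", term = "isomerisation"),
    PASSIVE = list(
      species = c(h2o_e = "e", h2o_c = "c"),
      reaction = rx("H2Ot", reactants = c(h2o_e = 1), products = c(h2o_c = 1),
                    reversible = TRUE),
      class = "TRANSPORT", term = "passive transport"),
    ACTIVE_ATP = list(
      species = c(atp_c = "c", h2o_c = "c", glc__D_e = "e", adp_c = "c",
                  pi_c = "c", h_c = "c", glc__D_c = "c"),
      reaction = rx("GLCabc",
                    reactants = c(atp_c = 1, h2o_c = 1, glc__D_e = 1),
                    products = c(adp_c = 1, pi_c = 1, h_c = 1, glc__D_c = 1)),
      class = "TRANSPORT", term = "active transport"),
    ACTIVE_PEP = list(
      species = c(glc__D_e = "e", pep_c = "c", g6p_c = "c", pyr_c = "c"),
      reaction = rx("GLCpts", reactants = c(glc__D_e = 1, pep_c = 1),
                    products = c(g6p_c = 1, pyr_c = 1)),
      class = "TRANSPORT", term = "active transport"),
    SYMPORT = list(
      species = c(na1_e = "e", pro__L_e = "e", na1_c = "c", pro__L_c = "c"),
      reaction = rx("PROt4", reactants = c(na1_e = 1, pro__L_e = 1),
                    products = c(na1_c = 1, pro__L_c = 1)),
      class = "TRANSPORT", term = "symporter-mediated transport"),
    ANTIPORT = list(
      species = c(ca2_c = "c", h_e = "e", ca2_e = "e", h_c = "c"),
      reaction = rx("CAt6", reactants = c(ca2_c = 1, h_e = 1),
                    products = c(ca2_e = 1, h_c = 1)),
      class = "TRANSPORT", term = "antiporter-mediated transport"),
    GENERIC_TRANSPORT = list(
      species = c(ala__L_e = "e", gly_c = "c"),
      reaction = rx("ALAGLYt", reactants = c(ala__L_e = 1),
                    products = c(gly_c = 1)),
      class = "TRANSPORT", term = "transport reaction"),
    EC_ONE_TO_ONE = list(
      species = c(akg_c = "c", ala__L_c = "c", glu__L_c = "c", pyr_c = "c"),
      reaction = rx("ALATA_L", reactants = c(akg_c = 1, ala__L_c = 1),
                    products = c(glu__L_c = 1, pyr_c = 1), reversible = TRUE,
                    ec = "2.6.1.2"),
      class = "BIOCHEMICAL", term = "transamination"),
    EC_ONE_TO_FEW = list(
      species = c(macoa_c = "c", pept_c = "c", coa_c = "c", mpept_c = "c"),
      reaction = rx("NMYRT", reactants = c(macoa_c = 1, pept_c = 1),
                    products = c(coa_c = 1, mpept_c = 1), ec = "2.3.1.97"),
      class = "BIOCHEMICAL", term = "myristoylation"),
    EC_ONE_TO_MANY = list(
      species = c(accoa_c = "c", glu__L_c = "c", coa_c = "c", acglu_c = "c"),
      reaction = rx("ACGS", reactants = c(accoa_c = 1, glu__L_c = 1),
                    products = c(coa_c = 1, acglu_c = 1), ec = "2.3.1.1"),
      class = "BIOCHEMICAL", term = "acetylation"),
    EC_CLASS_6 = list(
      species = c(ala__D_c = "c", atp_c = "c", alaala_c = "c", adp_c = "c",
                  pi_c = "c", h_c = "c"),
      reaction = rx("ALAALAr", reactants = c(ala__D_c = 2, atp_c = 1),
                    products = c(alaala_c = 1, adp_c = 1, pi_c = 1, h_c = 1),
                    ec = "6.3.2.4"),
      class = "BIOCHEMICAL", term = "formation of a covalent bond"),
    NO_EC = list(
      species = c(akg_c = "c", sucsal_c = "c"),
      reaction = rx("UNK1", reactants = c(akg_c = 1),
                    products = c(sucsal_c = 1)),
      class = "BIOCHEMICAL", term = "biochemical reaction"),
    MODIFIER = list(
      species = c(asp__L_c = "c", akg_c = "c", oaa_c = "c", glu__L_c = "c",
                  prot_aspC_c = "c"),
      reaction = rx("ASPTA", reactants = c(asp__L_c = 1, akg_c = 1),
                    products = c(oaa_c = 1, glu__L_c = 1), reversible = TRUE,
                    ec = "2.6.1.1", modifiers = "prot_aspC_c"),
      class = "BIOCHEMICAL", term = "transamination")
  )
}

#' Branch tags known to the fixture forge
#' @return Character vector of tags accepted by [fixture_spec()].
#' @export
fixture_branches <- function() names(fixture_templates())

#' Describe a fixture model
#'
#' @param name Model/file name stem.
#' @param branches Character vector of branch tags (see
#'   [fixture_branches()]); each requested branch contributes one reaction
#'   whose expected class and term label are recorded in the sidecar
#'   expectations file.
#' @param seed Integer recorded with the fixture; generation is fully
#'   deterministic, so the same spec always yields byte-identical files.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(name, branches, seed = 1L) {
  stopifnot(length(branches) >= 1L)
  unknown <- setdiff(branches, fixture_branches())
  if (length(unknown))
    stop("unknown fixture branch tag(s): ", paste(unknown, collapse = ", "),
         "; known tags: ", paste(fixture_branches(), collapse = ", "),
         call. = FALSE)
  structure(list(name = name, branches = unique(branches),
                 seed = as.integer(seed)), class = "fixture_spec")
}

#' The all-branches fixture specification
#' @param name Model name stem.
#' @return A [fixture_spec()] covering every known branch.
#' @export
full_branch_spec <- function(name = "full_branch") {
  fixture_spec(name, fixture_branches())
}

#' Generate a miniature SBML fixture model
#'
#' Writes `<name>.xml` (SBML Level 3 Version 1 + fbc v2, BiGG-style ids) and
#' a sidecar `<name>_expectations.tsv` with columns `reaction_id`,
#' `expected_class`, `expected_term_label` into `dir`. Two fbc gene products
#' are always included so gene annotation is exercised. Generation is pure
#' string assembly: identical specs produce identical bytes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Path to the SBML file, with the sidecar path as attribute
#'   `expectations`.
#' @export
build_fixture <- function(spec, dir = ".") {
  stopifnot(inherits(spec, "fixture_spec"))
  tpl <- fixture_templates()[spec$branches]
  sp_comp <- character(0)
  for (t in tpl) {
    clash <- intersect(names(t$species), names(sp_comp))
    stopifnot(all(sp_comp[clash] == t$species[clash]))
    sp_comp <- c(sp_comp, t$species[setdiff(names(t$species), names(sp_comp))])
  }
  comps <- sort(unique(sp_comp))
  comp_names <- c(c = "cytosol", e = "extracellular space", p = "periplasm")

  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
             'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
             'level="3" version="1" fbc:required="false">'))
  add('  <model id="%s" fbc:strict="false">', esc(spec$name))
  add('    <listOfCompartments>')
  for (cm in comps)
    add('      <compartment id="%s" name="%s" constant="true"/>',
        cm, comp_names[cm] %||% cm)
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (sid in names(sp_comp))
    add(paste0('      <species id="%s" compartment="%s" ',
               'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
               'constant="false"/>'), sid, sp_comp[[sid]])
  add('    </listOfSpecies>')
  add('    <listOfReactions>')
  exp_rows <- list()
  objective_rxn <- NULL
  for (tag in names(tpl)) {
    t <- tpl[[tag]]
    r <- t$reaction
    if (r$objective) objective_rxn <- r$id
    add('      <reaction id="%s" metaid="meta_%s" reversible="%s" fast="false">',
        r$id, r$id, tolower(as.character(r$reversible)))
    if (length(r$ec)) {
      add('        <annotation>')
      add(paste0('          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/',
                 '22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/',
                 'biology-qualifiers/">'))
      add('            <rdf:Description rdf:about="#meta_%s">', r$id)
      add('              <bqbiol:isDescribedBy>')
      add('                <rdf:Bag>')
      for (ec in r$ec)
        add('                  <rdf:li rdf:resource="https://identifiers.org/ec-code/%s"/>', ec)
      add('                </rdf:Bag>')
      add('              </bqbiol:isDescribedBy>')
      add('            </rdf:Description>')
      add('          </rdf:RDF>')
      add('        </annotation>')
    }
    side <- function(v, listname) {
      if (length(v) == 0L) return()
      add('        <%s>', listname)
      for (s in names(v))
        add(paste0('          <speciesReference species="%s" ',
                   'stoichiometry="%s" constant="true"/>'), s,
            format(v[[s]], trim = TRUE))
      add('        </%s>', listname)
    }
    side(r$reactants, "listOfReactants")
    side(r$products, "listOfProducts")
    if (length(r$modifiers)) {
      add('        <listOfModifiers>')
      for (s in r$modifiers)
        add('          <modifierSpeciesReference species="%s"/>', s)
      add('        </listOfModifiers>')
    }
    add('      </reaction>')
    exp_rows[[tag]] <- data.frame(
      reaction_id = r$id, expected_class = t$class,
      expected_term_label = t$term, stringsAsFactors = FALSE)
  }
  add('    </listOfReactions>')
  if (!is.null(objective_rxn)) {
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    add(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
               'fbc:coefficient="1"/>'), objective_rxn)
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  add('    <fbc:listOfGeneProducts>')
  add('      <fbc:geneProduct fbc:id="G_b0001" fbc:label="thrA"/>')
  add('      <fbc:geneProduct fbc:id="G_b0002" fbc:label="thrB"/>')
  add('    </fbc:listOfGeneProducts>')
  add('  </model>')
  add('</sbml>')

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(spec$name, ".xml"))
  writeLines(L, path)
  side_path <- file.path(dir, paste0(spec$name, "_expectations.tsv"))
  utils::write.table(do.call(rbind, exp_rows), side_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  structure(path, expectations = side_path)
}

# --- randomized generators for property tests ------------------------------

#' Random miniature model document
#'
#' Draws `n_reactions` reactions from the classification branches (pseudo,
#' transport, biochemical variants) with randomized species ids,
#' compartments, stoichiometries and reversibility. Used to check that
#' triage always yields a partition. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param n_reactions Number of reactions (default 8).
#' @return An in-memory `sbml_model` built with [model_doc()].
#' @export
random_model_doc <- function(seed, n_reactions = 8L) {
  set.seed(seed)
  comps <- c("c", "e", if (stats::runif(1) < 0.5) "p")
  species <- list()
  new_sp <- function(comp, boundary = FALSE) {
    id <- sprintf("x%04d_%s", length(species) + 1L, comp)
    species[[id]] <<- data.frame(id = id, compartment = comp,
                                 is_boundary = boundary,
                                 stringsAsFactors = FALSE)
    id
  }
  rxns <- list()
  kinds <- c("exchange", "demand", "sink", "biomass", "transport",
             "biochemical", "weird")
  for (i in seq_len(n_reactions)) {
    kind <- sample(kinds, 1L)
    id <- sprintf("RX%03d", i)
    rev <- stats::runif(1) < 0.5
    r <- switch(kind,
      exchange = {
        s <- new_sp("e", boundary = stats::runif(1) < 0.3)
        pre <- if (stats::runif(1) < 0.7) "EX_" else ""
        list(id = paste0(pre, id), reactants = stats::setNames(1, s),
             reversible = TRUE)
      },
      demand = {
        s <- new_sp("c")
        pre <- if (stats::runif(1) < 0.5) "DM_" else ""
        list(id = paste0(pre, id), reactants = stats::setNames(1, s),
             reversible = if (nzchar(pre)) rev else FALSE)
      },
      sink = {
        s <- new_sp("c")
        pre <- if (stats::runif(1) < 0.5) "SK_" else ""
        list(id = paste0(pre, id), reactants = stats::setNames(1, s),
             reversible = TRUE)
      },
      biomass = {
        s1 <- new_sp("c"); s2 <- new_sp("c")
        list(id = paste0("BIOMASS_", id),
             reactants = stats::setNames(stats::runif(1, 0.1, 2), s1),
             products = stats::setNames(1, s2),
             objective = stats::runif(1) < 0.5)
      },
      transport = {
        from <- sample(comps, 1L)
        to <- sample(setdiff(comps, from), 1L)
        s1 <- new_sp(from); s2 <- new_sp(to)
        list(id = paste0(id, "t"), reactants = stats::setNames(1, s1),
             products = stats::setNames(1, s2), reversible = rev)
      },
      biochemical = {
        s1 <- new_sp("c"); s2 <- new_sp("c")
        ec <- if (stats::runif(1) < 0.5)
          sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                  sample(1:9, 1), sample(1:99, 1)) else character(0)
        list(id = id, reactants = stats::setNames(1, s1),
             products = stats::setNames(1, s2), reversible = rev, ec = ec)
      },
      weird = {
        n_r <- sample(1:3, 1L); n_p <- sample(0:3, 1L)
        if (n_p == 0L && stats::runif(1) < 0.5) { n_p <- n_r; n_r <- 0L }
        rs <- vapply(seq_len(n_r), function(j) new_sp(sample(comps, 1L)),
                     character(1))
        ps <- vapply(seq_len(n_p), function(j) new_sp(sample(comps, 1L)),
                     character(1))
        list(id = id,
             reactants = stats::setNames(rep(1, n_r), rs),
             products = stats::setNames(rep(1, n_p), ps),
             reversible = rev)
      })
    rxns[[length(rxns) + 1L]] <- r
  }
  model_doc(model_id = sprintf("random_%d", seed),
            compartments = comps,
            species = do.call(rbind, species),
            reactions = rxns)
}

#' Random is-a DAG
#'
#' Generates a rooted random directed acyclic graph shaped like a term
#' hierarchy: term `i` picks one or two parents among earlier terms. Used to
#' test common-ancestor resolution against a brute-force oracle.
#'
#' @param seed Integer seed.
#' @param n_terms Number of terms (>= 2).
#' @return An `sbo_graph`.
#' @export
random_ontology <- function(seed, n_terms = 12L) {
  set.seed(seed)
  ids <- sort(sample.int(9999L, n_terms))
  terms <- list()
  for (i in seq_along(ids)) {
    parents <- if (i == 1L) integer(0) else {
      pool <- ids[seq_len(i - 1L)]
      n_par <- min(length(pool), sample(1:2, 1L))
      sort(pool[sample.int(length(pool), n_par)])
    }
    terms[[as.character(ids[i])]] <- list(
      id = ids[i], label = sprintf("term %d", ids[i]), parents = parents)
  }
  g <- structure(list(terms = terms), class = "sbo_graph")
  g$roots <- ids[vapply(terms, function(t) length(t$parents) == 0L,
                        logical(1))]
  g$depth <- graph_depths(g)
  g
}
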