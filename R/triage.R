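## Reaction triage: every reaction gets exactly one class out of
## EXCHANGE / DEMAND / SINK / BIOMASS / TRANSPORT / BIOCHEMICAL.

REACTION_CLASSES <- c("EXCHANGE", "DEMAND", "SINK", "BIOMASS",
                      "TRANSPORT", "BIOCHEMICAL")

# strip an optional SBML-style "R_" SId prefix before prefix matching
reaction_core_id <- function(id) sub("^R_", "", id)

has_prefix <- function(id, prefixes) {
  core <- reaction_core_id(id)
  any(vapply(prefixes, function(p)
    startsWith(tolower(core), tolower(p)), logical(1)))
}

#' Identify a model's extracellular compartment
#'
#' The compartment in which the sole participants of `EX_`-prefixed
#' one-sided reactions live; failing that, the compartment with id `e` or an
#' id/name matching "extracellular". `NA` when neither heuristic applies.
#'
#' @param doc An `sbml_model`.
#' @return Compartment id or `NA`.
#' @export
extracellular_compartment <- function(doc) {
  sp <- doc$species
  for (rxn in doc$reactions) {
    if (!has_prefix(rxn$id, "EX_")) next
    ids <- c(rxn$reactants$species, rxn$products$species)
    if (length(ids) == 0L) next
    comps <- unique(sp$compartment[match(ids, sp$id)])
    if (length(comps) == 1L && !is.na(comps)) return(comps)
  }
  cand <- doc$compartments$id[
    doc$compartments$id == "e" |
      grepl("extracellular", doc$compartments$id, ignore.case = TRUE) |
      (!is.na(doc$compartments$name) &
         grepl("extracellular", doc$compartments$name, ignore.case = TRUE))]
  if (length(cand) > 0L) cand[1L] else NA_character_
}

#' Classify one reaction
#'
#' Decision order (first match wins):
#' \enumerate{
#'   \item BIOMASS — objective member, or "biomass" appears in the id or name;
#'   \item one-sided reactions (a side with no participants):
#'     EXCHANGE if `EX_`-prefixed or the species are boundary/extracellular;
#'     SINK if `SK_`/`sink_`-prefixed, DEMAND if `DM_`-prefixed, otherwise
#'     sink when reversible, demand when irreversible;
#'   \item TRANSPORT — participants span two or more compartments;
#'   \item BIOCHEMICAL otherwise.
#' }
#' A biomass reaction spanning compartments is still BIOMASS: precedence is
#' biomass > pseudo > transport > biochemical. Modifiers do not count as
#' participants (an enzyme's location must not make a reaction a transporter).
#'
#' @param rxn A reaction record from an `sbml_model`.
#' @param doc The containing `sbml_model`.
#' @return Class string with attribute `rule` naming the rule that fired.
#' @export
triage_reaction <- function(rxn, doc) {
  res <- function(class, rule) structure(class, rule = rule)
  part_ids <- c(rxn$reactants$species, rxn$products$species)
  if (length(part_ids) == 0L)
    stop("degenerate reaction '", rxn$id,
         "' has no participants on either side", call. = FALSE)

  if (isTRUE(rxn$is_objective))
    return(res("BIOMASS", "biomass-objective"))
  if (grepl("biomass", rxn$id, ignore.case = TRUE) ||
      (!is.na(rxn$name) && grepl("biomass", rxn$name, ignore.case = TRUE)))
    return(res("BIOMASS", "biomass-id-pattern"))

  one_sided <- nrow(rxn$reactants) == 0L || nrow(rxn$products) == 0L
  if (one_sided) {
    sp <- doc$species[match(part_ids, doc$species$id), , drop = FALSE]
    ext <- extracellular_compartment(doc)
    if (has_prefix(rxn$id, "EX_"))
      return(res("EXCHANGE", "exchange-prefix"))
    if (any(sp$is_boundary) ||
        (!is.na(ext) && all(sp$compartment == ext)))
      return(res("EXCHANGE", "exchange-boundary"))
    if (has_prefix(rxn$id, c("SK_", "sink_")))
      return(res("SINK", "sink-prefix"))
    if (has_prefix(rxn$id, "DM_"))
      return(res("DEMAND", "demand-prefix"))
    if (isTRUE(rxn$reversible))
      return(res("SINK", "sink-reversible"))
    return(res("DEMAND", "demand-irreversible"))
  }

  comps <- unique(doc$species$compartment[match(part_ids, doc$species$id)])
  if (length(comps) >= 2L)
    return(res("TRANSPORT", "transport-compartment-span"))
  res("BIOCHEMICAL", "biochemical-default")
}

#' Partition a model's reactions by class
#'
#' @param doc An `sbml_model`.
#' @return Named list, one element per class in `REACTION_CLASSES`, each a
#'   character vector of reaction ids in model order. Every reaction appears
#'   in exactly one bucket.
#' @export
partition_model <- function(doc) {
  buckets <- stats::setNames(
    replicate(length(REACTION_CLASSES), character(0), simplify = FALSE),
    REACTION_CLASSES)
  for (rxn in doc$reactions) {
    cls <- tryCatch(triage_reaction(rxn, doc), error = function(e)
      stop("triage failed for reaction '", rxn$id, "': ",
           conditionMessage(e), call. = FALSE))
    buckets[[as.character(cls)]] <- c(buckets[[as.character(cls)]], rxn$id)
  }
  buckets
}
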