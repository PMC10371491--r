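## Transport mechanism typing. A TRANSPORT reaction is sub-classified as
## PASSIVE, ACTIVE_ATP, ACTIVE_PEP, SYMPORT, ANTIPORT or GENERIC based on
## which species physically cross compartments and whether ATP hydrolysis or
## the PEP/pyruvate phosphotransferase (PTS) couple powers the movement.

TRANSPORT_TYPES <- c("PASSIVE", "ACTIVE_ATP", "ACTIVE_PEP",
                     "SYMPORT", "ANTIPORT", "GENERIC")

# base id for moiety matching: compartment suffix already stripped by the
# gateway; additionally drop an SBML-style "M_" SId prefix
moiety_base <- function(base_id) sub("^M_", "", base_id)

species_base <- function(doc, species_ids) {
  doc$species$base_id[match(species_ids, doc$species$id)]
}
species_comp <- function(doc, species_ids) {
  doc$species$compartment[match(species_ids, doc$species$id)]
}

#' Species translocation events of a transport reaction
#'
#' One event per base species id that appears as a reactant in one
#' compartment and as a product in a different one — the species that
#' physically cross. A substrate whose chemical identity changes in transit
#' (e.g. a PTS sugar arriving phosphorylated) produces no event here; the
#' PTS pattern is recognized separately in [classify_transport()].
#'
#' @param rxn A reaction record (should be triaged TRANSPORT, not enforced).
#' @param doc The containing `sbml_model`.
#' @return data.frame `(base_id, from_compartment, to_compartment)` in
#'   reactant order; zero rows when nothing crosses intact.
#' @export
translocation_events <- function(rxn, doc) {
  out <- data.frame(base_id = character(0), from_compartment = character(0),
                    to_compartment = character(0), stringsAsFactors = FALSE)
  r_base <- species_base(doc, rxn$reactants$species)
  r_comp <- species_comp(doc, rxn$reactants$species)
  p_base <- species_base(doc, rxn$products$species)
  p_comp <- species_comp(doc, rxn$products$species)
  seen <- character(0)
  for (i in seq_along(r_base)) {
    b <- r_base[i]
    if (b %in% seen) next
    j <- which(p_base == b & p_comp != r_comp[i])
    if (length(j) > 0L) {
      out <- rbind(out, data.frame(
        base_id = b, from_compartment = r_comp[i],
        to_compartment = p_comp[j[1L]], stringsAsFactors = FALSE))
      seen <- c(seen, b)
    }
  }
  out
}

# does the reaction consume `consumed` and produce all of `produced`
# (base ids, compartment ignored)?
moiety_couple <- function(rxn, doc, consumed, produced) {
  r <- moiety_base(species_base(doc, rxn$reactants$species))
  p <- moiety_base(species_base(doc, rxn$products$species))
  all(consumed %in% r) && all(produced %in% p)
}

#' Sub-classify a transport reaction by mechanism
#'
#' Decision order (first match wins; energy coupling beats multi-species
#' patterns beats the single-species default):
#' \enumerate{
#'   \item ACTIVE_ATP — ATP is consumed and both ADP and Pi are produced
#'     (water optional; this separates ABC-style pumps from
#'     compartment-spanning kinases), alongside at least one translocation
#'     event or a non-moiety substrate spanning compartments;
#'   \item ACTIVE_PEP — PEP is consumed, pyruvate produced, and a sugar from
#'     the PTS table crosses compartments, possibly arriving phosphorylated
#'     (glc__D in, g6p out);
#'   \item SYMPORT / ANTIPORT — two or more translocation events, all in the
#'     same direction / at least two in opposite directions;
#'   \item PASSIVE — exactly one translocation event and no co-substrate
#'     other than the translocated species;
#'   \item GENERIC otherwise.
#' }
#' A proton crossing compartments counts as a translocation event, so a
#' substrate-plus-proton importer types as SYMPORT, while a proton-only
#' uniport reaction is PASSIVE.
#'
#' @param rxn A reaction record triaged TRANSPORT.
#' @param doc The containing `sbml_model`.
#' @param config An `sbo_config` (for moiety base ids and the PTS table).
#' @return One of `TRANSPORT_TYPES`, with attribute `rule`.
#' @export
classify_transport <- function(rxn, doc, config = default_config()) {
  cls <- triage_reaction(rxn, doc)
  if (as.character(cls) != "TRANSPORT")
    stop("classify_transport called on non-transport reaction '", rxn$id,
         "' (triaged ", as.character(cls), ")", call. = FALSE)
  res <- function(type, rule) structure(type, rule = rule)
  m <- config$moieties
  events <- translocation_events(rxn, doc)
  moiety_ids <- c(m$atp_consumed, m$atp_produced, m$pep_consumed,
                  m$pep_produced, "h2o", "h")

  if (moiety_couple(rxn, doc, m$atp_consumed, m$atp_produced)) {
    part <- c(rxn$reactants$species, rxn$products$species)
    keep <- !(moiety_base(species_base(doc, part)) %in% moiety_ids)
    span <- length(unique(species_comp(doc, part[keep]))) >= 2L
    if (nrow(events) >= 1L || span)
      return(res("ACTIVE_ATP", "transport-active-atp"))
  }

  if (moiety_couple(rxn, doc, m$pep_consumed, m$pep_produced)) {
    r_base <- moiety_base(species_base(doc, rxn$reactants$species))
    r_comp <- species_comp(doc, rxn$reactants$species)
    p_base <- moiety_base(species_base(doc, rxn$products$species))
    p_comp <- species_comp(doc, rxn$products$species)
    crossing <- any(moiety_base(events$base_id) %in% config$pts$substrate)
    if (!crossing) {
      for (k in seq_len(nrow(config$pts))) {
        i <- which(r_base == config$pts$substrate[k])
        j <- which(p_base == config$pts$phospho_product[k])
        if (length(i) && length(j) && any(outer(r_comp[i], p_comp[j], "!=")))
          crossing <- TRUE
      }
    }
    if (crossing)
      return(res("ACTIVE_PEP", "transport-active-pep"))
  }

  if (nrow(events) >= 2L) {
    dirs <- paste(events$from_compartment, events$to_compartment, sep = "->")
    rdirs <- paste(events$to_compartment, events$from_compartment, sep = "->")
    if (any(dirs %in% rdirs))
      return(res("ANTIPORT", "transport-antiport"))
    if (length(unique(dirs)) == 1L)
      return(res("SYMPORT", "transport-symport"))
    return(res("GENERIC", "transport-generic-multi"))
  }

  if (nrow(events) == 1L) {
    all_base <- unique(c(species_base(doc, rxn$reactants$species),
                         species_base(doc, rxn$products$species)))
    if (all(all_base == events$base_id[1L]))
      return(res("PASSIVE", "transport-passive"))
  }

  res("GENERIC", "transport-generic")
}
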