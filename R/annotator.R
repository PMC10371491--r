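## Pipeline orchestration: triage -> transport typing -> EC resolution ->
## entity annotation -> report, mirroring the six-step workflow: classify
## pseudo- and transport reactions, refine biochemical reactions through the
## EC mapping, then annotate the remaining entities and store the model.

transport_config_key <- c(
  PASSIVE = "transport_passive", ACTIVE_ATP = "transport_active_atp",
  ACTIVE_PEP = "transport_active_pep", SYMPORT = "transport_symport",
  ANTIPORT = "transport_antiport", GENERIC = "transport_generic")

pseudo_config_key <- c(EXCHANGE = "exchange", DEMAND = "demand",
                       SINK = "sink", BIOMASS = "biomass")

#' Annotate every entity of a model with SBO terms
#'
#' Reactions get exactly one term each: pseudo-reaction subtypes their
#' configured terms, transport reactions the term for their mechanism
#' ([classify_transport()]), biochemical reactions the term resolved from
#' their EC numbers ([resolve_reaction_term()]). Species and genes get their
#' configured entity terms, and each modifier of an enzyme-backed reaction
#' (one carrying at least one EC number) is tagged as an enzymatic catalyst.
#'
#' @param doc An `sbml_model`.
#' @param config An `sbo_config`.
#' @param preserve_existing Keep a pre-existing `sboTerm` when it is a strict
#'   descendant (more specific term) of what would be assigned; never
#'   downgrade curated annotations. Set `FALSE` to force overwrite.
#' @param fetch_ec Optional function `(reaction_id) -> character vector of
#'   EC numbers`, consulted for biochemical reactions lacking EC annotations
#'   (see [fetch_reaction_ec()]); fetched numbers are reported in the
#'   `ec_backfill` element so they can be written back into the model.
#' @return List of class `sbo_annotation`: `assignments`
#'   ([sbo_assignments()] table), `report` (see [annotation_report()]),
#'   `classes` (reaction id -> ReactionClass), `ec_backfill` (named list).
#' @export
annotate_model <- function(doc, config = default_config(),
                           preserve_existing = TRUE, fetch_ec = NULL) {
  stopifnot(inherits(doc, "sbml_model"), inherits(config, "sbo_config"))
  graph <- config$graph
  ids <- config$ids
  generic <- ids[["generic_biochemical"]]
  out <- list()
  classes <- character(0)
  backfilled <- list()

  choose <- function(existing, chosen_id, rule) {
    if (preserve_existing && !is.na(existing) &&
        !is.null(graph$terms[[as.character(existing)]]) &&
        existing != chosen_id && sbo_is_a(graph, existing, chosen_id))
      list(sbo_id = existing, rule = "preserved-existing")
    else list(sbo_id = chosen_id, rule = rule)
  }

  for (rxn in doc$reactions) {
    cls <- triage_reaction(rxn, doc)
    classes[[rxn$id]] <- as.character(cls)
    if (as.character(cls) %in% names(pseudo_config_key)) {
      key <- pseudo_config_key[[as.character(cls)]]
      dec <- choose(rxn$existing_sbo, ids[[key]],
                    paste0("pseudo-", tolower(as.character(cls))))
    } else if (as.character(cls) == "TRANSPORT") {
      ttype <- classify_transport(rxn, doc, config)
      dec <- choose(rxn$existing_sbo, ids[[transport_config_key[[ttype]]]],
                    attr(ttype, "rule"))
    } else {
      ecs <- rxn$ec_numbers
      if (length(ecs) == 0L && !is.null(fetch_ec)) {
        ecs <- fetch_ec(rxn$id)
        if (length(ecs) > 0L) backfilled[[rxn$id]] <- ecs
      }
      # translocases (EC class 7) describe transport, not the biochemical
      # conversion; they never feed the biochemical mapping
      ecs <- ecs[!vapply(ecs, function(e) {
        p <- ec_parse(e); !is.null(p) && unclass(p)[1L] == 7L
      }, logical(1))]
      resv <- resolve_reaction_term(ecs, graph, config$store, generic)
      rule <- if (length(resv$categories))
        paste0(resv$rule, ":", paste(sort(resv$categories), collapse = "+"))
      else resv$rule
      dec <- choose(rxn$existing_sbo, resv$sbo_id, rule)
    }
    out[[length(out) + 1L]] <- data.frame(
      entity_id = rxn$id, entity_kind = "reaction",
      sbo_id = dec$sbo_id, rule = dec$rule, stringsAsFactors = FALSE)
    if (length(rxn$modifiers) > 0L) {
      mods <- annotate_modifiers(rxn, config)
      if (nrow(mods)) out[[length(out) + 1L]] <- mods
    }
  }

  for (i in seq_len(nrow(doc$species))) {
    sp <- doc$species[i, ]
    key <- "species"
    if (length(config$macromolecule_patterns) &&
        any(vapply(config$macromolecule_patterns, function(p)
          grepl(p, sp$id, ignore.case = TRUE), logical(1))))
      key <- "macromolecule"
    dec <- choose(sp$existing_sbo, ids[[key]],
                  paste0("species-", gsub("_", "-", key)))
    out[[length(out) + 1L]] <- data.frame(
      entity_id = sp$id, entity_kind = "species",
      sbo_id = dec$sbo_id, rule = dec$rule, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(doc$genes))) {
    g <- doc$genes[i, ]
    dec <- choose(g$existing_sbo, ids[["gene"]], "gene")
    out[[length(out) + 1L]] <- data.frame(
      entity_id = g$id, entity_kind = "gene",
      sbo_id = dec$sbo_id, rule = dec$rule, stringsAsFactors = FALSE)
  }

  asn <- do.call(rbind, out)
  asn <- sbo_assignments(asn$entity_id, asn$entity_kind, asn$sbo_id, asn$rule)
  rpt <- annotation_report(asn, classes, generic)
  structure(list(assignments = asn, report = rpt, classes = classes,
                 ec_backfill = backfilled),
            class = "sbo_annotation")
}

#' Annotate the modifiers of one reaction
#'
#' A modifier attached to an enzyme-backed reaction (at least one EC number)
#' is assigned the "enzymatic catalyst" term; modifiers of EC-less reactions
#' get nothing — without enzymatic evidence the modifier could equally be an
#' inhibitor or another stimulator.
#'
#' @param rxn A reaction record.
#' @param config An `sbo_config`.
#' @return An [sbo_assignments()] table (possibly empty); modifier
#'   `entity_id` is `"<reaction id>:<species id>"`.
#' @export
annotate_modifiers <- function(rxn, config = default_config()) {
  if (length(rxn$modifiers) == 0L || length(rxn$ec_numbers) == 0L)
    return(sbo_assignments())
  sbo_assignments(
    entity_id = paste0(rxn$id, ":", rxn$modifiers),
    entity_kind = "modifier",
    sbo_id = config$ids[["modifier_enzymatic"]],
    rule = "modifier-enzymatic-catalyst")
}

#' Summarise an assignment set
#'
#' @param assignments An [sbo_assignments()] table.
#' @param classes Named character vector, reaction id -> ReactionClass.
#' @param generic_id Generic biochemical-reaction term id.
#' @return List of class `annotation_report`: `histogram` (data.frame
#'   `entity_kind`, `sbo_id`, `count`), `generic_reaction_fraction`
#'   (proportion of reactions carrying the generic term), `class_counts`.
#' @export
annotation_report <- function(assignments, classes = character(0),
                              generic_id = 176L) {
  rx <- assignments[assignments$entity_kind == "reaction", , drop = FALSE]
  hist <- stats::aggregate(
    list(count = rep(1L, nrow(assignments))),
    by = list(entity_kind = assignments$entity_kind,
              sbo_id = assignments$sbo_id),
    FUN = sum)
  hist <- hist[order(hist$entity_kind, hist$sbo_id), , drop = FALSE]
  rownames(hist) <- NULL
  cc <- table(factor(classes, levels = REACTION_CLASSES))
  structure(list(
    histogram = hist,
    generic_reaction_fraction =
      if (nrow(rx)) mean(rx$sbo_id == generic_id) else NA_real_,
    class_counts = stats::setNames(as.integer(cc), names(cc))
  ), class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("Annotation report\n")
  cat("  reaction classes:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = " "), "\n")
  cat(sprintf("  generic biochemical-reaction fraction: %s\n",
              format(x$generic_reaction_fraction, digits = 3)))
  cat(sprintf("  %d (entity kind, term) combinations\n", nrow(x$histogram)))
  invisible(x)
}

#' @export
print.sbo_annotation <- function(x, ...) {
  cat(sprintf("SBO annotation: %d assignments (%d reactions, %d species, %d genes, %d modifiers)\n",
              nrow(x$assignments),
              sum(x$assignments$entity_kind == "reaction"),
              sum(x$assignments$entity_kind == "species"),
              sum(x$assignments$entity_kind == "gene"),
              sum(x$assignments$entity_kind == "modifier")))
  print(x$report)
  invisible(x)
}

#' Compare SBO coverage before and after annotation
#'
#' Computes the per-kind histogram of `sboTerm` values in the after state
#' and the generic biochemical-reaction fraction in both states: the
#' proportion, among reactions that carry any term, of those carrying the
#' generic term. A falling fraction means reactions gained more specific
#' terms.
#'
#' @param doc_before,doc_after Two `sbml_model`s over the same entity sets.
#' @param generic_id Generic biochemical-reaction term id.
#' @return List of class `coverage_report`: `histogram`,
#'   `generic_fraction_before`, `generic_fraction_after` (each `NA` when no
#'   reaction carries a term in that state).
#' @export
coverage_report <- function(doc_before, doc_after, generic_id = 176L) {
  same <- identical(sort(names(doc_before$reactions)),
                    sort(names(doc_after$reactions))) &&
    identical(sort(doc_before$species$id), sort(doc_after$species$id)) &&
    identical(sort(doc_before$genes$id), sort(doc_after$genes$id))
  if (!same)
    stop("documents have different entity sets; cannot compare coverage",
         call. = FALSE)
  generic_fraction <- function(doc) {
    sbo <- vapply(doc$reactions, function(r) r$existing_sbo, integer(1))
    sbo <- sbo[!is.na(sbo)]
    if (length(sbo) == 0L) NA_real_ else mean(sbo == generic_id)
  }
  rows <- list()
  add <- function(kind, sbo) {
    sbo <- sbo[!is.na(sbo)]
    if (length(sbo) == 0L) return()
    t <- table(sbo)
    rows[[length(rows) + 1L]] <<- data.frame(
      entity_kind = kind, sbo_id = as.integer(names(t)),
      count = as.integer(t), stringsAsFactors = FALSE)
  }
  add("reaction", vapply(doc_after$reactions, function(r) r$existing_sbo,
                         integer(1)))
  add("species", doc_after$species$existing_sbo)
  add("gene", doc_after$genes$existing_sbo)
  hist <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_kind = character(0), sbo_id = integer(0),
               count = integer(0))
  structure(list(
    histogram = hist,
    generic_fraction_before = generic_fraction(doc_before),
    generic_fraction_after = generic_fraction(doc_after)
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Coverage: generic-term fraction %s -> %s over %d annotated (kind, term) combinations\n",
    format(x$generic_fraction_before, digits = 3),
    format(x$generic_fraction_after, digits = 3), nrow(x$histogram)))
  invisible(x)
}

#' Annotate an SBML file end to end
#'
#' Loads the model, runs [annotate_model()], writes
#' `<stem>_SBOannotated.xml` into `out_dir` (back-filling any fetched EC
#' numbers as controlled-vocabulary annotations) and returns the coverage
#' comparison between input and output.
#'
#' @param path Input SBML file.
#' @param out_dir Output directory (default: current working directory).
#' @param config An `sbo_config`.
#' @param preserve_existing See [annotate_model()]; default `TRUE`.
#' @param gateway Optional EC gateway (see [offline_gateway()]); when given,
#'   biochemical reactions without EC numbers are back-filled through it.
#' @param cache Optional cache directory for the gateway.
#' @return List of class `sbo_run`: `output_path`, `annotation`
#'   (`sbo_annotation`), `coverage` (`coverage_report`).
#' @export
sbo_annotate <- function(path, out_dir = ".", config = default_config(),
                         preserve_existing = TRUE, gateway = NULL,
                         cache = NULL) {
  doc <- load_model(path)
  fetch <- if (is.null(gateway)) NULL else function(rid)
    fetch_reaction_ec(rid, gateway = gateway, cache = cache)$ec_numbers
  ann <- annotate_model(doc, config, preserve_existing = preserve_existing,
                        fetch_ec = fetch)
  out_path <- apply_and_save(doc, ann$assignments, out_dir = out_dir,
                             ec_backfill = ann$ec_backfill)
  after <- load_model(out_path)
  structure(list(
    output_path = out_path,
    annotation = ann,
    coverage = coverage_report(doc, after,
                               config$ids[["generic_biochemical"]])
  ), class = "sbo_run")
}

#' @export
print.sbo_run <- function(x, ...) {
  cat("Annotated model written to", x$output_path, "\n")
  print(x$annotation)
  print(x$coverage)
  invisible(x)
}

#' Serialize an annotation or coverage report
#'
#' @param report An `annotation_report` or `coverage_report`.
#' @param path Output file; `NULL` returns the text.
#' @param format `"json"` or `"tsv"` (TSV carries the histogram; scalar
#'   summaries go to JSON or the TSV header comment).
#' @return The serialized text, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
  } else {
    scalars <- unclass(report)
    scalars$histogram <- NULL
    hdr <- sprintf("# %s: %s", names(scalars),
                   vapply(scalars, function(v)
                     paste(format(v, digits = 6), collapse = ","),
                     character(1)))
    con <- textConnection("txt_out", "w", local = TRUE)
    writeLines(hdr, con)
    utils::write.table(report$histogram, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    txt <- paste(txt_out, collapse = "\n")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
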