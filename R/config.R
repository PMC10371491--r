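## Label-keyed configuration.
##
## All SBO ids used by the annotator (entity defaults, pseudo-reaction
## subtypes, transport mechanism terms) live in a delimited table keyed by
## term label. At load time each (label, id) pair is asserted against the
## ontology: a row whose id is missing, or whose label differs from the
## ontology's, is a configuration error. This prevents drifting or invented
## numeric ids from ever reaching a model.

.sbotagger_cache <- new.env(parent = emptyenv())

#' Load the bundled miniature SBO is-a graph
#'
#' A condensed synthetic subset of the Systems Biology Ontology shipped with
#' the package (see `inst/extdata/sbo_subset_synthetic.obo`), containing only
#' the terms the default configuration references plus their ancestor
#' chains. Pass your own OBO release to [load_ontology()] for full coverage.
#'
#' @param path OBO file; defaults to the bundled subset.
#' @return An `sbo_graph`.
#' @export
default_ontology <- function(path = system.file("extdata",
                                                "sbo_subset_synthetic.obo",
                                                package = "sbotagger")) {
  key <- paste0("obo:", path)
  g <- get0(key, envir = .sbotagger_cache)
  if (is.null(g)) {
    g <- load_ontology(path)
    assign(key, g, envir = .sbotagger_cache)
  }
  g
}

#' Assemble the annotator configuration
#'
#' Bundles everything the pipeline needs: the is-a graph, the EC-to-SBO
#' mapping store, the label-keyed term table, the energetic-moiety base ids
#' used for active-transport detection, and the phosphotransferase (PTS)
#' sugar/product pairs.
#'
#' @param obo Path to an OBO file (default: bundled subset).
#' @param mapping Path to the EC-to-SBO seed table (default: bundled seed).
#' @param term_labels Path to the label-keyed term table.
#' @param pts_sugars Path to the PTS substrate/phospho-product table.
#' @return A list of class `sbo_config`: `graph`, `store`, `ids` (named
#'   integer vector keyed by role, e.g. `exchange`, `transport_passive`,
#'   `generic_biochemical`), `labels`, `moieties` (list with `atp_set`,
#'   `pep_set`), `pts` (data.frame).
#' @export
sbo_config <- function(obo = NULL, mapping = NULL, term_labels = NULL,
                       pts_sugars = NULL) {
  graph <- if (is.null(obo)) default_ontology() else load_ontology(obo)
  if (is.null(term_labels))
    term_labels <- system.file("extdata", "term_labels.tsv",
                               package = "sbotagger")
  tl <- utils::read.delim(term_labels, stringsAsFactors = FALSE,
                          colClasses = c(sbo_id = "integer"))
  for (i in seq_len(nrow(tl))) {
    term <- graph$terms[[as.character(tl$sbo_id[i])]]
    if (is.null(term))
      stop("configuration error: term ", sbo_format(tl$sbo_id[i]),
           " ('", tl$sbo_label[i], "') not present in the ontology",
           call. = FALSE)
    if (!identical(term$label, tl$sbo_label[i]))
      stop(sprintf(
        "configuration error: %s is labelled '%s' in the ontology but '%s' in the config",
        sbo_format(tl$sbo_id[i]), term$label, tl$sbo_label[i]), call. = FALSE)
  }
  ids <- stats::setNames(tl$sbo_id, tl$key)
  labels <- stats::setNames(tl$sbo_label, tl$key)
  store <- load_mapping_store(
    path = if (is.null(mapping))
      system.file("extdata", "ec_sbo_seed.tsv", package = "sbotagger")
    else mapping,
    graph = graph, generic_id = ids[["generic_biochemical"]])
  if (is.null(pts_sugars))
    pts_sugars <- system.file("extdata", "pts_sugars.tsv",
                              package = "sbotagger")
  pts <- utils::read.delim(pts_sugars, stringsAsFactors = FALSE)
  structure(list(
    graph = graph,
    store = store,
    ids = ids,
    labels = labels,
    moieties = list(
      atp_consumed = "atp", atp_produced = c("adp", "pi"),
      pep_consumed = "pep", pep_produced = "pyr"),
    pts = pts,
    macromolecule_patterns = character(0)   # species sub-typing off by default
  ), class = "sbo_config")
}

#' @export
print.sbo_config <- function(x, ...) {
  cat(sprintf(
    "SBO annotator config: %d terms in graph, %d mapping entries (%d classes), %d labelled roles\n",
    length(x$graph$terms), nrow(x$store),
    enzymatic_class_count(x$store, x$ids[["generic_biochemical"]]),
    length(x$ids)))
  invisible(x)
}

#' Default configuration (cached)
#' @return An `sbo_config` built from the bundled data files.
#' @export
default_config <- function() {
  cfg <- get0("default_config", envir = .sbotagger_cache)
  if (is.null(cfg)) {
    cfg <- sbo_config()
    assign("default_config", cfg, envir = .sbotagger_cache)
  }
  cfg
}
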