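#' Load the EC-to-SBO mapping store
#'
#' The store is a small relational table with one row per EC pattern:
#' `(ec_pattern, sbo_label, sbo_id, category, class_label)`. The shipped seed
#' (`inst/extdata/ec_sbo_seed.tsv`) encodes three mapping categories:
#' \describe{
#'   \item{one_to_one}{one term covers a whole EC class/subclass/sub-subclass
#'     (pattern depth 1-3), e.g. transamination for 2.6.1.-;}
#'   \item{one_to_few}{one term covers a small explicit set of four-field EC
#'     numbers, e.g. myristoylation for 2.3.1.97;}
#'   \item{one_to_many}{one term covers a larger explicit set within one
#'     sub-subclass, e.g. acetylation.}
#' }
#'
#' When `graph` is supplied every row is validated against the ontology:
#' the id must exist, carry exactly the stated label, and be a
#' descendant-or-equal of the generic biochemical-reaction term. This keeps
#' numeric ids honest: labels are the source of truth, ids are asserted.
#'
#' @param path Path to a tab-separated seed file; default is the shipped seed.
#' @param graph Optional `sbo_graph` used to validate labels and placement.
#' @param generic_id Id of the generic biochemical-reaction term used for the
#'   descendant check (default 176).
#' @return A `data.frame` of class `ec_sbo_store` with columns
#'   `ec_pattern`, `sbo_label`, `sbo_id`, `category`, `class_label`, `depth`.
#' @export
load_mapping_store <- function(path = system.file("extdata", "ec_sbo_seed.tsv",
                                                  package = "sbotagger"),
                               graph = NULL, generic_id = 176L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(sbo_id = "integer"))
  need <- c("ec_pattern", "sbo_label", "sbo_id", "category", "class_label")
  if (!all(need %in% names(tab)))
    stop("mapping seed must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$ec_pattern))
    stop("duplicate ec_pattern in mapping store: ",
         paste(tab$ec_pattern[duplicated(tab$ec_pattern)], collapse = ", "),
         call. = FALSE)
  bad_cat <- setdiff(tab$category, c("one_to_one", "one_to_few", "one_to_many"))
  if (length(bad_cat))
    stop("unknown mapping category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  pats <- lapply(tab$ec_pattern, ec_parse, strict = TRUE)
  tab$depth <- vapply(pats, ec_depth, integer(1))
  if (any(tab$category == "one_to_one" & tab$depth > 3L))
    stop("one_to_one entries must be patterns of depth <= 3", call. = FALSE)
  if (any(tab$category != "one_to_one" & tab$depth != 4L))
    stop("one_to_few/one_to_many entries must list explicit four-field ECs",
         call. = FALSE)
  if (!is.null(graph)) {
    for (i in seq_len(nrow(tab))) {
      key <- as.character(tab$sbo_id[i])
      term <- graph$terms[[key]]
      if (is.null(term))
        stop("mapping store references ", sbo_format(tab$sbo_id[i]),
             " which is absent from the ontology", call. = FALSE)
      if (!identical(term$label, tab$sbo_label[i]))
        stop(sprintf("label mismatch for %s: store says '%s', ontology '%s'",
                     sbo_format(tab$sbo_id[i]), tab$sbo_label[i], term$label),
             call. = FALSE)
      if (!sbo_is_a(graph, tab$sbo_id[i], generic_id))
        stop(sbo_format(tab$sbo_id[i]),
             " is not a descendant of the generic biochemical-reaction term",
             call. = FALSE)
    }
  }
  class(tab) <- c("ec_sbo_store", "data.frame")
  tab
}

#' Resolve one EC number against the mapping store
#'
#' The most specific matching entry wins: an exact four-field entry beats a
#' depth-3 prefix, which beats depth-2, which beats depth-1. ECs that match
#' no entry (including translocases, EC class 7, which are deliberately
#' absent from the biochemical map) resolve to nothing.
#'
#' @param ec An EC string or `ec_number`.
#' @param store An `ec_sbo_store`.
#' @return One-row `data.frame` (columns as the store) or `NULL`.
#' @examples
#' store <- load_mapping_store()
#' ec_lookup("6.3.2.4", store)$sbo_id   # ligase -> formation of a covalent bond
#' @export
ec_lookup <- function(ec, store) {
  if (is.character(ec)) ec <- ec_parse(ec, strict = FALSE)
  if (is.null(ec)) return(NULL)
  hits <- integer(0)
  depths <- integer(0)
  for (i in seq_len(nrow(store))) {
    pat <- ec_parse(store$ec_pattern[i], strict = TRUE)
    if (ec_matches(ec, pat)) {
      hits <- c(hits, i)
      depths <- c(depths, store$depth[i])
    }
  }
  if (length(hits) == 0L) return(NULL)
  store[hits[which.max(depths)], , drop = FALSE]
}

#' Resolve a biochemical reaction's SBO term from its EC numbers
#'
#' Policy: no ECs (or none that map) gives the generic biochemical-reaction
#' term; if all mapped ECs agree on one term, that term is used; if they map
#' to different terms the deepest common ancestor in the is-a graph is used,
#' clipped at the generic term — a common ancestor above "biochemical
#' reaction" is replaced by it, since a reaction term must stay within the
#' biochemical-reaction branch.
#'
#' @param ecs Character vector of EC numbers (may be empty).
#' @param graph An `sbo_graph` containing all mapped term ids.
#' @param store An `ec_sbo_store`.
#' @param generic_id Generic biochemical-reaction term id (default 176).
#' @return A list: `sbo_id` (integer), `rule` (one of `"no-ec-fallback"`,
#'   `"ec-unmapped-fallback"`, `"ec-direct"`, `"ec-common-ancestor"`), and
#'   `categories` (mapping categories of the entries that fired).
#' @export
resolve_reaction_term <- function(ecs, graph, store, generic_id = 176L) {
  if (is.null(graph$terms[[as.character(generic_id)]]))
    stop("generic term ", sbo_format(generic_id), " missing from ontology",
         call. = FALSE)
  if (length(ecs) == 0L)
    return(list(sbo_id = generic_id, rule = "no-ec-fallback",
                categories = character(0)))
  entries <- lapply(ecs, ec_lookup, store = store)
  entries <- entries[!vapply(entries, is.null, logical(1))]
  if (length(entries) == 0L)
    return(list(sbo_id = generic_id, rule = "ec-unmapped-fallback",
                categories = character(0)))
  ids <- unique(vapply(entries, function(e) e$sbo_id, integer(1)))
  cats <- unique(vapply(entries, function(e) e$category, character(1)))
  missing <- ids[!vapply(ids, function(i)
    !is.null(graph$terms[[as.character(i)]]), logical(1))]
  if (length(missing))
    stop("mapped term(s) absent from ontology: ",
         paste(sbo_format(missing), collapse = ", "), call. = FALSE)
  if (length(ids) == 1L)
    return(list(sbo_id = ids, rule = "ec-direct", categories = cats))
  anc <- sbo_common_ancestor(graph, ids)
  if (is.na(anc) || !sbo_is_a(graph, anc, generic_id)) anc <- generic_id
  list(sbo_id = as.integer(anc), rule = "ec-common-ancestor", categories = cats)
}

#' Number of distinct enzymatic-function classes in a mapping store
#'
#' Counts the distinct specific SBO term ids reachable through biochemical EC
#' lookup, excluding the generic fallback term. The shipped seed
#' distinguishes 18 such classes.
#'
#' @param store An `ec_sbo_store` (or plain data.frame with an `sbo_id` column).
#' @param generic_id Generic biochemical-reaction id excluded from the count.
#' @return Integer count.
#' @export
enzymatic_class_count <- function(store, generic_id = 176L) {
  length(setdiff(unique(store$sbo_id), generic_id))
}
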