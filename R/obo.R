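#' Load an SBO is-a hierarchy from an OBO flat file
#'
#' Parses `[Term]` stanzas, keeping the `id`, `name` and `is_a` tags.
#' Obsolete terms (`is_obsolete: true`) are dropped, as are is-a edges
#' pointing at them. Only the is-a relation is modelled; other OBO relations
#' are ignored.
#'
#' @param path Path to an OBO file.
#' @return An object of class `sbo_graph`: a list with
#'   \describe{
#'     \item{terms}{named list keyed by numeric id (as character); each entry
#'       has `id` (integer), `label`, `parents` (integer vector).}
#'     \item{roots}{integer vector of ids with no parents.}
#'     \item{depth}{named integer vector: longest path from a root.}
#'   }
#' @details Cyclic `is_a` chains are a hard error naming the cycle: ancestor
#'   reasoning (term specificity, common-ancestor resolution) is meaningless
#'   on a cyclic graph.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L)
    stop("no [Term] stanzas in OBO file: ", path, call. = FALSE)
  # stanza bounds: from each [Term] to the next stanza header or EOF
  headers <- grep("^\\[", lines)
  terms <- list()
  for (s in term_starts) {
    e <- headers[headers > s]
    e <- if (length(e)) e[1L] - 1L else length(lines)
    block <- lines[(s + 1L):e]
    tagval <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", hits))
    }
    id_raw <- tagval("id")
    if (length(id_raw) == 0L) next
    id <- sbo_id_from_string(id_raw[1L])
    if (is.na(id)) stop("unparseable term id '", id_raw[1L], "'", call. = FALSE)
    obsolete <- any(tolower(tagval("is_obsolete")) == "true")
    if (obsolete) next
    name <- tagval("name")
    isa_raw <- tagval("is_a")
    # "SBO:0000176 ! biochemical reaction" -> id before any comment
    parents <- vapply(isa_raw, function(v)
      sbo_id_from_string(sub("\\s*!.*$", "", v)), integer(1), USE.NAMES = FALSE)
    terms[[as.character(id)]] <- list(
      id = id,
      label = if (length(name)) name[1L] else "",
      parents = parents[!is.na(parents)]
    )
  }
  ids <- as.integer(names(terms))
  # drop dangling parent references (e.g. edges into obsolete terms)
  for (k in names(terms))
    terms[[k]]$parents <- terms[[k]]$parents[terms[[k]]$parents %in% ids]
  g <- structure(list(terms = terms), class = "sbo_graph")
  g$roots <- ids[vapply(terms, function(t) length(t$parents) == 0L, logical(1))]
  g$depth <- graph_depths(g)   # also detects cycles
  g
}

#' @export
print.sbo_graph <- function(x, ...) {
  cat(sprintf("SBO is-a graph: %d terms, %d root(s), max depth %d\n",
              length(x$terms), length(x$roots), max(x$depth)))
  invisible(x)
}

# "SBO:0000176" / "0000176" / "176" -> 176L
sbo_id_from_string <- function(s) {
  s <- trimws(s)
  s <- sub("^SBO:", "", s, ignore.case = TRUE)
  if (!grepl("^[0-9]+$", s)) return(NA_integer_)
  as.integer(s)
}

#' Render a numeric SBO id in canonical form
#'
#' @param id Integer id(s) in `[0, 9999999]`.
#' @return Character like `"SBO:0000176"`.
#' @examples sbo_format(176)
#' @export
sbo_format <- function(id) {
  stopifnot(all(!is.na(id)), all(id >= 0), all(id <= 9999999))
  sprintf("SBO:%07d", as.integer(id))
}

# longest-path-from-root depths; errors on cycles (naming one cycle)
graph_depths <- function(graph) {
  terms <- graph$terms
  depth <- integer(0)
  state <- new.env(parent = emptyenv())  # 1 = in progress, 2 = done
  memo <- new.env(parent = emptyenv())
  visit <- function(id, trail) {
    key <- as.character(id)
    st <- get0(key, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      cyc <- c(trail[which(trail == id)[1L]:length(trail)], id)
      stop("cyclic is_a relation: ", paste(sbo_format(cyc), collapse = " -> "),
           call. = FALSE)
    }
    if (st == 2L) return(get(key, envir = memo))
    assign(key, 1L, envir = state)
    p <- terms[[key]]$parents
    d <- if (length(p) == 0L) 0L else
      1L + max(vapply(p, visit, integer(1), trail = c(trail, id)))
    assign(key, 2L, envir = state)
    assign(key, d, envir = memo)
    d
  }
  ids <- as.integer(names(terms))
  out <- vapply(ids, visit, integer(1), trail = integer(0))
  names(out) <- names(terms)
  out
}

#' Ancestors of a term (including the term itself)
#'
#' @param graph An `sbo_graph`.
#' @param id Integer term id.
#' @return Integer vector of ancestor-or-self ids (unordered).
#' @export
sbo_ancestors <- function(graph, id) {
  key <- as.character(id)
  if (is.null(graph$terms[[key]]))
    stop("term ", sbo_format(id), " not in ontology", call. = FALSE)
  seen <- new.env(parent = emptyenv())
  stack <- id
  out <- integer(0)
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    k <- as.character(cur)
    if (isTRUE(get0(k, envir = seen))) next
    assign(k, TRUE, envir = seen)
    out <- c(out, cur)
    stack <- c(stack, graph$terms[[k]]$parents)
  }
  out
}

#' Is `id` a descendant of (or equal to) `ancestor`?
#' @param graph An `sbo_graph`.
#' @param id,ancestor Integer term ids; `id` must exist in the graph.
#' @return Logical scalar.
#' @export
sbo_is_a <- function(graph, id, ancestor) {
  ancestor %in% sbo_ancestors(graph, id)
}

#' Deepest common ancestor of a set of terms
#'
#' The common ancestor (ancestor-or-self of every input) of maximal depth,
#' with depth measured as the longest path from a root; ties are broken by
#' the smaller term id so the result is deterministic.
#'
#' @param graph An `sbo_graph`.
#' @param ids Integer vector of term ids (length >= 1).
#' @return Integer id of the deepest common ancestor, or `NA` if the terms
#'   share no ancestor (disjoint branches with different roots).
#' @export
sbo_common_ancestor <- function(graph, ids) {
  ids <- unique(as.integer(ids))
  stopifnot(length(ids) >= 1L)
  common <- Reduce(intersect, lapply(ids, function(i) sbo_ancestors(graph, i)))
  if (length(common) == 0L) return(NA_integer_)
  d <- graph$depth[as.character(common)]
  cand <- common[d == max(d)]
  min(cand)
}
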