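## Optional BiGG Models web API client for back-filling EC numbers.
## The network gateway is injectable so the whole pipeline is testable
## hermetically; the default is strictly offline.

#' Gateways for the BiGG Models API
#'
#' A gateway is a function `(reaction_id) -> character vector of EC numbers,
#' or NULL when the reaction is unknown`. Three constructors:
#' \describe{
#'   \item{offline_gateway()}{never touches the network; every lookup is an
#'     immediate `absent` result.}
#'   \item{stub_gateway(map)}{serves from a named list (tests); attribute
#'     `calls` on the returned function's environment counts invocations.}
#'   \item{remote_gateway(base_url)}{queries the live BiGG REST API
#'     (universal reaction resource, `database_links` section), retrying
#'     once; failures warn and return `NULL` so annotation falls back to
#'     generic terms instead of aborting.}
#' }
#'
#' @param map Named list, reaction id -> character vector of ECs.
#' @param base_url BiGG API root.
#' @return A gateway function.
#' @name bigg_gateways
NULL

#' @rdname bigg_gateways
#' @export
offline_gateway <- function() {
  f <- function(reaction_id) NULL
  attr(f, "offline") <- TRUE
  f
}

#' @rdname bigg_gateways
#' @export
stub_gateway <- function(map = list()) {
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  f <- function(reaction_id) {
    env$calls <- env$calls + 1L
    map[[reaction_id]]
  }
  attr(f, "counter") <- env
  f
}

#' @rdname bigg_gateways
#' @export
remote_gateway <- function(base_url = "http://bigg.ucsd.edu/api/v2") {
  function(reaction_id) {
    url <- sprintf("%s/universal/reactions/%s", base_url, reaction_id)
    for (attempt in 1:2) {
      res <- tryCatch(jsonlite::fromJSON(url, simplifyVector = FALSE),
                      error = function(e) e)
      if (!inherits(res, "error")) {
        links <- res$database_links
        ec <- links[["EC Number"]]
        if (is.null(ec)) return(character(0))
        return(vapply(ec, function(x) as.character(x$id), character(1)))
      }
    }
    warning("BiGG lookup failed for '", reaction_id, "': ",
            conditionMessage(res), "; falling back to generic annotation",
            call. = FALSE)
    NULL
  }
}

#' Fetch EC numbers for a BiGG reaction id
#'
#' Strips an SBML-style `R_` prefix, consults the on-disk cache, then the
#' gateway. Results (including negative ones) are cached in a single
#' tab-separated table `(reaction_id, ec, fetched_at)` under `cache`, so
#' repeated calls never re-query the network.
#'
#' @param bigg_reaction_id Reaction id (with or without `R_` prefix).
#' @param gateway A gateway function; default [offline_gateway()].
#' @param cache Cache directory (created if needed) or `NULL` to disable.
#' @return List of class `ec_fetch_result`: `reaction_id`, `ec_numbers`
#'   (canonical strings), `source` (`"cache"`, `"remote"` or `"absent"`).
#' @export
fetch_reaction_ec <- function(bigg_reaction_id, gateway = offline_gateway(),
                              cache = NULL) {
  rid <- sub("^R_", "", bigg_reaction_id)
  result <- function(ecs, source) {
    ecs <- if (length(ecs)) ec_normalize_chr(ecs) else character(0)
    structure(list(reaction_id = rid, ec_numbers = ecs, source = source),
              class = "ec_fetch_result")
  }
  cached <- cache_get(cache, rid)
  if (!is.null(cached)) return(result(cached, "cache"))
  if (isTRUE(attr(gateway, "offline"))) return(result(character(0), "absent"))
  ecs <- gateway(rid)
  if (is.null(ecs)) {
    cache_put(cache, rid, character(0))
    return(result(character(0), "absent"))
  }
  cache_put(cache, rid, ecs)
  result(ecs, "remote")
}

#' @export
print.ec_fetch_result <- function(x, ...) {
  cat(sprintf("EC fetch [%s] %s: %s\n", x$source, x$reaction_id,
              if (length(x$ec_numbers)) paste(x$ec_numbers, collapse = ", ")
              else "(none)"))
  invisible(x)
}

cache_file <- function(cache) file.path(cache, "ec_cache.tsv")

cache_read <- function(cache) {
  f <- cache_file(cache)
  if (!file.exists(f))
    return(data.frame(reaction_id = character(0), ec = character(0),
                      fetched_at = character(0), stringsAsFactors = FALSE))
  utils::read.delim(f, stringsAsFactors = FALSE,
                    colClasses = "character")
}

# NULL when never fetched; character(0) when fetched-and-absent
cache_get <- function(cache, rid) {
  if (is.null(cache)) return(NULL)
  tab <- cache_read(cache)
  hit <- tab[tab$reaction_id == rid, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit$ec[nzchar(hit$ec)]
}

cache_put <- function(cache, rid, ecs) {
  if (is.null(cache)) return(invisible(NULL))
  dir.create(cache, showWarnings = FALSE, recursive = TRUE)
  tab <- cache_read(cache)
  tab <- tab[tab$reaction_id != rid, , drop = FALSE]
  add <- data.frame(reaction_id = rid,
                    ec = if (length(ecs)) ecs else "",
                    fetched_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stringsAsFactors = FALSE)
  utils::write.table(rbind(tab, add), cache_file(cache), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
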