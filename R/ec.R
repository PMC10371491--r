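#' Parse an Enzyme Commission number or pattern
#'
#' An EC number has four dot-separated fields: class.subclass.sub-subclass.serial.
#' Patterns may truncate from the right, or use `-` for trailing wildcard
#' fields ("2.6.1.-" and "2.6.1" are the same pattern). Wildcards are only
#' allowed as a suffix: once a field is wild, all later fields must be wild.
#'
#' @param x A single EC string, e.g. `"2.6.1.1"` or `"6.-.-.-"`.
#' @param strict If `TRUE`, invalid input is an error; otherwise `NULL` is
#'   returned (used by lookup, where an unmatchable EC simply maps to nothing).
#' @return An object of class `ec_number`: integer vector of length 4 with
#'   `NA` for wildcard fields, or `NULL` when invalid and `strict = FALSE`.
#' @examples
#' ec_parse("2.6.1.1")
#' ec_parse("6.-.-.-")
#' @export
ec_parse <- function(x, strict = FALSE) {
  fail <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else return(NULL)
  }
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(fail("empty EC string"))
  x <- trimws(x)
  # optional "EC " prefix as seen in some resource annotations
  x <- sub("^[Ee][Cc][: ]\\s*", "", x)
  parts <- strsplit(x, ".", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 4L)
    return(fail(sprintf("malformed EC number '%s'", x)))
  parts <- c(parts, rep("-", 4L - length(parts)))
  ok <- grepl("^([0-9]+|-)$", parts)
  if (!all(ok)) return(fail(sprintf("malformed EC number '%s'", x)))
  d <- suppressWarnings(as.integer(ifelse(parts == "-", NA, parts)))
  # wildcards must be a suffix: no digit after a wildcard
  wild <- is.na(d)
  if (any(wild) && any(diff(wild) < 0))
    return(fail(sprintf("non-suffix wildcard in EC pattern '%s'", x)))
  if (is.na(d[1L]) || d[1L] < 1L || d[1L] > 7L)
    return(fail(sprintf("EC class must be 1-7, got '%s'", x)))
  if (any(!wild[-1L] & d[-1L] < 1L, na.rm = TRUE))
    return(fail(sprintf("EC fields must be positive in '%s'", x)))
  structure(d, class = "ec_number")
}

#' @export
format.ec_number <- function(x, ...) {
  paste(ifelse(is.na(unclass(x)), "-", unclass(x)), collapse = ".")
}

#' @export
print.ec_number <- function(x, ...) {
  cat("EC ", format(x), "\n", sep = "")
  invisible(x)
}

#' Depth of an EC pattern
#'
#' Number of leading non-wildcard fields (1 for "2.-.-.-", 4 for "2.6.1.1").
#' @param ec An `ec_number`.
#' @return Integer in 1..4.
#' @export
ec_depth <- function(ec) {
  d <- unclass(ec)
  w <- which(is.na(d))
  if (length(w) == 0L) 4L else w[1L] - 1L
}

#' Does an EC number fall under a pattern?
#'
#' @param ec An `ec_number` (usually fully specified).
#' @param pattern An `ec_number` pattern (wildcards allowed).
#' @return `TRUE` when all non-wildcard fields of `pattern` equal the
#'   corresponding fields of `ec`.
#' @export
ec_matches <- function(ec, pattern) {
  dp <- ec_depth(pattern)
  if (ec_depth(ec) < dp) return(FALSE)
  all(unclass(ec)[seq_len(dp)] == unclass(pattern)[seq_len(dp)])
}

# normalize a character vector of EC strings to canonical text form,
# dropping invalid entries (with one warning naming them) and duplicates
ec_normalize_chr <- function(x) {
  parsed <- lapply(x, ec_parse, strict = FALSE)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    warning(sprintf("skipping malformed EC number(s): %s",
                    paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  out <- vapply(parsed[!bad], format, character(1))
  out[!duplicated(out)]
}
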