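# Brute-force ontology oracle, independent of the package's graph routines:
# ancestor sets by fixpoint iteration over parent links, depths by full
# recursive longest-path enumeration.

oracle_ancestors <- function(graph, id) {
  s <- id
  repeat {
    p <- unique(unlist(lapply(s, function(i)
      graph$terms[[as.character(i)]]$parents)))
    n <- union(s, p)
    if (length(n) == length(s)) return(s)
    s <- n
  }
}

oracle_depth <- function(graph, id) {
  p <- graph$terms[[as.character(id)]]$parents
  if (length(p) == 0L) return(0L)
  1L + max(vapply(p, function(q) oracle_depth(graph, q), integer(1)))
}

# enumerate all common ancestors, take maximal depth, break ties by min id
oracle_common_ancestor <- function(graph, ids) {
  common <- Reduce(intersect, lapply(ids, function(i)
    oracle_ancestors(graph, i)))
  if (length(common) == 0L) return(NA_integer_)
  d <- vapply(common, function(i) oracle_depth(graph, i), integer(1))
  min(common[d == max(d)])
}
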