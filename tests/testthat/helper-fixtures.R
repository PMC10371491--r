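# Shared fixtures, built once per test run.

tcfg <- default_config()

# full-branch fixture model on disk (plus expectations sidecar)
fixture_env <- new.env()
full_fixture <- function() {
  if (is.null(fixture_env$path)) {
    dir <- file.path(tempdir(), "sbotagger-fixtures")
    fixture_env$path <- build_fixture(full_branch_spec(), dir = dir)
  }
  fixture_env$path
}

read_expectations <- function(path) {
  read.delim(attr(path, "expectations"), stringsAsFactors = FALSE)
}

# a one-reaction-per-class document built in memory
six_class_doc <- function() {
  model_doc(
    model_id = "six",
    compartments = c("c", "e"),
    species = data.frame(
      id = c("o2_e", "amob_c", "ppi_c", "bm_c", "aa_c", "o2_c",
             "g6p_c", "f6p_c"),
      compartment = c("e", "c", "c", "c", "c", "c", "c", "c"),
      stringsAsFactors = FALSE),
    reactions = list(
      list(id = "EX_o2_e", reactants = c(o2_e = 1), reversible = TRUE),
      list(id = "DM_amob_c", reactants = c(amob_c = 1)),
      list(id = "SK_ppi_c", reactants = c(ppi_c = 1), reversible = TRUE),
      list(id = "GROWTH", reactants = c(aa_c = 1), products = c(bm_c = 1),
           objective = TRUE),
      list(id = "O2t", reactants = c(o2_e = 1), products = c(o2_c = 1),
           reversible = TRUE),
      list(id = "PGI", reactants = c(g6p_c = 1), products = c(f6p_c = 1),
           reversible = TRUE)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
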