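test_that("the shipped seed loads, validates against the ontology, and spans 18 classes", {
  store <- load_mapping_store(graph = tcfg$graph)
  expect_s3_class(store, "ec_sbo_store")
  expect_true(all(store$category %in%
                    c("one_to_one", "one_to_few", "one_to_many")))
  expect_true(all(store$depth[store$category == "one_to_one"] <= 3L))
  expect_true(all(store$depth[store$category != "one_to_one"] == 4L))
  expect_equal(enzymatic_class_count(store), 18L)
})

test_that("class counting is over distinct terms", {
  expect_equal(enzymatic_class_count(data.frame(sbo_id = integer(0))), 0L)
  expect_equal(enzymatic_class_count(data.frame(sbo_id = c(214L, 214L))), 1L)
  expect_equal(enzymatic_class_count(data.frame(sbo_id = c(176L, 214L))), 1L)
})

test_that("seed validation catches duplicates, bad categories and label drift", {
  seed <- read.delim(system.file("extdata", "ec_sbo_seed.tsv",
                                 package = "sbotagger"))
  dup <- rbind(seed, seed[1, ])
  f <- tempfile(fileext = ".tsv")
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_mapping_store(f), "duplicate ec_pattern")
  drift <- seed
  drift$sbo_label[drift$sbo_id == 402][1] <- "transaminationX"
  write.table(drift, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_mapping_store(f, graph = tcfg$graph), "label mismatch")
})

test_that("lookup resolves printed and labelled examples", {
  store <- tcfg$store
  expect_equal(ec_lookup("6.3.2.4", store)$sbo_id, 695L)
  hit <- ec_lookup("2.6.1.1", store)
  expect_equal(hit$sbo_label, "transamination")
  expect_equal(tcfg$graph$terms[[as.character(hit$sbo_id)]]$label,
               "transamination")
  expect_null(ec_lookup("9.9.9.9", store))
  expect_null(ec_lookup("7.1.1.1", store))  # translocases stay unmapped
})

test_that("the most specific pattern wins, including on randomized stores", {
  store <- tcfg$store
  # explicit depth-4 acetylation entry beats the depth-1 transferase fallback
  expect_equal(ec_lookup("2.3.1.9", store)$sbo_id, 215L)
  # an unlisted sibling serial falls back to the prefix entry
  expect_equal(ec_lookup("2.3.1.2", store)$sbo_id, 210L)

  set.seed(42)
  for (i in 1:25) {
    d <- c(sample(1:6, 1), sample(1:20, 3, replace = TRUE))
    ec <- paste(d, collapse = ".")
    prefix_depth <- sample(1:3, 1)
    prefix <- paste(c(d[seq_len(prefix_depth)],
                      rep("-", 4 - prefix_depth)), collapse = ".")
    f <- tempfile(fileext = ".tsv")
    write.table(data.frame(
      ec_pattern = c(prefix, ec),
      sbo_label = c("addition of a chemical group", "methylation"),
      sbo_id = c(210L, 214L),
      category = c("one_to_one", "one_to_few"),
      class_label = c("p", "x")), f, sep = "\t", quote = FALSE,
      row.names = FALSE)
    st <- load_mapping_store(f)
    expect_equal(ec_lookup(ec, st)$sbo_id, 214L, info = ec)
  }
})

test_that("reaction-term resolution follows fallback, unanimity and ancestor rules", {
  g <- tcfg$graph; store <- tcfg$store
  r <- resolve_reaction_term(character(0), g, store)
  expect_equal(r$sbo_id, 176L)
  expect_equal(r$rule, "no-ec-fallback")

  r <- resolve_reaction_term(c("2.6.1.1", "2.6.1.2"), g, store)
  expect_equal(r$sbo_id, 402L)
  expect_equal(r$rule, "ec-direct")

  # methylation and acetylation are siblings under group addition
  r <- resolve_reaction_term(c("2.1.1.1", "2.3.1.1"), g, store)
  expect_equal(r$sbo_id, 210L)
  expect_equal(r$rule, "ec-common-ancestor")

  # oxidoreduction and hydrolysis only meet above the generic term: clipped
  r <- resolve_reaction_term(c("1.1.1.1", "3.1.1.1"), g, store)
  expect_equal(r$sbo_id, 176L)

  # unmapped ECs fall back to the generic term
  r <- resolve_reaction_term("7.1.1.1", g, store)
  expect_equal(r$sbo_id, 176L)
  expect_equal(r$rule, "ec-unmapped-fallback")
})

test_that("a store term missing from the graph is a configuration error", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(ec_pattern = "1.-.-.-", sbo_label = "nope",
                         sbo_id = 9999L, category = "one_to_one",
                         class_label = "x"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- load_mapping_store(f)  # no graph: loads fine
  expect_error(resolve_reaction_term("1.1.1.1", tcfg$graph, st),
               "absent from ontology")
})

test_that("every seed term is a descendant of the generic biochemical term", {
  for (id in unique(tcfg$store$sbo_id))
    expect_true(sbo_is_a(tcfg$graph, id, 176L), info = sbo_format(id))
})
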