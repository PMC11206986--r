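test_that("library generation is a pure function of its spec", {
  spec <- library_spec(n_known = 3, n_analog = 4, n_decoy = 4, seed = 7)
  g1 <- generate_library(spec)
  g2 <- generate_library(spec)
  expect_identical(g1$library$records, g2$library$records)
  expect_identical(g1$truth, g2$truth)

  other <- generate_library(library_spec(n_known = 3, n_analog = 4,
                                         n_decoy = 4, seed = 8))
  expect_false(identical(g1$library$records$smiles,
                         other$library$records$smiles))
})

test_that("degenerate partition sizes are honored", {
  g <- generate_library(library_spec(n_known = 4, n_analog = 0, n_decoy = 0))
  expect_equal(nrow(g$library$records), 4L)
  expect_equal(n_known(g$library), 4L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("default planted library straddles the selection threshold by construction", {
  g <- generate_library(library_spec(seed = 1))
  expect_equal(n_known(g$library), 5L)
  expect_equal(n_candidate(g$library), 20L)

  m <- pairwise_similarity(g$library)
  sc <- score_candidates(m)
  analogs <- g$truth$compound_id[g$truth$role == "analog"]
  decoys <- g$truth$compound_id[g$truth$role == "decoy"]
  expect_setequal(sc$candidate_id[sc$selected], analogs)
  expect_true(all(!sc$selected[sc$candidate_id %in% decoys]))

  # per-pair planted property: every analog has an edge, no decoy does
  net <- build_network(m)
  expect_true(all(analogs %in% net$nodes$compound_id))
  expect_true(all(!decoys %in% net$nodes$compound_id))
})

test_that("planted targets survive the retention filters and background does not", {
  lib <- generate_library(library_spec(seed = 2))$library
  gen <- generate_predictions(lib, prediction_spec(seed = 2))
  tset <- aggregate_and_filter(gen$predictions)
  planted <- gen$truth$gene_symbol[gen$truth$planted]
  expect_setequal(tset$gene_symbol[tset$retained], planted)

  # identical seed, identical tables
  gen2 <- generate_predictions(lib, prediction_spec(seed = 2))
  expect_identical(gen$predictions, gen2$predictions)

  # background-only spec with very low scores retains nothing
  bg <- generate_predictions(lib, prediction_spec(
    n_targets = 10, n_planted = 0, background_score_max = 0.05, seed = 3))
  expect_warning(tbg <- aggregate_and_filter(bg$predictions), "no target")
  expect_equal(sum(tbg$retained), 0L)
})

test_that("planted gene set ranks first in both sources and is the sole normalized overlap", {
  lib <- generate_library(library_spec(seed = 4))$library
  gen <- generate_predictions(lib, prediction_spec(seed = 4))
  tset <- aggregate_and_filter(gen$predictions)
  gs <- generate_genesets(tset, geneset_spec(seed = 4))
  retained <- tset$gene_symbol[tset$retained]

  res_a <- ora(retained, gs$source_a)
  res_b <- ora(retained, gs$source_b)
  expect_equal(res_a$set_name[1], gs$truth$name_a)
  expect_equal(res_b$set_name[1], gs$truth$name_b)

  ov <- top_k_overlap(res_a, res_b, k = 5, name_matcher = "normalized")
  expect_equal(ov$shared_name, gs$truth$normalized)

  # planted set absent from source B -> empty normalized overlap
  b_sets <- gs$source_b$sets
  b_sets[[gs$truth$name_b]] <- NULL
  crippled <- new_geneset_collection(b_sets, "crippled",
                                     universe = gs$source_b$universe)
  res_b2 <- ora(retained, crippled)
  ov2 <- top_k_overlap(res_a, res_b2, k = 5, name_matcher = "normalized")
  expect_equal(nrow(ov2), 0L)

  # fixed seed -> byte-identical GMT output
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(generate_genesets(tset, geneset_spec(seed = 4))$source_a, f1)
  write_gmt(generate_genesets(tset, geneset_spec(seed = 4))$source_a, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unsatisfiable generation requests fail loudly", {
  # distance-3 analogs are decoy-like; similarity verification is skipped
  # for them, so this must succeed
  spec3 <- library_spec(n_known = 1, n_analog = 1, n_decoy = 0,
                        analog_distance = 3, seed = 1)
  expect_no_error(generate_library(spec3))
  # requesting analogs with no knowns is a generation error
  bad <- library_spec(n_known = 0, n_analog = 2, n_decoy = 0)
  expect_error(generate_library(bad), "known active")
})
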