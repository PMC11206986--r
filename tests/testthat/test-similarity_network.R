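labeled_tiny <- function() {
  label_activity(read_compound_table(tiny_library()), c("c1", "c2"))
}

test_that("pairwise similarity grids are complete, bounded and flag identity", {
  lib <- labeled_tiny()
  m <- pairwise_similarity(lib)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m >= 0 & m <= 1))

  # a candidate structurally identical to a known scores 1.0
  path <- write_lib_csv(data.frame(
    compound_id = c("k", "same", "other"),
    smiles = c("c1ccccc1O", "Oc1ccccc1", "CCCCCC"),
    stringsAsFactors = FALSE
  ))
  lib2 <- label_activity(read_compound_table(path), "k")
  m2 <- pairwise_similarity(lib2)
  expect_equal(unname(m2["k", "same"]), 1)

  unlabeled <- read_compound_table(tiny_library())
  expect_error(pairwise_similarity(unlabeled), "at least one")
})

test_that("candidate selection is strict at the boundary and ranks deterministically", {
  m <- sim_matrix(c(0.6, 0.2,   # C1: avg exactly 0.4 -> excluded
                    0.9, 0.9,   # C2: avg 0.9
                    0.5, 0.5),  # C3: avg 0.5
                  c("K1", "K2"), c("C1", "C2", "C3"))
  sc <- score_candidates(m)
  expect_false(sc$selected[sc$candidate_id == "C1"])
  expect_true(is.na(sc$rank[sc$candidate_id == "C1"]))
  expect_equal(sc$candidate_id[sc$rank %in% 1L], "C2")
  expect_equal(sc$candidate_id[sc$rank %in% 2L], "C3")

  # ties in avg_tc break by candidate_id, ascending
  tie <- sim_matrix(rep(0.7, 4), c("K1", "K2"), c("Cb", "Ca"))
  sct <- score_candidates(tie)
  expect_equal(sct$candidate_id[order(sct$rank)], c("Ca", "Cb"))
})

test_that("neighbors-only averaging defines zero-neighbor candidates as unselected", {
  m <- sim_matrix(c(0.8, 0.1,    # C1: one neighbor at 0.8
                    0.3, 0.2),   # C2: no neighbor
                  c("K1", "K2"), c("C1", "C2"))
  sc <- score_candidates(m, averaging_mode = "neighbors_only")
  expect_equal(sc$avg_tc[sc$candidate_id == "C1"], 0.8)
  expect_equal(sc$n_known_neighbors[sc$candidate_id == "C1"], 1L)
  expect_equal(sc$avg_tc[sc$candidate_id == "C2"], 0)
  expect_false(sc$selected[sc$candidate_id == "C2"])
})

test_that("edges are inclusive at the threshold and isolated nodes are dropped", {
  m <- sim_matrix(c(0.5, 0.40, 0.39), "K1", c("C1", "C2", "C3"))
  net <- build_network(m)
  expect_equal(nrow(net$edges), 2L)                # 0.40 is included
  expect_setequal(net$edges$candidate_id, c("C1", "C2"))
  expect_false("C3" %in% net$nodes$compound_id)    # isolated, excluded

  expect_warning(empty <- build_network(m, edge_threshold = 1.01),
                 "no compound pair")
  expect_equal(nrow(empty$edges), 0L)
})

test_that("edge and selection counts are monotone in their thresholds", {
  set.seed(7)
  m <- sim_matrix(runif(30), paste0("K", 1:5), paste0("C", 1:6))
  thresholds <- seq(0, 1, by = 0.1)
  edge_counts <- vapply(thresholds, function(t)
    nrow(suppressWarnings(build_network(m, edge_threshold = t))$edges),
    numeric(1))
  sel_counts <- vapply(thresholds, function(t)
    sum(score_candidates(m, selection_threshold = t)$selected), numeric(1))
  expect_true(all(diff(edge_counts) <= 0))
  expect_true(all(diff(sel_counts) <= 0))
})

test_that("all-knowns averages agree with a brute-force row mean", {
  set.seed(11)
  for (i in 1:50) {
    nk <- sample(2:6, 1); nc <- sample(2:6, 1)
    m <- sim_matrix(runif(nk * nc), paste0("K", 1:nk), paste0("C", 1:nc))
    sc <- score_candidates(m)
    brute <- vapply(sc$candidate_id, function(id)
      mean(unclass(m)[, id]), numeric(1))
    expect_identical(sc$avg_tc, unname(brute))
  }
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  lib <- labeled_tiny()
  m <- pairwise_similarity(lib)
  sc <- score_candidates(m, selection_threshold = 0)
  net <- build_network(m, edge_threshold = 0.01)
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, format = "graphml", scores = sc, library = lib)
  back <- read_network_graphml(path)

  expect_setequal(back$nodes$compound_id, net$nodes$compound_id)
  expect_equal(back$nodes$role[order(back$nodes$compound_id)],
               net$nodes$role[order(net$nodes$compound_id)])
  expect_equal(back$edges[order(back$edges$candidate_id), ],
               net$edges[order(net$edges$candidate_id), ],
               tolerance = 1e-12)
  expect_equal(back$threshold, net$threshold)
  cand <- back$nodes[back$nodes$role == "potential_active", ]
  expect_equal(cand$avg_tc[order(cand$compound_id)],
               sc$avg_tc[match(sort(cand$compound_id), sc$candidate_id)],
               tolerance = 1e-12)
})

test_that("SIF export uses the tc_sim relation with known id first", {
  m <- sim_matrix(c(0.5, 0.45), c("K1", "K2"), "C1")
  net <- build_network(m)
  path <- tempfile(fileext = ".sif")
  export_network(net, path, format = "sif")
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  fields <- strsplit(lines, "[\t ]+")
  for (f in fields) {
    expect_equal(length(f), 3L)
    expect_equal(f[2], "tc_sim")
    expect_match(f[1], "^K")
    expect_equal(f[3], "C1")
  }
})
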