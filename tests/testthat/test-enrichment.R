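test_that("GMT files parse with member dedup and line-numbered rejection of bad lines", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c(
    "SetA\tdesc\tA\tB\tC",
    "SetB\tdesc\tD\tE\tF\tG",
    "NameOnly",
    "SetC\tdesc\tH\tH\tI"
  ), path)
  col <- read_gmt(path)
  expect_equal(length(col$sets), 3L)
  expect_equal(attr(col, "rejected_lines"), 3L)
  expect_equal(col$sets$SetC, c("H", "I"))          # duplicate stored once
  expect_equal(length(col$universe), 9L)

  allbad <- tempfile(fileext = ".gmt")
  writeLines("JustAName", allbad)
  expect_error(read_gmt(allbad), "parse error.*line")

  # round trip
  out <- tempfile(fileext = ".gmt")
  write_gmt(col, out)
  expect_equal(read_gmt(out)$sets, col$sets)
})

test_that("hypergeometric p-values are exact on analytic cases", {
  col <- new_geneset_collection(
    list(Full = paste0("g", 1:5)), "one-set",
    universe = paste0("g", 1:10)
  )
  res <- ora(paste0("g", 1:5), col)
  expect_equal(res$p_value, 1 / choose(10, 5))      # all 5 of 5 drawn

  # zero overlap -> p = 1 exactly
  res0 <- ora(paste0("g", 6:10), col)
  expect_equal(res0$k, 0L)
  expect_equal(res0$p_value, 1)

  # query = universe -> k = K and p = 1 for every set
  toy <- toy_collection()
  resU <- ora(toy$universe, toy)
  expect_equal(resU$k, resU$K)
  expect_true(all(resU$p_value == 1))
})

test_that("hypergeometric tail matches stats::phyper across random instances", {
  set.seed(3)
  for (i in 1:200) {
    N <- sample(5:500, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(npscreen:::hyper_upper_tail(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("p-values are monotone in the overlap and results deterministically ordered", {
  for (k in 1:5) {
    expect_lte(npscreen:::hyper_upper_tail(k + 1, 6, 6, 20),
               npscreen:::hyper_upper_tail(k, 6, 6, 20))
  }
  toy <- toy_collection()
  res <- ora(c("A", "B", "C"), toy)
  expect_equal(res$set_name[1], "S1")
  expect_true(!is.unsorted(res$p_value))
  expect_true(all(res$q_value >= res$p_value))
  expect_equal(res$neg_log10_p, -log10(res$p_value))
})

test_that("query symbols outside the universe are dropped with a message, empty query errors", {
  toy <- toy_collection()
  expect_message(res <- ora(c("A", "B", "NOPE"), toy), "1 query symbol")
  expect_equal(res$n[1], 2L)
  expect_equal(attr(res, "n_dropped"), 1L)
  expect_error(suppressMessages(ora(c("NOPE1", "NOPE2"), toy)), "no query symbol")
})

test_that("EASE variant is more conservative than the plain tail", {
  toy <- toy_collection()
  plain <- ora(c("A", "B", "C"), toy)
  ease <- ora(c("A", "B", "C"), toy, ease = TRUE)
  expect_true(all(ease$p_value >= plain$p_value))
})

test_that("BH adjustment obeys the step-up closed form and its invariances", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))

  set.seed(13)
  p <- runif(20)
  q <- adjust_bh(p)
  expect_true(all(q >= p) && all(q <= 1))
  perm <- sample(20)
  expect_equal(adjust_bh(p[perm]), q[perm])          # permutation invariance

  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, -0.1)), "\\[0, 1\\]")
})

fake_results <- function(names) {
  p <- seq(0.001, 0.001 + 0.01 * (length(names) - 1), by = 0.01)
  tibble::tibble(set_name = names, k = 1L, K = 2L, n = 3L, N = 10L,
                 p_value = p, q_value = p, neg_log10_p = -log10(p),
                 overlap_members = "")
}

test_that("top-k overlap intersects rankings with optional name normalization", {
  a <- fake_results(paste0("P", 1:7))
  b <- fake_results(paste0("P", 5:9))
  ov <- top_k_overlap(a, b, k = 5, name_matcher = "exact")
  expect_equal(ov$shared_name, "P5")

  same <- top_k_overlap(a, a, k = 5, name_matcher = "exact")
  expect_equal(nrow(same), 5L)

  disjoint <- top_k_overlap(fake_results(c("X1", "X2")),
                            fake_results(c("Y1", "Y2")),
                            k = 2, name_matcher = "exact")
  expect_equal(nrow(disjoint), 0L)

  ipa <- fake_results(c("HIF-1 Signaling", "Other Module"))
  kegg <- fake_results(c("HIF-1 signaling pathway", "Different pathway"))
  norm <- top_k_overlap(ipa, kegg, k = 2, name_matcher = "normalized")
  expect_equal(norm$shared_name, "hif 1")
  expect_equal(norm$name_a, "HIF-1 Signaling")
  expect_equal(norm$name_b, "HIF-1 signaling pathway")
  exact <- top_k_overlap(ipa, kegg, k = 2, name_matcher = "exact")
  expect_equal(nrow(exact), 0L)

  expect_warning(top_k_overlap(fake_results(c("A", "B")), b, k = 5),
                 "exceeds")
})
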