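write_pred_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("prediction tables ingest, collapse duplicates, and reject bad scores", {
  path <- write_pred_csv(data.frame(
    compound_id = c("x", "x", "y", "z"),
    gene_symbol = c("EGFR", "EGFR", "EGFR", "AKT1"),
    score = c(0.2, 0.6, 0.3, 1.7)
  ))
  preds <- read_target_predictions(path)
  expect_equal(nrow(preds), 2L)
  expect_equal(preds$score[preds$compound_id == "x"], 0.6)  # max wins
  rej <- attr(preds, "rejections")
  expect_equal(rej$compound_id, "z")
  expect_match(rej$reason, "outside")

  bad <- write_pred_csv(data.frame(compound_id = "x", score = 0.5))
  expect_error(read_target_predictions(bad), "mandatory column")
})

test_that("retention filters are strict at both boundaries", {
  preds <- tibble::tibble(
    compound_id = c("a", "b", "c",  "a", "b",  "a", "b", "c"),
    target_name = NA_character_, uniprot_id = NA_character_,
    gene_symbol = c(rep("T_IN", 3), rep("T_FEW", 2), rep("T_LOW", 3)),
    score = c(0.2, 0.05, 0.15,  0.5, 0.5,  0.1, 0.1, 0.1)
  )
  tset <- aggregate_and_filter(preds)
  row <- function(g) tset[tset$gene_symbol == g, ]

  expect_equal(row("T_IN")$mean_score, mean(c(0.2, 0.05, 0.15)))
  expect_true(row("T_IN")$retained)                 # mean 0.1333, support 3
  expect_false(row("T_FEW")$retained)               # support 2, not > 2
  expect_false(row("T_LOW")$retained)               # mean exactly 0.1, strict
})

test_that("aggregation is order-independent and matches a brute-force oracle", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    preds <- tibble::tibble(
      compound_id = sample(paste0("c", 1:8), n, replace = TRUE),
      target_name = NA_character_, uniprot_id = NA_character_,
      gene_symbol = sample(paste0("G", 1:6), n, replace = TRUE),
      score = round(runif(n), 3)
    )
    tset <- suppressWarnings(aggregate_and_filter(preds))
    shuffled <- suppressWarnings(aggregate_and_filter(preds[sample(nrow(preds)), ]))
    expect_equal(tset, shuffled)

    # brute force: collapse per (compound, gene) to max, group, average
    key <- paste(preds$compound_id, preds$gene_symbol)
    collapsed <- tapply(preds$score, key, max)
    genes <- sub("^\\S+ ", "", names(collapsed))
    for (g in unique(genes)) {
      expected_mean <- mean(collapsed[genes == g])
      expected_support <- sum(genes == g)
      row <- tset[tset$gene_symbol == g, ]
      expect_equal(row$mean_score, unname(expected_mean))
      expect_equal(row$n_supporting_compounds, expected_support)
      expect_equal(row$retained,
                   expected_mean > 0.1 + 1e-9 && expected_support > 2)
    }
  }
})

test_that("the retained set shrinks monotonically in both thresholds", {
  set.seed(9)
  preds <- tibble::tibble(
    compound_id = sample(paste0("c", 1:10), 80, replace = TRUE),
    target_name = NA_character_, uniprot_id = NA_character_,
    gene_symbol = sample(paste0("G", 1:12), 80, replace = TRUE),
    score = runif(80)
  )
  n_ret_score <- vapply(seq(0, 1, 0.1), function(t)
    sum(suppressWarnings(aggregate_and_filter(preds, score_threshold = t))$retained),
    numeric(1))
  n_ret_support <- vapply(0:6, function(s)
    sum(suppressWarnings(aggregate_and_filter(preds, support_threshold = s))$retained),
    numeric(1))
  expect_true(all(diff(n_ret_score) <= 0))
  expect_true(all(diff(n_ret_support) <= 0))
})

test_that("an empty retained set warns rather than errors", {
  preds <- tibble::tibble(
    compound_id = c("a", "b"), target_name = NA_character_,
    uniprot_id = NA_character_, gene_symbol = c("G1", "G1"),
    score = c(0.02, 0.03)
  )
  expect_warning(tset <- aggregate_and_filter(preds), "no target")
  expect_equal(sum(tset$retained), 0L)
})
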