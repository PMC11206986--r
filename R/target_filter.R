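# Aggregation of per-compound target predictions and the two retention
# filters of the screening procedure: a target is kept when its average
# prediction score over the compounds predicting it exceeds 0.1 AND it is
# predicted for more than two distinct compounds (i.e. at least three).

#' Column mapping for target-prediction tables
#'
#' Defaults mirror a SwissTargetPrediction-style long-format export:
#' one row per (compound, target) with a 0-1 probability score.
#'
#' @param compound_id,gene_symbol,score Mandatory column names.
#' @param target_name,uniprot_id Optional column names (`NULL` to skip).
#' @param sep Field separator.
#' @return A named list of class `prediction_dialect`.
#' @export
prediction_dialect <- function(compound_id = "compound_id",
                               gene_symbol = "gene_symbol",
                               score = "score",
                               target_name = "target_name",
                               uniprot_id = "uniprot_id",
                               sep = ",") {
  structure(
    list(compound_id = compound_id, gene_symbol = gene_symbol, score = score,
         target_name = target_name, uniprot_id = uniprot_id, sep = sep),
    class = "prediction_dialect"
  )
}

#' Read per-compound target predictions
#'
#' Rows with scores outside `[0, 1]` are rejected (listed in the
#' `rejections` attribute); duplicate (compound, gene) rows are collapsed
#' to their maximum score.
#'
#' @param path Path to a delimited prediction table.
#' @param dialect A [prediction_dialect()].
#' @return Tibble with `compound_id`, `target_name`, `gene_symbol`,
#'   `uniprot_id`, `score`; attribute `rejections` holds the dropped rows.
#' @export
read_target_predictions <- function(path, dialect = prediction_dialect()) {
  if (!file.exists(path)) stop("cannot read prediction table: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (field in c("compound_id", "gene_symbol", "score")) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(raw))) {
      stop("prediction table is missing mandatory column '", col,
           "' (mapped to field '", field, "')")
    }
  }
  pick <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) as.character(raw[[col]])
    else rep(NA_character_, nrow(raw))
  }
  preds <- tibble::tibble(
    compound_id = as.character(raw[[dialect$compound_id]]),
    target_name = pick("target_name"),
    gene_symbol = as.character(raw[[dialect$gene_symbol]]),
    uniprot_id = pick("uniprot_id"),
    score = suppressWarnings(as.numeric(raw[[dialect$score]]))
  )
  bad <- is.na(preds$score) | preds$score < 0 | preds$score > 1
  rejections <- tibble::tibble(
    row = which(bad),
    compound_id = preds$compound_id[bad],
    gene_symbol = preds$gene_symbol[bad],
    reason = "score outside [0, 1]"
  )
  preds <- preds[!bad, , drop = FALSE]
  preds <- collapse_duplicates(preds)
  attr(preds, "rejections") <- rejections
  preds
}

# Within-compound duplicates collapse to the maximum score.
collapse_duplicates <- function(preds) {
  key <- paste(preds$compound_id, preds$gene_symbol, sep = "\r")
  if (!anyDuplicated(key)) return(preds)
  ord <- order(key, -preds$score)
  preds <- preds[ord, , drop = FALSE]
  preds <- preds[!duplicated(key[ord]), , drop = FALSE]
  preds[order(preds$compound_id, preds$gene_symbol), , drop = FALSE]
}

#' Aggregate predictions and apply the retention filters
#'
#' Per gene symbol, computes the arithmetic mean score over the distinct
#' compounds predicting it and the supporting-compound count, then
#' retains targets with mean score strictly greater than
#' `score_threshold` ("greater than 0.1") and support strictly greater
#' than `support_threshold` ("more than two related compounds", i.e. at
#' least three). Aggregation is order-independent, and because the mean
#' runs over supporting compounds only, filtering before or after
#' averaging gives identical results.
#'
#' @param predictions Prediction tibble (see
#'   [read_target_predictions()]); duplicates per (compound, gene) are
#'   collapsed to the maximum score first.
#' @param score_threshold Strict lower bound on the mean score
#'   (default 0.1).
#' @param support_threshold Strict lower bound on the supporting-compound
#'   count (default 2).
#' @return A `target_set` tibble: `gene_symbol`,
#'   `n_supporting_compounds`, `mean_score`, `retained`, ordered by
#'   decreasing mean score then symbol. An empty retained set triggers a
#'   warning, not an error.
#' @export
aggregate_and_filter <- function(predictions, score_threshold = 0.1,
                                 support_threshold = 2) {
  if (nrow(predictions) == 0L) stop("predictions are empty")
  predictions <- collapse_duplicates(predictions)
  grp <- split(predictions$score, predictions$gene_symbol)
  out <- tibble::tibble(
    gene_symbol = names(grp),
    n_supporting_compounds = unname(vapply(grp, length, integer(1))),
    mean_score = unname(vapply(grp, mean, numeric(1)))
  )
  out$retained <- strictly_above(out$mean_score, score_threshold) &
    out$n_supporting_compounds > support_threshold
  out <- out[order(-out$mean_score, out$gene_symbol), , drop = FALSE]
  if (!any(out$retained)) {
    warning("no target passes the retention filters")
  }
  class(out) <- c("target_set", class(out))
  out
}

#' Write a target-set table
#'
#' @param target_set An [aggregate_and_filter()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_set <- function(target_set, path) {
  utils::write.table(as.data.frame(target_set), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
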