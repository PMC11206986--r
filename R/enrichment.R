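# Over-representation analysis of the retained target set against
# pathway/disease gene-set collections, with -log10 p ranking and the
# top-k cross-source overlap rule.

#' Construct a gene-set collection
#'
#' Duplicate members within a set are collapsed; empty sets are dropped
#' with a report. The background universe defaults to the union of all
#' members and can be overridden with a user-supplied list.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param source_label Free-text label of the annotation source.
#' @param universe Optional background symbol list; defaults to the union
#'   of all set members.
#' @return A `geneset_collection`: list with `source_label`, `sets`,
#'   `universe`; attribute `rejected_sets` names any empty sets dropped.
#' @export
new_geneset_collection <- function(sets, source_label = "geneset-source",
                                   universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s[!is.na(s) & nzchar(s)])))
  empty <- vapply(sets, length, integer(1)) == 0L
  rejected <- names(sets)[empty]
  sets <- sets[!empty]
  member_union <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- member_union
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(member_union, universe)
    if (length(outside)) {
      sets <- lapply(sets, intersect, y = universe)
      sets <- sets[vapply(sets, length, integer(1)) > 0L]
    }
  }
  out <- structure(
    list(source_label = source_label, sets = sets, universe = universe),
    class = "geneset_collection"
  )
  attr(out, "rejected_sets") <- rejected
  out
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> '", x$source_label, "': ", length(x$sets),
      " sets, universe of ", length(x$universe), " symbols\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the standard tab-separated exchange format: set name,
#' description, then one member symbol per field. Lines without at least
#' one member (for example a name-only line) are dropped and listed, with
#' their line numbers, in the `rejected_lines` attribute; a file yielding
#' no usable set at all is a parse error.
#'
#' @param path Path to a GMT file.
#' @param source_label Label for the collection; defaults to the file
#'   name.
#' @param universe Optional background symbol list.
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path, source_label = NULL, universe = NULL) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  if (is.null(source_label)) source_label <- basename(path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  rejected <- integer(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(fields) < 3L || !nzchar(fields[1L]) || length(members) == 0L) {
      rejected <- c(rejected, i)
      next
    }
    sets[[fields[1L]]] <- members
  }
  if (length(sets) == 0L) {
    stop("GMT parse error: no usable set in ", path,
         if (length(rejected)) paste0(" (malformed line(s): ",
                                      paste(rejected, collapse = ", "), ")"))
  }
  out <- new_geneset_collection(sets, source_label, universe)
  attr(out, "rejected_lines") <- rejected
  out
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `geneset_collection`.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set description
#'   fields (defaults to the source label).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (is.null(descriptions)) {
    descriptions <- rep(collection$source_label, length(collection$sets))
  }
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], descriptions[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Hypergeometric upper tail P(X >= k) for overlap k, set size K, query
# size n, universe N. Exact integer-valued sum while C(N, n) < 2^53
# (every Vandermonde term is bounded by it, so double arithmetic is
# exact); falls back to stats::phyper beyond that.
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n))
  if (k <= 0) return(1)
  kmax <- min(K, n)
  if (k > kmax) return(0)
  denom <- choose(N, n)
  if (denom < 2^53) {
    i <- k:kmax
    sum(choose(K, i) * choose(N - K, n - i)) / denom
  } else {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query symbols with
#' the one-sided hypergeometric upper tail
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}}
#' where N is the universe size, K the set size, n the query size within
#' the universe and k the overlap. Query symbols outside the universe are
#' dropped with a logged count. Benjamini-Hochberg q-values and
#' \eqn{-\log_{10} p} ranks are attached; ties in p are broken by set
#' name for determinism.
#'
#' @param query Character vector of gene symbols (the retained target
#'   set).
#' @param collection A `geneset_collection`.
#' @param ease Use the conservative EASE variant (overlap decremented by
#'   one); default off.
#' @return An `enrichment_result` tibble: `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `neg_log10_p`, `overlap_members`
#'   (semicolon-joined), sorted by increasing p then set name. Attribute
#'   `n_dropped` counts query symbols outside the universe.
#' @export
ora <- function(query, collection, ease = FALSE) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- unique(as.character(query))
  effective <- intersect(query, collection$universe)
  n_dropped <- length(query) - length(effective)
  if (n_dropped > 0L) {
    message(n_dropped, " query symbol(s) outside the '",
            collection$source_label, "' universe were dropped")
  }
  if (length(effective) == 0L) {
    stop("no query symbol lies in the universe of '",
         collection$source_label, "'")
  }
  N <- length(collection$universe)
  n <- length(effective)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    hit <- intersect(effective, members)
    K <- length(members)
    k <- length(hit)
    k_test <- if (ease) max(k - 1L, 0L) else k
    tibble::tibble(
      set_name = nm, k = k, K = K, n = n, N = N,
      p_value = hyper_upper_tail(k_test, K, n, N),
      overlap_members = paste(sort(hit), collapse = ";")
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  out <- out[, c("set_name", "k", "K", "n", "N", "p_value", "q_value",
                 "neg_log10_p", "overlap_members")]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "source_label") <- collection$source_label
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin validated wrapper around
#' [stats::p.adjust()]. q-values satisfy q >= p elementwise, q <= 1, and
#' invariance to input order (up to the inverse permutation).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Normalize a gene-set name for cross-source matching
#'
#' Case-folds, strips punctuation, collapses whitespace, and removes the
#' trailing "signaling pathway" / "signaling" / "pathway" suffixes so
#' that differently-branded labels of the same pathway (for example
#' "HIF-1 Signaling" vs "HIF-1 signaling pathway") compare equal.
#'
#' @param x Character vector of set names.
#' @return Normalized names.
#' @export
normalize_set_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  x <- sub(" (signalling|signaling) pathway$", "", x)
  x <- sub(" (signalling|signaling|pathway)$", "", x)
  trimws(x)
}

#' Top-k overlap between two enrichment rankings
#'
#' Ranks each result collection by decreasing \eqn{-\log_{10} p} (ties by
#' set name), takes the top k set names from each, and intersects them --
#' the cross-source consistency rule used to nominate a pathway shared by
#' two independent annotation engines.
#'
#' @param results_a,results_b Nonempty `enrichment_result` tibbles.
#' @param k Number of top sets per collection (default 5); a k beyond a
#'   collection's size uses the whole collection with a warning.
#' @param name_matcher `"normalized"` (default; see
#'   [normalize_set_name()]) or `"exact"`.
#' @return Tibble with `shared_name` (the matching key), `name_a`,
#'   `name_b` (the original labels in each source).
#' @export
top_k_overlap <- function(results_a, results_b, k = 5,
                          name_matcher = c("normalized", "exact")) {
  name_matcher <- match.arg(name_matcher)
  if (nrow(results_a) == 0L || nrow(results_b) == 0L) {
    stop("both result collections must be nonempty")
  }
  top_names <- function(res) {
    if (k > nrow(res)) {
      warning("k = ", k, " exceeds the collection size (", nrow(res),
              "); using all sets")
    }
    res <- res[order(-res$neg_log10_p, res$set_name), , drop = FALSE]
    utils::head(res$set_name, k)
  }
  a <- top_names(results_a)
  b <- top_names(results_b)
  key_a <- if (name_matcher == "normalized") normalize_set_name(a) else a
  key_b <- if (name_matcher == "normalized") normalize_set_name(b) else b
  shared <- intersect(key_a, key_b)
  tibble::tibble(
    shared_name = shared,
    name_a = a[match(shared, key_a)],
    name_b = b[match(shared, key_b)]
  )
}

#' Write an enrichment result table
#'
#' @param result An `enrichment_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
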