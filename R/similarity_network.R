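# Activity-transfer similarity network: known actives vs candidates.
#
# Threshold semantics follow the screening procedure's wording exactly:
# network edges require Tc >= 0.4 ("0.4 or higher"), candidate selection
# requires average Tc strictly greater than 0.4. Comparisons carry a 1e-9
# guard so that averages meant to equal the threshold (representable only
# approximately in binary doubles) land on the side the wording dictates.

EPS_THRESH <- 1e-9

strictly_above <- function(x, threshold) x > threshold + EPS_THRESH
at_least <- function(x, threshold) x >= threshold - EPS_THRESH

#' Known-by-candidate Tanimoto similarity matrix
#'
#' Computes ECFP fingerprints for every compound and the full grid of
#' Tanimoto similarities between the known-active and candidate
#' partitions.
#'
#' @param library A labeled `compound_library` with at least one
#'   known-active and one candidate record.
#' @param radius,n_bits Fingerprint parameters (see
#'   [fingerprint_matrix()]).
#' @return Numeric matrix (rows = known actives, columns = candidates) of
#'   class `similarity_matrix`, with `radius`/`n_bits` attributes.
#' @export
pairwise_similarity <- function(library, radius = 2, n_bits = 2048) {
  stopifnot(inherits(library, "compound_library"))
  records <- library$records
  known <- records[records$activity_status %in% "known_active", , drop = FALSE]
  cand <- records[records$activity_status %in% "candidate", , drop = FALSE]
  if (nrow(known) == 0L || nrow(cand) == 0L) {
    stop("library must contain at least one known_active and one candidate")
  }
  smiles <- c(stats::setNames(known$smiles, known$compound_id),
              stats::setNames(cand$smiles, cand$compound_id))
  fps <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
  grid <- tanimoto_grid(fps[known$compound_id, , drop = FALSE],
                        fps[cand$compound_id, , drop = FALSE])
  attr(grid, "radius") <- as.integer(radius)
  attr(grid, "n_bits") <- as.integer(n_bits)
  class(grid) <- c("similarity_matrix", class(grid))
  grid
}

#' Score and select candidates by average similarity
#'
#' For every candidate, averages its Tanimoto similarities to the known
#' actives and selects those strictly above the threshold
#' ("greater than 0.4"). In `all_knowns` mode the average runs over every
#' known active; in `neighbors_only` mode over the knowns connected at the
#' edge threshold (0 when there is no neighbor, never selected).
#'
#' @param matrix A `similarity_matrix` from [pairwise_similarity()].
#' @param selection_threshold Strict lower bound on the average Tc
#'   (default 0.4).
#' @param averaging_mode `"all_knowns"` (default) or `"neighbors_only"`.
#' @param edge_threshold Inclusive Tc bound defining a neighbor
#'   (default 0.4).
#' @return Tibble with `candidate_id`, `avg_tc`, `n_known_neighbors`,
#'   `selected`, `rank` (1..n over selected candidates, by decreasing
#'   `avg_tc`, ties broken by `candidate_id`; `NA` otherwise), ordered by
#'   rank then `candidate_id`.
#' @export
score_candidates <- function(matrix, selection_threshold = 0.4,
                             averaging_mode = c("all_knowns", "neighbors_only"),
                             edge_threshold = 0.4) {
  averaging_mode <- match.arg(averaging_mode)
  if (length(matrix) == 0L) stop("similarity matrix is empty")
  m <- unclass(matrix)
  neighbors <- at_least(m, edge_threshold)
  n_neigh <- colSums(neighbors)
  avg <- if (averaging_mode == "all_knowns") {
    colMeans(m)
  } else {
    vapply(seq_len(ncol(m)), function(j) {
      idx <- neighbors[, j]
      if (!any(idx)) 0 else mean(m[idx, j])
    }, numeric(1))
  }
  selected <- strictly_above(avg, selection_threshold)
  out <- tibble::tibble(
    candidate_id = colnames(m),
    avg_tc = as.numeric(avg),
    n_known_neighbors = as.integer(n_neigh),
    selected = as.logical(selected)
  )
  out <- out[order(-out$avg_tc, out$candidate_id), , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[out$selected] <- seq_len(sum(out$selected))
  out
}

#' Build the compound-compound similarity network
#'
#' Creates the bipartite activity-transfer network whose edges are the
#' known/candidate pairs at or above the edge threshold ("0.4 or
#' higher"). Compounds that meet no edge are excluded from the network
#' (but remain in score tables), matching the convention that isolated
#' nodes are dropped from published interaction maps.
#'
#' @param matrix A `similarity_matrix`.
#' @param edge_threshold Inclusive Tc bound for an edge (default 0.4).
#' @param scores Optional [score_candidates()] table; required for
#'   `restrict_to_selected`.
#' @param restrict_to_selected Keep only candidates with
#'   `selected == TRUE`.
#' @return A `similarity_network`: list with `nodes` (tibble
#'   `compound_id`, `role` of `known_active`/`potential_active`), `edges`
#'   (tibble `known_id`, `candidate_id`, `tc`), and `threshold`.
#' @export
build_network <- function(matrix, edge_threshold = 0.4, scores = NULL,
                          restrict_to_selected = FALSE) {
  if (length(matrix) == 0L) stop("similarity matrix is empty")
  m <- unclass(matrix)
  if (restrict_to_selected) {
    if (is.null(scores)) stop("restrict_to_selected requires a scores table")
    keep <- scores$candidate_id[scores$selected]
    m <- m[, colnames(m) %in% keep, drop = FALSE]
  }
  hits <- which(at_least(m, edge_threshold), arr.ind = TRUE)
  edges <- tibble::tibble(
    known_id = unname(rownames(m)[hits[, 1L]]),
    candidate_id = unname(colnames(m)[hits[, 2L]]),
    tc = unname(m[hits])
  )
  edges <- edges[order(edges$known_id, edges$candidate_id), , drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("no compound pair meets the edge threshold; network is empty")
  }
  nodes <- tibble::tibble(
    compound_id = c(unique(edges$known_id), unique(edges$candidate_id)),
    role = c(rep("known_active", length(unique(edges$known_id))),
             rep("potential_active", length(unique(edges$candidate_id))))
  )
  structure(
    list(nodes = nodes, edges = edges, threshold = edge_threshold),
    class = "similarity_network"
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("<similarity_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$role == "known_active"), " known, ",
      sum(x$nodes$role == "potential_active"), " potential), ",
      nrow(x$edges), " edges at Tc >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Export a similarity network for Cytoscape
#'
#' GraphML output carries node attributes `role`, `avg_tc` (drives node
#' size in typical styles) and `compound_class`, plus edge attribute
#' `tc`; SIF output uses the relation `tc_sim`. GraphML files are
#' re-importable with [read_network_graphml()].
#'
#' @param network A nonempty `similarity_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @param scores Optional [score_candidates()] table supplying `avg_tc`.
#' @param library Optional `compound_library` supplying `compound_class`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif"),
                           scores = NULL, library = NULL) {
  stopifnot(inherits(network, "similarity_network"))
  format <- match.arg(format)
  if (nrow(network$edges) == 0L) stop("cannot export an empty network")
  if (format == "sif") {
    writeLines(paste(network$edges$known_id, "tc_sim",
                     network$edges$candidate_id, sep = "\t"), path)
    return(invisible(path))
  }
  nodes <- network$nodes
  nodes$avg_tc <- NA_real_
  if (!is.null(scores)) {
    idx <- match(nodes$compound_id, scores$candidate_id)
    nodes$avg_tc <- scores$avg_tc[idx]
  }
  nodes$compound_class <- NA_character_
  if (!is.null(library)) {
    idx <- match(nodes$compound_id, library$records$compound_id)
    nodes$compound_class <- library$records$compound_class[idx]
  }
  nodes$compound_class[is.na(nodes$compound_class)] <- "unknown"
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$known_id,
                   to = network$edges$candidate_id,
                   tc = network$edges$tc),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import a GraphML similarity network
#'
#' @param path A GraphML file written by [export_network()].
#' @return A `similarity_network` with the node/edge attributes restored.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::as_data_frame(g, what = "vertices")
  eat <- igraph::as_data_frame(g, what = "edges")
  # igraph's GraphML reader maps the reserved name column to "id"
  idcol <- if ("name" %in% names(vat)) "name" else "id"
  nodes <- tibble::tibble(
    compound_id = vat[[idcol]],
    role = vat$role,
    avg_tc = if ("avg_tc" %in% names(vat)) vat$avg_tc else NA_real_,
    compound_class = if ("compound_class" %in% names(vat)) vat$compound_class
                     else NA_character_
  )
  nodes$avg_tc[is.nan(nodes$avg_tc)] <- NA_real_
  role_of <- stats::setNames(nodes$role, nodes$compound_id)
  known_first <- ifelse(role_of[eat$from] == "known_active", eat$from, eat$to)
  cand_second <- ifelse(role_of[eat$from] == "known_active", eat$to, eat$from)
  edges <- tibble::tibble(known_id = unname(known_first),
                          candidate_id = unname(cand_second),
                          tc = eat$tc)
  edges <- edges[order(edges$known_id, edges$candidate_id), , drop = FALSE]
  thr <- igraph::graph_attr(g, "threshold")
  structure(
    list(nodes = nodes, edges = edges,
         threshold = if (is.null(thr)) NA_real_ else thr),
    class = "similarity_network"
  )
}

#' Write the candidate score table
#'
#' @param scores A [score_candidates()] tibble.
#' @param path Output TSV path.
#' @param library Optional `compound_library` supplying the
#'   `available` column from its `commercially_available` flags.
#' @return `path`, invisibly.
#' @export
write_candidate_scores <- function(scores, path, library = NULL) {
  out <- as.data.frame(scores)
  if (!is.null(library)) {
    idx <- match(out$candidate_id, library$records$compound_id)
    out$available <- library$records$commercially_available[idx]
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
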