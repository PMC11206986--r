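# Seeded synthetic-data generators.
#
# The generators plant the statistical structure the screening assumes --
# candidates that share a decorated scaffold with a known active (and so
# sit above the 0.4 similarity threshold), structurally distant decoys,
# targets supported by enough compounds at high enough scores to survive
# the retention filters, and one gene set enriched for the retained
# targets under two differently-branded names. Each generator verifies
# its own planted property at generation time, so pipeline tests measure
# recovery against an honest truth table.

default_scaffolds <- c(
  "O=C1C=C(c2ccc({R1})cc2)Oc2cc({R2})ccc21",      # flavone core
  "O=C1C(O)=C(c2ccc({R1})cc2)Oc2cc({R2})ccc21"    # flavonol core
)

default_decorations <- c(
  "O", "OC", "C", "CC", "N", "Cl", "F", "OCC", "C(C)C", "OC(C)=O"
)

default_decoys <- c(
  "CCCCCCCCCC", "CCCCCC(C)CC", "CCCCOC(=O)CC", "C1CCCCC1CCCC",
  "CC(C)CCCC(C)CCO", "CCCCCCCC(=O)O", "CCCC(CC)COC(C)=O",
  "C1CCCCC1C1CCCCC1", "CCCCCCCCCCCC", "CC(C)(C)CCCCC(C)(C)C"
)

decorate_scaffold <- function(scaffold, r1, r2) {
  gsub("{R2}", r2, gsub("{R1}", r1, scaffold, fixed = TRUE), fixed = TRUE)
}

#' Specification of a synthetic compound library
#'
#' @param n_known,n_analog,n_decoy Partition sizes: literature-style known
#'   actives, planted structural analogs, and structurally distant
#'   decoys. Defaults (5/10/10) are the package's reference study
#'   conditions.
#' @param scaffold_pool Templates (with `{R1}`/`{R2}` substituent slots)
#'   for the known-active scaffold family.
#' @param decoration_pool Substituent SMILES fragments.
#' @param decoy_pool Base structures of the disjoint (aliphatic) decoy
#'   family.
#' @param analog_distance Decoration distance of analogs from their
#'   parent known: 1 swaps one substituent (default), 2 swaps both, 3 or
#'   more replaces the scaffold entirely (analog becomes decoy-like).
#'   Used to sweep sensitivity.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_known = 5, n_analog = 10, n_decoy = 10,
                         scaffold_pool = default_scaffolds,
                         decoration_pool = default_decorations,
                         decoy_pool = default_decoys,
                         analog_distance = 1, seed = 1) {
  stopifnot(n_known >= 0, n_analog >= 0, n_decoy >= 0,
            length(scaffold_pool) >= 1, length(decoration_pool) >= 2,
            length(decoy_pool) >= 1, analog_distance >= 1)
  structure(
    list(n_known = as.integer(n_known), n_analog = as.integer(n_analog),
         n_decoy = as.integer(n_decoy), scaffold_pool = scaffold_pool,
         decoration_pool = decoration_pool, decoy_pool = decoy_pool,
         analog_distance = as.integer(analog_distance),
         seed = as.integer(seed)),
    class = "library_spec"
  )
}

#' Generate a synthetic compound library with a truth table
#'
#' Known actives are decorated scaffolds from the flavonoid-like pool;
#' analogs reuse a parent known's scaffold with `analog_distance`
#' substituents swapped; decoys come from a disjoint aliphatic family.
#' With `verify = TRUE` (default) the generator proves its planted
#' properties before returning: each analog's Tanimoto similarity to its
#' parent is at least 0.4 and its average over all knowns strictly
#' exceeds 0.4 (redrawn on failure, bounded attempts), and every decoy's
#' maximum similarity to any known stays below 0.4. Disable verification
#' when sweeping `analog_distance` beyond the similarity threshold.
#'
#' @param spec A [library_spec()].
#' @param verify Enforce the planted similarity properties at generation
#'   time.
#' @param max_attempts Redraw budget per planted compound before a
#'   generation error.
#' @return List with `library` (an activity-labeled `compound_library`)
#'   and `truth` (tibble `compound_id`, `role` of `analog`/`decoy`,
#'   `parent_id`).
#' @export
generate_library <- function(spec = library_spec(), verify = TRUE,
                             max_attempts = 40L) {
  stopifnot(inherits(spec, "library_spec"))
  withr::with_seed(spec$seed, generate_library_impl(spec, verify, max_attempts))
}

generate_library_impl <- function(spec, verify, max_attempts) {
  used <- character(0)
  fp_of <- function(smiles) fingerprint_matrix(smiles, radius = 2, n_bits = 2048)
  tani_vec <- function(fp, mat) {
    inter <- as.vector(mat %*% fp)
    union <- rowSums(mat) + sum(fp) - inter
    ifelse(union == 0, 0, inter / union)
  }

  knowns <- list()
  for (i in seq_len(spec$n_known)) {
    scaffold <- spec$scaffold_pool[(i - 1L) %% length(spec$scaffold_pool) + 1L]
    for (attempt in seq_len(max_attempts)) {
      d <- sample(spec$decoration_pool, 2L)
      smiles <- decorate_scaffold(scaffold, d[1L], d[2L])
      can <- ob_canonicalize(smiles)$canonical
      if (!is.na(can) && !(can %in% used)) break
      if (attempt == max_attempts) {
        stop("generation error: could not draw a unique known active ",
             "(n_known = ", spec$n_known, ")")
      }
    }
    used <- c(used, can)
    knowns[[i]] <- list(id = sprintf("K%02d", i), smiles = can,
                        scaffold = scaffold, decorations = d)
  }
  known_fps <- if (spec$n_known > 0L) {
    fp_of(stats::setNames(vapply(knowns, `[[`, character(1), "smiles"),
                          vapply(knowns, `[[`, character(1), "id")))
  } else NULL

  decoy_structure <- function(j) {
    base <- spec$decoy_pool[(j - 1L) %% length(spec$decoy_pool) + 1L]
    tail_len <- (j - 1L) %/% length(spec$decoy_pool)
    paste0(base, strrep("C", tail_len))
  }

  analogs <- list()
  if (spec$n_analog > 0L && spec$n_known == 0L) {
    stop("generation error: analogs require at least one known active")
  }
  for (i in seq_len(spec$n_analog)) {
    parent <- knowns[[(i - 1L) %% spec$n_known + 1L]]
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      if (spec$analog_distance >= 3L) {
        smiles <- decoy_structure(i + spec$n_decoy + attempt - 1L)
      } else {
        d <- parent$decorations
        slots <- if (spec$analog_distance == 1L) sample(1:2, 1L) else 1:2
        for (s in slots) d[s] <- sample(setdiff(spec$decoration_pool, d[s]), 1L)
        smiles <- decorate_scaffold(parent$scaffold, d[1L], d[2L])
      }
      can <- ob_canonicalize(smiles)$canonical
      if (is.na(can) || can %in% used) next
      if (verify && spec$analog_distance < 3L) {
        fp <- fp_of(stats::setNames(can, "x"))[1L, ]
        tcs <- tani_vec(fp, known_fps)
        if (!at_least(tcs[parent$id], 0.4) || !strictly_above(mean(tcs), 0.4)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("generation error: could not plant analog ", i,
           " at distance ", spec$analog_distance,
           " within ", max_attempts, " attempts")
    }
    used <- c(used, can)
    analogs[[i]] <- list(id = sprintf("A%02d", i), smiles = can,
                         parent = parent$id)
  }

  decoys <- list()
  for (i in seq_len(spec$n_decoy)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      smiles <- decoy_structure(i + (attempt - 1L) * length(spec$decoy_pool))
      can <- ob_canonicalize(smiles)$canonical
      if (is.na(can) || can %in% used) next
      if (verify && spec$n_known > 0L) {
        fp <- fp_of(stats::setNames(can, "x"))[1L, ]
        if (max(tani_vec(fp, known_fps)) >= 0.4) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("generation error: could not plant decoy ", i)
    used <- c(used, can)
    decoys[[i]] <- list(id = sprintf("D%02d", i), smiles = can)
  }

  rec <- function(id, smiles, class, role) {
    tibble::tibble(
      compound_id = id, name = paste0("synthetic-", tolower(id)),
      cas = NA_character_, smiles = smiles, compound_class = class,
      activity_status = NA_character_, commercially_available = TRUE,
      provenance = paste0("synthetic ", role)
    )
  }
  analog_class <- if (spec$analog_distance >= 3L) "hydrocarbon" else "flavonoid"
  records <- rbind(
    do.call(rbind, lapply(knowns, function(x)
      rec(x$id, x$smiles, "flavonoid", "known active"))),
    do.call(rbind, lapply(analogs, function(x)
      rec(x$id, x$smiles, analog_class, "planted analog"))),
    do.call(rbind, lapply(decoys, function(x)
      rec(x$id, x$smiles, "hydrocarbon", "planted decoy")))
  )
  library <- new_compound_library(records)
  library <- label_activity(library,
                            vapply(knowns, `[[`, character(1), "id"))
  truth <- tibble::tibble(
    compound_id = c(vapply(analogs, `[[`, character(1), "id"),
                    vapply(decoys, `[[`, character(1), "id")),
    role = c(rep("analog", length(analogs)), rep("decoy", length(decoys))),
    parent_id = c(vapply(analogs, `[[`, character(1), "parent"),
                  rep(NA_character_, length(decoys)))
  )
  list(library = library, truth = truth)
}

#' Specification of synthetic target predictions
#'
#' @param n_targets Total number of distinct targets.
#' @param n_planted Number of planted targets that must survive the
#'   retention filters (supported by at least three compounds with
#'   scores drawn well above 0.1).
#' @param planted_symbols Optional symbols for the planted targets;
#'   defaults to a small osteoporosis-flavored panel.
#' @param planted_score_range Uniform score range of planted predictions
#'   (entirely above the 0.1 filter).
#' @param background_score_max Upper bound of the low-score background
#'   distribution (below the 0.1 filter).
#' @param seed Integer seed.
#' @return A `prediction_spec` list.
#' @export
prediction_spec <- function(n_targets = 30, n_planted = 3,
                            planted_symbols = NULL,
                            planted_score_range = c(0.15, 0.8),
                            background_score_max = 0.08, seed = 1) {
  stopifnot(n_targets >= n_planted, n_planted >= 0,
            planted_score_range[1] > 0.1, background_score_max < 0.1)
  if (is.null(planted_symbols)) {
    planted_symbols <- c("HIF1A", "ESR1", "AKT1", "VEGFA", "EGFR",
                         "SRC", "MAPK1", "STAT3")[seq_len(n_planted)]
  }
  stopifnot(length(planted_symbols) == n_planted)
  structure(
    list(n_targets = as.integer(n_targets), n_planted = as.integer(n_planted),
         planted_symbols = planted_symbols,
         planted_score_range = planted_score_range,
         background_score_max = background_score_max,
         seed = as.integer(seed)),
    class = "prediction_spec"
  )
}

#' Generate synthetic target predictions with a truth table
#'
#' Planted targets are predicted for 3-5 distinct compounds with scores
#' uniform in the planted range, so they satisfy both retention filters
#' by construction. Background targets fail at least one filter: half
#' have too few supporting compounds (1-2, any score), half have enough
#' support but scores below the mean-score threshold.
#'
#' @param library A `compound_library` (the compounds predictions are
#'   drawn for).
#' @param spec A [prediction_spec()].
#' @return List with `predictions` (tibble in the
#'   [read_target_predictions()] schema) and `truth` (tibble
#'   `gene_symbol`, `planted`).
#' @export
generate_predictions <- function(library, spec = prediction_spec()) {
  stopifnot(inherits(library, "compound_library"),
            inherits(spec, "prediction_spec"))
  ids <- library$records$compound_id
  stopifnot(length(ids) >= 3L)
  withr::with_seed(spec$seed, {
    rows <- list()
    symbols <- character(0)
    add_target <- function(symbol, support, scores) {
      comps <- sample(ids, support)
      tibble::tibble(
        compound_id = comps,
        target_name = paste("protein", symbol),
        gene_symbol = symbol,
        uniprot_id = sprintf("P%05d", abs(sum(utf8ToInt(symbol))) %% 99999L),
        score = round(scores, 6)
      )
    }
    for (s in spec$planted_symbols) {
      support <- sample(3:min(5L, length(ids)), 1L)
      rows[[length(rows) + 1L]] <- add_target(
        s, support,
        stats::runif(support, spec$planted_score_range[1],
                     spec$planted_score_range[2])
      )
      symbols <- c(symbols, s)
    }
    n_background <- spec$n_targets - spec$n_planted
    for (i in seq_len(n_background)) {
      symbol <- sprintf("BG%03d", i)
      if (i %% 2L == 1L) {
        support <- sample(1:2, 1L)                    # fails the support filter
        scores <- stats::runif(support, 0, 1)
      } else {
        support <- sample(3:min(5L, length(ids)), 1L) # fails the score filter
        scores <- stats::runif(support, 0, spec$background_score_max)
      }
      rows[[length(rows) + 1L]] <- add_target(symbol, support, scores)
      symbols <- c(symbols, symbol)
    }
    predictions <- do.call(rbind, rows)
    truth <- tibble::tibble(
      gene_symbol = symbols,
      planted = symbols %in% spec$planted_symbols
    )
    list(predictions = predictions, truth = truth)
  })
}

#' Specification of synthetic gene-set collections
#'
#' @param n_sets Sets per collection (including the planted one).
#' @param set_size_range Bounds on background set sizes.
#' @param planted_label Stem of the planted set's name; source A brands
#'   it "<stem> Signaling", source B "<stem> signaling pathway".
#' @param universe_size Size of the filler symbol pool per source.
#' @param seed Integer seed.
#' @return A `geneset_spec` list.
#' @export
geneset_spec <- function(n_sets = 20, set_size_range = c(5, 20),
                         planted_label = "HIF-1", universe_size = 300,
                         seed = 1) {
  stopifnot(n_sets >= 2, set_size_range[1] >= 2,
            set_size_range[2] >= set_size_range[1], universe_size >= 50)
  structure(
    list(n_sets = as.integer(n_sets),
         set_size_range = as.integer(set_size_range),
         planted_label = planted_label,
         universe_size = as.integer(universe_size),
         seed = as.integer(seed)),
    class = "geneset_spec"
  )
}

#' Generate two gene-set collections with one planted enriched set
#'
#' Emulates the two-annotation-source situation: both collections carry
#' the planted set (holding every retained target symbol) under
#' differently formatted names, while background sets are drawn from
#' filler symbols with distinct names per source. By construction the
#' planted set ranks first under [ora()] in both sources and is the sole
#' normalized top-k overlap.
#'
#' @param target_set A `target_set` with at least one retained target.
#' @param spec A [geneset_spec()].
#' @return List with `source_a`, `source_b` (`geneset_collection`s) and
#'   `truth` (list `name_a`, `name_b`, `normalized`).
#' @export
generate_genesets <- function(target_set, spec = geneset_spec()) {
  stopifnot(inherits(spec, "geneset_spec"))
  retained <- target_set$gene_symbol[target_set$retained]
  if (length(retained) == 0L) stop("target set has no retained target")
  withr::with_seed(spec$seed, {
    name_a <- paste(spec$planted_label, "Signaling")
    name_b <- paste(spec$planted_label, "signaling pathway")
    make_source <- function(tag, planted_name, bg_name_fmt) {
      filler <- sprintf("%s%04d", tag, seq_len(spec$universe_size))
      planted_size <- max(spec$set_size_range[1],
                          min(spec$set_size_range[2],
                              length(retained) + 5L))
      planted <- unique(c(retained,
                          sample(filler, max(0L, planted_size - length(retained)))))
      sets <- stats::setNames(list(planted), planted_name)
      for (i in seq_len(spec$n_sets - 1L)) {
        size <- sample(spec$set_size_range[1]:spec$set_size_range[2], 1L)
        members <- sample(filler, size)
        # occasionally let a background set touch one query symbol
        if (stats::runif(1) < 0.25 && length(retained) > 1L) {
          members <- c(members[-1L], sample(retained, 1L))
        }
        sets[[sprintf(bg_name_fmt, i)]] <- unique(members)
      }
      new_geneset_collection(sets, source_label = paste0("source-", tag))
    }
    source_a <- make_source("GA", name_a, "Canonical Module %02d Signaling")
    source_b <- make_source("GB", name_b, "map%04d metabolic pathway")
    list(
      source_a = source_a, source_b = source_b,
      truth = list(name_a = name_a, name_b = name_b,
                   normalized = normalize_set_name(name_a))
    )
  })
}
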