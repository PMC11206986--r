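#' Compound class vocabulary
#'
#' Controlled vocabulary for herbal compound classes used throughout the
#' package: flavonoids dominate *Epimedium*-type libraries, with smaller
#' numbers of acids, esters, glycosides, hydrocarbons, lignans, phenols,
#' steroids, and an "other" catch-all.
#'
#' @format Character vector of the nine admissible class labels.
#' @export
compound_classes <- c(
  "flavonoid", "acid", "ester", "glycoside", "hydrocarbon",
  "lignan", "phenol", "steroid", "other"
)

lib_columns <- c(
  "compound_id", "name", "cas", "smiles", "compound_class",
  "activity_status", "commercially_available", "provenance"
)

new_compound_library <- function(records, rejections = NULL) {
  if (is.null(rejections)) {
    rejections <- tibble::tibble(
      row = integer(), compound_id = character(), reason = character()
    )
  }
  structure(
    list(records = tibble::as_tibble(records), rejections = tibble::as_tibble(rejections)),
    class = "compound_library"
  )
}

#' Column mapping for compound tables
#'
#' Describes which columns of a delimited file hold each compound field.
#' Only `compound_id` and `smiles` are mandatory; the remaining fields are
#' filled with `NA` when unmapped.
#'
#' @param compound_id,smiles Column names of the two mandatory fields.
#' @param name,cas,compound_class,activity_status,commercially_available,provenance
#'   Optional column names (`NULL` to leave the field unmapped).
#' @param sep Field separator of the file (`","` for CSV, `"\t"` for TSV).
#' @return A named list of class `compound_dialect`.
#' @export
compound_dialect <- function(compound_id = "compound_id", smiles = "smiles",
                             name = "name", cas = "cas",
                             compound_class = "compound_class",
                             activity_status = "activity_status",
                             commercially_available = "commercially_available",
                             provenance = "provenance", sep = ",") {
  structure(
    list(
      compound_id = compound_id, smiles = smiles, name = name, cas = cas,
      compound_class = compound_class, activity_status = activity_status,
      commercially_available = commercially_available,
      provenance = provenance, sep = sep
    ),
    class = "compound_dialect"
  )
}

#' Read a compound library table
#'
#' Ingests a delimited compound table, validates every structure with the
#' cheminformatics toolkit, and returns a library containing exactly the
#' rows whose SMILES parse. Failed rows are not an error: they are listed
#' in the library's rejection report (herbal libraries routinely contain
#' unresolved entries).
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect A [compound_dialect()] mapping file columns to fields.
#' @return A `compound_library`: list with `records` (tibble of parsed
#'   compounds) and `rejections` (tibble with `row`, `compound_id`,
#'   `reason`).
#' @seealso [write_compound_table()], [canonicalize_and_dedup()],
#'   [label_activity()]
#' @export
read_compound_table <- function(path, dialect = compound_dialect()) {
  if (!file.exists(path)) stop("cannot read compound table: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         na.strings = "")
  for (field in c("compound_id", "smiles")) {
    col <- dialect[[field]]
    if (is.null(col) || !(col %in% names(raw))) {
      stop("compound table is missing mandatory column '", col,
           "' (mapped to field '", field, "')")
    }
  }
  pick <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  records <- tibble::tibble(
    compound_id = pick("compound_id"),
    name = pick("name"),
    cas = pick("cas"),
    smiles = pick("smiles"),
    compound_class = pick("compound_class"),
    activity_status = pick("activity_status"),
    commercially_available = pick("commercially_available"),
    provenance = pick("provenance")
  )
  records$commercially_available <- as.logical(records$commercially_available)

  rejections <- tibble::tibble(row = integer(), compound_id = character(),
                               reason = character())
  reject <- function(rows, reason) {
    tibble::tibble(row = rows, compound_id = records$compound_id[rows],
                   reason = reason)
  }

  bad_id <- which(is.na(records$compound_id) | !nzchar(records$compound_id))
  if (length(bad_id)) rejections <- rbind(rejections, reject(bad_id, "missing compound_id"))

  dup_id <- which(duplicated(records$compound_id) &
                    !seq_len(nrow(records)) %in% bad_id)
  if (length(dup_id)) rejections <- rbind(rejections, reject(dup_id, "duplicate compound_id"))

  remaining <- setdiff(seq_len(nrow(records)), c(bad_id, dup_id))
  parsed <- ob_canonicalize(records$smiles[remaining])
  bad_smiles <- remaining[!parsed$ok]
  if (length(bad_smiles)) {
    rejections <- rbind(rejections, reject(bad_smiles, "unparseable structure"))
  }

  keep <- setdiff(remaining, bad_smiles)
  records <- records[keep, , drop = FALSE]
  bad_class <- !is.na(records$compound_class) &
    !(records$compound_class %in% compound_classes)
  records$compound_class[bad_class] <- "other"
  status_ok <- records$activity_status %in% c("known_active", "candidate")
  records$activity_status[!status_ok] <- NA_character_

  rejections <- rejections[order(rejections$row), , drop = FALSE]
  new_compound_library(records, rejections)
}

#' Write a compound library table
#'
#' Writes the library's records as CSV in the package's standard column
#' layout; [read_compound_table()] on the result restores every field.
#'
#' @param library A `compound_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(library, path) {
  stopifnot(inherits(library, "compound_library"))
  utils::write.csv(library$records[, lib_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Canonicalize structures and merge duplicates
#'
#' Replaces every record's SMILES by the toolkit's canonical isomeric form
#' (stereochemistry is preserved: glycoside stereocenters distinguish many
#' herbal flavonoids) and, when `dedup` is on, merges structurally
#' identical records, first-seen identifier winning. With `strip_salts`
#' (default on) the largest organic fragment of a salt/solvate is kept
#' before comparison.
#'
#' @param library A `compound_library` whose records all parse.
#' @param strip_salts Keep only the largest organic fragment of
#'   multi-fragment structures.
#' @param dedup Merge records sharing an identical canonical structure.
#' @return A `compound_library`; merged identifiers are recorded in the
#'   `merged_ids` attribute of the returned object (named list,
#'   survivor id -> absorbed ids).
#' @export
canonicalize_and_dedup <- function(library, strip_salts = TRUE, dedup = TRUE) {
  stopifnot(inherits(library, "compound_library"))
  records <- library$records
  parsed <- ob_canonicalize(records$smiles)
  if (any(!parsed$ok)) {
    stop("canonicalize_and_dedup requires parseable structures; offending id(s): ",
         paste(records$compound_id[!parsed$ok], collapse = ", "))
  }
  canonical <- parsed$canonical
  if (strip_salts) {
    canonical <- vapply(canonical, ob_strip_salts, character(1), USE.NAMES = FALSE)
  }
  records$smiles <- canonical

  merged <- list()
  if (dedup) {
    first <- !duplicated(records$smiles)
    if (any(!first)) {
      for (i in which(!first)) {
        survivor <- records$compound_id[match(records$smiles[i], records$smiles)]
        merged[[survivor]] <- c(merged[[survivor]], records$compound_id[i])
      }
      records <- records[first, , drop = FALSE]
    }
  }
  out <- new_compound_library(records, library$rejections)
  attr(out, "merged_ids") <- merged
  out
}

#' Partition a library into known actives and candidates
#'
#' Flags the given identifiers as `known_active` (compounds with reported
#' activity for the indication under study) and every other record as
#' `candidate`. The labeling is a partition: each record carries exactly
#' one of the two statuses afterwards.
#'
#' @param library A `compound_library`.
#' @param known_ids Character vector of compound identifiers with reported
#'   activity; must all be present in the library.
#' @return The re-labeled `compound_library`.
#' @export
label_activity <- function(library, known_ids) {
  stopifnot(inherits(library, "compound_library"))
  known_ids <- unique(as.character(known_ids))
  missing <- setdiff(known_ids, library$records$compound_id)
  if (length(missing)) {
    stop("known_ids not present in the library: ",
         paste(missing, collapse = ", "))
  }
  library$records$activity_status <-
    ifelse(library$records$compound_id %in% known_ids,
           "known_active", "candidate")
  library
}

#' @export
print.compound_library <- function(x, ...) {
  cat("<compound_library> ", nrow(x$records), " compounds (",
      n_known(x), " known_active, ", n_candidate(x), " candidate, ",
      sum(is.na(x$records$activity_status)), " unlabeled); ",
      nrow(x$rejections), " rejected at ingest\n", sep = "")
  invisible(x)
}

#' Library partition counts
#'
#' @param library A `compound_library`.
#' @return Integer count of known-active (`n_known`) or candidate
#'   (`n_candidate`) records.
#' @export
n_known <- function(library) {
  sum(library$records$activity_status == "known_active", na.rm = TRUE)
}

#' @rdname n_known
#' @export
n_candidate <- function(library) {
  sum(library$records$activity_status == "candidate", na.rm = TRUE)
}

#' Write the rejection report of a library
#'
#' @param library A `compound_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(library, path) {
  utils::write.table(library$rejections, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
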