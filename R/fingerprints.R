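# Circular substructure fingerprints and Tanimoto similarity.
#
# The extended-connectivity family encodes, for every atom, hashed
# identifiers of its neighborhood grown over `radius` iterations of bond
# connectivity; ECFP4 (radius 2, diameter 4) is the de-facto standard for
# ligand-based similarity. The toolkit emits 4096-bit vectors which are
# OR-folded down to the requested length (2048 by default, the dominant
# convention).

OB_NATIVE_BITS <- 4096L

ecfp_name <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0 ||
      radius != round(radius) || radius > 5) {
    stop("radius must be an integer between 0 and 5 (ECFP0..ECFP10)")
  }
  paste0("ECFP", 2L * as.integer(radius))
}

fold_bits <- function(mat, n_bits) {
  native <- ncol(mat)
  if (n_bits > native || native %% n_bits != 0L) {
    stop("n_bits must be a divisor of the native fingerprint length (",
         native, ")")
  }
  if (n_bits == native) {
    mode(mat) <- "integer"
    return(mat)
  }
  out <- matrix(0L, nrow(mat), n_bits, dimnames = list(rownames(mat), NULL))
  for (block in seq_len(native %/% n_bits)) {
    cols <- ((block - 1L) * n_bits + 1L):(block * n_bits)
    out <- out | mat[, cols, drop = FALSE]
  }
  mode(out) <- "integer"
  out
}

new_fingerprint <- function(bits, radius) {
  bits <- as.integer(bits)
  structure(
    list(bits = bits, n_bits = length(bits), radius = as.integer(radius),
         popcount = sum(bits)),
    class = "fingerprint"
  )
}

#' Batch fingerprint computation
#'
#' Computes circular fingerprints for a vector of SMILES in one toolkit
#' pass. All structures must parse.
#'
#' @param smiles Character vector of valid SMILES; names (or the strings
#'   themselves) become row names.
#' @param radius Neighborhood iterations (2 = ECFP4, the default).
#' @param n_bits Folded fingerprint length; must divide 4096.
#' @return Integer 0/1 matrix, one row per structure, with attributes
#'   `radius` and `n_bits`.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 2048) {
  fpname <- ecfp_name(radius)
  ids <- if (!is.null(names(smiles))) names(smiles) else smiles
  valid <- ob_canonicalize(smiles)
  if (any(!valid$ok)) {
    stop("unparseable structure(s): ",
         paste(ids[!valid$ok], collapse = ", "))
  }
  input <- paste(paste0(smiles, "\t", ids), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  raw <- ChemmineOB::fingerprint_OB(mols, fpname, reverse = TRUE)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  rownames(raw) <- ids
  out <- fold_bits(raw, n_bits)
  attr(out, "radius") <- as.integer(radius)
  attr(out, "n_bits") <- as.integer(n_bits)
  out
}

#' Compute one circular fingerprint
#'
#' Deterministic: any SMILES writing of the same molecule yields an
#' identical bit vector, because the underlying atom environments are
#' order-independent.
#'
#' @param smiles A single valid SMILES string.
#' @inheritParams fingerprint_matrix
#' @return A `fingerprint`: list with `bits` (integer 0/1 vector),
#'   `n_bits`, `radius`, and `popcount`.
#' @export
compute_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  mat <- fingerprint_matrix(smiles, radius = radius, n_bits = n_bits)
  new_fingerprint(mat[1L, ], radius)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ECFP", 2L * x$radius, ", ", x$n_bits, " bits, ",
      x$popcount, " set\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' The Tanimoto coefficient of binary fingerprints A and B is
#' \eqn{|A \cap B| / (|A| + |B| - |A \cap B|)}: 0 means no shared
#' substructure bits, 1 identical bit sets. Computed in exact integer
#' arithmetic (a single final division), so values such as 2/5 are as
#' exact as doubles allow. Two all-zero fingerprints compare as 0 by
#' convention: featureless structures are never called similar.
#'
#' @param a,b `fingerprint` objects with matching `n_bits` and `radius`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits || a$radius != b$radius) {
    stop("fingerprints are not comparable: n_bits/radius differ")
  }
  inter <- sum(a$bits & b$bits)
  union <- a$popcount + b$popcount - inter
  if (union == 0L) return(0)
  inter / union
}

# Dense known x candidate Tanimoto grid from two 0/1 matrices.
# Integer cross-products keep intersection and union counts exact.
tanimoto_grid <- function(A, B) {
  storage.mode(A) <- "integer"
  storage.mode(B) <- "integer"
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- ifelse(union == 0, 0, inter / union)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Fingerprint cache files
#'
#' Persists a fingerprint matrix as a plain-text TSV (`compound_id`,
#' `radius`, `n_bits`, hex-encoded bits) so pipeline reruns are
#' reproducible without recomputation.
#'
#' @param fps Matrix from [fingerprint_matrix()].
#' @param path Cache file path.
#' @return For the writer, `path` invisibly; for the reader, the restored
#'   matrix with `radius`/`n_bits` attributes.
#' @export
write_fingerprint_cache <- function(fps, path) {
  radius <- attr(fps, "radius")
  n_bits <- attr(fps, "n_bits")
  hex <- apply(fps, 1L, function(bits) {
    nib <- vapply(seq_len(length(bits) %/% 4L), function(j) {
      sum(bits[(4L * j - 3L):(4L * j)] * c(8L, 4L, 2L, 1L))
    }, numeric(1))
    paste(format.hexmode(nib), collapse = "")
  })
  df <- data.frame(compound_id = rownames(fps), radius = radius,
                   n_bits = n_bits, bits_hex = hex)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_cache
#' @export
read_fingerprint_cache <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  stopifnot(length(unique(df$radius)) == 1L, length(unique(df$n_bits)) == 1L)
  n_bits <- df$n_bits[1L]
  mat <- t(vapply(df$bits_hex, function(h) {
    nib <- strtoi(strsplit(h, "")[[1L]], 16L)
    as.integer(unlist(lapply(nib, function(v) {
      c(v %/% 8L, v %/% 4L %% 2L, v %/% 2L %% 2L, v %% 2L)
    })))
  }, integer(n_bits)))
  rownames(mat) <- df$compound_id
  attr(mat, "radius") <- df$radius[1L]
  attr(mat, "n_bits") <- n_bits
  mat
}
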