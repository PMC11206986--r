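# Internal wrappers around the OpenBabel bindings (ChemmineOB).
# All structure parsing in the package funnels through here so that the
# "parses or is rejected" contract is enforced in exactly one place.

# Parse one SMILES string; return its OBMol reference or NULL on failure.
ob_mol <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles) || grepl("[\t\n ]", smiles)) {
    return(NULL)
  }
  mols <- tryCatch(
    suppressWarnings(
      ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tmol"), identity)
    ),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) == 0L) NULL else mols[[1L]]
}

# Vectorized validity + canonical (isomeric) SMILES.
# Returns a data.frame with columns ok (logical) and canonical (character).
ob_canonicalize <- function(smiles) {
  out <- data.frame(
    ok = logical(length(smiles)),
    canonical = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(smiles)) {
    mol <- ob_mol(smiles[[i]])
    if (is.null(mol)) next
    props <- tryCatch(ChemmineOB::prop_OB(mol), error = function(e) NULL)
    can <- if (is.null(props)) NA_character_ else as.character(props$cansmi[1L])
    if (!is.na(can) && nzchar(can)) {
      out$ok[i] <- TRUE
      out$canonical[i] <- trimws(can)
    }
  }
  out
}

# Heavy (non-hydrogen) atom count from a molecular formula such as "C15H10O4".
ob_heavy_atoms <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  total <- 0L
  for (tok in tokens) {
    elem <- gsub("[0-9]", "", tok)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", tok)))
    if (is.na(n)) n <- 1L
    if (elem != "H") total <- total + n
  }
  total
}

# Largest-organic-fragment rule for salt/solvate stripping: among the
# dot-separated components, keep the fragment with the most heavy atoms,
# preferring carbon-containing fragments; ties broken by canonical SMILES.
ob_strip_salts <- function(canonical_smiles) {
  if (!grepl(".", canonical_smiles, fixed = TRUE)) return(canonical_smiles)
  frags <- strsplit(canonical_smiles, ".", fixed = TRUE)[[1L]]
  info <- lapply(frags, function(f) {
    mol <- ob_mol(f)
    if (is.null(mol)) return(NULL)
    props <- tryCatch(ChemmineOB::prop_OB(mol), error = function(e) NULL)
    if (is.null(props)) return(NULL)
    list(
      canonical = trimws(as.character(props$cansmi[1L])),
      heavy = ob_heavy_atoms(as.character(props$formula[1L])),
      organic = grepl("C", as.character(props$formula[1L]))
    )
  })
  info <- Filter(Negate(is.null), info)
  if (length(info) == 0L) return(canonical_smiles)
  ord <- order(
    vapply(info, function(x) !x$organic, logical(1)),
    -vapply(info, function(x) x$heavy, numeric(1)),
    vapply(info, function(x) x$canonical, character(1))
  )
  info[[ord[1L]]]$canonical
}
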