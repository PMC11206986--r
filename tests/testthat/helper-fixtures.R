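# Shared fixtures: all built in code at test time.

# Wrap a raw 0/1 vector as a fingerprint object (internal constructor).
make_fp <- function(bits, radius = 2L) {
  npscreen:::new_fingerprint(bits, radius)
}

# Random fingerprint pair with controllable density.
random_fp_pair <- function(n_bits = 256L, density = 0.2) {
  a <- as.integer(runif(n_bits) < density)
  b <- as.integer(runif(n_bits) < density)
  list(a = make_fp(a), b = make_fp(b))
}

# Brute-force Tanimoto by explicit set arithmetic over bit positions.
tanimoto_bruteforce <- function(a, b) {
  pa <- which(a$bits == 1L)
  pb <- which(b$bits == 1L)
  u <- length(union(pa, pb))
  if (u == 0L) 0 else length(intersect(pa, pb)) / u
}

# Write a compound table CSV from a data.frame of partial columns.
write_lib_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A tiny 4-compound library on disk: two ring systems, two aliphatics.
tiny_library <- function() {
  write_lib_csv(data.frame(
    compound_id = c("c1", "c2", "c3", "c4"),
    name = c("flavone", "hydroxyflavone", "octane", "octanol"),
    smiles = c("O=C1C=C(c2ccccc2)Oc2ccccc21",
               "O=C1C=C(c2ccc(O)cc2)Oc2ccccc21",
               "CCCCCCCC", "CCCCCCCCO"),
    compound_class = c("flavonoid", "flavonoid", "hydrocarbon", "other"),
    stringsAsFactors = FALSE
  ))
}

# Manual similarity matrix with the package's class tag.
sim_matrix <- function(values, known_ids, candidate_ids) {
  m <- matrix(values, nrow = length(known_ids),
              dimnames = list(known_ids, candidate_ids))
  class(m) <- c("similarity_matrix", class(m))
  m
}

# Exhaustive-enumeration hypergeometric upper tail: probability that a
# uniform size-n subset of 1..N overlaps 1..K in at least k elements.
hyper_enum_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  subsets <- combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# A small geneset collection built in code.
toy_collection <- function() {
  new_geneset_collection(
    list(S1 = c("A", "B", "C"), S2 = c("C", "D", "E", "F"),
         S3 = c("G", "H")),
    source_label = "toy"
  )
}
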