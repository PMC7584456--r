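# Shared fixtures, built in code at test time.

# Minimal hand-written PDB with two atoms.
write_two_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       4.500  -2.250   0.125  1.00  0.00           C",
    "END"
  ), path)
  path
}

# Structure from a bare coordinate matrix (all CA carbon atoms, one
# residue per atom).
structure_from_xyz <- function(xyz, chain = "A", name = "CA",
                               element = "C") {
  n <- nrow(xyz)
  atom <- data.frame(
    serial = seq_len(n), name = name, element = element, resname = "ALA",
    chain = chain, resid = seq_len(n), is_hydrogen = FALSE,
    stringsAsFactors = FALSE
  )
  kda:::new_structure(atom, list(xyz))
}

# Two-chain complex: a column of atoms (chain A) facing a second column
# (chain B) at a given gap.
two_column_complex <- function(gap = 4, n = 5) {
  a <- structure_from_xyz(cbind(0, 0, seq_len(n) * 3), chain = "A")
  b <- structure_from_xyz(cbind(gap, 0, seq_len(n) * 3), chain = "B")
  merge_structures(a, b)
}

# Restraint set data frame builder.
restraints_df <- function(chain_a, res_a, chain_b, res_b,
                          kind = "disulfide", state = "both",
                          bound = NA_real_) {
  df <- data.frame(chain_a = chain_a, res_a = res_a, chain_b = chain_b,
                   res_b = res_b, kind = kind, state = state,
                   bound = bound, source = "test",
                   stringsAsFactors = FALSE)
  df$bound <- ifelse(is.na(df$bound), kda:::default_bound(df$kind), df$bound)
  kda:::new_restraint_set(df)
}

# Random rigid pose for property tests.
random_pose <- function() {
  a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
  rigid_pose(kda:::rotation_matrix(a, stats::runif(1, 0, 360)),
             stats::rnorm(3, sd = 5))
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); the brute-force oracle for max-modularity community tests.
set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(1L, 1L)
  out
}

# The toy complex is expensive enough to share across tests.
toy_cache <- new.env()
get_toy <- function() {
  if (is.null(toy_cache$tc)) toy_cache$tc <- make_toy_complex()
  toy_cache$tc
}
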