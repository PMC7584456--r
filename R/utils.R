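# Shared geometric and numeric helpers (internal).

# van der Waals radii (Bondi-style, Angstrom) used for clash detection,
# SASA and pore profiling. Elements not listed fall back to carbon.
.vdw_table <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
  S = 1.80, P = 1.80, F = 1.47, CL = 1.75, BR = 1.85,
  I = 1.98, SE = 1.90
)

#' van der Waals radius lookup
#'
#' Per-element van der Waals radii (Angstrom) used throughout the
#' package for clash scoring, solvent accessibility and pore profiling.
#' Unknown elements fall back to the carbon radius (1.70 A).
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- .vdw_table[["C"]]
  unname(r)
}

# Squared pairwise distances between rows of two n x 3 matrices.
pairdist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

pairdist <- function(a, b) sqrt(pairdist2(a, b))

# Deterministic quasi-uniform points on the unit sphere (Fibonacci
# lattice); used by the Shrake-Rupley quadrature.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Orthonormal basis (3x3, columns) whose third column is `axis`.
axis_basis <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(
    w[2] * u[3] - w[3] * u[2],
    w[3] * u[1] - w[1] * u[3],
    w[1] * u[2] - w[2] * u[1]
  )
  cbind(u, v, w, deparse.level = 0)
}

# Rotation matrix for a right-handed rotation by `angle_deg` about `axis`.
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
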