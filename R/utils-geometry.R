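# Internal geometry primitives shared by the builders and annotators.

# Boltzmann constant times Avogadro, kJ/(mol K)
KB_KJ <- 0.0083144621

#' Thermal energy kT in kJ/mol
#' @param temperature Temperature in kelvin.
#' @return kT in kJ/mol (2.4943 kJ/mol at 300 K).
#' @export
kT_kJmol <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KJ * temperature
}

KCAL_PER_KJ <- 1 / 4.184

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for angle theta (radians) about unit axis k (Rodrigues).
rotation_matrix <- function(axis, theta) {
  k <- unit(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Place atom D given positions A, B, C and internal coordinates:
# |C-D| = bond, angle(B,C,D) = angle (deg), dihedral(A,B,C,D) = dihedral (deg).
# Standard natural-extension-reference-frame construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  as.numeric(c - bond * cos(th) * bc + bond * sin(th) * cos(chi) * m -
               bond * sin(th) * sin(chi) * n)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, unit(b2)) * n2)
  atan2(y, x) * 180 / pi
}

# Run thunk under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# van der Waals radii (Angstrom) by element; CHAP-like fixed table.
VDW_TABLE <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, NA. = 2.27, CL = 1.75)

#' Van der Waals radius lookup
#'
#' Fixed per-element radii used by the pore radius profiler
#' (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Angstrom; 1.70 for
#' unknown elements).
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  r <- VDW_TABLE[key]
  r[is.na(r)] <- 1.70
  unname(r)
}
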