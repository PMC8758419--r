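# Pore axis, radius profiling and the pore-centred residue-orientation frame.

#' Construct a pore axis directly
#'
#' @param origin 3-vector, Angstrom.
#' @param direction 3-vector; normalized internally. +z is the
#'   extracellular (selectivity-filter) side.
#' @return A `PoreAxis`.
#' @export
pore_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  out <- list(origin = as.numeric(origin), direction = unit(direction))
  class(out) <- "PoreAxis"
  out
}

#' Fit the pore axis of a pseudo-symmetric channel
#'
#' The axis origin is the centroid of the four subunit selections. The four
#' per-subunit centroids of a pseudo-C4 channel lie in a plane perpendicular
#' to the pore; the direction is the normal of that best-fit plane (the
#' smallest principal component of the centroids). The sign is chosen so the
#' selectivity-filter end lies at +z (by default: positive projection onto
#' the laboratory z axis; supply `sf_point` to anchor the sign on a known
#' extracellular-side coordinate). A structure with no extent along the
#' fitted axis (planar geometry) is rejected.
#'
#' @param structure A `Structure`.
#' @param subunit_selections List of exactly four selections (strings or
#'   lists, see [atom_mask()]), one per subunit, with equal atom counts.
#' @param sf_point Optional 3-vector on the selectivity-filter side used to
#'   orient the axis.
#' @return A `PoreAxis`: list with `origin` (3-vector, Angstrom) and
#'   `direction` (unit 3-vector).
#' @export
fit_pore_axis <- function(structure, subunit_selections, sf_point = NULL) {
  if (length(subunit_selections) != 4)
    stop("need exactly four subunit selections, got ",
         length(subunit_selections))
  xyz_list <- lapply(subunit_selections, function(sel)
    coords(subset_structure(structure, sel)))
  counts <- vapply(xyz_list, nrow, integer(1))
  if (length(unique(counts)) != 1)
    stop("subunit selections have unequal atom counts: ",
         paste(counts, collapse = ", "))
  if (counts[1] == 0) stop("empty subunit selection")
  xyz <- do.call(rbind, xyz_list)
  origin <- colMeans(xyz)
  cents <- do.call(rbind, lapply(xyz_list, colMeans))
  cc <- sweep(cents, 2, colMeans(cents))
  sv <- svd(cc, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9)
    stop("degenerate bundle geometry: subunit centroids are collinear")
  dir <- sv$v[, 3]  # normal of the centroid plane
  t_span <- range(sweep(xyz, 2, origin) %*% dir)
  if (diff(t_span) < 1e-3)
    stop("degenerate (planar) bundle geometry: no extent along the pore axis")
  ref <- if (is.null(sf_point)) c(0, 0, 1) else unit(sf_point - origin)
  if (sum(dir * ref) < 0) dir <- -dir
  out <- list(origin = as.numeric(origin), direction = unit(dir))
  class(out) <- "PoreAxis"
  out
}

#' @export
print.PoreAxis <- function(x, ...) {
  cat(sprintf("PoreAxis: origin (%.2f, %.2f, %.2f) A, direction (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# Axial (z) and radial coordinates of points relative to a PoreAxis.
axis_coordinates <- function(xyz, axis) {
  rel <- sweep(xyz, 2, axis$origin)
  zc <- as.numeric(rel %*% axis$direction)
  radial <- rel - outer(zc, axis$direction)
  list(z = zc, r = sqrt(rowSums(radial^2)))
}

#' Pore radius profile over a trajectory
#'
#' HOLE-style straight-axis profile: for every frame and axial bin, the pore
#' radius is the minimum over atoms whose axial coordinate falls inside the
#' bin slab of (distance from the axis minus the atom's van der Waals
#' radius), floored at zero. Bins covered by no atom in a frame are assigned
#' the probe cap and flagged. The profile aggregates mean, standard
#' deviation, and extremes over frames.
#'
#' @param trajectory A `Trajectory` (or a `Structure`, treated as one frame).
#' @param axis A `PoreAxis`.
#' @param z_range Axial range `c(zmin, zmax)` in Angstrom, relative to the
#'   axis origin.
#' @param bin_width Bin width, Angstrom (default 1).
#' @param selection Optional selection restricting the atoms considered
#'   (e.g. protein only).
#' @param probe_cap Radius assigned to empty slabs, Angstrom (default 10).
#' @return A `PoreProfile`: data.frame with columns `z`, `mean_radius`,
#'   `sd_radius`, `min_radius`, `max_radius`, `empty_flag` (TRUE where any
#'   frame had an empty slab); Angstrom throughout.
#' @export
radius_profile <- function(trajectory, axis, z_range, bin_width = 1,
                           selection = NULL, probe_cap = 10) {
  if (inherits(trajectory, "Structure"))
    trajectory <- new_trajectory(trajectory, list(coords(trajectory)))
  stopifnot(inherits(trajectory, "Trajectory"), inherits(axis, "PoreAxis"))
  if (bin_width <= 0) stop("bin_width must be positive")
  mask <- if (is.null(selection)) rep(TRUE, nrow(trajectory$topology$atoms))
  else atom_mask(trajectory$topology, selection)
  vdw <- vdw_radius(trajectory$topology$atoms$element[mask])
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  nf <- n_frames(trajectory)
  radii <- matrix(NA_real_, nf, nb)
  empty <- matrix(FALSE, nf, nb)
  for (f in seq_len(nf)) {
    ac <- axis_coordinates(trajectory$frames[[f]][mask, , drop = FALSE], axis)
    bin <- findInterval(ac$z, edges, rightmost.closed = TRUE)
    inside <- bin >= 1 & bin <= nb
    rad <- pmax(ac$r - vdw, 0)
    mins <- rep(NA_real_, nb)
    if (any(inside)) {
      agg <- tapply(rad[inside], bin[inside], min)
      mins[as.integer(names(agg))] <- agg
    }
    miss <- is.na(mins)
    mins[miss] <- probe_cap
    radii[f, ] <- mins
    empty[f, ] <- miss
  }
  out <- data.frame(
    z = centers,
    mean_radius = colMeans(radii),
    sd_radius = apply(radii, 2, function(v) if (nf > 1) sd(v) else 0),
    min_radius = apply(radii, 2, min),
    max_radius = apply(radii, 2, max),
    empty_flag = apply(empty, 2, any))
  class(out) <- c("PoreProfile", "data.frame")
  out
}

#' Pore-lining residues
#'
#' Residues with any atom lying within `cutoff` of the pore axis inside an
#' axial window, sorted by their minimum axial distance. This is how the
#' hydrophobic constriction (e.g. the Leu/Ile ring at the activation gate)
#' is located.
#'
#' @param structure A `Structure`.
#' @param axis A `PoreAxis`.
#' @param z_window Axial window `c(zmin, zmax)`, Angstrom.
#' @param cutoff Lining distance cutoff from the axis, Angstrom (default 6).
#' @return data.frame with columns `chain`, `resno`, `resname`,
#'   `min_axis_distance`, sorted ascending by distance.
#' @export
pore_lining_residues <- function(structure, axis, z_window, cutoff = 6) {
  a <- structure$atoms
  ac <- axis_coordinates(coords(structure), axis)
  inside <- ac$z >= z_window[1] & ac$z <= z_window[2] & ac$r <= cutoff
  if (!any(inside))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), min_axis_distance = numeric(),
                      stringsAsFactors = FALSE))
  d <- data.frame(chain = a$chain[inside], resno = a$resno[inside],
                  resname = a$resname[inside], r = ac$r[inside],
                  stringsAsFactors = FALSE)
  agg <- aggregate(r ~ chain + resno + resname, data = d, FUN = min)
  agg <- agg[order(agg$r), , drop = FALSE]
  names(agg)[names(agg) == "r"] <- "min_axis_distance"
  rownames(agg) <- NULL
  agg
}

#' Pore-centred orientation of a residue sidechain
#'
#' Builds the per-residue reference frame used to score whether the conserved
#' asparagine points toward the pore: the residue's Calpha is the origin; the
#' x axis is the unit vector from Calpha toward its projection onto the pore
#' axis (so positive x means pore-facing); z is the pore-axis direction; and
#' y completes the right-handed frame. The returned point is the (x, y)
#' component pair of the Calpha -> Cgamma vector in that frame.
#'
#' @param structure A `Structure`.
#' @param axis A `PoreAxis`.
#' @param chain Chain id of the residue.
#' @param resno Residue number.
#' @param gamma_name Name of the sidechain gamma atom (default `"CG"`).
#' @return An `OrientationPoint`: list with `chain`, `resno`, `x`, `y`
#'   (Angstrom).
#' @export
residue_orientation <- function(structure, axis, chain, resno,
                                gamma_name = "CG") {
  a <- structure$atoms
  ca <- atom_xyz(a, chain, resno, "CA")
  cg <- atom_xyz(a, chain, resno, gamma_name)
  if (is.null(ca)) stop("residue ", chain, ":", resno, " lacks CA")
  if (is.null(cg)) stop("residue ", chain, ":", resno, " lacks ", gamma_name)
  rel <- ca - axis$origin
  zc <- sum(rel * axis$direction)
  foot <- axis$origin + zc * axis$direction  # projection of CA onto the axis
  radial <- foot - ca
  if (vec_norm(radial) < 1e-9)
    stop("residue ", chain, ":", resno,
         " has its CA on the pore axis; orientation frame undefined")
  xhat <- unit(radial)
  zhat <- unit(axis$direction - sum(axis$direction * xhat) * xhat)
  yhat <- cross3(zhat, xhat)
  v <- cg - ca
  out <- list(chain = chain, resno = resno,
              x = sum(v * xhat), y = sum(v * yhat))
  class(out) <- "OrientationPoint"
  out
}

#' @export
print.OrientationPoint <- function(x, ...) {
  cat(sprintf("OrientationPoint %s:%d  (x, y) = (%.3f, %.3f) A  [%s]\n",
              x$chain, x$resno, x$x, x$y,
              if (x$x > 0) "pore-facing" else "away-facing"))
  invisible(x)
}
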