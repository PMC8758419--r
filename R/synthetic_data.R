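# Synthetic fixtures: ideal helices, C4 toy channels, Boltzmann-distributed
# water fields, noisy PMF windows, and planted pose ensembles. Every
# generator is a pure function of (spec, seed): identical inputs give
# identical outputs.

# Classic ideal repeat dihedrals. For the pi-helix the ideal repeat
# (-57, -70; 4.4 residues/turn) is used rather than the average observed in
# structures (-76, -41): only the former reproduces i+5 -> i hydrogen-bond
# geometry when repeated with ideal bond lengths and angles.
HELIX_DIHEDRALS <- list(alpha = c(phi = -57, psi = -47),
                        pi = c(phi = -57, psi = -70),
                        three_ten = c(phi = -49, psi = -26))

# ideal backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

#' Build an ideal helix backbone
#'
#' Constructs N, CA, C, O (and on request CB) for a poly-peptide with
#' canonical helical dihedrals: alpha phi=-57, psi=-47; pi phi=-76, psi=-41;
#' 3-10 phi=-49, psi=-26 (degrees), ideal bond lengths and angles, omega
#' 180. The helix axis is aligned with +z and the CA centroid sits at the
#' origin. Deterministic.
#'
#' @param n_residues Number of residues (>= 2).
#' @param kind `"alpha"`, `"pi"`, or `"three_ten"`.
#' @param sequence Optional one-letter sequence (length `n_residues`);
#'   default poly-alanine. Residue names only; no sidechains beyond CB are
#'   built.
#' @param chain_id Chain id (default `"A"`).
#' @param first_resno Residue number of the first residue (default 1).
#' @param add_cb Also place CB at the standard tetrahedral position.
#' @return A `Structure`.
#' @export
make_ideal_helix <- function(n_residues, kind = c("alpha", "pi", "three_ten"),
                             sequence = NULL, chain_id = "A",
                             first_resno = 1, add_cb = FALSE) {
  kind <- match.arg(kind)
  if (n_residues < 2) stop("need at least 2 residues")
  dih <- HELIX_DIHEDRALS[[kind]]
  if (is.null(sequence)) sequence <- rep("A", n_residues)
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != n_residues)
    stop("sequence length must equal n_residues")
  g <- BB_GEOM
  n_pos <- ca_pos <- c_pos <- vector("list", n_residues + 1)
  n_pos[[1]] <- c(0, 0, 0)
  ca_pos[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  c_pos[[1]] <- ca_pos[[1]] +
    g$ca_c * c(cos(ang) * -1, sin(ang), 0)
  for (i in seq_len(n_residues)) {
    n_pos[[i + 1]] <- place_atom(n_pos[[i]], ca_pos[[i]], c_pos[[i]],
                                 g$c_n, g$ang_ca_c_n, dih["psi"])
    ca_pos[[i + 1]] <- place_atom(ca_pos[[i]], c_pos[[i]], n_pos[[i + 1]],
                                  g$n_ca, g$ang_c_n_ca, g$omega)
    if (i < n_residues)
      c_pos[[i + 1]] <- place_atom(c_pos[[i]], n_pos[[i + 1]],
                                   ca_pos[[i + 1]], g$ca_c, g$ang_n_ca_c,
                                   dih["phi"])
  }
  rows <- list()
  serial <- 1L
  emit <- function(name, elem, resno, resname, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, element = elem, resname = resname,
      resno = resno, chain = chain_id, x = p[1], y = p[2], z = p[3],
      stringsAsFactors = FALSE)
    serial <<- serial + 1L
  }
  resnames <- aa_three(sequence)
  for (i in seq_len(n_residues)) {
    rn <- first_resno + i - 1L
    emit("N", "N", rn, resnames[i], n_pos[[i]])
    emit("CA", "C", rn, resnames[i], ca_pos[[i]])
    emit("C", "C", rn, resnames[i], c_pos[[i]])
    # carbonyl O anti to the next amide nitrogen across the sp2 carbon
    o <- place_atom(n_pos[[i + 1]], ca_pos[[i]], c_pos[[i]],
                    g$c_o, g$ang_ca_c_o, 180)
    emit("O", "O", rn, resnames[i], o)
    if (add_cb && resnames[i] != "GLY") {
      cb <- place_atom(c_pos[[i]], n_pos[[i]], ca_pos[[i]],
                       1.53, 110.5, 122.6)
      emit("CB", "C", rn, resnames[i], cb)
    }
  }
  s <- new_structure(do.call(rbind, rows))
  align_axis_to_z(s)
}

# Rotate a structure so the principal axis of its CA trace lies along +z and
# the CA centroid is at the origin.
align_axis_to_z <- function(structure) {
  ca <- structure$atoms$name == "CA"
  xyz <- coords(structure)
  ctr <- colMeans(xyz[ca, , drop = FALSE])
  centred <- sweep(xyz, 2, ctr)
  sv <- svd(sweep(xyz[ca, , drop = FALSE], 2, ctr), nu = 0)
  axis <- sv$v[, 1]
  # orient from first CA to last CA
  ca_idx <- which(ca)
  span <- xyz[ca_idx[length(ca_idx)], ] - xyz[ca_idx[1], ]
  if (sum(axis * span) < 0) axis <- -axis
  z <- c(0, 0, 1)
  v <- cross3(axis, z)
  if (vec_norm(v) < 1e-12) {
    rot <- if (sum(axis * z) > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    theta <- acos(pmin(1, pmax(-1, sum(axis * z))))
    rot <- rotation_matrix(v, theta)
  }
  set_coords(structure, centred %*% t(rot))
}

#' Build a C4 toy channel
#'
#' Four ideal alpha-helices placed with C4 symmetry about the z axis at
#' `bundle_radius`, chains A-D. The residue at `gate_ring_position` (index
#' along the helix) carries pseudo-sidechain CB and CG atoms placed along
#' the radial direction; with `inward = TRUE` the CG ring sits at radial
#' distance `gate_radius` plus the carbon van der Waals radius, so the pore
#' radius profile reads `gate_radius` at the gate ring's z.
#'
#' @param helix_length Residues per helix (>= 10).
#' @param bundle_radius Helix-axis distance from the pore axis, Angstrom.
#' @param gate_radius Intended open pore radius at the gate ring, Angstrom
#'   (> 0).
#' @param gate_ring_position Residue index (1-based along the helix) of the
#'   gate ring.
#' @param inward Point the gate CG atoms toward the pore axis (TRUE,
#'   default) or away from it.
#' @param first_resno Residue number of the first helix residue (default
#'   201, echoing pore-domain numbering).
#' @return A `Structure` with chains A, B, C, D.
#' @export
make_toy_channel <- function(helix_length = 20, bundle_radius = 12,
                             gate_radius = 4.3, gate_ring_position = 10,
                             inward = TRUE, first_resno = 201) {
  if (gate_radius <= 0) stop("gate_radius must be positive")
  if (helix_length < 10) stop("helix_length must be >= 10")
  if (gate_ring_position < 1 || gate_ring_position > helix_length)
    stop("gate_ring_position outside the helix")
  proto <- make_ideal_helix(helix_length, "alpha", first_resno = first_resno)
  xyz <- coords(proto)
  xyz[, 1] <- xyz[, 1] + bundle_radius
  proto <- set_coords(proto, xyz)
  # pseudo-sidechain for the gate ring residue, along the radial direction
  gate_resno <- first_resno + gate_ring_position - 1L
  a <- proto$atoms
  ca <- atom_xyz(a, "A", gate_resno, "CA")
  radial <- unit(c(ca[1], ca[2], 0))
  r_cg <- if (inward) gate_radius + vdw_radius("C")
  else vec_norm(ca[1:2]) + 2.5
  cg <- c(radial[1:2] * r_cg, ca[3])
  cb <- (ca + cg) / 2
  nmax <- max(a$serial)
  extra <- data.frame(
    serial = nmax + 1:2, name = c("CB", "CG"), element = "C",
    resname = a$resname[a$resno == gate_resno][1], resno = gate_resno,
    chain = "A", x = c(cb[1], cg[1]), y = c(cb[2], cg[2]),
    z = c(cb[3], cg[3]), stringsAsFactors = FALSE)
  a <- rbind(a, extra)
  chains <- c("A", "B", "C", "D")
  parts <- list()
  for (k in 0:3) {
    rot <- rotation_matrix(c(0, 0, 1), k * pi / 2)
    part <- a
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
    part$x <- xyz[, 1]; part$y <- xyz[, 2]; part$z <- xyz[, 3]
    part$chain <- chains[k + 1]
    parts[[k + 1]] <- part
  }
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms)
  # refuse geometrically overlapping bundles
  ach <- atoms$chain == "A"; bch <- atoms$chain == "B"
  axy <- as.matrix(atoms[ach, c("x", "y", "z")])
  bxy <- as.matrix(atoms[bch, c("x", "y", "z")])
  d2 <- outer(rowSums(axy^2), rowSums(bxy^2), "+") - 2 * axy %*% t(bxy)
  if (min(d2) < 2.0^2)
    stop("bundle_radius too small: adjacent helices overlap")
  out
}

#' Sample a water field against an imposed free-energy profile
#'
#' Generates trajectory frames of point-particle waters whose axial
#' distribution follows the Boltzmann weight of an imposed profile
#' dG*(z) (a sum of Gaussians): in each axial bin the per-frame count is
#' Poisson with mean `bulk_density * exp(-dG*(z)/kT) * pi r^2 dz`, and
#' positions are uniform within the bin's cylinder. This is the exact
#' statistical inverse of the density-to-free-energy estimator, so
#' [hydration_free_energy()] applied to [water_density_profile()] of the
#' output recovers dG*(z).
#'
#' Because every frame of a `Trajectory` must hold the same atom count,
#' frames are padded to the ensemble maximum with inert placeholder
#' particles parked far below `z_range` (they fall outside any analysis
#' window and never enter a bin).
#'
#' @param gaussians data.frame with columns `height` (kJ/mol), `center`
#'   (Angstrom), `width` (Gaussian sigma, Angstrom; > 0) defining dG*(z) as
#'   their sum. Zero rows give a flat profile.
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed (the generator is bit-reproducible given the seed).
#' @param bulk_density Bulk water density, nm^-3 (default 33.4).
#' @param cylinder_radius Cylinder radius, Angstrom (default 10).
#' @param z_range Axial range, Angstrom (default c(-31, 31): with the
#'   default bin width the bin centers fall on even z, so a feature placed
#'   at the activation gate, z = -10, sits on a bin center).
#' @param bin_width Sampling bin width, Angstrom (default 2).
#' @param temperature Temperature, kelvin (default 300).
#' @return A `Trajectory` of water oxygens (residue name HOH, atom name OW)
#'   with attributes `imposed_dg` (function of z), `spec` (the generator
#'   parameters) recorded on the trajectory.
#' @export
sample_waters <- function(gaussians, n_frames, seed, bulk_density = 33.4,
                          cylinder_radius = 10, z_range = c(-31, 31),
                          bin_width = 2, temperature = 300) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (bulk_density <= 0) stop("bulk_density must be positive")
  if (nrow(gaussians) && any(gaussians$width <= 0))
    stop("Gaussian widths must be positive")
  dg_fun <- function(z) {
    if (!nrow(gaussians)) return(rep(0, length(z)))
    Reduce(`+`, lapply(seq_len(nrow(gaussians)), function(i)
      gaussians$height[i] *
        exp(-(z - gaussians$center[i])^2 / (2 * gaussians$width[i]^2))))
  }
  kt <- kT_kJmol(temperature)
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  lambda <- bulk_density * exp(-dg_fun(centers) / kt) *
    pi * cylinder_radius^2 * bin_width / 1000
  park_z <- z_range[1] - 100  # placeholder particles, outside any window
  frames_raw <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      counts <- rpois(length(lambda), lambda)
      total <- sum(counts)
      if (total == 0) return(matrix(numeric(0), 0, 3))
      zlo <- rep(edges[-length(edges)], counts)
      z <- zlo + runif(total) * bin_width
      rr <- cylinder_radius * sqrt(runif(total))
      th <- runif(total, 0, 2 * pi)
      cbind(rr * cos(th), rr * sin(th), z)
    })
  })
  nmax <- max(vapply(frames_raw, nrow, integer(1)))
  if (nmax == 0) stop("sampled zero waters in every frame; check parameters")
  frames <- lapply(frames_raw, function(m) {
    pad <- nmax - nrow(m)
    if (pad > 0)
      m <- rbind(m, cbind(rep(0, pad), 0, park_z - seq_len(pad) * 0))
    m
  })
  topo <- new_structure(data.frame(
    serial = seq_len(nmax), name = "OW", element = "O", resname = "HOH",
    resno = seq_len(nmax), chain = "W",
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    stringsAsFactors = FALSE))
  traj <- new_trajectory(topo, frames)
  attr(traj, "imposed_dg") <- dg_fun
  attr(traj, "spec") <- list(bulk_density = bulk_density,
                             cylinder_radius = cylinder_radius,
                             z_range = z_range, bin_width = bin_width,
                             temperature = temperature, seed = seed,
                             n_frames = n_frames)
  traj
}

#' Generate noisy PMF windows
#'
#' Emulates profiles estimated at regular intervals over the tail of an
#' adaptive-bias run: the base profile plus i.i.d. per-bin Gaussian noise in
#' each window.
#'
#' @param base_profile A `ProfileTable` with a `dg` column.
#' @param n_windows Number of windows (>= 2).
#' @param noise_sd Noise standard deviation, kJ/mol (>= 0).
#' @param seed RNG seed.
#' @return List of `ProfileTable`s.
#' @export
make_pmf_windows <- function(base_profile, n_windows = 10, noise_sd = 0.5,
                             seed = 1) {
  if (n_windows < 2) stop("need at least 2 windows")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, lapply(seq_len(n_windows), function(w)
    profile_table(z = base_profile$z,
                  dg = base_profile$dg + rnorm(length(base_profile$z),
                                               0, noise_sd),
                  units = c(z = "Angstrom", dg = "kJ/mol"),
                  reference = "raw")))
}

#' Generate a ligand pose ensemble with planted clusters
#'
#' Rigid copies of a small ligand template translated to each cluster
#' centroid plus a bounded jitter (uniform in a cube scaled so the
#' translation never exceeds `spread_nm`). With
#' `spread_nm < min separation / 2` the planted partition is exactly
#' recoverable by RMSD-cutoff clustering.
#'
#' @param cluster_centroids List of 3-vectors (nm), the planted cluster
#'   centers.
#' @param members_per_cluster Integer vector of cluster sizes (recycled to
#'   the number of centroids).
#' @param spread_nm Maximum jitter translation, nm.
#' @param seed RNG seed.
#' @return List of pose coordinate matrices (nm; pass
#'   `input_unit = "nm"` to [cluster_poses()]), with attribute
#'   `planted_membership`.
#' @export
make_pose_ensemble <- function(cluster_centroids, members_per_cluster,
                               spread_nm = 0.02, seed = 1) {
  ncl <- length(cluster_centroids)
  members_per_cluster <- rep_len(members_per_cluster, ncl)
  if (ncl > 1) {
    seps <- c()
    for (i in seq_len(ncl - 1)) for (j in seq(i + 1, ncl))
      seps <- c(seps, vec_norm(cluster_centroids[[i]] -
                                 cluster_centroids[[j]]))
    if (spread_nm >= min(seps) / 2)
      stop("spread_nm must be below half the minimum centroid separation (",
           signif(min(seps) / 2, 3), " nm)")
  }
  template <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0, 0.15, 0), c(0, 0, 0.15))
  half <- spread_nm / sqrt(3)
  frames <- list()
  membership <- integer(0)
  with_seed(seed, {
    for (k in seq_len(ncl)) {
      for (m in seq_len(members_per_cluster[k])) {
        shift <- cluster_centroids[[k]] + runif(3, -half, half)
        frames[[length(frames) + 1]] <- sweep(template, 2, shift, "+")
        membership <- c(membership, k)
      }
    }
  })
  attr(frames, "planted_membership") <- membership
  frames
}
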