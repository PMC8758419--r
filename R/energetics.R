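# Post-processing of 1D permeation PMFs, short-range interaction energies,
# RMSD-cutoff pose clustering, and drug ionization/partition arithmetic.

COULOMB_F <- 138.935  # kJ nm / (mol e^2)
GAS_R_KJ <- 0.0083145  # kJ/(mol K)

#' Average a set of PMF windows
#'
#' Implements the window-averaging protocol used on adaptive-bias outputs:
#' profiles estimated at regular intervals over the tail of a run are
#' averaged per bin, with the standard deviation over the window set as the
#' error bar.
#'
#' @param profiles List of at least two `ProfileTable`s on identical z grids,
#'   each with a `dg` column (kJ/mol).
#' @param column Name of the value column (default `"dg"`).
#' @return A `FreeEnergyProfile`: `ProfileTable` with columns `dg` and `err`
#'   (kJ/mol), reference `"raw"`.
#' @export
average_pmf <- function(profiles, column = "dg") {
  if (length(profiles) < 2) stop("need at least two profiles to average")
  z0 <- profiles[[1]]$z
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (!column %in% names(p))
      stop("profile ", i, " lacks column '", column, "'")
    if (length(p$z) != length(z0) || any(abs(p$z - z0) > 1e-9))
      stop("profile ", i, " is on a different z grid")
  }
  mat <- vapply(profiles, function(p) p[[column]], numeric(length(z0)))
  # population SD over the window set (the error-bar convention of the
  # averaging protocol: the windows ARE the data set, not a sample from one)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- profile_table(z = z0, dg = rowMeans(mat),
                       err = apply(mat, 1, pop_sd),
                       units = c(z = "Angstrom", dg = "kJ/mol",
                                 err = "kJ/mol"),
                       reference = "raw")
  class(out) <- c("FreeEnergyProfile", class(out))
  out
}

#' Shift a free-energy profile to a reference point
#'
#' Subtracts the profile value at the anchor bin so the reference (bulk water
#' or the bilayer center) reads zero; error bars are unchanged. Barrier
#' heights, being differences, are invariant under this shift.
#'
#' @param profile A `ProfileTable` with a `dg` column.
#' @param mode Reference tag to record: `"bulk"` or `"bilayer_center"`.
#' @param anchor_z z position (Angstrom) of the reference; the nearest bin
#'   center is used, and `anchor_z` must fall inside the grid.
#' @return The shifted profile with its `reference` attribute updated.
#' @export
shift_reference <- function(profile, mode = c("bulk", "bilayer_center"),
                            anchor_z) {
  mode <- match.arg(mode)
  z <- profile$z
  if (anchor_z < min(z) - diff(z[1:2]) / 2 ||
      anchor_z > max(z) + diff(z[1:2]) / 2)
    stop("anchor_z = ", anchor_z, " lies outside the profile grid")
  i <- which.min(abs(z - anchor_z))
  profile$dg <- profile$dg - profile$dg[i]
  attr(profile, "reference") <- mode
  attr(profile, "anchor_z") <- z[i]
  profile
}

#' Barrier height of a free-energy profile
#'
#' Height of the maximum inside a region above the minimum of a bulk-side
#' reference window (the whole grid outside the region by default). Ties at
#' the maximum resolve to the smaller z.
#'
#' @param profile A `ProfileTable` with a `dg` column (kJ/mol).
#' @param region_z Region `c(zmin, zmax)` (Angstrom) to search for the
#'   barrier maximum.
#' @param reference_z Optional window `c(zmin, zmax)` whose minimum is the
#'   baseline; default: all bins outside `region_z` (or the global minimum if
#'   the region covers the grid).
#' @return List with `height_kJmol`, `height_kcalmol`, `z_at_max`, and
#'   `baseline_kJmol`.
#' @export
barrier_height <- function(profile, region_z, reference_z = NULL) {
  z <- profile$z
  inreg <- z >= region_z[1] & z <= region_z[2]
  if (!any(inreg)) stop("empty barrier region")
  if (is.null(reference_z)) {
    base_mask <- !inreg
    if (!any(base_mask)) base_mask <- rep(TRUE, length(z))
  } else {
    base_mask <- z >= reference_z[1] & z <= reference_z[2]
    if (!any(base_mask)) stop("empty reference window")
  }
  dgr <- profile$dg[inreg]
  zr <- z[inreg]
  imax <- which(dgr == max(dgr))[1]  # ties: bins ascend in z, keep smallest
  height <- dgr[imax] - min(profile$dg[base_mask])
  list(height_kJmol = height, height_kcalmol = height / 4.184,
       z_at_max = zr[imax], baseline_kJmol = min(profile$dg[base_mask]))
}

#' Short-range residue-ion interaction energies
#'
#' Sum of short-range Coulombic and Lennard-Jones interactions between each
#' residue of a selection and an ion selection, truncated at a cutoff,
#' averaged over frames:
#' E = sum_pairs f q_i q_j / r + 4 eps ((sigma/r)^12 - (sigma/r)^6),
#' with f = 138.935 kJ nm / (mol e^2) and r in nm. Lorentz-Berthelot
#' combination is applied to per-atom sigma/epsilon.
#'
#' @param trajectory A `Trajectory`.
#' @param residue_selection Selection for the residue atoms (see
#'   [atom_mask()]).
#' @param ion_selection Selection for the ion atoms.
#' @param charges Named numeric vector of partial charges (e) keyed by atom
#'   serial, covering every selected atom.
#' @param lj_params data.frame with columns `serial`, `sigma` (nm),
#'   `epsilon` (kJ/mol) covering every selected atom.
#' @param cutoff Short-range cutoff, Angstrom (default 12).
#' @return An `InteractionEnergyTable`: data.frame with columns `chain`,
#'   `resno`, `mean_energy`, `sd_energy` (kJ/mol); attribute `cutoff`.
#' @export
residue_ion_interaction_energy <- function(trajectory, residue_selection,
                                           ion_selection, charges, lj_params,
                                           cutoff = 12) {
  stopifnot(inherits(trajectory, "Trajectory"))
  topo <- trajectory$topology
  rmask <- atom_mask(topo, residue_selection)
  imask <- atom_mask(topo, ion_selection)
  if (!any(rmask)) stop("empty residue selection")
  if (!any(imask)) stop("empty ion selection")
  sel <- topo$atoms[rmask | imask, ]
  missing_q <- setdiff(as.character(sel$serial), names(charges))
  if (length(missing_q))
    stop("missing charge for atom serial(s): ",
         paste(head(missing_q, 5), collapse = ", "))
  ljs <- setNames(lj_params$sigma, as.character(lj_params$serial))
  lje <- setNames(lj_params$epsilon, as.character(lj_params$serial))
  missing_lj <- setdiff(as.character(sel$serial), names(ljs))
  if (length(missing_lj))
    stop("missing LJ parameters for atom serial(s): ",
         paste(head(missing_lj, 5), collapse = ", "))
  ratoms <- which(rmask); iatoms <- which(imask)
  rser <- as.character(topo$atoms$serial[ratoms])
  iser <- as.character(topo$atoms$serial[iatoms])
  qr <- charges[rser]; qi <- charges[iser]
  sr <- ljs[rser]; si <- ljs[iser]
  er <- lje[rser]; ei <- lje[iser]
  sig <- outer(sr, si, function(x, y) (x + y) / 2)
  eps <- outer(er, ei, function(x, y) sqrt(x * y))
  qq <- outer(qr, qi)
  res_key <- paste(topo$atoms$chain[ratoms], topo$atoms$resno[ratoms])
  keys <- unique(res_key)
  nf <- n_frames(trajectory)
  per_frame <- matrix(0, nf, length(keys), dimnames = list(NULL, keys))
  cutoff_nm <- cutoff / 10
  for (f in seq_len(nf)) {
    xyz <- trajectory$frames[[f]]
    rx <- xyz[ratoms, , drop = FALSE]
    ix <- xyz[iatoms, , drop = FALSE]
    # pairwise distances in nm
    d2 <- outer(rowSums(rx^2), rowSums(ix^2), "+") - 2 * rx %*% t(ix)
    r_nm <- sqrt(pmax(d2, 0)) / 10
    within <- r_nm <= cutoff_nm & r_nm > 0
    e_pair <- matrix(0, nrow(rx), nrow(ix))
    if (any(within)) {
      rr <- r_nm[within]
      sr6 <- (sig[within] / rr)^6
      e_pair[within] <- COULOMB_F * qq[within] / rr +
        4 * eps[within] * (sr6^2 - sr6)
    }
    per_frame[f, ] <- tapply(rowSums(e_pair), res_key, sum)[keys]
  }
  out <- data.frame(
    chain = sub(" .*", "", keys),
    resno = as.integer(sub(".* ", "", keys)),
    mean_energy = colMeans(per_frame),
    sd_energy = apply(per_frame, 2, function(v) if (nf > 1) sd(v) else 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("InteractionEnergyTable", "data.frame")
  out
}

# RMS distance between two pose coordinate matrices (Angstrom in, nm out
# when divide = 10). No re-superposition: the pose position in the channel
# frame is the variable of interest.
pose_rms <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Cluster ligand poses by RMSD cutoff (single linkage)
#'
#' Snapshots belong to the same cluster when the RMS distance of the ligand
#' position is below the cutoff from any other element of the cluster:
#' single-linkage connected components of the graph with edges where
#' RMS < cutoff. Clusters are ordered by size (ties: smallest member index);
#' each cluster's representative is its medoid (the member minimizing the
#' mean RMS distance to the rest of the cluster).
#'
#' @param frames List of n x 3 pose coordinate matrices (one per snapshot),
#'   all with the same atom count. Units: Angstrom by default; set
#'   `input_unit = "nm"` if already in nm.
#' @param cutoff RMS cutoff in nm (default 0.1).
#' @param superpose Optional n x 3 reference; when supplied, every frame is
#'   least-squares superposed onto it before distances are computed
#'   (default NULL: distances in the channel frame).
#' @param input_unit `"Angstrom"` (default) or `"nm"`.
#' @return A `ClusterSet`: list with `clusters` (list of frame-index
#'   vectors, size-descending), `representative` (one frame index per
#'   cluster), `sizes`, `membership` (integer vector over frames), and
#'   `cutoff` (nm).
#' @export
cluster_poses <- function(frames, cutoff = 0.1, superpose = NULL,
                          input_unit = c("Angstrom", "nm")) {
  input_unit <- match.arg(input_unit)
  if (!length(frames)) stop("empty frame list")
  if (cutoff <= 0) stop("cutoff must be positive")
  nat <- nrow(frames[[1]])
  for (f in frames) if (nrow(f) != nat)
    stop("pose frames have differing atom counts")
  scale <- if (input_unit == "Angstrom") 0.1 else 1
  if (!is.null(superpose)) {
    frames <- lapply(frames, function(f) {
      fit <- kabsch_fit(f, superpose)
      fit
    })
  }
  n <- length(frames)
  # union-find over edges RMS < cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    fi <- frames[[i]]
    for (j in seq(i + 1, n)) {
      if (pose_rms(fi, frames[[j]]) * scale < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  ord <- order(-vapply(comp, length, integer(1)),
               vapply(comp, min, integer(1)))
  clusters <- unname(comp[ord])
  representative <- vapply(clusters, function(idx) {
    if (length(idx) == 1) return(idx)
    md <- vapply(idx, function(i)
      mean(vapply(setdiff(idx, i), function(j)
        pose_rms(frames[[i]], frames[[j]]) * scale, numeric(1))), numeric(1))
    idx[which.min(md)]
  }, integer(1))
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  out <- list(clusters = clusters, representative = representative,
              sizes = lengths(clusters), membership = membership,
              cutoff = cutoff)
  class(out) <- "ClusterSet"
  out
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d clusters over %d frames (cutoff %.3f nm); sizes: %s\n",
              length(x$clusters), length(x$membership), x$cutoff,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# Least-squares (Kabsch) superposition of mobile onto ref; returns moved mobile.
kabsch_fit <- function(mobile, ref) {
  mc <- colMeans(mobile); rc <- colMeans(ref)
  m0 <- sweep(mobile, 2, mc); r0 <- sweep(ref, 2, rc)
  s <- svd(t(m0) %*% r0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(m0 %*% t(rot), 2, rc, "+")
}

#' Henderson-Hasselbalch ionization fraction
#'
#' Fraction of a monoprotic drug carrying charge at a given pH:
#' a base (e.g. lidocaine, flecainide) is protonated/charged with fraction
#' 1 / (1 + 10^(pH - pKa)); an acid is deprotonated/charged with fraction
#' 1 / (1 + 10^(pKa - pH)).
#'
#' @param pKa Acid dissociation constant (negative log).
#' @param pH Solution pH.
#' @param species `"base"` (default) or `"acid"`.
#' @return A `LigandIonization`: list with `pKa`, `pH`, `species`,
#'   `charged_fraction`, `neutral_fraction`.
#' @export
ionization_fraction <- function(pKa, pH, species = c("base", "acid")) {
  species <- match.arg(species)
  stopifnot(is.finite(pKa), is.finite(pH))
  charged <- if (species == "base") 1 / (1 + 10^(pH - pKa))
  else 1 / (1 + 10^(pKa - pH))
  out <- list(pKa = pKa, pH = pH, species = species,
              charged_fraction = charged, neutral_fraction = 1 - charged)
  class(out) <- "LigandIonization"
  out
}

#' @export
print.LigandIonization <- function(x, ...) {
  cat(sprintf("%s with pKa %.2f at pH %.2f: %.0f%% charged, %.0f%% neutral\n",
              x$species, x$pKa, x$pH, 100 * x$charged_fraction,
              100 * x$neutral_fraction))
  invisible(x)
}

#' Partition coefficient to transfer free energy
#'
#' Converts a lipid-water partition coefficient log(P) into the free energy
#' of partitioning: dG = -ln(10) R T log(P), R = 8.3145 J/(mol K). Positive
#' log(P) (lipid-preferring) gives negative dG.
#'
#' @param logP Decimal log of the partition coefficient.
#' @param temperature Temperature, kelvin (default 298).
#' @return dG in kJ/mol.
#' @export
logp_to_dg <- function(logP, temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  -log(10) * GAS_R_KJ * temperature * logP
}
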