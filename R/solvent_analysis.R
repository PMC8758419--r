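# Water density along the pore and CHAP-style hydration free energy:
# dG(z) = -kT ln(n(z)/n_bulk). Hydrophobic gating shows up as a density hole
# (a free-energy barrier) at the activation gate even when the pore is
# sterically wide enough for water.

WATER_RESNAMES <- c("HOH", "SOL", "TIP3", "TIP", "WAT", "SPC", "W")
WATER_O_NAMES <- c("O", "OW", "OH2")

water_oxygen_mask <- function(structure) {
  a <- structure$atoms
  a$resname %in% WATER_RESNAMES &
    (a$name %in% WATER_O_NAMES | a$element == "O")
}

#' Axial water number-density profile
#'
#' Counts water oxygens per axial bin inside a cylinder around the pore axis,
#' frame by frame, and converts counts to number densities (per nm^3). The
#' bulk density is estimated from the outermost z bands (or supplied).
#'
#' @param trajectory A `Trajectory` whose topology contains water residues
#'   (residue names HOH/SOL/TIP3/WAT/...).
#' @param axis A `PoreAxis`.
#' @param z_range Axial range `c(zmin, zmax)`, Angstrom, relative to the axis
#'   origin.
#' @param cylinder_radius Sampling cylinder radius, Angstrom (default 8).
#' @param bin_width Bin width, Angstrom (default 1).
#' @param bulk_density Optional fixed bulk density, nm^-3; when `NULL`
#'   (default) it is estimated as the mean density over the outermost
#'   `bulk_band` of z on each side.
#' @param bulk_band Width of each bulk-estimation band, Angstrom (default 5).
#' @param stride Use every `stride`-th frame (default 1; the error bars are
#'   standard deviations over the frames used).
#' @return A `DensityProfile` (`ProfileTable` with columns `mean_density`,
#'   `sd_density`, nm^-3) carrying attributes `bulk_density` (nm^-3),
#'   `sampling_area` (nm^2), `counts` (frames x bins matrix) and `n_frames`.
#' @export
water_density_profile <- function(trajectory, axis, z_range,
                                  cylinder_radius = 8, bin_width = 1,
                                  bulk_density = NULL, bulk_band = 5,
                                  stride = 1) {
  stopifnot(inherits(trajectory, "Trajectory"), inherits(axis, "PoreAxis"))
  if (cylinder_radius <= 0) stop("cylinder_radius must be positive")
  if (n_frames(trajectory) == 0) stop("trajectory has zero frames")
  wmask <- water_oxygen_mask(trajectory$topology)
  if (!any(wmask)) stop("no water oxygen atoms found in the topology")
  use <- seq(1, n_frames(trajectory), by = stride)
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  counts <- matrix(0L, length(use), nb)
  for (k in seq_along(use)) {
    ac <- axis_coordinates(
      trajectory$frames[[use[k]]][wmask, , drop = FALSE], axis)
    inside <- ac$r <= cylinder_radius
    bin <- findInterval(ac$z[inside], edges, rightmost.closed = TRUE)
    bin <- bin[bin >= 1 & bin <= nb]
    if (length(bin)) {
      tb <- tabulate(bin, nbins = nb)
      counts[k, ] <- tb
    }
  }
  # bin volume in nm^3 (1 A^3 = 1e-3 nm^3)
  vol_nm3 <- pi * cylinder_radius^2 * bin_width / 1000
  dens <- counts / vol_nm3
  mean_density <- colMeans(dens)
  sd_density <- apply(dens, 2, function(v) if (length(v) > 1) sd(v) else 0)
  if (is.null(bulk_density)) {
    band <- centers <= z_range[1] + bulk_band | centers >= z_range[2] - bulk_band
    bulk_density <- mean(mean_density[band])
    if (!is.finite(bulk_density) || bulk_density <= 0)
      stop("bulk density estimate failed; supply bulk_density explicitly")
  }
  out <- profile_table(z = centers, mean_density = mean_density,
                       sd_density = sd_density,
                       units = c(z = "Angstrom", mean_density = "nm^-3",
                                 sd_density = "nm^-3"),
                       reference = "raw")
  attr(out, "bulk_density") <- bulk_density
  attr(out, "sampling_area") <- pi * (cylinder_radius / 10)^2
  attr(out, "cylinder_radius") <- cylinder_radius
  attr(out, "counts") <- counts
  attr(out, "n_frames") <- length(use)
  class(out) <- c("DensityProfile", class(out))
  out
}

#' Hydration free-energy profile from a water density profile
#'
#' Boltzmann inversion of the density against bulk:
#' dG(z) = -kT ln(n(z)/n_bulk). Bins with zero observed density cannot be
#' inverted and are reported at a cap value with a flag. The first-order
#' error propagation gives err = kT * sd / mean.
#'
#' @param density A `DensityProfile` from [water_density_profile()].
#' @param temperature Temperature, kelvin (default 300).
#' @param cap Value assigned to zero-density bins, kJ/mol (default 25).
#' @param unit `"kJ/mol"` (default) or `"kcal/mol"`.
#' @return A `ProfileTable` with columns `dg`, `err`, `capped_flag`;
#'   reference `"bulk"`.
#' @export
hydration_free_energy <- function(density, temperature = 300, cap = 25,
                                  unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  if (temperature <= 0) stop("temperature must be positive")
  bulk <- attr(density, "bulk_density")
  if (is.null(bulk) || bulk <= 0) stop("density profile lacks a positive bulk_density")
  kt <- kT_kJmol(temperature)
  ratio <- density$mean_density / bulk
  capped <- ratio <= 0
  dg <- ifelse(capped, cap, -kt * log(pmax(ratio, 1e-300)))
  err <- ifelse(capped, NA_real_,
                kt * density$sd_density / pmax(density$mean_density, 1e-300))
  scale <- if (unit == "kcal/mol") KCAL_PER_KJ else 1
  out <- profile_table(z = density$z, dg = dg * scale, err = err * scale,
                       capped_flag = as.numeric(capped),
                       units = c(z = "Angstrom", dg = unit, err = unit,
                                 capped_flag = "boolean"),
                       reference = "bulk")
  attr(out, "temperature") <- temperature
  attr(out, "cap") <- cap * scale
  out
}

#' Per-frame wetted/dewetted classification at the gate
#'
#' Counts water oxygens in the gate window (inside the sampling cylinder)
#' frame by frame and calls a frame wet when the count reaches
#' `threshold_fraction` of the bulk-expected count for that volume.
#'
#' @param trajectory A `Trajectory` containing waters.
#' @param axis A `PoreAxis`.
#' @param gate_z_window Axial window `c(zmin, zmax)` of the gate, Angstrom.
#' @param cylinder_radius Sampling cylinder radius, Angstrom (default 8).
#' @param bulk_density Bulk water density, nm^-3 (default 33.4).
#' @param threshold_fraction Wet threshold as a fraction of the bulk-expected
#'   count (default 0.1).
#' @return A `WettingSeries`: data.frame with columns `frame`, `count`,
#'   `state` (`"wet"`/`"dry"`); attribute `n_transitions` counts state
#'   changes and `expected_bulk_count` records the threshold basis.
#' @export
classify_wetting <- function(trajectory, axis, gate_z_window,
                             cylinder_radius = 8, bulk_density = 33.4,
                             threshold_fraction = 0.1) {
  stopifnot(inherits(trajectory, "Trajectory"))
  if (gate_z_window[2] <= gate_z_window[1]) stop("empty gate window")
  wmask <- water_oxygen_mask(trajectory$topology)
  if (!any(wmask)) stop("no water oxygen atoms found in the topology")
  counts <- vapply(trajectory$frames, function(f) {
    ac <- axis_coordinates(f[wmask, , drop = FALSE], axis)
    sum(ac$r <= cylinder_radius & ac$z >= gate_z_window[1] &
          ac$z <= gate_z_window[2])
  }, numeric(1))
  vol_nm3 <- pi * cylinder_radius^2 * diff(gate_z_window) / 1000
  expected <- bulk_density * vol_nm3
  state <- ifelse(counts >= threshold_fraction * expected, "wet", "dry")
  out <- data.frame(frame = seq_along(counts), count = counts, state = state,
                    stringsAsFactors = FALSE)
  attr(out, "n_transitions") <- sum(state[-1] != state[-length(state)])
  attr(out, "expected_bulk_count") <- expected
  class(out) <- c("WettingSeries", "data.frame")
  out
}
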