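mk_profile <- function(z, dg) profile_table(z = z, dg = dg,
                                            units = c(z = "Angstrom",
                                                      dg = "kJ/mol"))

test_that("identical PMF windows average to themselves with zero error", {
  base <- mk_profile(seq(-20, 0), rep(c(0, 5), length.out = 21))
  avg <- average_pmf(replicate(10, base, simplify = FALSE))
  expect_equal(avg$dg, base$dg)
  expect_equal(avg$err, rep(0, 21))
})

test_that("two windows at 0 and 2 kJ/mol give mean 1 and SD 1", {
  z <- seq(-5, 5)
  avg <- average_pmf(list(mk_profile(z, rep(0, 11)), mk_profile(z, rep(2, 11))))
  expect_equal(avg$dg, rep(1, 11))
  expect_equal(avg$err, rep(1, 11))
  expect_error(average_pmf(list(mk_profile(z, rep(0, 11)),
                                mk_profile(z + 0.5, rep(0, 11)))), "grid")
  expect_error(average_pmf(list(mk_profile(z, rep(0, 11)))), "two")
})

test_that("window SDs of planted noise fall in the chi-square band", {
  z <- seq(-50, 50, by = 0.5)
  base <- mk_profile(z, 6 * exp(-(z + 10)^2 / 18))
  wins <- make_pmf_windows(base, n_windows = 10, noise_sd = 0.5, seed = 108)
  avg <- average_pmf(wins)
  # spec'd acceptance band for n = 10 draws of sd 0.5
  inside <- avg$err >= 0.25 & avg$err <= 0.9
  expect_gte(mean(inside), 0.95)
})

test_that("reference shifting zeroes the anchor and is idempotent", {
  z <- seq(-20, 0)
  p <- mk_profile(z, z^2 / 40 + 5)
  s1 <- shift_reference(p, "bilayer_center", anchor_z = 0)
  expect_equal(s1$dg[s1$z == 0], 0)
  expect_equal(s1$dg, p$dg - p$dg[p$z == 0])
  expect_identical(attr(s1, "reference"), "bilayer_center")
  s2 <- shift_reference(s1, "bilayer_center", anchor_z = 0)
  expect_equal(s2$dg, s1$dg)
  expect_error(shift_reference(p, "bulk", anchor_z = 50), "outside")
})

test_that("barrier height is shift-invariant and finds the gate maximum", {
  z <- seq(-30, 0)
  dg <- 18 * exp(-(z + 10)^2 / 8)
  p <- mk_profile(z, dg)
  b <- barrier_height(p, region_z = c(-16, -4))
  expect_equal(b$height_kJmol, 18, tolerance = 1e-6)
  expect_equal(b$z_at_max, -10)
  expect_equal(b$height_kcalmol, 18 / 4.184)
  shifted <- shift_reference(p, "bulk", anchor_z = -30)
  b2 <- barrier_height(shifted, region_z = c(-16, -4))
  expect_equal(b2$height_kJmol, b$height_kJmol, tolerance = 1e-12)
  # flat profile: zero barrier
  expect_equal(barrier_height(mk_profile(z, rep(2, 31)),
                              c(-16, -4))$height_kJmol, 0)
  # two equal maxima: the smaller z wins
  dg2 <- rep(0, 31); dg2[z == -20] <- 7; dg2[z == -5] <- 7
  b3 <- barrier_height(mk_profile(z, dg2), c(-25, 0))
  expect_equal(b3$z_at_max, -20)
  expect_error(barrier_height(p, c(10, 20)), "empty")
})

test_that("point-charge Coulomb energies match the closed form", {
  topo <- new_structure(data.frame(
    serial = 1:2, name = c("X", "NA"), element = c("C", "NA"),
    resname = c("GLY", "NA"), resno = c(1L, 2L), chain = c("A", "B"),
    x = c(0, 3), y = 0, z = 0))
  tr <- new_trajectory(topo, list(coords(topo)))
  lj0 <- data.frame(serial = 1:2, sigma = 0, epsilon = 0)
  tab <- residue_ion_interaction_energy(tr, list(chain = "A"),
                                        list(chain = "B"),
                                        charges = c("1" = -1, "2" = 1),
                                        lj_params = lj0)
  expect_equal(tab$mean_energy, -138.935 / 0.3, tolerance = 1e-9)
  # beyond the cutoff the interaction vanishes
  topo2 <- set_coords(topo, rbind(c(0, 0, 0), c(13, 0, 0)))
  tr2 <- new_trajectory(topo2, list(coords(topo2)))
  tab2 <- residue_ion_interaction_energy(tr2, list(chain = "A"),
                                         list(chain = "B"),
                                         charges = c("1" = -1, "2" = 1),
                                         lj_params = lj0, cutoff = 12)
  expect_equal(tab2$mean_energy, 0)
  # LJ vanishes exactly at r = sigma
  ljs <- data.frame(serial = 1:2, sigma = 0.3, epsilon = 1)
  tab3 <- residue_ion_interaction_energy(tr, list(chain = "A"),
                                         list(chain = "B"),
                                         charges = c("1" = 0, "2" = 0),
                                         lj_params = ljs)
  expect_equal(tab3$mean_energy, 0, tolerance = 1e-12)
  # missing parameters are reported by atom
  expect_error(residue_ion_interaction_energy(
    tr, list(chain = "A"), list(chain = "B"),
    charges = c("1" = -1), lj_params = lj0), "charge")
})

test_that("interaction energy is symmetric and additive over residues", {
  set.seed(109)
  n <- 6
  topo <- new_structure(data.frame(
    serial = 1:(n + 2), name = c(paste0("X", 1:n), "NA", "NA"),
    element = c(rep("C", n), "NA", "NA"),
    resname = c(rep("GLY", n), "NA", "NA"),
    resno = c(rep(1:3, each = 2), 10L, 11L),
    chain = c(rep("A", n), "B", "B"),
    x = c(runif(n, -4, 4), 1, -1), y = c(runif(n, -4, 4), 0, 1),
    z = c(runif(n, -4, 4), 0.5, -0.5)))
  tr <- new_trajectory(topo, list(coords(topo), coords(topo) + 0.2))
  q <- setNames(runif(n + 2, -1, 1), as.character(1:(n + 2)))
  lj <- data.frame(serial = 1:(n + 2), sigma = runif(n + 2, 0.2, 0.35),
                   epsilon = runif(n + 2, 0.1, 1))
  ab <- residue_ion_interaction_energy(tr, list(chain = "A"),
                                       list(chain = "B"), q, lj)
  ba <- residue_ion_interaction_energy(tr, list(chain = "B"),
                                       list(chain = "A"), q, lj)
  expect_equal(sum(ab$mean_energy), sum(ba$mean_energy), tolerance = 1e-9)
  # additivity over disjoint residue selections
  parts <- lapply(1:3, function(r)
    residue_ion_interaction_energy(tr, list(chain = "A", resid = r),
                                   list(chain = "B"), q, lj))
  expect_equal(sum(vapply(parts, function(p) sum(p$mean_energy),
                          numeric(1))),
               sum(ab$mean_energy), tolerance = 1e-9)
})

test_that("translated pose sets cluster by single linkage at the cutoff", {
  lig <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))  # Angstrom
  shift_nm <- function(d) sweep(lig, 2, c(d * 10, 0, 0), "+")
  # centroids at 0.00, 0.05, 0.50 nm: {1,2}, {3}
  cs <- cluster_poses(list(shift_nm(0), shift_nm(0.05), shift_nm(0.5)),
                      cutoff = 0.1)
  expect_equal(cs$clusters, list(c(1L, 2L), 3L))
  # chain 0.00, 0.08, 0.16: one cluster by transitivity
  cs2 <- cluster_poses(list(shift_nm(0), shift_nm(0.08), shift_nm(0.16)),
                       cutoff = 0.1)
  expect_equal(length(cs2$clusters), 1)
  # all identical: one cluster, representative frame 1
  cs3 <- cluster_poses(list(lig, lig, lig), cutoff = 0.1)
  expect_equal(cs3$representative, 1L)
  expect_error(cluster_poses(list(), 0.1), "empty")
})

test_that("clustering equals independent connected components on 200 frames", {
  skip_if_not_installed("igraph")
  frames <- poregate:::with_seed(110, {
    lig <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5))
    lapply(1:200, function(i)
      sweep(lig, 2, rnorm(3, sd = 0.6), "+"))  # Angstrom, sd 0.06 nm
  })
  cs <- cluster_poses(frames, cutoff = 0.1)
  n <- length(frames)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    adj[i, j] <- adj[j, i] <-
      sqrt(mean(rowSums((frames[[i]] - frames[[j]])^2))) / 10 < 0.1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ref <- igraph::components(g)$membership
  expect_identical(partition_canonical(cs$membership),
                   partition_canonical(ref))
})

test_that("planted pose ensembles are recovered exactly", {
  fr <- make_pose_ensemble(list(c(0, 0, 0), c(1, 0, 0)), c(5, 3),
                           spread_nm = 0.02, seed = 111)
  cs <- cluster_poses(fr, cutoff = 0.1, input_unit = "nm")
  expect_equal(cs$sizes, c(5L, 3L))
  expect_identical(partition_canonical(cs$membership),
                   partition_canonical(attr(fr, "planted_membership")))
  # single centroid: one cluster
  fr1 <- make_pose_ensemble(list(c(0, 0, 0)), 4, 0.02, seed = 112)
  expect_equal(length(cluster_poses(fr1, 0.1,
                                    input_unit = "nm")$clusters), 1)
})

test_that("Henderson-Hasselbalch fractions match the closed form", {
  flec <- ionization_fraction(9.3, 7.4, "base")
  expect_equal(flec$charged_fraction, 1 / (1 + 10^(7.4 - 9.3)),
               tolerance = 1e-12)
  expect_equal(round(100 * flec$charged_fraction), 99)
  expect_equal(ionization_fraction(7.4, 7.4, "base")$charged_fraction, 0.5)
  lido <- ionization_fraction(7.56, 7.4, "base")
  expect_equal(lido$charged_fraction, 0.591, tolerance = 5e-4)
  # charged + neutral = 1; monotone in pKa
  pkas <- seq(4, 10, by = 0.5)
  fr <- vapply(pkas, function(p)
    ionization_fraction(p, 7.4, "base")$charged_fraction, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(fr + vapply(pkas, function(p)
    ionization_fraction(p, 7.4, "base")$neutral_fraction, numeric(1)),
    rep(1, length(pkas)))
  # acids mirror bases
  expect_equal(ionization_fraction(4.5, 7.4, "acid")$charged_fraction,
               1 / (1 + 10^(4.5 - 7.4)))
})

test_that("log(P) converts to partition free energy via -ln10 RT logP", {
  expect_equal(logp_to_dg(1.49, 298), -8.5, tolerance = 0.05)
  expect_equal(logp_to_dg(0, 310), 0)
  expect_equal(logp_to_dg(1, 298.15), -5.708, tolerance = 1e-3)
  expect_error(logp_to_dg(1, -5), "temperature")
})
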