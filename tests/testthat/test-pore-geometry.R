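test_that("the fitted axis of a z-built bundle is (0,0,1)", {
  ch <- make_toy_channel(helix_length = 16, bundle_radius = 12,
                         gate_radius = 4.3, gate_ring_position = 8)
  ax <- fit_pore_axis(ch, toy_subunit_selections())
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-6)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
})

test_that("axis fitting is equivariant under rigid rotation", {
  ch <- make_toy_channel(helix_length = 16, bundle_radius = 12,
                         gate_radius = 4.3, gate_ring_position = 8)
  rot <- poregate:::rotation_matrix(c(1, 0, 0), 30 * pi / 180)
  moved <- set_coords(ch, coords(ch) %*% t(rot))
  ax <- fit_pore_axis(moved, toy_subunit_selections())
  expect_lt(max(abs(ax$direction - as.numeric(rot %*% c(0, 0, 1)))), 1e-6)
})

test_that("axis fitting rejects bad subunit sets and degenerate geometry", {
  ch <- make_toy_channel(helix_length = 16, bundle_radius = 12,
                         gate_radius = 4.3, gate_ring_position = 8)
  expect_error(fit_pore_axis(ch, toy_subunit_selections()[1:3]), "four")
  sels <- toy_subunit_selections()
  sels[[1]] <- list(chain = "A", name = "CA")
  expect_error(fit_pore_axis(ch, sels), "unequal")
  # a flat square ring has no principal axis
  ring <- new_structure(data.frame(
    serial = 1:8, name = "CA", element = "C", resname = "ALA",
    resno = rep(1:2, 4), chain = rep(c("A", "B", "C", "D"), each = 2),
    x = c(10, 11, -10, -11, -10, -11, 10, 11),
    y = c(10, 11, 10, 11, -10, -11, -10, -11), z = 0))
  expect_error(fit_pore_axis(ring, toy_subunit_selections()), "degenerate")
})

test_that("an analytic cylinder of atoms gives radius minus vdW exactly", {
  # carbon atoms (vdW 1.70) on a ring of radius 6.0 at many z levels:
  # pore radius 4.3 everywhere, SD 0 over two identical frames
  zs <- seq(-5, 5, by = 1)
  ring <- expand.grid(th = seq(0, 2 * pi, length.out = 13)[-13], z = zs)
  atoms <- data.frame(
    serial = seq_len(nrow(ring)), name = "C1", element = "C",
    resname = "CYL", resno = seq_len(nrow(ring)), chain = "A",
    x = 6 * cos(ring$th), y = 6 * sin(ring$th), z = ring$z)
  s <- new_structure(atoms)
  tr <- new_trajectory(s, list(coords(s), coords(s)))
  rp <- radius_profile(tr, pore_axis(), z_range = c(-5, 5), bin_width = 1)
  expect_equal(rp$mean_radius, rep(4.3, nrow(rp)), tolerance = 1e-12)
  expect_equal(rp$sd_radius, rep(0, nrow(rp)))
  expect_equal(rp$min_radius, rp$max_radius)
  expect_false(any(rp$empty_flag))
})

test_that("frames with alternating cylinder radii aggregate correctly", {
  mk <- function(r) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    ring <- expand.grid(th = th, z = seq(-3, 3, by = 1))
    cbind(r * cos(ring$th), r * sin(ring$th), ring$z)
  }
  topo <- new_structure(data.frame(
    serial = seq_len(nrow(mk(6))), name = "C1", element = "C",
    resname = "CYL", resno = seq_len(nrow(mk(6))), chain = "A",
    x = mk(6)[, 1], y = mk(6)[, 2], z = mk(6)[, 3]))
  tr <- new_trajectory(topo, list(mk(6), mk(8)))
  rp <- radius_profile(tr, pore_axis(), z_range = c(-3, 3), bin_width = 1)
  expect_equal(rp$mean_radius, rep(5.3, nrow(rp)), tolerance = 1e-12)
  expect_equal(rp$min_radius, rep(4.3, nrow(rp)), tolerance = 1e-12)
  expect_equal(rp$max_radius, rep(6.3, nrow(rp)), tolerance = 1e-12)
})

test_that("empty slabs are capped at the probe radius and flagged", {
  s <- new_structure(data.frame(
    serial = 1:4, name = "C1", element = "C", resname = "X", resno = 1:4,
    chain = "A", x = c(6, -6, 0, 0), y = c(0, 0, 6, -6), z = 0))
  rp <- radius_profile(s, pore_axis(), z_range = c(-1, 3), bin_width = 1)
  expect_true(any(rp$empty_flag))
  expect_equal(rp$mean_radius[rp$empty_flag], rep(10, sum(rp$empty_flag)))
})

test_that("radius_profile equals a brute-force per-bin minimum", {
  ch <- make_toy_channel(helix_length = 14, bundle_radius = 11,
                         gate_radius = 3.0, gate_ring_position = 7)
  ax <- pore_axis()
  z_range <- c(-8, 8); bw <- 1
  rp <- radius_profile(ch, ax, z_range, bw)
  xyz <- coords(ch)
  vdw <- vdw_radius(ch$atoms$element)
  centers <- rp$z
  for (k in seq_along(centers)) {
    lo <- centers[k] - bw / 2; hi <- centers[k] + bw / 2
    vals <- c()
    for (i in seq_len(nrow(xyz))) {
      if (xyz[i, 3] >= lo && xyz[i, 3] < hi ||
          (k == length(centers) && xyz[i, 3] == hi))
        vals <- c(vals, max(sqrt(xyz[i, 1]^2 + xyz[i, 2]^2) - vdw[i], 0))
    }
    expected <- if (length(vals)) min(vals) else 10
    expect_equal(rp$mean_radius[k], expected, tolerance = 1e-12,
                 info = paste("bin", k))
  }
})

test_that("pore-lining detection returns the inward gate ring", {
  ch <- make_toy_channel(helix_length = 20, bundle_radius = 12,
                         gate_radius = 4.3, gate_ring_position = 10,
                         first_resno = 201)
  ax <- fit_pore_axis(ch, toy_subunit_selections())
  gate_z <- ch$atoms$z[ch$atoms$name == "CG"][1]
  lin <- pore_lining_residues(ch, ax, gate_z + c(-1.5, 1.5), cutoff = 6.5)
  expect_equal(nrow(lin), 4)
  expect_true(all(lin$resno == 210))
  expect_setequal(lin$chain, c("A", "B", "C", "D"))
  # outside the structure, and with a zero cutoff: nothing
  expect_equal(nrow(pore_lining_residues(ch, ax, c(90, 100))), 0)
  expect_equal(nrow(pore_lining_residues(ch, ax, gate_z + c(-1.5, 1.5),
                                         cutoff = 0)), 0)
})

test_that("the hand-built pore-facing case gives (2, 0)", {
  atoms <- data.frame(serial = 1:3, name = c("CA", "CB", "CG"),
                      element = "C", resname = "ASN", resno = 212L,
                      chain = "A", x = c(10, 9, 8), y = 0, z = c(0, 0.5, 0))
  s <- new_structure(atoms)
  op <- residue_orientation(s, pore_axis(), "A", 212)
  expect_equal(op$x, 2.0, tolerance = 1e-12)
  expect_equal(op$y, 0.0, tolerance = 1e-12)
  # pointing away mirrors the x component
  s2 <- s
  s2$atoms$x[s2$atoms$name == "CG"] <- 12
  op2 <- residue_orientation(s2, pore_axis(), "A", 212)
  expect_equal(op2$x, -2.0, tolerance = 1e-12)
  expect_equal(op2$y, 0.0, tolerance = 1e-12)
})

test_that("residue orientation is invariant under rigid motion of the system", {
  ch <- make_toy_channel(helix_length = 20, bundle_radius = 12,
                         gate_radius = 4.3, gate_ring_position = 10,
                         first_resno = 201)
  ax <- fit_pore_axis(ch, toy_subunit_selections())
  base <- residue_orientation(ch, ax, "A", 210)
  for (seed in c(7, 17, 27)) {
    tf <- random_rigid_transform(seed)
    moved <- transform_structure(ch, tf)
    ax2 <- list(origin = as.numeric(apply_rigid(rbind(ax$origin), tf)),
                direction = as.numeric(tf$rot %*% ax$direction))
    class(ax2) <- "PoreAxis"
    op <- residue_orientation(moved, ax2, "A", 210)
    expect_equal(op$x, base$x, tolerance = 1e-9)
    expect_equal(op$y, base$y, tolerance = 1e-9)
  }
  # translation along the axis leaves the orientation unchanged
  shifted <- set_coords(ch, sweep(coords(ch), 2, c(0, 0, 14), "+"))
  op <- residue_orientation(shifted, ax, "A", 210)
  expect_equal(op$x, base$x, tolerance = 1e-9)
  expect_equal(op$y, base$y, tolerance = 1e-9)
})

test_that("inward and outward gate rings give opposite orientation signs", {
  for (inward in c(TRUE, FALSE)) {
    ch <- make_toy_channel(helix_length = 20, bundle_radius = 12,
                           gate_radius = 4.3, gate_ring_position = 10,
                           inward = inward, first_resno = 201)
    ax <- fit_pore_axis(ch, toy_subunit_selections())
    xs <- vapply(c("A", "B", "C", "D"), function(c)
      residue_orientation(ch, ax, c, 210)$x, numeric(1))
    if (inward) expect_true(all(xs > 0)) else expect_true(all(xs < 0))
  }
})

test_that("orientation errors on missing atoms and on-axis CA", {
  atoms <- data.frame(serial = 1:2, name = c("CA", "CG"), element = "C",
                      resname = "ASN", resno = 1L, chain = "A",
                      x = c(0, 1), y = 0, z = c(5, 5))
  s <- new_structure(atoms)
  expect_error(residue_orientation(s, pore_axis(), "A", 1), "axis")
  atoms2 <- data.frame(serial = 1, name = "CA", element = "C",
                       resname = "ASN", resno = 1L, chain = "A",
                       x = 10, y = 0, z = 0)
  expect_error(residue_orientation(new_structure(atoms2), pore_axis(),
                                   "A", 1), "CG")
})
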