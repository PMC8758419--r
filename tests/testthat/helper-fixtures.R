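# Shared fixture builders; everything is generated in code at test time.

# Minimal one-line PDB with a single atom at (1, 2, 3).
one_atom_pdb <- function() {
  paste0("ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
         "  1.00  0.00           C")
}

# Random rigid-body transform (rotation + translation), deterministic per seed.
random_rigid_transform <- function(seed) {
  poregate:::with_seed(seed, {
    ax <- stats::rnorm(3)
    th <- stats::runif(1, 0, 2 * pi)
    list(rot = poregate:::rotation_matrix(ax, th),
         trans = stats::rnorm(3, sd = 20))
  })
}

apply_rigid <- function(xyz, tf) {
  sweep(xyz %*% t(tf$rot), 2, tf$trans, "+")
}

transform_structure <- function(structure, tf) {
  set_coords(structure, apply_rigid(coords(structure), tf))
}

# Four per-chain selections for the toy channel.
toy_subunit_selections <- function() lapply(c("A", "B", "C", "D"),
                                            function(ch) list(chain = ch))

# Brute-force all-pairs DSSP hydrogen-bond search: for every amide donor,
# score every carbonyl acceptor at sequence separation >= 2 and keep the
# minimum-energy acceptor below the threshold. Independent of the package's
# bookkeeping (plain loops over a coordinate lookup).
brute_force_hbonds <- function(structure, cutoff = -0.5) {
  s <- reconstruct_amide_hydrogens(structure)
  a <- s$atoms
  res <- unique(a[order(a$chain, a$resno), c("chain", "resno")])
  get <- function(ch, r, nm) {
    row <- a[a$chain == ch & a$resno == r & a$name == nm, ]
    if (nrow(row) != 1) return(NULL)
    as.numeric(row[, c("x", "y", "z")])
  }
  out <- NULL
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rd <- res$resno[i]
    n <- get(ch, rd, "N"); h <- get(ch, rd, "H")
    if (is.null(n) || is.null(h)) next
    best_e <- Inf; best_acc <- NA
    for (j in seq_len(nrow(res))) {
      if (res$chain[j] != ch) next
      ra <- res$resno[j]
      if (abs(rd - ra) < 2) next
      cc <- get(ch, ra, "C"); o <- get(ch, ra, "O")
      if (is.null(cc) || is.null(o)) next
      r_on <- sqrt(sum((o - n)^2)); r_ch <- sqrt(sum((cc - h)^2))
      r_oh <- sqrt(sum((o - h)^2)); r_cn <- sqrt(sum((cc - n)^2))
      e <- if (min(r_on, r_ch, r_oh, r_cn) < 0.5) -9.9 else
        27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      if (e < cutoff && (e < best_e - 1e-12 ||
                         (abs(e - best_e) <= 1e-12 &&
                          abs(rd - ra) < abs(rd - best_acc))))
        { best_e <- e; best_acc <- ra }
    }
    if (is.finite(best_e))
      out <- rbind(out, data.frame(chain = ch, donor_resno = rd,
                                   acceptor_resno = best_acc,
                                   offset = rd - best_acc, energy = best_e))
  }
  out
}

# Canonical form of a partition of 1..n for comparisons.
partition_canonical <- function(membership) {
  unname(split(seq_along(membership), membership)[
    order(vapply(split(seq_along(membership), membership), min, integer(1)))])
}
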