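# Backbone hydrogen-bond detection and helical-pattern classification.
#
# The pi-helix (i+5 -> i backbone hydrogen bonds) carries one extra residue
# per turn relative to the alpha-helix (i+4 -> i); detecting the switch, and
# the helical defect (unpaired carbonyls) at the register boundary, is how
# pore models are annotated as alpha- or pi-helical at the gate.

DSSP_Q1Q2F <- 27.888  # 0.084 e^2 * 332 kcal A / (mol e^2), DSSP's constant

atom_xyz <- function(atoms, chain, resno, name) {
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$name == name
  if (sum(sel) != 1) return(NULL)
  as.numeric(atoms[sel, c("x", "y", "z")])
}

dssp_energy <- function(n, h, c, o) {
  r_on <- vec_norm(o - n); r_ch <- vec_norm(c - h)
  r_oh <- vec_norm(o - h); r_cn <- vec_norm(c - n)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-9.9)  # DSSP clash floor
  DSSP_Q1Q2F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

hbond_angle <- function(d, h, a) {
  v1 <- unit(d - h); v2 <- unit(a - h)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

#' Detect backbone hydrogen bonds
#'
#' Pairs each backbone amide donor (N-H) with its best-scoring carbonyl
#' acceptor (C=O) within the same chain, reporting the sequence offset
#' (donor residue number minus acceptor residue number). Amide hydrogens are
#' reconstructed geometrically when absent. Two criteria are available:
#'
#' * `"dssp"` (default): the DSSP electrostatic model
#'   E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol,
#'   accepting bonds with E below `energy_cutoff` (-0.5 kcal/mol).
#' * `"geom"`: donor-acceptor N...O distance at most `dist_cutoff` (3.5 A)
#'   and N-H...O angle at least `angle_min` (120 deg); the reported score is
#'   the N...O distance.
#'
#' A donor with both an i+4 and an i+5 acceptor below threshold keeps the
#' better-scoring one; exact ties go to the smaller offset.
#'
#' @param structure A `Structure`.
#' @param selection Optional selection (string or list, see [atom_mask()])
#'   restricting the residues considered.
#' @param criterion `"dssp"` or `"geom"`.
#' @param energy_cutoff DSSP acceptance threshold, kcal/mol.
#' @param dist_cutoff Geometric donor-acceptor cutoff, Angstrom.
#' @param angle_min Geometric D-H...A angle minimum, degrees.
#' @param min_offset Smallest |donor - acceptor| sequence separation
#'   considered (default 2; intra-helical bonds).
#' @return data.frame with columns `chain`, `donor_resno`, `acceptor_resno`,
#'   `offset`, `energy` (kcal/mol for dssp; N...O distance for geom).
#' @export
detect_backbone_hbonds <- function(structure, selection = NULL,
                                   criterion = c("dssp", "geom"),
                                   energy_cutoff = -0.5, dist_cutoff = 3.5,
                                   angle_min = 120, min_offset = 2) {
  criterion <- match.arg(criterion)
  s <- if (is.null(selection)) structure else
    subset_structure(structure, selection)
  s <- reconstruct_amide_hydrogens(s)
  a <- s$atoms
  res <- residue_table(s)
  out <- list()
  for (ch in unique(res$chain)) {
    rr <- res$resno[res$chain == ch]
    geom <- lapply(rr, function(r) list(
      N = atom_xyz(a, ch, r, "N"), H = atom_xyz(a, ch, r, "H"),
      C = atom_xyz(a, ch, r, "C"), O = atom_xyz(a, ch, r, "O")))
    names(geom) <- as.character(rr)
    incomplete <- vapply(geom, function(g)
      is.null(g$N) || is.null(g$C) || is.null(g$O), logical(1))
    if (any(incomplete))
      warning("chain ", ch, ": skipping residue(s) with missing backbone ",
              "atoms: ", paste(rr[incomplete], collapse = ", "))
    for (i in seq_along(rr)) {
      gd <- geom[[i]]
      if (is.null(gd$N) || is.null(gd$H)) next  # not a usable donor
      best <- NULL
      for (j in seq_along(rr)) {
        off <- rr[i] - rr[j]
        if (abs(off) < min_offset) next
        ga <- geom[[j]]
        if (is.null(ga$C) || is.null(ga$O)) next
        if (criterion == "dssp") {
          e <- dssp_energy(gd$N, gd$H, ga$C, ga$O)
          ok <- e < energy_cutoff
        } else {
          e <- vec_norm(ga$O - gd$N)
          ok <- e <= dist_cutoff &&
            hbond_angle(gd$N, gd$H, ga$O) >= angle_min
        }
        if (!ok) next
        if (is.null(best) || e < best$e - 1e-12 ||
            (abs(e - best$e) <= 1e-12 && abs(off) < abs(best$off)))
          best <- list(e = e, off = off, acc = rr[j])
      }
      if (!is.null(best))
        out[[length(out) + 1]] <- data.frame(
          chain = ch, donor_resno = rr[i], acceptor_resno = best$acc,
          offset = best$off, energy = best$e, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), donor_resno = integer(),
                      acceptor_resno = integer(), offset = integer(),
                      energy = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify helical hydrogen-bond patterns
#'
#' Assigns each residue of a segment one of `pi`, `alpha`, `three_ten`,
#' `defect`, or `none` from a backbone hydrogen-bond list:
#'
#' * `pi` if the residue donates or accepts an i+5 -> i bond,
#' * otherwise `alpha` for i+4 -> i, `three_ten` for i+3 -> i,
#' * `defect` if it participates in no helical bond although an i+4 partner
#'   position exists inside the segment (the expected bond is absent with no
#'   i+5 replacement),
#' * `none` for non-participating terminal residues.
#'
#' A lone missing i+4 bond is a defect, not pi: the pi label requires an
#' actual i+5 bond.
#'
#' @param hbonds data.frame from [detect_backbone_hbonds()] computed over the
#'   segment.
#' @param chain Chain id of the segment.
#' @param segment Integer range `c(first, last)` of residue numbers.
#' @return A `HelixAnnotation`: list with `labels` (data.frame `chain`,
#'   `resno`, `label`), `unpaired_carbonyls` (residue numbers whose carbonyl
#'   accepts nothing although a donor position exists), and `defect_segments`
#'   (data.frame `start`, `end`; maximal runs of `defect`).
#' @export
classify_helix_pattern <- function(hbonds, chain, segment) {
  if (length(segment) != 2 || segment[1] > segment[2])
    stop("segment must be c(first, last) with first <= last")
  rr <- seq(segment[1], segment[2])
  if (!length(rr)) stop("empty segment")
  hb <- hbonds[hbonds$chain == chain, , drop = FALSE]
  lab <- character(length(rr))
  donated <- lapply(rr, function(r) hb$offset[hb$donor_resno == r])
  accepted <- lapply(rr, function(r) hb$offset[hb$acceptor_resno == r])
  for (i in seq_along(rr)) {
    offs <- c(donated[[i]], accepted[[i]])
    offs <- offs[offs >= 3 & offs <= 5]
    r <- rr[i]
    if (5 %in% offs) lab[i] <- "pi"
    else if (4 %in% offs) lab[i] <- "alpha"
    else if (3 %in% offs) lab[i] <- "three_ten"
    else {
      expected <- (r - 4 >= segment[1]) || (r + 4 <= segment[2])
      lab[i] <- if (expected) "defect" else "none"
    }
  }
  unpaired <- rr[vapply(seq_along(rr), function(i)
    length(accepted[[i]]) == 0 && rr[i] + 4 <= segment[2], logical(1))]
  runs <- rle(lab == "defect")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  def <- which(runs$values)
  defect_segments <- data.frame(start = rr[starts[def]], end = rr[ends[def]])
  out <- list(labels = data.frame(chain = chain, resno = rr, label = lab,
                                  stringsAsFactors = FALSE),
              unpaired_carbonyls = unpaired,
              defect_segments = defect_segments)
  class(out) <- "HelixAnnotation"
  out
}

#' @export
print.HelixAnnotation <- function(x, ...) {
  tab <- table(factor(x$labels$label,
                      levels = c("alpha", "pi", "three_ten", "defect", "none")))
  cat("HelixAnnotation:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  if (nrow(x$defect_segments))
    cat("defect segments:",
        paste(x$defect_segments$start, x$defect_segments$end, sep = "-",
              collapse = ", "), "\n")
  invisible(x)
}

#' Detect sidechain-to-backbone hydrogen bonds of an asparagine
#'
#' Searches for hydrogen bonds between the sidechain amide of an asparagine
#' (ND2 as donor to backbone carbonyl O; OD1 as acceptor from backbone N-H)
#' and the backbone of other residues in the same chain, reporting partners
#' with their sequence offsets (partner residue number minus the asparagine's;
#' the conserved-Asn interaction with the backbone four positions below is
#' offset -4).
#'
#' @param structure A `Structure`.
#' @param chain Chain id of the asparagine.
#' @param resno Residue number of the asparagine.
#' @param dist_cutoff Heavy-atom donor-acceptor cutoff, Angstrom (3.5).
#' @param angle_min D-H...A angle minimum, degrees, applied when the hydrogen
#'   is present in the structure (120).
#' @return data.frame with columns `partner_resno`, `offset`, `distance`,
#'   `role` (`"sidechain_donor"` or `"sidechain_acceptor"`); zero rows when
#'   no partner satisfies the criterion.
#' @export
detect_asn_sidechain_hbond <- function(structure, chain, resno,
                                       dist_cutoff = 3.5, angle_min = 120) {
  a <- structure$atoms
  nd2 <- atom_xyz(a, chain, resno, "ND2")
  od1 <- atom_xyz(a, chain, resno, "OD1")
  if (is.null(nd2) || is.null(od1))
    stop("residue ", chain, ":", resno,
         " lacks sidechain amide atoms ND2/OD1 (not an asparagine?)")
  hd <- a[a$chain == chain & a$resno == resno &
            a$name %in% c("HD21", "HD22"), c("x", "y", "z")]
  others <- residue_table(structure)
  others <- others[others$chain == chain & others$resno != resno, ,
                   drop = FALSE]
  hits <- list()
  for (r in others$resno) {
    # ND2 donating to the partner's carbonyl O
    o <- atom_xyz(a, chain, r, "O")
    if (!is.null(o) && vec_norm(o - nd2) <= dist_cutoff) {
      ok <- TRUE
      if (nrow(hd)) {
        angs <- apply(as.matrix(hd), 1, function(h)
          hbond_angle(nd2, as.numeric(h), o))
        ok <- any(angs >= angle_min)
      }
      if (ok)
        hits[[length(hits) + 1]] <- data.frame(
          partner_resno = r, offset = r - resno,
          distance = vec_norm(o - nd2), role = "sidechain_donor",
          stringsAsFactors = FALSE)
    }
    # partner's amide donating to OD1
    n <- atom_xyz(a, chain, r, "N")
    h <- atom_xyz(a, chain, r, "H")
    if (!is.null(n) && vec_norm(od1 - n) <= dist_cutoff) {
      ok <- if (!is.null(h)) hbond_angle(n, h, od1) >= angle_min else TRUE
      if (ok)
        hits[[length(hits) + 1]] <- data.frame(
          partner_resno = r, offset = r - resno,
          distance = vec_norm(od1 - n), role = "sidechain_acceptor",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(partner_resno = integer(), offset = integer(),
                      distance = numeric(), role = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
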