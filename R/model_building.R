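# Register-shift (pi-helix) model construction: a gapped template/target
# alignment that shifts the target sequence one position upstream across a
# helix segment, and deterministic backbone threading of the target onto the
# template coordinates. Inserting the pi-turn this way rotates every
# downstream sidechain by ~100 degrees about the helix axis, which is what
# reorients the conserved asparagine toward the pore.

#' Describe a one-position upstream register shift
#'
#' @param chain_id Chain the shift applies to.
#' @param shift_start First shifted residue number (the residue left over the
#'   template gap; e.g. Thr-207 in NavMs numbering).
#' @param shift_end Last shifted residue number (the inner end of the helix;
#'   e.g. Thr-234).
#' @return A `RegisterShift` list.
#' @export
register_shift <- function(chain_id, shift_start, shift_end) {
  if (shift_start > shift_end)
    stop("shift_start must not exceed shift_end")
  out <- list(chain_id = chain_id, shift_start = as.integer(shift_start),
              shift_end = as.integer(shift_end),
              direction = "one position upstream")
  class(out) <- "RegisterShift"
  out
}

#' Build the gapped register-shift alignment
#'
#' One gap is introduced in the template row immediately before the first
#' shifted residue, and one in the target row immediately after the last
#' shifted residue. Inside the region every target residue k then pairs with
#' template residue k-1 (the one-position upstream shift); the target's
#' first shifted residue sits over the template gap, the template's last
#' shifted residue over the target gap, and both flanks stay
#' identity-aligned.
#'
#' @param sequence Character vector of one-letter residue codes, named by
#'   residue number (names optional: numbering then starts at
#'   `first_resno`).
#' @param shift A `RegisterShift`.
#' @param first_resno Residue number of the first sequence position when
#'   `sequence` is unnamed (default 1).
#' @return A `PairwiseAlignment`: list with `template_row`, `target_row`
#'   (gapped strings), and `column_map` (data.frame `template_resno`,
#'   `target_resno`, NA at gaps).
#' @export
build_shift_alignment <- function(sequence, shift, first_resno = 1) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  resno <- if (!is.null(names(sequence))) as.integer(names(sequence))
  else seq(first_resno, length.out = length(sequence))
  if (any(diff(resno) != 1)) stop("sequence numbering must be contiguous")
  k <- match(shift$shift_start, resno)
  m <- match(shift$shift_end, resno)
  if (is.na(k) || is.na(m))
    stop("shift residues ", shift$shift_start, "-", shift$shift_end,
         " not found in the sequence numbering")
  if (k == 1)
    stop("shift_start is the first residue of the chain: ",
         "no upstream position to shift onto")
  n <- length(sequence)
  # template: gap immediately before shift_start
  template <- c(sequence[seq_len(k - 1)], "-", sequence[k:n])
  template_resno <- c(resno[seq_len(k - 1)], NA, resno[k:n])
  # target: gap immediately after shift_end
  target <- c(sequence[seq_len(m)], "-",
              if (m < n) sequence[(m + 1):n] else character(0))
  target_resno <- c(resno[seq_len(m)], NA,
                    if (m < n) resno[(m + 1):n] else integer(0))
  stopifnot(length(template) == length(target))
  out <- list(template_row = paste(template, collapse = ""),
              target_row = paste(target, collapse = ""),
              column_map = data.frame(template_resno = template_resno,
                                      target_resno = target_resno),
              shift = shift)
  class(out) <- "PairwiseAlignment"
  out
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat("PairwiseAlignment (register shift ", x$shift$shift_start, "-",
      x$shift$shift_end, "):\n", sep = "")
  cat("  template: ", x$template_row, "\n  target:   ", x$target_row, "\n",
      sep = "")
  invisible(x)
}

#' Write a pairwise alignment as FASTA
#' @param alignment A `PairwiseAlignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_fasta <- function(alignment, path) {
  writeLines(c(">template", alignment$template_row,
               ">target", alignment$target_row), path)
  invisible(path)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Thread target backbone coordinates onto a template
#'
#' Deterministic stand-in for restraint-based homology modelling: every
#' aligned target residue receives its template partner's backbone
#' (N, CA, C, O) coordinates verbatim; the gap-bridged target residue (the
#' one over the template gap) receives backbone positions linearly
#' interpolated between its threaded neighbours and is flagged
#' low-confidence. Sidechains beyond the backbone are not built. No energy
#' refinement is applied.
#'
#' @param template A `Structure` holding backbone atoms for every aligned
#'   template residue of the shift chain.
#' @param alignment A `PairwiseAlignment` from [build_shift_alignment()].
#' @param chain_id Chain to thread (default: the alignment's shift chain).
#' @return A `Structure` with the target chain's backbone; column
#'   `low_confidence` marks interpolated residues. An attribute
#'   `register_shift` records the applied shift.
#' @export
thread_backbone <- function(template, alignment,
                            chain_id = alignment$shift$chain_id) {
  cm <- alignment$column_map
  a <- template$atoms
  get_bb <- function(resno) {
    rows <- lapply(BACKBONE_NAMES, function(nm)
      atom_xyz(a, chain_id, resno, nm))
    if (any(vapply(rows, is.null, logical(1))))
      stop("template residue ", chain_id, ":", resno,
           " lacks backbone atoms")
    do.call(rbind, rows)
  }
  paired <- cm[!is.na(cm$target_resno), , drop = FALSE]
  coords_by_target <- list()
  flag <- logical(0)
  for (i in seq_len(nrow(paired))) {
    tr <- paired$target_resno[i]
    tp <- paired$template_resno[i]
    if (!is.na(tp)) {
      coords_by_target[[as.character(tr)]] <- get_bb(tp)
      flag[as.character(tr)] <- FALSE
    }
  }
  bridged <- paired$target_resno[is.na(paired$template_resno)]
  for (tr in bridged) {
    lo <- as.character(tr - 1); hi <- as.character(tr + 1)
    if (is.null(coords_by_target[[lo]]) || is.null(coords_by_target[[hi]]))
      stop("gap-bridged residue ", tr, " lacks threaded flanking residues")
    coords_by_target[[as.character(tr)]] <-
      (coords_by_target[[lo]] + coords_by_target[[hi]]) / 2
    flag[as.character(tr)] <- TRUE
  }
  trs <- sort(as.integer(names(coords_by_target)))
  seqchars <- strsplit(gsub("-", "", alignment$target_row), "")[[1]]
  target_resnos <- cm$target_resno[!is.na(cm$target_resno)]
  resname_of <- setNames(aa_three(seqchars), as.character(target_resnos))
  rows <- list()
  serial <- 1L
  for (tr in trs) {
    bb <- coords_by_target[[as.character(tr)]]
    for (j in seq_along(BACKBONE_NAMES)) {
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = BACKBONE_NAMES[j],
        element = substr(BACKBONE_NAMES[j], 1, 1),
        resname = resname_of[[as.character(tr)]], resno = tr,
        chain = chain_id, x = bb[j, 1], y = bb[j, 2], z = bb[j, 3],
        low_confidence = flag[[as.character(tr)]],
        stringsAsFactors = FALSE)
      serial <- serial + 1L
    }
  }
  out <- new_structure(do.call(rbind, rows))
  attr(out, "register_shift") <- alignment$shift
  out
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_three <- function(one) {
  out <- AA1TO3[toupper(one)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

# Sequence of a chain from a Structure, named by residue number.
chain_sequence <- function(structure, chain_id) {
  res <- residue_table(structure)
  res <- res[res$chain == chain_id, , drop = FALSE]
  inv <- setNames(names(AA1TO3), AA1TO3)
  one <- inv[res$resname]
  one[is.na(one)] <- "X"
  setNames(one, res$resno)
}

#' Apply the register shift to all four subunits of a tetramer
#'
#' Threads the shift identically through every chain of a C4 channel. The
#' chains must carry identical sequences over the shift region, and a
#' structure that already carries a register shift is rejected (the shift is
#' not composable).
#'
#' @param model A `Structure` with (at least) four chains.
#' @param chain_ids The four chain ids (default the first four chains).
#' @param shift A `RegisterShift` (its `chain_id` is ignored; the shift is
#'   applied per chain).
#' @return A `Structure` combining the four threaded chains, with
#'   `low_confidence` flags and a `register_shift` attribute.
#' @export
symmetrize_tetramer <- function(model, chain_ids = NULL, shift) {
  if (!is.null(attr(model, "register_shift")))
    stop("structure already carries a register shift; re-shifting is not ",
         "supported")
  chains <- sort(unique(model$atoms$chain))
  if (is.null(chain_ids)) chain_ids <- chains
  if (length(chain_ids) != 4)
    stop("a tetramer needs exactly four chains; got ", length(chain_ids))
  seqs <- lapply(chain_ids, function(ch) chain_sequence(model, ch))
  region <- as.character(seq(shift$shift_start, shift$shift_end))
  ref <- seqs[[1]][region]
  for (i in 2:4) {
    if (any(is.na(seqs[[i]][region])) ||
        !identical(unname(seqs[[i]][region]), unname(ref)))
      stop("chain ", chain_ids[i],
           " sequence differs from chain ", chain_ids[1],
           " over the shift region")
  }
  parts <- lapply(chain_ids, function(ch) {
    aln <- build_shift_alignment(seqs[[which(chain_ids == ch)]],
                                 register_shift(ch, shift$shift_start,
                                                shift$shift_end))
    thread_backbone(model, aln, chain_id = ch)
  })
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  out <- new_structure(atoms)
  attr(out, "register_shift") <- shift
  out
}
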