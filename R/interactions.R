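# Simplified geometric detectors for non-covalent residue-residue contacts.
# Heavy-atom criteria only: no hydrogen placement and no angular terms, so
# absolute counts are coarser than a full interaction profiler would report;
# downstream statistics consume the counts, not the geometry.

#' Detect hydrogen bonds (simplified heavy-atom criterion)
#'
#' Reports a hydrogen bond for every donor/acceptor heavy-atom pair of two
#' different residues within \code{d_max}: donors are nitrogens plus the
#' Ser/Thr/Tyr hydroxyl oxygens; acceptors are oxygens plus the histidine
#' ring nitrogens. Backbone-backbone pairs of sequence neighbors (separation
#' 1) are excluded as covalent artifacts. Counting granularity is per atom
#' pair, so one residue pair can contribute several bonds.
#'
#' @param structure A \code{protein_structure}.
#' @param d_max Donor-acceptor heavy-atom distance cutoff in Angstrom
#'   (default 3.5).
#' @return Data frame with one row per bond: \code{res_i}, \code{res_j}
#'   (residue ids, \code{res_i < res_j}), \code{atom_i}, \code{atom_j},
#'   \code{distance}.
#' @export
detect_hydrogen_bonds <- function(structure, d_max = 3.5) {
  stopifnot(inherits(structure, "protein_structure"), d_max > 0)
  a <- structure$atoms
  res <- structure$residues

  hydroxyl <- mapply(function(aa, el) {
    !is.null(HYDROXYL_DONORS[[aa]]) && el %in% HYDROXYL_DONORS[[aa]]
  }, a$aa, a$elety)
  donor <- a$elesy == "N" | hydroxyl
  acceptor <- a$elesy == "O" |
    (a$aa == "HIS" & a$elety %in% HIS_ACCEPTOR_N)

  di <- which(donor)
  ai <- which(acceptor)
  if (length(di) == 0 || length(ai) == 0)
    return(empty_interactions())

  xyz <- as.matrix(a[, c("x", "y", "z")])
  seqpos <- res$seq_index[a$residue_id]
  chains <- res$chain[a$residue_id]

  rows <- list()
  for (d in di) {
    dd <- sqrt(colSums((t(xyz[ai, , drop = FALSE]) - xyz[d, ])^2))
    hit <- ai[dd <= d_max & a$residue_id[ai] != a$residue_id[d]]
    ddist <- dd[dd <= d_max & a$residue_id[ai] != a$residue_id[d]]
    if (length(hit) == 0) next
    # drop sequential backbone-backbone pairs
    bb <- a$elety[d] %in% BACKBONE_ATOMS & a$elety[hit] %in% BACKBONE_ATOMS &
      chains[hit] == chains[d] & abs(seqpos[hit] - seqpos[d]) == 1
    hit <- hit[!bb]; ddist <- ddist[!bb]
    if (length(hit) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      res_i = pmin(a$residue_id[d], a$residue_id[hit]),
      res_j = pmax(a$residue_id[d], a$residue_id[hit]),
      atom_i = ifelse(a$residue_id[d] < a$residue_id[hit],
                      a$elety[d], a$elety[hit]),
      atom_j = ifelse(a$residue_id[d] < a$residue_id[hit],
                      a$elety[hit], a$elety[d]),
      distance = ddist, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty_interactions())
  out <- do.call(rbind, rows)
  # one bond per unordered atom pair (an atom that is both donor and
  # acceptor would otherwise be reported twice)
  key <- paste(out$res_i, out$res_j, out$atom_i, out$atom_j)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$res_i, out$res_j, out$atom_i, out$atom_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_interactions <- function() {
  data.frame(res_i = integer(), res_j = integer(), atom_i = character(),
             atom_j = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic interactions (simplified heavy-atom criterion)
#'
#' A hydrophobic interaction is reported when an apolar side-chain carbon of
#' one residue lies within \code{d_max} of an apolar side-chain carbon of
#' another residue. The apolar atom set is a fixed per-amino-acid list
#' (aliphatic and aromatic carbons); polar residues never participate. At
#' most one interaction is reported per residue pair (the closest atom
#' pair).
#'
#' @param structure A \code{protein_structure}.
#' @param d_max Carbon-carbon distance cutoff in Angstrom (default 4.0).
#' @return Data frame with one row per interacting residue pair:
#'   \code{res_i}, \code{res_j}, \code{atom_i}, \code{atom_j},
#'   \code{distance}.
#' @export
detect_hydrophobic <- function(structure, d_max = 4.0) {
  stopifnot(inherits(structure, "protein_structure"), d_max > 0)
  a <- structure$atoms
  apolar <- mapply(function(aa, el) {
    !is.null(HYDROPHOBIC_ATOMS[[aa]]) && el %in% HYDROPHOBIC_ATOMS[[aa]]
  }, a$aa, a$elety)
  idx <- which(apolar)
  if (length(idx) < 2) return(empty_interactions())

  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d <= d_max, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_interactions())

  ri <- a$residue_id[idx[hit[, 1]]]
  rj <- a$residue_id[idx[hit[, 2]]]
  keep <- ri != rj
  if (!any(keep)) return(empty_interactions())
  out <- data.frame(
    res_i = pmin(ri, rj)[keep], res_j = pmax(ri, rj)[keep],
    atom_i = ifelse(ri < rj, a$elety[idx[hit[, 1]]],
                    a$elety[idx[hit[, 2]]])[keep],
    atom_j = ifelse(ri < rj, a$elety[idx[hit[, 2]]],
                    a$elety[idx[hit[, 1]]])[keep],
    distance = d[hit][keep], stringsAsFactors = FALSE
  )
  # collapse to the closest atom pair per residue pair
  out <- out[order(out$res_i, out$res_j, out$distance), , drop = FALSE]
  out <- out[!duplicated(out[, c("res_i", "res_j")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue interaction counts and participation
#'
#' Counts, for each residue of the structure, the number of hydrogen bonds
#' and hydrophobic interactions it appears in.
#'
#' @param structure A \code{protein_structure}.
#' @param hbonds Output of \code{\link{detect_hydrogen_bonds}}.
#' @param hydrophobic Output of \code{\link{detect_hydrophobic}}.
#' @return Data frame with \code{residue_id}, \code{n_hbond},
#'   \code{n_hydrophobic}, and logical participation flags
#'   \code{in_hbond}, \code{in_hydrophobic}.
#' @export
interaction_counts <- function(structure, hbonds, hydrophobic) {
  n <- nrow(structure$residues)
  ids <- structure$residues$residue_id
  count <- function(set) {
    tab <- tabulate(c(set$res_i, set$res_j), nbins = max(ids))
    tab[ids]
  }
  n_hb <- count(hbonds)
  n_hp <- count(hydrophobic)
  data.frame(residue_id = ids, n_hbond = n_hb, n_hydrophobic = n_hp,
             in_hbond = n_hb > 0, in_hydrophobic = n_hp > 0)
}
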