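# Deterministic near-uniform point set on the unit sphere (golden-spiral
# lattice). No RNG: ASA values are bit-for-bit reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area by the Shrake-Rupley algorithm
#'
#' For each heavy atom, \code{n_points} test points are placed on a sphere of
#' radius \code{r_vdw + probe}; a point is accessible when it is not inside
#' any other atom's expanded sphere. The atom's ASA is the accessible
#' fraction times the full sphere area. Residue ASA is the sum over its
#' atoms; relative accessibility (RASA) divides by a fixed per-amino-acid
#' maximum-ASA scale (values may exceed 1 and are not clipped; RASA is
#' undefined for \code{UNK} residues). Residues with RASA strictly below
#' \code{burial_threshold} are flagged buried.
#'
#' Atoms with coincident centers do not occlude each other. Unknown elements
#' fall back to a 1.7 Angstrom radius with a warning.
#'
#' @param structure A \code{protein_structure}.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere points per atom (default 960).
#' @param burial_threshold RASA burial cutoff (default 0.16, strict).
#' @return A list of class \code{asa_result}: \code{asa_per_atom} (numeric,
#'   one per atom row), \code{residues} (data frame with \code{residue_id},
#'   \code{asa}, \code{rasa}, \code{buried}), and the parameters.
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960,
                          burial_threshold = 0.16) {
  stopifnot(inherits(structure, "protein_structure"),
            probe >= 0, n_points >= 12)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)

  radii <- VDW_RADII[a$elesy]
  unknown <- is.na(radii)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(a$elesy[unknown]),
                                         collapse = ", "),
            "; using fallback radius ", VDW_DEFAULT, " A")
    radii[unknown] <- VDW_DEFAULT
  }
  radii <- unname(radii)
  expanded <- radii + probe
  pts <- sphere_points(n_points)

  asa <- numeric(n)
  # two atoms can only occlude each other within the sum of their expanded
  # radii; coincident centers (d ~ 0) never occlude
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < expanded[i] + expanded & di > 1e-9 & seq_len(n) != i)
    p <- pts * expanded[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      occluded <- rep(FALSE, n_points)
      for (j in nb) {
        d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
              (p[, 3] - xyz[j, 3])^2
        occluded <- occluded | d2 < expanded[j]^2
        if (all(occluded)) break
      }
      acc <- sum(!occluded)
    }
    asa[i] <- acc / n_points * 4 * pi * expanded[i]^2
  }

  res <- structure$residues
  res_asa <- vapply(res$residue_id,
                    function(id) sum(asa[a$residue_id == id]), numeric(1))
  rasa_val <- rasa(res_asa, res$aa)
  residues <- data.frame(residue_id = res$residue_id, asa = res_asa,
                         rasa = rasa_val, buried = is_buried(rasa_val,
                                                             burial_threshold))
  structure(list(asa_per_atom = asa, residues = residues, probe = probe,
                 n_points = n_points, burial_threshold = burial_threshold),
            class = "asa_result")
}

#' Relative accessible surface area
#'
#' Residue ASA divided by the amino acid's tabulated maximum ASA. Values may
#' exceed 1 and are not clipped; \code{UNK} residues yield \code{NA}.
#'
#' @param asa Residue ASA in squared Angstrom.
#' @param aa_type Three-letter amino acid code(s).
#' @param scale Named maximum-ASA scale (defaults to the shipped table).
#' @return Numeric RASA fraction(s).
#' @export
rasa <- function(asa, aa_type, scale = MAX_ASA) {
  stopifnot(length(asa) == length(aa_type))
  unname(asa / scale[aa_type])
}

#' Burial classification from RASA
#'
#' A residue is buried when its RASA is strictly below the threshold
#' (default 0.16).
#'
#' @param rasa Numeric RASA value(s).
#' @param threshold Burial cutoff (default 0.16).
#' @return Logical vector (\code{NA} where RASA is undefined).
#' @export
is_buried <- function(rasa, threshold = 0.16) {
  rasa < threshold
}

#' Loop fraction in a sliding sequence window
#'
#' Fraction of coil (\code{C}) residues among the window of \code{window}
#' positions centered on each residue. High values mark disordered regions;
#' residues embedded in helices or sheets score close to zero. At the chain
#' termini the window is truncated and the denominator is the number of
#' existing positions.
#'
#' @param sse3 Character vector of 3-state codes (one chain, in sequence
#'   order).
#' @param window Odd window length (default 9).
#' @return Numeric vector of fractions.
#' @export
loop_fraction <- function(sse3, window = 9) {
  stopifnot(window %% 2 == 1, window >= 1)
  n <- length(sse3)
  half <- (window - 1) / 2
  is_c <- as.numeric(sse3 == "C")
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(is_c[idx])
  }, numeric(1))
}

#' Distance of each residue centroid to the structure centroid
#'
#' Euclidean distance between the unweighted mean coordinate of a residue's
#' heavy atoms and the unweighted mean coordinate of all heavy atoms of the
#' structure. Small values mark the protein core.
#'
#' @param structure A \code{protein_structure}.
#' @return Numeric vector, one value per residue.
#' @export
centroid_distance <- function(structure) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  global <- colMeans(xyz)
  vapply(structure$residues$residue_id, function(id) {
    m <- colMeans(xyz[a$residue_id == id, , drop = FALSE])
    sqrt(sum((m - global)^2))
  }, numeric(1))
}

#' Relative sequence distance to the nearest chain terminus
#'
#' Minimal number of positions to traverse to reach the N- or C-terminus,
#' divided by the chain length.
#'
#' @param seq_index 0-based position(s) within the chain.
#' @param chain_length Total number of residues in the chain.
#' @return Numeric fraction(s) in [0, 0.5).
#' @export
terminus_distance <- function(seq_index, chain_length) {
  stopifnot(all(seq_index >= 0), all(seq_index < chain_length))
  pmin(seq_index, chain_length - 1 - seq_index) / chain_length
}
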