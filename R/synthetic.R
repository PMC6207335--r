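# Synthetic structure generator. Backbones are built from ideal internal
# coordinates (bond lengths/angles with per-segment phi/psi), which yields
# physically plausible traces: helical CA on a ~2.3 A radius helix with
# ~1.5 A rise and ~100 deg twist per residue, consecutive CA-CA ~3.8 A.
# Side chains are reduced to C-beta plus up to two ideal pseudo-atoms --
# enough for the contact, accessibility and interaction detectors.

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  }, add = TRUE)
  force(code)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

# Natural-extension placement: position D with |CD| = L, angle B-C-D = theta
# and dihedral A-B-C-D = chi (angles in degrees).
place_atom <- function(A, B, C, L, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  C + L * (-cos(theta) * bc + sin(theta) * (cos(chi) * m + sin(chi) * n))
}

# ideal geometry constants
GEO <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.521,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, ang_c_ca_cb = 110.4, dih_cb = -122.6)

# second pseudo side-chain atom attaches to CB (branched) or to the first
# extra atom (linear)
SIDE_EXTRAS <- list(
  LEU = c("CG", "CD1"), ILE = c("CG1", "CD1"), VAL = c("CG1", "CG2"),
  MET = c("CG", "CE"), PHE = c("CG", "CD1"), TRP = c("CG", "CD2"),
  TYR = c("CG", "CD1"), PRO = c("CG", "CD"), LYS = c("CG", "CD"),
  ARG = c("CG", "CD"), GLU = c("CG", "CD"), GLN = c("CG", "CD"),
  ASP = "CG", ASN = "CG", HIS = c("CG", "ND1"), SER = "OG",
  THR = c("OG1", "CG2"), CYS = "SG"
)
BRANCHED_AT_CB <- c("VAL", "THR")

bond_length_for <- function(atom_name) {
  switch(substr(atom_name, 1, 1), O = 1.42, S = 1.82, N = 1.46, 1.53)
}

# Build a single-chain peptide from phi/psi sequences (degrees). Returns a
# protein_structure. psi of the last residue is used only to place its
# carbonyl oxygen.
build_peptide <- function(aa_seq, phi, psi, id = "synthetic", chain = "A") {
  n <- length(aa_seq)
  stopifnot(n >= 1, length(phi) == n, length(psi) == n,
            all(aa_seq %in% AA_STANDARD))
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(GEO$n_ca, 0, 0)
  ang <- GEO$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + GEO$ca_c * c(-cos(ang), sin(ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           GEO$c_n, GEO$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            GEO$n_ca, GEO$ang_c_n_ca, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           GEO$ca_c, GEO$ang_n_ca_c, phi[i])
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    aa <- aa_seq[i]
    O <- place_atom(N[i, ], CA[i, ], C[i, ], GEO$c_o, GEO$ang_ca_c_o,
                    psi[i] + 180)
    atoms <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O)
    if (aa != "GLY") {
      CB <- place_atom(N[i, ], C[i, ], CA[i, ], GEO$ca_cb,
                       GEO$ang_c_ca_cb, GEO$dih_cb)
      atoms$CB <- CB
      extras <- SIDE_EXTRAS[[aa]]
      if (!is.null(extras)) {
        x1 <- place_atom(N[i, ], CA[i, ], CB, bond_length_for(extras[1]),
                         114, -60)
        atoms[[extras[1]]] <- x1
        if (length(extras) >= 2) {
          x2 <- if (aa %in% BRANCHED_AT_CB) {
            place_atom(N[i, ], CA[i, ], CB, bond_length_for(extras[2]),
                       114, 65)
          } else {
            place_atom(CA[i, ], CB, x1, bond_length_for(extras[2]), 114, 180)
          }
          atoms[[extras[2]]] <- x2
        }
      }
    }
    nm <- names(atoms)
    rows[[i]] <- data.frame(
      residue_id = i, chain = chain, resno = i, insert = "", aa = aa,
      elety = nm, elesy = substr(nm, 1, 1),
      x = vapply(atoms, `[`, numeric(1), 1),
      y = vapply(atoms, `[`, numeric(1), 2),
      z = vapply(atoms, `[`, numeric(1), 3),
      o = 1, stringsAsFactors = FALSE
    )
  }
  atoms_df <- do.call(rbind, rows)
  rownames(atoms_df) <- NULL
  residues <- data.frame(residue_id = seq_len(n), chain = chain,
                         resno = seq_len(n), insert = "", aa = aa_seq,
                         seq_index = seq_len(n) - 1L, stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms_df, residues = residues),
            class = "protein_structure")
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_from_to <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b); s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) unit(cross3(a, c(1, 0, 0)))
         else unit(cross3(a, c(0, 1, 0)))
    v <- p; s <- 0; cth <- -1
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# uniform random rotation matrix (consumes RNG)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}

# align the dominant CA axis of a peptide to `axis` and move its CA centroid
# to `origin`
align_to_axis <- function(structure, origin, axis) {
  ca <- residue_coords(structure, "CA")
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2, ctr)
  pc1 <- svd(cc)$v[, 1]
  if (sum(pc1 * (ca[nrow(ca), ] - ca[1, ])) < 0) pc1 <- -pc1
  R <- rotation_from_to(pc1, unit(axis))
  s <- transform_structure(structure, R, c(0, 0, 0))
  ca2 <- residue_coords(s, "CA")
  transform_structure(s, diag(3), origin - colMeans(ca2))
}

#' Generate an ideal alpha-helix
#'
#' Builds an \code{n}-residue helix from ideal internal coordinates
#' (phi = -57, psi = -47 degrees), giving the canonical C-alpha helix of
#' about 2.3 Angstrom radius, 1.5 Angstrom rise and 100 degrees twist per
#' residue; consecutive C-alpha atoms are 3.8 +/- 0.1 Angstrom apart and
#' the i, i+4 backbone carbonyl/amide pairs are in hydrogen-bond range.
#' Deterministic: no randomness is involved for a fixed sequence.
#'
#' @param n Number of residues (>= 4).
#' @param origin Target C-alpha centroid.
#' @param axis Helix axis direction.
#' @param aa_seq Amino acid sequence (3-letter codes); defaults to
#'   poly-alanine.
#' @return A \code{protein_structure}.
#' @export
make_helix <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1),
                       aa_seq = rep("ALA", n)) {
  stopifnot(n >= 4, length(aa_seq) == n)
  s <- build_peptide(aa_seq, phi = rep(-57, n), psi = rep(-47, n),
                     id = "helix")
  align_to_axis(s, origin, axis)
}

#' Generate an ideal beta-strand
#'
#' Extended backbone with phi = -139, psi = 135 degrees.
#'
#' @inheritParams make_helix
#' @param n Number of residues (>= 2).
#' @return A \code{protein_structure}.
#' @export
make_strand <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1),
                        aa_seq = rep("ALA", n)) {
  stopifnot(n >= 2, length(aa_seq) == n)
  s <- build_peptide(aa_seq, phi = rep(-139, n), psi = rep(135, n),
                     id = "strand")
  align_to_axis(s, origin, axis)
}

#' Generate a self-avoiding random coil
#'
#' Backbone dihedrals are sampled from a broad coil region; with ideal bond
#' geometry every step advances the C-alpha trace by ~3.8 Angstrom. The
#' walk is self-avoiding: any two non-consecutive C-alpha atoms are kept at
#' least \code{min_dist} apart, resampling dihedrals (bounded retries) when
#' violated.
#'
#' @param n Number of residues (>= 1).
#' @param seed RNG seed; the seed fully determines the output.
#' @param aa_seq Amino acid sequence; defaults to poly-serine.
#' @param min_dist Minimum non-neighbor C-alpha distance (default 4.0).
#' @return A \code{protein_structure}.
#' @export
make_coil <- function(n, seed = 1, aa_seq = rep("SER", n), min_dist = 4.0) {
  stopifnot(n >= 1, length(aa_seq) == n)
  with_seed(seed, {
    for (attempt in 1:25) {
      phi <- numeric(n); psi <- numeric(n)
      phi[1] <- stats::runif(1, -160, -50)
      # incremental NeRF state: backbone N/CA/C of the growing chain.
      # psi_i steers where CA_{i+1} lands, so it is what gets resampled.
      Nm <- matrix(NA_real_, n, 3); CAm <- Nm; Cm <- Nm
      Nm[1, ] <- c(0, 0, 0)
      CAm[1, ] <- c(GEO$n_ca, 0, 0)
      ang <- GEO$ang_n_ca_c * pi / 180
      Cm[1, ] <- CAm[1, ] + GEO$ca_c * c(-cos(ang), sin(ang), 0)
      ok <- TRUE
      for (i in seq_len(n - 1)) {
        placed <- FALSE
        for (try in 1:60) {
          psi[i] <- stats::runif(1, -70, 170)
          N2 <- place_atom(Nm[i, ], CAm[i, ], Cm[i, ], GEO$c_n,
                           GEO$ang_ca_c_n, psi[i])
          CA2 <- place_atom(CAm[i, ], Cm[i, ], N2, GEO$n_ca,
                            GEO$ang_c_n_ca, 180)
          if (i < 2 ||
              min(sqrt(rowSums(sweep(CAm[seq_len(i - 1), , drop = FALSE], 2,
                                     CA2)^2))) >= min_dist) {
            phi[i + 1] <- stats::runif(1, -160, -50)
            Nm[i + 1, ] <- N2
            CAm[i + 1, ] <- CA2
            Cm[i + 1, ] <- place_atom(Cm[i, ], N2, CA2, GEO$ca_c,
                                      GEO$ang_n_ca_c, phi[i + 1])
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        psi[n] <- stats::runif(1, -70, 170)
        return(build_peptide(aa_seq, phi, psi, id = "coil"))
      }
    }
    stop("failed to place self-avoiding coil of length ", n,
         "; try a smaller n")
  })
}

#' Specification for a synthetic globular structure
#'
#' Describes the synthetic protein emulated by
#' \code{\link{assemble_globule}}: a small single-chain globule in the
#' 56-164 residue range typical of experimentally characterized folding
#' datasets, with helices/strands forming a hydrophobic core and polar
#' coils at the surface.
#'
#' @param n_residues Total residue count (default 80).
#' @param layout List of segments, each \code{list(kind, length)} with kind
#'   \code{"H"}, \code{"E"} or \code{"C"}; segment lengths must sum to
#'   \code{n_residues}. Defaults to a repeating helix/coil/strand/coil
#'   pattern.
#' @param packing Packing factor (dimensionless, default 1): larger values
#'   shrink the placement radii and densify the core.
#' @param seed RNG seed; the spec plus seed fully determine the structure.
#' @return List of class \code{generator_spec}.
#' @export
globule_spec <- function(n_residues = 80, layout = NULL, packing = 1,
                         seed = 1) {
  stopifnot(n_residues >= 20, packing > 0)
  if (is.null(layout)) {
    layout <- list()
    kinds <- c("H", "C", "E", "C")
    lens <- c(12, 4, 7, 4)
    left <- n_residues
    k <- 1
    while (left > 0) {
      take <- min(lens[(k - 1) %% 4 + 1], left)
      # avoid a trailing fragment too short for its kind
      if (left - take > 0 && left - take < 4) take <- left
      kind <- kinds[(k - 1) %% 4 + 1]
      if (take < 4) kind <- "C"
      layout[[k]] <- list(kind = kind, length = take)
      left <- left - take
      k <- k + 1
    }
  }
  total <- sum(vapply(layout, function(s) s$length, numeric(1)))
  if (total != n_residues)
    stop("segment lengths sum to ", total, ", not n_residues = ", n_residues)
  structure(list(n_residues = n_residues, layout = layout, packing = packing,
                 seed = seed), class = "generator_spec")
}

sample_segment_sequence <- function(kind, len) {
  # helices/strands hydrophobic-biased (core), coils polar-biased (surface)
  w <- if (kind %in% c("H", "E")) exp(KD_HYDROPATHY / 2.5)
       else exp(-KD_HYDROPATHY / 2.5)
  w <- w[setdiff(names(w), "PRO")]  # keep backbone geometry simple
  sample(names(w), len, replace = TRUE, prob = w)
}

#' Assemble a synthetic globular protein
#'
#' Generates the segments of the layout (ideal helices and strands, random
#' coils), then places them rigidly around a common center with
#' hydrophobic-rich segments buried inward and polar segments toward the
#' surface, rejecting orientations that clash. The resulting single-chain
#' structure has a hydrophobic core, so burial frequencies derived from it
#' order hydrophobic amino acids below polar ones in the pseudo-energy
#' table. Ground-truth secondary structure follows the layout.
#'
#' Output is fully determined by the spec (including its seed).
#'
#' @param spec A \code{generator_spec} from \code{\link{globule_spec}}.
#' @return List of class \code{synthetic_globule}: \code{structure} (a
#'   \code{protein_structure}), \code{sse3} (ground-truth 3-state codes),
#'   \code{spec}.
#' @export
assemble_globule <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    segs <- list()
    seqs <- list()
    for (k in seq_along(spec$layout)) {
      sg <- spec$layout[[k]]
      aa <- sample_segment_sequence(sg$kind, sg$length)
      seqs[[k]] <- aa
      segs[[k]] <- switch(sg$kind,
        H = make_helix(sg$length, aa_seq = aa),
        E = make_strand(sg$length, aa_seq = aa),
        C = make_coil(sg$length, seed = sample.int(2^30, 1), aa_seq = aa))
    }
    # placement radius per segment: hydrophobic segments inward
    R0 <- (3 * spec$n_residues * 134 / (4 * pi))^(1 / 3) / spec$packing
    hfrac <- vapply(seqs, function(aa) mean(KD_HYDROPATHY[aa] > 0),
                    numeric(1))
    radius <- R0 * (0.10 + 0.70 * (1 - hfrac))

    # place segments from the core outward, then compact
    place_order <- order(radius)
    placed <- vector("list", length(segs))
    clash_min <- 2.5
    for (k in place_order) {
      s <- segs[[k]]
      others <- do.call(rbind, lapply(placed[!vapply(placed, is.null,
                                                     logical(1))],
                                      function(p)
                                        as.matrix(p$atoms[, c("x", "y",
                                                              "z")])))
      ok <- FALSE
      r_k <- radius[k]
      for (try in 1:800) {
        u <- stats::rnorm(3); u <- unit(u)
        R <- random_rotation()
        cand <- transform_structure(s, R, c(0, 0, 0))
        ctr2 <- colMeans(as.matrix(cand$atoms[, c("x", "y", "z")]))
        cand <- transform_structure(cand, diag(3), u * r_k - ctr2)
        cxyz <- as.matrix(cand$atoms[, c("x", "y", "z")])
        ok <- is.null(others) ||
          min(fields_min_dist(cxyz, others)) >= clash_min
        if (ok) { placed[[k]] <- cand; break }
        if (try %% 30 == 0) r_k <- r_k * 1.12
      }
      if (!ok) stop("clash resolution failed while placing segment ", k)
    }
    # compaction: pull each segment toward the origin until contact, then
    # anneal with small rigid perturbations that shrink the assembly, so the
    # globule is densely packed and the core well buried
    if (length(placed) > 1) {
      for (pass in 1:4) {
        for (k in place_order) {
          repeat {
            ctr <- colMeans(as.matrix(placed[[k]]$atoms[, c("x", "y", "z")]))
            r_now <- sqrt(sum(ctr^2))
            if (r_now < 0.8) break
            step <- -unit(ctr) * min(1.0, r_now)
            cand <- transform_structure(placed[[k]], diag(3), step)
            others <- do.call(rbind, lapply(placed[-k], function(p)
              as.matrix(p$atoms[, c("x", "y", "z")])))
            cxyz <- as.matrix(cand$atoms[, c("x", "y", "z")])
            if (min(fields_min_dist(cxyz, others)) < clash_min) break
            placed[[k]] <- cand
          }
        }
      }
      seg_xyz <- lapply(placed, function(p)
        as.matrix(p$atoms[, c("x", "y", "z")]))
      rg2 <- function(xyzs) {
        m <- do.call(rbind, xyzs)
        sum(sweep(m, 2, colMeans(m))^2)
      }
      current <- rg2(seg_xyz)
      for (iter in seq_len(60 * length(placed))) {
        k <- sample(length(placed), 1)
        ctr <- colMeans(seg_xyz[[k]])
        ang <- stats::runif(1, -0.12, 0.12)
        ax <- unit(stats::rnorm(3))
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
        shift <- -unit(ctr + stats::rnorm(3, 0, 0.2)) * stats::runif(1, 0.1, 0.5)
        cand <- sweep(sweep(seg_xyz[[k]], 2, ctr) %*% t(R), 2, ctr + shift,
                      "+")
        others <- do.call(rbind, seg_xyz[-k])
        if (min(fields_min_dist(cand, others)) < clash_min) next
        trial <- seg_xyz; trial[[k]] <- cand
        val <- rg2(trial)
        if (val < current) { seg_xyz <- trial; current <- val }
      }
      for (k in seq_along(placed)) {
        placed[[k]]$atoms$x <- seg_xyz[[k]][, 1]
        placed[[k]]$atoms$y <- seg_xyz[[k]][, 2]
        placed[[k]]$atoms$z <- seg_xyz[[k]][, 3]
      }
    }
    # concatenate into one chain
    atoms <- NULL
    offset <- 0L
    for (k in seq_along(placed)) {
      a <- placed[[k]]$atoms
      a$residue_id <- a$residue_id + offset
      a$resno <- a$resno + offset
      offset <- offset + nrow(placed[[k]]$residues)
      atoms <- rbind(atoms, a)
    }
    n <- offset
    residues <- atoms[!duplicated(atoms$residue_id),
                      c("residue_id", "chain", "resno", "insert", "aa")]
    residues$seq_index <- seq_len(n) - 1L
    rownames(atoms) <- rownames(residues) <- NULL
    st <- structure(list(id = sprintf("globule_seed%d", spec$seed),
                         atoms = atoms, residues = residues),
                    class = "protein_structure")
    # burial-correlated composition: residues buried in the assembled
    # geometry become hydrophobic with high probability, exposed residues
    # with low probability; side chains are rebuilt on the fixed backbone.
    # This plants the buried/exposed occupancy contrast that an
    # inverse-Boltzmann potential derived from the output must recover.
    # several rounds, because rebuilding side chains shifts accessibility;
    # after the first round only residues whose burial state disagrees with
    # their assigned class are resampled, so the assignment converges
    aa_cur <- NULL
    for (round in 1:5) {
      asa0 <- shrake_rupley(st)
      bur0 <- asa0$residues$rasa < 0.16
      want_h <- stats::runif(n) < ifelse(bur0, 0.97, 0.03)
      if (is.null(aa_cur)) {
        aa_cur <- ifelse(want_h,
                         sample(HYDROPHOBIC_SET, n, replace = TRUE),
                         sample(POLAR_SET, n, replace = TRUE))
      } else {
        is_h <- aa_cur %in% HYDROPHOBIC_SET
        flip <- is_h != want_h
        if (!any(flip)) break
        aa_cur[flip] <- ifelse(want_h[flip],
                               sample(HYDROPHOBIC_SET, sum(flip),
                                      replace = TRUE),
                               sample(POLAR_SET, sum(flip), replace = TRUE))
      }
      st <- set_sequence(st, aa_cur)
    }
    sse3 <- unlist(lapply(spec$layout,
                          function(sg) rep(sg$kind, sg$length)))
    list(structure = st, sse3 = sse3, spec = spec)
  })
}

# Replace the amino-acid sequence of a structure, rebuilding side chains
# (CB plus pseudo-atoms) from each residue's backbone frame.
set_sequence <- function(structure, aa_seq) {
  res <- structure$residues
  stopifnot(length(aa_seq) == nrow(res), all(aa_seq %in% AA_STANDARD))
  a <- structure$atoms
  rows <- list()
  for (i in seq_len(nrow(res))) {
    id <- res$residue_id[i]
    sub <- a[a$residue_id == id, , drop = FALSE]
    bb <- sub[sub$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
    get <- function(nm) unlist(bb[bb$elety == nm, c("x", "y", "z")])
    N <- get("N"); CA <- get("CA"); C <- get("C")
    aa <- aa_seq[i]
    bb$aa <- aa
    extra <- list()
    if (aa != "GLY" && length(N) == 3 && length(CA) == 3 && length(C) == 3) {
      CB <- place_atom(N, C, CA, GEO$ca_cb, GEO$ang_c_ca_cb, GEO$dih_cb)
      extra$CB <- CB
      ex <- SIDE_EXTRAS[[aa]]
      if (!is.null(ex)) {
        x1 <- place_atom(N, CA, CB, bond_length_for(ex[1]), 114, -60)
        extra[[ex[1]]] <- x1
        if (length(ex) >= 2) {
          extra[[ex[2]]] <- if (aa %in% BRANCHED_AT_CB)
            place_atom(N, CA, CB, bond_length_for(ex[2]), 114, 65)
          else place_atom(CA, CB, x1, bond_length_for(ex[2]), 114, 180)
        }
      }
    }
    if (length(extra)) {
      nm <- names(extra)
      bb <- rbind(bb, data.frame(
        residue_id = id, chain = res$chain[i], resno = res$resno[i],
        insert = res$insert[i], aa = aa, elety = nm,
        elesy = substr(nm, 1, 1),
        x = vapply(extra, `[`, numeric(1), 1),
        y = vapply(extra, `[`, numeric(1), 2),
        z = vapply(extra, `[`, numeric(1), 3),
        o = 1, stringsAsFactors = FALSE))
    }
    rows[[i]] <- bb
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  res$aa <- aa_seq
  structure(list(id = structure$id, atoms = atoms, residues = res),
            class = "protein_structure")
}

HYDROPHOBIC_SET <- c("LEU", "VAL", "ILE", "PHE", "MET", "ALA", "TRP")
POLAR_SET <- c("SER", "THR", "ASN", "GLN", "ASP", "GLU", "LYS", "ARG",
               "HIS", "GLY", "TYR", "CYS")

# minimal pairwise distances between two coordinate sets (rowwise minima)
fields_min_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1))
}

#' Write a synthetic globule with its ground-truth sidecar
#'
#' Emits a standard PDB file plus a JSON sidecar carrying the ground-truth
#' secondary structure, the generator spec, and optional label sets.
#'
#' @param globule Output of \code{\link{assemble_globule}}.
#' @param pdb_file,json_file Output paths.
#' @param labels Optional list as returned by \code{\link{generate_labels}}.
#' @return Invisibly, the two paths.
#' @export
write_globule <- function(globule, pdb_file, json_file, labels = NULL) {
  write_pdb(globule$structure, pdb_file)
  payload <- list(
    id = globule$structure$id,
    sse3 = paste(globule$sse3, collapse = ""),
    spec = list(n_residues = globule$spec$n_residues,
                packing = globule$spec$packing, seed = globule$spec$seed,
                layout = lapply(globule$spec$layout, function(s)
                  list(kind = s$kind, length = s$length)))
  )
  if (!is.null(labels)) payload$labels <- labels
  jsonlite::write_json(payload, json_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pdb_file, json_file))
}

#' Generate binary label sets with a controlled joint probability
#'
#' Exact-count sampling of two binary label sets over \code{N} positions:
#' \code{round(p_J N)} positions carry both labels, \code{round(p_A N)}
#' carry label A in total and \code{round(p_B N)} label B, with positions
#' shuffled by the seed. Because counts are exact, the overlap shift of the
#' generated sets equals \code{100 (n_obs/N - n_A n_B / N^2)}
#' deterministically at any \code{N}.
#'
#' @param N Number of positions.
#' @param p_A,p_B Marginal label probabilities.
#' @param p_J Target joint probability; must satisfy
#'   \code{max(0, p_A + p_B - 1) <= p_J <= min(p_A, p_B)}.
#' @param seed RNG seed for the position shuffle.
#' @return List with integer position vectors \code{A} and \code{B} and the
#'   realized counts \code{n_A}, \code{n_B}, \code{n_obs}.
#' @export
generate_labels <- function(N, p_A, p_B, p_J, seed = 1) {
  stopifnot(N >= 1, p_A >= 0, p_A <= 1, p_B >= 0, p_B <= 1)
  if (p_J < max(0, p_A + p_B - 1) - 1e-12 || p_J > min(p_A, p_B) + 1e-12)
    stop("p_J must lie within [", max(0, p_A + p_B - 1), ", ",
         min(p_A, p_B), "]")
  n_j <- round(p_J * N)
  n_a <- round(p_A * N)
  n_b <- round(p_B * N)
  if (n_j > min(n_a, n_b) || n_a + n_b - n_j > N)
    stop("rounded counts infeasible: need n_obs <= min(", n_a, ", ", n_b,
         ") and n_A + n_B - n_obs <= ", N)
  with_seed(seed, {
    pos <- sample.int(N)
    both <- pos[seq_len(n_j)]
    a_only <- pos[seq_len(n_a - n_j) + n_j]
    b_only <- pos[seq_len(n_b - n_j) + n_a]
    list(A = sort(c(both, a_only)), B = sort(c(both, b_only)),
         n_A = n_a, n_B = n_b, n_obs = n_j)
  })
}
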