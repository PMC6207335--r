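# hand-built two-residue structures for detector edge cases
two_residue_structure <- function(atoms1, atoms2, aa1, aa2, resno2 = 5) {
  mk <- function(atoms, aa, rid, resno) {
    data.frame(residue_id = rid, chain = "A", resno = resno, insert = "",
               aa = aa, elety = names(atoms),
               elesy = substr(names(atoms), 1, 1),
               x = vapply(atoms, `[`, numeric(1), 1),
               y = vapply(atoms, `[`, numeric(1), 2),
               z = vapply(atoms, `[`, numeric(1), 3),
               o = 1, stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(atoms1, aa1, 1L, 1L), mk(atoms2, aa2, 2L, resno2))
  residues <- data.frame(residue_id = c(1L, 2L), chain = "A",
                         resno = c(1L, resno2), insert = "",
                         aa = c(aa1, aa2), seq_index = c(0L, resno2 - 1L),
                         stringsAsFactors = FALSE)
  structure(list(id = "pair", atoms = atoms, residues = residues),
            class = "protein_structure")
}

gly_pair <- function(no_dist) {
  two_residue_structure(
    list(N = c(0, 0, 0), CA = c(1.5, 0, 0), C = c(2.2, 1.3, 0),
         O = c(1.6, 2.4, 0)),
    list(N = c(1.6, 2.4 + no_dist, 0), CA = c(2.9, 3.2 + no_dist, 0),
         C = c(4.2, 2.6 + no_dist, 0), O = c(4.4, 1.4 + no_dist, 0)),
    "GLY", "GLY")
}

test_that("backbone amide-carbonyl pairs within 3.5 A count as hydrogen bonds", {
  hb <- detect_hydrogen_bonds(gly_pair(2.9))
  # N2...O1 at 2.9 A qualifies; check it is reported
  expect_true(any(hb$atom_i == "O" & hb$atom_j == "N" & hb$res_i == 1))
  expect_true(all(hb$distance <= 3.5))

  hb_far <- detect_hydrogen_bonds(gly_pair(3.6))
  expect_false(any(hb_far$atom_i == "O" & hb_far$atom_j == "N"))
})

test_that("sequential backbone-backbone pairs are excluded", {
  st <- gly_pair(2.9)
  st$residues$resno[2] <- 2L
  st$residues$seq_index[2] <- 1L
  st$atoms$resno[st$atoms$residue_id == 2] <- 2L
  hb <- detect_hydrogen_bonds(st)
  expect_equal(nrow(hb), 0)
})

test_that("every interior residue of an ideal helix hydrogen-bonds", {
  h <- make_helix(14)
  hb <- detect_hydrogen_bonds(h)
  ic <- interaction_counts(h, hb, detect_hydrophobic(h))
  expect_true(all(ic$n_hbond[3:12] >= 1))
})

test_that("hydrophobic contacts need apolar atoms on both sides", {
  leu <- list(CB = c(0, 0, 0), CG = c(1.5, 0, 0), CD1 = c(2.3, 1.2, 0))
  leu2 <- list(CB = c(6.5, 1.2, 0), CG = c(5.2, 1.6, 0),
               CD1 = c(3.9, 1.2 + 2.3, 0))
  st <- two_residue_structure(c(list(CA = c(-1.5, 0, 0)), leu),
                              c(list(CA = c(8, 1.2, 0)), leu2),
                              "LEU", "LEU")
  hp <- detect_hydrophobic(st)
  expect_equal(nrow(hp), 1)  # one interaction per residue pair at most
  expect_lte(hp$distance, 4.0)

  ser <- two_residue_structure(
    list(CA = c(0, 0, 0), CB = c(1.5, 0, 0), OG = c(2.2, 1.2, 0)),
    list(CA = c(3.5, 0, 0), CB = c(3.0, 1.2, 0), OG = c(2.8, 2.6, 0)),
    "SER", "SER")
  expect_equal(nrow(detect_hydrophobic(ser)), 0)
})

test_that("a packed hydrophobic core matches brute-force pair enumeration", {
  g <- shared_globules()[[1]]$structure
  hp <- detect_hydrophobic(g)
  # brute force: closest apolar-carbon pair per residue pair within 4 A
  a <- g$atoms
  apolar <- mapply(function(aa, el)
    !is.null(earlyfold:::HYDROPHOBIC_ATOMS[[aa]]) &&
      el %in% earlyfold:::HYDROPHOBIC_ATOMS[[aa]], a$aa, a$elety)
  sub <- a[apolar, ]
  d <- as.matrix(dist(sub[, c("x", "y", "z")]))
  pairs <- which(upper.tri(d) & d <= 4.0, arr.ind = TRUE)
  keys <- unique(vapply(seq_len(nrow(pairs)), function(r) {
    ri <- sub$residue_id[pairs[r, 1]]; rj <- sub$residue_id[pairs[r, 2]]
    if (ri == rj) return(NA_character_)
    paste(min(ri, rj), max(ri, rj))
  }, character(1)))
  keys <- keys[!is.na(keys)]
  expect_setequal(paste(hp$res_i, hp$res_j), keys)
})

test_that("interaction counts are symmetric and participation flags follow", {
  st <- gly_pair(2.9)
  none <- interaction_counts(st, earlyfold:::empty_interactions(),
                             earlyfold:::empty_interactions())
  expect_equal(none$n_hbond, c(0, 0))
  expect_false(any(none$in_hbond))

  one <- data.frame(res_i = 1L, res_j = 2L, atom_i = "O", atom_j = "N",
                    distance = 2.9)
  ic <- interaction_counts(st, one, earlyfold:::empty_interactions())
  expect_equal(ic$n_hbond, c(1, 1))

  g <- shared_globules()[[1]]$structure
  hb <- detect_hydrogen_bonds(g)
  ic_g <- interaction_counts(g, hb, detect_hydrophobic(g))
  expect_equal(sum(ic_g$n_hbond), 2 * nrow(hb))
})

test_that("detectors are invariant under rigid-body motion", {
  g <- shared_globules()[[2]]$structure
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  g2 <- earlyfold:::transform_structure(g, R, c(-7, 3, 12))
  expect_equal(nrow(detect_hydrogen_bonds(g2)),
               nrow(detect_hydrogen_bonds(g)))
  expect_equal(nrow(detect_hydrophobic(g2)), nrow(detect_hydrophobic(g)))
})

test_that("all-polar chains form no hydrophobic interactions", {
  coil <- make_coil(20, seed = 5,
                    aa_seq = rep(c("SER", "ASN", "ASP", "GLN"), 5))
  expect_equal(nrow(detect_hydrophobic(coil)), 0)
})
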