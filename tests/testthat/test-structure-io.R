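test_that("a minimal PDB parses into chains, residues and consecutive indices", {
  st <- read_structure(pdb_three_residues())
  expect_s3_class(st, "protein_structure")
  expect_equal(length(unique(st$residues$chain)), 1)
  expect_equal(nrow(st$residues), 3)
  expect_equal(st$residues$seq_index, c(0L, 1L, 2L))
  expect_equal(st$residues$aa, c("ALA", "GLY", "LEU"))
  expect_equal(nrow(st$atoms), 12)
})

test_that("alternate locations resolve to the highest-occupancy atom", {
  lines <- c(
    pdb_atom_line(1, "N", " ", "ALA", "A", 1, " ", 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 1, " ", 1.5, 0, 0),
    pdb_atom_line(3, "N", " ", "GLY", "A", 2, " ", 3.0, 0, 0),
    pdb_atom_line(4, "CA", "A", "GLY", "A", 2, " ", 4.1, 0, 0, occ = 0.6),
    pdb_atom_line(5, "CA", "B", "GLY", "A", 2, " ", 4.9, 0, 0, occ = 0.4),
    "END")
  st <- read_structure(paste(lines, collapse = "\n"))
  ca2 <- st$atoms[st$atoms$residue_id == 2 & st$atoms$elety == "CA", ]
  expect_equal(nrow(ca2), 1)
  expect_equal(ca2$x, 4.1)
  expect_equal(ca2$o, 0.6)
})

test_that("insertion codes get consecutive seq_index with author numbers kept", {
  lines <- c(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 10, " ", 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 10, "A", 3.8, 0, 0),
    pdb_atom_line(3, "CA", " ", "LEU", "A", 11, " ", 7.6, 0, 0),
    "END")
  st <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(st$residues$seq_index, c(0L, 1L, 2L))
  expect_equal(st$residues$resno, c(10L, 10L, 11L))
  expect_equal(st$residues$insert, c("", "A", ""))
})

test_that("malformed ATOM records are rejected with the offending line", {
  txt <- paste(c(pdb_atom_line(1, "CA", " ", "ALA", "A", 1, " ", 0, 0, 0),
                 "ATOM      2  CA  ALA A   2      badcoords"),
               collapse = "\n")
  expect_error(read_structure(txt), "line 2")
  expect_error(read_structure("REMARK nothing here"), "ATOM")
})

test_that("PDB round-trip preserves atoms, order and coordinates to 3 dp", {
  h <- make_helix(12, aa_seq = rep(c("ALA", "LEU", "SER"), 4))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(h, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(h$atoms))
  expect_equal(back$residues$aa, h$residues$aa)
  expect_equal(back$atoms$elety, h$atoms$elety)
  expect_lt(max(abs(back$atoms$x - h$atoms$x)), 5e-4 + 1e-9)
  expect_lt(max(abs(back$atoms$z - h$atoms$z)), 5e-4 + 1e-9)
})

test_that("8-state DSSP codes reduce to 3 states", {
  expect_equal(reduce_sse("H"), "H")
  expect_equal(reduce_sse(c("G", "I", "B", "T", "S")),
               c("H", "H", "E", "C", "C"))
  expect_equal(reduce_sse(c("E", " ", "")), c("E", "C", "C"))
})

test_that("classic DSSP text maps onto the structure with coil defaults", {
  st <- read_structure(pdb_three_residues())
  dssp_line <- function(i, resno, chain, aa1, ss)
    sprintf("%5d%5d %1s %1s  %1s", i, resno, chain, aa1, ss)
  txt <- paste(c(
    "==== Secondary Structure Definition ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    dssp_line(1, 1, "A", "A", "H"),
    dssp_line(2, 2, "A", "G", "E")
    # residue 3 absent -> defaults to C
  ), collapse = "\n")
  sse <- read_dssp_annotation(txt, st)
  expect_equal(sse, c("H", "E", "C"))

  # an unmappable DSSP line is skipped with a warning
  txt2 <- paste(c(
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    dssp_line(1, 1, "A", "A", "H"),
    dssp_line(2, 99, "A", "G", "E")
  ), collapse = "\n")
  expect_warning(sse2 <- read_dssp_annotation(txt2, st), "did not map")
  expect_equal(sse2, c("H", "C", "C"))
})

test_that("Start2Fold JSON entries parse in order and verify declared counts", {
  good <- jsonlite::toJSON(list(
    list(protein = "protein alpha", start2fold_id = "STF0001",
         pdb_id = "1abc", chain = "A", uniprot_id = "P12345",
         n_efr = 5, efr_residues = c(4, 8, 15, 16, 23),
         residue_range = c(1, 86)),
    list(protein = "protein beta", start2fold_id = "STF0002",
         pdb_id = "2xyz", chain = "A",
         efr_residues = c(10, 11))
  ), auto_unbox = TRUE)
  entries <- read_start2fold_json(good)
  expect_equal(nrow(entries), 2)
  expect_equal(entries$start2fold_id, c("STF0001", "STF0002"))
  expect_equal(entries$n_efr, c(5L, 2L))
  expect_equal(entries$efr_residues[[1]], c(4L, 8L, 15L, 16L, 23L))
  expect_equal(entries$range_start[1], 1L)

  bad <- jsonlite::toJSON(list(
    list(protein = "broken entry", n_efr = 5,
         efr_residues = c(4, 8, 15, 16))
  ), auto_unbox = TRUE)
  expect_error(read_start2fold_json(bad), "broken entry")
})

test_that("labels attach by author number with LATE/non-functional defaults", {
  coords <- cbind(seq(0, 11.4, by = 3.8), 0, 0)
  st <- ca_structure(coords)  # residues numbered 1..4
  ann <- attach_annotations(st, efr = 2, functional = 3)
  expect_equal(ann$folding_class, c("LATE", "EARLY", "LATE", "LATE"))
  expect_equal(ann$functional, c(FALSE, FALSE, TRUE, FALSE))

  ann0 <- attach_annotations(st)
  expect_true(all(ann0$folding_class == "LATE"))
  expect_false(any(ann0$functional))

  expect_error(attach_annotations(st, efr = 99), "mapping error")
})

test_that("attaching labels is idempotent and order-independent", {
  st <- ca_structure(cbind(seq(0, 26.6, by = 3.8), 0, 0))
  a1 <- attach_annotations(st, efr = c(2, 5, 3), functional = c(7, 1))
  a2 <- attach_annotations(st, efr = c(5, 3, 2), functional = c(1, 7))
  expect_identical(a1$folding_class, a2$folding_class)
  expect_identical(a1$functional, a2$functional)
})

test_that("the EFR score threshold is strict and monotone in the threshold", {
  expect_equal(apply_efoldmine_threshold(0.163), "LATE")
  expect_equal(apply_efoldmine_threshold(0.164), "EARLY")
  expect_equal(apply_efoldmine_threshold(c(0, 0.5, 0.163)),
               c("LATE", "EARLY", "LATE"))
  expect_error(apply_efoldmine_threshold(c(0.2, 1.4)), "within")

  set.seed(42)
  scores <- stats::runif(200)
  n_early <- vapply(c(0.9, 0.5, 0.163, 0.05, 0),
                    function(th) sum(apply_efoldmine_threshold(scores, th) ==
                                       "EARLY"),
                    numeric(1))
  expect_true(all(diff(n_early) >= 0))
})
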