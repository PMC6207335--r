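#' Read a protein structure from PDB format
#'
#' Parses PDB-format text (or a file) into a \code{protein_structure} object:
#' an atom table plus a per-residue index. Only the first model is kept; for
#' atoms with alternate locations the highest-occupancy variant is retained;
#' waters, non-polymer ligands and hydrogens are dropped. Residues are indexed
#' by a consecutive, 0-based \code{seq_index} within each chain while the
#' author numbering (residue number plus insertion code) is preserved.
#'
#' Non-standard residues with a standard parent (e.g. selenomethionine) are
#' mapped to the parent amino acid; others become \code{UNK} and are excluded
#' from amino-acid-specific tables downstream.
#'
#' @param source Path to a PDB file, or a character scalar/vector of PDB text.
#' @param id Structure identifier; defaults to the file name or "structure".
#' @return An object of class \code{protein_structure} with elements
#'   \code{id}, \code{atoms} (one row per heavy atom: \code{residue_id},
#'   \code{chain}, \code{resno}, \code{insert}, \code{aa}, \code{elety},
#'   \code{elesy}, \code{x}, \code{y}, \code{z}, \code{o}) and
#'   \code{residues} (one row per residue: \code{residue_id}, \code{chain},
#'   \code{resno}, \code{insert}, \code{seq_index}, \code{aa}).
#' @seealso \code{\link{write_pdb}}, \code{\link{build_residue_graph}}
#' @export
read_structure <- function(source, id = NULL) {
  stopifnot(is.character(source), length(source) >= 1)
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    path <- source
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(id)) id <- "structure"
  }
  .validate_pdb_lines(lines)
  if (!any(grepl("^ATOM", lines)))
    stop("no ATOM records found in PDB input")

  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  # element symbol: use the PDB element column when present, else derive from
  # the atom name
  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(bad))
    elesy[bad] <- suppressWarnings(bio3d::atom2ele(at$elety[bad]))
  elesy <- toupper(trimws(elesy))

  resid <- toupper(trimws(at$resid))
  aa <- ifelse(resid %in% AA_STANDARD, resid,
               ifelse(resid %in% names(AA_PARENT), AA_PARENT[resid], "UNK"))

  keep <- !(resid %in% WATER_NAMES) &
    !(elesy %in% c("H", "D")) &
    (at$type == "ATOM" | resid %in% names(AA_PARENT))
  at <- at[keep, , drop = FALSE]
  aa <- aa[keep]
  elesy <- elesy[keep]
  if (nrow(at) == 0) stop("no polymer atoms left after filtering")

  insert <- ifelse(is.na(at$insert), "", at$insert)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)

  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = insert, aa = aa, elety = trimws(at$elety), elesy = elesy,
    x = at$x, y = at$y, z = at$z, o = occ, alt = alt,
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "

  # highest-occupancy alternate location per (residue, atom name); ties break
  # toward the alphabetically first altloc, matching common convention
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order of residues/atoms
  atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|"), key)), ,
                 drop = FALSE]
  atoms$alt <- NULL
  rownames(atoms) <- NULL

  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$residue_id <- match(rkey, unique(rkey))
  first <- !duplicated(atoms$residue_id)
  residues <- data.frame(
    residue_id = atoms$residue_id[first], chain = atoms$chain[first],
    resno = atoms$resno[first], insert = atoms$insert[first],
    aa = atoms$aa[first], stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$residue_id), , drop = FALSE]
  residues$seq_index <- stats::ave(seq_len(nrow(residues)), residues$chain,
                                   FUN = function(i) seq_along(i) - 1L)
  rownames(residues) <- NULL

  for (ch in unique(residues$chain)) {
    sub <- residues[residues$chain == ch, ]
    if (all(sub$aa == "UNK"))
      stop("chain '", ch, "' contains no standard residues")
  }
  no_ca <- vapply(split(atoms$elety, atoms$residue_id),
                  function(e) !("CA" %in% e), logical(1))
  std <- residues$aa != "UNK"
  if (any(no_ca[as.character(residues$residue_id[std])]))
    stop("standard residue(s) without a C-alpha atom: ",
         paste(utils::head(residues$residue_id[std][
           no_ca[as.character(residues$residue_id[std])]], 5), collapse = ", "))

  structure(list(id = id, atoms = atoms[, c("residue_id", "chain", "resno",
                                            "insert", "aa", "elety", "elesy",
                                            "x", "y", "z", "o")],
                 residues = residues),
            class = "protein_structure")
}

# Minimal syntactic validation of ATOM/HETATM records so a corrupt line is
# reported by line number rather than silently mangled downstream.
.validate_pdb_lines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)) || any(!is.finite(coords)))
      stop("malformed PDB record at line ", i, ": unparseable coordinates")
  }
  invisible(TRUE)
}

#' Write a structure in PDB format
#'
#' Serializes a \code{protein_structure} back to PDB. Round-tripping through
#' \code{\link{read_structure}} preserves atom counts, residue order and
#' coordinates to 3 decimals.
#'
#' @param structure A \code{protein_structure}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$aa, chain = a$chain,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   elety = a$elety, elesy = a$elesy,
                   eleno = seq_len(nrow(a)), o = a$o, b = rep(0, nrow(a)),
                   end = TRUE)
  invisible(file)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "': ", nrow(x$residues), " residues in ",
      length(unique(x$residues$chain)), " chain(s), ", nrow(x$atoms),
      " heavy atoms\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A \code{protein_structure}.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

# One representative coordinate per residue. mode "CA" takes the C-alpha;
# mode "CB" takes the C-beta, falling back to C-alpha for glycine or when
# C-beta is absent. Residues with neither atom get NA rows.
residue_coords <- function(structure, mode = c("CA", "CB")) {
  mode <- match.arg(mode)
  a <- structure$atoms
  res <- structure$residues
  out <- matrix(NA_real_, nrow = nrow(res), ncol = 3,
                dimnames = list(res$residue_id, c("x", "y", "z")))
  pick <- function(names_wanted) {
    sel <- a[a$elety %in% names_wanted, ]
    sel[!duplicated(sel$residue_id), ]
  }
  if (mode == "CA") {
    ca <- pick("CA")
    out[match(ca$residue_id, res$residue_id), ] <-
      as.matrix(ca[, c("x", "y", "z")])
  } else {
    cb <- pick("CB")
    out[match(cb$residue_id, res$residue_id), ] <-
      as.matrix(cb[, c("x", "y", "z")])
    missing <- res$residue_id[!(res$residue_id %in% cb$residue_id)]
    if (length(missing)) {
      ca <- pick("CA")
      ca <- ca[ca$residue_id %in% missing, ]
      out[match(ca$residue_id, res$residue_id), ] <-
        as.matrix(ca[, c("x", "y", "z")])
    }
  }
  out
}
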