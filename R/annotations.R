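#' Reduce 8-state DSSP codes to 3 states
#'
#' Maps DSSP secondary-structure codes to the 3-state alphabet used
#' throughout: helices \code{H, G, I} become \code{H}; strands/bridges
#' \code{E, B} become \code{E}; everything else (turn, bend, blank) is coil
#' \code{C}.
#'
#' @param codes Character vector of single-letter DSSP codes (blanks allowed).
#' @return Character vector over \code{{"H","E","C"}}.
#' @export
reduce_sse <- function(codes) {
  codes <- toupper(trimws(codes))
  out <- rep("C", length(codes))
  out[codes %in% c("H", "G", "I")] <- "H"
  out[codes %in% c("E", "B")] <- "E"
  out
}

#' Read secondary structure from classic DSSP output
#'
#' Parses the fixed-column residue block of a classic DSSP text file and maps
#' each line onto the residues of \code{structure} by chain, author residue
#' number and insertion code. The 8-state annotation is reduced to 3 states
#' via \code{\link{reduce_sse}}. Structure residues absent from the DSSP file
#' default to coil \code{C}; DSSP lines that do not map onto the structure
#' are skipped with a warning.
#'
#' @param source Path to a DSSP file or DSSP-format text.
#' @param structure A \code{protein_structure}.
#' @return Character vector of 3-state codes, one per structure residue (in
#'   \code{structure$residues} order).
#' @export
read_dssp_annotation <- function(source, structure) {
  stopifnot(inherits(structure, "protein_structure"))
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1)
    stop("not a classic DSSP file: residue header line not found")
  body <- lines[seq(hdr + 1, length(lines))]
  body <- body[nchar(body) >= 17]

  res <- structure$residues
  sse3 <- rep("C", nrow(res))
  key <- paste(res$chain, res$resno, res$insert, sep = "|")

  n_unmapped <- 0
  for (ln in body) {
    aa1 <- substr(ln, 14, 14)
    if (aa1 == "!" || aa1 == " ") next  # chain break
    resno <- suppressWarnings(as.integer(trimws(substr(ln, 6, 10))))
    icode <- trimws(substr(ln, 11, 11))
    chain <- substr(ln, 12, 12)
    ss <- substr(ln, 17, 17)
    if (is.na(resno)) next
    i <- match(paste(chain, resno, icode, sep = "|"), key)
    if (is.na(i)) {
      n_unmapped <- n_unmapped + 1
      next
    }
    sse3[i] <- reduce_sse(ss)
  }
  if (n_unmapped > 0)
    warning(n_unmapped, " DSSP line(s) did not map onto the structure and ",
            "were skipped")
  sse3
}

#' Read Start2Fold-style EFR annotations from JSON
#'
#' Reads a JSON file listing, per protein entry, its identifiers and the set
#' of residue numbers annotated as early folding residues (EFR). Accepts a
#' top-level array of entries or an object with an \code{entries} array. Each
#' entry may carry \code{protein}, \code{start2fold_id}, \code{pdb_id},
#' \code{chain}, \code{uniprot_id}, a declared EFR count \code{n_efr}, the
#' residue-number list \code{efr_residues}, and an optional declared
#' \code{residue_range} \code{[from, to]}. When a declared count is present
#' it must equal the size of the parsed residue set.
#'
#' @param source Path to a JSON file or JSON text.
#' @return A data frame with one row per entry (file order): identifier
#'   columns, \code{n_efr}, \code{range_start}, \code{range_end}, and a list
#'   column \code{efr_residues} of integer vectors.
#' @export
read_start2fold_json <- function(source) {
  if (length(source) == 1 && !grepl("[{\\[]", source) && file.exists(source)) {
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    txt <- paste(source, collapse = "\n")
  }
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.null(parsed$entries)) parsed <- parsed$entries
  if (length(parsed) == 0) stop("no entries in Start2Fold JSON")

  one <- function(e, k) {
    entry_name <- if (!is.null(e$protein)) e$protein
                  else if (!is.null(e$start2fold_id)) e$start2fold_id
                  else paste0("entry ", k)
    resn <- sort(unique(as.integer(unlist(e$efr_residues))))
    if (!is.null(e$n_efr) && as.integer(e$n_efr) != length(resn))
      stop("integrity error in '", entry_name, "': declared EFR count ",
           e$n_efr, " but ", length(resn), " residue numbers listed")
    rng <- if (!is.null(e$residue_range)) as.integer(unlist(e$residue_range))
           else c(NA_integer_, NA_integer_)
    data.frame(
      protein = if (!is.null(e$protein)) e$protein else NA_character_,
      start2fold_id = if (!is.null(e$start2fold_id)) e$start2fold_id
                      else NA_character_,
      pdb_id = if (!is.null(e$pdb_id)) e$pdb_id else NA_character_,
      chain = if (!is.null(e$chain)) e$chain else NA_character_,
      uniprot_id = if (!is.null(e$uniprot_id)) e$uniprot_id else NA_character_,
      n_efr = length(resn),
      range_start = rng[1], range_end = rng[2],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(seq_along(parsed),
                               function(k) one(parsed[[k]], k)))
  out$efr_residues <- lapply(parsed, function(e)
    sort(unique(as.integer(unlist(e$efr_residues)))))
  rownames(out) <- NULL
  out
}

#' Attach EFR and functional labels to a structure
#'
#' Builds the per-residue annotation table: residues whose author number is
#' listed in \code{efr} are labeled \code{EARLY} (all others \code{LATE});
#' residues listed in \code{functional} get \code{functional = TRUE}.
#' Residue numbers refer to author numbering of one chain. If more than 10
#' percent of the provided numbers cannot be matched, a mapping error is
#' raised (a likely numbering-scheme mismatch); smaller mismatches are
#' reported via a warning and an attribute.
#'
#' @param structure A \code{protein_structure}.
#' @param efr Integer vector of author residue numbers annotated EFR.
#' @param functional Integer vector of author residue numbers annotated
#'   functional.
#' @param chain Chain identifier the numbers refer to; defaults to the first
#'   chain.
#' @param sse3 Optional 3-state secondary structure per residue.
#' @param efoldmine Optional per-residue EFoldMine scores in [0,1].
#' @param conservation Optional per-residue conservation scores.
#' @return A data frame (class \code{residue_annotations}) with one row per
#'   residue: identifiers plus \code{folding_class}, \code{functional}, and
#'   any optional columns. Attribute \code{unmatched} lists unmatched input
#'   numbers.
#' @export
attach_annotations <- function(structure, efr = integer(), functional = integer(),
                               chain = NULL, sse3 = NULL, efoldmine = NULL,
                               conservation = NULL) {
  stopifnot(inherits(structure, "protein_structure"))
  res <- structure$residues
  if (is.null(chain)) chain <- res$chain[1]
  efr <- unique(as.integer(efr))
  functional <- unique(as.integer(functional))

  in_chain <- res$chain == chain
  match_numbers <- function(nums) {
    hit <- in_chain & res$resno %in% nums
    unmatched <- setdiff(nums, res$resno[in_chain])
    list(hit = hit, unmatched = unmatched)
  }
  m_efr <- match_numbers(efr)
  m_fun <- match_numbers(functional)
  n_given <- length(efr) + length(functional)
  n_unmatched <- length(m_efr$unmatched) + length(m_fun$unmatched)
  if (n_given > 0 && n_unmatched / n_given > 0.10)
    stop("mapping error: ", n_unmatched, " of ", n_given,
         " annotation residue numbers not found in chain '", chain,
         "' (possible numbering-scheme mismatch)")
  if (n_unmatched > 0)
    warning(n_unmatched, " annotation residue number(s) unmatched: ",
            paste(c(m_efr$unmatched, m_fun$unmatched), collapse = ", "))

  ann <- data.frame(
    residue_id = res$residue_id, chain = res$chain, resno = res$resno,
    insert = res$insert, seq_index = res$seq_index, aa = res$aa,
    folding_class = ifelse(m_efr$hit, "EARLY", "LATE"),
    functional = m_fun$hit,
    stringsAsFactors = FALSE
  )
  if (!is.null(sse3)) {
    stopifnot(length(sse3) == nrow(res))
    ann$sse3 <- sse3
  }
  if (!is.null(efoldmine)) {
    stopifnot(length(efoldmine) == nrow(res))
    ann$efoldmine_score <- efoldmine
  }
  if (!is.null(conservation)) {
    stopifnot(length(conservation) == nrow(res))
    ann$conservation <- conservation
  }
  attr(ann, "unmatched") <- c(m_efr$unmatched, m_fun$unmatched)
  class(ann) <- c("residue_annotations", class(ann))
  ann
}

#' Classify residues as early/late folding from predictor scores
#'
#' Applies the published decision threshold to per-residue EFR propensity
#' scores: scores strictly exceeding the threshold are classified
#' \code{EARLY}, all others \code{LATE}. The default threshold 0.163 is the
#' published optimum for separating early from late folding residues.
#'
#' @param scores Numeric vector of per-residue scores in [0,1].
#' @param threshold Decision threshold (default 0.163); classification is
#'   strict (\code{score > threshold}).
#' @return Character vector over \code{{"EARLY","LATE"}}.
#' @export
apply_efoldmine_threshold <- function(scores, threshold = 0.163) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must be finite and within [0, 1]")
  ifelse(scores > threshold, "EARLY", "LATE")
}
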