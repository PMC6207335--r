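#' Derive the inverse-Boltzmann pseudo-energy table
#'
#' From a reference set of structures, counts how often each amino acid
#' occurs buried versus exposed to the solvent (burial: RASA strictly below
#' \code{burial_threshold}) and converts the ratio into a pseudo-energy via
#' the inverse Boltzmann relation \code{e(a) = -ln((n_buried + 1) /
#' (n_exposed + 1))} (add-one pseudocount; kT folded into the unit, so
#' energies are dimensionless). Hydrophobic amino acids, which prefer the
#' buried state, receive negative energies.
#'
#' @param reference List of \code{protein_structure} objects (or a single
#'   structure). At least ~200 residues covering the 20 amino acids are
#'   recommended, otherwise pseudocounts dominate.
#' @param probe,n_points Passed to \code{\link{shrake_rupley}}.
#' @param burial_threshold RASA burial cutoff (default 0.16).
#' @return An object of class \code{pseudo_energy_table}: data frame with
#'   \code{aa}, \code{n_buried}, \code{n_exposed}, \code{f_buried},
#'   \code{f_exposed}, \code{e}; attributes record \code{n_total} and the
#'   parameters.
#' @export
derive_pseudo_energy_table <- function(reference, probe = 1.4,
                                       n_points = 960,
                                       burial_threshold = 0.16) {
  if (inherits(reference, "protein_structure")) reference <- list(reference)
  stopifnot(length(reference) >= 1)

  n_buried <- stats::setNames(integer(20), AA_STANDARD)
  n_exposed <- stats::setNames(integer(20), AA_STANDARD)
  n_total <- 0L
  for (s in reference) {
    asa <- shrake_rupley(s, probe = probe, n_points = n_points,
                         burial_threshold = burial_threshold)
    aa <- s$residues$aa
    ok <- aa %in% AA_STANDARD & !is.na(asa$residues$buried)
    tb <- table(factor(aa[ok & asa$residues$buried], levels = AA_STANDARD))
    te <- table(factor(aa[ok & !asa$residues$buried], levels = AA_STANDARD))
    n_buried <- n_buried + as.integer(tb)
    n_exposed <- n_exposed + as.integer(te)
    n_total <- n_total + sum(ok)
  }
  absent <- (n_buried + n_exposed) == 0
  if (any(absent))
    warning("amino acid(s) absent from the reference set (pseudocounts ",
            "only): ", paste(AA_STANDARD[absent], collapse = ", "))

  f_b <- (n_buried + 1) / (n_buried + n_exposed + 2)
  tab <- data.frame(
    aa = AA_STANDARD,
    n_buried = unname(n_buried), n_exposed = unname(n_exposed),
    f_buried = unname(f_b), f_exposed = unname(1 - f_b),
    e = unname(-log((n_buried + 1) / (n_exposed + 1))),
    stringsAsFactors = FALSE
  )
  attr(tab, "n_total") <- n_total
  attr(tab, "burial_threshold") <- burial_threshold
  class(tab) <- c("pseudo_energy_table", class(tab))
  tab
}

#' Pseudo-energy for given buried/exposed counts
#'
#' The elementary inverse-Boltzmann conversion used by
#' \code{\link{derive_pseudo_energy_table}}, exposed for direct use:
#' \code{-ln((n_buried + 1) / (n_exposed + 1))}.
#'
#' @param n_buried,n_exposed Non-negative counts.
#' @return Pseudo-energy (dimensionless).
#' @export
pseudo_energy <- function(n_buried, n_exposed) {
  stopifnot(all(n_buried >= 0), all(n_exposed >= 0))
  -log((n_buried + 1) / (n_exposed + 1))
}

#' Serialize / read a pseudo-energy table as JSON
#'
#' @param table A \code{pseudo_energy_table}.
#' @param file Output (or input) path.
#' @return \code{write_energy_table}: the path, invisibly.
#'   \code{read_energy_table}: the table.
#' @export
write_energy_table <- function(table, file) {
  payload <- list(
    n_total = attr(table, "n_total"),
    burial_threshold = attr(table, "burial_threshold"),
    entries = as.data.frame(table)
  )
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(file) {
  payload <- jsonlite::fromJSON(file)
  tab <- payload$entries
  attr(tab, "n_total") <- payload$n_total
  attr(tab, "burial_threshold") <- payload$burial_threshold
  class(tab) <- c("pseudo_energy_table", class(tab))
  tab
}

#' Compute the per-residue energy profile of a structure
#'
#' Represents the structure as a one-dimensional vector of energies: two
#' residues are in contact when their C-beta atoms (C-alpha for glycine) lie
#' strictly within \code{cutoff}; the energy of a residue is the sum of the
#' pseudo-energies of its contact partners (mode \code{"partner"}, default).
#' Mode \code{"pair"} adds the center residue's own pseudo-energy once per
#' contact, for sensitivity checks. Residues without contacts have energy 0;
#' \code{UNK} residues are excluded both as centers (energy \code{NA}) and
#' as partners.
#'
#' Low energies occur for residues stabilized by many (hydrophobic)
#' contacts.
#'
#' @param structure A \code{protein_structure}.
#' @param table A \code{pseudo_energy_table}.
#' @param cutoff C-beta contact cutoff in Angstrom (default 8, strict).
#' @param mode \code{"partner"} or \code{"pair"}.
#' @return Data frame with \code{residue_id}, \code{energy},
#'   \code{n_energy_contacts}.
#' @export
compute_energy_profile <- function(structure, table, cutoff = 8.0,
                                   mode = c("partner", "pair")) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "protein_structure"), cutoff > 0)
  res <- structure$residues
  e_of <- stats::setNames(table$e, table$aa)

  xyz <- residue_coords(structure, "CB")
  std <- res$aa %in% AA_STANDARD & stats::complete.cases(xyz)
  n <- nrow(res)
  energy <- rep(NA_real_, n)
  ncontacts <- rep(NA_integer_, n)

  idx <- which(std)
  if (length(idx) == 1) {
    energy[idx] <- 0
    ncontacts[idx] <- 0L
  } else if (length(idx) > 1) {
    d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
    for (k in seq_along(idx)) {
      partners <- idx[d[k, ] < cutoff & seq_along(idx) != k]
      ncontacts[idx[k]] <- length(partners)
      e_sum <- sum(e_of[res$aa[partners]])
      if (mode == "pair")
        e_sum <- e_sum + length(partners) * e_of[[res$aa[idx[k]]]]
      energy[idx[k]] <- e_sum
    }
  }
  data.frame(residue_id = res$residue_id, energy = energy,
             n_energy_contacts = ncontacts)
}
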