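#' Default run configuration
#'
#' All tunable parameters of the pipeline with their standard values:
#' contact cutoff 8 Angstrom (C-alpha graph, C-beta energy contacts), RASA
#' burial threshold 0.16, loop-fraction window 9, EFR score threshold
#' 0.163, hydrogen-bond cutoff 3.5 and hydrophobic cutoff 4.0 Angstrom,
#' partner-only energy summation, add-one pseudocount.
#'
#' @param ... Named overrides of individual fields.
#' @return Named list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    contact_cutoff = 8.0,
    contact_atom = "CA",
    burial_threshold = 0.16,
    loop_window = 9,
    efoldmine_threshold = 0.163,
    hbond_cutoff = 3.5,
    hydrophobic_cutoff = 4.0,
    energy_cutoff = 8.0,
    energy_mode = "partner",
    probe_radius = 1.4,
    asa_points = 960,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical JSON serialization; embedded in output files
#' so that runs with identical configuration are identifiable.
#'
#' @param config A \code{run_config}.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Compute the full per-residue feature table
#'
#' Runs every descriptor stage on one structure and joins the results into
#' the per-residue feature table: graph topology (betweenness, closeness,
#' clustering coefficient, distinct neighborhood count, local/tertiary
#' contacts), solvent accessibility (RASA, burial), loop fraction, centroid
#' and terminus distance, hydrogen-bond and hydrophobic counts, and the
#' energy profile. Annotations (folding class, functional flag, secondary
#' structure, optional scores) are merged when provided; without them every
#' residue defaults to \code{LATE} / non-functional.
#'
#' @param structure A \code{protein_structure}.
#' @param annotations Optional \code{residue_annotations} from
#'   \code{\link{attach_annotations}}.
#' @param energy_table Optional \code{pseudo_energy_table}; when missing,
#'   the table is derived from the structure itself (self-referential, fine
#'   for synthetic data; supply a reference-derived table for real use).
#' @param config A \code{run_config}.
#' @return Data frame with one row per residue and a fixed column order;
#'   attribute \code{config_hash} records the configuration digest.
#' @export
featurize <- function(structure, annotations = NULL, energy_table = NULL,
                      config = default_config()) {
  stopifnot(inherits(structure, "protein_structure"))
  res <- structure$residues

  if (is.null(annotations))
    annotations <- attach_annotations(structure)
  stopifnot(nrow(annotations) == nrow(res))

  graph <- build_residue_graph(structure, mode = config$contact_atom,
                               cutoff = config$contact_cutoff)
  nm <- network_metrics(graph)

  asa <- shrake_rupley(structure, probe = config$probe_radius,
                       n_points = config$asa_points,
                       burial_threshold = config$burial_threshold)

  sse3 <- if ("sse3" %in% names(annotations)) annotations$sse3
          else rep("C", nrow(res))
  loopf <- numeric(nrow(res))
  for (idx in split(seq_len(nrow(res)), res$chain))
    loopf[idx] <- loop_fraction(sse3[idx], window = config$loop_window)

  chain_len <- stats::ave(rep(1L, nrow(res)), res$chain, FUN = sum)
  term <- terminus_distance(res$seq_index, chain_len)

  cdist <- centroid_distance(structure)

  hb <- detect_hydrogen_bonds(structure, d_max = config$hbond_cutoff)
  hp <- detect_hydrophobic(structure, d_max = config$hydrophobic_cutoff)
  ic <- interaction_counts(structure, hb, hp)

  if (is.null(energy_table))
    energy_table <- derive_pseudo_energy_table(
      structure, probe = config$probe_radius, n_points = config$asa_points,
      burial_threshold = config$burial_threshold)
  ep <- compute_energy_profile(structure, energy_table,
                               cutoff = config$energy_cutoff,
                               mode = config$energy_mode)

  ft <- data.frame(
    structure_id = structure$id,
    chain = res$chain, resno = res$resno, insert = res$insert,
    seq_index = res$seq_index, aa = res$aa,
    folding_class = annotations$folding_class,
    functional = annotations$functional,
    sse3 = sse3,
    rasa = asa$residues$rasa,
    buried = asa$residues$buried,
    loop_fraction = loopf,
    centroid_distance = cdist,
    terminus_distance = term,
    betweenness = nm$betweenness,
    closeness = nm$closeness,
    clustering_coefficient = nm$clustering_coefficient,
    distinct_neighborhood_count = nm$distinct_neighborhood_count,
    contacts_total = nm$contacts_total,
    contacts_local = nm$contacts_local,
    contacts_tertiary = nm$contacts_tertiary,
    n_hbond = ic$n_hbond,
    n_hydrophobic = ic$n_hydrophobic,
    energy = ep$energy,
    stringsAsFactors = FALSE
  )
  if ("efoldmine_score" %in% names(annotations))
    ft$efoldmine_score <- annotations$efoldmine_score
  if ("conservation" %in% names(annotations))
    ft$conservation <- annotations$conservation
  attr(ft, "config_hash") <- config_hash(config)
  ft
}

# feature columns compared between groups by default
DEFAULT_COMPARE_FEATURES <- c(
  "rasa", "loop_fraction", "centroid_distance", "terminus_distance",
  "betweenness", "closeness", "clustering_coefficient",
  "distinct_neighborhood_count", "contacts_total", "contacts_local",
  "contacts_tertiary", "n_hbond", "n_hydrophobic", "energy"
)

#' Compare all features between residue groups
#'
#' Runs \code{\link{compare_feature}} for every feature column over both
#' groupings (EARLY vs LATE, functional vs non-functional) and collects one
#' row per (feature, grouping) with group means/SDs over all residues, the
#' all-residue p-value and the buried-subset p-value that determines
#' significance.
#'
#' @param table Residue feature table from \code{\link{featurize}}.
#' @param features Feature columns to compare (defaults to all standard
#'   descriptors present in the table).
#' @param groupings Character subset of
#'   \code{c("folding_class", "functional")}.
#' @return Data frame, one row per feature and grouping; groups that are
#'   empty in the buried subset yield \code{NA} p_buried and are flagged in
#'   \code{note}.
#' @export
compare_features <- function(table,
                             features = intersect(DEFAULT_COMPARE_FEATURES,
                                                  names(table)),
                             groupings = c("folding_class", "functional")) {
  if (nrow(table) == 0) stop("empty feature table")
  rows <- list()
  for (grouping in groupings) {
    for (f in features) {
      cmp <- tryCatch(compare_feature(table, f, grouping),
                      error = function(e) e)
      if (inherits(cmp, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, grouping = grouping, group1 = NA, group2 = NA,
          n1 = NA, n2 = NA, mean1 = NA, sd1 = NA, mean2 = NA, sd2 = NA,
          p_all = NA, p_buried = NA, test = NA, significant = NA,
          note = conditionMessage(cmp), stringsAsFactors = FALSE)
        next
      }
      g <- cmp$groups
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, grouping = grouping,
        group1 = g$group[1], group2 = g$group[2],
        n1 = g$n[1], n2 = g$n[2],
        mean1 = g$mean[1], sd1 = g$sd[1], mean2 = g$mean[2], sd2 = g$sd[2],
        p_all = cmp$p_all, p_buried = cmp$p_buried, test = cmp$test,
        significant = cmp$significant,
        note = if (cmp$p_buried_defined) "" else "empty buried group",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-structure and pooled label-overlap table
#'
#' For each structure in a feature table, counts EFR and functional labels
#' and their intersection and evaluates \code{\link{overlap_shift}}; a
#' pooled row aggregates all structures. Structures without any functional
#' annotation are excluded from shift computation and reported with
#' \code{NA} (dash) shifts.
#'
#' @param table Residue feature table (possibly several structures,
#'   distinguished by \code{structure_id}).
#' @return Data frame with columns \code{structure_id}, \code{N},
#'   \code{n_efr}, \code{n_functional}, \code{n_both},
#'   \code{observed_pct}, \code{expected_pct}, \code{shift_pct} (rounded
#'   to 2 decimals); last row \code{"pooled"}.
#' @export
overlap_table <- function(table) {
  stopifnot(all(c("structure_id", "folding_class", "functional") %in%
                names(table)))
  one <- function(sub, id) {
    N <- nrow(sub)
    n_e <- sum(sub$folding_class == "EARLY")
    n_f <- sum(sub$functional)
    n_b <- sum(sub$folding_class == "EARLY" & sub$functional)
    if (n_f == 0) {
      data.frame(structure_id = id, N = N, n_efr = n_e, n_functional = 0,
                 n_both = 0, observed_pct = NA_real_,
                 expected_pct = NA_real_, shift_pct = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ov <- overlap_shift(n_b, n_e, n_f, N)
      data.frame(structure_id = id, N = N, n_efr = n_e, n_functional = n_f,
                 n_both = n_b, observed_pct = round(ov$observed_pct, 2),
                 expected_pct = round(ov$expected_pct, 2),
                 shift_pct = round(ov$shift_pct, 2),
                 stringsAsFactors = FALSE)
    }
  }
  parts <- lapply(split(table, table$structure_id), function(sub)
    one(sub, sub$structure_id[1]))
  annotated <- table[stats::ave(table$functional, table$structure_id,
                         FUN = function(x) sum(x)) > 0, , drop = FALSE]
  out <- rbind(do.call(rbind, parts), one(annotated, "pooled"))
  rownames(out) <- NULL
  out
}

#' Write / read a feature or result table as CSV with a config hash
#'
#' The CSV carries a single comment line \code{# config_hash: <md5>} before
#' the header, so equal-config runs on equal inputs produce byte-identical
#' files.
#'
#' @param table Data frame to write.
#' @param file Path.
#' @param config Optional \code{run_config}; its hash (or the table's
#'   \code{config_hash} attribute) is embedded.
#' @return \code{write_result_csv}: the path, invisibly;
#'   \code{read_result_csv}: the data frame with attribute
#'   \code{config_hash}.
#' @export
write_result_csv <- function(table, file, config = NULL) {
  hash <- if (!is.null(config)) config_hash(config)
          else attr(table, "config_hash")
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(file) {
  first <- readLines(file, n = 1)
  hash <- NULL
  if (startsWith(first, "# config_hash: "))
    hash <- sub("^# config_hash: ", "", first)
  out <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "config_hash") <- hash
  out
}
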