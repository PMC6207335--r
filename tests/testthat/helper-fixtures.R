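# Fixtures and independent oracles shared across test files. Everything is
# generated in code; expensive synthetic structures are cached for the
# duration of one test run.

pdb_atom_line <- function(serial, name, alt, resname, chain, resno, icode,
                          x, y, z, occ = 1, elem = substr(name, 1, 1)) {
  name_field <- if (nchar(name) < 4) sprintf(" %-3s", name)
                else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, alt, resname, chain, resno, icode,
          x, y, z, occ, 0, elem)
}

# minimal 3-residue single-chain PDB text (backbone only)
pdb_three_residues <- function() {
  lines <- c(
    pdb_atom_line(1, "N", " ", "ALA", "A", 1, " ", 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 1, " ", 1.5, 0.0, 0.0),
    pdb_atom_line(3, "C", " ", "ALA", "A", 1, " ", 2.0, 1.4, 0.0),
    pdb_atom_line(4, "O", " ", "ALA", "A", 1, " ", 1.5, 2.5, 0.0),
    pdb_atom_line(5, "N", " ", "GLY", "A", 2, " ", 3.3, 1.4, 0.0),
    pdb_atom_line(6, "CA", " ", "GLY", "A", 2, " ", 4.0, 2.6, 0.3),
    pdb_atom_line(7, "C", " ", "GLY", "A", 2, " ", 5.5, 2.4, 0.3),
    pdb_atom_line(8, "O", " ", "GLY", "A", 2, " ", 6.0, 1.3, 0.3),
    pdb_atom_line(9, "N", " ", "LEU", "A", 3, " ", 6.2, 3.5, 0.5),
    pdb_atom_line(10, "CA", " ", "LEU", "A", 3, " ", 7.7, 3.5, 0.5),
    pdb_atom_line(11, "C", " ", "LEU", "A", 3, " ", 8.3, 4.9, 0.6),
    pdb_atom_line(12, "O", " ", "LEU", "A", 3, " ", 7.6, 5.9, 0.6),
    "END")
  paste(lines, collapse = "\n")
}

# a bare-CA synthetic structure from a coordinate matrix (one chain)
ca_structure <- function(coords, aa = "ALA", chain = "A", id = "ca_toy") {
  n <- nrow(coords)
  atoms <- data.frame(
    residue_id = seq_len(n), chain = chain, resno = seq_len(n), insert = "",
    aa = rep(aa, length.out = n), elety = "CA", elesy = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], o = 1,
    stringsAsFactors = FALSE)
  residues <- data.frame(
    residue_id = seq_len(n), chain = chain, resno = seq_len(n), insert = "",
    aa = rep(aa, length.out = n), seq_index = seq_len(n) - 1L,
    stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms, residues = residues),
            class = "protein_structure")
}

# build a residue_graph directly from an adjacency matrix (nodes are one
# chain with consecutive seq_index, so local/tertiary labels follow the
# sequence-separation rule)
graph_from_adjacency <- function(adj) {
  n <- nrow(adj)
  nodes <- data.frame(
    residue_id = seq_len(n), chain = "A", resno = seq_len(n), insert = "",
    aa = "ALA", seq_index = seq_len(n) - 1L, stringsAsFactors = FALSE)
  hit <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = hit[, 1], to = hit[, 2],
                      distance = 1,
                      label = ifelse(hit[, 2] - hit[, 1] <= 5, "local",
                                     "tertiary"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, mode = "CA", cutoff = 8),
            class = "residue_graph")
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj + t(adj)
}

# --- independent brute-force oracles (Floyd-Warshall + explicit shortest
# path counting; no igraph) --------------------------------------------------

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k] + d[k, ]
      upd <- dk < d[i, ]
      d[i, upd] <- dk[upd]
    }
  }
  d
}

oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t])
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[v, reach])
  }, numeric(1))
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
}

oracle_dnc <- function(adj, v) {
  nb <- which(adj[v, ] == 1)
  if (length(nb) == 0) return(0L)
  # local edges among neighbors: adjacency restricted to pairs with
  # sequence separation <= 5 (node index = seq position + 1)
  groups <- as.list(nb)
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (i > length(groups)) break
      j <- i + 1
      while (j <= length(groups)) {
        link <- any(outer(groups[[i]], groups[[j]], function(a, b)
          adj[cbind(a, b)] == 1 & abs(a - b) <= 5))
        if (link) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1
      }
    }
  }
  length(groups)
}

# Mann-Whitney exact two-sided p by full enumeration of group assignments
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# --- cached synthetic fixtures ----------------------------------------------

.fixtures <- new.env(parent = emptyenv())

shared_globules <- function() {
  if (is.null(.fixtures$globules)) {
    .fixtures$globules <- lapply(c(5, 6, 7), function(sd)
      assemble_globule(globule_spec(n_residues = 100, seed = sd)))
  }
  .fixtures$globules
}

shared_energy_table <- function() {
  if (is.null(.fixtures$etab)) {
    .fixtures$etab <- suppressWarnings(derive_pseudo_energy_table(
      lapply(shared_globules(), `[[`, "structure")))
  }
  .fixtures$etab
}

# feature tables of the shared globules with burial-planted labels: early
# folding residues are the buried core, functional residues a sample of the
# exposed surface
shared_features <- function() {
  if (is.null(.fixtures$features)) {
    tabs <- lapply(seq_along(shared_globules()), function(k) {
      g <- shared_globules()[[k]]
      ann <- attach_annotations(g$structure, sse3 = g$sse3)
      ft <- featurize(g$structure, ann, energy_table = shared_energy_table())
      set.seed(1000 + k)
      ft$folding_class <- ifelse(ft$buried, "EARLY", "LATE")
      ft$functional <- !ft$buried & stats::runif(nrow(ft)) < 0.25
      ft
    })
    .fixtures$features <- do.call(rbind, tabs)
  }
  .fixtures$features
}
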