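test_that("contact edges follow the strict 8 A rule plus covalent adjacency", {
  # collinear CA at 0, 5, 10 A: (1,2) and (2,3) only, both local
  st <- ca_structure(cbind(c(0, 5, 10), 0, 0))
  g <- build_residue_graph(st)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$from, c(1, 2))
  expect_equal(g$edges$to, c(2, 3))
  expect_true(all(g$edges$label == "local"))

  # exactly 8.0 A between sequence-distant residues: no edge (strict <);
  # nudge inside the cutoff: tertiary edge appears. The rest of the chain
  # is spread far apart so only the pair under test matters.
  mk <- function(d) {
    coords <- cbind(seq(0, by = 20, length.out = 10), 0, 0)
    coords[8, ] <- c(0, d, 0)
    ca_structure(coords)
  }
  g8 <- build_residue_graph(mk(8.0))
  expect_false(any(g8$edges$from == 1 & g8$edges$to == 8 &
                     g8$edges$distance > 7))
  g79 <- build_residue_graph(mk(7.99))
  hit <- g79$edges[g79$edges$from == 1 & g79$edges$to == 8, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$label, "tertiary")

  # covalent neighbors are edges even when farther than the cutoff
  stretch <- ca_structure(cbind(c(0, 9, 18), 0, 0))
  gs <- build_residue_graph(stretch)
  expect_equal(nrow(gs$edges), 2)
  expect_true(all(gs$edges$label == "local"))
})

test_that("sequence separation classifies local vs tertiary at the 5/6 boundary", {
  expect_equal(classify_edge(0, 5), "local")
  expect_equal(classify_edge(0, 6), "tertiary")
  expect_equal(classify_edge(3, 4), "local")
  expect_equal(classify_edge(1, 2, same_chain = FALSE), "tertiary")
})

test_that("the edge set of a random-walk chain matches an all-pairs check", {
  ch <- make_coil(20, seed = 3)
  g <- build_residue_graph(ch)
  ca <- as.matrix(ch$atoms[ch$atoms$elety == "CA", c("x", "y", "z")])
  d <- as.matrix(dist(ca))
  expected <- (d < 8) | (abs(row(d) - col(d)) == 1)
  expected <- expected & upper.tri(d)
  got <- matrix(FALSE, 20, 20)
  got[cbind(g$edges$from, g$edges$to)] <- TRUE
  expect_equal(got, expected, ignore_attr = TRUE)
  # labels consistent with separation
  sep <- abs(g$edges$from - g$edges$to)
  expect_true(all((g$edges$label == "local") == (sep <= 5)))
})

test_that("betweenness and closeness reproduce hand-computed small cases", {
  path3 <- graph_from_adjacency(matrix(c(0, 1, 0,
                                         1, 0, 1,
                                         0, 1, 0), 3, 3, byrow = TRUE))
  m <- network_metrics(path3)
  expect_equal(m$betweenness, c(0, 1, 0))
  expect_equal(m$closeness, c(2 / 3, 1, 2 / 3))

  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  m4 <- network_metrics(k4)
  expect_equal(m4$betweenness, rep(0, 4))
  expect_equal(m4$closeness, rep(1, 4))
  expect_equal(m4$clustering_coefficient, rep(1, 4))

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  ms <- network_metrics(graph_from_adjacency(star))
  expect_equal(ms$clustering_coefficient[1], 0)
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(6:25, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.45))
    g <- graph_from_adjacency(adj)
    m <- network_metrics(g)
    expect_equal(m$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    expect_equal(m$closeness, oracle_closeness(adj), tolerance = 1e-9)
    expect_equal(m$clustering_coefficient, oracle_clustering(adj),
                 tolerance = 1e-9)
  }
})

test_that("distinct neighborhood count separates sequence-remote contact groups", {
  # v = node 10 contacts {9, 11} (one merged local group via edge 9-11) in a
  # 22-node chain backbone
  n <- 22
  chain <- matrix(0, n, n)
  for (i in seq_len(n - 1)) chain[i, i + 1] <- chain[i + 1, i] <- 1
  adj <- chain
  adj[9, 11] <- adj[11, 9] <- 1
  g <- graph_from_adjacency(adj)
  expect_equal(distinct_neighborhood_count(g, 10), 1L)

  # v adjacent to two sequence-remote residues with no edge between them
  adj2 <- matrix(0, n, n)
  adj2[10, 2] <- adj2[2, 10] <- 1
  adj2[10, 20] <- adj2[20, 10] <- 1
  g2 <- graph_from_adjacency(adj2)
  expect_equal(distinct_neighborhood_count(g2, 10), 2L)

  # folded chain: v contacts {v-2..v+2} (mutually connected, as helical
  # geometry implies) plus a remote pair {k, k+1}
  adj3 <- chain
  v <- 5; k <- 18
  for (j in c(v - 2, v + 2)) adj3[v, j] <- adj3[j, v] <- 1
  adj3[v - 1, v + 1] <- adj3[v + 1, v - 1] <- 1
  adj3[v, k] <- adj3[k, v] <- 1
  adj3[v, k + 1] <- adj3[k + 1, v] <- 1
  g3 <- graph_from_adjacency(adj3)
  expect_equal(distinct_neighborhood_count(g3, v), 2L)
})

test_that("distinct neighborhood count matches enumeration and its bounds", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(8:24, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.4))
    g <- graph_from_adjacency(adj)
    for (v in seq_len(n)) {
      got <- distinct_neighborhood_count(g, v)
      expect_equal(got, oracle_dnc(adj, v),
                   info = sprintf("n=%d v=%d", n, v))
      expect_lte(got, sum(adj[v, ]))
    }
  }
})

test_that("an extended chain gives one distinct neighborhood per interior residue", {
  st <- make_strand(20)
  g <- build_residue_graph(st)
  expect_equal(sum(g$edges$label == "tertiary"), 0)
  dnc <- vapply(2:19, function(v) distinct_neighborhood_count(g, v),
                integer(1))
  expect_true(all(dnc == 1))
})

test_that("contact counts split into local plus tertiary consistently", {
  g <- build_residue_graph(shared_globules()[[1]]$structure)
  m <- network_metrics(g)
  expect_equal(m$contacts_total, m$contacts_local + m$contacts_tertiary)
  expect_equal(sum(m$contacts_total), 2 * nrow(g$edges))
  expect_true(all(m$clustering_coefficient >= 0 &
                    m$clustering_coefficient <= 1))
})
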