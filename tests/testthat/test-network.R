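test_that("web-of-life reader preserves labels, binarizes and prunes", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(c(2, 1, 5, 1, 3, 0, 1, 0, 0), 3, byrow = TRUE,
              dimnames = list(paste0("Plant", 1:3), paste0("Bee", 1:3)))
  write.csv(as.data.frame(m), path)
  net <- read_web_of_life(path)
  expect_s3_class(net, "pp_network")
  expect_equal(net$plant_labels, paste0("Plant", 1:3))
  expect_equal(unname(species_degrees(net)), c(3, 2, 1, 3, 2, 1))
  expect_true(all(net$incidence %in% c(0, 1)))

  # all-zero column dropped with a warning, S_A decremented
  m2 <- cbind(m, Bee4 = 0)
  write.csv(as.data.frame(m2), path)
  expect_warning(net2 <- read_web_of_life(path), "Dropping")
  expect_equal(n_animals(net2), 3)

  # non-numeric body cell names the offender
  m3 <- as.data.frame(m)
  m3$Bee1 <- c("x", 1, 1)
  write.csv(m3, path)
  expect_error(read_web_of_life(path), "Plant1.*Bee1")

  # empty after pruning
  write.csv(data.frame(A = c(0, 0), row.names = c("p1", "p2")), path)
  expect_error(suppressWarnings(read_web_of_life(path)), "empty")
})

test_that("round trip through web-of-life CSV preserves the matrix", {
  net <- tri_net()
  path <- withr::local_tempfile(fileext = ".csv")
  write_web_of_life(net, path)
  back <- read_web_of_life(path, binarize = FALSE)
  expect_equal(back$incidence, net$incidence)
})

test_that("connectance honours both denominator conventions", {
  all1 <- bipartite_network(matrix(1, 3, 3))
  expect_equal(connectance(all1), 1)
  expect_equal(connectance(all1, "all_species_squared"), 9 / 36)
  # a single-link 2x2 prunes to 1x1; padding keeps the link count at 1
  m <- matrix(0, 2, 2)
  m[1, 1] <- 1
  expect_warning(net <- bipartite_network(m), "Dropping")
  expect_equal(n_links(net), 1)
  # unpruned 2x2 values computed directly from the formulas
  expect_equal(1 / (2 * 2), 0.25)
  expect_equal(1 / (2 + 2)^2, 1 / 16)
})

test_that("NODF scores nested and anti-nested archetypes correctly", {
  expect_equal(nodf(tri_net()), 1)
  expect_equal(nodf(diag(3)), 0) # equal marginals: decreasing-fill fails
  expect_warning(v <- nodf(matrix(1, 1, 3)), "undefined")
  expect_equal(v, 0)
})

test_that("NODF matches vegan and is permutation invariant", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rbinom(80, 1, 0.45), 8, 10)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) < 2 || ncol(m) < 2) next
    expect_equal(nodf(m),
                 unname(vegan::nestednodf(m)$statistic["NODF"]) / 100,
                 tolerance = 1e-12)
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nodf(perm), nodf(m), tolerance = 1e-12)
  }
})

test_that("weighted NODF agrees with a literal pairwise oracle and vegan", {
  # independent loop-over-pairs reimplementation of the published rule
  wnodf_oracle <- function(m) {
    half <- function(mm) {
      fill <- rowSums(mm > 0)
      n <- nrow(mm)
      terms <- c()
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (fill[i] == fill[j]) {
            terms <- c(terms, 0)
          } else {
            hi <- if (fill[i] > fill[j]) i else j
            lo <- if (hi == i) j else i
            terms <- c(terms,
                       sum(mm[lo, ] > 0 & mm[hi, ] > mm[lo, ]) / fill[lo])
          }
        }
      }
      terms
    }
    mean(c(half(m), half(t(m))))
  }
  set.seed(21)
  for (i in 1:6) {
    m <- matrix(rpois(100, 1.2), 10, 10)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    expect_equal(weighted_nodf(m), wnodf_oracle(m), tolerance = 1e-12)
  }
  skip_if_not_installed("vegan")
  set.seed(22)
  m <- matrix(rpois(100, 1.5), 10, 10)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  expect_equal(weighted_nodf(m),
               unname(vegan::nestednodf(m, weighted = TRUE)$statistic["NODF"]) / 100,
               tolerance = 1e-12)
})

test_that("weighted NODF handles binary fallback and nested weights", {
  expect_warning(v <- weighted_nodf(tri_net()), "falls back")
  expect_equal(v, nodf(tri_net()))
  # strictly nested triangle with strictly decreasing weights
  w <- matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, byrow = TRUE)
  expect_equal(weighted_nodf(w), 1)
})

test_that("modularity separates blocks and sees none in a full graph", {
  two_blocks <- bipartite_network(rbind(
    cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
    cbind(matrix(0, 3, 3), matrix(1, 3, 3))
  ))
  expect_gt(network_modularity(two_blocks), 0.4)
  expect_lt(abs(network_modularity(bipartite_network(matrix(1, 4, 4)))), 0.05)
  # deterministic across calls
  net <- ensemble_fixture()[[3]]
  expect_identical(network_modularity(net), network_modularity(net))
})

test_that("betweenness matches an exhaustive shortest-path oracle", {
  bw_star <- species_betweenness(star_net(4))
  expect_gt(bw_star$betweenness[1], 0)
  expect_equal(bw_star$betweenness[-1], rep(0, 4))

  # path graph P4: plant1 - animal1 - plant2 - animal2
  p4 <- bipartite_network(matrix(c(1, 0, 1, 1), 2, byrow = TRUE))
  bw <- species_betweenness(p4) # order: P1, P2, A1, A2; middle = P2, A1
  expect_true(all(bw$betweenness[c(2, 3)] > bw$betweenness[c(1, 4)]))

  # 8-node toy graph vs brute-force pair counting over all shortest paths
  set.seed(8)
  m <- matrix(rbinom(16, 1, 0.6), 4, 4)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  net <- bipartite_network(m)
  got <- species_betweenness(net)$betweenness
  g <- igraph::graph_from_biadjacency_matrix((net$incidence > 0) * 1)
  n <- igraph::vcount(g)
  brute <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- igraph::all_shortest_paths(g, s, t)$res
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) setdiff(as.integer(p), c(s, t))))
      for (v in unique(inner)) {
        brute[v] <- brute[v] + sum(inner == v) / length(paths)
      }
    }
  }
  brute <- brute / ((n - 1) * (n - 2) / 2)
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("target selection follows degree, centrality and seeded strategies", {
  # degrees plants (3,2,1), animals (3,2,1): plant 1 ties animal 4 -> plant 1
  expect_identical(select_targets(tri_net(), "highest_degree"), 1L)
  net <- revival_fixture()
  top3 <- select_targets(net, "top_centrality", k = 3)
  bw <- species_betweenness(net)$betweenness
  expect_equal(bw[top3], sort(bw, decreasing = TRUE)[1:3])
  expect_identical(select_targets(net, "random", k = 2, seed = 9),
                   select_targets(net, "random", k = 2, seed = 9))
  expect_error(select_targets(net, "random", k = 0), "k")
})

test_that("degree vectors satisfy the bipartite handshake on the ensemble", {
  for (net in ensemble_fixture()) {
    expect_equal(sum(species_degrees(net)), 2 * n_links(net))
  }
})

test_that("network_metrics returns one tidy row per network", {
  tab <- suppressWarnings(network_metrics(ensemble_fixture()[1:2]))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("network_id", "connectance", "nodf", "wnodf",
                    "modularity", "median_betweenness") %in% names(tab)))
  expect_true(all(tab$nodf >= 0 & tab$nodf <= 1))
  expect_true(all(tab$connectance > 0 & tab$connectance <= 1))
})
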