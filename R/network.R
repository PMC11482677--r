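#' Bipartite plant-pollinator network
#'
#' Wraps a plants-by-animals incidence matrix with species labels. Entries may
#' be 0/1 presences or interaction counts; all structural metrics work on the
#' binarized view (`entry > 0`). Every species must have degree at least one:
#' all-zero rows/columns are pruned (with a warning) at construction so that
#' the degree trade-off `gamma0 / d_i` in the dynamical model is always
#' defined.
#'
#' @param incidence numeric matrix, rows = plants, columns = animals,
#'   non-negative entries.
#' @param plant_labels,animal_labels optional character vectors; taken from
#'   `dimnames(incidence)` or autogenerated (`P1..`, `A1..`) when missing.
#' @param provenance free-text source tag carried along in outputs.
#'
#' @return An object of class `pp_network` with elements `incidence`,
#'   `plant_labels`, `animal_labels`, `provenance`.
#' @examples
#' net <- bipartite_network(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, byrow = TRUE))
#' connectance(net)
#' nodf(net)
#' @export
bipartite_network <- function(incidence, plant_labels = NULL,
                              animal_labels = NULL, provenance = "in-memory") {
  incidence <- as.matrix(incidence)
  if (!is.numeric(incidence)) {
    abort("`incidence` must be a numeric matrix.")
  }
  if (anyNA(incidence) || any(incidence < 0)) {
    abort("`incidence` must be non-negative with no missing values.")
  }
  if (is.null(plant_labels)) {
    plant_labels <- rownames(incidence) %||% paste0("P", seq_len(nrow(incidence)))
  }
  if (is.null(animal_labels)) {
    animal_labels <- colnames(incidence) %||% paste0("A", seq_len(ncol(incidence)))
  }
  keep_r <- rowSums(incidence > 0) > 0
  keep_c <- colSums(incidence > 0) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn(sprintf(
      "Dropping %d plant(s) and %d animal(s) with no interactions.",
      sum(!keep_r), sum(!keep_c)
    ))
    incidence <- incidence[keep_r, keep_c, drop = FALSE]
    plant_labels <- plant_labels[keep_r]
    animal_labels <- animal_labels[keep_c]
  }
  if (nrow(incidence) < 1 || ncol(incidence) < 1) {
    abort("Network is empty after pruning zero-degree species.")
  }
  dimnames(incidence) <- list(plant_labels, animal_labels)
  structure(
    list(
      incidence = incidence,
      plant_labels = plant_labels,
      animal_labels = animal_labels,
      provenance = provenance
    ),
    class = "pp_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pp_network <- function(x, ...) {
  cat(sprintf(
    "<pp_network> %d plants x %d animals, %d links (connectance %.3f)\n",
    n_plants(x), n_animals(x), n_links(x), connectance(x)
  ))
  cat("source:", x$provenance, "\n")
  invisible(x)
}

#' @rdname bipartite_network
#' @param x a `pp_network`.
#' @export
n_plants <- function(x) nrow(x$incidence)

#' @rdname bipartite_network
#' @export
n_animals <- function(x) ncol(x$incidence)

#' @rdname bipartite_network
#' @export
n_species <- function(x) nrow(x$incidence) + ncol(x$incidence)

#' @rdname bipartite_network
#' @export
n_links <- function(x) sum(x$incidence > 0)

binary_matrix <- function(net) (net$incidence > 0) * 1

#' Species degrees
#'
#' Degree of every species, plants first then animals, named by label.
#'
#' @param net a `pp_network`.
#' @return Named integer vector of length `n_species(net)`.
#' @export
species_degrees <- function(net) {
  b <- binary_matrix(net)
  c(rowSums(b), colSums(b))
}

#' Long (edge list) view of a network
#'
#' @param x a `pp_network`.
#' @param ... unused.
#' @return A tibble with columns `plant`, `animal`, `weight` (one row per
#'   realized interaction).
#' @method as_tibble pp_network
#' @export
as_tibble.pp_network <- function(x, ...) {
  idx <- which(x$incidence > 0, arr.ind = TRUE)
  tibble(
    plant = x$plant_labels[idx[, 1]],
    animal = x$animal_labels[idx[, 2]],
    weight = x$incidence[idx]
  )
}

#' Read a web-of-life style incidence matrix
#'
#' Comma-separated layout with plant names in the first column and animal
#' names in the header row; the numeric body holds presences or visit counts.
#' Zero-degree rows and columns are pruned with a warning.
#'
#' @param path CSV file path.
#' @param binarize map positive counts to 1 (default `TRUE`).
#' @return A [bipartite_network()].
#' @export
read_web_of_life <- function(path, binarize = TRUE) {
  raw <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  bad <- which(!is.finite(suppressWarnings(array(as.numeric(m), dim(m)))), arr.ind = TRUE)
  if (length(bad)) {
    abort(sprintf(
      "Non-numeric entry at row '%s', column '%s' in %s.",
      rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]], path
    ))
  }
  storage.mode(m) <- "double"
  if (binarize) m <- (m > 0) * 1
  bipartite_network(m, provenance = basename(path))
}

#' Write a network in web-of-life CSV layout
#'
#' @param net a `pp_network`.
#' @param path output CSV path.
#' @export
write_web_of_life <- function(net, path) {
  write.csv(as.data.frame(net$incidence), path, row.names = TRUE)
  invisible(path)
}

#' Connectance
#'
#' Realized fraction of possible links. The bipartite convention divides the
#' link count by `S_P * S_A`; the alternative divides by the squared total
#' species count `(S_P + S_A)^2`. The bipartite product is the default: it is
#' the convention under which reported plant-pollinator connectances up to
#' ~0.6 are attainable (the squared-total denominator caps connectance at
#' 0.25 for a bipartite matrix).
#'
#' @param net a `pp_network`.
#' @param denominator `"bipartite_product"` (default) or
#'   `"all_species_squared"`.
#' @return A number in (0, 1].
#' @export
connectance <- function(net, denominator = c("bipartite_product",
                                             "all_species_squared")) {
  denominator <- match.arg(denominator)
  L <- n_links(net)
  switch(denominator,
    bipartite_product = L / (n_plants(net) * n_animals(net)),
    all_species_squared = L / (n_plants(net) + n_animals(net))^2
  )
}

# Paired-overlap nestedness terms for the rows of a binary matrix.
# For rows i, j the pair contributes overlap/fill_lo when fill_i != fill_j
# (decreasing-fill condition; ties contribute 0), fill_lo the smaller fill.
nodf_pair_sum <- function(b) {
  n <- nrow(b)
  if (n < 2) return(c(sum = 0, pairs = 0))
  f <- rowSums(b)
  ov <- tcrossprod(b) # shared partners for every row pair
  lo <- outer(f, f, pmin)
  contrib <- ifelse(outer(f, f, "!=") & lo > 0, ov / lo, 0)
  c(sum = sum(contrib[upper.tri(contrib)]), pairs = n * (n - 1) / 2)
}

#' Nestedness (NODF)
#'
#' Paired-overlap nestedness with the decreasing-fill condition, averaged over
#' all row pairs and all column pairs of the binarized matrix, on a 0-1 scale.
#' A strictly nested matrix scores 1; a matrix whose rows (and columns) all
#' have equal fill scores 0 because the decreasing-fill condition fails for
#' every pair.
#'
#' @param net a `pp_network` or a 0/1 matrix.
#' @return A number in \[0, 1\].
#' @export
nodf <- function(net) {
  b <- if (inherits(net, "pp_network")) binary_matrix(net) else (as.matrix(net) > 0) * 1
  if (nrow(b) < 2 || ncol(b) < 2) {
    warn("NODF is undefined for a 1 x n matrix; returning 0.")
    return(0)
  }
  r <- nodf_pair_sum(b)
  cl <- nodf_pair_sum(t(b))
  (r[["sum"]] + cl[["sum"]]) / (r[["pairs"]] + cl[["pairs"]])
}

wnodf_pair_sum <- function(m) {
  fill <- rowSums(m > 0)
  n <- nrow(m)
  if (n < 2) return(c(sum = 0, pairs = 0))
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      # decreasing-fill condition; equal fills contribute 0
      hi <- if (fill[i] > fill[j]) i else if (fill[j] > fill[i]) j else next
      lo <- if (hi == i) j else i
      k <- sum(m[lo, ] > 0 & m[lo, ] < m[hi, ])
      s <- s + k / fill[lo]
    }
  }
  c(sum = s, pairs = n * (n - 1) / 2)
}

#' Weighted nestedness (weighted NODF)
#'
#' Weighted counterpart of [nodf()]: for each decreasing-total pair the
#' contribution is the fraction of the lower row's (column's) occupied cells
#' whose weights are positive and strictly smaller than the corresponding
#' cells of the upper vector. On an all-binary matrix the strict inequality
#' never holds, so the function falls back to [nodf()] with a warning.
#'
#' @param net a `pp_network` or a non-negative matrix.
#' @return A number in \[0, 1\].
#' @export
weighted_nodf <- function(net) {
  m <- if (inherits(net, "pp_network")) net$incidence else as.matrix(net)
  if (all(m %in% c(0, 1))) {
    warn("Matrix is binary; weighted NODF falls back to NODF.")
    return(nodf(m))
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    warn("Weighted NODF is undefined for a 1 x n matrix; returning 0.")
    return(0)
  }
  r <- wnodf_pair_sum(m)
  cl <- wnodf_pair_sum(t(m))
  (r[["sum"]] + cl[["sum"]]) / (r[["pairs"]] + cl[["pairs"]])
}

as_igraph <- function(net) {
  b <- binary_matrix(net)
  igraph::graph_from_biadjacency_matrix(b)
}

#' Bipartite modularity
#'
#' Newman modularity of the best partition found by the (deterministic)
#' fast-greedy community-detection heuristic on the bipartite graph.
#'
#' @param net a `pp_network`.
#' @return Modularity of the detected partition.
#' @export
network_modularity <- function(net) {
  g <- as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g)
  igraph::modularity(cl)
}

#' Betweenness centrality per species
#'
#' Normalized shortest-path betweenness on the (unweighted) bipartite graph.
#'
#' @param net a `pp_network`.
#' @return A tibble with columns `species`, `guild`, `betweenness`, ordered
#'   plants first then animals.
#' @export
species_betweenness <- function(net) {
  g <- as_igraph(net)
  bw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  tibble(
    species = c(net$plant_labels, net$animal_labels),
    guild = rep(c("plant", "animal"), c(n_plants(net), n_animals(net))),
    betweenness = unname(bw)
  )
}

#' Choose species to perturb
#'
#' Selection strategies used by the revival protocols. Species indices count
#' plants first (1..S_P) then animals (S_P+1..S_P+S_A).
#'
#' * `highest_degree` - the single most-connected species; degree ties are
#'   broken by lowest index (plants before animals).
#' * `top_centrality` - the `k` species with the highest betweenness
#'   centrality, in descending order.
#' * `random` - `k` species drawn uniformly, reproducible from `seed`.
#'
#' @param net a `pp_network`.
#' @param strategy one of `"highest_degree"`, `"top_centrality"`, `"random"`.
#' @param k number of species for the latter two strategies (default 3 and 1).
#' @param seed RNG seed for `random`.
#' @return Integer vector of species indices.
#' @export
select_targets <- function(net, strategy = c("highest_degree", "top_centrality",
                                             "random"),
                           k = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  S <- n_species(net)
  if (strategy == "highest_degree") {
    d <- species_degrees(net)
    return(unname(which.max(d))) # first (lowest-index) maximum wins ties
  }
  if (strategy == "top_centrality") {
    k <- k %||% 3
    if (k <= 0 || k > S) abort("`k` must be in 1..n_species(net).")
    bw <- species_betweenness(net)$betweenness
    return(order(bw, decreasing = TRUE)[seq_len(k)])
  }
  k <- k %||% 1
  if (k <= 0 || k > S) abort("`k` must be in 1..n_species(net).")
  with_seed(seed, sample.int(S, k))
}

#' Structural metrics for a set of networks
#'
#' @param nets a `pp_network`, or a list of them, or a character vector of
#'   web-of-life CSV paths.
#' @param connectance_mode passed to [connectance()].
#' @return One tidy row per network: `network_id`, `s_plant`, `s_animal`,
#'   `links`, `connectance`, `nodf`, `wnodf`, `modularity`,
#'   `mean_betweenness`, `median_betweenness`.
#' @export
network_metrics <- function(nets, connectance_mode = "bipartite_product") {
  if (inherits(nets, "pp_network")) nets <- list(nets)
  if (is.character(nets)) nets <- lapply(nets, read_web_of_life)
  purrr::map_dfr(nets, function(net) {
    bw <- species_betweenness(net)$betweenness
    tibble(
      network_id = net$provenance,
      s_plant = n_plants(net),
      s_animal = n_animals(net),
      links = n_links(net),
      connectance = connectance(net, connectance_mode),
      nodf = nodf(net),
      wnodf = suppressWarnings(weighted_nodf(net)),
      modularity = network_modularity(net),
      mean_betweenness = mean(bw),
      median_betweenness = stats::median(bw)
    )
  })
}
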