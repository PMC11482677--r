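# Maximally nested template at a fixed fill: a staircase (Young-diagram)
# incidence with non-increasing row fills, adjusted to hit the exact link
# count while keeping every row and column occupied. Its NODF is the largest
# achievable by the swap tuner at this size and connectance (distinct fills
# are not always possible at a given fill, so the maximum can be < 1).
max_nested_matrix <- function(s_plant, s_animal, links) {
  if (links < s_animal + (s_plant - 1) || links > s_plant * s_animal) {
    abort("Link count infeasible: need S_A + S_P - 1 <= L <= S_P * S_A.")
  }
  k <- pmax(1, pmin(s_animal, s_animal - seq_len(s_plant) + 1))
  k[1] <- s_animal # keep all columns occupied
  diff <- links - sum(k)
  while (diff != 0) {
    if (diff > 0) {
      # top-most row that can grow while staying non-increasing
      i <- which(k < s_animal & k < c(s_animal + 1, k)[seq_len(s_plant)])[1]
      if (is.na(i)) i <- which(k < s_animal)[1]
      k[i] <- k[i] + 1
      diff <- diff - 1
    } else {
      cand <- which(k > 1 & k > c(k[-1], 0))
      cand <- cand[cand > 1] # never shrink row 1 below full
      i <- cand[length(cand)]
      k[i] <- k[i] - 1
      diff <- diff + 1
    }
  }
  m <- matrix(0, s_plant, s_animal)
  for (i in seq_len(s_plant)) m[i, seq_len(k[i])] <- 1
  m
}

#' Generate a bipartite network with target connectance and nestedness
#'
#' Starts from the maximally nested (staircase) matrix at the exact target
#' link count, then applies fill-preserving link moves, accepted only when
#' they bring NODF strictly closer to `nodf`, until the achieved NODF is
#' within `tol` of the target. Connectance is exact throughout; no row or
#' column is ever emptied. The largest achievable NODF at a given size and
#' fill can be below 1 (distinct row and column fills may be infeasible);
#' `nodf = "max"` returns the staircase template itself.
#'
#' @param s_plant,s_animal guild sizes.
#' @param connectance target connectance `L / (S_P * S_A)`.
#' @param nodf target NODF in \[0, 1\], or `"max"` for the most nested
#'   matrix at this fill.
#' @param tol acceptance tolerance on NODF (default 0.02).
#' @param max_iter maximum proposed moves (default 1e5).
#' @param seed RNG seed; identical spec + seed gives identical matrices.
#' @return A [bipartite_network()].
#' @export
generate_nested_network <- function(s_plant, s_animal, connectance,
                                    nodf = "max", tol = 0.02,
                                    max_iter = 1e5, seed = NULL) {
  if (connectance <= 0 || connectance > 1) {
    abort("`connectance` must lie in (0, 1].")
  }
  links <- round(connectance * s_plant * s_animal)
  m <- max_nested_matrix(s_plant, s_animal, links)
  if (identical(nodf, "max")) {
    return(bipartite_network(m, provenance = sprintf(
      "synthetic max-nested %dx%d C=%.3f", s_plant, s_animal, connectance
    )))
  }
  target <- nodf
  if (target < 0 || target > 1) abort("`nodf` target must lie in [0, 1].")
  current <- pollinet::nodf(m)
  best <- current
  with_seed(seed, {
    iter <- 0
    while (abs(current - target) > tol && iter < max_iter) {
      iter <- iter + 1
      filled <- which(m > 0)
      empty <- which(m == 0)
      if (!length(empty)) break
      from <- filled[sample.int(length(filled), 1)]
      to <- empty[sample.int(length(empty), 1)]
      fr <- (from - 1) %% s_plant + 1
      fc <- (from - 1) %/% s_plant + 1
      if (sum(m[fr, ]) <= 1 || sum(m[, fc]) <= 1) next
      m2 <- m
      m2[from] <- 0
      m2[to] <- 1
      cand <- pollinet::nodf(m2)
      if (abs(cand - target) < abs(current - target)) {
        m <- m2
        current <- cand
        best <- cand
      }
    }
  })
  if (abs(current - target) > tol) {
    abort(sprintf(
      "Could not reach NODF target %.3f within tolerance %.3f; best achieved %.3f.",
      target, tol, best
    ))
  }
  bipartite_network(m, provenance = sprintf(
    "synthetic nested %dx%d C=%.3f NODF=%.3f", s_plant, s_animal,
    connectance, current
  ))
}

#' Ensemble of synthetic networks spanning a nestedness range
#'
#' Generates `n` networks of fixed size and connectance whose NODF targets
#' are evenly spaced over `nodf_range`, capped at the maximum NODF achievable
#' at this size and fill (so a requested upper bound of 1 maps to the most
#' nested attainable matrix).
#'
#' @param n number of networks.
#' @param s_plant,s_animal,connectance as in [generate_nested_network()].
#' @param nodf_range length-2 numeric range of NODF targets.
#' @param seeds integer seeds, one per network (default `1:n`).
#' @param tol,max_iter passed to [generate_nested_network()].
#' @return A list of `pp_network` objects.
#' @export
generate_network_ensemble <- function(n = 10, s_plant = 15, s_animal = 15,
                                      connectance = 0.42,
                                      nodf_range = c(0.3, 1), seeds = seq_len(n),
                                      tol = 0.02, max_iter = 1e5) {
  top <- nodf(generate_nested_network(s_plant, s_animal, connectance, "max"))
  targets <- seq(nodf_range[1], min(nodf_range[2], top), length.out = n)
  purrr::map2(targets, seeds, function(tg, sd) {
    generate_nested_network(s_plant, s_animal, connectance, nodf = tg,
                            tol = tol, max_iter = max_iter, seed = sd)
  })
}

#' Synthetic restoration-survey visitation table
#'
#' Emulates a paired restoration design: two treatment sites (restored /
#' unrestored), `months` consecutive sampling months, `plots` independent
#' plots per site. Each plot-month yields a small plant-pollinator visit
#' network whose nestedness varies across plots and whose mean per-pollinator
#' visit count follows the planted linear relation
#' `intercept(treatment) + slope * NODF + noise`, with the restored intercept
#' at or above the unrestored one. Per-pollinator totals are drawn from an
#' overdispersed negative-binomial model (or taken deterministically when
#' `dispersion = NULL`) and spread multinomially over the pollinator's links.
#' Visitation rate is visits per observation hour.
#'
#' @param seed RNG seed.
#' @param months,plots design dimensions (default 8 x 8 per treatment).
#' @param slope planted NODF-visits slope.
#' @param intercepts named numeric, planted treatment intercepts.
#' @param noise_sd Gaussian noise on the planted plot-month mean.
#' @param dispersion negative-binomial size for visit counts; `NULL` for
#'   deterministic counts (no sampling noise).
#' @param s_plant,s_animal,connectance plot-network dimensions.
#' @param nodf_range range of per-plot NODF targets.
#' @param effort_hours observation effort converting visits to rates.
#' @return A tibble with columns `treatment`, `month`, `plot`, `plant`,
#'   `pollinator`, `visits`, `rate`; the planted truth is attached as
#'   attribute `"truth"`.
#' @export
generate_visitation_dataset <- function(seed = NULL, months = 8, plots = 8,
                                        slope = 12,
                                        intercepts = c(restored = 9,
                                                       unrestored = 7),
                                        noise_sd = 1, dispersion = 8,
                                        s_plant = 5, s_animal = 6,
                                        connectance = 0.5,
                                        nodf_range = c(0.35, 0.8),
                                        effort_hours = 4) {
  if (intercepts[["restored"]] < intercepts[["unrestored"]]) {
    warn("Restored intercept below unrestored; planted design expects >=.")
  }
  design <- tidyr::expand_grid(
    treatment = c("restored", "unrestored"),
    month = seq_len(months),
    plot = seq_len(plots)
  )
  rows <- with_seed(seed, {
    purrr::pmap_dfr(design, function(treatment, month, plot) {
      tg <- runif(1, nodf_range[1], nodf_range[2])
      net <- generate_nested_network(
        s_plant, s_animal, connectance, nodf = tg, tol = 0.05,
        max_iter = 2e4, seed = sample.int(.Machine$integer.max / 2, 1)
      )
      achieved <- nodf(net)
      mu <- intercepts[[treatment]] + slope * achieved +
        if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
      mu <- max(mu, 1)
      b <- (net$incidence > 0) * 1
      purrr::map_dfr(seq_len(n_animals(net)), function(a) {
        total <- if (is.null(dispersion)) round(mu) else
          max(1, rnbinom(1, mu = mu, size = dispersion))
        pl <- which(b[, a] > 0)
        split <- if (length(pl) == 1) total else
          as.vector(stats::rmultinom(1, total, rep(1 / length(pl), length(pl))))
        tibble(
          treatment = treatment, month = month, plot = plot,
          plant = net$plant_labels[pl],
          pollinator = net$animal_labels[a],
          visits = split,
          rate = split / effort_hours
        )
      })
    })
  })
  structure(rows, truth = list(slope = slope, intercepts = intercepts,
                               noise_sd = noise_sd, effort_hours = effort_hours))
}
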