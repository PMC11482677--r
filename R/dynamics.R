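#' Model parameters for the eco-evolutionary dynamics
#'
#' Bundles every parameter of the trait-based mutualism model. All defaults
#' are the study's standard conditions: obligate mutualists (`b = 0`),
#' type-II handling time `H = 0.25`, Gaussian kernel width `omega = 0.35`,
#' heritability `h2 = 0.4`, and per-species trait standard deviations of
#' 0.005 ("low") or 0.02 ("high"). The competition matrix has
#' `alpha_ii = 1`, within-guild `alpha_ij ~ U[0.0001, 0.001]`, and zero
#' between guilds (plants only compete with plants, animals with animals).
#'
#' @param net a [bipartite_network()]; fixes guild sizes and, when `alpha` is
#'   not supplied, the dimension of the drawn competition matrix.
#' @param gamma0 average mutualistic strength.
#' @param sigma `"low"` (0.005), `"high"` (0.02), or a numeric scalar/vector
#'   of per-species trait standard deviations (plants first, then animals).
#' @param b intrinsic growth rate (0 = obligate mutualism).
#' @param H handling time of the type-II functional response.
#' @param omega width of the Gaussian interaction kernel.
#' @param h2 broad-sense heritability of the trait.
#' @param alpha optional `(S_P+S_A)^2` competition matrix; drawn from `seed`
#'   when `NULL`.
#' @param kernel `"gaussian"` or `"asymmetric_gamma"` (a gamma-density kernel
#'   `10 * dgamma((z - z')/W + 10, shape, rate)` scaled by `gamma0 / d_i`).
#' @param kernel_W,kernel_shape,kernel_rate asymmetric-kernel constants.
#' @param gh_nodes Gauss-Hermite nodes per trait dimension used for the
#'   double expectation in the growth integral. Seven nodes reproduce the
#'   closed-form Gaussian expectation to near machine precision for trait
#'   standard deviations up to ~0.03 at `omega = 0.35`.
#' @param mean_field use the cheaper mean-field approximation (saturating
#'   denominator evaluated at trait means); Gaussian kernel only.
#' @param seed seed for the competition-matrix draw.
#'
#' @return An object of class `pp_params`.
#' @export
sample_params <- function(net, gamma0 = 1, sigma = c("low", "high"), b = 0,
                          H = 0.25, omega = 0.35, h2 = 0.4, alpha = NULL,
                          kernel = c("gaussian", "asymmetric_gamma"),
                          kernel_W = 0.1, kernel_shape = 4.5, kernel_rate = 0.5,
                          gh_nodes = 7, mean_field = FALSE, seed = NULL) {
  kernel <- match.arg(kernel)
  S_P <- n_plants(net)
  S_A <- n_animals(net)
  S <- S_P + S_A
  if (is.character(sigma)) {
    sigma <- switch(match.arg(sigma), low = 0.005, high = 0.02)
  }
  sigma <- rep_len(sigma, S)
  if (any(sigma <= 0)) abort("`sigma` must be positive.")
  if (H < 0) abort("`H` must be non-negative.")
  if (omega <= 0) abort("`omega` must be positive.")
  if (h2 < 0 || h2 > 1) abort("`h2` must lie in [0, 1].")
  if (is.null(alpha)) {
    alpha <- with_seed(seed, {
      a <- matrix(0, S, S)
      pl <- seq_len(S_P)
      an <- S_P + seq_len(S_A)
      a[pl, pl] <- runif(S_P * S_P, 1e-4, 1e-3)
      a[an, an] <- runif(S_A * S_A, 1e-4, 1e-3)
      diag(a) <- 1
      a
    })
  } else {
    alpha <- as.matrix(alpha)
    if (!all(dim(alpha) == S)) abort("`alpha` must be (S_P+S_A) square.")
    if (any(diag(alpha) <= alpha[row(alpha) != col(alpha)])) {
      warn("Intraspecific competition should exceed interspecific competition.")
    }
  }
  structure(
    list(
      gamma0 = gamma0, sigma = sigma, b = b, H = H, omega = omega, h2 = h2,
      alpha = alpha, kernel = kernel, kernel_W = kernel_W,
      kernel_shape = kernel_shape, kernel_rate = kernel_rate,
      gh_nodes = gh_nodes, mean_field = mean_field,
      s_plant = S_P, s_animal = S_A
    ),
    class = "pp_params"
  )
}

#' @export
print.pp_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pp_params> %d plants + %d animals\n",
      "gamma0 = %g, b = %g, H = %g, omega = %g, h2 = %g, kernel = %s\n",
      "sigma in [%g, %g], %d Gauss-Hermite nodes%s\n"
    ),
    x$s_plant, x$s_animal, x$gamma0, x$b, x$H, x$omega, x$h2, x$kernel,
    min(x$sigma), max(x$sigma), x$gh_nodes,
    if (x$mean_field) " (mean-field)" else ""
  ))
  invisible(x)
}

# Probabilist Gauss-Hermite rule: nodes x and weights w such that
# E[f(Z)] for Z ~ N(mu, s^2) is approximated by sum_a w_a f(mu + sqrt(2) s x_a).
gauss_hermite <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

#' Expected pairwise mutualistic strength (closed form, H = 0)
#'
#' Expectation of the degree-scaled Gaussian interaction kernel over the two
#' species' trait distributions at zero handling time:
#' `(gamma0/d_i) * sqrt(omega^2/(omega^2 + 2 s^2)) *
#'  exp(-(u_i - u_k)^2 / (omega^2 + 2 s^2))`
#' with `s^2 = sigma_i^2 + sigma_k^2`. This is the analytical benchmark the
#' quadrature used inside the dynamics must reproduce.
#'
#' @param u_i,u_k mean traits of the two partners.
#' @param sigma_i,sigma_k trait standard deviations.
#' @param gamma0 average mutualistic strength.
#' @param omega kernel width.
#' @param d_i degree of the focal species (must be >= 1).
#' @return The expected interaction strength (non-negative scalar).
#' @export
pair_interaction_strength <- function(u_i, u_k, sigma_i, sigma_k, gamma0,
                                      omega, d_i) {
  if (any(d_i < 1)) abort("`d_i` must be at least 1 (networks are pruned).")
  s2 <- sigma_i^2 + sigma_k^2
  denom <- omega^2 + 2 * s2
  (gamma0 / d_i) * sqrt(omega^2 / denom) * exp(-(u_i - u_k)^2 / denom)
}

# Directed interaction edge list: species i (plants first, then animals)
# receives benefit from partner k; god = gamma0 / d_i per edge.
directed_edges <- function(net, gamma0) {
  b <- binary_matrix(net)
  S_P <- nrow(b)
  idx <- which(b > 0, arr.ind = TRUE)
  d <- species_degrees(net)
  i <- c(idx[, 1], S_P + idx[, 2]) # plant <- animal, then animal <- plant
  k <- c(S_P + idx[, 2], idx[, 1])
  list(i = i - 1L, k = k - 1L, god = gamma0 / d[i])
}

#' Growth and selection derivatives
#'
#' Right-hand side of the eco-evolutionary system at one community state:
#' per-species density growth `dN_i/dt = N_i * <r_i>` (intrinsic growth minus
#' within-guild competition plus saturating trait-matched mutualism) and mean
#' trait change `du_i/dt = h2 * <(z - u_i) r_i(z)>` (the selection
#' differential; z-independent terms drop out). Expectations over both trait
#' distributions use fixed-order Gauss-Hermite quadrature.
#'
#' @param N,u density and mean-trait vectors (plants first, then animals).
#' @param net a `pp_network`.
#' @param params a [sample_params()] object.
#' @return A list with vectors `dN` and `du`.
#' @export
growth_and_selection <- function(N, u, net, params) {
  S <- params$s_plant + params$s_animal
  if (length(N) != S || length(u) != S) {
    abort("`N` and `u` must have length S_P + S_A.")
  }
  if (anyNA(N) || anyNA(u)) {
    abort(sprintf(
      "Non-finite state for species %s.",
      paste(which(is.na(N) | is.na(u)), collapse = ", ")
    ))
  }
  ed <- directed_edges(net, params$gamma0)
  gh <- gauss_hermite(params$gh_nodes)
  d <- community_derivs_cpp(
    N, u, ed$i, ed$k, ed$god, params$alpha, params$sigma, params$omega,
    params$H, params$h2, params$b, gh$x, gh$w,
    if (params$kernel == "gaussian") 0L else 1L,
    params$kernel_W, params$kernel_shape, params$kernel_rate,
    as.integer(isTRUE(params$mean_field))
  )
  list(dN = d[seq_len(S)], du = d[S + seq_len(S)])
}

#' Forcing specification for revival runs
#'
#' Adds `nu * N_j` (multiplicative, a per-capita growth boost) or the constant
#' `nu` (additive, continuous introduction of individuals) to the density
#' equations of the chosen species for `t < duration`; the forcing is removed
#' at `t = duration`.
#'
#' @param species integer indices of the forced species (plants first).
#' @param strength forcing strength `nu` (multiplicative) or `nu_C`
#'   (additive).
#' @param duration forcing duration `T`.
#' @param mode `"multiplicative"` or `"additive"`.
#' @return A `pp_forcing` list.
#' @export
forcing_spec <- function(species, strength, duration,
                         mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (strength < 0) abort("Forcing strength must be non-negative.")
  if (duration < 0) abort("Forcing duration must be non-negative.")
  structure(
    list(species = as.integer(species), strength = strength,
         duration = duration, mode = mode),
    class = "pp_forcing"
  )
}

# Internal fast simulation: returns the unit-grid state matrix
# (rows = times 0..t_end, columns = N then u), with N clamped >= 0.
sim_core <- function(net, params, N0, u0, t_end = 1000, forcing = NULL,
                     sample_times = NULL) {
  S <- params$s_plant + params$s_animal
  ed <- directed_edges(net, params$gamma0)
  gh <- gauss_hermite(params$gh_nodes)
  kern <- if (params$kernel == "gaussian") 0L else 1L
  mf <- as.integer(isTRUE(params$mean_field))
  force_active <- FALSE
  force_now <- forcing

  rhs <- function(t, y, parms) {
    d <- community_derivs_cpp(
      y[seq_len(S)], y[S + seq_len(S)], ed$i, ed$k, ed$god, params$alpha,
      params$sigma, params$omega, params$H, params$h2, params$b, gh$x, gh$w,
      kern, params$kernel_W, params$kernel_shape, params$kernel_rate, mf
    )
    if (force_active) {
      j <- force_now$species
      if (force_now$mode == "multiplicative") {
        d[j] <- d[j] + force_now$strength * pmax(y[j], 0)
      } else {
        d[j] <- d[j] + force_now$strength
      }
    }
    list(d)
  }

  times <- sample_times %||% seq(0, t_end)
  y0 <- c(N0, u0)
  run_piece <- function(y, tt) {
    out <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-6, atol = 1e-9)
    if (attr(out, "istate")[1] < 0) {
      abort(sprintf("Integration failed at t = %g.", max(out[, 1])))
    }
    out
  }

  Tdur <- if (!is.null(forcing)) min(forcing$duration, t_end) else 0
  if (!is.null(forcing) && Tdur > 0 && forcing$strength > 0) {
    t1 <- unique(c(times[times <= Tdur], Tdur))
    force_active <- TRUE
    out1 <- run_piece(y0, t1)
    force_active <- FALSE
    yT <- out1[nrow(out1), -1]
    yT[1:S] <- pmax(yT[1:S], 0)
    t2 <- unique(c(Tdur, times[times > Tdur]))
    if (length(t2) > 1) {
      out2 <- run_piece(yT, t2)
      keep1 <- out1[, 1] %in% times
      keep2 <- out2[, 1] %in% times & !(out2[, 1] %in% out1[, 1])
      out <- rbind(out1[keep1, , drop = FALSE], out2[keep2, , drop = FALSE])
    } else {
      out <- out1[out1[, 1] %in% times, , drop = FALSE]
    }
  } else {
    out <- run_piece(y0, times)
  }
  out[, 1 + (1:S)] <- pmax(out[, 1 + (1:S)], 0)
  out
}

#' Simulate community eco-evolutionary dynamics
#'
#' Integrates densities and mean traits with an adaptive-step solver (lsoda,
#' rtol 1e-6, atol 1e-9), sampling states on a unit time grid. An optional
#' [forcing_spec()] perturbs the named species for `t < duration`; the
#' integration is split at the forcing switch-off so the discontinuity is
#' handled exactly. Densities are reported clamped at zero.
#'
#' @param net a `pp_network`.
#' @param params a [sample_params()] object.
#' @param N0,u0 initial densities and mean traits (plants first).
#' @param t_end final time (default 1000).
#' @param forcing optional [forcing_spec()].
#' @return A `pp_trajectory`: a tibble with columns `time`, `species`,
#'   `guild`, `N`, `u`, carrying the forcing schedule as attributes.
#' @export
simulate_community <- function(net, params, N0, u0, t_end = 1000,
                               forcing = NULL) {
  out <- sim_core(net, params, N0, u0, t_end, forcing)
  S <- params$s_plant + params$s_animal
  labels <- c(net$plant_labels, net$animal_labels)
  guild <- rep(c("plant", "animal"), c(params$s_plant, params$s_animal))
  traj <- tibble(
    time = rep(out[, 1], S),
    species = rep(labels, each = nrow(out)),
    guild = rep(guild, each = nrow(out)),
    N = as.vector(out[, 1 + (1:S)]),
    u = as.vector(out[, 1 + S + (1:S)])
  )
  structure(traj,
    class = c("pp_trajectory", class(traj)),
    forcing = forcing, s_plant = params$s_plant, s_animal = params$s_animal
  )
}

#' Quasi-equilibrium mean traits
#'
#' Runs the community from density 1 and uniform random initial traits at a
#' high average mutualistic strength (default `gamma0 = 4`, outside the
#' collapse regime) for `t_end` time units and returns the final mean trait
#' vector. These mutually adapted traits initialize the revival experiments.
#'
#' @param net a `pp_network`.
#' @param params a [sample_params()] object; its `gamma0` is overridden.
#' @param seed seed for the initial trait draw.
#' @param gamma0 override strength (default 4).
#' @param u_range half-width of the uniform initial trait distribution
#'   (default 0.5, i.e. `U[-0.5, 0.5]`).
#' @param t_end integration time (default 1000).
#' @return Numeric vector of final mean traits (plants first).
#' @export
quasi_equilibrium_traits <- function(net, params, seed = NULL, gamma0 = 4,
                                     u_range = 0.5, t_end = 1000) {
  S <- params$s_plant + params$s_animal
  p <- params
  p$gamma0 <- gamma0
  u0 <- with_seed(seed, runif(S, -u_range, u_range))
  out <- sim_core(net, p, rep(1, S), u0, t_end,
                  sample_times = c(0, t_end))
  unname(out[nrow(out), 1 + S + (1:S)])
}

#' Save and restore model configurations
#'
#' Serializes a [sample_params()] object (and optionally a [forcing_spec()])
#' to a JSON configuration file, including the drawn competition matrix, so
#' a run can be reproduced without re-seeding.
#'
#' @param params a `pp_params` object.
#' @param path JSON file path.
#' @param forcing optional `pp_forcing`.
#' @return `path`, invisibly (`write_model_config`); a list with elements
#'   `params` and `forcing` (`read_model_config`).
#' @export
write_model_config <- function(params, path, forcing = NULL) {
  cfg <- unclass(params)
  cfg$alpha <- as.vector(params$alpha)
  cfg$forcing <- if (!is.null(forcing)) unclass(forcing) else NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- cfg$s_plant + cfg$s_animal
  forcing <- NULL
  if (!is.null(cfg$forcing)) {
    forcing <- forcing_spec(cfg$forcing$species, cfg$forcing$strength,
                            cfg$forcing$duration, cfg$forcing$mode)
    cfg$forcing <- NULL
  }
  cfg$alpha <- matrix(cfg$alpha, S, S)
  cfg$sigma <- rep_len(cfg$sigma, S)
  params <- structure(cfg, class = "pp_params")
  list(params = params, forcing = forcing)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj a `pp_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
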