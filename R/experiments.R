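# Shared per-run summaries: per-species mean density over the last
# `window` unit samples plus the final state.
run_summary <- function(out, S, window = 100) {
  nr <- nrow(out)
  idx <- seq.int(max(1, nr - window + 1), nr)
  Nwin <- out[idx, 1 + (1:S), drop = FALSE]
  list(
    mean_N = colMeans(Nwin),
    final_N = out[nr, 1 + (1:S)],
    final_u = out[nr, 1 + S + (1:S)]
  )
}

sweep_one <- function(net, params, gamma0, N0, u0, t_end, collapse_at,
                      recovery_at) {
  S <- params$s_plant + params$s_animal
  p <- params
  p$gamma0 <- gamma0
  res <- tryCatch({
    out <- sim_core(net, p, N0, u0, t_end)
    sm <- run_summary(out, S)
    tibble(
      gamma0 = gamma0,
      richness = sum(sm$mean_N >= collapse_at),
      recovery_richness = mean(sm$final_N > recovery_at),
      total_biomass = sum(sm$mean_N),
      mean_biomass = mean(sm$mean_N),
      mean_pollinator_density = mean(sm$mean_N[params$s_plant + seq_len(params$s_animal)]),
      final_N = list(unname(sm$final_N)),
      error = NA_character_
    )
  }, error = function(e) {
    tibble(
      gamma0 = gamma0, richness = NA_integer_, recovery_richness = NA_real_,
      total_biomass = NA_real_, mean_biomass = NA_real_,
      mean_pollinator_density = NA_real_, final_N = list(NULL),
      error = conditionMessage(e)
    )
  })
  res
}

#' Collapse sweep over average mutualistic strength
#'
#' Sweeps `gamma0` downward (default 5 to 0 in steps of 0.15). Each cell is
#' an independent run: all densities start at 1, initial mean traits are
#' drawn fresh from `U[-0.5, 0.5]`, and the dynamics run to `t_end`.
#' Summaries come from the last 100 unit samples; a species counts as
#' collapsed when its mean density falls below the collapse threshold 0.05.
#'
#' @param net a `pp_network`.
#' @param params a [sample_params()] object (its `gamma0` is overridden per
#'   cell).
#' @param gamma0_grid strengths to visit, in sweep order.
#' @param seed seed for the per-cell initial trait draws.
#' @param t_end integration time per cell (default 1000).
#' @param collapse_at species-level collapse threshold (default 0.05).
#' @param recovery_at species-level recovery threshold (default 0.5).
#' @param u_range half-width of the initial trait distribution.
#' @return A `pp_sweep` tibble with one row per `gamma0`: richness, recovery
#'   richness, total/mean biomass, mean pollinator density, final densities
#'   (list column), and any per-cell integration error.
#' @export
collapse_sweep <- function(net, params, gamma0_grid = seq(5, 0, by = -0.15),
                           seed = NULL, t_end = 1000, collapse_at = 0.05,
                           recovery_at = 0.5, u_range = 0.5) {
  S <- params$s_plant + params$s_animal
  rows <- with_seed(seed, {
    purrr::map_dfr(gamma0_grid, function(g) {
      u0 <- runif(S, -u_range, u_range)
      sweep_one(net, params, g, rep(1, S), u0, t_end, collapse_at, recovery_at)
    })
  })
  structure(rows,
    class = c("pp_sweep", class(rows)),
    direction = "collapse", n_species = S, collapse_at = collapse_at
  )
}

#' Hysteresis (restoration) sweep from the collapsed state
#'
#' Sweeps `gamma0` upward (default 0 to 5 in steps of 0.15) with every cell
#' started from the collapsed state: initial densities drawn from
#' `U[0, 0.005]`, initial traits from `U[-0.5, 0.5]`. A network exhibits
#' strong hysteresis when its recovery richness (fraction of species above
#' 0.5) never reaches 1 up to `gamma0 = 4.85`; see [strong_hysteresis()].
#'
#' @inheritParams collapse_sweep
#' @param n0_max upper bound of the uniform initial density draw.
#' @return A `pp_sweep` tibble (direction `"hysteresis"`).
#' @export
hysteresis_sweep <- function(net, params, gamma0_grid = seq(0, 5, by = 0.15),
                             seed = NULL, t_end = 1000, collapse_at = 0.05,
                             recovery_at = 0.5, u_range = 0.5,
                             n0_max = 0.005) {
  S <- params$s_plant + params$s_animal
  rows <- with_seed(seed, {
    purrr::map_dfr(gamma0_grid, function(g) {
      u0 <- runif(S, -u_range, u_range)
      N0 <- runif(S, 0, n0_max)
      sweep_one(net, params, g, N0, u0, t_end, collapse_at, recovery_at)
    })
  })
  structure(rows,
    class = c("pp_sweep", class(rows)),
    direction = "hysteresis", n_species = S, collapse_at = collapse_at
  )
}

#' Collapse threshold from a sweep
#'
#' The largest `gamma0` in the sweep at which community richness is below
#' `fraction` of the initial richness. Returns `NA` (with a message) when no
#' cell is collapsed ("no-collapse").
#'
#' @param sweep a [collapse_sweep()] result.
#' @param fraction richness fraction defining collapse (0.9 default; 0.8 is
#'   the alternative convention).
#' @return The threshold `gamma0`, or `NA_real_` if the community never
#'   collapses on the grid.
#' @export
collapse_threshold <- function(sweep, fraction = 0.9) {
  S <- attr(sweep, "n_species")
  ok <- !is.na(sweep$richness)
  collapsed <- sweep$gamma0[ok][sweep$richness[ok] < fraction * S]
  if (!length(collapsed)) {
    message("No collapsed cell in sweep (no-collapse).")
    return(NA_real_)
  }
  max(collapsed)
}

#' Strong-hysteresis flag
#'
#' `TRUE` when the restoration branch never reaches full recovery richness at
#' any swept `gamma0` up to `gamma0_max`.
#'
#' @param sweep a [hysteresis_sweep()] result.
#' @param gamma0_max largest strength examined (default 4.85).
#' @return Logical scalar.
#' @export
strong_hysteresis <- function(sweep, gamma0_max = 4.85) {
  sub <- sweep[!is.na(sweep$recovery_richness) & sweep$gamma0 <= gamma0_max, ]
  all(sub$recovery_richness < 1)
}

#' Revive a collapsed network by forcing one (or a few) species
#'
#' Starts the community in the collapsed state (densities `U[0, 0.005]`) with
#' mutually adapted mean traits taken from the quasi-equilibrium at
#' `gamma0 = 4`, then applies a transient forcing to the species chosen by
#' `strategy` for `duration` time units and integrates to `t_end`. A
#' non-forced species counts as recovered when its final density exceeds 0.5.
#'
#' @param net a `pp_network`.
#' @param params a [sample_params()] object (the collapsed-regime `gamma0`,
#'   typically in \[0.5, 1.5\], comes from here).
#' @param strategy target-selection strategy, see [select_targets()]; or an
#'   integer vector of species indices.
#' @param nu multiplicative forcing strength in \[0, 1\].
#' @param nu_c optional additive (constant-introduction) strength; when
#'   given, overrides `nu`.
#' @param duration forcing duration `T` (default 500).
#' @param t_end evaluation time (default 1000, i.e. 500 unforced time units
#'   after the forcing stops).
#' @param seed seed governing initial densities, initial quasi-equilibrium
#'   traits, and any random target choice.
#' @param traits optional precomputed quasi-equilibrium trait vector (skips
#'   the `gamma0 = 4` spin-up; useful when many cells share a network).
#' @param k number of targets for `"top_centrality"` / `"random"`.
#' @param count_forced include the forced species in recovery richness
#'   (default `FALSE`: only non-forced species count).
#' @param keep_trajectory attach the full `pp_trajectory` (default `FALSE`).
#' @param recovery_at density defining a recovered species (default 0.5).
#' @return A one-row tibble: forced species, `recovery_richness`,
#'   `mean_biomass` and `total_biomass` over the last 100 samples,
#'   `mean_pollinator_density`, plus the trajectory when requested.
#' @export
revive <- function(net, params, strategy = "highest_degree", nu = 0.5,
                   nu_c = NULL, duration = 500, t_end = 1000, seed = NULL,
                   traits = NULL, k = NULL, count_forced = FALSE,
                   keep_trajectory = FALSE, recovery_at = 0.5) {
  S <- params$s_plant + params$s_animal
  if (is.numeric(strategy)) {
    targets <- as.integer(strategy)
    if (any(targets < 1 | targets > S)) {
      abort("Forced species index outside the network.")
    }
  } else {
    targets <- select_targets(net, strategy, k = k,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  }
  if (is.null(traits)) {
    traits <- quasi_equilibrium_traits(net, params, seed = seed)
  }
  N0 <- with_seed(if (is.null(seed)) NULL else seed + 2L, runif(S, 0, 0.005))
  forcing <- if (!is.null(nu_c)) {
    forcing_spec(targets, nu_c, duration, mode = "additive")
  } else if (nu > 0 && duration > 0) {
    forcing_spec(targets, nu, duration, mode = "multiplicative")
  } else {
    NULL
  }
  out <- sim_core(net, params, N0, traits, t_end, forcing)
  sm <- run_summary(out, S)
  eval_idx <- if (count_forced) seq_len(S) else setdiff(seq_len(S), targets)
  res <- tibble(
    gamma0 = params$gamma0,
    nu = if (!is.null(nu_c)) NA_real_ else nu,
    nu_c = if (!is.null(nu_c)) nu_c else NA_real_,
    duration = duration,
    targets = list(targets),
    recovery_richness = mean(sm$final_N[eval_idx] > recovery_at),
    mean_biomass = mean(sm$mean_N),
    total_biomass = sum(sm$mean_N),
    mean_pollinator_density = mean(sm$mean_N[params$s_plant + seq_len(params$s_animal)])
  )
  if (keep_trajectory) {
    labels <- c(net$plant_labels, net$animal_labels)
    guild <- rep(c("plant", "animal"), c(params$s_plant, params$s_animal))
    traj <- tibble(
      time = rep(out[, 1], S),
      species = rep(labels, each = nrow(out)),
      guild = rep(guild, each = nrow(out)),
      N = as.vector(out[, 1 + (1:S)]),
      u = as.vector(out[, 1 + S + (1:S)])
    )
    res$trajectory <- list(structure(traj,
      class = c("pp_trajectory", class(traj)),
      forcing = forcing, s_plant = params$s_plant, s_animal = params$s_animal
    ))
  }
  res
}

#' Recovery phase diagram
#'
#' Grid of [revive()] runs over `gamma0` and one forcing axis (`nu`, `nu_c`,
#' or `duration`); each cell reports recovery richness. Per-cell failures are
#' recorded and the diagram completes.
#'
#' @param net a `pp_network`.
#' @param params base [sample_params()] (its `gamma0` is overridden per
#'   cell).
#' @param axis which forcing parameter spans the first axis.
#' @param axis_grid values of that parameter.
#' @param gamma0_grid average mutualistic strengths.
#' @param strategy,k,duration,seed,count_forced passed to [revive()];
#'   `duration` is used when it is not the swept axis.
#' @return A `pp_phase` tibble: one row per cell with `gamma0`, the axis
#'   value, `recovery_richness`, biomass summaries and `error`.
#' @export
phase_diagram <- function(net, params, axis = c("nu", "nu_c", "duration"),
                          axis_grid, gamma0_grid,
                          strategy = "highest_degree", k = NULL,
                          duration = 500, seed = NULL, count_forced = FALSE) {
  axis <- match.arg(axis)
  traits <- quasi_equilibrium_traits(net, params, seed = seed)
  cells <- tidyr::expand_grid(gamma0 = gamma0_grid, axis_value = axis_grid)
  rows <- purrr::pmap_dfr(cells, function(gamma0, axis_value) {
    p <- params
    p$gamma0 <- gamma0
    args <- list(
      net = net, params = p, strategy = strategy, k = k, seed = seed,
      traits = traits, count_forced = count_forced,
      nu = 0.5, duration = duration
    )
    args[[if (axis == "nu_c") "nu_c" else axis]] <- axis_value
    res <- tryCatch(
      do.call(revive, args),
      error = function(e) {
        tibble(gamma0 = gamma0, recovery_richness = NA_real_,
               mean_biomass = NA_real_, total_biomass = NA_real_,
               mean_pollinator_density = NA_real_,
               error = conditionMessage(e))
      }
    )
    res$axis_value <- axis_value
    if (!"error" %in% names(res)) res$error <- NA_character_
    res[, c("gamma0", "axis_value", "recovery_richness", "mean_biomass",
            "total_biomass", "mean_pollinator_density", "error")]
  })
  names(rows)[names(rows) == "axis_value"] <- axis
  structure(rows, class = c("pp_phase", class(rows)), axis = axis)
}
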