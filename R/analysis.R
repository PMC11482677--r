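# Quadrature expectation of the saturating mutualistic gain
# E[ gamma / (1 + H gamma N_k) ] for one pair, matching the kernel used by
# the dynamics (R mirror of the compiled inner loop; used where a one-off
# evaluation is needed outside an integration).
quad_pair_gain <- function(du, sigma_i, sigma_k, god, H, N_k, params, gh) {
  z <- outer(sqrt(2) * sigma_i * gh$x, sqrt(2) * sigma_k * gh$x, function(a, b) du + a - b)
  g <- if (params$kernel == "gaussian") {
    god * exp(-z^2 / params$omega^2)
  } else {
    god * 10 * stats::dgamma(z / params$kernel_W + 10,
                             shape = params$kernel_shape,
                             rate = params$kernel_rate)
  }
  sum(outer(gh$w, gh$w) * g / (1 + H * g * N_k))
}

#' Net species-interaction matrix at a community state
#'
#' Assembles the square matrix `M` of pairwise effects used by the
#' indirect-effect summaries: positive mutualistic entries are the expected
#' saturating gain `E[gamma / (1 + H gamma N_k)]` of each realized
#' plant-animal pair (optionally multiplied by the partner's density),
#' negative entries are the within-guild competition coefficients
#' `-alpha_ij` (optionally scaled by density); the diagonal is zero. The
#' supplement-level construction is not fully pinned down, so the assembly is
#' explicit and configurable through `scale`.
#'
#' @param net a `pp_network`.
#' @param params a [sample_params()] object.
#' @param N,u current densities and mean traits (plants first).
#' @param scale `"density"` (entries scaled by the acting species' density,
#'   default) or `"per_capita"`.
#' @return An `S x S` numeric matrix.
#' @export
interaction_matrix <- function(net, params, N, u,
                               scale = c("density", "per_capita")) {
  scale <- match.arg(scale)
  S <- params$s_plant + params$s_animal
  gh <- gauss_hermite(params$gh_nodes)
  ed <- directed_edges(net, params$gamma0)
  M <- -params$alpha * if (scale == "density") {
    matrix(pmax(N, 0), S, S, byrow = TRUE)
  } else {
    1
  }
  diag(M) <- 0
  Np <- pmax(N, 0)
  for (e in seq_along(ed$i)) {
    i <- ed$i[e] + 1L
    k <- ed$k[e] + 1L
    gain <- quad_pair_gain(u[i] - u[k], params$sigma[i], params$sigma[k],
                           ed$god[e], params$H, Np[k], params, gh)
    M[i, k] <- gain * if (scale == "density") Np[k] else 1
  }
  M
}

#' Indirect-effect summaries of an interaction matrix
#'
#' Mean third-order indirect effect `beta3 = mean(M^3)` and mean net
#' indirect effect over all orders `beta = mean((I - M)^-1 - I - M)` (the sum
#' of all matrix powers of order two and higher), which converges only when
#' the spectral radius of `M` is below one; otherwise `beta` is `NA` and the
#' radius is still reported.
#'
#' @param M square numeric interaction matrix (mutualism positive,
#'   competition negative), e.g. from [interaction_matrix()].
#' @return A one-row tibble: `beta3`, `beta`, `spectral_radius`.
#' @export
indirect_effects <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort("`M` must be square.")
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  M3 <- M %*% M %*% M
  beta <- if (rho < 1) {
    I <- diag(nrow(M))
    mean(solve(I - M) - I - M)
  } else {
    NA_real_
  }
  tibble(beta3 = mean(M3), beta = beta, spectral_radius = rho)
}

# Explicit least squares via the normal equations (QR-solved); returns
# coefficients, standard errors and fit summaries without going through a
# modeling interface.
ols_fit <- function(X, y) {
  qrx <- qr(X)
  coef <- qr.coef(qrx, y)
  fitted <- as.vector(X %*% coef)
  res <- y - fitted
  n <- length(y)
  p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtX_inv) * s2)
  list(coef = coef, se = se, sigma2 = s2, fitted = fitted,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2), n = n)
}

#' Quasibinomial regression of recovery on a network metric
#'
#' Fits a logit-link quasibinomial GLM of a proportion response (recovery
#' richness, or the proportion of species above density 0.5) on one
#' predictor, by self-contained iteratively reweighted least squares. The
#' dispersion is estimated from the Pearson residuals, so standard errors do
#' not assume binomial variance.
#'
#' @param data a data frame (e.g. a recovery table with one row per
#'   network-condition).
#' @param predictor name of the predictor column (a network metric such as
#'   `"nodf"`).
#' @param response name of the response column; values must lie in \[0, 1\].
#' @param weights optional prior weights column name (e.g. species counts).
#' @param max_iter,tol IRLS controls.
#' @return A `pp_glm` object with `tidy()` and `glance()` methods.
#' @export
recovery_regression <- function(data, predictor, response,
                                weights = NULL, max_iter = 50, tol = 1e-10) {
  y <- data[[response]]
  x <- data[[predictor]]
  if (is.null(y) || is.null(x)) abort("Predictor or response column missing.")
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]
  x <- x[keep]
  if (any(y < 0 | y > 1)) abort("Response must lie in [0, 1].")
  w0 <- if (is.null(weights)) rep(1, length(y)) else data[[weights]][keep]
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2] <- predictor
  n <- length(y)
  if (n < 3) abort("Need at least 3 observations.")
  degenerate <- stats::var(y) == 0 || all(y %in% c(0, 1))
  if (degenerate) {
    warn("Degenerate response (constant or fully separated 0/1 values); coefficients may be unstable.")
  }
  mu <- pmin(pmax((w0 * y + 0.5) / (w0 + 1), 1e-6), 1 - 1e-6)
  eta <- log(mu / (1 - mu))
  beta <- rep(0, 2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    wirls <- w0 * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, wirls)
    new_beta <- fit$coefficients
    eta <- as.vector(X %*% new_beta)
    if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  pearson <- sum(w0 * (y - mu)^2 / (mu * (1 - mu)))
  dispersion <- pearson / (n - ncol(X))
  wirls <- w0 * mu * (1 - mu)
  XtWX <- crossprod(X, wirls * X)
  vc <- solve(XtWX) * dispersion
  structure(
    list(
      coefficients = setNames(as.vector(beta), colnames(X)),
      std_error = setNames(sqrt(diag(vc)), colnames(X)),
      dispersion = dispersion, fitted = mu, response = y, predictor = x,
      predictor_name = predictor, response_name = response,
      converged = converged, degenerate = degenerate, n = n
    ),
    class = "pp_glm"
  )
}

#' @export
print.pp_glm <- function(x, ...) {
  cat(sprintf(
    "<pp_glm> quasibinomial(logit) %s ~ %s, n = %d, dispersion = %.3g\n",
    x$response_name, x$predictor_name, x$n, x$dispersion
  ))
  print(round(rbind(estimate = x$coefficients, std.error = x$std_error), 4))
  invisible(x)
}

#' Summarise a visitation table into per-network rows
#'
#' Aggregates a long visitation table (one row per plant-pollinator link per
#' plot-month) into one row per sampled network: its NODF (computed on the
#' binarized plot network), the mean number of visits per pollinator, and
#' the mean visitation rate. Empty plot-month networks (or 1 x n networks,
#' where nestedness is undefined) are dropped with a warning.
#'
#' @param table a data frame with columns `treatment`, `month`, `plot`,
#'   `plant`, `pollinator`, `visits`, and optionally `rate`.
#' @return A tibble with one row per (treatment, month, plot):
#'   `nodf`, `mean_visits`, `mean_rate`, `n_plants`, `n_pollinators`.
#' @export
visitation_summary <- function(table) {
  needed <- c("treatment", "month", "plot", "plant", "pollinator", "visits")
  if (!all(needed %in% names(table))) {
    abort(paste("Visitation table needs columns:", paste(needed, collapse = ", ")))
  }
  groups <- dplyr::group_split(dplyr::group_by(
    as_tibble(table), .data$treatment, .data$month, .data$plot
  ))
  dropped <- 0
  rows <- purrr::map_dfr(groups, function(g) {
    g <- g[g$visits > 0, ]
    plants <- unique(g$plant)
    polls <- unique(g$pollinator)
    if (nrow(g) == 0 || length(plants) < 2 || length(polls) < 2) {
      dropped <<- dropped + 1
      return(NULL)
    }
    m <- matrix(0, length(plants), length(polls),
                dimnames = list(plants, polls))
    m[cbind(match(g$plant, plants), match(g$pollinator, polls))] <- g$visits
    per_poll <- colSums(m)
    tibble(
      treatment = g$treatment[1], month = g$month[1], plot = g$plot[1],
      nodf = nodf(m),
      mean_visits = mean(per_poll),
      mean_rate = if ("rate" %in% names(g)) {
        mean(tapply(g$rate, g$pollinator, sum))
      } else {
        NA_real_
      },
      n_plants = length(plants), n_pollinators = length(polls)
    )
  })
  if (dropped > 0) {
    warn(sprintf("Dropped %d empty or degenerate plot-month network(s).", dropped))
  }
  rows
}

#' Slope of visitation against nestedness
#'
#' Ordinary least squares of mean pollinator visits (or mean visitation
#' rate) on network NODF, pooled across treatments, via the explicit
#' normal-equation path.
#'
#' @param summary output of [visitation_summary()].
#' @param response `"mean_visits"` or `"mean_rate"`.
#' @return A one-row tibble: `slope`, `se`, `t_value`, `intercept`,
#'   `r_squared`, `n`.
#' @export
visitation_slope <- function(summary, response = c("mean_visits", "mean_rate")) {
  response <- match.arg(response)
  y <- summary[[response]]
  keep <- is.finite(y) & is.finite(summary$nodf)
  fit <- ols_fit(cbind(1, summary$nodf[keep]), y[keep])
  tibble(
    slope = fit$coef[2], se = fit$se[2], t_value = fit$coef[2] / fit$se[2],
    intercept = fit$coef[1], r_squared = fit$r_squared, n = fit$n
  )
}

#' Nestedness-density relation across networks
#'
#' For each level of average mutualistic strength, fits the ordinary
#' least-squares line of mean pollinator density at quasi-equilibrium against
#' network NODF across networks (the restoration-branch relation evaluated
#' above the collapse regime, typically at `gamma0 = 1.8` and `2`).
#'
#' @param data a data frame with columns `gamma0`, `nodf`, and
#'   `mean_pollinator_density` (one row per network and strength).
#' @return A tibble with one row per `gamma0`: `slope`, `se_slope`,
#'   `intercept`, `se_intercept`, `r_squared`, `n`.
#' @export
nestedness_density_relation <- function(data) {
  needed <- c("gamma0", "nodf", "mean_pollinator_density")
  if (!all(needed %in% names(data))) {
    abort(paste("Need columns:", paste(needed, collapse = ", ")))
  }
  purrr::map_dfr(split(as_tibble(data), data$gamma0), function(g) {
    if (nrow(g) < 3) abort("Need at least 3 networks per gamma0 level.")
    fit <- ols_fit(cbind(1, g$nodf), g$mean_pollinator_density)
    tibble(
      gamma0 = g$gamma0[1],
      slope = fit$coef[2], se_slope = fit$se[2],
      intercept = fit$coef[1], se_intercept = fit$se[1],
      r_squared = fit$r_squared, n = fit$n
    )
  })
}
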