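# Least-squares parameter estimation from trajectory observations and
# parameter-recovery experiments on synthetic data.

#' Fit model parameters to trajectory observations
#'
#' Minimises the unweighted sum of squared deviations between the
#' simulated and observed species over the observation grid, pooling all
#' replicates. Free parameters are optimised in log space (positivity
#' without explicit constraints) with [stats::nlminb()]; the starting
#' point is supplied explicitly and no random restarts are used, so the
#' fit is deterministic given the data and initial guess.
#' Non-convergence is reported through the `converged` flag, not as an
#' error.
#'
#' @param obs a [noisy_trajectories()] result.
#' @param free character vector of free scalar parameter names (any of
#'   `k1`..`k5`, `d1`..`d5`, `s1`, `s2`, `hill`, `herceptin`); may be
#'   empty, in which case the residual is evaluated at the observation
#'   model's own parameters and no optimisation happens.
#' @param init named numeric initial guess covering `free` (natural
#'   scale, positive).
#' @param lower,upper optional named bounds on the natural scale.
#' @param control passed to [stats::nlminb()].
#' @return Object of class `dusp_fit`: `estimates` (natural scale),
#'   `rss`, `converged`, `iterations`, `free`, `init`, `lower`, `upper`,
#'   `data_seed`, `obs`.
#' @export
fit_parameters <- function(obs, free, init = NULL, lower = NULL,
                           upper = NULL, control = list()) {
  stopifnot(inherits(obs, "dusp_observations"))
  unknown <- setdiff(free, .scalar_param_names)
  if (length(unknown)) {
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- obs$model$params
  topo <- obs$model$topology
  opts <- obs$truth$opts
  objective_at <- function(p) {
    tr <- tryCatch(simulate_trajectory(dusp_model(topo, p), opts),
                   error = function(e) NULL)
    if (is.null(tr)) return(sqrt(.Machine$double.xmax))
    sse <- 0
    for (sp in obs$species) {
      truth <- tr$state[, sp]
      m <- obs$replicates[[sp]]
      sse <- sse + sum((sweep(m, 2L, truth))^2)
    }
    sse
  }
  if (length(free) == 0L) {
    return(structure(list(estimates = numeric(0), rss = objective_at(base),
                          converged = TRUE, iterations = 0L,
                          free = character(0), init = init,
                          lower = lower, upper = upper,
                          data_seed = obs$seed, obs = obs),
                     class = "dusp_fit"))
  }
  if (is.null(init) || is.null(names(init)) ||
      !all(free %in% names(init))) {
    stop("'init' must be a named vector covering all free parameters",
         call. = FALSE)
  }
  init <- init[free]
  if (any(init <= 0)) {
    stop("initial guesses must be positive (fit is in log space)",
         call. = FALSE)
  }
  expand_bound <- function(b, default) {
    out <- rep(default, length(free))
    names(out) <- free
    if (!is.null(b)) out[names(b)] <- b
    out
  }
  lo <- expand_bound(lower, 1e-8)
  hi <- expand_bound(upper, 1e8)
  if (any(lo <= 0) || any(hi <= lo)) {
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  }
  fn <- function(lp) {
    p <- base
    est <- exp(lp)
    for (i in seq_along(free)) p[[free[i]]] <- est[i]
    p <- tryCatch(validate_params(p), error = function(e) NULL)
    if (is.null(p)) return(sqrt(.Machine$double.xmax))
    objective_at(p)
  }
  res <- stats::nlminb(start = log(init), objective = fn,
                       lower = log(lo), upper = log(hi),
                       control = control)
  structure(list(estimates = stats::setNames(exp(res$par), free),
                 rss = res$objective,
                 converged = res$convergence == 0,
                 iterations = res$iterations,
                 free = free, init = init, lower = lo, upper = hi,
                 data_seed = obs$seed, obs = obs),
            class = "dusp_fit")
}

#' @export
coef.dusp_fit <- function(object, ...) object$estimates

#' @export
print.dusp_fit <- function(x, ...) {
  cat("<dusp_fit> least-squares trajectory fit\n")
  if (length(x$estimates)) {
    print(round(x$estimates, 6))
  } else {
    cat("  (no free parameters)\n")
  }
  cat(sprintf("  RSS %.6g; %s after %d iterations\n", x$rss,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
summary.dusp_fit <- function(object, ...) {
  list(estimates = object$estimates, rss = object$rss,
       converged = object$converged, iterations = object$iterations,
       free = object$free, init = object$init,
       data_seed = object$data_seed)
}

#' @export
residuals.dusp_fit <- function(object, ...) {
  p <- object$obs$model$params
  for (nm in object$free) p[[nm]] <- object$estimates[[nm]]
  tr <- simulate_trajectory(dusp_model(object$obs$model$topology, p),
                            object$obs$truth$opts)
  out <- lapply(object$obs$species, function(sp) {
    sweep(object$obs$replicates[[sp]], 2L, tr$state[, sp])
  })
  names(out) <- object$obs$species
  out
}

#' Parameter-recovery experiment
#'
#' Generates noisy synthetic observations from a model whose parameters
#' are known, refits the chosen free parameters, and reports the
#' per-parameter recovery error.
#'
#' @param model the true [dusp_model()].
#' @param free free parameter names to recover.
#' @param noise_sd multiplicative noise sd for the synthetic data.
#' @param n_reps replicate count.
#' @param seed data-generation seed.
#' @param observed observed species (defaults to the five active forms
#'   plus Survival).
#' @param opts a [solver_options()] object (both for data generation and
#'   fitting).
#' @param init optional named initial guess; default displaces each true
#'   value to a fifth of it.
#' @return data.frame of class `dusp_recovery` with columns `parameter`,
#'   `truth`, `estimate`, `bias`, `rel_error`; the fit object is attached
#'   as attribute `fit`.
#' @export
recovery_experiment <- function(model, free, noise_sd = 0.05, n_reps = 3,
                                seed = 1, observed = .default_observed,
                                opts = solver_options(), init = NULL) {
  stopifnot(inherits(model, "dusp_model"), length(free) >= 1)
  truth <- unlist(model$params[free])
  if (any(truth <= 0)) {
    stop("recovery requires positive true values for the free parameters",
         call. = FALSE)
  }
  if (is.null(init)) init <- truth / 5
  obs <- noisy_trajectories(model, observed = observed,
                            noise_sd = noise_sd, n_reps = n_reps,
                            seed = seed, opts = opts)
  fit <- fit_parameters(obs, free, init = init)
  est <- fit$estimates[free]
  out <- data.frame(parameter = free, truth = unname(truth),
                    estimate = unname(est),
                    bias = unname(est - truth),
                    rel_error = unname(abs(est - truth) / truth),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "seed") <- seed
  class(out) <- c("dusp_recovery", "data.frame")
  out
}
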