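# Time-course integration and d5 inhibition scans.

#' Solver options
#'
#' Defaults: horizon 10 model-time units with 1001 output points (long
#' enough for the slowest relaxation modes to equilibrate so the
#' asymptotic survival slope dominates the tail) and tight tolerances
#' (`rtol` 1e-8, `atol` 1e-10) with the stiff-capable `lsoda` switching
#' integrator — the `herceptin * HER2ac` term creates rates of order 1e4.
#'
#' @param t_end simulation horizon (> 0, model time units).
#' @param n_points output grid size (>= 2).
#' @param rtol,atol relative/absolute integration tolerances (> 0).
#' @param method integration method passed to [deSolve::ode()]; the
#'   default `"lsoda"` switches automatically between stiff and
#'   non-stiff regimes.
#' @return List of class `solver_options`.
#' @export
solver_options <- function(t_end = 10, n_points = 1001,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end > 0,
            n_points >= 2, rtol > 0, atol > 0)
  structure(list(t_end = as.numeric(t_end),
                 n_points = as.integer(n_points),
                 rtol = rtol, atol = atol, method = method),
            class = "solver_options")
}

#' Simulate a time course
#'
#' Integrates the 11-variable system from the standard initial state.
#' Deterministic for fixed inputs; per-protein totals are conserved along
#' the trajectory up to solver tolerance.
#'
#' @param model a [dusp_model()] object.
#' @param opts a [solver_options()] object.
#' @return An object of class `dusp_trajectory`: list with `time`
#'   (length-`n_points` grid), `state` (matrix, one column per state
#'   variable), and provenance (`params`, `topology`, `opts`).
#' @examples
#' tr <- simulate_trajectory(dusp_model("constitutive", dusp_params(d5 = 1)))
#' tail(as.data.frame(tr))
#' @export
simulate_trajectory <- function(model, opts = solver_options()) {
  stopifnot(inherits(model, "dusp_model"), inherits(opts, "solver_options"))
  y0 <- initial_state(model)
  times <- seq(0, opts$t_end, length.out = opts$n_points)
  diag_msg <- NULL
  out <- withCallingHandlers(
    deSolve::ode(y = unname(y0), times = times, func = rhs_factory(model),
                 parms = NULL, method = opts$method,
                 rtol = opts$rtol, atol = opts$atol),
    warning = function(w) {
      diag_msg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    stop("ODE integration failed",
         if (!is.null(diag_msg)) paste0(": ", diag_msg) else "",
         call. = FALSE)
  }
  state <- unname(out[, -1L, drop = FALSE])
  colnames(state) <- .state_names
  structure(list(time = times, state = state, params = model$params,
                 topology = model$topology, opts = opts),
            class = "dusp_trajectory")
}

#' @export
as.data.frame.dusp_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$state, check.names = FALSE)
}

#' @export
print.dusp_trajectory <- function(x, ...) {
  cat(sprintf("<dusp_trajectory> topology %s, d5 = %g, t in [0, %g], %d points\n",
              x$topology, x$params$d5, x$opts$t_end, length(x$time)))
  s <- x$state[, "Survival"]
  cat(sprintf("  Survival: start %.4g, max %.4g, end %.4g\n",
              s[1L], max(s), s[length(s)]))
  invisible(x)
}

#' @export
plot.dusp_trajectory <- function(x, species = "Survival", ...) {
  species <- match.arg(species, .state_names, several.ok = TRUE)
  graphics::matplot(x$time, x$state[, species, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "amount / score", ...)
  graphics::legend("topleft", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Simulate from a model object
#'
#' With `noise_sd = 0` and `nsim = 1` returns the deterministic
#' trajectory; otherwise returns noisy replicate observations via
#' [noisy_trajectories()].
#'
#' @param object a `dusp_model`.
#' @param nsim number of replicate observations.
#' @param seed RNG seed for the noise (RNG state is restored afterwards).
#' @param opts a [solver_options()] object.
#' @param noise_sd multiplicative (lognormal) noise sd fraction.
#' @param observed species to observe when generating noisy replicates.
#' @param ... unused.
#' @export
simulate.dusp_model <- function(object, nsim = 1, seed = NULL,
                                opts = solver_options(), noise_sd = 0,
                                observed = NULL, ...) {
  if (noise_sd == 0 && nsim == 1 && is.null(observed)) {
    return(simulate_trajectory(object, opts))
  }
  if (is.null(observed)) observed <- .default_observed
  noisy_trajectories(object, observed = observed, noise_sd = noise_sd,
                     n_reps = nsim, seed = seed, opts = opts)
}

#' DUSP-inhibition scan
#'
#' Simulates the model once per value of the DUSP inactivation rate `d5`
#' (all other parameters fixed) and labels each survival trajectory as
#' increasing, inflected or decreasing. The default grid is the study
#' grid \{1, 10, 20, 50, 100, 500\}. Entries fail independently: an
#' integration failure is recorded with its message and the scan
#' continues.
#'
#' @param model a [dusp_model()]; its own `d5` is ignored in favour of
#'   the grid values.
#' @param d5_values nonempty nonnegative grid (sorted, deduplicated).
#' @param opts a [solver_options()] object.
#' @param eps_frac,delta_frac regime-classification thresholds, see
#'   [classify_regime()].
#' @return An object of class `dusp_scan`.
#' @examples
#' \donttest{
#' sc <- inhibition_scan(dusp_model("constitutive"))
#' summary(sc)
#' }
#' @export
inhibition_scan <- function(model, d5_values = c(1, 10, 20, 50, 100, 500),
                            opts = solver_options(),
                            eps_frac = 0.01, delta_frac = 0.05) {
  stopifnot(inherits(model, "dusp_model"))
  if (!length(d5_values) || !is.numeric(d5_values) || any(is.na(d5_values)) ||
      any(d5_values < 0)) {
    stop("'d5_values' must be a nonempty vector of nonnegative rates",
         call. = FALSE)
  }
  d5_values <- sort(unique(as.numeric(d5_values)))
  entries <- lapply(d5_values, function(v) {
    m <- dusp_model(model$topology, params_with(model$params, d5 = v))
    tr <- tryCatch(simulate_trajectory(m, opts), error = identity)
    if (inherits(tr, "error")) {
      return(list(d5 = v, error = conditionMessage(tr)))
    }
    met <- survival_metrics(tr)
    list(d5 = v, trajectory = tr, metrics = met,
         regime = classify_regime(met, eps_frac, delta_frac),
         eventually_decreasing = eventually_decreasing(met, eps_frac))
  })
  structure(list(entries = entries, d5_values = d5_values,
                 topology = model$topology, params = model$params,
                 opts = opts, eps_frac = eps_frac, delta_frac = delta_frac),
            class = "dusp_scan")
}

#' @export
summary.dusp_scan <- function(object, ...) {
  rows <- lapply(object$entries, function(e) {
    if (!is.null(e$error)) {
      data.frame(d5 = e$d5, regime = NA_character_,
                 eventually_decreasing = NA, s_end = NA_real_,
                 s_max = NA_real_, t_at_max = NA_real_,
                 error = e$error, stringsAsFactors = FALSE)
    } else {
      m <- e$metrics
      data.frame(d5 = e$d5, regime = e$regime,
                 eventually_decreasing = e$eventually_decreasing,
                 s_end = m$s_end, s_max = m$s_max, t_at_max = m$t_at_max,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "topology") <- object$topology
  out
}

#' @export
print.dusp_scan <- function(x, ...) {
  cat(sprintf("<dusp_scan> topology %s, %d d5 values, eps_frac %g, delta_frac %g\n",
              x$topology, length(x$entries), x$eps_frac, x$delta_frac))
  print(summary(x)[, c("d5", "regime", "eventually_decreasing",
                       "s_end", "s_max")], row.names = FALSE)
  thr <- decrease_threshold(x)
  cat("smallest eventually-decreasing d5:",
      if (is.na(thr)) "none" else thr, "\n")
  invisible(x)
}

#' @export
plot.dusp_scan <- function(x, ...) {
  ok <- !vapply(x$entries, function(e) is.null(e$trajectory), logical(1))
  surv <- vapply(x$entries[ok], function(e) e$trajectory$state[, "Survival"],
                 numeric(length(x$entries[[which(ok)[1]]]$trajectory$time)))
  graphics::matplot(x$entries[[which(ok)[1]]]$trajectory$time, surv,
                    type = "l", lty = 1, xlab = "time", ylab = "Survival",
                    ...)
  graphics::legend("topleft", lty = 1, col = seq_len(sum(ok)), bty = "n",
                   legend = sprintf("d5 = %g", x$d5_values[ok]))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Column 1 is time; one column per state variable, headers matching the
#' model's variable names.
#'
#' @param traj a `dusp_trajectory`.
#' @param file output path.
#' @export
write_trajectory_csv <- function(traj, file) {
  stopifnot(inherits(traj, "dusp_trajectory"))
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}
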