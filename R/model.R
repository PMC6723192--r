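# Model object, right-hand side, and closed-form steady states.

.state_names <- c("HER2ac", "HER2i", "ERK12ac", "ERK12i", "JNK12ac",
                  "JNK12i", "P38ac", "P38i", "DUSPac", "DUSPi", "Survival")
.topologies <- c("constitutive", "ERK12", "JNK12")

#' Kinetic model of DUSP-regulated HER2/MAPK signalling
#'
#' Bundles a parameter set with a DUSP-induction topology. Each of the
#' five proteins (HER2, ERK1/2, JNK1/2, p38, DUSP8/16) is represented by
#' an active/inactive pair under first-order mass-action kinetics;
#' Herceptin is a constant input driving HER2 inactivation; a scalar
#' survival score integrates `s1 * ERK12ac - s2 * (JNK12ac * P38ac)^hill`.
#'
#' The topology selects what drives DUSP activation:
#' \describe{
#'   \item{`constitutive`}{DUSP activates at rate `k5 * DUSPi` (the
#'     baseline DUSP16 model).}
#'   \item{`ERK12`}{activation term `k5 * DUSPi * ERK12ac` (DUSP8
#'     induced by ERK1/2).}
#'   \item{`JNK12`}{activation term `k5 * DUSPi * JNK12ac` (DUSP8
#'     induced by JNK1/2).}
#' }
#'
#' @param topology one of `"constitutive"`, `"ERK12"`, `"JNK12"`.
#' @param params a [dusp_params()] object.
#' @return An object of class `dusp_model`.
#' @examples
#' m <- dusp_model("constitutive", dusp_params(d5 = 50))
#' steady_state(m)
#' @export
dusp_model <- function(topology = c("constitutive", "ERK12", "JNK12"),
                       params = dusp_params()) {
  topology <- match.arg(topology)
  if (!inherits(params, "dusp_params")) params <- dusp_params(params)
  structure(list(topology = topology, params = params),
            class = "dusp_model")
}

#' @export
print.dusp_model <- function(x, ...) {
  cat("<dusp_model> DUSP induction topology:", x$topology, "\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.dusp_model <- function(object, ...) {
  p <- object$params
  c(unlist(p[.scalar_param_names]),
    stats::setNames(p$totals, paste0("total_", names(p$totals))))
}

# Fast index-based RHS for the integrator. State order follows
# .state_names. Tiny negative excursions from the solver are tolerated;
# the Hill term is defined as 0 when the JNK*p38 product is <= 0.
rhs_factory <- function(model) {
  p <- model$params
  k1 <- p$k1; k2 <- p$k2; k3 <- p$k3; k4 <- p$k4; k5 <- p$k5
  d1 <- p$d1; d2 <- p$d2; d3 <- p$d3; d4 <- p$d4; d5 <- p$d5
  s1 <- p$s1; s2 <- p$s2; hill <- p$hill; H <- p$herceptin
  ind_idx <- switch(model$topology, constitutive = 0L, ERK12 = 3L,
                    JNK12 = 5L)
  function(t, y, parms) {
    ind <- if (ind_idx == 0L) 1 else y[ind_idx]
    a1 <- k1 * y[2L];          r1 <- d1 * y[1L] * H
    a2 <- k2 * y[4L] * y[1L];  r2 <- d2 * y[3L]
    a3 <- k3 * y[6L] * y[1L];  r3 <- d3 * y[5L] * y[9L]
    a4 <- k4 * y[8L] * y[1L];  r4 <- d4 * y[7L] * y[9L]
    a5 <- k5 * y[10L] * ind;   r5 <- d5 * y[9L]
    jp <- y[5L] * y[7L]
    sv <- s1 * y[3L] - s2 * (if (jp > 0) jp^hill else 0)
    list(c(a1 - r1, r1 - a1, a2 - r2, r2 - a2, a3 - r3, r3 - a3,
           a4 - r4, r4 - a4, a5 - r5, r5 - a5, sv))
  }
}

#' Instantaneous rates of change
#'
#' Evaluates the model's right-hand side at one state. For every
#' active/inactive pair the two rates sum to zero identically (mass
#' conservation is structural).
#'
#' @param state named numeric vector over the 11 state variables (any
#'   order); protein amounts must be nonnegative.
#' @param model a [dusp_model()] object.
#' @return Named numeric vector of derivatives, one per state variable.
#' @examples
#' m <- dusp_model("constitutive")
#' dusp_rates(initial_state(m), m)
#' @export
dusp_rates <- function(state, model) {
  stopifnot(inherits(model, "dusp_model"))
  if (is.null(names(state)) || !all(.state_names %in% names(state))) {
    stop("'state' must be named over: ",
         paste(.state_names, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(state[.state_names])
  if (any(y[1:10] < 0)) {
    stop("protein amounts must be >= 0", call. = FALSE)
  }
  dy <- rhs_factory(model)(0, y, NULL)[[1L]]
  stats::setNames(dy, .state_names)
}

#' Closed-form steady state
#'
#' Solves the protein subsystem's fixed point algebraically. HER2 and
#' ERK1/2 steady actives follow directly from their pair balances; the
#' DUSP level is linear in the constitutive and ERK12-induced topologies
#' and the positive root of a quadratic when DUSP is induced by JNK1/2
#' (the inducer is itself dephosphorylated by DUSP). The eventual survival
#' slope is the survival rate evaluated at the fixed point.
#'
#' @param model a [dusp_model()] object.
#' @return An object of class `dusp_steady`: list with `active` (named
#'   steady active amounts for the five proteins) and `survival_slope`.
#' @examples
#' steady_state(dusp_model("constitutive", dusp_params(d5 = 1)))
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "dusp_model"))
  p <- model$params
  tot <- p$totals
  fail <- function(which) {
    stop("no unique nonnegative steady state for the ", which,
         " pair (degenerate rates)", call. = FALSE)
  }
  den_h <- p$k1 + p$d1 * p$herceptin
  if (den_h <= 0) fail("HER2")
  H2 <- p$k1 * tot[["HER2"]] / den_h
  den_e <- p$k2 * H2 + p$d2
  if (den_e <= 0) fail("ERK12")
  E <- p$k2 * H2 * tot[["ERK12"]] / den_e
  D <- switch(model$topology,
    constitutive = {
      den <- p$k5 + p$d5
      if (den <= 0) fail("DUSP")
      p$k5 * tot[["DUSP"]] / den
    },
    ERK12 = {
      den <- p$k5 * E + p$d5
      if (den <= 0) fail("DUSP")
      p$k5 * E * tot[["DUSP"]] / den
    },
    JNK12 = {
      # Balance k5*(T_D - D)*J = d5*D with J = aJ*T_J/(aJ + d3*D),
      # aJ = k3*HER2ac*: quadratic A*D^2 + B*D + C = 0.
      aJ <- p$k3 * H2
      A <- p$d5 * p$d3
      B <- aJ * (p$d5 + p$k5 * tot[["JNK12"]])
      C <- -p$k5 * aJ * tot[["JNK12"]] * tot[["DUSP"]]
      if (A == 0) {
        if (B <= 0) {
          if (C == 0 && p$d5 == 0) tot[["DUSP"]] else fail("DUSP")
        } else -C / B
      } else {
        disc <- B^2 - 4 * A * C
        if (disc < 0) fail("DUSP")
        (-B + sqrt(disc)) / (2 * A)
      }
    })
  active_given_dusp <- function(k, d, total, which) {
    a <- k * H2
    den <- a + d * D
    if (den <= 0) {
      if (total == 0) return(0)
      fail(which)
    }
    a * total / den
  }
  J <- active_given_dusp(p$k3, p$d3, tot[["JNK12"]], "JNK12")
  P <- active_given_dusp(p$k4, p$d4, tot[["P38"]], "P38")
  jp <- J * P
  slope <- p$s1 * E - p$s2 * (if (jp > 0) jp^p$hill else 0)
  structure(list(
    active = c(HER2ac = H2, ERK12ac = E, JNK12ac = J, P38ac = P,
               DUSPac = unname(D)),
    survival_slope = slope,
    topology = model$topology, params = p),
    class = "dusp_steady")
}

#' @export
print.dusp_steady <- function(x, ...) {
  cat("<dusp_steady> topology:", x$topology, "\n")
  print(round(x$active, 6))
  cat(sprintf("eventual survival slope: %.6g\n", x$survival_slope))
  invisible(x)
}

#' Asymptotic survival slope
#'
#' Sign predictor for the long-run behaviour of the survival trajectory:
#' the survival rate evaluated at the protein fixed point. Negative means
#' survival eventually decreases (inhibition reverses proliferation).
#'
#' @inheritParams steady_state
#' @return A single signed rate.
#' @export
survival_slope <- function(model) {
  steady_state(model)$survival_slope
}

#' @export
predict.dusp_model <- function(object, ...) {
  steady_state(object)$active
}

#' Closed-form DUSP trajectory (constitutive topology)
#'
#' In the constitutive topology the DUSP pair is autonomous and linear,
#' so the active-DUSP time course from the standard initial state has the
#' exact form `D* + (D0 - D*) * exp(-(k5 + d5) * t)` with
#' `D* = k5 * T_D / (k5 + d5)`. Used as an analytic oracle for the
#' integrator.
#'
#' @param model a `dusp_model` with `topology == "constitutive"`.
#' @param times numeric vector of time points.
#' @return Active DUSP amounts at `times`.
#' @export
duspac_closed_form <- function(model, times) {
  stopifnot(inherits(model, "dusp_model"))
  if (model$topology != "constitutive") {
    stop("closed form available only for the constitutive topology",
         call. = FALSE)
  }
  p <- model$params
  lam <- p$k5 + p$d5
  if (lam <= 0) stop("k5 + d5 must be > 0", call. = FALSE)
  dstar <- p$k5 * p$totals[["DUSP"]] / lam
  d0 <- unname(initial_state(p)["DUSPac"])
  dstar + (d0 - dstar) * exp(-lam * times)
}
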