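# Parameterisation of the HER2/MAPK/DUSP kinetic model.

.scalar_param_names <- c("k1", "k2", "k3", "k4", "k5",
                         "d1", "d2", "d3", "d4", "d5",
                         "s1", "s2", "hill", "herceptin")
.protein_names <- c("HER2", "ERK12", "JNK12", "P38", "DUSP")

# Prescribed initial ACTIVE amounts (inactive pools complete each protein
# to its configured total).
.init_active <- c(HER2 = 100, ERK12 = 100, JNK12 = 0, P38 = 0, DUSP = 100)

.reference_params <- function() {
  p <- as.list(c(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1,
                 d1 = 1, d2 = 1, d3 = 1, d4 = 1, d5 = 1,
                 s1 = 1, s2 = 1, hill = 0.6, herceptin = 100))
  p$totals <- c(HER2 = 100, ERK12 = 100, JNK12 = 100, P38 = 100, DUSP = 100)
  p
}

#' Kinetic parameter set
#'
#' Builds the reference parameterisation of the HER2/MAPK/DUSP model and
#' applies named overrides. The reference set uses unit rate constants
#' (`k1`--`k5`, `d1`--`d5`), unit survival weights (`s1`, `s2`), Hill
#' exponent `hill = 0.6` on the `JNK12ac * P38ac` product, a constant
#' Herceptin input of 100, and conserved per-protein totals of 100.
#'
#' `d5`, the DUSP inactivation rate, is the inhibition knob: raising it
#' emulates pharmacological inhibition or shRNA silencing of DUSP8/16.
#'
#' @param ... named overrides (e.g. `d5 = 500`), or a single named list of
#'   overrides. `totals` may be a single number (applied to every protein)
#'   or a named vector over `HER2`, `ERK12`, `JNK12`, `P38`, `DUSP`.
#' @return An object of class `dusp_params`: a list with elements
#'   `k1`..`k5`, `d1`..`d5`, `s1`, `s2`, `hill`, `herceptin` and the named
#'   `totals` vector.
#' @examples
#' dusp_params()            # reference parameterisation
#' dusp_params(d5 = 500)    # strong DUSP inhibition
#' @export
dusp_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      (is.null(names(overrides)) || !nzchar(names(overrides)[1L]))) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides) &&
      (is.null(names(overrides)) || any(!nzchar(names(overrides))))) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  p <- .reference_params()
  known <- c(.scalar_param_names, "totals")
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(names(overrides), .scalar_param_names)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
    p[[nm]] <- as.numeric(v)
  }
  if ("totals" %in% names(overrides)) {
    tv <- overrides$totals
    if (is.numeric(tv) && length(tv) == 1L && is.null(names(tv))) {
      p$totals[] <- as.numeric(tv)
    } else {
      bad <- setdiff(names(tv), .protein_names)
      if (!is.numeric(tv) || is.null(names(tv)) || length(bad)) {
        stop("'totals' must be one number or a vector named after: ",
             paste(.protein_names, collapse = ", "), call. = FALSE)
      }
      p$totals[names(tv)] <- as.numeric(tv)
    }
  }
  validate_params(p)
  structure(p, class = "dusp_params")
}

validate_params <- function(p) {
  for (nm in .scalar_param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' must be a single number", call. = FALSE)
    }
    if (nm == "hill") {
      if (v <= 0) stop("'hill' must be > 0", call. = FALSE)
    } else if (v < 0) {
      stop("parameter '", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
    }
  }
  if (any(p$totals < 0)) stop("protein totals must be >= 0", call. = FALSE)
  invisible(p)
}

# Rebuild a validated parameter set with some scalar fields replaced.
params_with <- function(params, ...) {
  repl <- list(...)
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  validate_params(params)
  params
}

#' @export
print.dusp_params <- function(x, ...) {
  cat("HER2/MAPK/DUSP kinetic parameters\n")
  sc <- unlist(x[.scalar_param_names])
  cat("  activation (k):  ", paste(sprintf("%s=%g", paste0("k", 1:5),
                                           sc[paste0("k", 1:5)]),
                                   collapse = " "), "\n")
  cat("  inactivation (d):", paste(sprintf("%s=%g", paste0("d", 1:5),
                                           sc[paste0("d", 1:5)]),
                                   collapse = " "), "\n")
  cat(sprintf("  survival weights: s1=%g s2=%g   hill=%g   herceptin=%g\n",
              x$s1, x$s2, x$hill, x$herceptin))
  cat("  totals:", paste(sprintf("%s=%g", names(x$totals), x$totals),
                         collapse = " "), "\n")
  invisible(x)
}

#' Initial model state
#'
#' Returns the model's initial condition: active HER2, ERK1/2 and DUSP at
#' 100, active JNK1/2 and p38 at 0, each inactive pool completing its
#' protein to the configured total, and the survival score at 0.
#'
#' @param x a `dusp_params` or `dusp_model` object.
#' @return Named numeric vector of length 11 (the ten active/inactive
#'   protein pools plus `Survival`).
#' @export
initial_state <- function(x) {
  p <- if (inherits(x, "dusp_model")) x$params else x
  if (!inherits(p, "dusp_params")) p <- dusp_params(p)
  act <- .init_active
  inact <- p$totals - act
  if (any(inact < 0)) {
    stop("totals smaller than the prescribed initial active amounts for: ",
         paste(.protein_names[inact < 0], collapse = ", "), call. = FALSE)
  }
  c(HER2ac = unname(act["HER2"]), HER2i = unname(inact["HER2"]),
    ERK12ac = unname(act["ERK12"]), ERK12i = unname(inact["ERK12"]),
    JNK12ac = unname(act["JNK12"]), JNK12i = unname(inact["JNK12"]),
    P38ac = unname(act["P38"]), P38i = unname(inact["P38"]),
    DUSPac = unname(act["DUSP"]), DUSPi = unname(inact["DUSP"]),
    Survival = 0)
}
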