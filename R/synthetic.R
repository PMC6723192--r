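# Seeded synthetic data with the structure of the study's measurements:
# noisy model trajectories, 72-h relative cell-count tables, qPCR Ct
# tables. All generators are pure functions of (inputs, seed): the global
# RNG state is saved and restored around each draw.

.default_observed <- c("HER2ac", "ERK12ac", "JNK12ac", "P38ac", "DUSPac",
                       "Survival")

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# value * exp(N(0, sd)): positive amounts stay positive, noise scales
# with magnitude.
lognoise <- function(truth, sd, n) truth * exp(stats::rnorm(n, 0, sd))

#' Noisy replicate observations of model trajectories
#'
#' Simulates the true trajectory, then applies independent multiplicative
#' lognormal noise per replicate and grid point to the observed species.
#'
#' @param model a [dusp_model()] object.
#' @param observed character vector of state-variable names to observe.
#' @param noise_sd sd of the log-scale noise (fraction; 0 = noiseless).
#' @param n_reps replicate count (>= 1).
#' @param seed RNG seed; same seed reproduces identical values.
#' @param opts a [solver_options()] object.
#' @return Object of class `dusp_observations`: `species`, `time`,
#'   `replicates` (one `n_reps` x `n_points` matrix per species),
#'   `truth` (the noiseless `dusp_trajectory`), `noise_sd`, `n_reps`,
#'   `seed`, `model`.
#' @export
noisy_trajectories <- function(model, observed = .default_observed,
                               noise_sd = 0.05, n_reps = 2, seed = NULL,
                               opts = solver_options()) {
  stopifnot(inherits(model, "dusp_model"), noise_sd >= 0, n_reps >= 1)
  unknown <- setdiff(observed, .state_names)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tr <- simulate_trajectory(model, opts)
  n <- length(tr$time)
  reps <- with_seed(seed, {
    out <- lapply(observed, function(sp) {
      truth <- tr$state[, sp]
      m <- matrix(NA_real_, nrow = n_reps, ncol = n)
      for (r in seq_len(n_reps)) m[r, ] <- lognoise(truth, noise_sd, n)
      m
    })
    names(out) <- observed
    out
  })
  structure(list(species = observed, time = tr$time, replicates = reps,
                 truth = tr, noise_sd = noise_sd, n_reps = n_reps,
                 seed = seed, model = model),
            class = "dusp_observations")
}

#' @export
print.dusp_observations <- function(x, ...) {
  cat(sprintf(
    "<dusp_observations> %d replicate(s) of %s; noise sd %g; seed %s\n",
    x$n_reps, paste(x$species, collapse = ", "), x$noise_sd,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Default true effect map for the synthetic cell-count assay
#'
#' Encodes the study's qualitative 72-h findings as true relative cell
#' numbers (72-h count / start count, normalised within each
#' sensitive/resistant pair to the sensitive value): under Herceptin the
#' resistant non-targeting (NT) line keeps growing (1.6), DUSP8 silencing
#' does not reverse resistance (2.0), DUSP16 silencing does (0.9, below
#' NT); without Herceptin all conditions grow alike (1.0).
#'
#' @return data.frame with columns `sensitivity`, `silencing`,
#'   `herceptin`, `truth`.
#' @export
default_effect_map <- function() {
  g <- expand.grid(
    silencing = c("NT", "shDUSP8", "shDUSP16"),
    sensitivity = c("sensitive", "resistant"),
    herceptin = c("yes", "no"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- rep(1, nrow(g))
  yes <- g$herceptin == "yes"
  truth[yes & g$sensitivity == "sensitive" & g$silencing == "shDUSP16"] <- 0.9
  truth[yes & g$sensitivity == "resistant" & g$silencing == "NT"] <- 1.6
  truth[yes & g$sensitivity == "resistant" & g$silencing == "shDUSP8"] <- 2.0
  truth[yes & g$sensitivity == "resistant" & g$silencing == "shDUSP16"] <- 0.9
  g$truth <- truth
  g[, c("sensitivity", "silencing", "herceptin", "truth")]
}

#' Synthetic 72-h relative cell-count table
#'
#' Lognormal replicate noise around each condition's true relative count.
#' The default design mirrors the study's assay: sensitive/resistant x
#' \{NT, shDUSP8, shDUSP16\} x Herceptin \{yes, no\}, two independent
#' replicates.
#'
#' @param effect_map data.frame as from [default_effect_map()]; `truth`
#'   must be positive.
#' @param noise_sd sd of the log-scale replicate noise.
#' @param n_reps replicates per condition.
#' @param seed RNG seed.
#' @return data.frame of class `cell_count_table` with columns
#'   `sensitivity`, `silencing`, `herceptin`, `replicate`, `rel_count`;
#'   attributes `seed`, `noise_sd`, `effect_map`.
#' @export
synth_cell_counts <- function(effect_map = default_effect_map(),
                              noise_sd = 0.05, n_reps = 2, seed = NULL) {
  stopifnot(is.data.frame(effect_map),
            all(c("sensitivity", "silencing", "herceptin", "truth") %in%
                  names(effect_map)),
            noise_sd >= 0, n_reps >= 1)
  if (any(effect_map$truth <= 0)) {
    stop("true relative counts must be > 0", call. = FALSE)
  }
  tab <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(effect_map)), function(i) {
      data.frame(sensitivity = effect_map$sensitivity[i],
                 silencing = effect_map$silencing[i],
                 herceptin = effect_map$herceptin[i],
                 replicate = seq_len(n_reps),
                 rel_count = lognoise(effect_map$truth[i], noise_sd, n_reps),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  structure(tab, seed = seed, noise_sd = noise_sd, effect_map = effect_map,
            class = c("cell_count_table", "data.frame"))
}

#' Synthetic qPCR Ct table
#'
#' Builds threshold-cycle values for one target DUSP gene and two
#' housekeeping genes so that the noiseless delta-delta-Ct fold change of
#' each silenced sample relative to the reference equals
#' `1 - knockdown`: the silenced sample's target Ct is shifted up by
#' `-log2(1 - knockdown)` cycles. Gaussian Ct noise is then added and
#' values are clamped to the instrument range [1, 40].
#'
#' @param knockdown named numeric vector of knockdown fractions in
#'   [0, 1), one per silenced sample (e.g. `c(shDUSP16 = 0.75)`).
#' @param target target gene name.
#' @param reference reference (non-targeting) sample name.
#' @param ct_noise_sd sd of the additive Ct noise, in cycles.
#' @param n_reps replicates per (sample, gene).
#' @param seed RNG seed.
#' @param base_ct named numeric: baseline Ct of the target in the
#'   reference sample and of the two housekeeping genes.
#' @return data.frame of class `ct_table` with columns `sample`, `gene`,
#'   `replicate`, `ct`; attributes `seed`, `ct_noise_sd`, `knockdown`,
#'   `target`, `housekeeping`, `reference`.
#' @export
synth_qpcr <- function(knockdown = c(shDUSP16 = 0.75), target = "DUSP16",
                       reference = "NT", ct_noise_sd = 0.15, n_reps = 2,
                       seed = NULL,
                       base_ct = c(target = 24, ACTB = 18, GAPDH = 20)) {
  if (!is.numeric(knockdown) || is.null(names(knockdown)) ||
      any(!nzchar(names(knockdown)))) {
    stop("'knockdown' must be a named numeric vector", call. = FALSE)
  }
  if (any(knockdown < 0 | knockdown >= 1)) {
    stop("knockdown fractions must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(ct_noise_sd >= 0, n_reps >= 1,
            all(c("target", "ACTB", "GAPDH") %in% names(base_ct)))
  hk <- c("ACTB", "GAPDH")
  samples <- c(reference, names(knockdown))
  true_ct <- function(sample, gene) {
    if (gene %in% hk) return(base_ct[[gene]])
    shift <- if (sample == reference) 0 else -log2(1 - knockdown[[sample]])
    base_ct[["target"]] + shift
  }
  tab <- with_seed(seed, {
    rows <- lapply(samples, function(s) {
      do.call(rbind, lapply(c(target, hk), function(g) {
        ct <- true_ct(s, g) + stats::rnorm(n_reps, 0, ct_noise_sd)
        data.frame(sample = s, gene = g, replicate = seq_len(n_reps),
                   ct = pmin(40, pmax(1, ct)), stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  structure(tab, seed = seed, ct_noise_sd = ct_noise_sd,
            knockdown = knockdown, target = target, housekeeping = hk,
            reference = reference,
            class = c("ct_table", "data.frame"))
}

#' Write a synthetic table with its provenance sidecar
#'
#' CSV of the table plus a JSON sidecar recording the seed and noise
#' descriptor.
#'
#' @param tab a `cell_count_table` or `ct_table`.
#' @param file CSV output path; the sidecar is written to
#'   `<file>.provenance.json`.
#' @export
write_synth_table <- function(tab, file) {
  utils::write.csv(as.data.frame(tab), file, row.names = FALSE)
  prov <- list(seed = attr(tab, "seed"),
               class = class(tab)[1L])
  for (a in c("noise_sd", "ct_noise_sd", "knockdown", "target",
              "housekeeping", "reference")) {
    if (!is.null(attr(tab, a))) prov[[a]] <- attr(tab, a)
  }
  jsonlite::write_json(prov, paste0(file, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
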