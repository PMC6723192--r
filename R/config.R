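# Run configuration: plain-text (YAML/JSON) config with strict key
# validation, and the end-to-end pipeline.

#' Default run configuration
#'
#' Reproduces the baseline inhibition scan: reference parameterisation,
#' constitutive DUSP topology, d5 grid \{1, 10, 20, 50, 100, 500\},
#' default solver options, and the default synthetic-experiment settings.
#'
#' @return Object of class `dusp_config` (a named list).
#' @export
default_config <- function() {
  structure(list(
    params = list(),
    topology = "constitutive",
    d5_grid = c(1, 10, 20, 50, 100, 500),
    solver = list(t_end = 10, n_points = 1001, rtol = 1e-8, atol = 1e-10),
    classify = list(eps_frac = 0.01, delta_frac = 0.05),
    synthetic = list(seed = 1, noise_sd = 0.05, n_reps = 2,
                     knockdown = 0.75, ct_noise_sd = 0.15),
    alpha = 0.05,
    out_dir = "duspkin-run"
  ), class = "dusp_config")
}

# Merge user values into defaults, rejecting unknown keys with their
# full dotted path.
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user) || (is.list(user) && length(user) == 0L)) {
    return(defaults)
  }
  if (!is.list(user) || is.null(names(user)) || any(!nzchar(names(user)))) {
    stop("configuration section '", paste(path, collapse = "."),
         "' must be a named mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    pfx <- if (length(path)) paste0(paste(path, collapse = "."), ".") else ""
    stop("unknown configuration key(s): ",
         paste0(pfx, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "params") {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     c(path, nm))
    } else if (nm == "d5_grid") {
      defaults[[nm]] <- as.numeric(unlist(user[[nm]]))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  cfg$topology <- match.arg(cfg$topology, .topologies)
  # these constructors perform the numeric validation
  dusp_params(cfg$params)
  do.call(solver_options, cfg$solver)
  cl <- cfg$classify
  stopifnot(cl$eps_frac > 0, cl$eps_frac < 1,
            cl$delta_frac > 0, cl$delta_frac < 1)
  if (!length(cfg$d5_grid) || any(cfg$d5_grid < 0)) {
    stop("'d5_grid' must be nonempty and nonnegative", call. = FALSE)
  }
  sy <- cfg$synthetic
  stopifnot(sy$noise_sd >= 0, sy$n_reps >= 1,
            sy$knockdown >= 0, sy$knockdown < 1, sy$ct_noise_sd >= 0)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "dusp_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration file, fills in
#' defaults, and validates. An empty file yields [default_config()].
#' Unknown keys are rejected by name, including nested ones
#' (e.g. `solver.n_points`).
#'
#' @param path configuration file path.
#' @return A validated `dusp_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(merge_config(unclass(default_config()), raw))
}

#' @export
print.dusp_config <- function(x, ...) {
  cat("<dusp_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end run driven by one configuration: inhibition scan with
#' regime classification, per-d5 trajectory CSVs, scan summary
#' (JSON + TSV), synthetic cell-count and qPCR tables with provenance
#' sidecars, delta-delta-Ct fold changes, and the directional
#' model-experiment concordance report. Model predictions map DUSP16
#' silencing to the constitutive topology and DUSP8 silencing to the
#' ERK12-induced topology, each at the scan grid's highest d5. Two runs
#' with the same configuration (including seeds) produce byte-identical
#' payloads; progress is logged to stderr.
#'
#' @param config a `dusp_config`, or a path to a configuration file.
#' @param out_dir output directory (default: the config's `out_dir`).
#' @return Invisibly, a list with the scan, synthetic tables, fold
#'   changes, concordance report, threshold and written file paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "dusp_config"))
  config <- validate_config(unclass(config))
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  log <- function(...) message("[duspkin] ", ...)
  files <- character(0)
  keep <- function(f) { files <<- c(files, f); f }

  params <- dusp_params(config$params)
  model <- dusp_model(config$topology, params)
  opts <- do.call(solver_options, config$solver)

  log("inhibition scan over d5 = {",
      paste(config$d5_grid, collapse = ", "), "}, topology ",
      config$topology)
  scan <- inhibition_scan(model, config$d5_grid, opts,
                          eps_frac = config$classify$eps_frac,
                          delta_frac = config$classify$delta_frac)
  for (e in scan$entries) {
    if (is.null(e$trajectory)) next
    write_trajectory_csv(
      e$trajectory,
      keep(file.path(out_dir, sprintf("trajectory_d5_%g.csv", e$d5))))
  }
  write_scan_summary(scan,
                     tsv = keep(file.path(out_dir, "regimes.tsv")),
                     json = keep(file.path(out_dir, "scan.json")))
  threshold <- decrease_threshold(scan, config$classify$eps_frac)
  log("smallest eventually-decreasing d5: ",
      if (is.na(threshold)) "none" else threshold)

  sy <- config$synthetic
  log("synthetic experiments (seed ", sy$seed, ")")
  counts <- synth_cell_counts(noise_sd = sy$noise_sd, n_reps = sy$n_reps,
                              seed = sy$seed)
  write_synth_table(counts, keep(file.path(out_dir, "cell_counts.csv")))
  qpcr <- list(
    DUSP8 = synth_qpcr(c(shDUSP8 = sy$knockdown), target = "DUSP8",
                       ct_noise_sd = sy$ct_noise_sd, n_reps = sy$n_reps,
                       seed = sy$seed + 1L),
    DUSP16 = synth_qpcr(c(shDUSP16 = sy$knockdown), target = "DUSP16",
                        ct_noise_sd = sy$ct_noise_sd, n_reps = sy$n_reps,
                        seed = sy$seed + 2L))
  folds <- list()
  for (tg in names(qpcr)) {
    write_synth_table(qpcr[[tg]],
                      keep(file.path(out_dir,
                                     sprintf("qpcr_%s.csv", tg))))
    folds[[tg]] <- delta_delta_ct(qpcr[[tg]])
  }
  write_json_file(lapply(folds, function(f) as.list(as.data.frame(f))),
                  keep(file.path(out_dir, "fold_changes.json")))

  log("concordance of model predictions with the synthetic assay")
  d5_hi <- max(config$d5_grid)
  preds <- c(
    shDUSP8 = predicted_direction(dusp_model("ERK12", params),
                                  d5 = d5_hi,
                                  eps_frac = config$classify$eps_frac,
                                  opts = opts),
    shDUSP16 = predicted_direction(dusp_model("constitutive", params),
                                   d5 = d5_hi,
                                   eps_frac = config$classify$eps_frac,
                                   opts = opts))
  conc <- concordance(preds, counts, alpha = config$alpha)
  write_json_file(as.list(as.data.frame(conc)),
                  keep(file.path(out_dir, "concordance.json")))

  prov <- list(package = "duspkin",
               version = as.character(utils::packageVersion("duspkin")),
               config = unclass(config))
  write_json_file(prov, keep(file.path(out_dir, "provenance.json")))
  log("wrote ", length(files), " files to ", out_dir)
  invisible(list(out_dir = out_dir, files = files, scan = scan,
                 threshold = threshold, counts = counts, qpcr = qpcr,
                 fold_changes = folds, predictions = preds,
                 concordance = conc))
}
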