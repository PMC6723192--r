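# Survival-trajectory metrics, regime classification, conservation.

#' Survival-trajectory summary metrics
#'
#' @param x a `dusp_trajectory`, or a numeric vector of survival values.
#' @param time optional time grid when `x` is a plain vector (defaults to
#'   `0, 1, 2, ...`).
#' @return Object of class `survival_metrics`: `s0`, `s_end`, `s_min`,
#'   `s_max`, `t_at_max` and `range` (`s_max - s_min`).
#' @examples
#' survival_metrics(c(0, 5, 2))
#' @export
survival_metrics <- function(x, time = NULL) {
  if (inherits(x, "dusp_trajectory")) {
    s <- x$state[, "Survival"]
    time <- x$time
  } else {
    s <- as.numeric(x)
    if (is.null(time)) time <- seq_along(s) - 1
  }
  if (!length(s)) stop("empty trajectory", call. = FALSE)
  stopifnot(length(time) == length(s))
  i <- which.max(s)
  structure(list(s0 = s[1L], s_end = s[length(s)], s_min = min(s),
                 s_max = s[i], t_at_max = time[i],
                 range = s[i] - min(s)),
            class = "survival_metrics")
}

#' @export
print.survival_metrics <- function(x, ...) {
  cat(sprintf(
    "survival: s0=%.4g end=%.4g min=%.4g max=%.4g (at t=%.4g) range=%.4g\n",
    x$s0, x$s_end, x$s_min, x$s_max, x$t_at_max, x$range))
  invisible(x)
}

#' Does a survival trajectory eventually decrease?
#'
#' TRUE when the final value sits below the running maximum by more than
#' `eps_frac` of the trajectory's range.
#'
#' @param metrics a [survival_metrics()] object.
#' @param eps_frac tolerated terminal drop, as a fraction of range.
#' @export
eventually_decreasing <- function(metrics, eps_frac = 0.01) {
  stopifnot(inherits(metrics, "survival_metrics"),
            eps_frac > 0, eps_frac < 1)
  metrics$range > 0 &&
    (metrics$s_max - metrics$s_end) > eps_frac * metrics$range
}

#' Classify a survival trajectory
#'
#' Shape-only decision on the discrete grid, mirroring the three
#' behaviours seen across the inhibition scan: `"increasing"` when the
#' maximum is effectively terminal (`s_max - s_end <= eps_frac * range`;
#' a flat trajectory counts as increasing), otherwise `"inflected"` when
#' there was a substantial rise before the fall
#' (`s_max - s0 > delta_frac * range`), else `"decreasing"`. Invariant to
#' affine rescaling of the survival values.
#'
#' @param metrics a [survival_metrics()] object.
#' @param eps_frac terminal-drop tolerance, in (0, 1).
#' @param delta_frac minimum interior rise separating inflected from
#'   decreasing, in (0, 1).
#' @return One of `"increasing"`, `"inflected"`, `"decreasing"`.
#' @export
classify_regime <- function(metrics, eps_frac = 0.01, delta_frac = 0.05) {
  stopifnot(inherits(metrics, "survival_metrics"),
            eps_frac > 0, eps_frac < 1, delta_frac > 0, delta_frac < 1)
  rng <- metrics$range
  if (rng <= 0) return("increasing")
  if ((metrics$s_max - metrics$s_end) <= eps_frac * rng) return("increasing")
  if ((metrics$s_max - metrics$s0) > delta_frac * rng) "inflected"
  else "decreasing"
}

#' Smallest eventually-decreasing d5 in a scan
#'
#' @param scan a `dusp_scan`.
#' @param eps_frac terminal-drop tolerance passed to
#'   [eventually_decreasing()].
#' @return The smallest scanned `d5` whose survival trajectory eventually
#'   decreases, or `NA` if none does (failed entries are skipped).
#' @export
decrease_threshold <- function(scan, eps_frac = 0.01) {
  stopifnot(inherits(scan, "dusp_scan"))
  for (e in scan$entries) {
    if (is.null(e$metrics)) next
    if (eventually_decreasing(e$metrics, eps_frac)) return(e$d5)
  }
  NA_real_
}

#' Per-protein conservation check
#'
#' For each active/inactive pair, the maximum over the grid of
#' `|ac + i - total| / total` (absolute deviation when the total is 0).
#'
#' @param traj a `dusp_trajectory`.
#' @param tol deviation threshold for flagging.
#' @return data.frame with columns `protein`, `total`, `max_dev`,
#'   `relative` (whether `max_dev` is a relative deviation) and
#'   `flagged`.
#' @export
conservation_check <- function(traj, tol = 1e-6) {
  stopifnot(inherits(traj, "dusp_trajectory"))
  rows <- lapply(.protein_names, function(p) {
    sums <- traj$state[, paste0(p, "ac")] + traj$state[, paste0(p, "i")]
    tot <- traj$params$totals[[p]]
    rel <- tot > 0
    dev <- if (rel) max(abs(sums - tot)) / tot else max(abs(sums))
    data.frame(protein = p, total = tot, max_dev = dev, relative = rel,
               flagged = dev > tol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tol") <- tol
  out
}

#' Serialize scan regimes
#'
#' Writes the per-d5 regime table as tab-separated text and, optionally,
#' a JSON summary including the decrease threshold.
#'
#' @param scan a `dusp_scan`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @export
write_scan_summary <- function(scan, tsv = NULL, json = NULL) {
  stopifnot(inherits(scan, "dusp_scan"))
  tab <- summary(scan)
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    thr <- decrease_threshold(scan, scan$eps_frac)
    payload <- list(
      topology = scan$topology,
      eps_frac = scan$eps_frac, delta_frac = scan$delta_frac,
      threshold_d5 = if (is.na(thr)) "none" else thr,
      entries = lapply(scan$entries, function(e) {
        if (!is.null(e$error)) return(list(d5 = e$d5, error = e$error))
        m <- e$metrics
        list(d5 = e$d5, regime = e$regime,
             eventually_decreasing = e$eventually_decreasing,
             s0 = m$s0, s_end = m$s_end, s_min = m$s_min, s_max = m$s_max,
             t_at_max = m$t_at_max)
      }))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(scan)
}
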