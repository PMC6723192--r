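# The study's quantification and comparison statistics: delta-delta-Ct
# relative expression, a two-sample Z-test on means, and directional
# model-experiment concordance.

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per (sample, gene). For each target
#' gene (any gene that is not housekeeping):
#' `dCt = Ct(target) - mean Ct(housekeeping)`,
#' `ddCt = dCt(sample) - dCt(reference)`, fold change `2^-ddCt`. The
#' housekeeping normaliser is the arithmetic mean over the housekeeping
#' genes, so the result is invariant to their order.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (a `ct_table`
#'   from [synth_qpcr()] qualifies).
#' @param housekeeping housekeeping gene names; every sample must carry
#'   all of them.
#' @param reference reference sample name (fold change 1 by
#'   construction).
#' @return data.frame of class `fold_change_table` with columns `sample`,
#'   `gene`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @examples
#' ct <- synth_qpcr(c(shDUSP16 = 0.75), ct_noise_sd = 0, seed = 1)
#' delta_delta_ct(ct)
#' @export
delta_delta_ct <- function(ct, housekeeping = c("ACTB", "GAPDH"),
                           reference = "NT") {
  stopifnot(is.data.frame(ct),
            all(c("sample", "gene", "ct") %in% names(ct)),
            length(housekeeping) >= 1)
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = as.data.frame(ct),
                              FUN = mean)
  samples <- unique(mean_ct$sample)
  if (!reference %in% samples) {
    stop("reference sample '", reference, "' not present", call. = FALSE)
  }
  for (s in samples) {
    have <- mean_ct$gene[mean_ct$sample == s]
    miss <- setdiff(housekeeping, have)
    if (length(miss)) {
      stop("sample '", s, "' is missing housekeeping gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  hk_mean <- vapply(samples, function(s) {
    mean(mean_ct$ct[mean_ct$sample == s & mean_ct$gene %in% housekeeping])
  }, numeric(1))
  names(hk_mean) <- samples
  targets <- setdiff(unique(mean_ct$gene), housekeeping)
  if (!length(targets)) stop("no target genes in the table", call. = FALSE)
  rows <- lapply(targets, function(g) {
    sub <- mean_ct[mean_ct$gene == g, , drop = FALSE]
    dct <- sub$ct - hk_mean[sub$sample]
    ref_dct <- dct[sub$sample == reference]
    if (!length(ref_dct)) {
      stop("reference sample lacks target gene '", g, "'", call. = FALSE)
    }
    ddct <- dct - ref_dct
    data.frame(sample = sub$sample, gene = g, delta_ct = unname(dct),
               delta_delta_ct = unname(ddct),
               fold_change = 2^(-unname(ddct)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "housekeeping") <- housekeeping
  attr(out, "reference") <- reference
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Two-sample Z-test on group means
#'
#' `z = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)` with a two-sided
#' p-value from the standard normal. Standard errors are estimated as
#' `sd / sqrt(n)` unless supplied.
#'
#' @param a,b numeric replicate values (each of length >= 2 unless its
#'   standard error is supplied).
#' @param se_a,se_b optional known standard errors of the group means.
#' @return An object of class `htest` with the z statistic, two-sided
#'   p-value and the two group means.
#' @examples
#' z_test_counts(c(1.02, 0.98), c(0.52, 0.48))
#' @export
z_test_counts <- function(a, b, se_a = NULL, se_b = NULL) {
  se_of <- function(x, se, label) {
    if (!is.null(se)) {
      stopifnot(is.numeric(se), length(se) == 1L, se >= 0)
      return(se)
    }
    if (length(x) < 2L) {
      stop("group ", label,
           " needs >= 2 values (or a supplied standard error)",
           call. = FALSE)
    }
    stats::sd(x) / sqrt(length(x))
  }
  sa <- se_of(a, se_a, "a")
  sb <- se_of(b, se_b, "b")
  pooled <- sqrt(sa^2 + sb^2)
  if (pooled == 0) {
    stop("zero pooled standard error: Z-test undefined", call. = FALSE)
  }
  z <- (mean(a) - mean(b)) / pooled
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(`mean a` = mean(a), `mean b` = mean(b)),
                 stderr = pooled,
                 method = "Two-sample Z-test on means",
                 data.name = paste(deparse1(substitute(a)), "vs",
                                   deparse1(substitute(b)))),
            class = "htest")
}

#' Predicted response direction under DUSP silencing
#'
#' Maps shRNA silencing onto the model as an elevated DUSP inactivation
#' rate, simulates, and reports `"decrease"` when the survival trajectory
#' eventually decreases, else `"no_decrease"`.
#'
#' @param model a [dusp_model()] for the relevant induction topology.
#' @param d5 elevated inactivation rate representing the knockdown.
#' @param eps_frac terminal-drop tolerance, see
#'   [eventually_decreasing()].
#' @param opts a [solver_options()] object.
#' @return `"decrease"` or `"no_decrease"`.
#' @export
predicted_direction <- function(model, d5 = 500, eps_frac = 0.01,
                                opts = solver_options()) {
  stopifnot(inherits(model, "dusp_model"), d5 >= 0)
  m <- dusp_model(model$topology, params_with(model$params, d5 = d5))
  met <- survival_metrics(simulate_trajectory(m, opts))
  if (eventually_decreasing(met, eps_frac)) "decrease" else "no_decrease"
}

#' Model-experiment concordance
#'
#' For each silenced condition, compares the silenced against the
#' non-targeting (NT) replicates with the Z-test; the observed direction
#' is `"decrease"` or `"increase"` only when `p < alpha`, otherwise
#' `"none"` (flagged non-informative). The model direction comes from the
#' supplied predictions (`"decrease"` if the simulated trajectory at
#' elevated d5 eventually decreases, else `"no_decrease"`). Agreement is
#' directional: a predicted decrease must be observed as a decrease; a
#' predicted no-decrease must be observed as an increase.
#'
#' @param predictions named character vector, one entry per silencing
#'   condition (names matching the table's `silencing` levels), with
#'   values `"decrease"` or `"no_decrease"`; see
#'   [predicted_direction()].
#' @param counts a `cell_count_table` from [synth_cell_counts()].
#' @param alpha significance level for calling a direction.
#' @param sensitivity,herceptin which stratum to score (defaults:
#'   resistant cells under Herceptin, the study's key comparison).
#' @return data.frame of class `concordance_report` with one row per
#'   condition: `silencing`, `model_direction`, `observed_direction`,
#'   `z`, `p_value`, `informative`, `agreement` (`NA` when
#'   non-informative).
#' @export
concordance <- function(predictions, counts, alpha = 0.05,
                        sensitivity = "resistant", herceptin = "yes") {
  stopifnot(is.character(predictions), !is.null(names(predictions)),
            all(predictions %in% c("decrease", "no_decrease")),
            is.data.frame(counts), alpha > 0, alpha < 1)
  df <- as.data.frame(counts)
  stratum <- df[df$sensitivity == sensitivity & df$herceptin == herceptin, ]
  nt <- stratum$rel_count[stratum$silencing == "NT"]
  if (!length(nt)) stop("no NT rows in the selected stratum", call. = FALSE)
  rows <- lapply(names(predictions), function(cond) {
    x <- stratum$rel_count[stratum$silencing == cond]
    if (!length(x)) {
      stop("condition '", cond, "' not present in the cell-count table",
           call. = FALSE)
    }
    zt <- z_test_counts(x, nt)
    z <- unname(zt$statistic)
    observed <- if (zt$p.value < alpha) {
      if (z < 0) "decrease" else "increase"
    } else "none"
    informative <- observed != "none"
    agreement <- if (!informative) NA else {
      (predictions[[cond]] == "decrease") == (observed == "decrease")
    }
    data.frame(silencing = cond, model_direction = predictions[[cond]],
               observed_direction = observed, z = z,
               p_value = zt$p.value, informative = informative,
               agreement = agreement, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "sensitivity") <- sensitivity
  attr(out, "herceptin") <- herceptin
  class(out) <- c("concordance_report", "data.frame")
  out
}
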