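# Shared fixtures. Heavy objects (full-resolution scans) are built once
# per test run and cached.

.fixtures <- new.env(parent = emptyenv())

ref_model <- function(d5 = 1, topology = "constitutive") {
  dusp_model(topology, dusp_params(d5 = d5))
}

# Coarser output grid for tests where only the shape matters.
fast_opts <- function(n_points = 201) solver_options(n_points = n_points)

ref_scan <- function(topology = "constitutive") {
  key <- paste0("scan_", topology)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- inhibition_scan(ref_model(topology = topology))
  }
  .fixtures[[key]]
}

scan_regimes <- function(scan) {
  vapply(scan$entries, function(e) e$regime, character(1))
}
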