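test_that("zero-noise observations equal the true trajectory", {
  m <- ref_model(d5 = 50)
  obs <- noisy_trajectories(m, observed = c("DUSPac", "Survival"),
                            noise_sd = 0, n_reps = 3, seed = 11,
                            opts = fast_opts(51))
  for (sp in obs$species) {
    for (r in 1:3) {
      expect_equal(unname(obs$replicates[[sp]][r, ]),
                   unname(obs$truth$state[, sp]))
    }
  }
})

test_that("generators are pure functions of (inputs, seed)", {
  m <- ref_model(d5 = 50)
  o1 <- noisy_trajectories(m, "DUSPac", 0.05, 2, seed = 1, fast_opts(21))
  o2 <- noisy_trajectories(m, "DUSPac", 0.05, 2, seed = 1, fast_opts(21))
  expect_identical(o1$replicates, o2$replicates)
  expect_false(identical(
    o1$replicates,
    noisy_trajectories(m, "DUSPac", 0.05, 2, seed = 2,
                       fast_opts(21))$replicates))

  c1 <- synth_cell_counts(seed = 9)
  c2 <- synth_cell_counts(seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  q1 <- synth_qpcr(c(shDUSP16 = 0.75), seed = 9)
  q2 <- synth_qpcr(c(shDUSP16 = 0.75), seed = 9)
  expect_identical(as.data.frame(q1), as.data.frame(q2))

  # the global RNG stream is untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(synth_cell_counts(seed = 4))
  expect_identical(stats::runif(1), before)
})

test_that("replicate means converge to the truth (law of large numbers)", {
  m <- ref_model(d5 = 1)
  obs <- noisy_trajectories(m, "DUSPac", noise_sd = 0.05, n_reps = 100,
                            seed = 1, opts = fast_opts(41))
  truth <- obs$truth$state[, "DUSPac"]
  reps <- obs$replicates[["DUSPac"]]
  se <- apply(reps, 2L, stats::sd) / sqrt(nrow(reps))
  expect_true(all(abs(colMeans(reps) - truth) <= 3 * se))
})

test_that("unknown observed species are rejected", {
  expect_error(noisy_trajectories(ref_model(), "AKT", 0, 1, 1),
               "unknown species")
})

test_that("default effect map encodes the qualitative 72-h findings", {
  em <- default_effect_map()
  truth_of <- function(sens, sil) {
    em$truth[em$sensitivity == sens & em$silencing == sil &
               em$herceptin == "yes"]
  }
  expect_lt(truth_of("resistant", "shDUSP16"), truth_of("resistant", "NT"))
  expect_gt(truth_of("resistant", "shDUSP8"), truth_of("resistant", "NT"))
  # noiseless table reproduces the map exactly
  tab <- synth_cell_counts(noise_sd = 0, n_reps = 2, seed = 1)
  r16 <- tab$rel_count[tab$sensitivity == "resistant" &
                         tab$silencing == "shDUSP16" &
                         tab$herceptin == "yes"]
  rnt <- tab$rel_count[tab$sensitivity == "resistant" &
                         tab$silencing == "NT" & tab$herceptin == "yes"]
  expect_true(all(r16 < rnt))
  expect_true(all(tab$rel_count > 0))
})

test_that("cell-count noise calibrates towards the truth as sd shrinks", {
  em <- default_effect_map()
  tab <- synth_cell_counts(em, noise_sd = 1e-6, n_reps = 2, seed = 3)
  merged <- merge(as.data.frame(tab), em)
  expect_equal(merged$rel_count, merged$truth, tolerance = 1e-4)
  expect_error(synth_cell_counts(transform(em, truth = 0)), "> 0")
})

test_that("qPCR construction inverts exactly under delta-delta-Ct", {
  ct <- synth_qpcr(c(shDUSP16 = 0.75), ct_noise_sd = 0, seed = 2)
  fc <- delta_delta_ct(ct)
  expect_equal(fc$fold_change[fc$sample == "shDUSP16"], 0.25)
  expect_equal(fc$fold_change[fc$sample == "NT"], 1)
  # satisfies the >70% knockdown selection rule
  expect_lt(fc$fold_change[fc$sample == "shDUSP16"], 0.30)
  # zero knockdown leaves expression unchanged
  fc0 <- delta_delta_ct(synth_qpcr(c(shDUSP16 = 0), ct_noise_sd = 0,
                                   seed = 2))
  expect_equal(fc0$fold_change[fc0$sample == "shDUSP16"], 1)
  # generic fractions round-trip to numerical precision
  fcx <- delta_delta_ct(synth_qpcr(c(shDUSP16 = 0.83), ct_noise_sd = 0,
                                   seed = 2))
  expect_equal(fcx$fold_change[fcx$sample == "shDUSP16"], 0.17)
})

test_that("Ct tables stay within the instrument range and carry both housekeepers", {
  ct <- synth_qpcr(c(shDUSP8 = 0.9), target = "DUSP8", ct_noise_sd = 2,
                   n_reps = 5, seed = 8)
  expect_true(all(ct$ct > 0 & ct$ct <= 40))
  for (s in unique(ct$sample)) {
    expect_true(all(c("ACTB", "GAPDH") %in% ct$gene[ct$sample == s]))
  }
  expect_error(synth_qpcr(c(shDUSP8 = 1)), "\\[0, 1\\)")
  expect_error(synth_qpcr(0.5), "named")
})

test_that("synthetic tables write CSVs with provenance sidecars", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_synth_table(synth_cell_counts(seed = 2), f)
  expect_true(file.exists(f))
  prov <- jsonlite::read_json(paste0(f, ".provenance.json"))
  expect_equal(prov$seed, 2)
  expect_equal(prov$noise_sd, 0.05)
})
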