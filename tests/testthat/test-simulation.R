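test_that("trajectories start at the initial state and conserve totals", {
  tr <- simulate_trajectory(ref_model(d5 = 1), fast_opts())
  expect_equal(unname(tr$state[1L, ]), unname(initial_state(ref_model())))
  final <- tr$state[nrow(tr$state), ]
  expect_equal(final[["HER2ac"]] + final[["HER2i"]], 100,
               tolerance = 1e-6)
  chk <- conservation_check(tr, tol = 1e-6)
  expect_false(any(chk$flagged))
})

test_that("weak inhibition yields strictly increasing survival", {
  tr <- simulate_trajectory(ref_model(d5 = 1), fast_opts())
  expect_true(all(diff(tr$state[, "Survival"]) > 0))
})

test_that("with no Herceptin and no inactivation HER2ac stays at 100", {
  p <- dusp_params(herceptin = 0, d1 = 0, d2 = 0, d3 = 0, d4 = 0, d5 = 0)
  tr <- simulate_trajectory(dusp_model("constitutive", p), fast_opts())
  expect_equal(max(abs(tr$state[, "HER2ac"] - 100)), 0, tolerance = 1e-8)
})

test_that("simulation is deterministic (bitwise-identical reruns)", {
  a <- simulate_trajectory(ref_model(d5 = 50), fast_opts())
  b <- simulate_trajectory(ref_model(d5 = 50), fast_opts())
  expect_identical(a$state, b$state)
  expect_identical(a$time, b$time)
})

test_that("halving rel_tol barely moves the survival endpoint", {
  o1 <- solver_options(rtol = 1e-8, n_points = 101)
  o2 <- solver_options(rtol = 5e-9, n_points = 101)
  for (d5 in c(1, 100)) {
    s1 <- simulate_trajectory(ref_model(d5 = d5), o1)$state[101, "Survival"]
    s2 <- simulate_trajectory(ref_model(d5 = d5), o2)$state[101, "Survival"]
    expect_lt(abs(s1 - s2) / abs(s1), 1e-4)
  }
})

test_that("integrated DUSPac matches its exponential closed form", {
  # autonomous linear DUSP pair: D(t) = D* + (100 - D*) exp(-(k5+d5) t)
  for (d5 in c(1, 50, 500)) {
    m <- ref_model(d5 = d5)
    tr <- simulate_trajectory(m)
    dstar <- 100 * 1 / (1 + d5)
    expected <- dstar + (100 - dstar) * exp(-(1 + d5) * tr$time)
    reldev <- abs(tr$state[, "DUSPac"] - expected) /
      pmax(abs(expected), 1e-12)
    expect_lt(max(reldev), 1e-6)
    # the package's own closed form agrees with the inline formula
    expect_equal(duspac_closed_form(m, tr$time), expected)
  }
})

test_that("scan simulates each grid value and labels regimes", {
  sc <- ref_scan()
  expect_s3_class(sc, "dusp_scan")
  expect_equal(vapply(sc$entries, `[[`, numeric(1), "d5"),
               c(1, 10, 20, 50, 100, 500))
  expect_identical(scan_regimes(sc)[1:3], rep("increasing", 3))
  expect_identical(scan_regimes(sc)[4], "inflected")
  tab <- summary(sc)
  expect_true(all(!is.na(tab$regime)))
})

test_that("induced-DUSP topologies never show eventual decrease on the grid", {
  for (topo in c("ERK12", "JNK12")) {
    sc <- ref_scan(topo)
    dec <- vapply(sc$entries, `[[`, logical(1), "eventually_decreasing")
    expect_false(any(dec), info = topo)
  }
})

test_that("no inhibition pins DUSP high and maximises the survival slope", {
  sc0 <- inhibition_scan(ref_model(), d5_values = 0, opts = fast_opts())
  tr0 <- sc0$entries[[1]]$trajectory
  expect_gt(min(tr0$state[, "DUSPac"]), 99.9)
  expect_false(sc0$entries[[1]]$eventually_decreasing)
  slope0 <- survival_slope(dusp_model("constitutive", dusp_params(d5 = 0)))
  for (v in c(1, 10, 20, 50, 100, 500)) {
    expect_gt(slope0, survival_slope(ref_model(d5 = v)))
  }
})

test_that("a failing scan entry is flagged without aborting the scan", {
  sc <- inhibition_scan(ref_model(), d5_values = c(1, 1e308),
                        opts = fast_opts(11))
  expect_null(sc$entries[[1]]$error)
  expect_type(sc$entries[[2]]$error, "character")
  expect_null(sc$entries[[2]]$trajectory)
  expect_true(is.na(summary(sc)$regime[2]))
})

test_that("scan input validation rejects empty or negative grids", {
  expect_error(inhibition_scan(ref_model(), numeric(0)), "nonempty")
  expect_error(inhibition_scan(ref_model(), c(1, -5)), "nonneg")
})

test_that("trajectory CSV round-trips through the documented layout", {
  tr <- simulate_trajectory(ref_model(d5 = 1), fast_opts(11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_identical(names(back), c("time", duspkin:::.state_names))
  expect_equal(back$DUSPac, unname(tr$state[, "DUSPac"]))
})
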