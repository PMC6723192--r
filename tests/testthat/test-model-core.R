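test_that("derivatives at the standard initial state match hand evaluation", {
  m <- ref_model()
  r <- dusp_rates(initial_state(m), m)
  # dSurvival/dt = s1*ERK12ac - s2*(JNK12ac*P38ac)^0.6 = 1*100 - 0
  expect_equal(r[["Survival"]], 100)
  # dHER2ac/dt = k1*HER2i - d1*HER2ac*Herceptin = 0 - 1*100*100
  expect_equal(r[["HER2ac"]], -10000)
  expect_equal(r[["HER2i"]], 10000)
})

test_that("every active/inactive pair conserves mass identically", {
  set.seed(42)
  pairs <- list(c("HER2ac", "HER2i"), c("ERK12ac", "ERK12i"),
                c("JNK12ac", "JNK12i"), c("P38ac", "P38i"),
                c("DUSPac", "DUSPi"))
  for (topo in c("constitutive", "ERK12", "JNK12")) {
    m <- dusp_model(topo, dusp_params(d5 = runif(1, 0, 100)))
    for (i in 1:20) {
      st <- stats::setNames(c(runif(10, 0, 150), runif(1, -50, 50)),
                            duspkin:::.state_names)
      r <- dusp_rates(st, m)
      for (pr in pairs) {
        expect_identical(r[[pr[1]]] + r[[pr[2]]], 0)
      }
    }
  }
})

test_that("mass-action rates vanish at the origin", {
  m <- ref_model()
  st <- stats::setNames(rep(0, 11), duspkin:::.state_names)
  r <- dusp_rates(st, m)
  expect_true(all(r[1:10] == 0))
})

test_that("negative protein amounts are rejected", {
  m <- ref_model()
  st <- initial_state(m)
  st[["JNK12ac"]] <- -1
  expect_error(dusp_rates(st, m), ">= 0")
})

test_that("constitutive steady DUSP follows k5*T/(k5+d5)", {
  expect_equal(steady_state(ref_model(d5 = 1))$active[["DUSPac"]], 50)
  expect_equal(steady_state(ref_model(d5 = 500))$active[["DUSPac"]],
               100 / 501)
})

test_that("JNK12-topology steady DUSP is the positive quadratic root", {
  # independent oracle: root of d5*d3*x^2 + aJ*(d5 + k5*T_J)*x -
  # k5*aJ*T_J*T_D from polyroot()
  p <- dusp_params(d5 = 500)
  aJ <- p$k3 * (p$k1 * 100 / (p$k1 + p$d1 * p$herceptin))
  roots <- polyroot(c(-p$k5 * aJ * 100 * 100, aJ * (p$d5 + p$k5 * 100),
                      p$d5 * p$d3))
  pos <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 0])
  ss <- steady_state(dusp_model("JNK12", p))
  expect_equal(ss$active[["DUSPac"]], pos, tolerance = 1e-10)
  expect_equal(ss$active[["DUSPac"]], 3.8953, tolerance = 1e-4)
})

test_that("steady state agrees with long-time integration in all topologies", {
  long <- solver_options(t_end = 60, n_points = 61)
  for (topo in c("constitutive", "ERK12", "JNK12")) {
    for (d5 in c(1, 50, 500)) {
      m <- dusp_model(topo, dusp_params(d5 = d5))
      ss <- steady_state(m)$active
      tr <- simulate_trajectory(m, long)
      final <- tr$state[nrow(tr$state), names(ss)]
      expect_equal(unname(final), unname(ss), tolerance = 1e-6,
                   info = paste(topo, d5))
    }
  }
})

test_that("steady state substituted into the derivatives is a fixed point", {
  for (topo in c("constitutive", "ERK12", "JNK12")) {
    for (d5 in c(1, 20, 100, 500)) {
      m <- dusp_model(topo, dusp_params(d5 = d5))
      a <- steady_state(m)$active
      st <- c(HER2ac = a[["HER2ac"]], HER2i = 100 - a[["HER2ac"]],
              ERK12ac = a[["ERK12ac"]], ERK12i = 100 - a[["ERK12ac"]],
              JNK12ac = a[["JNK12ac"]], JNK12i = 100 - a[["JNK12ac"]],
              P38ac = a[["P38ac"]], P38i = 100 - a[["P38ac"]],
              DUSPac = a[["DUSPac"]], DUSPi = 100 - a[["DUSPac"]],
              Survival = 0)
      expect_lt(max(abs(dusp_rates(st, m)[1:10])), 1e-8)
      expect_true(all(a >= 0 & a <= 100))
    }
  }
})

test_that("eventual survival slope changes sign where expected", {
  # constitutive: positive at weak inhibition, negative from d5 = 50
  expect_gt(survival_slope(ref_model(d5 = 20)), 0)
  expect_equal(survival_slope(ref_model(d5 = 20)), 49.75 - 30.4,
               tolerance = 0.01)
  expect_lt(survival_slope(ref_model(d5 = 50)), 0)
  expect_equal(survival_slope(ref_model(d5 = 50)), 49.75 - 67.8,
               tolerance = 0.01)
  # induced topologies stay positive at strong inhibition
  expect_gt(survival_slope(ref_model(500, "ERK12")), 0)
  expect_equal(survival_slope(ref_model(500, "ERK12")), 49.75 - 15.5,
               tolerance = 0.01)
  expect_gt(survival_slope(ref_model(500, "JNK12")), 0)
  # zero weights give zero slope
  expect_equal(survival_slope(dusp_model("constitutive",
                                         dusp_params(s1 = 0, s2 = 0))), 0)
})

test_that("steady active DUSP is strictly decreasing in d5 in all topologies", {
  grid <- c(0.5, 1, 5, 10, 20, 50, 100, 200, 500)
  for (topo in c("constitutive", "ERK12", "JNK12")) {
    dusp <- vapply(grid, function(v) {
      steady_state(dusp_model(topo, dusp_params(d5 = v)))$active[["DUSPac"]]
    }, numeric(1))
    expect_true(all(diff(dusp) < 0), info = topo)
  }
})

test_that("degenerate rate combinations are reported, not silently solved", {
  expect_error(steady_state(dusp_model("constitutive",
                                       dusp_params(k1 = 0, d1 = 0))),
               "degenerate")
  expect_error(steady_state(dusp_model("constitutive",
                                       dusp_params(k5 = 0, d5 = 0))),
               "degenerate")
})
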