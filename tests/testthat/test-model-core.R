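# Compartment model definitions and numerical integration.

protocol <- silk_protocol()
t13 <- seq(0, 36.2, length.out = 13)

test_that("tracer input is the documented two-level step", {
  expect_equal(tracer_input(protocol, 12), 0)
  expect_equal(tracer_input(protocol, 5), protocol$infusion_rate)
  expect_equal(tracer_input(protocol, 0.05), protocol$bolus_rate)
  expect_error(tracer_input(protocol, -1), "negative")
  # normalised dose integrates to 1, so g can never exceed 1
  expect_equal(protocol$bolus_rate * protocol$bolus_duration +
                 protocol$infusion_rate * protocol$infusion_duration, 1)
  # single-level simplification preserves the delivered dose and window
  p1 <- silk_protocol(single_level = TRUE)
  expect_equal(p1$total_label_window, protocol$total_label_window)
  expect_equal(tracer_input(p1, 0.05), tracer_input(p1, 8))
})

test_that("degenerate inputs give zero trajectories", {
  m <- silk_model("single")
  tr <- ria_trajectory(m, c(a = 0, b = 0.3), protocol, t13)
  expect_equal(tr$r, rep(0, 13), tolerance = 1e-12)
  # zero protocol: no tracer, nothing happens
  p0 <- silk_protocol(bolus_rate = 0, infusion_rate = 0, normalize = FALSE)
  tr0 <- ria_trajectory(m, c(a = 0.05, b = 0.1), p0, t13)
  expect_true(all(abs(as.matrix(tr0[, -1])) < 1e-14))
  # no inflow to CSF
  m2 <- silk_model("two_bc")
  tr2 <- ria_trajectory(m2, c(a = 0.05, b_p = 0.1, k_pc = 0, k_cp = 0.2,
                              b_c = 0.1), protocol, t13)
  expect_equal(tr2$r_csf, rep(0, 13), tolerance = 1e-12)
})

test_that("every variant starts at zero and stays finite and nonnegative", {
  set.seed(42)
  for (v in c("single", "two_bc", "three_bc_full", "three_bc_simplified")) {
    m <- silk_model(v)
    for (i in 1:10) {
      p <- draw_params(v, m$rate_names)
      tr <- ria_trajectory(m, p, protocol, t13, method = "analytic")
      st <- as.matrix(tr[, -1])
      expect_true(all(abs(st[1, ]) < 1e-12))
      expect_true(all(is.finite(st)))
      expect_true(all(st > -1e-9))
      expect_true(all(tr$g <= 1 + 1e-9))
    }
  }
})

test_that("RADAU and analytic engines match the closed-form oracle", {
  set.seed(7)
  variants <- c("single", "two_bc", "three_bc_full", "three_bc_simplified")
  for (v in variants) {
    m <- silk_model(v)
    worst_r <- 0; worst_a <- 0
    for (i in 1:8) {
      p <- draw_params(v, m$rate_names)
      ora <- oracle_trajectory(v, p, protocol, t13)
      tr_r <- as.matrix(ria_trajectory(m, p, protocol, t13,
                                       rtol = 1e-10, atol = 1e-12)[, -1])
      tr_a <- as.matrix(ria_trajectory(m, p, protocol, t13,
                                       method = "analytic")[, -1])
      worst_r <- max(worst_r, max(abs(tr_r - ora)))
      worst_a <- max(worst_a, max(abs(tr_a - ora)))
    }
    expect_lt(worst_r, 1e-8)
    expect_lt(worst_a, 1e-10)
  }
})

test_that("two_bc decouples to the single-fluid solution without transfers", {
  m1 <- silk_model("single")
  m2 <- silk_model("two_bc")
  tr1 <- ria_trajectory(m1, c(a = 0.06, b = 0.12), protocol, t13,
                        method = "analytic")
  tr2 <- ria_trajectory(m2, c(a = 0.06, b_p = 0.12, k_pc = 0, k_cp = 0,
                              b_c = 0.2), protocol, t13, method = "analytic")
  expect_equal(tr2$r_plasma, tr1$r, tolerance = 1e-12)
})

test_that("simplified model nests inside the full model", {
  mf <- silk_model("three_bc_full")
  ms <- silk_model("three_bc_simplified")
  set.seed(11)
  for (i in 1:5) {
    ps <- draw_params("three_bc_simplified", ms$rate_names)
    pf <- c(ps, k_pn = 0, k_np = 0, b_c = 0)
    trf <- ria_trajectory(mf, pf, protocol, t13, method = "analytic")
    trs <- ria_trajectory(ms, ps, protocol, t13, method = "analytic")
    expect_lt(max(abs(as.matrix(trf[, -1]) - as.matrix(trs[, -1]))), 1e-10)
  }
  # removing the CNS reduces the CSF dynamics to the 2-bc solution
  m2 <- silk_model("two_bc")
  p2 <- c(a = 0.05, b_p = 0.1, k_pc = 0.08, k_cp = 0.15, b_c = 0)
  pf <- c(a_p = 0.05, a_n = 0, b_p = 0.1, b_n = 0.2, b_c = 0,
          k_pc = 0.08, k_cp = 0.15, k_pn = 0, k_np = 0, k_nc = 0, k_cn = 0)
  tr2 <- ria_trajectory(m2, p2, protocol, t13, method = "analytic")
  trf <- ria_trajectory(mf, pf, protocol, t13, method = "analytic")
  expect_equal(trf$r_csf, tr2$r_csf, tolerance = 1e-12)
  expect_equal(trf$r_plasma, tr2$r_plasma, tolerance = 1e-12)
})

test_that("delay model collapses to two_bc at tau = 0 and matches the
           method-of-steps oracle", {
  md <- silk_model("two_bc_delay")
  m2 <- silk_model("two_bc")
  p2 <- c(a = 0.06, b_p = 0.12, k_pc = 0.08, k_cp = 0.1, b_c = 0.05)
  tr0 <- ria_trajectory(md, c(p2, tau = 0), protocol, t13)
  tr2 <- ria_trajectory(m2, p2, protocol, t13)
  expect_lt(max(abs(as.matrix(tr0[, -1]) - as.matrix(tr2[, -1]))), 1e-6)
  # a delay longer than the horizon starves the CSF completely
  trL <- ria_trajectory(md, c(p2, tau = 40), protocol, t13)
  expect_true(all(abs(trL$r_csf) < 1e-10))
  # tau = 2 h against the segment-wise oracle
  pd <- c(p2, tau = 2)
  trd <- ria_trajectory(md, pd, protocol, t13)
  ora <- oracle_dde(pd, protocol, t13)
  expect_lt(max(abs(as.matrix(trd[, -1]) - ora)), 1e-6)
})

test_that("halving solver tolerances barely moves default trajectories", {
  m <- silk_model("three_bc_simplified")
  p <- archetype_params("comparable")
  tr1 <- ria_trajectory(m, p, protocol, t13, rtol = 1e-8, atol = 1e-10)
  tr2 <- ria_trajectory(m, p, protocol, t13, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(tr1[, -1]) - as.matrix(tr2[, -1]))), 1e-6)
})

test_that("integration failure carries the parameter values", {
  m <- silk_model("single")
  expect_error(ria_trajectory(m, c(a = 0.1), protocol, t13), "missing")
  expect_error(ria_trajectory(m, c(a = -1, b = 0.1), protocol, t13),
               "negative")
  err <- tryCatch(ria_trajectory(m, c(a = NaN, b = 0.1), protocol, t13),
                  error = function(e) e)
  expect_true(inherits(err, "error"))
})
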