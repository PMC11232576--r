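# RIA computation, the weighted objective, bounded fitting, the two-step
# outlier procedure, bootstrap intervals, and protein pooling.

test_that("adjusted RIA follows the heavy-fraction formula", {
  expect_equal(compute_ria(100, 0, 1), 0)
  expect_equal(compute_ria(100, 100, 2), 0.25)
  expect_equal(compute_ria(300, 100, 2), 0.125)
  # zero total signal is missing, not zero
  expect_true(is.na(compute_ria(0, 0, 1)))
  expect_true(is.na(compute_ria(NA, 50, 1)))
  expect_equal(count_leucines(c("AGDVK", "ALDVK", "LLDVK")), c(0L, 1L, 2L))
})

test_that("weighted objective weights squared errors by relative I0", {
  obs <- clean_single_obs()
  tr <- ria_trajectory(silk_model("single"), single_truth, test_protocol,
                       obs$points$time, method = "analytic")
  # perfect fit, any weights
  expect_equal(weighted_objective(tr, obs, shift = 0.004), 0, tolerance = 1e-18)
  # equal I0 everywhere reduces to the ordinary SSE
  obs2 <- obs_from_ria(tr$r + 0.01, times = obs$points$time)
  expect_equal(weighted_objective(tr, obs2, shift = 0),
               sum((0.01)^2 * 13), tolerance = 1e-10)
  # two-point toy: raw weights {1, 3}, residuals {0.01, -0.02}; with the
  # mean-normalised weights the objective is (1e-4 + 3*4e-4) / mean(I0)
  toy_curve <- structure(data.frame(time = c(1, 2), r = c(0.05, 0.08)),
                         class = c("silk_trajectory", "data.frame"))
  toy <- obs_from_ria(c(0.05 + 0.01, 0.08 - 0.02), times = c(1, 2),
                      i0 = c(1, 3))
  expect_equal(weighted_objective(toy_curve, toy, shift = 0),
               (1 * 1e-4 + 3 * 4e-4) / mean(c(1, 3)), tolerance = 1e-12)
})

test_that("basis expansion reproduces the system matrix", {
  set.seed(5)
  for (v in c("single", "two_bc", "three_bc_full", "three_bc_simplified")) {
    m <- silk_model(v)
    p <- draw_params(v, m$rate_names)
    B <- silkdyn:::param_basis(m)
    A <- Reduce(`+`, Map(`*`, p[names(B)], B))
    expect_equal(unname(A), unname(silkdyn:::system_matrix(m, p)),
                 tolerance = 1e-15)
  }
})

test_that("bounded fit recovers noiseless single-fluid truth", {
  obs <- lapply(1:3, function(i) clean_single_obs(fraction = paste0("F", i)))
  fit <- fit_bounded(silk_model("single"), obs, test_protocol,
                     control = list(maxit = 2000, factr = 1e1))
  expect_lt(abs(fit$params[["a"]] - single_truth[["a"]]) / single_truth[["a"]],
            1e-4)
  expect_lt(abs(fit$params[["b"]] - single_truth[["b"]]) / single_truth[["b"]],
            1e-4)
  expect_lt(abs(fit$shifts[[1]] - 0.004), 1e-6)
  expect_true(fit$converged)
})

test_that("all-zero RIA data drives synthesis to the lower bound", {
  obs <- obs_from_ria(rep(0, 13))
  fit <- fit_bounded(silk_model("single"), obs, test_protocol)
  expect_equal(fit$params[["a"]], 0, tolerance = 1e-8)
})

test_that("fit beats a brute-force grid search on noisy data", {
  set.seed(21)
  tr <- ria_trajectory(silk_model("single"), single_truth, test_protocol,
                       seq(0, 36.2, length.out = 13), method = "analytic")
  y <- pmax(tr$r + 0.004 + rnorm(13, 0, 0.004), 0)
  obs <- obs_from_ria(y)
  fit <- fit_bounded(silk_model("single"), obs, test_protocol)
  w <- rep(1, 13)
  grid_best <- Inf
  for (a in seq(0.01, 0.2, length.out = 25))
    for (b in seq(0.01, 0.5, length.out = 25)) {
      r <- ria_trajectory(silk_model("single"), c(a = a, b = b),
                          test_protocol, obs$points$time,
                          method = "analytic")$r
      for (s in seq(-0.02, 0.02, length.out = 25))
        grid_best <- min(grid_best, sum(w * (r - (y - s))^2))
    }
  expect_lte(fit$weighted_sse, grid_best + 1e-10)
})

test_that("fitting is deterministic and invariant to rescaling all I0", {
  set.seed(9)
  des <- silk_design(obs_per_fluid = 2)
  gp <- generate_protein(archetype_params("comparable"), des, seed = 4)
  obs <- Filter(function(o) o$fluid == "plasma", gp$observations)
  f1 <- fit_bounded(silk_model("single"), obs, test_protocol)
  f2 <- fit_bounded(silk_model("single"), obs, test_protocol)
  expect_identical(f1$params, f2$params)
  obs_scaled <- lapply(obs, function(ob) {
    ob$points$i0 <- 2 * ob$points$i0
    ob$points$i6 <- 2 * ob$points$i6
    ob
  })
  f3 <- fit_bounded(silk_model("single"), obs_scaled, test_protocol)
  expect_equal(f1$params, f3$params, tolerance = 1e-9)
  expect_error(fit_bounded(silk_model("single"), obs, test_protocol,
                           init = c(a = 20, b = 0.1, s = 0)), "bounds")
})

test_that("two-step procedure flags time-0 and band outliers, then refits", {
  obs <- clean_single_obs()
  fit <- robust_two_step_fit(silk_model("single"), obs, test_protocol)
  fl <- fit$outlier_flags
  expect_true(all(fl$outlier[fl$time == 0]))
  expect_true(all(fl$reason[fl$time == 0] == "time0"))
  expect_false(any(fl$outlier[fl$time > 0]))

  # plant one spike beyond half the fitted dynamic range
  tr <- ria_trajectory(silk_model("single"), single_truth, test_protocol,
                       obs$points$time, method = "analytic")
  rng <- diff(range(ria_trajectory(silk_model("single"), single_truth,
                                   test_protocol, seq(0, 36.2, 0.1),
                                   method = "analytic")$r))
  y <- tr$r + 0.004
  y[7] <- y[7] + 1.5 * rng
  spiked <- obs_from_ria(y)
  fit2 <- robust_two_step_fit(silk_model("single"), spiked, test_protocol)
  fl2 <- fit2$outlier_flags
  expect_true(fl2$outlier[7])
  expect_equal(fl2$reason[7], "band")
  # the refit without the spike recovers the clean parameters
  expect_equal(fit2$params[["b"]], single_truth[["b"]], tolerance = 1e-3)
  # step-2 SSE on retained points cannot exceed step 1 on the same points
  tabs <- fit2$data
  tu <- sort(unique(c(0, unlist(lapply(tabs, `[[`, "time")))))
  obj <- silkdyn:::make_objective(silk_model("single"), tabs, test_protocol,
                                  tu)
  th1 <- c(fit2$step1$params, s = unname(fit2$step1$shifts[[1]]))
  expect_lte(fit2$weighted_sse, obj(th1) + 1e-12)
})

test_that("bootstrap intervals are tight on clean data and reproducible", {
  obs <- clean_single_obs()
  fit <- robust_two_step_fit(silk_model("single"), obs, test_protocol)
  fb <- bootstrap_ci(fit, n_boot = 40, seed = 11)
  expect_true(all(fb$ci95[, "hi"] - fb$ci95[, "lo"] <= 1e-3))
  expect_false(fb$ci_flagged)
  fb2 <- bootstrap_ci(fit, n_boot = 40, seed = 11)
  expect_identical(fb$ci95, fb2$ci95)
  # single replicate: the interval collapses onto it
  fb1 <- bootstrap_ci(fit, n_boot = 1, seed = 3)
  expect_equal(fb1$ci95[, "lo"], fb1$ci95[, "hi"], tolerance = 1e-12)
})

test_that("bootstrap intervals cover the clearance rate at design noise", {
  hits <- 0
  for (rep in 1:15) {
    des <- silk_design(obs_per_fluid = 2)
    gp <- generate_protein(archetype_params("comparable"), des,
                           seed = 300 + rep)
    obs <- Filter(function(o) o$fluid == "plasma", gp$observations)
    # reference value: the estimate on noise-free data from the same truth
    gp0 <- generate_protein(archetype_params("comparable"), clean_design(),
                            seed = 300 + rep)
    obs0 <- Filter(function(o) o$fluid == "plasma", gp0$observations)
    b_ref <- robust_two_step_fit(silk_model("single"), obs0,
                                 test_protocol)$params[["b"]]
    ft <- robust_two_step_fit(silk_model("single"), obs, test_protocol)
    fb <- bootstrap_ci(ft, n_boot = 60, seed = rep)
    if (b_ref >= fb$ci95["b", "lo"] && b_ref <= fb$ci95["b", "hi"])
      hits <- hits + 1
  }
  expect_gte(hits, 11)  # ~95% nominal; generous floor for 15 replicates
})

test_that("pooling drops shared peptides and clearance outliers, then aligns", {
  # single observation: pooling is the identity
  obs <- clean_single_obs()
  po <- pool_protein(obs, test_protocol, n_boot = 0)
  expect_equal(po$status, "ok")
  expect_length(po$observations, 1)
  expect_equal(po$offsets, 0)

  # shared peptides never enter the pooled model
  shared <- clean_single_obs(fraction = "F9")
  shared$shared <- TRUE
  po2 <- pool_protein(list(obs, shared), test_protocol, n_boot = 0)
  expect_length(po2$observations, 1)
  expect_true("shared_peptide" %in% po2$dropped$reason)

  # clearance screen: Tukey fences (boxplot.stats hinges) on {0.10, 0.11,
  # 0.12, 0.13, 0.50} flag exactly the 0.50 observation
  b_vals <- c(0.10, 0.11, 0.12, 0.13, 0.50)
  expect_equal(grDevices::boxplot.stats(b_vals)$out, 0.50)
  obs5 <- lapply(1:5, function(i) clean_single_obs(fraction = paste0("F", i)))
  fake_fits <- lapply(seq_along(obs5), function(i)
    list(params = c(a = 0.05, b = b_vals[i])))
  names(fake_fits) <- vapply(obs5, silkdyn:::obs_id, "")
  po3 <- pool_protein(obs5, test_protocol, n_boot = 0,
                      individual_fits = fake_fits)
  expect_length(po3$observations, 4)
  expect_equal(po3$dropped$reason, "clearance_outlier")
  expect_equal(po3$dropped$id, silkdyn:::obs_id(obs5[[5]]))

  # two observations differing by a constant RIA offset coincide after
  # alignment on the higher-intensity reference
  hi <- clean_single_obs(i0 = rep(2e5, 13), fraction = "F1")
  lo <- clean_single_obs(shift = 0.004 + 0.01, fraction = "F2")
  po4 <- pool_protein(list(hi, lo), test_protocol, n_boot = 0)
  expect_equal(po4$reference, silkdyn:::obs_id(hi))
  expect_lt(max(abs(po4$observations[[1]]$points$ria -
                    po4$observations[[2]]$points$ria), na.rm = TRUE), 1e-9)
})
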