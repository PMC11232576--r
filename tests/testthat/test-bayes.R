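# Priors, the MCMC sampler, posterior curve bands, and multimodality
# diagnostics.

m3 <- silk_model("three_bc_simplified")

fake_posterior <- function(log_samples, model = m3) {
  structure(list(model = model$name, model_spec = model,
                 rate_names = model$rate_names,
                 samples = list(log_samples),
                 protocol = test_protocol),
            class = "silk_posterior")
}

test_that("default priors are seeded from the single-fluid estimates", {
  fp <- list(params = c(a = 0.05, b = 0.2))
  fc <- list(params = c(a = 0.02, b = 0.08))
  pri <- default_priors(m3, fp, fc)
  expect_equal(pri$rate_means[["b_p"]], log(0.2))
  expect_equal(pri$rate_means[["a_p"]], log(0.05))
  expect_equal(pri$rate_means[["a_n"]], log(0.02))
  expect_equal(pri$rate_means[["b_n"]], log(0.08))
  # transfers fall back to the empirical constant
  expect_equal(unname(pri$rate_means[c("k_pc", "k_cp", "k_nc", "k_cn")]),
               rep(log(0.1), 4))
  expect_equal(pri$rate_precision, 10)
  expect_equal(pri$shift_precision, 5000)
  expect_warning(default_priors(m3), "no single-fluid fits")
})

test_that("with the likelihood off the kernel reproduces the priors", {
  des <- silk_design(obs_per_fluid = 1)
  gp <- generate_protein(archetype_params("comparable"), des, seed = 2)
  pri <- prior_spec(m3, stats::setNames(rep(log(0.1), 8), m3$rate_names))
  post <- run_mcmc(m3, gp$observations, pri, test_protocol,
                   n_iter = 12000, n_burn = 2000, seed = 5,
                   likelihood = FALSE)
  pooled <- do.call(rbind, post$samples)
  ks <- function(x, cdf, ...) suppressWarnings(
    stats::ks.test(x, cdf, ...)$statistic)
  for (j in 1:2)  # spot-check two log-rates
    expect_lt(ks(pooled[, j], "pnorm", log(0.1), 1 / sqrt(10)), 0.05)
  expect_lt(ks(pooled[, "s_p"], "pnorm", 0, 1 / sqrt(5000)), 0.05)
  # the vague gamma prior underflows near zero, so compare against an iid
  # reference draw (two-sample KS) rather than the analytic CDF
  set.seed(99)
  ref <- stats::rgamma(20000, 0.001, 0.001)
  expect_lt(suppressWarnings(
    stats::ks.test(pooled[, "tau_plasma"], ref)$statistic), 0.05)
})

test_that("MCMC is reproducible and chains with equal seeds coincide", {
  des <- silk_design(obs_per_fluid = 1)
  gp <- generate_protein(archetype_params("comparable"), des, seed = 3)
  p1 <- run_mcmc(m3, gp$observations, NULL, test_protocol,
                 n_iter = 600, n_burn = 300, seed = 9) |>
    suppressWarnings()
  p2 <- run_mcmc(m3, gp$observations, NULL, test_protocol,
                 n_iter = 600, n_burn = 300, seed = 9) |>
    suppressWarnings()
  expect_identical(p1$samples, p2$samples)
  p3 <- suppressWarnings(
    run_mcmc(m3, gp$observations, NULL, test_protocol, n_iter = 600,
             n_burn = 300, chain_seeds = c(4, 4)))
  expect_identical(p3$samples[[1]], p3$samples[[2]])
})

# one moderately long run shared by several checks below
concentrated_post <- local({
  truth <- archetype_params("comparable")
  des <- silk_design(obs_per_fluid = 4,
                     precision = c(plasma = 1e6, csf = 1e6),
                     fluid_shift = c(plasma = 0.003, csf = -0.002),
                     obs_shift_sd = 0, outlier_rate = 0, missing_rate = 0)
  gp <- generate_protein(truth, des, seed = 17)
  pri <- prior_spec(m3, log(truth), rate_precision = 100)
  run_mcmc(m3, gp$observations, pri, test_protocol,
           n_iter = 15000, n_burn = 5000, seed = 31)
})

test_that("a concentrated posterior recovers truth, shifts within 0.005", {
  truth <- archetype_params("comparable")
  summ <- concentrated_post$summary
  for (nm in names(truth)) {
    med <- summ$median[summ$parameter == nm]
    expect_lt(abs(med - truth[[nm]]) / truth[[nm]], 0.05)
  }
  expect_lt(abs(summ$median[summ$parameter == "s_p"] - 0.003), 0.005)
  expect_lt(abs(summ$median[summ$parameter == "s_c"] - (-0.002)), 0.005)
  expect_true(all(concentrated_post$rhat < 1.2, na.rm = TRUE))
})

test_that("posterior curve bands are coherent and cover the truth curve", {
  cv <- posterior_curves(concentrated_post, n_draws = 300)
  truth <- archetype_params("comparable")
  tr <- ria_trajectory(m3, truth, test_protocol, cv$grid,
                       method = "analytic")
  for (cc in c("r_plasma", "r_csf")) {
    b <- cv$bands[[cc]]
    # quantile ordering at every grid point
    expect_true(all(b["2.5%", ] <= b["50%", ] + 1e-12 &
                    b["50%", ] <= b["97.5%", ] + 1e-12))
    inside <- tr[[cc]] >= b["2.5%", ] - 1e-9 & tr[[cc]] <= b["97.5%", ] + 1e-9
    expect_gte(mean(inside), 0.9)
  }
  # unimodal and concentrated: mean-parameter curve hugs the median curve
  expect_true(all(cv$sup_dist < cv$band_width / 10 + 1e-12))
  expect_false(cv$flag)
})

test_that("a bimodal posterior is flagged: mean-parameter curve off the modes", {
  set.seed(6)
  thA <- log(archetype_params("comparable"))
  thB <- log(archetype_params("faster_csf"))
  n <- 300
  S <- rbind(
    matrix(rep(thA, each = n), n) + matrix(rnorm(8 * n, 0, 0.02), n),
    matrix(rep(thB, each = n), n) + matrix(rnorm(8 * n, 0, 0.02), n))
  colnames(S) <- paste0("log_", m3$rate_names)
  fp <- fake_posterior(S)
  cv <- posterior_curves(fp, n_draws = 200)
  expect_true(cv$flag)

  dm <- detect_multimodality(fp, c("k_cn", "k_nc"))
  expect_true(dm$flag)
  expect_true(dm$mean_off_mode)

  # a unimodal cloud is not flagged
  S1 <- matrix(rep(thA, each = 2 * n), 2 * n) +
    matrix(rnorm(16 * n, 0, 0.05), 2 * n)
  colnames(S1) <- paste0("log_", m3$rate_names)
  dm1 <- detect_multimodality(fake_posterior(S1), c("k_cn", "k_nc"))
  expect_false(dm1$flag)
  expect_false(dm1$mean_off_mode)

  # too few samples: indeterminate
  dm2 <- detect_multimodality(fake_posterior(S1[1:50, ]), c("k_cn", "k_nc"))
  expect_true(is.na(dm2$flag))
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(8)
  good <- list(matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("x", "y"))),
               matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("x", "y"))))
  bad <- list(good[[1]], good[[2]] + 5)
  expect_true(all(silkdyn:::split_rhat(good) < 1.05))
  expect_true(any(silkdyn:::split_rhat(bad) > 1.5))
})
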