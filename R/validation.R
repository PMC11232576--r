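# Reproducible simulation studies: numerical validation of the integrators
# and end-to-end statistical performance of the estimation workflows on
# synthetic data with known ground truth. These drive both the package's
# validation report (scripts/acceptance.R) and the heavier tests.

# in-bounds random rate draw; synthesis rates kept at RIA-plausible
# magnitudes so trajectories stay O(1)
random_rates <- function(model) {
  rn <- model$rate_names
  p <- stats::setNames(stats::runif(length(rn), 0.01, 2), rn)
  syn <- grepl("^a", rn)
  p[syn] <- stats::runif(sum(syn), 0.005, 0.3)
  if ("tau" %in% rn) p["tau"] <- stats::runif(1, 0.5, 6)
  p
}

#' Integrator validation sweep
#'
#' Draws random in-bounds parameter sets for every non-delay model variant
#' and compares the RADAU5 numerical solution against the segment-wise
#' matrix-exponential closed form (the piecewise-constant input makes the
#' system exactly solvable per segment). Returns the worst absolute
#' deviation over all draws, variants, states and time points.
#'
#' @param n_draws Total number of random parameter draws (default 100,
#'   spread over the variants).
#' @param seed RNG seed.
#' @param times Evaluation grid (default the 13-point sampling design).
#' @param rtol,atol RADAU tolerances for the sweep.
#' @return List with `max_abs_err` and the per-variant worst deviations.
#' @export
ode_oracle_sweep <- function(n_draws = 100, seed = 1,
                             times = seq(0, 36.2, length.out = 13),
                             rtol = 1e-10, atol = 1e-12) {
  set.seed(seed)
  protocol <- silk_protocol()
  variants <- c("single", "two_bc", "three_bc_full", "three_bc_simplified")
  per <- ceiling(n_draws / length(variants))
  worst <- stats::setNames(numeric(length(variants)), variants)
  total <- 0
  for (v in variants) {
    m <- silk_model(v)
    for (i in seq_len(per)) {
      if (total >= n_draws) break
      p <- random_rates(m)
      num <- as.matrix(ria_trajectory(m, p, protocol, times,
                                      rtol = rtol, atol = atol)[, -1])
      ana <- as.matrix(ria_trajectory(m, p, protocol, times,
                                      method = "analytic")[, -1])
      worst[[v]] <- max(worst[[v]], max(abs(num - ana)))
      total <- total + 1
    }
  }
  list(max_abs_err = max(worst), per_variant = worst, n_draws = total)
}

#' Model nesting check
#'
#' The full three-compartment model with the plasma-CNS transfers and the
#' CSF elimination fixed at zero must reproduce the simplified model
#' exactly.
#'
#' @param n_draws Random simplified-model parameter draws.
#' @param seed RNG seed.
#' @return List with `max_abs_err` over all draws.
#' @export
nesting_check <- function(n_draws = 20, seed = 1) {
  set.seed(seed)
  protocol <- silk_protocol()
  t13 <- seq(0, 36.2, length.out = 13)
  mf <- silk_model("three_bc_full")
  ms <- silk_model("three_bc_simplified")
  worst <- 0
  for (i in seq_len(n_draws)) {
    ps <- random_rates(ms)
    pf <- c(ps, k_pn = 0, k_np = 0, b_c = 0)
    trf <- ria_trajectory(mf, pf, protocol, t13, method = "analytic")
    trs <- ria_trajectory(ms, ps, protocol, t13, method = "analytic")
    worst <- max(worst, max(abs(as.matrix(trf[, -1]) - as.matrix(trs[, -1]))))
  }
  list(max_abs_err = worst, n_draws = n_draws)
}

#' Delay-model degeneracy check
#'
#' The delay differential variant with `tau = 0` must coincide with the
#' plain two-compartment transfer model.
#'
#' @param n_draws Random parameter draws.
#' @param seed RNG seed.
#' @return List with `max_abs_err`.
#' @export
dde_degeneracy_check <- function(n_draws = 5, seed = 1) {
  set.seed(seed)
  protocol <- silk_protocol()
  t13 <- seq(0, 36.2, length.out = 13)
  md <- silk_model("two_bc_delay")
  m2 <- silk_model("two_bc")
  worst <- 0
  for (i in seq_len(n_draws)) {
    p2 <- random_rates(m2)
    trd <- ria_trajectory(md, c(p2, tau = 0), protocol, t13)
    tr2 <- ria_trajectory(m2, p2, protocol, t13)
    worst <- max(worst, max(abs(as.matrix(trd[, -1]) - as.matrix(tr2[, -1]))))
  }
  list(max_abs_err = worst, n_draws = n_draws)
}

#' Prepare observations of one protein for joint plasma-CSF modeling
#'
#' Runs per-fluid protein pooling ([pool_protein()]: shared-peptide and
#' clearance screens, alignment, two-step robust fit) and returns the
#' aligned, outlier-blanked observations of both fluids together with the
#' per-fluid single-fluid fits — the inputs the joint frequentist and
#' Bayesian fits expect.
#'
#' @param observations List of `silk_observation`s covering both fluids.
#' @param protocol A [silk_protocol()].
#' @return List with `observations` (aligned, both fluids) and `fits`
#'   (per-fluid pooled `silk_fit`s).
#' @export
prepare_joint_data <- function(observations, protocol = silk_protocol()) {
  aligned <- list()
  fits <- list()
  refs <- list()
  for (f in c("plasma", "csf")) {
    po <- pool_protein(Filter(function(o) o$fluid == f, observations),
                       protocol, n_boot = 0)
    if (po$status != "ok") stop("pooling failed for ", f)
    aligned <- c(aligned, po$fit$observations)
    fits[[f]] <- po$fit
    refs[[f]] <- po$reference
  }
  list(observations = aligned, fits = fits, references = refs)
}

#' Frequentist parameter-recovery study
#'
#' Generates simplified-model synthetic proteins at the study design
#' (13 time points, 4 observations per fluid, design noise), runs the full
#' estimation workflow (per-fluid pooling with alignment and outlier
#' removal, then the bound-constrained multi-start joint fit) and measures
#' relative errors of the recovered rates and absolute errors of the
#' shifts. Archetypes are cycled across replicates.
#'
#' @param n_rep Number of replicates (default 100).
#' @param seed RNG seed.
#' @param design A [silk_design()].
#' @return List with `median_rel_error` (pooled over rates and replicates),
#'   `per_rate` medians, `shift_mae`, and the error matrix.
#' @export
recovery_study <- function(n_rep = 100, seed = 1, design = silk_design()) {
  protocol <- silk_protocol()
  m3 <- silk_model("three_bc_simplified")
  archetypes <- rep(c("comparable", "faster_csf", "faster_plasma"),
                    length.out = n_rep)
  errs <- NULL
  shift_err <- c()
  for (r in seq_len(n_rep)) {
    truth <- archetype_params(archetypes[r])
    res <- tryCatch({
      gp <- generate_protein(truth, design, seed = seed + 7 * r,
                             protocol = protocol)
      d <- prepare_joint_data(gp$observations, protocol)
      ft <- fit_bounded(m3, d$observations, protocol)
      # after alignment the pooled series carries the reference
      # observation's realised shift, which is the estimable target
      sh_true <- vapply(names(ft$shifts), function(f)
        gp$truth$obs_shifts[[d$references[[f]]]], 0)
      list(rel = abs(ft$params - truth) / truth,
           sh = abs(unname(ft$shifts) - unname(sh_true)))
    }, error = function(e) NULL)
    if (is.null(res)) next
    errs <- rbind(errs, res$rel)
    shift_err <- c(shift_err, res$sh)
  }
  list(median_rel_error = stats::median(errs),
       per_rate = apply(errs, 2, stats::median),
       shift_mae = stats::median(shift_err),
       errors = errs, n_rep = nrow(errs))
}

#' Bayesian credibility-interval coverage study
#'
#' Simulation-based calibration of the MCMC machinery: per replicate, the
#' true rates are drawn from the priors and the shifts from their prior,
#' data are generated from the model at the study design (no contamination:
#' the likelihood is exactly the generating process), the sampler runs with
#' the same priors, and coverage of the 95% credibility intervals is
#' tallied over all rates and shifts. A correct sampler yields close to 95%.
#'
#' @param n_rep Replicates (default 50).
#' @param seed RNG seed.
#' @param n_iter,n_burn Per-chain iterations (defaults are the study's
#'   iteration budget scaled tenfold down, which suffices at this data
#'   size).
#' @return List with `coverage` (fraction), `converged` (fraction of runs
#'   with all split-Rhat < 1.1), `n_checks`.
#' @export
coverage_study <- function(n_rep = 50, seed = 1, n_iter = 20000,
                           n_burn = 10000) {
  protocol <- silk_protocol()
  m3 <- silk_model("three_bc_simplified")
  rn <- m3$rate_names
  hits <- 0; checks <- 0; conv <- c()
  for (r in seq_len(n_rep)) {
    set.seed(seed + 131 * r)
    priors <- prior_spec(m3, stats::setNames(rep(log(0.1), length(rn)), rn))
    truth <- stats::setNames(
      exp(stats::rnorm(length(rn), priors$rate_means,
                       1 / sqrt(priors$rate_precision))), rn)
    sh <- stats::rnorm(2, 0, 1 / sqrt(priors$shift_precision))
    design <- silk_design(outlier_rate = 0, missing_rate = 0,
                          obs_shift_sd = 0,
                          fluid_shift = c(plasma = sh[1], csf = sh[2]))
    res <- tryCatch({
      gp <- generate_protein(truth, design, seed = seed + 131 * r + 1,
                             protocol = protocol)
      post <- run_mcmc(m3, gp$observations, priors, protocol,
                       n_iter = n_iter, n_burn = n_burn,
                       seed = seed + 131 * r + 2)
      truth_all <- c(truth, s_p = sh[1], s_c = sh[2])
      summ <- post$summary
      cov <- vapply(names(truth_all), function(nm) {
        row <- summ[summ$parameter == nm, ]
        truth_all[[nm]] >= row$lo95 && truth_all[[nm]] <= row$hi95
      }, TRUE)
      list(cov = cov, conv = post$converged)
    }, error = function(e) NULL)
    if (is.null(res)) next
    hits <- hits + sum(res$cov)
    checks <- checks + length(res$cov)
    conv <- c(conv, res$conv)
  }
  list(coverage = hits / checks, converged = mean(conv), n_checks = checks,
       n_rep = length(conv))
}

#' Two- versus three-compartment goodness-of-fit contrast
#'
#' On faster-CSF proteins (TTR/PROS1-like dynamics) the two-biological-
#' compartment model cannot reproduce a CSF signal that rises before and
#' above plasma, whereas the simplified three-compartment model can; on
#' comparable-dynamics proteins (SERPINF2-like) both fit similarly. The
#' study fits both models to the same pooled synthetic data and reports
#' the weighted-SSE ratios.
#'
#' @param n_rep Proteins per archetype (default 9; the median ratio is
#'   reported).
#' @param seed RNG seed.
#' @return List with `ratio_faster_csf` and `ratio_comparable` (median
#'   2-bc SSE / simplified 3-bc SSE), plus the per-replicate ratios.
#' @export
model_contrast_study <- function(n_rep = 9, seed = 1) {
  protocol <- silk_protocol()
  m2 <- silk_model("two_bc")
  m3 <- silk_model("three_bc_simplified")
  design <- silk_design()
  one <- function(arch, sd) {
    gp <- generate_protein(archetype_params(arch), design, seed = sd,
                           protocol = protocol)
    d <- prepare_joint_data(gp$observations, protocol)
    f2 <- fit_bounded(m2, d$observations, protocol)
    f3 <- fit_bounded(m3, d$observations, protocol)
    f2$weighted_sse / f3$weighted_sse
  }
  rf <- vapply(seq_len(n_rep), function(i) one("faster_csf", seed + i), 0)
  rc <- vapply(seq_len(n_rep), function(i) one("comparable", seed + 50 + i), 0)
  list(ratio_faster_csf = stats::median(rf),
       ratio_comparable = stats::median(rc),
       ratios_faster_csf = rf, ratios_comparable = rc)
}

#' Full- versus simplified-model multimodality study
#'
#' Fits both three-compartment variants by MCMC to the same faster-CSF
#' synthetic protein and runs the multimodality diagnostic over the full
#' model's redundant rate trio (CSF elimination and the two CSF export
#' rates) and the simplified model's CSF export pair.
#'
#' @param seed RNG seed.
#' @param n_iter,n_burn Per-chain iterations.
#' @param update Sampler kernel (see [run_mcmc()]).
#' @return List with `flag_full`, `flag_simplified`, the per-pair tables,
#'   and the posteriors' convergence diagnostics.
#' @export
multimodality_study <- function(seed = 1, n_iter = 20000, n_burn = 10000,
                                update = "block") {
  protocol <- silk_protocol()
  mf <- silk_model("three_bc_full")
  m3 <- silk_model("three_bc_simplified")
  design <- silk_design()
  gp <- generate_protein(archetype_params("faster_csf"), design,
                         seed = seed + 2, protocol = protocol)
  d <- prepare_joint_data(gp$observations, protocol)
  ish <- c(s_p = unname(d$fits$plasma$shifts[[1]]),
           s_c = unname(d$fits$csf$shifts[[1]]))
  pf <- run_mcmc(mf, d$observations,
                 default_priors(mf, d$fits$plasma, d$fits$csf), protocol,
                 n_iter = n_iter, n_burn = n_burn, seed = seed,
                 init_shifts = ish, update = update)
  ps <- run_mcmc(m3, d$observations,
                 default_priors(m3, d$fits$plasma, d$fits$csf), protocol,
                 n_iter = n_iter, n_burn = n_burn, seed = seed,
                 init_shifts = ish, update = update)
  df <- detect_multimodality(pf, c("b_c", "k_cp", "k_cn"))
  ds <- detect_multimodality(ps, c("k_cp", "k_cn"))
  list(flag_full = df$flag, flag_simplified = ds$flag,
       pairs_full = df$pairs, pairs_simplified = ds$pairs,
       rhat_full = pf$rhat, rhat_simplified = ps$rhat)
}

#' Synthetic QC-funnel study
#'
#' Generates a cohort with planted QC defects, runs the full pipeline on
#' its Skyline-like exports and checks that every planted defect is
#' rejected.
#'
#' @param seed RNG seed.
#' @param n_proteins Cohort size.
#' @param defect_rate Fraction of proteins given a planted defect.
#' @return List with `n_defects`, `n_rejected` (planted defects actually
#'   rejected), and the pipeline's stage table.
#' @export
qc_funnel_study <- function(seed = 1, n_proteins = 6, defect_rate = 0.5) {
  dir <- tempfile("silkdyn_funnel_")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  design <- silk_design(n_proteins = n_proteins, defect_rate = defect_rate,
                        outlier_rate = 0.02, missing_rate = 0.02)
  coh <- generate_cohort(design, seed = seed, dir = dir)
  run <- run_pipeline(coh$paths[["plasma"]], coh$paths[["csf"]],
                      config = qc_config(n_boot = 20), seed = seed)
  rejected <- sum(coh$defects$id %in% run$report$rejections$id)
  list(n_defects = nrow(coh$defects), n_rejected = rejected,
       stages = run$report$stages,
       n_joint = length(run$joint_proteins),
       n_eligible = length(run$joint_eligible))
}
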