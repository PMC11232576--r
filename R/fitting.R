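# Point estimation of compartment-model parameters from RIA observations:
# intensity-weighted least squares with per-fluid vertical shifts, bound
# constraints, a two-step outlier-robust refit, bootstrap confidence
# intervals, and protein-level pooling of observations.

# Map a fluid to the trajectory column carrying its model RIA.
fluid_column <- function(model, fluid) {
  if (model$name == "single") return("r")
  c(plasma = "r_plasma", csf = "r_csf")[[fluid]]
}

# Split observations into per-fluid point tables (with weights), validating
# that the fluids present match the model.
fit_tables <- function(model, observations) {
  if (inherits(observations, "silk_observation"))
    observations <- list(observations)
  fluids <- unique(vapply(observations, `[[`, "", "fluid"))
  if (model$name == "single") {
    if (length(fluids) != 1)
      stop("the single-fluid model requires observations from one fluid")
  }
  tabs <- lapply(fluids, function(f) {
    obs_points(observations[vapply(observations, `[[`, "", "fluid") == f])
  })
  names(tabs) <- fluids
  tabs
}

#' Intensity-weighted squared-error objective
#'
#' Squared residuals between the model RIA curve and the shift-corrected
#' observed RIAs, weighted proportionally to the light-peptide intensity
#' `I0` (stronger signals give more accurate RIAs). Weights are normalised
#' to `w = I0 / mean(I0)` over the usable points so that the objective scale
#' is comparable across observations.
#'
#' @param model_curve A [ria_trajectory()] evaluated at (at least) the
#'   observation times.
#' @param obs A [silk_observation()].
#' @param shift Vertical RIA shift applied to the observed values.
#' @param state Trajectory column to compare against (default `"r"` for the
#'   single-fluid model).
#' @return The weighted sum of squared errors.
#' @export
weighted_objective <- function(model_curve, obs, shift, state = "r") {
  tab <- obs_points(obs)
  idx <- match(round(tab$time, 9), round(model_curve$time, 9))
  if (any(is.na(idx)))
    stop("model curve was not evaluated at all observation times")
  r <- model_curve[[state]][idx]
  sum(tab$w * (r - (tab$ria - shift))^2)
}

# Internal objective over per-fluid tables; returns a large penalty on
# integration failure so that L-BFGS-B backtracks. The closure precomputes
# input segments and index maps so each evaluation is one propagator call.
make_objective <- function(model, tabs, protocol, times_union) {
  delay <- model$delay
  seg <- protocol_segments(protocol,
                           max(times_union, protocol$total_label_window))
  idx <- lapply(tabs, function(tb) match(round(tb$time, 9),
                                         round(times_union, 9)))
  cols <- vapply(names(tabs), function(f)
    match(fluid_column(model, f), model$state_names), 0L)
  snames <- vapply(names(tabs), function(f) shift_name(model, f), "")
  y <- lapply(tabs, `[[`, "ria")
  w <- lapply(tabs, `[[`, "w")
  rn <- model$rate_names
  basis <- if (!delay) param_basis(model)
  bn <- names(basis)
  n <- model$n_states
  function(theta) {
    st <- tryCatch({
      if (delay) {
        as.matrix(ria_trajectory(model, theta[rn], protocol, times_union,
                                 rtol = 1e-8, atol = 1e-10)[, -1])
      } else {
        A <- matrix(0, n, n)
        for (j in seq_along(basis)) A <- A + theta[[bn[j]]] * basis[[j]]
        lin_propagate(A, seg, times_union)
      }
    }, error = function(e) NULL)
    if (is.null(st)) return(1e12)
    sse <- 0
    for (i in seq_along(y)) {
      r <- st[idx[[i]], cols[[i]]]
      sse <- sse + sum(w[[i]] * (r - (y[[i]] - theta[[snames[[i]]]]))^2)
    }
    if (!is.finite(sse)) 1e12 else sse
  }
}

# back-compatible wrapper used by the bootstrap
fit_objective <- function(theta, model, tabs, protocol, times_union) {
  make_objective(model, tabs, protocol, times_union)(theta)
}

shift_name <- function(model, fluid) {
  if (model$name == "single") "s" else c(plasma = "s_p", csf = "s_c")[[fluid]]
}

#' Bound-constrained weighted least-squares fit
#'
#' Minimises the intensity-weighted squared-error objective jointly over the
#' model rates and one vertical shift per observed fluid, by quasi-Newton
#' iteration with box constraints (`optim`, method `"L-BFGS-B"`). Rates are
#' constrained to be nonnegative (unconstrained search can wander into
#' infeasible negative transfer rates); shifts to a small symmetric band.
#'
#' For the joint plasma-CSF models, when `init` is not supplied the plasma
#' and CSF blocks are seeded from independent single-fluid fits and the
#' remaining (CNS-related and transfer) rates are multi-started over a fixed
#' 5-point ladder around 0.1/h; the start with the best final objective wins,
#' ties broken by ladder order.
#'
#' @param model A [silk_model()].
#' @param observations A `silk_observation` or list of them (both fluids for
#'   joint models).
#' @param protocol A [silk_protocol()].
#' @param init Optional named start vector over `c(rate_names, shift_names)`.
#' @param min_points Minimum usable points per fitted fluid (default 4).
#' @param control Passed to [stats::optim()].
#' @return An object of class `silk_fit` with elements `params` (rates),
#'   `shifts`, `weighted_sse`, `convergence`, `data` (per-fluid point
#'   tables), `init`, and `model`.
#' @export
fit_bounded <- function(model, observations, protocol = silk_protocol(),
                        init = NULL, min_points = 4,
                        control = list(maxit = 500, factr = 1e5)) {
  tabs <- fit_tables(model, observations)
  for (f in names(tabs))
    if (nrow(tabs[[f]]) < min_points)
      stop(sprintf("fewer than %d usable points in %s", min_points, f))
  shift_names <- vapply(names(tabs), function(f) shift_name(model, f), "")
  par_names <- c(model$rate_names, unname(shift_names))
  lower <- model$lower[par_names]
  upper <- model$upper[par_names]
  times_union <- sort(unique(c(0, unlist(lapply(tabs, `[[`, "time")))))

  inits <- if (!is.null(init)) {
    list(check_init(init, par_names, lower, upper))
  } else {
    default_inits(model, observations, tabs, protocol, par_names, lower, upper,
                  min_points)
  }

  obj <- make_objective(model, tabs, protocol, times_union)
  runs <- lapply(inits, function(th0) {
    res <- stats::optim(
      par = th0, fn = obj,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = utils::modifyList(list(parscale = pmax(abs(th0), 0.01)),
                                  control))
    res$init <- th0
    res
  })
  best <- which.min(vapply(runs, function(r)
    round(r$value, 12), numeric(1)))  # ties by first
  res <- runs[[best]]
  theta <- stats::setNames(res$par, par_names)
  structure(
    list(model = model$name, model_spec = model,
         params = theta[model$rate_names],
         shifts = stats::setNames(theta[unname(shift_names)], names(tabs)),
         weighted_sse = res$value,
         convergence = res$convergence, message = res$message,
         converged = res$convergence == 0,
         data = tabs, protocol = protocol, init = res$init,
         n_starts = length(inits),
         outlier_flags = NULL, ci95 = NULL, n_boot = 0L),
    class = "silk_fit")
}

check_init <- function(init, par_names, lower, upper) {
  miss <- setdiff(par_names, names(init))
  if (length(miss))
    stop("init is missing: ", paste(miss, collapse = ", "))
  th0 <- stats::setNames(as.numeric(init[par_names]), par_names)
  if (any(th0 < lower - 1e-12 | th0 > upper + 1e-12))
    stop("init outside bounds")
  pmin(pmax(th0, lower), upper)
}

# Default starting points. Single-fluid: a small fixed grid. Joint models:
# per-fluid single-fluid estimates seed the observed blocks; the remaining
# rates are multi-started on a fixed ladder around 0.1/h.
default_inits <- function(model, observations, tabs, protocol, par_names,
                          lower, upper, min_points) {
  base <- stats::setNames(rep(0.1, length(par_names)), par_names)
  base[grepl("^s", par_names) & par_names %in% c("s", "s_p", "s_c")] <- 0
  if ("tau" %in% par_names) base["tau"] <- 1
  if (model$name == "single") {
    starts <- lapply(c(0.02, 0.1, 0.5), function(r) {
      th <- base; th["a"] <- r; th["b"] <- r; th
    })
    return(starts)
  }
  if (inherits(observations, "silk_observation"))
    observations <- list(observations)
  seed_fluid <- function(f) {
    sub <- observations[vapply(observations, `[[`, "", "fluid") == f]
    if (!length(sub)) return(NULL)
    tryCatch(fit_bounded(silk_model("single"), sub, protocol,
                         min_points = min(min_points, 4)),
             error = function(e) NULL)
  }
  fp <- seed_fluid("plasma")
  fc <- seed_fluid("csf")
  if (model$name %in% c("two_bc", "two_bc_delay")) {
    if (!is.null(fp)) {
      base["a"] <- fp$params[["a"]]; base["b_p"] <- fp$params[["b"]]
      base["s_p"] <- fp$shifts[[1]]
    }
    if (!is.null(fc)) {
      base["b_c"] <- fc$params[["b"]]
      base["s_c"] <- fc$shifts[[1]]
    }
    free <- intersect(c("k_pc", "k_cp"), par_names)
  } else {
    if (!is.null(fp)) {
      base["a_p"] <- fp$params[["a"]]; base["b_p"] <- fp$params[["b"]]
      base["s_p"] <- fp$shifts[[1]]
    }
    if (!is.null(fc)) {
      base["a_n"] <- fc$params[["a"]]; base["b_n"] <- fc$params[["b"]]
      base["s_c"] <- fc$shifts[[1]]
    }
    free <- intersect(c("k_pc", "k_cp", "k_pn", "k_np", "k_nc", "k_cn",
                        if (is.null(fc)) c("a_n", "b_n"), "b_c"),
                      par_names)
  }
  ladder <- c(0.025, 0.05, 0.1, 0.2, 0.4)
  lapply(ladder, function(v) {
    th <- base
    th[free] <- v
    pmin(pmax(th, lower), upper)
  })
}

#' @export
print.silk_fit <- function(x, ...) {
  cat(sprintf("silkdyn fit (%s): weighted SSE %.4g, %sconverged\n",
              x$model, x$weighted_sse, if (x$converged) "" else "NOT "))
  est <- c(x$params, stats::setNames(x$shifts, paste0("shift_", names(x$shifts))))
  print(round(est, 5))
  if (!is.null(x$ci95)) {
    cat(sprintf("bootstrap CI95 (%d replicates%s):\n", x$n_boot,
                if (isTRUE(x$ci_flagged)) ", FLAGGED: many failed refits" else ""))
    print(round(x$ci95, 5))
  }
  invisible(x)
}

#' Two-step outlier-robust fit
#'
#' Step 1 fits the model on all usable points. A point is then flagged as an
#' outlier when its absolute shift-corrected residual exceeds half the
#' dynamic range (max minus min) of the step-1 fitted curve for its fluid;
#' RIAs at time 0 are always flagged, since no tracer has been incorporated
#' yet and they only reflect noise and coeluting material. Step 2 refits on
#' the retained points, starting from the step-1 estimate.
#'
#' @inheritParams fit_bounded
#' @param ... Passed on to [fit_bounded()].
#' @return A `silk_fit` for step 2 whose `outlier_flags` element is a data
#'   frame (fluid, obs id, time, ria, outlier, reason) covering every usable
#'   point; `step1` holds the first-pass fit.
#' @export
robust_two_step_fit <- function(model, observations, protocol = silk_protocol(),
                                ...) {
  step1 <- fit_bounded(model, observations, protocol, ...)
  dense <- seq(0, max(unlist(lapply(step1$data, `[[`, "time"))), by = 0.1)
  tr <- ria_trajectory(model, step1$params, protocol, dense, method = "analytic")
  flags <- NULL
  kept_obs <- list()
  for (f in names(step1$data)) {
    tab <- step1$data[[f]]
    col <- fluid_column(model, f)
    rng <- diff(range(tr[[col]]))
    r_at <- ria_trajectory(model, step1$params, protocol,
                           sort(unique(c(0, tab$time))),
                           method = "analytic")
    ri <- r_at[[col]][match(round(tab$time, 9), round(r_at$time, 9))]
    resid <- abs(tab$ria - step1$shifts[[f]] - ri)
    reason <- rep("", nrow(tab))
    reason[resid > rng / 2] <- "band"
    reason[tab$time == 0] <- "time0"
    flags <- rbind(flags, data.frame(
      fluid = f, id = tab$id, time = tab$time, ria = tab$ria,
      outlier = reason != "", reason = reason, stringsAsFactors = FALSE))
  }
  if (all(flags$outlier)) stop("all points flagged as outliers")
  retained <- retained_observations(observations, flags)
  step2 <- fit_bounded(model, retained, protocol,
                       init = c(step1$params,
                                stats::setNames(step1$shifts,
                                  vapply(names(step1$shifts),
                                         function(f) shift_name(model, f), ""))),
                       ...)
  step2$outlier_flags <- flags
  step2$step1 <- step1
  step2$observations <- retained
  step2
}

# Rebuild observations with flagged points removed (blanked intensities).
retained_observations <- function(observations, flags) {
  if (inherits(observations, "silk_observation"))
    observations <- list(observations)
  lapply(observations, function(ob) {
    key <- flags$id == obs_id(ob) & flags$outlier
    bad_times <- flags$time[key]
    drop <- ob$points$time %in% bad_times
    ob$points$i0[drop] <- NA
    ob$points$i6[drop] <- NA
    ob$points$ria[drop] <- NA
    ob
  })
}

#' Bootstrap confidence intervals for a fit
#'
#' Resamples the retained (non-outlier) data points with replacement within
#' each fluid, refits from the point estimate, and returns percentile 2.5
#' and 97.5% intervals for every rate and shift. Reproducible under a fixed
#' seed.
#'
#' @param fit A `silk_fit`, normally from [robust_two_step_fit()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return `fit` with elements `ci95` (matrix with columns `lo`, `hi`),
#'   `n_boot`, `boot_samples`, and `ci_flagged` (`TRUE` when more than 20%
#'   of the refits failed).
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "silk_fit"))
  model <- fit$model_spec
  shift_names <- vapply(names(fit$shifts), function(f) shift_name(model, f), "")
  theta_hat <- c(fit$params, stats::setNames(fit$shifts, unname(shift_names)))
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(theta_hat),
                  dimnames = list(NULL, names(theta_hat)))
  for (b in seq_len(n_boot)) {
    tabs_b <- lapply(fit$data, function(tab)
      tab[sample.int(nrow(tab), replace = TRUE), , drop = FALSE])
    res <- tryCatch({
      times_union <- sort(unique(c(0, unlist(lapply(tabs_b, `[[`, "time")))))
      obj_b <- make_objective(model, tabs_b, fit$protocol, times_union)
      opt <- stats::optim(theta_hat, obj_b,
                          method = "L-BFGS-B",
                          lower = model$lower[names(theta_hat)],
                          upper = model$upper[names(theta_hat)],
                          control = list(maxit = 300, factr = 1e7,
                                         parscale = pmax(abs(theta_hat), 0.01)))
      opt$par
    }, error = function(e) NULL)
    if (!is.null(res)) draws[b, ] <- res
  }
  ok <- stats::complete.cases(draws)
  ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  fit$ci95 <- ci
  fit$n_boot <- as.integer(n_boot)
  fit$boot_samples <- draws
  fit$ci_flagged <- mean(!ok) > 0.2
  fit
}

#' Pool the observations of one protein in one fluid
#'
#' Combines validated observations into a single protein-level model:
#' (i) peptides shared by several proteins are dropped; (ii) when at least
#' three observations are available, each is fitted independently and those
#' whose clearance-rate estimate is a Tukey boxplot outlier (beyond the
#' quartiles plus/minus 1.5 IQR, as `boxplot.stats`) are discarded;
#' (iii) the remaining observations are aligned, by additive RIA offset, on
#' the reference observation with the highest median heavy-Leu signal
#' (the vertical shift differs between observations); (iv) the model is
#' refitted on the pooled points with the two-step robust procedure and a
#' bootstrap provides parameter CI95s.
#'
#' @param observations List of `silk_observation`s for one protein and fluid.
#' @param protocol A [silk_protocol()].
#' @param n_boot Bootstrap replicates for the pooled fit (0 to skip).
#' @param seed Bootstrap seed.
#' @param individual_fits Optional precomputed per-observation robust fits
#'   (as produced by the QC pipeline), keyed by observation id.
#' @return An object of class `silk_pooled`: `status` (`"ok"` or
#'   `"dropped"`), `fit`, `observations` (aligned, retained), `offsets`,
#'   `reference`, and `dropped` (data frame of discarded observation ids and
#'   reasons).
#' @export
pool_protein <- function(observations, protocol = silk_protocol(),
                         n_boot = 1000, seed = 1, individual_fits = NULL) {
  if (inherits(observations, "silk_observation"))
    observations <- list(observations)
  stopifnot(length(observations) >= 1)
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  shared <- vapply(observations, `[[`, TRUE, "shared")
  dropped <- rbind(dropped, data.frame(
    id = vapply(observations[shared], obs_id, ""),
    reason = rep("shared_peptide", sum(shared))))
  observations <- observations[!shared]
  if (!length(observations))
    return(structure(list(status = "dropped", reason = "no unique peptides",
                          dropped = dropped), class = "silk_pooled"))

  single <- silk_model("single")
  # per-observation robust fits: clearance screen and outlier knowledge
  fits <- lapply(observations, function(ob) {
    id <- obs_id(ob)
    if (!is.null(individual_fits) && !is.null(individual_fits[[id]]))
      individual_fits[[id]]
    else tryCatch(robust_two_step_fit(single, ob, protocol),
                  error = function(e) NULL)
  })
  b_hat <- vapply(fits, function(ft)
    if (is.null(ft)) NA_real_ else ft$params[["b"]], numeric(1))
  bad <- is.na(b_hat)
  if (length(observations) >= 3) {
    out_vals <- grDevices::boxplot.stats(b_hat[!is.na(b_hat)])$out
    bad <- bad | (!is.na(b_hat) & b_hat %in% out_vals)
  }
  if (any(bad)) {
    dropped <- rbind(dropped, data.frame(
      id = vapply(observations[bad], obs_id, ""),
      reason = ifelse(is.na(b_hat[bad]), "unfittable", "clearance_outlier")))
    observations <- observations[!bad]
    fits <- fits[!bad]
  }
  if (!length(observations))
    return(structure(list(status = "dropped",
                          reason = "no observations after clearance screen",
                          dropped = dropped), class = "silk_pooled"))

  # only non-outlier RIAs feed alignment and the pooled fit
  observations <- lapply(seq_along(observations), function(j) {
    ft <- fits[[j]]
    if (is.null(ft$outlier_flags)) return(observations[[j]])
    retained_observations(observations[[j]], ft$outlier_flags)[[1]]
  })

  med_i6 <- vapply(observations, function(ob)
    stats::median(ob$points$i6, na.rm = TRUE), numeric(1))
  ref <- which.max(med_i6)
  ref_pts <- observations[[ref]]$points
  offsets <- vapply(seq_along(observations), function(j) {
    if (j == ref) return(0)
    pts <- observations[[j]]$points
    shared_t <- intersect(ref_pts$time[!is.na(ref_pts$ria)],
                          pts$time[!is.na(pts$ria)])
    if (!length(shared_t)) shared_t <- pts$time[!is.na(pts$ria)]
    m_ref <- stats::median(ref_pts$ria[ref_pts$time %in% shared_t], na.rm = TRUE)
    m_j <- stats::median(pts$ria[pts$time %in% shared_t], na.rm = TRUE)
    m_ref - m_j
  }, numeric(1))
  aligned <- observations
  for (j in seq_along(aligned))
    aligned[[j]]$points$ria <- aligned[[j]]$points$ria + offsets[j]

  fit <- robust_two_step_fit(single, aligned, protocol)
  if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot = n_boot, seed = seed)
  structure(
    list(status = "ok", fit = fit, observations = aligned,
         offsets = offsets, reference = obs_id(observations[[ref]]),
         dropped = dropped),
    class = "silk_pooled")
}

#' @export
print.silk_pooled <- function(x, ...) {
  if (x$status == "dropped") {
    cat("pooled protein model: DROPPED -", x$reason, "\n")
  } else {
    cat(sprintf("pooled protein model: %d observation(s), reference %s\n",
                length(x$observations), x$reference))
    print(x$fit)
  }
  invisible(x)
}
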