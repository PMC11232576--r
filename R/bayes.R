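# Bayesian estimation of the joint plasma-CSF compartment models.
#
# Likelihood: each shift-corrected observed RIA is normal around the model
# value, with per-fluid precision scaled multiplicatively by the intensity
# weight w = I0 / mean(I0). Rates carry normal priors on their logs (hence
# strictly positive a posteriori), shifts carry tight normal priors around
# zero, and the two error precisions carry vague gamma priors.
#
# The sampler combines an adaptive random-walk Metropolis block update of
# the log-rates (Haario-style covariance adaptation) with exact conjugate
# Gibbs draws of the per-fluid shifts and error precisions. Two chains are
# run and convergence is assessed by the split-Rhat statistic comparing
# within- and between-chain variability.

#' Prior specification for Bayesian fitting
#'
#' @param model A [silk_model()].
#' @param rate_means Named vector of prior means for the log-rates (natural
#'   log, rates in 1/h).
#' @param rate_precision Normal prior precision of every log-rate
#'   (default 10).
#' @param shift_precision Normal prior precision of the per-fluid shifts
#'   (default 5000); shift prior means are 0.
#' @param gamma_shape,gamma_rate Vague gamma prior for the per-fluid error
#'   precisions (default 0.001, 0.001).
#' @return An object of class `silk_priors`.
#' @export
prior_spec <- function(model, rate_means, rate_precision = 10,
                       shift_precision = 5000,
                       gamma_shape = 0.001, gamma_rate = 0.001) {
  stopifnot(inherits(model, "silk_model"),
            rate_precision > 0, shift_precision > 0)
  rn <- setdiff(model$rate_names, "tau")
  miss <- setdiff(rn, names(rate_means))
  if (length(miss))
    stop("rate_means missing: ", paste(miss, collapse = ", "))
  structure(
    list(model = model$name,
         rate_means = rate_means[rn],
         rate_precision = rate_precision,
         shift_precision = shift_precision,
         gamma_shape = gamma_shape, gamma_rate = gamma_rate),
    class = "silk_priors")
}

#' Default priors built from independent single-fluid fits
#'
#' Prior means of the log-rates are set from the corresponding single-fluid
#' quasi-Newton estimates where a correspondence exists: the plasma
#' synthesis and clearance rates from the plasma fit, and the CNS synthesis
#' and elimination rates from the CSF fit (the CSF dynamics being the
#' observable reflection of the hidden CNS pool). All transfer rates, and
#' any parameter without a fit, default to an empirical constant
#' (`log(0.1)`/h). Shift priors are centred at 0 with precision 5000; all
#' other precisions are 10.
#'
#' @param model A [silk_model()] (a joint plasma-CSF variant).
#' @param plasma_fit,csf_fit Optional single-fluid `silk_fit`s.
#' @param empirical_mean Fallback prior mean for log-rates (default
#'   `log(0.1)`).
#' @return A [prior_spec()].
#' @export
default_priors <- function(model, plasma_fit = NULL, csf_fit = NULL,
                           empirical_mean = log(0.1)) {
  rn <- setdiff(model$rate_names, "tau")
  means <- stats::setNames(rep(empirical_mean, length(rn)), rn)
  safe_log <- function(x) log(max(x, 1e-4))
  if (is.null(plasma_fit) && is.null(csf_fit))
    warning("no single-fluid fits supplied; all prior means at the default")
  if (!is.null(plasma_fit)) {
    if ("a" %in% rn) means["a"] <- safe_log(plasma_fit$params[["a"]])
    if ("a_p" %in% rn) means["a_p"] <- safe_log(plasma_fit$params[["a"]])
    if ("b_p" %in% rn) means["b_p"] <- safe_log(plasma_fit$params[["b"]])
  }
  if (!is.null(csf_fit)) {
    if ("a_n" %in% rn) means["a_n"] <- safe_log(csf_fit$params[["a"]])
    if ("b_n" %in% rn) means["b_n"] <- safe_log(csf_fit$params[["b"]])
    if ("b_c" %in% rn) means["b_c"] <- safe_log(csf_fit$params[["b"]])
  }
  prior_spec(model, means)
}

#' Bayesian fit by adaptive MCMC
#'
#' Samples the posterior of a joint plasma-CSF compartment model. Each chain
#' initialises the log-rates by a draw from their priors while the shifts
#' start at the supplied single-fluid quasi-Newton estimates (or 0), and the
#' error precisions at an empirical residual-based value. Convergence is
#' diagnosed by split-Rhat; values above 1.1 flag the run as non-converged
#' (samples are still returned).
#'
#' @param model A [silk_model()] (non-delay variant).
#' @param observations Validated observations covering both fluids (list of
#'   `silk_observation`); points flagged as outliers upstream should already
#'   be blanked.
#' @param priors A [prior_spec()]; built by [default_priors()] when `NULL`.
#' @param protocol A [silk_protocol()].
#' @param n_iter Total iterations per chain (default 200000).
#' @param n_burn Burn-in iterations discarded per chain (default 100000).
#' @param chains Number of chains (default 2).
#' @param seed Integer seed; per-chain seeds are derived as
#'   `seed + 1000 * (chain - 1)` unless `chain_seeds` is given.
#' @param chain_seeds Optional explicit per-chain seeds.
#' @param init_shifts Optional named vector `c(s_p=, s_c=)` of shift
#'   initial values.
#' @param likelihood `FALSE` samples the prior through the same kernel (a
#'   correctness check: the marginals must then reproduce the priors).
#' @param drop_time0 Exclude time-0 points (always outliers; default TRUE).
#' @param update `"block"` (default) adapts a joint proposal covariance for
#'   all log-rates; `"componentwise"` updates one log-rate at a time with
#'   per-coordinate adaptive scales, the single-site regime of BUGS-style
#'   Gibbs samplers (slower per iteration, and the regime in which
#'   redundantly parametrised models reveal their multimodal explored
#'   densities).
#' @return An object of class `silk_posterior`: per-chain sample matrices
#'   (log-rates, shifts, precisions), `summary` (rate-scale estimates,
#'   CI95, relative CI95), `rhat`, `converged`, acceptance rates, and the
#'   data used.
#' @export
run_mcmc <- function(model, observations, priors = NULL,
                     protocol = silk_protocol(),
                     n_iter = 200000, n_burn = 100000, chains = 2,
                     seed = 1, chain_seeds = NULL, init_shifts = NULL,
                     likelihood = TRUE, drop_time0 = TRUE,
                     update = c("block", "componentwise")) {
  update <- match.arg(update)
  stopifnot(inherits(model, "silk_model"), !model$delay,
            n_iter > n_burn)
  tabs <- fit_tables(model, observations)
  if (drop_time0)
    tabs <- lapply(tabs, function(tb) tb[tb$time > 0, , drop = FALSE])
  if (is.null(priors)) priors <- default_priors(model)
  rn <- names(priors$rate_means)
  d <- length(rn)
  fluids <- names(tabs)
  if (is.null(chain_seeds)) chain_seeds <- seed + 1000 * (seq_len(chains) - 1)

  times_union <- sort(unique(c(0, unlist(lapply(tabs, `[[`, "time")))))
  seg <- protocol_segments(protocol,
                           max(times_union, protocol$total_label_window))
  idx <- lapply(tabs, function(tb) match(round(tb$time, 9),
                                         round(times_union, 9)))
  cols <- vapply(fluids, function(f)
    match(fluid_column(model, f), model$state_names), 0L)
  y <- lapply(tabs, `[[`, "ria")
  w <- lapply(tabs, `[[`, "w")

  basis <- param_basis(model)[rn]
  nst <- model$n_states
  curves_at <- function(theta) {
    rates <- exp(theta)
    A <- matrix(0, nst, nst)
    for (j in seq_along(basis)) A <- A + rates[j] * basis[[j]]
    st <- lin_propagate(A, seg, times_union)
    lapply(seq_along(fluids), function(i) st[idx[[i]], cols[[i]]])
  }
  loglik <- function(r_list, s, tau) {
    if (!likelihood) return(0)
    ll <- 0
    for (i in seq_along(fluids)) {
      f <- fluids[i]
      res <- y[[i]] - s[[f]] - r_list[[i]]
      ll <- ll + 0.5 * sum(log(tau[[f]] * w[[i]])) -
        0.5 * tau[[f]] * sum(w[[i]] * res^2)
    }
    ll
  }
  logprior_rates <- function(theta)
    -0.5 * priors$rate_precision * sum((theta - priors$rate_means)^2)

  par_names <- c(paste0("log_", rn),
                 vapply(fluids, function(f) shift_name(model, f), ""),
                 paste0("tau_", fluids))
  run_chain <- function(cseed) {
    set.seed(cseed)
    theta <- stats::rnorm(d, priors$rate_means, 1 / sqrt(priors$rate_precision))
    s <- stats::setNames(rep(0, length(fluids)), fluids)
    if (!is.null(init_shifts))
      for (f in fluids) {
        nm <- shift_name(model, f)
        if (nm %in% names(init_shifts)) s[[f]] <- init_shifts[[nm]]
      }
    r_list <- if (likelihood) curves_at(theta) else NULL
    tau <- stats::setNames(rep(1000, length(fluids)), fluids)
    if (likelihood)
      for (i in seq_along(fluids)) {
        v <- stats::var(y[[i]] - s[[fluids[i]]] - r_list[[i]])
        tau[[fluids[i]]] <- min(max(1 / max(v, 1e-10), 10), 1e8)
      }
    ll <- loglik(r_list, s, tau)
    lp <- logprior_rates(theta)

    keep <- n_iter - n_burn
    out <- matrix(NA_real_, keep, d + 2 * length(fluids),
                  dimnames = list(NULL, par_names))
    # adaptive proposal state
    mu <- theta; Sg <- diag(0.01, d); cnt <- 0; acc <- 0; n_prop <- 0
    chol_prop <- chol(diag(0.1^2, d))
    ls <- rep(0.2, d)                  # componentwise proposal SDs
    acc_j <- integer(d)
    for (it in seq_len(n_iter)) {
      if (update == "block") {
        # 1a. joint Metropolis on the log-rates
        z <- stats::rnorm(d)
        theta_p <- theta + drop(crossprod(chol_prop, z))
        r_p <- if (likelihood) tryCatch(curves_at(theta_p),
                                        error = function(e) NULL) else NULL
        n_prop <- n_prop + 1
        if (likelihood && is.null(r_p)) {
          # integration failure: reject
        } else {
          ll_p <- loglik(r_p, s, tau)
          lp_p <- logprior_rates(theta_p)
          if (log(stats::runif(1)) < (ll_p + lp_p) - (ll + lp)) {
            theta <- theta_p; r_list <- r_p; ll <- ll_p; lp <- lp_p
            acc <- acc + 1
          }
        }
      } else {
        # 1b. single-site Metropolis sweep over the log-rates
        for (j in seq_len(d)) {
          theta_p <- theta
          theta_p[j] <- theta[j] + ls[j] * stats::rnorm(1)
          r_p <- if (likelihood) tryCatch(curves_at(theta_p),
                                          error = function(e) NULL) else NULL
          n_prop <- n_prop + 1
          if (likelihood && is.null(r_p)) next
          ll_p <- loglik(r_p, s, tau)
          lp_p <- logprior_rates(theta_p)
          if (log(stats::runif(1)) < (ll_p + lp_p) - (ll + lp)) {
            theta <- theta_p; r_list <- r_p; ll <- ll_p; lp <- lp_p
            acc <- acc + 1; acc_j[j] <- acc_j[j] + 1
          }
        }
        if (it %% 50 == 0) {
          dlt_s <- min(0.1, 3 / sqrt(it))
          ls <- ls * exp(ifelse(acc_j / 50 > 0.44, dlt_s, -dlt_s))
          acc_j <- integer(d)
        }
      }
      # 2. Gibbs: shifts (normal-conjugate)
      for (i in seq_along(fluids)) {
        f <- fluids[i]
        if (likelihood) {
          P <- priors$shift_precision + tau[[f]] * sum(w[[i]])
          m <- tau[[f]] * sum(w[[i]] * (y[[i]] - r_list[[i]])) / P
        } else {
          P <- priors$shift_precision; m <- 0
        }
        s[[f]] <- stats::rnorm(1, m, 1 / sqrt(P))
      }
      # 3. Gibbs: precisions (gamma-conjugate)
      for (i in seq_along(fluids)) {
        f <- fluids[i]
        if (likelihood) {
          res2 <- sum(w[[i]] * (y[[i]] - s[[f]] - r_list[[i]])^2)
          tau[[f]] <- stats::rgamma(1, priors$gamma_shape + length(y[[i]]) / 2,
                                    priors$gamma_rate + res2 / 2)
        } else {
          tau[[f]] <- stats::rgamma(1, priors$gamma_shape, priors$gamma_rate)
        }
      }
      ll <- loglik(r_list, s, tau)
      # adaptation (diminishing influence through growing history)
      cnt <- cnt + 1
      dlt <- theta - mu
      mu <- mu + dlt / cnt
      Sg <- Sg + (tcrossprod(dlt, theta - mu) - Sg) / cnt
      if (it > 200 && it %% 50 == 0)
        chol_prop <- tryCatch(
          chol(2.38^2 / d * (Sg + diag(1e-8, d))),
          error = function(e) chol_prop)
      if (it > n_burn)
        out[it - n_burn, ] <- c(theta, s, tau)
    }
    list(samples = out, accept = acc / max(n_prop, 1))
  }

  chains_out <- lapply(chain_seeds, run_chain)
  samples <- lapply(chains_out, `[[`, "samples")
  rhat <- split_rhat(samples)
  pooled <- do.call(rbind, samples)

  # rate-scale summaries (exp of the log-rate samples)
  summarise <- function(x, name) {
    qs <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = name, mean = mean(x), median = qs[2],
               lo95 = qs[1], hi95 = qs[3],
               rel_ci95 = (qs[3] - qs[1]) / max(abs(qs[2]), 1e-12),
               stringsAsFactors = FALSE)
  }
  summ <- rbind(
    do.call(rbind, lapply(seq_len(d), function(j)
      summarise(exp(pooled[, j]), rn[j]))),
    do.call(rbind, lapply((d + 1):ncol(pooled), function(j)
      summarise(pooled[, j], colnames(pooled)[j]))))

  structure(
    list(model = model$name, model_spec = model, priors = priors,
         samples = samples, par_names = par_names, rate_names = rn,
         summary = summ, rhat = rhat,
         converged = all(rhat < 1.1, na.rm = TRUE),
         accept = vapply(chains_out, `[[`, 0, "accept"),
         data = tabs, protocol = protocol,
         n_iter = n_iter, n_burn = n_burn, seeds = chain_seeds),
    class = "silk_posterior")
}

# Split-Rhat over a list of per-chain sample matrices.
split_rhat <- function(samples) {
  halves <- list()
  for (ch in samples) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(samples[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), 0)
    vars <- vapply(halves, function(h) stats::var(h[, j]), 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0, USE.NAMES = FALSE) -> r
  stats::setNames(r, colnames(samples[[1]]))
}

#' @export
print.silk_posterior <- function(x, ...) {
  cat(sprintf("silkdyn posterior (%s): %d chain(s) x %d kept iterations; %s\n",
              x$model, length(x$samples), nrow(x$samples[[1]]),
              if (x$converged) "converged (all split-Rhat < 1.1)"
              else "NOT converged (split-Rhat > 1.1 for some parameters)"))
  print(transform(x$summary, mean = signif(mean, 4), median = signif(median, 4),
                  lo95 = signif(lo95, 4), hi95 = signif(hi95, 4),
                  rel_ci95 = signif(rel_ci95, 3)), row.names = FALSE)
  invisible(x)
}

#' Posterior trajectory bands and mean-versus-median diagnostics
#'
#' Integrates the model for a thinned subset of posterior draws and returns
#' pointwise credibility bands per compartment, together with the trajectory
#' at the posterior-mean parameters. A large sup-norm distance between the
#' mean-parameter curve and the pointwise-median curve — in particular the
#' mean-parameter curve leaving the pointwise interquartile band — is the
#' signature of a multimodal posterior, where the parameter means fit none
#' of the modes.
#'
#' @param post A `silk_posterior`.
#' @param grid Time grid (default 0.1 h steps over the study window).
#' @param n_draws Number of thinned posterior draws (default 500).
#' @return List of class `silk_curves`: `grid`, per-compartment `bands`
#'   (quantiles 2.5/25/50/75/97.5%), `mean_curve`, `sup_dist` (per
#'   compartment, mean-parameter vs pointwise-median curve), `band_width`
#'   (median 95% band width per compartment), `flag` (mean-parameter curve
#'   outside the interquartile band anywhere), and `n_failed` draws.
#' @export
posterior_curves <- function(post, grid = seq(0, 36.2, by = 0.1),
                             n_draws = 500) {
  model <- post$model_spec
  rn <- post$rate_names
  pooled <- do.call(rbind, post$samples)
  take <- unique(round(seq(1, nrow(pooled), length.out = min(n_draws,
                                                             nrow(pooled)))))
  comp <- setdiff(model$state_names, "g")
  arr <- array(NA_real_, c(length(take), length(grid), length(comp)),
               dimnames = list(NULL, NULL, comp))
  n_failed <- 0L
  for (i in seq_along(take)) {
    th <- stats::setNames(exp(pooled[take[i], seq_along(rn)]), rn)
    tr <- tryCatch(ria_trajectory(model, th, post$protocol, grid,
                                  method = "analytic"),
                   error = function(e) NULL)
    if (is.null(tr)) { n_failed <- n_failed + 1L; next }
    for (cc in comp) arr[i, , cc] <- tr[[cc]]
  }
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  bands <- lapply(comp, function(cc)
    apply(arr[, , cc], 2, stats::quantile, probs = qs, na.rm = TRUE))
  names(bands) <- comp
  mean_par <- stats::setNames(colMeans(exp(pooled[, seq_along(rn),
                                                  drop = FALSE])), rn)
  tr_mean <- ria_trajectory(model, mean_par, post$protocol, grid,
                            method = "analytic")
  sup_dist <- vapply(comp, function(cc)
    max(abs(tr_mean[[cc]] - bands[[cc]]["50%", ])), 0)
  band_width <- vapply(comp, function(cc)
    stats::median(bands[[cc]]["97.5%", ] - bands[[cc]]["2.5%", ]), 0)
  outside_iqr <- vapply(comp, function(cc)
    any(tr_mean[[cc]] < bands[[cc]]["25%", ] - 1e-12 |
          tr_mean[[cc]] > bands[[cc]]["75%", ] + 1e-12), TRUE)
  structure(
    list(grid = grid, bands = bands,
         mean_params = mean_par, mean_curve = tr_mean,
         sup_dist = sup_dist, band_width = band_width,
         flag = any(outside_iqr), outside_iqr = outside_iqr,
         n_failed = n_failed),
    class = "silk_curves")
}

#' Detect posterior multimodality over a set of rate parameters
#'
#' Computes a 2-D kernel density over every pair of the named rates (on the
#' rate scale, as explored by the sampler) and flags multimodality when more
#' than one local density maximum exceeds 10% of the global peak. Also
#' reports whether the posterior mean lies off all modes (low interpolated
#' density at the mean), the failure signature of redundantly parametrised
#' models: parameter means taken across several modes fit none of them.
#'
#' @param post A `silk_posterior`.
#' @param rate_subset Two or more rate names (for the full model, the
#'   redundant trio is the CSF elimination and the two CSF export rates).
#' @param n_grid KDE grid resolution per axis (default 50).
#' @param peak_frac Minimum relative height of a countable local maximum
#'   (default 0.10).
#' @param bw_scale Bandwidth inflation over the normal-reference rule
#'   (default 1.5): MCMC samples are autocorrelated, and the default
#'   kernel width lets sampling wiggles masquerade as modes.
#' @param min_samples Below this many pooled samples the flag is
#'   indeterminate (`NA`).
#' @return List of class `silk_modes`: per-pair data frame (`n_modes`,
#'   `multimodal`, `mean_density_frac`, `mean_off_mode`) and overall
#'   `flag` / `mean_off_mode`.
#' @export
detect_multimodality <- function(post, rate_subset, n_grid = 50,
                                 peak_frac = 0.10, min_samples = 500,
                                 bw_scale = 1.5) {
  stopifnot(length(rate_subset) >= 2)
  rn <- post$rate_names
  miss <- setdiff(rate_subset, rn)
  if (length(miss)) stop("unknown rate(s): ", paste(miss, collapse = ", "))
  pooled <- do.call(rbind, post$samples)
  if (nrow(pooled) < min_samples)
    return(structure(list(pairs = NULL, flag = NA, mean_off_mode = NA),
                     class = "silk_modes"))
  X <- exp(pooled[, match(rate_subset, rn), drop = FALSE])
  colnames(X) <- rate_subset
  prs <- utils::combn(rate_subset, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    x <- X[, pr[1]]; yv <- X[, pr[2]]
    kd <- MASS::kde2d(x, yv, n = n_grid,
                      h = bw_scale * c(MASS::bandwidth.nrd(x),
                                       MASS::bandwidth.nrd(yv)))
    pk <- local_maxima(kd$z)
    pk <- pk[kd$z[pk] > peak_frac * max(kd$z), , drop = FALSE]
    pk <- merge_modes(kd, pk)
    mx <- mean(x); my <- mean(yv)
    dens_at_mean <- interp2(kd, mx, my)
    data.frame(x = pr[1], y = pr[2], n_modes = nrow(pk),
               multimodal = nrow(pk) > 1,
               mean_density_frac = dens_at_mean / max(kd$z),
               mean_off_mode = dens_at_mean < 0.25 * max(kd$z),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, flag = any(pairs$multimodal),
                 mean_off_mode = any(pairs$mean_off_mode)),
            class = "silk_modes")
}

# Strict-neighborhood local maxima of a matrix (8-neighbour rule).
local_maxima <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nb <- z[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (z[i, j] >= max(nb) && sum(nb == max(nb)) == 1)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) out <- matrix(integer(), 0, 2)
  out
}

# Two candidate peaks belong to the same mode unless the density along the
# straight path between them dips below a quarter of the lower peak (a
# valley test);
# this keeps sampling wiggles on one broad mode from counting as extra
# modes. Peaks are absorbed greedily into higher ones.
merge_modes <- function(kd, pk) {
  if (nrow(pk) <= 1) return(pk)
  ord <- order(kd$z[pk], decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))[-1]) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      t_seq <- seq(0, 1, length.out = 50)
      xs <- kd$x[pk[j, 1]] + t_seq * (kd$x[pk[i, 1]] - kd$x[pk[j, 1]])
      ys <- kd$y[pk[j, 2]] + t_seq * (kd$y[pk[i, 2]] - kd$y[pk[j, 2]])
      valley <- min(vapply(seq_along(t_seq), function(k)
        interp2(kd, xs[k], ys[k]), 0))
      if (valley >= 0.25 * kd$z[pk[i, 1], pk[i, 2]]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pk[keep, , drop = FALSE]
}

# Bilinear interpolation of a kde2d surface at one point.
interp2 <- function(kd, x0, y0) {
  i <- findInterval(x0, kd$x, all.inside = TRUE)
  j <- findInterval(y0, kd$y, all.inside = TRUE)
  fx <- (x0 - kd$x[i]) / (kd$x[i + 1] - kd$x[i])
  fy <- (y0 - kd$y[j]) / (kd$y[j + 1] - kd$y[j])
  fx <- min(max(fx, 0), 1); fy <- min(max(fy, 0), 1)
  (1 - fx) * (1 - fy) * kd$z[i, j] + fx * (1 - fy) * kd$z[i + 1, j] +
    (1 - fx) * fy * kd$z[i, j + 1] + fx * fy * kd$z[i + 1, j + 1]
}
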