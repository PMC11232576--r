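# Quality-control pipeline turning a Skyline peak-intensity export into
# validated per-fluid observations and pooled protein models. Each filter
# mirrors one stage of the initial data-processing funnel: leucine screen,
# coverage/intensity screen, model-based shape validation, protein pooling.

#' Default pipeline configuration
#'
#' Thresholds and the Skyline column map used by [run_pipeline()]. Every
#' value is echoed into the QC report header so a run documents its own
#' settings.
#'
#' @param min_timepoints Minimum non-missing time points per observation
#'   (default 9 of the 13 collected).
#' @param min_intensity Intensity floor applied to the total (light + heavy)
#'   signal of a point; 0 disables the filter (no published value exists, so
#'   this is a declared assumption).
#' @param max_outlier_frac Maximum tolerated fraction of band outliers among
#'   the non-time-0 points of an observation (default 0.25; declared
#'   assumption).
#' @param min_spearman Minimum Spearman correlation between non-outlier RIAs
#'   and fitted model values (default 0.75).
#' @param loess_span LOESS span for the confidence envelope (default 0.75).
#' @param min_inside_frac Minimum fraction of the evaluation grid on which
#'   the model curve must stay inside the LOESS 95% envelope (default 0.75).
#' @param loess_grid_step Evaluation grid step in hours (default 0.5).
#' @param early_late Two-point anchoring rule: require at least 2 non-outlier
#'   points before `early_late[1]` h and 2 after `early_late[2]` h.
#' @param min_joint_obs Validated observations per fluid required for
#'   joint-model eligibility (default 4).
#' @param n_boot Bootstrap replicates for pooled protein fits.
#' @param column_map Named list mapping logical fields (`protein`, `peptide`,
#'   `fraction`, `charge`, `label`, `time`, `intensity`) to CSV column names.
#' @param labels Two-element list naming the light and heavy channel values.
#' @return A named list of settings.
#' @export
qc_config <- function(min_timepoints = 9, min_intensity = 0,
                      max_outlier_frac = 0.25, min_spearman = 0.75,
                      loess_span = 0.75, min_inside_frac = 0.75,
                      loess_grid_step = 0.5, early_late = c(10, 20),
                      min_joint_obs = 4, n_boot = 1000,
                      column_map = list(protein = "Protein",
                                        peptide = "Peptide",
                                        fraction = "Fraction",
                                        charge = "Charge",
                                        label = "Label",
                                        time = "Time",
                                        intensity = "Intensity"),
                      labels = list(light = "light", heavy = "heavy")) {
  as.list(environment())
}

#' Parse a Skyline peak-intensity export
#'
#' Reads a long-format CSV of per-precursor peak intensities (one row per
#' peptide, fraction, charge, isotope channel and time point), pairs the
#' light and heavy channels, and assembles one [silk_observation()] per
#' peptide x fraction x charge. Peptides mapping to more than one protein
#' accession are marked as shared. A heavy row with no matching light row
#' (or vice versa) yields a point with the missing channel set to `NA`.
#'
#' @param path CSV file path.
#' @param fluid `"plasma"` or `"csf"`, tagged onto every observation.
#' @param config A [qc_config()] (its `column_map` and `labels` are used).
#' @return List with `observations` and `counts` (rows, peptides,
#'   observations, proteins in the raw export).
#' @export
parse_skyline <- function(path, fluid, config = qc_config()) {
  cm <- config$column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(cm)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("Skyline export is missing required column(s): ",
         paste(miss, collapse = ", "), " (check the column map)")
  df <- data.frame(protein = as.character(raw[[cm$protein]]),
                   peptide = as.character(raw[[cm$peptide]]),
                   fraction = as.character(raw[[cm$fraction]]),
                   charge = as.integer(raw[[cm$charge]]),
                   label = as.character(raw[[cm$label]]),
                   time = as.numeric(raw[[cm$time]]),
                   intensity = as.numeric(raw[[cm$intensity]]),
                   stringsAsFactors = FALSE)
  pep_prot <- unique(df[, c("peptide", "protein")])
  shared_peps <- names(which(table(pep_prot$peptide) > 1))
  key <- paste(df$protein, df$peptide, df$fraction, df$charge, sep = "|")
  observations <- lapply(split(df, key), function(d) {
    times <- sort(unique(d$time))
    light <- d[d$label == config$labels$light, ]
    heavy <- d[d$label == config$labels$heavy, ]
    i0 <- light$intensity[match(times, light$time)]
    i6 <- heavy$intensity[match(times, heavy$time)]
    silk_observation(d$protein[1], d$peptide[1], d$fraction[1], d$charge[1],
                     fluid, times, i0, i6,
                     shared = d$peptide[1] %in% shared_peps)
  })
  names(observations) <- NULL
  list(observations = observations,
       counts = c(rows = nrow(df),
                  peptides = length(unique(df$peptide)),
                  observations = length(observations),
                  proteins = length(unique(df$protein))))
}

#' Remove peptides devoid of leucine
#'
#' Only leucine-containing peptides can incorporate the `13C6`-Leu tracer.
#'
#' @param observations List of `silk_observation`s.
#' @return The observations whose peptide contains at least one leucine.
#' @export
filter_leucine <- function(observations) {
  observations[vapply(observations, function(o) o$n_leu >= 1, TRUE)]
}

#' Coverage and intensity filter
#'
#' Points whose total signal falls below the intensity floor are blanked,
#' then observations detected at fewer than `min_timepoints` of the
#' collected time points (in the same fraction and charge state) are
#' removed.
#'
#' @param observations List of `silk_observation`s.
#' @param min_timepoints Minimum usable points (default 9).
#' @param min_intensity Total-intensity floor (default 0 = off).
#' @return Filtered list; attribute `"rejected"` holds the ids and reasons.
#' @export
filter_coverage <- function(observations, min_timepoints = 9,
                            min_intensity = 0) {
  rejected <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  kept <- list()
  for (ob in observations) {
    low <- !is.na(ob$points$i0 + ob$points$i6) &
      (ob$points$i0 + ob$points$i6) < min_intensity
    ob$points$i0[low] <- NA
    ob$points$i6[low] <- NA
    ob$points$ria[low] <- NA
    n_ok <- sum(!is.na(ob$points$ria))
    if (n_ok >= min_timepoints) {
      kept[[length(kept) + 1]] <- ob
    } else {
      rejected <- rbind(rejected, data.frame(
        id = obs_id(ob),
        reason = if (any(low)) "insufficient_intensity" else "too_few_timepoints"))
    }
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Model-based shape validation of one observation
#'
#' Fits the single-fluid model with the two-step robust procedure and
#' applies the shape acceptance rules: the fit must not be aberrant
#' (clearance stuck at a bound, or a fitted dynamic range smaller than twice
#' the shift magnitude, neither of which can represent tracer
#' incorporation); at most a fraction `max_outlier_frac` of the non-time-0
#' points may be band outliers; the Spearman correlation between non-outlier
#' RIAs and fitted values must reach `min_spearman`; the model curve must
#' stay inside the LOESS 95% confidence envelope of the non-outlier points
#' on at least `min_inside_frac` of the evaluation grid; and at least two
#' non-outlier points are required both before 10 h and after 20 h to
#' anchor the initial and final dynamics.
#'
#' @param observation A `silk_observation` that passed the coverage filter.
#' @param protocol A [silk_protocol()].
#' @param config A [qc_config()].
#' @return List with `accept` (logical), `reasons` (character vector of
#'   failed rules, empty when accepted) and `fit` (the robust fit or `NULL`).
#' @export
validate_shape <- function(observation, protocol = silk_protocol(),
                           config = qc_config()) {
  model <- silk_model("single")
  fit <- tryCatch(robust_two_step_fit(model, observation, protocol),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(list(accept = FALSE, reasons = "fit_failed", fit = NULL))
  reasons <- character()
  flags <- fit$outlier_flags

  dense <- seq(0, max(flags$time), by = 0.1)
  curve <- ria_trajectory(model, fit$params, protocol, dense,
                          method = "analytic")$r
  rng <- diff(range(curve))
  b <- fit$params[["b"]]
  at_bound <- b <= model$lower[["b"]] + 1e-6 || b >= model$upper[["b"]] - 1e-6
  if (at_bound || rng < 2 * abs(fit$shifts[[1]]))
    reasons <- c(reasons, "aberrant_shape")

  non_t0 <- flags[flags$time > 0, ]
  if (mean(non_t0$outlier) > config$max_outlier_frac)
    reasons <- c(reasons, "too_many_outliers")

  good <- flags[!flags$outlier, ]
  r_at <- ria_trajectory(model, fit$params, protocol,
                         sort(unique(c(0, good$time))), method = "analytic")
  r_good <- r_at$r[match(round(good$time, 9), round(r_at$time, 9))]
  rho <- suppressWarnings(stats::cor(good$ria, r_good, method = "spearman"))
  if (!is.finite(rho) || rho < config$min_spearman)
    reasons <- c(reasons, "low_spearman")

  env <- loess_envelope(good$time, good$ria, config)
  if (is.null(env)) {
    reasons <- c(reasons, "loess_failed")
  } else {
    m <- ria_trajectory(model, fit$params, protocol, env$grid,
                        method = "analytic")$r + fit$shifts[[1]]
    inside <- m >= env$lo & m <= env$hi
    if (mean(inside, na.rm = TRUE) < config$min_inside_frac)
      reasons <- c(reasons, "outside_loess_envelope")
  }

  if (sum(good$time < config$early_late[1]) < 2 ||
      sum(good$time > config$early_late[2]) < 2)
    reasons <- c(reasons, "missing_anchor_points")

  list(accept = length(reasons) == 0, reasons = reasons, fit = fit)
}

# Pointwise normal-approximation 95% LOESS band; NULL when the smoother
# cannot be fitted (fewer than 5 points or numerical failure).
loess_envelope <- function(time, ria, config) {
  if (length(time) < 5) return(NULL)
  lo <- tryCatch(
    stats::loess(ria ~ time, span = config$loess_span, degree = 2,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(lo)) return(NULL)
  grid <- seq(min(time), max(time), by = config$loess_grid_step)
  pr <- tryCatch(stats::predict(lo, newdata = data.frame(time = grid),
                                se = TRUE),
                 error = function(e) NULL)
  if (is.null(pr) || all(!is.finite(pr$se.fit))) return(NULL)
  list(grid = grid, lo = pr$fit - 1.96 * pr$se.fit,
       hi = pr$fit + 1.96 * pr$se.fit)
}

#' Run the full QC pipeline on a pair of Skyline exports
#'
#' Executes, per fluid: parse, leucine screen, coverage/intensity screen,
#' shape validation, then protein-level pooling of the validated
#' observations. Proteins with dynamics in both fluids are intersected, and
#' those with at least `min_joint_obs` validated observations in each fluid
#' are marked eligible for the joint plasma-CSF models.
#'
#' @param csv_plasma,csv_csf Paths to the per-fluid Skyline exports.
#' @param config A [qc_config()].
#' @param protocol A [silk_protocol()].
#' @param seed Bootstrap seed for pooled fits.
#' @return An object of class `silk_qc_run`: per-fluid lists (`validated`
#'   observations, `proteins` pooled results), `report` (a `silk_qc_report`),
#'   `joint_proteins`, and `joint_eligible`.
#' @export
run_pipeline <- function(csv_plasma, csv_csf, config = qc_config(),
                         protocol = silk_protocol(), seed = 1) {
  fluids <- list(plasma = csv_plasma, csf = csv_csf)
  out <- list()
  stages <- NULL
  rejections <- NULL
  for (f in names(fluids)) {
    parsed <- parse_skyline(fluids[[f]], f, config)
    obs <- parsed$observations
    stage_row <- function(stage, obs) data.frame(
      fluid = f, stage = stage, observations = length(obs),
      peptides = length(unique(vapply(obs, `[[`, "", "peptide"))),
      proteins = length(unique(vapply(obs, `[[`, "", "protein"))),
      stringsAsFactors = FALSE)
    stages <- rbind(stages, stage_row("parsed", obs))

    with_leu <- filter_leucine(obs)
    no_leu <- setdiff(vapply(obs, obs_id, ""), vapply(with_leu, obs_id, ""))
    if (length(no_leu))
      rejections <- rbind(rejections, data.frame(
        fluid = f, id = no_leu, stage = "leucine", reason = "no_leucine"))
    stages <- rbind(stages, stage_row("leucine", with_leu))

    covered <- filter_coverage(with_leu, config$min_timepoints,
                               config$min_intensity)
    rej <- attr(covered, "rejected")
    if (nrow(rej))
      rejections <- rbind(rejections, data.frame(
        fluid = f, id = rej$id, stage = "coverage", reason = rej$reason))
    stages <- rbind(stages, stage_row("coverage", covered))

    fits <- list()
    validated <- list()
    for (ob in covered) {
      v <- validate_shape(ob, protocol, config)
      if (v$accept) {
        validated[[length(validated) + 1]] <- ob
        fits[[obs_id(ob)]] <- v$fit
      } else {
        rejections <- rbind(rejections, data.frame(
          fluid = f, id = obs_id(ob), stage = "shape",
          reason = paste(v$reasons, collapse = ";")))
      }
    }
    stages <- rbind(stages, stage_row("shape", validated))

    prot <- split(validated,
                  vapply(validated, `[[`, "", "protein"))
    pooled <- lapply(prot, pool_protein, protocol = protocol,
                     n_boot = config$n_boot, seed = seed,
                     individual_fits = fits)
    ok <- vapply(pooled, function(p) p$status == "ok", TRUE)
    for (nm in names(pooled)[!ok])
      rejections <- rbind(rejections, data.frame(
        fluid = f, id = nm, stage = "pooling", reason = pooled[[nm]]$reason))
    stages <- rbind(stages, stage_row("pooled",
                                      unlist(lapply(pooled[ok], `[[`,
                                                    "observations"),
                                             recursive = FALSE)))
    out[[f]] <- list(validated = validated, proteins = pooled[ok],
                     n_validated_obs = table(vapply(validated, `[[`, "",
                                                    "protein")))
  }
  common <- intersect(names(out$plasma$proteins), names(out$csf$proteins))
  if (!length(common))
    warning("no protein has dynamics in both fluids")
  eligible <- common[vapply(common, function(p)
    out$plasma$n_validated_obs[[p]] >= config$min_joint_obs &&
      out$csf$n_validated_obs[[p]] >= config$min_joint_obs, TRUE)]
  report <- structure(list(stages = stages, rejections = rejections,
                           config = config), class = "silk_qc_report")
  structure(list(plasma = out$plasma, csf = out$csf, report = report,
                 joint_proteins = common, joint_eligible = eligible),
            class = "silk_qc_run")
}

#' @export
print.silk_qc_report <- function(x, ...) {
  cat("QC funnel (per-stage surviving counts):\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$rejections) && nrow(x$rejections)) {
    cat("rejections by reason:\n")
    print(table(x$rejections$fluid, x$rejections$reason))
  }
  invisible(x)
}

#' @export
print.silk_qc_run <- function(x, ...) {
  print(x$report)
  cat(sprintf("proteins with dynamics in both fluids: %d; joint-eligible: %d\n",
              length(x$joint_proteins), length(x$joint_eligible)))
  invisible(x)
}
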