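# Ground-truth-known synthetic data: RIA time courses with the statistical
# structure the analysis assumes (per-fluid vertical shifts, I0-proportional
# error precision, outlier contamination, missing points, multi-leucine
# peptides) and Skyline-like CSV exports, so the whole stack is testable
# without any external download.

#' Synthetic study design
#'
#' Defaults emulate the SILK acquisition: 13 time points roughly every 3 h
#' over 36.2 h, 4 observations per protein per fluid, log-normal light
#' intensities, per-fluid error precision with variance inversely
#' proportional to the intensity weight, small per-fluid vertical shifts
#' with observation-level jitter, sparse outlier contamination and missing
#' points, and an even mix of the three archetype dynamics (comparable,
#' faster-CSF, faster-plasma).
#'
#' @param times Sampling grid in hours.
#' @param n_proteins Number of proteins in a cohort.
#' @param obs_per_fluid Observations per protein per fluid.
#' @param n_leu_probs Probabilities of 1, 2, 3 leucines per peptide.
#' @param i0_meanlog,i0_sdlog Log-normal parameters of the light intensity.
#' @param precision Named per-fluid error precisions (1/variance at unit
#'   weight); the default 4e4 corresponds to a residual SD of 0.005 RIA
#'   units at an average-intensity point.
#' @param fluid_shift Named per-fluid vertical shifts.
#' @param obs_shift_sd SD of the observation-level shift jitter.
#' @param outlier_rate,missing_rate Per-point contamination probabilities.
#' @param archetype_mix Named mixing proportions over
#'   `c("comparable", "faster_csf", "faster_plasma")`; must sum to 1.
#' @param defect_rate Fraction of cohort proteins receiving one planted
#'   QC-defect observation (no-leucine peptide, sparse coverage, or
#'   shape-violating series, cycled in that order).
#' @return A list of class `silk_design`.
#' @export
silk_design <- function(times = seq(0, 36.2, length.out = 13),
                        n_proteins = 10, obs_per_fluid = 4,
                        n_leu_probs = c(0.55, 0.3, 0.15),
                        i0_meanlog = log(1e5), i0_sdlog = 1,
                        precision = c(plasma = 4e4, csf = 4e4),
                        fluid_shift = c(plasma = 0.004, csf = -0.003),
                        obs_shift_sd = 0.002,
                        outlier_rate = 0.05, missing_rate = 0.05,
                        archetype_mix = c(comparable = 1 / 3,
                                          faster_csf = 1 / 3,
                                          faster_plasma = 1 / 3),
                        defect_rate = 0) {
  stopifnot(all(times >= 0), all(times <= 36.2),
            abs(sum(archetype_mix) - 1) < 1e-9,
            all(precision > 0))
  structure(as.list(environment()), class = "silk_design")
}

#' Archetype ground-truth parameter sets
#'
#' Simplified three-compartment parameter sets reproducing the three
#' qualitative patterns of simultaneously observed dynamics: comparable
#' dynamics in both fluids (SERPINF1/SERPINF2-like), faster dynamics in the
#' CSF driven by a strong CNS route (TTR/PROS1-like), and faster plasma
#' dynamics (APOH-like).
#'
#' @param archetype One of `"comparable"`, `"faster_csf"`,
#'   `"faster_plasma"`.
#' @return Named rate vector for `silk_model("three_bc_simplified")`.
#' @export
archetype_params <- function(archetype = c("comparable", "faster_csf",
                                           "faster_plasma")) {
  archetype <- match.arg(archetype)
  switch(archetype,
    comparable = c(a_p = 0.040, a_n = 0.060, b_p = 0.130, b_n = 0.150,
                   k_pc = 0.030, k_cp = 0.150, k_nc = 0.300, k_cn = 0.020),
    faster_csf = c(a_p = 0.015, a_n = 0.140, b_p = 0.060, b_n = 0.250,
                   k_pc = 0.020, k_cp = 0.060, k_nc = 0.500, k_cn = 0.350),
    faster_plasma = c(a_p = 0.080, a_n = 0.012, b_p = 0.400, b_n = 0.060,
                      k_pc = 0.050, k_cp = 0.040, k_nc = 0.030, k_cn = 0.010))
}

random_peptide <- function(n_leu, len = NULL) {
  aa <- strsplit("ACDEFGHIKMNPQRSTVWY", "")[[1]]  # leucine-free alphabet
  if (is.null(len)) len <- sample(8:14, 1)
  p <- sample(aa, len, replace = TRUE)
  if (n_leu > 0) p[sample(len, n_leu)] <- "L"
  paste(p, collapse = "")
}

#' Generate the observations of one synthetic protein
#'
#' Simulates the model trajectories for the given truth parameters, then for
#' each observation draws light intensities, adds shift and
#' intensity-weighted normal noise to the RIA, injects outlier spikes and
#' missing points, and back-computes the heavy intensity
#' `I6 = RIA_adj * n * I0 / (1 - RIA_adj * n)` so that intensity ratios stay
#' realistic. Time-0 points carry shift and noise only (no tracer is
#' incorporated yet). Infeasible noisy RIAs (below 0 or at/above `1/n`)
#' are clipped and counted in the truth record.
#'
#' @param params Named truth rates for `model`.
#' @param design A [silk_design()].
#' @param seed Integer seed (full determinism).
#' @param protein Protein accession for the generated observations.
#' @param model Model variant name (default `"three_bc_simplified"`).
#' @param protocol A [silk_protocol()].
#' @param archetype Optional archetype label stored in the truth record.
#' @return List with `observations` (both fluids) and `truth` (class
#'   `silk_truth`: parameters, per-observation shifts, outlier/missing
#'   positions, clip count).
#' @export
generate_protein <- function(params, design = silk_design(), seed = 1,
                             protein = "PROT1",
                             model = "three_bc_simplified",
                             protocol = silk_protocol(),
                             archetype = NA_character_) {
  set.seed(seed)
  mspec <- silk_model(model)
  tr <- ria_trajectory(mspec, params, protocol, design$times,
                       method = "analytic")
  observations <- list()
  obs_shifts <- list()
  outliers <- NULL
  missing <- NULL
  n_clipped <- 0L
  for (fluid in c("plasma", "csf")) {
    r <- tr[[fluid_column(mspec, fluid)]]
    rng <- diff(range(r))
    prec <- design$precision[[fluid]]
    for (j in seq_len(design$obs_per_fluid)) {
      n_leu <- sample(seq_along(design$n_leu_probs), 1,
                      prob = design$n_leu_probs)
      pep <- random_peptide(n_leu)
      s_obs <- design$fluid_shift[[fluid]] +
        stats::rnorm(1, 0, design$obs_shift_sd)
      i0 <- stats::rlnorm(length(design$times), design$i0_meanlog,
                          design$i0_sdlog)
      w <- i0 / mean(i0)
      y <- r + s_obs + stats::rnorm(length(r), 0, 1 / sqrt(prec * w))
      is_out <- design$outlier_rate > 0 &
        stats::runif(length(y)) < design$outlier_rate & design$times > 0
      if (any(is_out))
        y[is_out] <- r[is_out] + s_obs +
          stats::runif(sum(is_out), 1, 2) * rng
      hi <- 0.999 / n_leu
      clip <- y < 0 | y > hi
      n_clipped <- n_clipped + sum(clip)
      y <- pmin(pmax(y, 0), hi)
      i6 <- y * n_leu * i0 / (1 - y * n_leu)
      is_miss <- stats::runif(length(y)) < design$missing_rate
      i0[is_miss] <- NA
      i6[is_miss] <- NA
      ob <- silk_observation(protein, pep, fraction = "F1", charge = 2L,
                             fluid = fluid, times = design$times,
                             i0 = i0, i6 = i6, n_leu = n_leu)
      observations[[length(observations) + 1]] <- ob
      obs_shifts[[obs_id(ob)]] <- s_obs
      if (any(is_out))
        outliers <- rbind(outliers, data.frame(
          id = obs_id(ob), time = design$times[is_out]))
      if (any(is_miss))
        missing <- rbind(missing, data.frame(
          id = obs_id(ob), time = design$times[is_miss]))
    }
  }
  truth <- structure(
    list(protein = protein, model = model, params = params,
         archetype = archetype, fluid_shift = design$fluid_shift,
         obs_shifts = obs_shifts, outliers = outliers, missing = missing,
         n_clipped = n_clipped, seed = seed, defects = NULL),
    class = "silk_truth")
  list(observations = observations, truth = truth)
}

# One deliberately defective observation for QC-funnel testing.
plant_defect <- function(type, protein, design, tr_csf) {
  times <- design$times
  n <- length(times)
  i0 <- stats::rlnorm(n, design$i0_meanlog, design$i0_sdlog)
  if (type == "no_leucine") {
    y <- pmax(tr_csf + stats::rnorm(n, 0, 0.003), 0)
    pep <- random_peptide(0)
    n_leu_eff <- 1
  } else if (type == "sparse") {
    y <- pmax(tr_csf + stats::rnorm(n, 0, 0.003), 0)
    pep <- random_peptide(1)
    n_leu_eff <- 1
    if (n > 8) {  # keep 8 of the collected points
      drop <- sample(which(times > 0), n - 8)
      i0[drop] <- NA
    }
  } else { # aberrant shape: monotone decline, incompatible with labelling
    y <- pmax(0.06 - 0.0015 * times + stats::rnorm(n, 0, 0.002), 0)
    pep <- random_peptide(1)
    n_leu_eff <- 1
  }
  y <- pmin(y, 0.999 / n_leu_eff)
  i6 <- y * n_leu_eff * i0 / (1 - y * n_leu_eff)
  i6[is.na(i0)] <- NA
  silk_observation(protein, pep, fraction = "F9", charge = 2L, fluid = "csf",
                   times = times, i0 = i0, i6 = i6)
}

#' Generate a synthetic cohort and its Skyline-like exports
#'
#' Draws per-protein archetypes from the design mix, generates observations
#' for both fluids, optionally plants labelled QC defects, and writes
#' plasma/CSF CSV exports in the dialect read by [parse_skyline()], plus a
#' truth table.
#'
#' @param design A [silk_design()].
#' @param seed Integer seed.
#' @param dir Output directory for `plasma.csv`, `csf.csv` and
#'   `truth.json`; `NULL` writes nothing and returns the data only.
#' @param protocol A [silk_protocol()].
#' @return List with `observations`, `truths` (per protein), `defects`
#'   (data frame: protein, observation id, defect type, expected failing
#'   stage), and `paths` when `dir` was given.
#' @export
generate_cohort <- function(design = silk_design(), seed = 1, dir = NULL,
                            protocol = silk_protocol()) {
  set.seed(seed)
  archetypes <- sample(names(design$archetype_mix), design$n_proteins,
                       replace = TRUE, prob = design$archetype_mix)
  n_defect <- round(design$defect_rate * design$n_proteins)
  defect_types <- rep(c("no_leucine", "sparse", "aberrant"),
                      length.out = n_defect)
  defect_for <- rep(NA_character_, design$n_proteins)
  if (n_defect > 0)
    defect_for[sample(design$n_proteins, n_defect)] <- defect_types
  sub_seeds <- sample.int(2^31 - 2, design$n_proteins)

  observations <- list()
  truths <- list()
  defects <- NULL
  for (i in seq_len(design$n_proteins)) {
    prot <- sprintf("SYN%03d", i)
    gp <- generate_protein(archetype_params(archetypes[i]), design,
                           seed = sub_seeds[i], protein = prot,
                           protocol = protocol, archetype = archetypes[i])
    if (!is.na(defect_for[i])) {
      tr <- ria_trajectory(silk_model("three_bc_simplified"),
                           archetype_params(archetypes[i]), protocol,
                           design$times, method = "analytic")
      bad <- plant_defect(defect_for[i], prot, design, tr$r_csf)
      gp$observations <- c(gp$observations, list(bad))
      stage <- c(no_leucine = "leucine", sparse = "coverage",
                 aberrant = "shape")[[defect_for[i]]]
      defects <- rbind(defects, data.frame(
        protein = prot, id = obs_id(bad), type = defect_for[i],
        stage = stage, stringsAsFactors = FALSE))
      gp$truth$defects <- defects[defects$protein == prot, ]
    }
    observations <- c(observations, gp$observations)
    truths[[prot]] <- gp$truth
  }

  out <- list(observations = observations, truths = truths, defects = defects)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(plasma = file.path(dir, "plasma.csv"),
               csf = file.path(dir, "csf.csv"),
               truth = file.path(dir, "truth.json"))
    for (f in c("plasma", "csf")) {
      sub <- observations[vapply(observations, `[[`, "", "fluid") == f]
      utils::write.csv(observations_to_export(sub), paths[[f]],
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(truths, function(tt) tt[c("protein", "model", "archetype",
                                       "params", "fluid_shift", "seed")]),
      paths[["truth"]], auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

# Long-format Skyline-like export rows; missing points are absent rows.
observations_to_export <- function(observations) {
  rows <- lapply(observations, function(ob) {
    pts <- ob$points[!is.na(ob$points$i0) | !is.na(ob$points$i6), ,
                     drop = FALSE]
    if (!nrow(pts)) return(NULL)
    do.call(rbind, lapply(c("light", "heavy"), function(lab) {
      val <- if (lab == "light") pts$i0 else pts$i6
      ok <- !is.na(val)
      if (!any(ok)) return(NULL)
      data.frame(Protein = ob$protein, Peptide = ob$peptide,
                 Fraction = ob$fraction, Charge = ob$charge, Label = lab,
                 Time = pts$time[ok], Intensity = val[ok],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
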