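# Skyline-export parsing and the QC funnel.

write_export <- function(observations, path) {
  utils::write.csv(silkdyn:::observations_to_export(observations), path,
                   row.names = FALSE)
}

test_that("parser pairs light/heavy channels and flags shared peptides", {
  dir <- withr::local_tempdir()
  obs <- clean_single_obs()
  write_export(list(obs), file.path(dir, "one.csv"))
  parsed <- parse_skyline(file.path(dir, "one.csv"), "plasma")
  expect_length(parsed$observations, 1)
  expect_equal(nrow(parsed$observations[[1]]$points), 13)
  expect_equal(parsed$counts[["peptides"]], 1)

  # heavy row without a matching light row: point kept with missing I0
  df <- silkdyn:::observations_to_export(list(obs))
  df <- df[!(df$Label == "light" & df$Time == df$Time[3]), ]
  utils::write.csv(df, file.path(dir, "gap.csv"), row.names = FALSE)
  gap <- parse_skyline(file.path(dir, "gap.csv"), "plasma")$observations[[1]]
  expect_true(is.na(gap$points$i0[3]))
  expect_false(is.na(gap$points$i6[3]))
  expect_true(is.na(gap$points$ria[3]))

  # the same peptide under two accessions is shared under both
  ob2 <- obs; ob2$protein <- "P2"; ob2 <- silk_observation(
    "P2", obs$peptide, "F1", 2, "plasma", obs$points$time,
    obs$points$i0, obs$points$i6)
  write_export(list(obs, ob2), file.path(dir, "shared.csv"))
  sh <- parse_skyline(file.path(dir, "shared.csv"), "plasma")$observations
  expect_true(all(vapply(sh, `[[`, TRUE, "shared")))

  # a missing required column is named in the error
  df2 <- silkdyn:::observations_to_export(list(obs))
  names(df2)[names(df2) == "Charge"] <- "Z"
  utils::write.csv(df2, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(parse_skyline(file.path(dir, "bad.csv"), "plasma"), "Charge")
})

test_that("leucine and coverage filters apply the published rules", {
  times <- seq(0, 36.2, length.out = 13)
  mk <- function(pep) silk_observation("P1", pep, "F1", 2, "csf", times,
                                       rep(1e5, 13), rep(1e3, 13))
  obs <- lapply(c("AGDVK", "ALDVK", "LLDVK"), mk)
  kept <- filter_leucine(obs)
  expect_equal(vapply(kept, `[[`, "", "peptide"), c("ALDVK", "LLDVK"))
  # two leucines halve the adjusted RIA
  expect_equal(kept[[2]]$points$ria, kept[[1]]$points$ria / 2)

  # nine-of-13 detection rule
  o9 <- clean_single_obs(); o9$points$i0[1:4] <- NA; o9$points$ria[1:4] <- NA
  o8 <- clean_single_obs(); o8$points$i0[1:5] <- NA; o8$points$ria[1:5] <- NA
  kept2 <- filter_coverage(list(o9, o8), min_timepoints = 9)
  expect_length(kept2, 1)
  expect_equal(attr(kept2, "rejected")$reason, "too_few_timepoints")

  # intensity floor blanks weak points
  weak <- clean_single_obs(i0 = rep(10, 13))
  expect_length(filter_coverage(list(weak), min_intensity = 1e4), 0)
})

test_that("shape validation accepts model-like series and rejects aberrant ones", {
  des <- silk_design(obs_per_fluid = 1)
  gp <- generate_protein(archetype_params("comparable"), des, seed = 14)
  ob <- Filter(function(o) o$fluid == "plasma", gp$observations)[[1]]
  v <- validate_shape(ob, test_protocol)
  expect_true(v$accept)
  expect_length(v$reasons, 0)

  # a decreasing-then-rising (time-reversed) series cannot be traced by any
  # rise-then-clear curve: the Spearman rule fires
  times <- seq(0, 36.2, length.out = 13)
  set.seed(9)
  y <- pmax(0.05 + 0.02 * abs(times - 18) / 18 + rnorm(13, 0, 0.002), 1e-4)
  bad <- obs_from_ria(y, times = times)
  vb <- validate_shape(bad, test_protocol)
  expect_false(vb$accept)
  expect_true("low_spearman" %in% vb$reasons)

  # a monotone-declining series is likewise rejected (degenerate fitted
  # shape and LOESS envelope violations)
  y2 <- pmax(0.06 - 0.0015 * times + rnorm(13, 0, 0.001), 1e-4)
  vb2 <- validate_shape(obs_from_ria(y2, times = times), test_protocol)
  expect_false(vb2$accept)

  # fewer than two late anchor points
  late <- clean_single_obs()
  keep <- late$points$time <= 20 | late$points$time == max(late$points$time)
  late$points$i0[!keep] <- NA; late$points$i6[!keep] <- NA
  late$points$ria[!keep] <- NA
  vl <- validate_shape(late, test_protocol)
  expect_false(vl$accept)
  expect_true("missing_anchor_points" %in% vl$reasons)
})

test_that("pipeline reproduces the funnel with planted defects", {
  dir <- withr::local_tempdir()
  des <- silk_design(n_proteins = 3, obs_per_fluid = 4, defect_rate = 1,
                     outlier_rate = 0.02, missing_rate = 0.02)
  coh <- generate_cohort(des, seed = 21, dir = dir)
  cfg <- qc_config(n_boot = 20)
  run <- run_pipeline(coh$paths[["plasma"]], coh$paths[["csf"]],
                      config = cfg, seed = 1)

  # funnel monotonicity per fluid
  for (f in c("plasma", "csf")) {
    st <- run$report$stages
    n <- st$observations[st$fluid == f]
    expect_true(all(diff(n[1:4]) <= 0))
  }
  # every planted defect is rejected at (or before) its expected stage
  rej <- run$report$rejections
  for (i in seq_len(nrow(coh$defects))) {
    expect_true(coh$defects$id[i] %in% rej$id)
    expect_true(rej$stage[rej$id == coh$defects$id[i]] %in%
                  c(coh$defects$stage[i], "coverage", "shape"))
  }
  # accounting: rejected observations + validated = parsed (per fluid)
  for (f in c("plasma", "csf")) {
    st <- run$report$stages
    parsed_n <- st$observations[st$fluid == f & st$stage == "parsed"]
    obs_rej <- rej[rej$fluid == f & rej$stage != "pooling", ]
    expect_equal(parsed_n,
                 nrow(obs_rej) + length(run[[f]]$validated))
  }
  # all three proteins have dynamics in both fluids and 4 clean obs each
  expect_setequal(run$joint_proteins, names(coh$truths))
  expect_true(all(run$joint_eligible %in% run$joint_proteins))
})

test_that("joint eligibility needs four validated observations per fluid", {
  dir <- withr::local_tempdir()
  des <- silk_design(n_proteins = 1, obs_per_fluid = 4, outlier_rate = 0,
                     missing_rate = 0)
  coh <- generate_cohort(des, seed = 33, dir = NULL)
  # drop one plasma observation: 3 in plasma, 4 in CSF
  obs <- coh$observations
  pl <- which(vapply(obs, `[[`, "", "fluid") == "plasma")
  obs <- obs[-pl[1]]
  write_export(Filter(function(o) o$fluid == "plasma", obs),
               file.path(dir, "p.csv"))
  write_export(Filter(function(o) o$fluid == "csf", obs),
               file.path(dir, "c.csv"))
  run <- run_pipeline(file.path(dir, "p.csv"), file.path(dir, "c.csv"),
                      config = qc_config(n_boot = 10), seed = 1)
  expect_equal(run$joint_proteins, "SYN001")
  expect_length(run$joint_eligible, 0)
})

test_that("empty exports produce empty outputs without error", {
  dir <- withr::local_tempdir()
  hdr <- "Protein,Peptide,Fraction,Charge,Label,Time,Intensity\n"
  writeLines(hdr, file.path(dir, "p.csv"))
  writeLines(hdr, file.path(dir, "c.csv"))
  expect_warning(
    run <- run_pipeline(file.path(dir, "p.csv"), file.path(dir, "c.csv"),
                        config = qc_config(n_boot = 5), seed = 1),
    "no protein")
  expect_length(run$joint_proteins, 0)
  expect_length(run$plasma$validated, 0)
})
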