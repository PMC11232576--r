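# Run configuration and provenance for the command-line workflow.

run_config_schema <- function() {
  list(
    paths = c("plasma_csv", "csf_csv", "out_dir"),
    qc = names(formals(qc_config)),
    model = c("variant"),
    fit = c("n_boot", "min_points"),
    mcmc = c("n_iter", "n_burn", "chains", "empirical_mean"),
    design = names(formals(silk_design)),
    seed = NULL)
}

#' Read and validate a run configuration
#'
#' Loads a structured-text (YAML) configuration for the command-line
#' workflow. Unknown keys are rejected so that typos cannot silently revert
#' a threshold to its default; every threshold is echoed into the output
#' manifest.
#'
#' @param path YAML file path.
#' @return Nested list of settings with class `silk_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- run_config_schema()
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.null(schema[[sec]])) next
    unknown <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(unknown))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "silk_config")
}

#' Write a reproducibility manifest
#'
#' Records the configuration (and its hash), seeds, package and R versions
#' alongside a run's outputs, sufficient to reproduce the deterministic
#' stages bit-for-bit.
#'
#' @param out_dir Output directory.
#' @param config The configuration list used.
#' @param seed The run seed.
#' @param extra Optional named list of additional entries.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, seed, extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- c(list(
    package = "silkdyn",
    package_version = as.character(utils::packageVersion("silkdyn")),
    r_version = R.version.string,
    seed = seed,
    config_sha1 = substr(digest_string(cfg_json), 1, 16),
    config = unclass(config),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Small dependency-free content fingerprint (polynomial rolling hash).
digest_string <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
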