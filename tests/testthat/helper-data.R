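# Shared builders for deterministic test data.

test_protocol <- silk_protocol()

# essentially noise-free design (tiny residual SD, no contamination)
clean_design <- function(...) {
  silk_design(precision = c(plasma = Inf, csf = Inf),
              fluid_shift = c(plasma = 0, csf = 0), obs_shift_sd = 0,
              outlier_rate = 0, missing_rate = 0, ...)
}

# observation with exactly prescribed adjusted RIA values
obs_from_ria <- function(ria, times = seq(0, 36.2, length.out = length(ria)),
                         i0 = rep(1e5, length(ria)), n_leu = 1,
                         fluid = "plasma", protein = "P1", peptide = "ALDVK",
                         fraction = "F1", charge = 2) {
  stopifnot(all(ria * n_leu < 1), all(ria >= 0))
  i6 <- ria * n_leu * i0 / (1 - ria * n_leu)
  silk_observation(protein, peptide, fraction, charge, fluid, times, i0, i6,
                   n_leu = n_leu)
}

single_truth <- c(a = 0.05, b = 0.12)

# noiseless single-fluid observation from the model curve plus a shift
clean_single_obs <- function(params = single_truth, shift = 0.004,
                             times = seq(0, 36.2, length.out = 13),
                             n_leu = 1, i0 = rep(1e5, length(times)), ...) {
  tr <- ria_trajectory(silk_model("single"), params, test_protocol, times,
                       method = "analytic")
  obs_from_ria(tr$r + shift, times = times, i0 = i0, n_leu = n_leu, ...)
}
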