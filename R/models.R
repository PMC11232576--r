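#' Compartment model specifications
#'
#' The package models the relative isotope abundance (RIA) of a protein as a
#' linear compartment system driven by tracer availability `g(t)`, itself
#' driven by the infusion input `u(t)`. Five variants are available:
#'
#' * `"single"` — one observed fluid. `g' = u - a g`, `r' = a g - b r`.
#'   `a` (1/h) feeds newly synthesised protein and acts essentially as a
#'   scale parameter; `b` (1/h) is the clearance rate shaping the curve.
#' * `"two_bc"` — two biological compartments (plasma and CSF) with linear
#'   RIA transfers `k_pc` (plasma to CSF) and `k_cp` (CSF to plasma), plasma
#'   clearance `b_p` and CSF elimination `b_c`; synthesis only in plasma.
#' * `"two_bc_delay"` — as `"two_bc"` but the plasma signal reaching CSF is
#'   delayed by `tau` hours (zero history before `tau`), yielding a delay
#'   differential equation.
#' * `"three_bc_full"` — plasma, hidden CNS, and CSF. Synthesis `a_p`, `a_n`
#'   into plasma and CNS, per-compartment eliminations `b_p`, `b_n`, `b_c`,
#'   and all six pairwise transfers `k_pc`, `k_cp`, `k_pn`, `k_np`, `k_nc`,
#'   `k_cn` (13 parameters counting the two per-fluid shifts fitted with it).
#' * `"three_bc_simplified"` — the full model with `k_pn`, `k_np` and `b_c`
#'   fixed at zero (10 parameters with the shifts): CNS-to-plasma export is
#'   regarded as already integrated in the plasma data, plasma entry to CSF
#'   via the CNS as negligible, and no in-situ CSF degradation.
#'
#' The tracer-availability pool is consumed by synthesis, so its decay rate
#' is `a` (single fluid / two compartments) or `a_p + a_n` (three
#' compartments). All states start at zero: no tracer is incorporated at
#' `t = 0`.
#'
#' @param name One of `"single"`, `"two_bc"`, `"two_bc_delay"`,
#'   `"three_bc_full"`, `"three_bc_simplified"`.
#' @param rate_upper Upper bound for all rate parameters (1/h); default 10.
#' @param shift_bound Symmetric bound for the per-fluid vertical RIA shifts;
#'   default 0.05.
#' @return An object of class `silk_model` with elements `name`,
#'   `rate_names`, `shift_names`, `state_names`, `lower`, `upper` (named
#'   bounds over rates then shifts), and `delay` (logical).
#' @examples
#' m <- silk_model("three_bc_simplified")
#' m$rate_names
#' @export
silk_model <- function(name = c("single", "two_bc", "two_bc_delay",
                                "three_bc_full", "three_bc_simplified"),
                       rate_upper = 10, shift_bound = 0.05) {
  name <- match.arg(name)
  spec <- switch(name,
    single = list(
      rate_names = c("a", "b"),
      shift_names = "s",
      state_names = c("g", "r")),
    two_bc = list(
      rate_names = c("a", "b_p", "k_pc", "k_cp", "b_c"),
      shift_names = c("s_p", "s_c"),
      state_names = c("g", "r_plasma", "r_csf")),
    two_bc_delay = list(
      rate_names = c("a", "b_p", "k_pc", "k_cp", "b_c", "tau"),
      shift_names = c("s_p", "s_c"),
      state_names = c("g", "r_plasma", "r_csf")),
    three_bc_full = list(
      rate_names = c("a_p", "a_n", "b_p", "b_n", "b_c",
                     "k_pc", "k_cp", "k_pn", "k_np", "k_nc", "k_cn"),
      shift_names = c("s_p", "s_c"),
      state_names = c("g", "r_plasma", "r_cns", "r_csf")),
    three_bc_simplified = list(
      rate_names = c("a_p", "a_n", "b_p", "b_n",
                     "k_pc", "k_cp", "k_nc", "k_cn"),
      shift_names = c("s_p", "s_c"),
      state_names = c("g", "r_plasma", "r_cns", "r_csf"))
  )
  lower <- c(stats::setNames(rep(0, length(spec$rate_names)), spec$rate_names),
             stats::setNames(rep(-shift_bound, length(spec$shift_names)),
                             spec$shift_names))
  upper <- c(stats::setNames(rep(rate_upper, length(spec$rate_names)),
                             spec$rate_names),
             stats::setNames(rep(shift_bound, length(spec$shift_names)),
                             spec$shift_names))
  if (name == "two_bc_delay") upper["tau"] <- 36.2
  structure(
    c(spec,
      list(name = name, lower = lower, upper = upper,
           delay = identical(name, "two_bc_delay"),
           n_states = length(spec$state_names))),
    class = "silk_model")
}

#' @export
print.silk_model <- function(x, ...) {
  cat(sprintf("silkdyn compartment model '%s': states (%s); rates (%s); shifts (%s)\n",
              x$name, paste(x$state_names, collapse = ", "),
              paste(x$rate_names, collapse = ", "),
              paste(x$shift_names, collapse = ", ")))
  invisible(x)
}

# Validate/complete a named rate vector against a model spec.
check_params <- function(model, params) {
  stopifnot(inherits(model, "silk_model"))
  miss <- setdiff(model$rate_names, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- as.numeric(params[model$rate_names])
  names(p) <- model$rate_names
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p[setdiff(model$rate_names, "tau")] < 0))
    stop("negative rate parameter")
  p
}

# The system matrix is linear in the rates: A(theta) = sum_j theta_j B_j.
# Precomputing the basis matrices B_j lets the fitting and MCMC loops
# rebuild A with a handful of scalar-matrix operations.
param_basis <- function(model) {
  n <- model$n_states
  sn <- model$state_names
  basis <- lapply(setdiff(model$rate_names, "tau"), function(nm) {
    B <- matrix(0, n, n, dimnames = list(sn, sn))
    add <- function(i, j) B[i, j] <<- B[i, j] + 1
    sub <- function(i, j) B[i, j] <<- B[i, j] - 1
    if (model$name == "single") {
      if (nm == "a") { sub("g", "g"); add("r", "g") }
      if (nm == "b") sub("r", "r")
    } else if (model$name %in% c("two_bc", "two_bc_delay")) {
      switch(nm,
        a = { sub("g", "g"); add("r_plasma", "g") },
        b_p = sub("r_plasma", "r_plasma"),
        k_pc = { sub("r_plasma", "r_plasma"); add("r_csf", "r_plasma") },
        k_cp = { add("r_plasma", "r_csf"); sub("r_csf", "r_csf") },
        b_c = sub("r_csf", "r_csf"))
    } else {
      switch(nm,
        a_p = { sub("g", "g"); add("r_plasma", "g") },
        a_n = { sub("g", "g"); add("r_cns", "g") },
        b_p = sub("r_plasma", "r_plasma"),
        b_n = sub("r_cns", "r_cns"),
        b_c = sub("r_csf", "r_csf"),
        k_pc = { sub("r_plasma", "r_plasma"); add("r_csf", "r_plasma") },
        k_cp = { add("r_plasma", "r_csf"); sub("r_csf", "r_csf") },
        k_pn = { sub("r_plasma", "r_plasma"); add("r_cns", "r_plasma") },
        k_np = { add("r_plasma", "r_cns"); sub("r_cns", "r_cns") },
        k_nc = { sub("r_cns", "r_cns"); add("r_csf", "r_cns") },
        k_cn = { add("r_cns", "r_csf"); sub("r_csf", "r_csf") })
    }
    B
  })
  names(basis) <- setdiff(model$rate_names, "tau")
  basis
}

# Linear system matrix A (state' = A state + u(t) e1) for non-delay variants.
# The simplified 3-bc matrix is the full matrix with its excluded rates at 0.
system_matrix <- function(model, params) {
  p <- check_params(model, params)
  z <- function(nm) if (nm %in% names(p)) p[[nm]] else 0
  switch(model$name,
    single = {
      a <- z("a"); b <- z("b")
      matrix(c(-a, 0,
                a, -b), nrow = 2, byrow = TRUE,
             dimnames = list(model$state_names, model$state_names))
    },
    two_bc = ,
    two_bc_delay = {
      a <- z("a"); b_p <- z("b_p"); k_pc <- z("k_pc")
      k_cp <- z("k_cp"); b_c <- z("b_c")
      matrix(c(-a,      0,               0,
                a, -(b_p + k_pc),        k_cp,
                0,      k_pc,   -(k_cp + b_c)),
             nrow = 3, byrow = TRUE,
             dimnames = list(model$state_names, model$state_names))
    },
    three_bc_full = ,
    three_bc_simplified = {
      a_p <- z("a_p"); a_n <- z("a_n")
      b_p <- z("b_p"); b_n <- z("b_n"); b_c <- z("b_c")
      k_pc <- z("k_pc"); k_cp <- z("k_cp")
      k_pn <- z("k_pn"); k_np <- z("k_np")
      k_nc <- z("k_nc"); k_cn <- z("k_cn")
      matrix(c(
        -(a_p + a_n), 0, 0, 0,
        a_p, -(b_p + k_pc + k_pn), k_np, k_cp,
        a_n, k_pn, -(b_n + k_np + k_nc), k_cn,
        0, k_pc, k_nc, -(b_c + k_cp + k_cn)),
        nrow = 4, byrow = TRUE,
        dimnames = list(model$state_names, model$state_names))
    })
}
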