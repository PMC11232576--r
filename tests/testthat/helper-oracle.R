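# Independent oracles for the compartment models.
#
# oracle_trajectory() re-derives the system matrices from the model
# equations (no reuse of package internals) and solves the linear
# constant-coefficient system exactly on each constant-input segment via the
# eigendecomposition closed form:
#   x(t0+dt) = V e^{L dt} V^-1 x0 + u V diag(phi) V^-1 e1,
#   phi_i = (e^{l_i dt} - 1) / l_i  (dt if l_i ~ 0).
# oracle_dde() integrates the delay variant by the method of steps, feeding
# an interpolant of the stored plasma history into a plain ODE solve.

oracle_matrix <- function(variant, p) {
  gv <- function(nm) if (nm %in% names(p)) unname(p[[nm]]) else 0
  if (variant == "single") {
    rbind(c(-gv("a"), 0),
          c(gv("a"), -gv("b")))
  } else if (variant %in% c("two_bc", "two_bc_delay")) {
    rbind(c(-gv("a"), 0, 0),
          c(gv("a"), -(gv("b_p") + gv("k_pc")), gv("k_cp")),
          c(0, gv("k_pc"), -(gv("k_cp") + gv("b_c"))))
  } else {
    rbind(
      c(-(gv("a_p") + gv("a_n")), 0, 0, 0),
      c(gv("a_p"), -(gv("b_p") + gv("k_pc") + gv("k_pn")), gv("k_np"),
        gv("k_cp")),
      c(gv("a_n"), gv("k_pn"), -(gv("b_n") + gv("k_np") + gv("k_nc")),
        gv("k_cn")),
      c(0, gv("k_pc"), gv("k_nc"), -(gv("b_c") + gv("k_cp") + gv("k_cn"))))
  }
}

# input levels/breaks of the two-level step protocol
oracle_segments <- function(protocol, t_max) {
  brk <- sort(unique(c(0, protocol$bolus_duration,
                       protocol$total_label_window, t_max)))
  brk <- brk[brk <= t_max + 1e-12]
  if (max(brk) < t_max) brk <- c(brk, t_max)
  lev <- vapply(brk[-length(brk)], function(t0) {
    if (t0 < protocol$bolus_duration) protocol$bolus_rate
    else if (t0 < protocol$total_label_window) protocol$infusion_rate
    else 0
  }, 0)
  list(brk = brk, lev = lev)
}

oracle_trajectory <- function(variant, p, protocol, times) {
  A <- oracle_matrix(variant, p)
  n <- nrow(A)
  eg <- eigen(A)
  V <- eg$vectors
  Vi <- solve(V)
  step <- function(x0, u, dt) {
    el <- exp(eg$values * dt)
    phi <- ifelse(abs(eg$values) < 1e-12, dt, (el - 1) / eg$values)
    x <- V %*% (el * (Vi %*% x0)) + u * V %*% (phi * Vi[, 1])
    Re(x)
  }
  seg <- oracle_segments(protocol, max(times, protocol$total_label_window))
  pts <- sort(unique(c(times, seg$brk)))
  x <- matrix(0, n, 1)
  out <- matrix(0, length(times), n)
  out[times == 0, ] <- 0
  si <- 1
  for (k in seq_along(pts)[-1]) {
    t0 <- pts[k - 1]; t1 <- pts[k]
    while (si < length(seg$lev) && t0 >= seg$brk[si + 1] - 1e-12) si <- si + 1
    x <- step(x, seg$lev[si], t1 - t0)
    hit <- abs(times - t1) < 1e-12
    if (any(hit)) out[hit, ] <- matrix(rep(t(x), sum(hit)), ncol = n,
                                       byrow = TRUE)
  }
  out
}

# method-of-steps DDE oracle for the two_bc_delay variant
oracle_dde <- function(p, protocol, times, h = 0.005) {
  tau <- unname(p[["tau"]])
  t_max <- max(times)
  grid <- sort(unique(c(seq(0, t_max, by = h), times, t_max)))
  u_fun <- function(t) {
    if (t < protocol$bolus_duration) protocol$bolus_rate
    else if (t < protocol$total_label_window) protocol$infusion_rate
    else 0
  }
  rp_hist <- function(t) 0  # zero history
  sol_all <- NULL
  k0 <- 0
  while (k0 < t_max - 1e-12) {
    k1 <- min(k0 + tau, t_max)
    sub <- grid[grid >= k0 - 1e-12 & grid <= k1 + 1e-12]
    sub <- sort(unique(c(k0, sub, k1)))
    y0 <- if (is.null(sol_all)) c(0, 0, 0) else
      as.numeric(sol_all[nrow(sol_all), -1])
    f <- function(t, y, parms) {
      list(c(u_fun(t) - p[["a"]] * y[1],
             p[["a"]] * y[1] - (p[["b_p"]] + p[["k_pc"]]) * y[2] +
               p[["k_cp"]] * y[3],
             p[["k_pc"]] * rp_hist(t - tau) - (p[["k_cp"]] + p[["b_c"]]) * y[3]))
    }
    sol <- deSolve::ode(y0, sub, f, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    sol_all <- if (is.null(sol_all)) sol else rbind(sol_all, sol[-1, ])
    rp_hist <- stats::approxfun(sol_all[, 1], sol_all[, 3], rule = 2,
                                yleft = 0)
    k0 <- k1
  }
  idx <- vapply(times, function(t) which.min(abs(sol_all[, 1] - t)), 0L)
  out <- sol_all[idx, -1, drop = FALSE]
  colnames(out) <- c("g", "r_plasma", "r_csf")
  out
}

# random in-bounds parameter draw for a variant; synthesis rates kept at
# RIA-plausible magnitudes so trajectories stay O(1)
draw_params <- function(variant, rate_names) {
  p <- stats::setNames(stats::runif(length(rate_names), 0.01, 2), rate_names)
  p[grepl("^a", names(p))] <- stats::runif(sum(grepl("^a", names(p))),
                                           0.005, 0.3)
  if ("tau" %in% names(p)) p["tau"] <- stats::runif(1, 0.5, 6)
  p
}
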