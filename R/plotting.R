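# Figure data for dynamics plots and compartment-graph renderings. The
# functions return plain data structures (usable from any plotting layer);
# plot_dynamics() draws them with ggplot2 when it is installed.

#' Assemble dynamics-plot data for one protein
#'
#' Collects, per fluid: the fitted (or posterior-mean) RIA curve, the tracer
#' availability curve, the observed RIA dots with sizes proportional to the
#' square root of the heavy intensity, the 9 h end-of-tracer marker, and —
#' for Bayesian input — the pointwise 95% credibility bands.
#'
#' @param fit A `silk_fit`, or a `silk_posterior`.
#' @param curves Optional precomputed [posterior_curves()] (Bayesian input
#'   only); computed on demand otherwise.
#' @param grid Plotting grid in hours.
#' @return List of class `silk_plot_data`: `curves` (time, compartment,
#'   value), `points` (time, ria, size, fluid, outlier), `bands` (`NULL`
#'   for fit-only input), `label_end` (9 h marker).
#' @export
render_dynamics_plot <- function(fit, curves = NULL,
                                 grid = seq(0, 36.2, by = 0.1)) {
  if (inherits(fit, "silk_posterior")) {
    model <- fit$model_spec
    if (is.null(curves)) curves <- posterior_curves(fit, grid = grid)
    grid <- curves$grid
    tr <- curves$mean_curve
    bands <- do.call(rbind, lapply(names(curves$bands), function(cc)
      data.frame(time = grid, compartment = cc,
                 lo = curves$bands[[cc]]["2.5%", ],
                 hi = curves$bands[[cc]]["97.5%", ])))
    tabs <- fit$data
    shifts <- NULL
  } else if (inherits(fit, "silk_fit")) {
    model <- fit$model_spec
    tr <- ria_trajectory(model, fit$params, fit$protocol, grid,
                         method = "analytic")
    bands <- NULL
    # plot every point (including flagged outliers): the pre-screen tables
    tabs <- if (!is.null(fit$step1)) fit$step1$data else fit$data
    shifts <- fit$shifts
  } else stop("fit must be a silk_fit or silk_posterior")

  curve_df <- do.call(rbind, lapply(model$state_names, function(cc)
    data.frame(time = grid, compartment = cc, value = tr[[cc]])))
  pts <- do.call(rbind, lapply(names(tabs), function(f) {
    tb <- tabs[[f]]
    i6 <- tb$i6
    i6[is.na(i6)] <- 0
    data.frame(time = tb$time, ria = tb$ria, fluid = f,
               size = sqrt(i6), stringsAsFactors = FALSE)
  }))
  if (!is.null(fit$outlier_flags) && inherits(fit, "silk_fit")) {
    key <- paste(fit$outlier_flags$fluid, fit$outlier_flags$time,
                 fit$outlier_flags$ria)
    pts$outlier <- paste(pts$fluid, pts$time, pts$ria) %in%
      key[fit$outlier_flags$outlier]
  } else pts$outlier <- FALSE
  structure(list(curves = curve_df, points = pts, bands = bands,
                 shifts = shifts, label_end = 9),
            class = "silk_plot_data")
}

#' Draw dynamics-plot data with ggplot2
#'
#' @param x A `silk_plot_data` from [render_dynamics_plot()].
#' @return A ggplot object.
#' @export
plot_dynamics <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  stopifnot(inherits(x, "silk_plot_data"))
  g <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = x$label_end, colour = "grey60") +
    ggplot2::geom_line(data = x$curves,
                       ggplot2::aes(.data$time, .data$value,
                                    colour = .data$compartment,
                                    linetype = .data$compartment == "g"))
  if (!is.null(x$bands))
    g <- g + ggplot2::geom_ribbon(
      data = x$bands,
      ggplot2::aes(.data$time, ymin = .data$lo, ymax = .data$hi,
                   group = .data$compartment),
      fill = "grey70", alpha = 0.4)
  g + ggplot2::geom_point(
    data = x$points,
    ggplot2::aes(.data$time, .data$ria, size = .data$size,
                 shape = .data$outlier, fill = .data$fluid),
    alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "time (h)", y = "RIA")
}

# Directed edge list of a model variant: synthesis edges from the tracer
# pool, elimination edges to a sink, transfer edges between compartments.
rate_edges <- function(model) {
  e <- switch(model$name,
    single = data.frame(
      rate = c("a", "b"),
      from = c("tracer", "fluid"), to = c("fluid", "out")),
    two_bc = , two_bc_delay = data.frame(
      rate = c("a", "b_p", "k_pc", "k_cp", "b_c"),
      from = c("tracer", "plasma", "plasma", "csf", "csf"),
      to = c("plasma", "out", "csf", "plasma", "out")),
    three_bc_full = data.frame(
      rate = c("a_p", "a_n", "b_p", "b_n", "b_c",
               "k_pc", "k_cp", "k_pn", "k_np", "k_nc", "k_cn"),
      from = c("tracer", "tracer", "plasma", "cns", "csf",
               "plasma", "csf", "plasma", "cns", "cns", "csf"),
      to = c("plasma", "cns", "out", "out", "out",
             "csf", "plasma", "cns", "plasma", "csf", "cns")),
    three_bc_simplified = data.frame(
      rate = c("a_p", "a_n", "b_p", "b_n", "k_pc", "k_cp", "k_nc", "k_cn"),
      from = c("tracer", "tracer", "plasma", "cns", "plasma", "csf", "cns",
               "csf"),
      to = c("plasma", "cns", "out", "out", "csf", "plasma", "csf", "cns")))
  e$rate <- as.character(e$rate)
  e
}

#' Compartment-graph specification from posterior summaries
#'
#' Builds the node/edge description of the fitted model: edge width is
#' proportional to the posterior-mean rate magnitude and edge colour is
#' keyed to the relative 95% credibility interval (interval range divided by
#' the estimate) — the coldest colour marks the best-constrained rates.
#'
#' @param post A `silk_posterior` (or a data frame shaped like its
#'   `summary` element together with `model`).
#' @param model A [silk_model()]; taken from `post` when omitted.
#' @param max_width Width of the largest-magnitude edge (default 8).
#' @return List of class `silk_graph`: `nodes`, and `edges` with columns
#'   `rate`, `from`, `to`, `mean`, `rel_ci95`, `width`, `color_value`
#'   (0 = coldest, 1 = hottest).
#' @export
render_model_graph <- function(post, model = NULL, max_width = 8) {
  if (inherits(post, "silk_posterior")) {
    summ <- post$summary
    model <- post$model_spec
  } else summ <- post
  stopifnot(inherits(model, "silk_model"))
  e <- rate_edges(model)
  idx <- match(e$rate, summ$parameter)
  if (any(is.na(idx))) stop("summary lacks some rate parameters")
  e$mean <- summ$mean[idx]
  e$rel_ci95 <- summ$rel_ci95[idx]
  e$width <- max_width * e$mean / max(e$mean)
  rng <- range(e$rel_ci95)
  e$color_value <- if (diff(rng) > 0) (e$rel_ci95 - rng[1]) / diff(rng)
                   else rep(0, nrow(e))
  nodes <- unique(c(e$from, e$to))
  structure(list(nodes = nodes, edges = e), class = "silk_graph")
}
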