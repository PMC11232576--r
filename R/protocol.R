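#' Tracer infusion protocol
#'
#' Describes the intravenous administration of the `13C6`-leucine tracer as a
#' two-level step function: a short initial bolus followed by a constant
#' infusion, after which no tracer is delivered. The default reproduces the
#' SILK protocol used for serial plasma/CSF sampling: a 10 min bolus at
#' 2 mg/kg followed by an 8 h 50 infusion at 2 mg/kg/h, i.e. 9 h of tracer
#' availability in total.
#'
#' The driving input `u(t)` of the kinetic models is this step function,
#' normalised (by default) so that its time integral equals one. Because the
#' tracer-availability compartment `g` only receives input through `u(t)` and
#' otherwise decays, this guarantees `g(t) <= 1` for every nonnegative
#' parameter set, making `g` interpretable as a fractional availability.
#'
#' @param bolus_duration Bolus length in hours (default 10 min).
#' @param bolus_rate Bolus delivery rate. With the default 2 mg/kg given over
#'   10 min this is 12 mg/kg/h.
#' @param infusion_duration Infusion length in hours (default 8 h 50).
#' @param infusion_rate Infusion delivery rate in mg/kg/h.
#' @param normalize If `TRUE` (default) rescale both levels so that the total
#'   delivered dose integrates to 1; `u(t)` then has units 1/h.
#' @param single_level If `TRUE`, replace the bolus + infusion profile by a
#'   single constant level over the whole label window (a deliberate
#'   simplification toggle; the plateau behaviour of `g` is nearly identical).
#' @return An object of class `silk_protocol`.
#' @examples
#' pr <- silk_protocol()
#' tracer_input(pr, c(0.05, 5, 12))
#' @export
silk_protocol <- function(bolus_duration = 10 / 60,
                          bolus_rate = 2 / (10 / 60),
                          infusion_duration = 8 + 50 / 60,
                          infusion_rate = 2,
                          normalize = TRUE,
                          single_level = FALSE) {
  stopifnot(bolus_duration >= 0, infusion_duration >= 0,
            bolus_rate >= 0, infusion_rate >= 0)
  total_window <- bolus_duration + infusion_duration
  if (single_level) {
    dose <- bolus_rate * bolus_duration + infusion_rate * infusion_duration
    bolus_duration <- 0
    bolus_rate <- 0
    infusion_duration <- total_window
    infusion_rate <- if (total_window > 0) dose / total_window else 0
  }
  if (normalize) {
    dose <- bolus_rate * bolus_duration + infusion_rate * infusion_duration
    if (dose > 0) {
      bolus_rate <- bolus_rate / dose
      infusion_rate <- infusion_rate / dose
    }
  }
  structure(
    list(bolus_duration = bolus_duration,
         bolus_rate = bolus_rate,
         infusion_duration = infusion_duration,
         infusion_rate = infusion_rate,
         total_label_window = total_window),
    class = "silk_protocol"
  )
}

#' Tracer input function u(t)
#'
#' Piecewise-constant tracer delivery: bolus level on `[0, bolus_duration)`,
#' infusion level on `[bolus_duration, total_label_window)`, zero afterwards.
#'
#' @param protocol A [silk_protocol()].
#' @param t Time(s) in hours; must be nonnegative.
#' @return Numeric vector of input levels, same length as `t`.
#' @export
tracer_input <- function(protocol, t) {
  stopifnot(inherits(protocol, "silk_protocol"))
  if (any(t < 0)) stop("tracer_input: negative time not in the domain")
  ifelse(t < protocol$bolus_duration, protocol$bolus_rate,
         ifelse(t < protocol$total_label_window, protocol$infusion_rate, 0))
}

#' @export
print.silk_protocol <- function(x, ...) {
  cat(sprintf(
    "SILK infusion protocol: bolus %.3f h at %.4g, infusion %.3f h at %.4g (label window %.3f h)\n",
    x$bolus_duration, x$bolus_rate, x$infusion_duration, x$infusion_rate,
    x$total_label_window))
  invisible(x)
}

# Piecewise-constant segments of u(t) up to t_max: matrix with columns
# (start, end, level). Internal; used by both integration engines.
protocol_segments <- function(protocol, t_max) {
  brk <- sort(unique(c(0, protocol$bolus_duration, protocol$total_label_window, t_max)))
  brk <- brk[brk <= t_max + 1e-12]
  if (max(brk) < t_max) brk <- c(brk, t_max)
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  keep <- ends > starts + 1e-15
  starts <- starts[keep]; ends <- ends[keep]
  lev <- tracer_input(protocol, starts)
  cbind(start = starts, end = ends, level = lev)
}
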