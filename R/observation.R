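#' Adjusted relative isotope abundance
#'
#' The RIA of a peptide at one time point is the heavy (`+6` Da per labelled
#' leucine) precursor intensity divided by the total (heavy plus light)
#' intensity. Peptides carrying `n` leucines have a proportionally higher
#' chance of incorporating at least one label, so the ratio is divided by
#' `n` to put peptides on a common scale.
#'
#' @param i0 Light (unlabelled) intensity, `>= 0`.
#' @param i6 Heavy (labelled) intensity, `>= 0`.
#' @param n_leu Number of leucines in the peptide, `>= 1`.
#' @return `(i6 / (i0 + i6)) / n_leu`; `NA` where the total signal is zero or
#'   either intensity is missing.
#' @examples
#' compute_ria(100, 100, 2) # 0.25
#' @export
compute_ria <- function(i0, i6, n_leu = 1) {
  stopifnot(all(n_leu >= 1))
  tot <- i0 + i6
  out <- ifelse(is.na(tot) | tot <= 0, NA_real_, (i6 / tot) / n_leu)
  as.numeric(out)
}

#' Count leucine residues in a peptide sequence
#'
#' @param peptide Character vector of amino-acid sequences (one-letter code).
#' @return Integer vector of leucine counts.
#' @export
count_leucines <- function(peptide) {
  vapply(strsplit(toupper(peptide), ""), function(x) sum(x == "L"), integer(1))
}

#' Construct an observation (one peptide x fraction x charge time series)
#'
#' An observation is the unit of dynamics estimation: the RIA time course of
#' a given peptide, in a given chromatographic fraction, at a given precursor
#' charge state, in one fluid.
#'
#' @param protein Protein accession.
#' @param peptide Peptide sequence (one-letter amino-acid code).
#' @param fraction Chromatographic fraction label.
#' @param charge Precursor charge state.
#' @param fluid `"plasma"` or `"csf"`.
#' @param times Time points in hours.
#' @param i0,i6 Light and heavy intensities at `times` (`NA` = missing).
#' @param n_leu Leucine count; counted from `peptide` when `NULL`.
#' @param shared `TRUE` if the peptide maps to more than one protein
#'   accession in the export (such observations are excluded from protein
#'   pooling).
#' @return An object of class `silk_observation` whose `points` element is a
#'   data frame with columns `time`, `i0`, `i6`, `ria`.
#' @export
silk_observation <- function(protein, peptide, fraction, charge, fluid,
                             times, i0, i6, n_leu = NULL, shared = FALSE) {
  fluid <- match.arg(fluid, c("plasma", "csf"))
  if (is.null(n_leu)) n_leu <- count_leucines(peptide)
  stopifnot(length(times) == length(i0), length(i0) == length(i6))
  o <- order(times)
  pts <- data.frame(time = as.numeric(times)[o],
                    i0 = as.numeric(i0)[o], i6 = as.numeric(i6)[o])
  # peptides without leucine cannot incorporate the label: RIA undefined
  pts$ria <- if (n_leu >= 1) compute_ria(pts$i0, pts$i6, n_leu) else NA_real_
  structure(
    list(protein = protein, peptide = peptide, fraction = fraction,
         charge = charge, fluid = fluid, n_leu = as.integer(n_leu),
         shared = isTRUE(shared), points = pts),
    class = "silk_observation")
}

#' @export
print.silk_observation <- function(x, ...) {
  cat(sprintf("observation %s | %s | fraction %s | charge %s | %s | %d Leu | %d/%d points\n",
              x$protein, x$peptide, x$fraction, x$charge, x$fluid, x$n_leu,
              sum(!is.na(x$points$ria)), nrow(x$points)))
  invisible(x)
}

obs_id <- function(obs) {
  paste(obs$protein, obs$peptide, obs$fraction, obs$charge, obs$fluid, sep = "|")
}

# Flatten a list of observations (one fluid) into one point table with
# relative intensity weights w = I0 / mean(I0) over the usable points.
obs_points <- function(observations, drop_missing = TRUE) {
  if (inherits(observations, "silk_observation"))
    observations <- list(observations)
  tabs <- lapply(seq_along(observations), function(j) {
    ob <- observations[[j]]
    cbind(ob$points, obs = j, id = obs_id(ob),
          fluid = ob$fluid, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (drop_missing) tab <- tab[!is.na(tab$ria) & !is.na(tab$i0), , drop = FALSE]
  if (nrow(tab) == 0) stop("no usable data points")
  tab$w <- tab$i0 / mean(tab$i0)
  tab
}
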