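#' Cell-cycle timing from growth rate
#'
#' In B. subtilis the DNA replication period lengthens as growth slows,
#' following the empirical relation \eqn{\tau_{rep} = 0.78 + 0.15/g} (hours),
#' while the cell-cycle length is \eqn{\tau_{cyc} = \ln(2)/g}. The
#' post-replication period is their difference. Overlapping replication
#' rounds (\eqn{\tau_{rep} \ge \tau_{cyc}}, reached for fast growth) are not
#' modelled and are rejected unless \code{allow_overlap = TRUE}, in which
#' case \code{tau_post} is reported as 0 and dosage logic caps the copy
#' ratio at 1:2.
#'
#' @param g growth rate in 1/h; must be positive.
#' @param tau_rep optional override of the replication period (h); by
#'   default computed from \code{g}.
#' @param tau_post optional override of the post-replication period (h).
#'   Supplying \code{tau_rep} and/or \code{tau_post} redefines
#'   \code{tau_cyc = tau_rep + tau_post}; this is how cycle-phase scenarios
#'   (replication-only or post-replication-only slowdown) are constructed.
#' @param allow_overlap permit \code{tau_rep >= tau_cyc} configurations.
#' @return An object of class \code{cycle_timing}: a list with fields
#'   \code{g}, \code{tau_rep}, \code{tau_cyc}, \code{tau_post}.
#' @examples
#' timing_from_growth(0.2)   # tau_rep 1.53 h, tau_cyc 3.47 h, tau_post 1.94 h
#' @export
timing_from_growth <- function(g = NULL, tau_rep = NULL, tau_post = NULL,
                               allow_overlap = FALSE) {
  if (is.null(g) && (is.null(tau_rep) || is.null(tau_post)))
    stop("either g, or both tau_rep and tau_post, must be given")
  if (!is.null(g)) {
    if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
      stop("growth rate g must be a single positive number")
    if (is.null(tau_rep)) tau_rep <- 0.78 + 0.15 / g
    tau_cyc <- if (is.null(tau_post)) log(2) / g else tau_rep + tau_post
  } else {
    tau_cyc <- tau_rep + tau_post
    g <- log(2) / tau_cyc
  }
  tau_post <- tau_cyc - tau_rep
  if (tau_rep <= 0) stop("tau_rep must be positive")
  if (tau_post < 0) {
    if (!allow_overlap)
      stop("overlapping replication rounds (tau_rep >= tau_cyc) are not ",
           "modelled; pass allow_overlap = TRUE to cap the dosage ratio")
    tau_post <- 0
  }
  structure(list(g = g, tau_rep = tau_rep, tau_cyc = tau_cyc,
                 tau_post = tau_post),
            class = "cycle_timing")
}

#' @export
print.cycle_timing <- function(x, ...) {
  cat(sprintf(
    "cell cycle at g = %.4g 1/h: tau_rep = %.3g h, tau_post = %.3g h, tau_cyc = %.3g h\n",
    x$g, x$tau_rep, x$tau_post, x$tau_cyc))
  invisible(x)
}

#' Growth-rate dependence of cell size
#'
#' Average cell size (hence the copy-number-to-concentration production
#' scaling) decreases with growth rate as \eqn{F(g) = a e^{b g} + c}. The
#' default coefficients a = 3.5, b = -ln 2, c = 3.7 come from in vivo
#' measurements used to parameterize the phosphorelay model.
#'
#' @param g growth rate (1/h), may be a vector; non-negative.
#' @param a,b,c coefficients (a, c dimensionless; b in h).
#' @return F(g), dimensionless.
#' @export
size_factor <- function(g, a = 3.5, b = -log(2), c = 3.7) {
  if (any(!is.finite(g)) || any(g < 0)) stop("g must be finite and >= 0")
  a * exp(b * g) + c
}

#' Gene position on the chromosome
#'
#' Position is expressed as the fraction p of the replication period at
#' which the locus is duplicated: p = 0 for an oriC-proximal gene (spo0F),
#' p = 1 for a terminus-proximal gene (kinA). The replication offset within
#' the cycle is \code{p * tau_rep} (replication initiates at cycle start).
#'
#' @param p fractional position in [0, 1].
#' @param name optional gene name.
#' @return object of class \code{gene_position}.
#' @export
gene_position <- function(p, name = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("p must be a single number in [0, 1]")
  structure(list(p = p, name = name), class = "gene_position")
}

#' Discrete gene copy number within the cell cycle
#'
#' One copy before the locus is replicated, two copies from the moment of
#' replication (at \code{p * tau_rep} into the cycle) until division, at
#' which point the count resets to one. Time is taken modulo nothing: the
#' caller supplies time-within-cycle.
#'
#' @param t_in_cycle time since cycle start (h), in [0, tau_cyc); vectorized.
#' @param gene a \code{gene_position}.
#' @param timing a \code{cycle_timing}.
#' @return integer vector of copy numbers (1 or 2).
#' @export
discrete_copy_number <- function(t_in_cycle, gene, timing) {
  stopifnot(inherits(gene, "gene_position"), inherits(timing, "cycle_timing"))
  if (any(t_in_cycle < 0) || any(t_in_cycle >= timing$tau_cyc))
    stop("t_in_cycle must lie in [0, tau_cyc)")
  offset <- gene$p * min(timing$tau_rep, timing$tau_cyc)
  ifelse(t_in_cycle >= offset, 2L, 1L)
}

#' Population-average gene copy number
#'
#' Exponential-age-distribution average \eqn{n = 2^{1 - \tau_{rep} p /
#' \tau_{cyc}}}: oriC-proximal genes (p = 0) average two copies per cell,
#' terminus-proximal genes fewer, approaching one when replication occupies
#' the whole cycle.
#'
#' @param gene a \code{gene_position} (or numeric p).
#' @param timing a \code{cycle_timing}.
#' @return average copy number in [1, 2].
#' @export
average_copy_number <- function(gene, timing) {
  p <- if (inherits(gene, "gene_position")) gene$p else gene
  stopifnot(inherits(timing, "cycle_timing"))
  frac <- min(timing$tau_rep / timing$tau_cyc, 1)
  2^(1 - frac * p)
}
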