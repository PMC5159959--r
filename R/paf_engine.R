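# Population attributable fractions for continuous exposures:
#   PAF = (E[RR] - RR(TMREL)) / E[RR],  E[RR] = integral over [l, u] of
#   RR(x) P(x) dx, with the exposure density renormalized on [l, u].
# Curves are normalized so RR(TMREL) = 1, hence PAF = 1 - 1/E[RR], which lies
# in [0, 1) for capped curves.

#' Evaluate a relative-risk curve at an exposure level
#'
#' @param curve an [rr_curve()]
#' @param x exposure values (must lie in the curve's support)
#' @param tmrel_value the TMREL in exposure units; the curve is anchored so
#'   that `RR(tmrel_value) = 1`
#' @return relative risks (> 0)
#' @export
evaluate_rr <- function(curve, x, tmrel_value) {
  assert_that(inherits(curve, "rr_curve"), "curve must be an rr_curve")
  if (any(x < curve$support[1] | x > curve$support[2])) {
    stop_validation(sprintf("exposure outside curve support [%g, %g]",
                            curve$support[1], curve$support[2]))
  }
  excess <- if (curve$direction == "harmful_high") x - tmrel_value
            else tmrel_value - x
  if (curve$cap_at_tmrel) excess <- pmax(excess, 0)
  exp(curve$log_rr_per_unit * excess)
}

#' Evaluate a mediated relative-risk chain at an exposure level
#'
#' Composes the exposure-to-mediator slope with the mediator's RR curve:
#' a unit of harmful excess shifts the mediator by `slope` units, and the
#' mediator RR (anchored at zero mediator change) supplies the risk. Equals 1
#' at the TMREL; a zero slope gives RR identically 1.
#'
#' @param chain a [mediation_chain()]
#' @param x exposure values
#' @param tmrel_value TMREL in exposure units
#' @return relative risks (> 0)
#' @export
compose_mediated_rr <- function(chain, x, tmrel_value) {
  assert_that(inherits(chain, "mediation_chain"), "chain must be a mediation_chain")
  excess <- if (chain$direction == "harmful_high") x - tmrel_value
            else tmrel_value - x
  if (chain$cap_at_tmrel) excess <- pmax(excess, 0)
  delta_med <- chain$slope * excess
  exp(chain$mediator_rr$log_rr_per_unit * delta_med)
}

# Dispatch helper: RR as a function of exposure for either curve type.
rr_function <- function(curve, tmrel_value) {
  if (inherits(curve, "mediation_chain")) {
    function(x) compose_mediated_rr(curve, x, tmrel_value)
  } else {
    function(x) evaluate_rr(curve, x, tmrel_value)
  }
}

# E[RR] over the distribution support by n-node Gauss-Legendre quadrature.
quad_expected_rr <- function(dist, rr_fun, nodes) {
  ref <- gl_reference(nodes)
  l <- dist$support[1]
  u <- dist$support[2]
  mid <- (l + u) / 2
  half <- (u - l) / 2
  x <- mid + half * ref$x
  sum(half * ref$w * rr_fun(x) * exposure_density(dist, x))
}

#' Population attributable fraction for one exposure distribution and curve
#'
#' Integrates the relative-risk curve against the stratum exposure
#' distribution by Gauss-Legendre quadrature on the distribution's support,
#' doubling the node count until the expected RR is stable to `tol`, then
#' returns `(E[RR] - RR(TMREL)) / E[RR]`. Since curves are anchored at the
#' TMREL this is `1 - 1/E[RR]`, in `[0, 1)` for capped curves. A point-mass
#' distribution short-circuits to `RR(mean)`.
#'
#' @param dist an [exposure_distribution()]
#' @param curve an [rr_curve()] or [mediation_chain()]
#' @param tmrel_value TMREL in exposure units
#' @param nodes starting quadrature node count (>= 64)
#' @param tol absolute tolerance on `E[RR]` checked against node doubling
#' @param refine double nodes until `tol` is met (up to 4096 nodes); disable
#'   for speed inside draw loops where the node count is fixed
#' @return the PAF point value (scalar)
#' @export
compute_paf <- function(dist, curve, tmrel_value, nodes = 256L, tol = 1e-8,
                        refine = TRUE) {
  assert_that(inherits(dist, "exposure_distribution"),
              "dist must be an exposure_distribution")
  assert_that(nodes >= 64, "quadrature needs at least 64 nodes")
  rr_fun <- rr_function(curve, tmrel_value)
  if (dist$family == "point") {
    e_rr <- rr_fun(dist$mean)
  } else {
    e_rr <- quad_expected_rr(dist, rr_fun, nodes)
    if (refine) {
      repeat {
        nodes2 <- nodes * 2L
        e2 <- quad_expected_rr(dist, rr_fun, nodes2)
        converged <- abs(e2 - e_rr) <= tol
        e_rr <- e2
        nodes <- nodes2
        if (converged || nodes >= 4096L) break
      }
    }
  }
  if (!is.finite(e_rr)) stop_validation("expected relative risk is not finite")
  if (e_rr <= 0) stop_validation("expected relative risk must be positive")
  rr_ref <- rr_fun(tmrel_value)
  (e_rr - rr_ref) / e_rr
}

#' Combine attributable fractions across risk factors
#'
#' For several risks acting on the same outcome and stratum, combines PAFs
#' under independence as `1 - prod(1 - PAF_i)` (multiplicative complement).
#' The combined value never exceeds the sum of the inputs (which is why
#' summed single-risk percentages can exceed the all-risk total) and never
#' falls below the largest input.
#'
#' @param pafs numeric vector of PAFs, each `<= 1`
#' @return the combined PAF
#' @export
combine_pafs <- function(pafs) {
  assert_that(length(pafs) >= 1, "need at least one PAF")
  assert_that(all(pafs <= 1), "PAFs cannot exceed 1")
  if (any(pafs == 1)) {
    message("degenerate PAF of 1 encountered; combined PAF is 1")
    return(1)
  }
  1 - prod(1 - pafs)
}
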