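# Adsorption-energy linear scaling relation E_ads,O = slope * E_ads,HO + intercept.

#' Adsorption-energy scaling relation between O and HO
#'
#' The empirical linear relation `E_ads,O = slope * E_ads,HO + intercept`
#' across material surfaces, reflecting that atomic O and the HO radical
#' prefer the same adsorption sites. The defaults (slope 1.87, intercept
#' 1.42 eV) are the published fit over transition-metal, fluorite and
#' rutile surfaces; [fit_scaling_relation()] refits it from user data.
#'
#' @param slope dimensionless slope (default 1.87).
#' @param intercept intercept in eV (default 1.42).
#' @return an object of class `scaling_relation`.
#' @seealso [fit_scaling_relation()], [o_from_oh()]
#' @export
scaling_relation <- function(slope = 1.87, intercept = 1.42) {
  slope <- check_number(slope, "slope")
  intercept <- check_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept,
                 n_points = 0L, residual_rms = NA_real_),
            class = "scaling_relation")
}

#' Fit the O-vs-HO adsorption-energy scaling relation
#'
#' Ordinary least-squares fit of `e_ads_o ~ e_ads_ho` over a set of
#' surfaces, returning a [scaling_relation()] carrying the fitted slope,
#' intercept, number of points and root-mean-square residual.
#'
#' @param e_ads_ho numeric vector of HO adsorption energies (eV), or a
#'   two-column matrix/data frame of (HO, O) pairs with `e_ads_o` missing.
#' @param e_ads_o numeric vector of O adsorption energies (eV).
#' @return an object of class `scaling_relation`.
#' @examples
#' fit_scaling_relation(c(0, 1), c(1, 3))   # exact two-point line
#' @export
fit_scaling_relation <- function(e_ads_ho, e_ads_o = NULL) {
  if (is.null(e_ads_o)) {
    m <- as.data.frame(e_ads_ho)
    if (ncol(m) < 2L) sod_abort("supply (e_ads_ho, e_ads_o) pairs")
    e_ads_o <- as.numeric(m[[2L]])
    e_ads_ho <- as.numeric(m[[1L]])
  }
  e_ads_ho <- as.numeric(e_ads_ho)
  e_ads_o <- as.numeric(e_ads_o)
  if (length(e_ads_ho) != length(e_ads_o)) {
    sod_abort("`e_ads_ho` and `e_ads_o` must have equal length")
  }
  ok <- is.finite(e_ads_ho) & is.finite(e_ads_o)
  if (any(!ok)) sod_abort("non-finite adsorption energies in fit input")
  if (length(e_ads_ho) < 2L || length(unique(e_ads_ho)) < 2L) {
    sod_abort("degenerate fit: need >= 2 points with distinct e_ads_ho",
              class = "sodscreen_degenerate_fit")
  }
  fit <- stats::lm(e_ads_o ~ e_ads_ho)
  cf <- stats::coef(fit)
  out <- scaling_relation(slope = unname(cf[2L]), intercept = unname(cf[1L]))
  out$n_points <- length(e_ads_ho)
  out$residual_rms <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' @export
print.scaling_relation <- function(x, ...) {
  cat(sprintf("Scaling relation: E_ads,O = %.4g * E_ads,HO + %.4g eV\n",
              x$slope, x$intercept))
  if (x$n_points > 0L) {
    cat(sprintf("  fitted on %d points, residual RMS %.3g eV\n",
                x$n_points, x$residual_rms))
  } else {
    cat("  (reference values, not fitted)\n")
  }
  invisible(x)
}

#' @export
coef.scaling_relation <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.scaling_relation <- function(object, e_ads_ho, ...) {
  o_from_oh(e_ads_ho, object)
}

#' Predict the O adsorption energy from the HO adsorption energy
#'
#' Evaluates the linear scaling relation at `e_ads_ho`.
#'
#' @param e_ads_ho HO adsorption energy (eV); vectorized.
#' @param relation a [scaling_relation()].
#' @return predicted O adsorption energy (eV).
#' @examples
#' o_from_oh(-2.7)   # 1.87 * (-2.7) + 1.42
#' @export
o_from_oh <- function(e_ads_ho, relation = scaling_relation()) {
  if (!is.numeric(e_ads_ho) || length(e_ads_ho) < 1L ||
      any(!is.finite(e_ads_ho))) {
    sod_abort("`e_ads_ho` must be finite")
  }
  stopifnot(inherits(relation, "scaling_relation"))
  relation$slope * e_ads_ho + relation$intercept
}
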