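# Two-state linear free energy model of formamide denaturation.
#
# Local equilibrium P + T = PT with the target as the limiting species gives
# the hybridization efficiency (fraction of locally available target bound)
#   E([FA]) = {P}o K / (1 + {P}o K),  K = exp(-(dG + m [FA]) / RT),
# a logistic that decreases sigmoidally with formamide concentration; the
# m-value is the linear free-energy cost per percent formamide (v/v).

#' Hybridization efficiency under formamide
#'
#' @param dg duplex standard free energy at 0% formamide, kcal/mol
#'   (vectorized).
#' @param fa formamide concentration, percent v/v (vectorized; recycled
#'   against `dg`).
#' @param params a `thermo_params` object.
#' @return efficiency in (0, 1), the fraction of locally available target
#'   bound by probe.
#' @examples
#' p <- synthetic_params()
#' hyb_efficiency(-7, c(0, 15, 30), p)
#' @export
hyb_efficiency <- function(dg, fa, params = default_params()) {
  if (any(fa < 0)) stop("formamide concentration must be >= 0", call. = FALSE)
  rt <- rt_of(params)
  # log-scale arithmetic keeps very stable duplexes finite
  logpk <- log(params$effective_probe_conc) - (dg + params$m_value * fa) / rt
  stats::plogis(logpk)
}

#' Predicted melting point (half-denaturation formamide concentration)
#'
#' The formamide concentration at which efficiency falls to half of its value
#' at 0% formamide. Solving the logistic gives the closed form
#' `[FA]1/2 = (RT/m) * log(2 + {P}o exp(-dG/RT))`, clamped at 0.
#'
#' @param dg duplex free energy at 0% formamide, kcal/mol (vectorized).
#' @param params a `thermo_params` object.
#' @return melting point in percent formamide (v/v).
#' @export
melting_point <- function(dg, params = default_params()) {
  rt <- rt_of(params)
  loga <- log(params$effective_probe_conc) - dg / rt
  # log(2 + a) computed stably for large a
  log2pa <- ifelse(loga > 35, loga, log(2 + exp(loga)))
  pmax(0, rt / params$m_value * log2pa)
}

#' Default 8-point formamide series (% v/v)
#' @return numeric vector `c(0, 5, 10, 15, 20, 25, 32.5, 45)`.
#' @export
fa_series_default <- function() c(0, 5, 10, 15, 20, 25, 32.5, 45)

#' Predicted melting curve for a probe/target duplex
#'
#' Composes the free-energy rules with the efficiency model: free energy of
#' the (minimized) conformation of the probe against its target site,
#' evaluated over a formamide series.
#'
#' @param probe_seq probe DNA sequence, 5'->3'.
#' @param target_site target site sequence, 5'->3' on the target gene sense
#'   strand (same length as the probe for substitution-only duplexes; may
#'   differ by one base for bulges). `NULL` means a perfect-match duplex.
#' @param fa_series formamide concentrations, ascending (% v/v).
#' @param params a `thermo_params` object.
#' @param minimize apply relaxed-end minimization (default TRUE).
#' @return a `melting_curve` data.frame with columns `fa` and `efficiency`,
#'   and attributes `dg`, `melting_point`, `extended`.
#' @export
predicted_curve <- function(probe_seq, target_site = NULL,
                            fa_series = fa_series_default(),
                            params = default_params(), minimize = TRUE) {
  if (is.unsorted(fa_series, strictly = TRUE)) {
    stop("fa_series must be strictly ascending", call. = FALSE)
  }
  extended <- FALSE
  if (is.null(target_site)) {
    dg <- dg_perfect(probe_seq, params)
  } else {
    conf <- align_probe_site(probe_seq, target_site)
    if (minimize) {
      conf <- minimize_conformation(conf, params)
      dg <- attr(conf, "dg"); extended <- isTRUE(attr(conf, "extended"))
    } else {
      dg <- dg_of_conformation(conf, params)
      extended <- isTRUE(attr(dg, "extended")); dg <- as.numeric(dg)
    }
  }
  out <- data.frame(fa = fa_series,
                    efficiency = hyb_efficiency(dg, fa_series, params))
  class(out) <- c("melting_curve", "data.frame")
  attr(out, "dg") <- as.numeric(dg)
  attr(out, "melting_point") <- melting_point(dg, params)
  attr(out, "extended") <- extended
  out
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> dG = %.3f kcal/mol, [FA]1/2 = %.2f%%%s\n",
              attr(x, "dg"), attr(x, "melting_point"),
              if (isTRUE(attr(x, "extended"))) " [extended rules]" else ""))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
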