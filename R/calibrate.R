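# Preprocessing of replicated intensity profiles over a formamide series and
# bi-level calibration of the melting model.
#
# Experimental profiles are normalized by the probe's maximum
# background-corrected signal (I_max) and matched to theoretical efficiency
# curves through a per-probe proportionality factor gamma:
#   I/I_max = gamma * E([FA]).
# The outer fit adjusts global model parameters (the m-value and the
# effective probe concentration, optionally free-energy terms) while the
# inner fit solves each gamma in closed form.

#' Preprocess raw replicate intensities
#'
#' Per probe and formamide point: a replicate more than three standard
#' deviations (of the remaining replicates) away from the mean of the
#' remaining replicates is eliminated; the mean of the nonsense-control
#' probes is then subtracted as background, with standard deviations combined
#' in quadrature.
#'
#' @param raw long data.frame with columns `probe`, `fa`, `intensity` (one
#'   row per replicate; pixel scale 0-65536).
#' @param nonsense name (or vector of names) of the background control
#'   probes.
#' @return data.frame of profiles: `probe`, `fa`, `mean`, `sd`, `n_used`,
#'   background-corrected, plus per-probe `i_max`; class
#'   `intensity_profiles`.
#' @export
preprocess_intensities <- function(raw, nonsense = "Nonsense") {
  stopifnot(all(c("probe", "fa", "intensity") %in% names(raw)))
  agg <- function(x) {
    keep <- outlier_filter(x)
    x <- x[keep]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0, n = length(x))
  }
  key <- paste(raw$probe, raw$fa, sep = "\r")  # \r cannot occur in names
  stats_m <- t(vapply(split(raw$intensity, key), agg, numeric(3)))
  ids <- do.call(rbind, strsplit(rownames(stats_m), "\r", fixed = TRUE))
  prof <- data.frame(probe = ids[, 1], fa = as.numeric(ids[, 2]),
                     mean = stats_m[, "mean"], sd = stats_m[, "sd"],
                     n_used = as.integer(stats_m[, "n"]),
                     stringsAsFactors = FALSE, row.names = NULL)
  is_bg <- prof$probe %in% nonsense
  bg <- prof[is_bg, , drop = FALSE]
  prof <- prof[!is_bg, , drop = FALSE]
  if (nrow(bg)) {
    bg_by_fa <- split(bg, bg$fa)
    bmean <- vapply(bg_by_fa, function(d) mean(d$mean), numeric(1))
    bsd <- vapply(bg_by_fa, function(d) sqrt(sum(d$sd^2)) / nrow(d), numeric(1))
    i <- match(as.character(prof$fa), names(bmean))
    prof$mean <- prof$mean - bmean[i]
    prof$sd <- sqrt(prof$sd^2 + bsd[i]^2)
  }
  prof <- prof[order(prof$probe, prof$fa), , drop = FALSE]
  imax <- tapply(prof$mean, prof$probe, max)
  prof$i_max <- as.numeric(imax[prof$probe])
  rownames(prof) <- NULL
  class(prof) <- c("intensity_profiles", "data.frame")
  prof
}

#' Replicate outlier test
#'
#' @param x numeric replicate values at one probe/formamide point.
#' @return logical keep-mask: FALSE for any replicate more than 3 standard
#'   deviations of the remaining replicates away from their mean (at least
#'   two replicates are always kept).
#' @export
outlier_filter <- function(x) {
  n <- length(x)
  if (n < 3) return(rep(TRUE, n))
  dev <- vapply(seq_len(n), function(i) {
    rest <- x[-i]
    s <- stats::sd(rest)
    if (s == 0) return(if (x[i] == rest[1]) 0 else Inf)
    abs(x[i] - mean(rest)) / s
  }, numeric(1))
  keep <- dev <= 3
  if (sum(keep) < 2) {  # never discard below two replicates
    keep <- rep(TRUE, n); keep[which.max(dev)] <- FALSE
  }
  keep
}

#' Filter probes by signal level and first-increment drop
#'
#' Removes probes whose signal is too close to background to constrain the
#' fit: perfect-match probes with `i_max < 1000` a.u., mismatched probes with
#' `i_max < 500` a.u., and mismatched probes whose signal drops by more than
#' 50% over the first increment of the formamide series (0% to 5%).
#'
#' @param profiles an `intensity_profiles` data.frame.
#' @param classes named character vector probe -> `"perfect"` or
#'   `"mismatched"`.
#' @return the retained rows of `profiles`.
#' @export
filter_probes <- function(profiles, classes) {
  keep_probe <- vapply(split(profiles, profiles$probe), function(d) {
    cls <- classes[[d$probe[1]]]
    imax <- d$i_max[1]
    if (identical(cls, "perfect")) return(imax >= 1000)
    if (imax < 500) return(FALSE)
    i0 <- d$mean[d$fa == 0]; i5 <- d$mean[d$fa == 5]
    if (length(i0) == 1 && length(i5) == 1 && i0 > 0 &&
        (i0 - i5) / i0 > 0.5) return(FALSE)
    TRUE
  }, logical(1))
  profiles[profiles$probe %in% names(keep_probe)[keep_probe], , drop = FALSE]
}

#' Mask points left of the plateau
#'
#' Signal at formamide concentrations below the profile maximum that is less
#' than 80% of `i_max` reflects kinetic limitation, not equilibrium melting,
#' and is excluded from fitting.
#'
#' @param fa formamide points (ascending).
#' @param intensity background-corrected means at those points.
#' @return logical keep-mask over the points.
#' @export
trim_left_of_plateau <- function(fa, intensity) {
  stopifnot(length(fa) == length(intensity))
  imax_at <- which.max(intensity)
  keep <- rep(TRUE, length(fa))
  left <- seq_along(fa) < imax_at
  keep[left & intensity < 0.8 * intensity[imax_at]] <- FALSE
  keep
}

#' Experimental half-denaturation point
#'
#' Linear interpolation between the two subsequent points (at or after the
#' profile maximum) that bracket half of the maximum signal.
#'
#' @param fa formamide points (ascending).
#' @param intensity signal at those points (any scale).
#' @return formamide concentration of half-denaturation, or `NA` when the
#'   profile never crosses half of its maximum.
#' @export
fa_half_exp <- function(fa, intensity) {
  stopifnot(length(fa) == length(intensity))
  imax_at <- which.max(intensity)
  half <- intensity[imax_at] / 2
  if (imax_at < length(fa)) {
    for (j in imax_at:(length(fa) - 1L)) {
      if (intensity[j] > half && intensity[j + 1L] <= half) {
        return(fa[j] + (fa[j + 1L] - fa[j]) *
                 (intensity[j] - half) / (intensity[j] - intensity[j + 1L]))
      }
    }
  }
  NA_real_
}

#' Gamma factors under the three alignment policies
#'
#' @param y normalized intensities of one probe (I / I_max).
#' @param eff theoretical efficiencies at the same formamide points.
#' @param mode `"fitted"` (closed-form least squares of `y ~ gamma * eff`),
#'   `"unity"` (gamma = 1), or `"inverse_max_eff"` (gamma = 1 / efficiency at
#'   the first, lowest-formamide point, so the theoretical curve starts at 1).
#' @return scalar gamma.
#' @export
gamma_factor <- function(y, eff, mode = c("fitted", "unity", "inverse_max_eff")) {
  mode <- match.arg(mode)
  switch(mode,
         fitted = sum(eff * y) / sum(eff^2),
         unity = 1,
         inverse_max_eff = 1 / eff[1])
}

#' Fit statistics of the calibrated model
#'
#' @param ssr residual sum of squares.
#' @param y fitted data values (for the total sum of squares), or `NULL` to
#'   skip the coefficient of determination.
#' @param n number of fitted formamide data points.
#' @param n_probes number of probes contributing a gamma factor.
#' @param n_global number of global fitted parameters.
#' @return list with `n`, `nu` (degrees of freedom `n - (n_probes +
#'   n_global)`), `mean_sq_resid` (`ssr/n`), `s2` (`ssr/nu`), and `r2`.
#' @export
fit_statistics <- function(ssr, y = NULL, n, n_probes, n_global) {
  nu <- n - (n_probes + n_global)
  list(n = n, nu = nu,
       mean_sq_resid = ssr / n,
       s2 = ssr / nu,
       r2 = if (is.null(y)) NA_real_ else 1 - ssr / sum((y - mean(y))^2))
}

#' Bi-level calibration of the melting model
#'
#' Outer derivative-free least squares over the global parameters (the
#' m-value and log10 of the effective probe concentration by default); for
#' every outer iterate the probe-specific gamma factors are solved in closed
#' form. Deterministic given the starting point.
#'
#' @param profiles data.frame with columns `probe`, `fa`, `y` (normalized
#'   intensity I / I_max; pre-masked points simply absent).
#' @param dg named numeric: duplex free energy per probe (kcal/mol at 0%
#'   formamide), fixed during the fit.
#' @param params a `thermo_params` object supplying constants and start
#'   values.
#' @param free character vector of global parameters to fit, from
#'   `c("m", "log10_po")`.
#' @param gamma_mode gamma policy, see [gamma_factor()].
#' @param start named numeric start point (defaults `m = 0.2`,
#'   `log10_po = -2`).
#' @param validation_fraction fraction of probes held out of the outer fit
#'   for validation (0 = none).
#' @param seed integer seed for the validation split (recorded in the
#'   result).
#' @param reltol relative convergence tolerance on the cost (default 1e-8).
#' @param maxit maximum outer iterations (default 500 per parameter set).
#' @return object of class `lfem_fit`: list with `global` (fitted parameter
#'   values), `params` (updated `thermo_params`), `gammas`, `stats` (see
#'   [fit_statistics()]), `eps2_val`, `eps2_ov`, `err_fa_half` (data.frame
#'   per probe: predicted, experimental, signed and absolute error),
#'   `n_fit_probes`, `n_total_probes`, `seed`, `convergence`.
#' @export
bilevel_fit <- function(profiles, dg, params = default_params(),
                        free = c("m", "log10_po"),
                        gamma_mode = "fitted",
                        start = c(m = 0.2, log10_po = -2),
                        validation_fraction = 0, seed = 1L,
                        reltol = 1e-8, maxit = 500L) {
  stopifnot(all(c("probe", "fa", "y") %in% names(profiles)))
  free <- match.arg(free, c("m", "log10_po"), several.ok = TRUE)
  probes_all <- unique(profiles$probe)
  miss <- setdiff(probes_all, names(dg))
  if (length(miss)) stop("no free energy supplied for probes: ",
                         paste(utils::head(miss, 3), collapse = ","), call. = FALSE)
  set.seed(seed)
  n_val <- floor(validation_fraction * length(probes_all))
  val_probes <- if (n_val > 0) sample(probes_all, n_val) else character(0)
  fit_probes <- setdiff(probes_all, val_probes)

  apply_theta <- function(theta, p) {
    if ("m" %in% names(theta)) p$m_value <- unname(theta[["m"]])
    if ("log10_po" %in% names(theta)) p$effective_probe_conc <- 10^unname(theta[["log10_po"]])
    p
  }
  sub_fit <- profiles[profiles$probe %in% fit_probes, , drop = FALSE]
  idx_fit <- split(seq_len(nrow(sub_fit)), sub_fit$probe)

  residuals_of <- function(theta, sub, idx) {
    p <- apply_theta(theta, params)
    eff <- hyb_efficiency(dg[sub$probe], sub$fa, p)
    r <- numeric(nrow(sub))
    gam <- numeric(length(idx)); names(gam) <- names(idx)
    for (pr in names(idx)) {
      i <- idx[[pr]]
      g <- gamma_factor(sub$y[i], eff[i], gamma_mode)
      gam[[pr]] <- g
      r[i] <- sub$y[i] - g * eff[i]
    }
    list(r = r, gammas = gam)
  }
  obj <- function(th) {
    names(th) <- free
    sum(residuals_of(th, sub_fit, idx_fit)$r^2)
  }
  start <- start[free]
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit * length(free)))
  if (opt$convergence != 0) {
    stop("bilevel_fit failed to converge (code ", opt$convergence,
         "); last iterate: ", paste(sprintf("%s=%.5g", free, opt$par), collapse = ", "),
         call. = FALSE)
  }
  theta <- stats::setNames(opt$par, free)
  fitted_params <- apply_theta(theta, params)
  res <- residuals_of(theta, sub_fit, idx_fit)
  ssr <- sum(res$r^2)
  st <- fit_statistics(ssr, y = sub_fit$y, n = nrow(sub_fit),
                       n_probes = length(fit_probes), n_global = length(free))

  # prediction errors on validation and overall sets (gammas re-solved per
  # probe, globals fixed)
  pred_eps2 <- function(probe_set) {
    if (!length(probe_set)) return(NA_real_)
    sub <- profiles[profiles$probe %in% probe_set, , drop = FALSE]
    idx <- split(seq_len(nrow(sub)), sub$probe)
    mean(residuals_of(theta, sub, idx)$r^2)
  }
  eps2_val <- pred_eps2(val_probes)
  eps2_ov <- pred_eps2(probes_all)

  # half-denaturation point errors, all probes
  err <- do.call(rbind, lapply(split(profiles, profiles$probe), function(d) {
    pred <- melting_point(dg[[d$probe[1]]], fitted_params)
    exp_ <- fa_half_exp(d$fa, d$y)
    data.frame(probe = d$probe[1], fa_half_pred = pred, fa_half_exp = exp_,
               err = pred - exp_, abs_err = abs(pred - exp_),
               stringsAsFactors = FALSE)
  }))
  rownames(err) <- NULL

  all_idx <- split(seq_len(nrow(profiles)), profiles$probe)
  gam_all <- residuals_of(theta, profiles, all_idx)$gammas

  structure(list(
    global = theta, params = fitted_params, gammas = gam_all,
    stats = st, eps2_val = eps2_val, eps2_ov = eps2_ov,
    err_fa_half = err,
    n_fit_probes = length(fit_probes), n_total_probes = length(probes_all),
    gamma_mode = gamma_mode, seed = seed, convergence = opt$convergence
  ), class = "lfem_fit")
}

#' @export
print.lfem_fit <- function(x, ...) {
  cat("<lfem_fit>\n")
  cat("  globals:", paste(sprintf("%s = %.5g", names(x$global), x$global),
                          collapse = ", "), "\n")
  cat(sprintf("  N_F/N_T = %d/%d, n = %d, nu = %d\n",
              x$n_fit_probes, x$n_total_probes, x$stats$n, x$stats$nu))
  cat(sprintf("  sum r^2/n = %.4g, s^2 = %.4g, R^2 = %.3f\n",
              x$stats$mean_sq_resid, x$stats$s2, x$stats$r2))
  mu <- mean(x$err_fa_half$abs_err, na.rm = TRUE)
  lt5 <- mean(x$err_fa_half$abs_err < 5, na.rm = TRUE)
  cat(sprintf("  |err[FA]1/2|: mean %.2f%% FA, %.1f%% of probes < 5%%\n",
              mu, 100 * lt5))
  invisible(x)
}

#' Normalize profiles by their maximum signal
#'
#' @param profiles an `intensity_profiles` data.frame (from
#'   [preprocess_intensities()]).
#' @param trim apply [trim_left_of_plateau()] per probe (default TRUE).
#' @return data.frame `probe`, `fa`, `y` suitable for [bilevel_fit()].
#' @export
normalize_profiles <- function(profiles, trim = TRUE) {
  out <- do.call(rbind, lapply(split(profiles, profiles$probe), function(d) {
    d <- d[order(d$fa), , drop = FALSE]
    keep <- if (trim) trim_left_of_plateau(d$fa, d$mean) else rep(TRUE, nrow(d))
    data.frame(probe = d$probe[keep], fa = d$fa[keep],
               y = d$mean[keep] / d$i_max[keep], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
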