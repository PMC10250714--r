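#' Serial dilution series
#'
#' The plate design used throughout the binding assays: a starting
#' concentration serially diluted `factor`-fold, `n_points - 1` times.
#'
#' @param start_conc Starting concentration in molar (> 0).
#' @param factor Fold dilution per step (> 1).
#' @param n_points Number of concentrations (>= 2).
#' @return Object of class `dilution_series` with fields `start_conc`,
#'   `factor`, `n_points` and `concentrations` (strictly descending, M).
#' @examples
#' ds <- make_dilution_series(2.7e-4, 3, 18)
#' min(ds$concentrations)  # about 2.1e-12 M
#' @export
make_dilution_series <- function(start_conc, factor, n_points) {
  if (!(is.numeric(start_conc) && start_conc > 0))
    stop("start_conc must be positive")
  if (!(is.numeric(factor) && factor > 1)) stop("factor must exceed 1")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop("n_points must be at least 2")
  structure(list(start_conc = start_conc, factor = factor,
                 n_points = n_points,
                 concentrations = start_conc / factor^(seq_len(n_points) - 1)),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("<dilution series> ", x$n_points, " points, ",
      format(x$start_conc, digits = 3), " M / ", x$factor, "-fold -> ",
      format(min(x$concentrations), digits = 3), " M\n", sep = "")
  invisible(x)
}

#' One-site total binding model
#'
#' Saturation binding signal as the sum of a specific one-site hyperbola,
#' a linear nonspecific component, and a constant background:
#' `bmax * conc / (kd + conc) + ns_slope * conc + background`.
#'
#' @param conc Ligand concentration(s), M (>= 0).
#' @param kd Equilibrium dissociation constant, M (> 0).
#' @param bmax Maximal specific signal.
#' @param ns_slope Nonspecific signal per molar (default 0).
#' @param background Signal at zero ligand (default 0).
#' @return Model signal, same length as `conc`.
#' @examples
#' saturation_model(1e-7, kd = 1e-7, bmax = 100)  # half-saturation: 50
#' @export
saturation_model <- function(conc, kd, bmax, ns_slope = 0, background = 0) {
  stopifnot(all(conc >= 0), kd > 0)
  bmax * conc / (kd + conc) + ns_slope * conc + background
}

#' One-site competitive displacement model
#'
#' Displacement of a labeled ("hot") ligand by an unlabeled competitor,
#' as a logistic in log10 concentration with unit slope and the midpoint
#' tied to the inhibition constant through the Cheng-Prusoff correction
#' `IC50 = Ki * (1 + hot_conc / hot_kd)`:
#' `bottom + (top - bottom) / (1 + 10^(log10_conc - log10(IC50)))`.
#'
#' @param log10_conc log10 competitor concentration(s) (conc in M).
#' @param ki Inhibition constant, M (> 0).
#' @param top,bottom Plateau signals at zero and saturating competitor.
#' @param hot_conc Labeled-ligand concentration, M (> 0).
#' @param hot_kd Labeled-ligand dissociation constant, M (> 0).
#' @return Model signal, same length as `log10_conc`.
#' @export
competition_model <- function(log10_conc, ki, top, bottom, hot_conc,
                              hot_kd) {
  stopifnot(ki > 0, hot_conc > 0, hot_kd > 0)
  ic50 <- ki * (1 + hot_conc / hot_kd)
  bottom + (top - bottom) / (1 + 10^(log10_conc - log10(ic50)))
}

check_observations <- function(obs, min_conc = 5L) {
  stopifnot(all(c("conc", "signal") %in% names(obs)))
  if (any(obs$conc <= 0)) stop("concentrations must be positive")
  if (length(unique(obs$conc)) < min_conc)
    stop("at least ", min_conc, " distinct concentrations are required")
  if (!("replicate" %in% names(obs))) obs$replicate <- 1L
  obs
}

fit_ci95 <- function(est, se, df) {
  tq <- stats::qt(0.975, df)
  cbind(low = est - tq * se, high = est + tq * se)
}

# Levenberg-Marquardt least squares on a residual function, with the
# asymptotic covariance sigma^2 (J'J)^-1 at the solution
lm_least_squares <- function(par0, resid_fun, label) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(label, " fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  if (out$info < 1 || out$info > 4)
    stop(label, " fit did not converge (", out$message,
         "); final residual ", format(out$deviance, digits = 4),
         call. = FALSE)
  p <- length(out$par)
  dfree <- length(out$fvec) - p
  resvar <- out$deviance / dfree
  vc <- tryCatch(chol2inv(chol(out$hessian)) * resvar,
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(names(out$par), names(out$par))
  list(par = unlist(out$par), se = sqrt(diag(vc)), vcov = vc,
       rss = out$deviance, df = dfree, optim = out)
}

#' Fit the one-site total binding model
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' [saturation_model()] to a saturation series. Kd is estimated on the
#' log10 scale to enforce positivity; replicates are pooled into one
#' residual vector. Starting values come from the data (background from
#' the low-concentration signal, Bmax from the dynamic range, Kd from the
#' concentration nearest half-range). 95% confidence intervals are
#' asymptotic (t quantile on the parameter standard errors; Kd's interval
#' is back-transformed from the log scale).
#'
#' @param obs data.frame with columns `conc` (M), `signal`, and
#'   optionally `replicate`; at least 5 distinct concentrations.
#' @return Object of class `saturation_fit`: `kd`, `bmax`, `ns_slope`,
#'   `background`, `ci95` (matrix, rows kd/bmax/ns_slope/background),
#'   `rss`, `fit` (the underlying `nls` object).
#' @export
fit_saturation <- function(obs) {
  obs <- check_observations(obs)
  sig <- obs$signal; conc <- obs$conc
  rng <- max(sig) - min(sig)
  if (rng <= 0) stop("constant signal; nothing to fit")
  bg0 <- min(sig)
  bmax0 <- max(rng, 1e-12)
  half <- bg0 + bmax0 / 2
  kd0 <- conc[which.min(abs(sig - half))]
  # the nonspecific slope is fitted per fraction of the top concentration
  # so its gradient column is on the same scale as the other parameters
  cmax <- max(conc)
  res <- lm_least_squares(
    list(lkd = log10(kd0), bmax = bmax0, nss = 0, bg = bg0),
    function(par) sig - (par$bmax * conc / (10^par$lkd + conc) +
                           par$nss * (conc / cmax) + par$bg),
    label = "saturation")
  cf <- res$par
  ci_l <- fit_ci95(cf, res$se, res$df)
  ci <- rbind(kd = 10^ci_l["lkd", ],
              bmax = ci_l["bmax", ],
              ns_slope = ci_l["nss", ] / cmax,
              background = ci_l["bg", ])
  structure(list(kd = unname(10^cf["lkd"]), bmax = unname(cf["bmax"]),
                 ns_slope = unname(cf["nss"]) / cmax,
                 background = unname(cf["bg"]),
                 ci95 = ci, rss = res$rss, fit = res$optim),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<one-site total binding fit>\n",
      "  Kd  = ", format(x$kd, digits = 3), " M  (95% CI ",
      format(x$ci95["kd", "low"], digits = 3), " - ",
      format(x$ci95["kd", "high"], digits = 3), ")\n",
      "  Bmax = ", format(x$bmax, digits = 4),
      ", ns slope = ", format(x$ns_slope, digits = 3),
      ", background = ", format(x$background, digits = 4),
      ", RSS = ", format(x$rss, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Fit the one-site competition model and derive Ki
#'
#' Least-squares fit of [competition_model()] to a displacement series,
#' with Ki estimated in log10 space and the IC50 tied to Ki by the
#' Cheng-Prusoff correction for the known labeled-ligand concentration
#' and affinity. Replicates are pooled. Data showing no displacement
#' (the fitted span not distinguishable from zero) raise an error.
#'
#' @param obs data.frame with `conc` (M), `signal`, optionally
#'   `replicate`; at least 5 distinct concentrations spanning the
#'   transition.
#' @param hot_conc Labeled-ligand concentration, M.
#' @param hot_kd Labeled-ligand Kd, M.
#' @return Object of class `competition_fit`: `ki`, `ic50`, `top`,
#'   `bottom`, `hot_conc`, `hot_kd`, `ci95` (rows ki/ic50/top/bottom),
#'   `rss`, `fit`.
#' @export
fit_competition <- function(obs, hot_conc, hot_kd) {
  stopifnot(hot_conc > 0, hot_kd > 0)
  obs <- check_observations(obs)
  lc <- log10(obs$conc); sig <- obs$signal
  cp <- 1 + hot_conc / hot_kd
  lo3 <- utils::head(unique(sort(obs$conc)), 3)
  hi3 <- utils::tail(unique(sort(obs$conc)), 3)
  top0 <- mean(sig[obs$conc %in% lo3])
  bot0 <- mean(sig[obs$conc %in% hi3])
  if (abs(top0 - bot0) < .Machine$double.eps * 100) top0 <- bot0 + 1e-6
  mid <- (top0 + bot0) / 2
  lic50_0 <- lc[which.min(abs(sig - mid))]
  res <- tryCatch(
    lm_least_squares(
      list(lki = lic50_0 - log10(cp), top = top0, bottom = bot0),
      function(par) sig - (par$bottom + (par$top - par$bottom) /
                             (1 + 10^(lc - (par$lki + log10(cp))))),
      label = "competition"),
    error = function(e) stop("no displacement detected (",
                             conditionMessage(e), ")", call. = FALSE))
  cf <- res$par
  vc <- res$vcov
  span <- cf["top"] - cf["bottom"]
  se_span <- sqrt(vc["top", "top"] + vc["bottom", "bottom"] -
                    2 * vc["top", "bottom"])
  displaced <- is.finite(se_span) && se_span >= 0 && span > 0 &&
    (se_span == 0 || 2 * stats::pt(-abs(span / se_span), res$df) <= 0.05)
  if (!displaced) stop("no displacement detected")
  ci_l <- fit_ci95(cf, res$se, res$df)
  ki <- unname(10^cf["lki"])
  ci <- rbind(ki = 10^ci_l["lki", ],
              ic50 = 10^ci_l["lki", ] * cp,
              top = ci_l["top", ],
              bottom = ci_l["bottom", ])
  structure(list(ki = ki, ic50 = ki * cp, top = unname(cf["top"]),
                 bottom = unname(cf["bottom"]), hot_conc = hot_conc,
                 hot_kd = hot_kd, ci95 = ci,
                 rss = res$rss, fit = res$optim),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("<one-site competition fit (Cheng-Prusoff)>\n",
      "  Ki   = ", format(x$ki, digits = 3), " M  (95% CI ",
      format(x$ci95["ki", "low"], digits = 3), " - ",
      format(x$ci95["ki", "high"], digits = 3), ")\n",
      "  IC50 = ", format(x$ic50, digits = 3),
      " M, top = ", format(x$top, digits = 4),
      ", bottom = ", format(x$bottom, digits = 4),
      ", RSS = ", format(x$rss, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Normalize millipolarization readings to a 0-100 scale
#'
#' Rescales each replicate series linearly onto 0-100. With
#' `method = "extremes"` (default) the observed per-series minimum maps
#' to 0 and the maximum to 100. With `method = "fitted"` a free logistic
#' in log10 concentration (top, bottom, midpoint) is fitted per series
#' and its plateau estimates define 0 and 100, which is robust to noise
#' at the extremes but assumes a sigmoid series.
#'
#' @param obs data.frame with `conc`, `signal`, optionally `replicate`.
#' @param method `"extremes"` or `"fitted"`.
#' @return The same data.frame with `signal` rescaled per replicate.
#' @examples
#' normalize_mp(data.frame(conc = c(1, 2, 3), signal = c(10, 20, 30)))
#' @export
normalize_mp <- function(obs, method = c("extremes", "fitted")) {
  method <- match.arg(method)
  obs <- check_observations(obs, min_conc = 2L)
  for (r in unique(obs$replicate)) {
    idx <- obs$replicate == r
    x <- obs$signal[idx]
    rng <- max(x) - min(x)
    if (rng == 0) stop("constant signal in replicate ", r,
                       "; cannot normalize")
    if (method == "extremes") {
      obs$signal[idx] <- (x - min(x)) / rng * 100
    } else {
      lc <- log10(obs$conc[idx])
      res <- lm_least_squares(
        list(top = max(x), bottom = min(x), lmid = stats::median(lc)),
        function(par) x - (par$bottom + (par$top - par$bottom) /
                             (1 + 10^(lc - par$lmid))),
        label = "normalization")
      span <- res$par["top"] - res$par["bottom"]
      if (!is.finite(span) || span == 0)
        stop("fitted plateaus are degenerate in replicate ", r)
      obs$signal[idx] <- (x - res$par["bottom"]) / span * 100
    }
  }
  obs
}
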