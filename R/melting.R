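#' Boltzmann sigmoid survival curves
#'
#' `boltzmann_curve()` is the standard four-parameter sigmoid
#' S(T) = S_bottom + (S_top - S_bottom) / (1 + exp((T - T_half)/w));
#' `double_boltzmann_curve()` mixes two transitions with fraction `phi`:
#' S(T) = S_bottom + (S_top - S_bottom) * \[phi/(1 + exp((T - T1)/w1)) +
#' (1 - phi)/(1 + exp((T - T2)/w2))\].
#'
#' @param T temperature(s) in degC.
#' @param S_top,S_bottom plateau values (`S_bottom <= S_top`).
#' @param T_half,w midpoint and width of the transition.
#' @param T1,w1,T2,w2,phi per-transition midpoints/widths and mixing
#'   fraction.
#' @return survival value(s).
#' @export
boltzmann_curve <- function(T, S_top, S_bottom, T_half, w) {
  S_bottom + (S_top - S_bottom) / (1 + exp((T - T_half) / w))
}

#' @rdname boltzmann_curve
#' @export
double_boltzmann_curve <- function(T, S_top, S_bottom, T1, w1, T2, w2, phi) {
  S_bottom + (S_top - S_bottom) *
    (phi / (1 + exp((T - T1) / w1)) + (1 - phi) / (1 + exp((T - T2) / w2)))
}

#' Target-band mass and assembly yield from a standard band
#'
#' Deduces the target band's mass from the linear intensity-mass correlation
#' set by a standard band of known mass (e.g. the 1500-bp band of a 1-kb
#' ladder): `mass = intensity_target * known_mass / intensity_standard`.
#'
#' @param bands a band table (see [gen_band_table()]) with exactly one
#'   `role == "standard"` row carrying `known_mass`.
#' @param lane,band lane and band id of the target.
#' @param input_mass optional loaded input mass (ng); if given, the yield
#'   `mass/input_mass` is returned as well.
#' @return list with `mass` (ng) and `yield` (or `NA` without `input_mass`).
#' @export
yield_from_standard <- function(bands, lane, band, input_mass = NULL) {
  std <- bands[bands$role == "standard", , drop = FALSE]
  if (nrow(std) != 1L || is.na(std$known_mass) || std$known_mass <= 0) {
    stop("band table must contain exactly one standard band with known_mass > 0",
         call. = FALSE)
  }
  if (std$intensity == 0) {
    stop("computation error: standard band intensity is zero", call. = FALSE)
  }
  tg <- bands[bands$lane == lane & bands$band == band, , drop = FALSE]
  if (nrow(tg) != 1L) stop("target band not found (or not unique)", call. = FALSE)
  mass <- tg$intensity * std$known_mass / std$intensity
  list(mass = mass,
       yield = if (is.null(input_mass)) NA_real_ else mass / input_mass)
}

#' Survival rates from a band table
#'
#' Normalizes each target band's intensity by the matching replicate's
#' control band (the untreated 4 degC sample): S = intensity / control.
#' Values can exceed 1 through gel noise and are deliberately not clipped.
#'
#' @param bands a survival-mode band table (see [gen_survival_band_table()]):
#'   `role` is `"target"` or `"control"`, with columns `temperature_C` and
#'   `replicate`.
#' @return a `survival_dataset` data frame (`temperature_C`, `replicate`,
#'   `survival`).
#' @export
survival_rates <- function(bands) {
  ctrl <- bands[bands$role == "control", , drop = FALSE]
  tgt <- bands[bands$role == "target", , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no control band(s) in table", call. = FALSE)
  if (any(ctrl$intensity == 0)) {
    stop("computation error: control band intensity is zero", call. = FALSE)
  }
  cint <- ctrl$intensity[match(tgt$replicate, ctrl$replicate)]
  if (anyNA(cint)) stop("missing control band for some replicate", call. = FALSE)
  out <- data.frame(temperature_C = tgt$temperature_C,
                    replicate = tgt$replicate,
                    survival = tgt$intensity / cint)
  class(out) <- c("survival_dataset", "data.frame")
  out
}

# shared initializer pieces (documented defaults: plateaus from the replicate
# means, midpoint at the temperature nearest the 0.5 crossing of the means,
# width = span/10)
melt_init <- function(data) {
  Tm_ <- sort(unique(data$temperature_C))
  mu <- tapply(data$survival, data$temperature_C, mean)[as.character(Tm_)]
  S_top <- max(mu); S_bot <- min(mu)
  cross <- which.min(abs(mu - 0.5))
  list(T = Tm_, mu = as.numeric(mu),
       S_top = S_top, S_bot = S_bot,
       T_half = Tm_[cross], w = (max(Tm_) - min(Tm_)) / 10)
}

#' Fit a Boltzmann sigmoid melting curve
#'
#' Unweighted least-squares fit of the four-parameter Boltzmann sigmoid to
#' raw replicate survival points (means are for display only). The melting
#' temperature Tm is defined as the incubation temperature at which the
#' *fitted* curve crosses survival 0.5 — not the inflection parameter: the
#' two differ whenever the plateaus are not exactly \{0, 1\}.
#'
#' @param data a `survival_dataset` (columns `temperature_C`, `replicate`,
#'   `survival`) with at least 4 distinct temperatures.
#' @return an object of class `melt_fit`: list with `model = "single"`,
#'   `par` (S_top, S_bottom, T_half, w), `Tm`, `rss`, `n`, `aic`,
#'   `converged`, and `curve(T)`.
#' @export
fit_boltzmann <- function(data) {
  check_survival_data(data, min_temps = 4L)
  init <- melt_init(data)
  df <- data.frame(T = data$temperature_C, S = data$survival)
  fit <- minpack.lm::nlsLM(
    S ~ S_bot + (S_top - S_bot) / (1 + exp((T - T_half) / w)),
    data = df,
    start = list(S_top = init$S_top, S_bot = init$S_bot,
                 T_half = init$T_half, w = max(init$w, 0.5)),
    lower = c(S_top = -Inf, S_bot = -Inf, T_half = -Inf, w = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- as.list(stats::coef(fit))
  if (p$S_bot > p$S_top) {  # enforce the plateau ordering convention
    stop("fit error: inverted plateaus (S_bottom > S_top); data may not be ",
         "sigmoidal in the fitted orientation", call. = FALSE)
  }
  Tm <- boltzmann_tm(p$S_top, p$S_bot, p$T_half, p$w)
  rss <- sum(stats::resid(fit)^2)
  n <- nrow(df)
  structure(list(model = "single",
                 par = c(S_top = p$S_top, S_bottom = p$S_bot,
                         T_half = p$T_half, w = p$w),
                 Tm = Tm, rss = rss, n = n,
                 aic = melt_aic(rss, n, 4L),
                 converged = fit$convInfo$isConv %||% TRUE,
                 curve = function(T) boltzmann_curve(T, p$S_top, p$S_bot,
                                                     p$T_half, p$w)),
            class = "melt_fit")
}

# closed-form 0.5 crossing of the single sigmoid
boltzmann_tm <- function(S_top, S_bot, T_half, w) {
  if (!(S_bot < 0.5 && S_top > 0.5)) {
    stop("Tm undefined error: fitted curve never crosses survival 0.5",
         call. = FALSE)
  }
  T_half + w * log((S_top - 0.5) / (0.5 - S_bot))
}

melt_aic <- function(rss, n, k) n * log(rss / n + 1e-300) + 2 * k

check_survival_data <- function(data, min_temps) {
  need <- c("temperature_C", "replicate", "survival")
  if (!all(need %in% names(data))) {
    stop("survival data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nt <- length(unique(data$temperature_C))
  if (nt < min_temps) {
    stop("at least ", min_temps, " distinct temperatures required (got ",
         nt, ")", call. = FALSE)
  }
  if (stats::sd(data$survival) == 0) {
    stop("fit error: survival data are constant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a double-Boltzmann (two-stage) melting curve
#'
#' Least-squares fit of a two-transition sigmoid mixture (see
#' [double_boltzmann_curve()]); used when short stem domains melt in a first
#' stage well below the root-domain melting (as in unligated lattices pairing
#' 6-bp stems against 13-bp roots). The ordering T1 < T2 is
#' enforced by fitting the gap dT = T2 - T1 >= 0. Tm is the survival-0.5
#' crossing of the combined fitted curve. Model preference relative to the
#' single fit is advisory, via the residual-based AIC in `aic`; selection is
#' never automatic.
#'
#' The initializer seeds T1/T2 at the two steepest descent points of the
#' smoothed mean curve.
#'
#' @param data a `survival_dataset` with at least 6 distinct temperatures.
#' @return a `melt_fit` with `model = "double"` and parameters S_top,
#'   S_bottom, T1, w1, T2, w2, phi.
#' @export
fit_double_boltzmann <- function(data) {
  check_survival_data(data, min_temps = 6L)
  init <- melt_init(data)
  # smoothed mean-curve slopes; the two steepest descents seed T1/T2
  mu <- init$mu
  if (length(mu) >= 3) {
    mu_s <- stats::filter(mu, rep(1 / 3, 3), sides = 2)
    mu_s[is.na(mu_s)] <- mu[is.na(mu_s)]
  } else mu_s <- mu
  slope <- as.numeric(diff(mu_s)) / diff(init$T)
  mids <- (init$T[-1] + init$T[-length(init$T)]) / 2
  span <- max(init$T) - min(init$T)
  first <- mids[which.min(slope)]
  # steepest-pair seed: second steepest descent at least span/5 away, so the
  # two sigmoids start on distinct transitions
  far <- abs(mids - first) >= span / 5
  second <- if (any(far)) mids[far][which.min(slope[far])] else
    first + span / 4
  # level-crossing seed: transitions bracket the upper/lower quartile levels
  lvl <- function(q) init$T[which.min(abs(init$mu - (init$S_bot +
    q * (init$S_top - init$S_bot))))]
  starts <- list(
    c(T1 = min(first, second), T2 = max(first, second)),
    c(T1 = min(lvl(0.75), lvl(0.25) - 1), T2 = lvl(0.25)),
    c(T1 = init$T_half - span / 6, T2 = init$T_half + span / 6))
  Tv <- data$temperature_C
  Sv <- data$survival
  resid_fn <- function(par) {
    Sv - (par[["S_bot"]] + (par[["S_top"]] - par[["S_bot"]]) *
            (par[["phi"]] / (1 + exp((Tv - par[["T1"]]) / par[["w1"]])) +
             (1 - par[["phi"]]) /
               (1 + exp((Tv - (par[["T1"]] + par[["dT"]])) / par[["w2"]]))))
  }
  lower <- c(S_top = -Inf, S_bot = -Inf, T1 = -Inf, dT = 0,
             w1 = 1e-3, w2 = 1e-3, phi = 0)
  upper <- c(S_top = Inf, S_bot = Inf, T1 = Inf, dT = Inf,
             w1 = Inf, w2 = Inf, phi = 1)
  best <- NULL
  for (s0 in starts) for (w0 in c(max(init$w / 2, 0.5), 1.5)) {
    par0 <- c(S_top = init$S_top, S_bot = init$S_bot,
              T1 = s0[["T1"]], dT = max(s0[["T2"]] - s0[["T1"]], 1),
              w1 = w0, w2 = w0, phi = 0.5)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("fit error: double-Boltzmann fit failed from every initialization",
         call. = FALSE)
  }
  fit <- best
  p <- as.list(stats::coef(fit))
  p$T2 <- p$T1 + p$dT
  curve <- function(T) double_boltzmann_curve(T, p$S_top, p$S_bot,
                                              p$T1, p$w1, p$T2, p$w2, p$phi)
  Tm <- melt_tm_root(curve, range(data$temperature_C))
  rss <- fit$deviance
  n <- length(Sv)
  structure(list(model = "double",
                 par = c(S_top = p$S_top, S_bottom = p$S_bot,
                         T1 = p$T1, w1 = p$w1, T2 = p$T2, w2 = p$w2,
                         phi = p$phi),
                 Tm = Tm, rss = rss, n = n,
                 aic = melt_aic(rss, n, 7L),
                 converged = fit$info %in% 1:3,
                 curve = curve),
            class = "melt_fit")
}

# numeric survival-0.5 crossing of an arbitrary fitted curve
melt_tm_root <- function(curve, trange) {
  span <- diff(trange)
  lo <- trange[1] - 2 * span; hi <- trange[2] + 2 * span
  f <- function(T) curve(T) - 0.5
  if (f(lo) * f(hi) > 0) {
    stop("Tm undefined error: fitted curve never crosses survival 0.5",
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("<melt_fit> ", x$model, "-Boltzmann: Tm = ", sprintf("%.2f", x$Tm),
      " degC (rss = ", sprintf("%.4g", x$rss), ", aic = ",
      sprintf("%.1f", x$aic), ")\n", sep = "")
  print(round(x$par, 4))
  invisible(x)
}

#' Melting-temperature increment between two fits
#'
#' @param fit_ligated,fit_unligated `melt_fit` objects with defined Tm.
#' @return Delta-Tm in degC (ligated minus unligated).
#' @examples
#' # a pair melting at 74 degC ligated vs 53 degC unligated gives +21
#' @export
delta_tm <- function(fit_ligated, fit_unligated) {
  stopifnot(inherits(fit_ligated, "melt_fit"),
            inherits(fit_unligated, "melt_fit"))
  fit_ligated$Tm - fit_unligated$Tm
}

#' Advisory comparison of single vs double melting fits
#'
#' @param fit_single,fit_double `melt_fit` objects fitted to the same data.
#' @return data frame with per-model `rss` and `aic` and attribute
#'   `preferred` (lower AIC); the choice remains with the analyst.
#' @export
compare_melt_fits <- function(fit_single, fit_double) {
  out <- data.frame(model = c(fit_single$model, fit_double$model),
                    rss = c(fit_single$rss, fit_double$rss),
                    aic = c(fit_single$aic, fit_double$aic))
  attr(out, "preferred") <- out$model[which.min(out$aic)]
  out
}
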