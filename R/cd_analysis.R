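GAS_R_kJ <- 8.31446261815324e-3  # kJ mol^-1 K^-1

#' Circular dichroism spectrum
#'
#' Observed ellipticity in millidegrees on a wavelength grid, with the sample
#' metadata needed to compute mean residue ellipticity: molecular weight
#' (g/mol), residue count, cuvette path length (cm) and protein concentration
#' (g/L).
#'
#' @param wavelength_nm strictly increasing wavelength grid.
#' @param millideg observed ellipticity per wavelength, millidegrees.
#' @param MW,n_residues,path_cm,conc_g_per_L sample metadata (may be `NA`
#'   when only raw-signal operations are needed).
#' @param label sample label.
#' @return data frame of class `cd_spectrum` with columns `wavelength_nm`,
#'   `millideg`; metadata kept as attributes.
#' @export
cd_spectrum <- function(wavelength_nm, millideg, MW = NA_real_,
                        n_residues = NA_integer_, path_cm = NA_real_,
                        conc_g_per_L = NA_real_, label = "sample") {
  stopifnot(length(wavelength_nm) == length(millideg))
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(data.frame(wavelength_nm = wavelength_nm, millideg = millideg),
            MW = MW, n_residues = n_residues, path_cm = path_cm,
            conc_g_per_L = conc_g_per_L, label = label,
            class = c("cd_spectrum", "data.frame"))
}

#' Mean residue ellipticity (MRE)
#'
#' Converts observed millidegrees to mean residue ellipticity:
#' \deqn{MRE(\lambda) = m^0(\lambda) \cdot MW / ((n - 1) \cdot 10 \cdot L \cdot C)}
#' with molecular weight MW (g/mol), `n` residues (n - 1 peptide bonds),
#' path length L (cm) and concentration C (g/L); units deg cm^2 dmol^-1.
#'
#' @param spectrum a [cd_spectrum] with complete, positive metadata.
#' @return data frame with columns `wavelength_nm`, `mre` and the input's
#'   attributes.
#' @export
mre <- function(spectrum) {
  MW <- attr(spectrum, "MW"); n <- attr(spectrum, "n_residues")
  L <- attr(spectrum, "path_cm"); C <- attr(spectrum, "conc_g_per_L")
  if (anyNA(c(MW, n, L, C)) || any(c(MW, L, C) <= 0))
    stop("complete positive sample metadata (MW, n_residues, path_cm, conc_g_per_L) required")
  if (n < 2) stop("n_residues must be >= 2")
  out <- data.frame(wavelength_nm = spectrum$wavelength_nm,
                    mre = spectrum$millideg * MW / ((n - 1) * 10 * L * C))
  structure(out, label = attr(spectrum, "label"),
            class = c("mre_spectrum", "data.frame"))
}

#' MRE at 222 nm
#'
#' Helper extracting (or linearly interpolating) the mean residue ellipticity
#' at 222 nm from a spectrum.
#' @param spectrum a [cd_spectrum].
#' @return scalar MRE at 222 nm.
#' @export
mre222 <- function(spectrum) {
  m <- mre(spectrum)
  if (222 < min(m$wavelength_nm) || 222 > max(m$wavelength_nm))
    stop("222 nm outside the measured wavelength range")
  stats::approx(m$wavelength_nm, m$mre, xout = 222)$y
}

#' Fractional helicity from MRE at 222 nm
#'
#' Helix content by the single-wavelength (222 nm) method:
#' `(mre222 - theta_u) / (theta_h - theta_u)` with coil and full-helix
#' reference values `theta_u` and `theta_h` (defaults -3000 and -39000
#' deg cm^2 dmol^-1). Values outside [0, 1] are returned as-is with attribute
#' `out_of_range = TRUE` and a warning.
#'
#' @param mre222 scalar MRE at 222 nm.
#' @param theta_u reference MRE for 0% helix.
#' @param theta_h reference MRE for 100% helix (must differ from `theta_u`).
#' @return fractional helicity (scalar).
#' @export
fractional_helicity <- function(mre222, theta_u = -3000, theta_h = -39000) {
  if (theta_h == theta_u) stop("theta_h must differ from theta_u")
  f <- (mre222 - theta_u) / (theta_h - theta_u)
  if (f < 0 || f > 1) {
    warning("fractional helicity outside [0, 1]: ", signif(f, 4))
    attr(f, "out_of_range") <- TRUE
  }
  f
}

#' Subtract a DNA spectrum from a protein-DNA complex spectrum
#'
#' Pointwise millidegree subtraction isolating the protein component of a
#' complex spectrum. Grids must match exactly in `"exact"` mode; in
#' `"interpolate"` mode the DNA spectrum is linearly interpolated onto the
#' complex grid over the overlapping range. The protein sample's metadata is
#' retained.
#'
#' @param complex_spec,dna_spec [cd_spectrum] objects.
#' @param method `"exact"` (default) or `"interpolate"`.
#' @return A [cd_spectrum] (restricted to the overlap in interpolation mode).
#' @export
subtract_dna_signal <- function(complex_spec, dna_spec,
                                method = c("exact", "interpolate")) {
  method <- match.arg(method)
  wl <- complex_spec$wavelength_nm
  if (method == "exact") {
    if (length(wl) != length(dna_spec$wavelength_nm) ||
        any(wl != dna_spec$wavelength_nm))
      stop("wavelength grids differ; use method = 'interpolate'")
    m <- complex_spec$millideg - dna_spec$millideg
    keep <- rep(TRUE, length(wl))
  } else {
    lo <- max(min(wl), min(dna_spec$wavelength_nm))
    hi <- min(max(wl), max(dna_spec$wavelength_nm))
    if (lo > hi) stop("wavelength ranges are disjoint")
    keep <- wl >= lo & wl <= hi
    dna_i <- stats::approx(dna_spec$wavelength_nm, dna_spec$millideg,
                           xout = wl[keep])$y
    m <- complex_spec$millideg[keep] - dna_i
  }
  cd_spectrum(wl[keep], m, MW = attr(complex_spec, "MW"),
              n_residues = attr(complex_spec, "n_residues"),
              path_cm = attr(complex_spec, "path_cm"),
              conc_g_per_L = attr(complex_spec, "conc_g_per_L"),
              label = paste0(attr(complex_spec, "label"), " - DNA"))
}

#' Thermal melt curve
#'
#' @param temperature_C strictly increasing temperature grid, deg C.
#' @param signal CD signal (e.g. MRE or millidegrees at 222 nm).
#' @param label curve label.
#' @return data frame of class `melt_curve`.
#' @export
melt_curve <- function(temperature_C, signal, label = "melt") {
  stopifnot(length(temperature_C) == length(signal))
  if (is.unsorted(temperature_C, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  structure(data.frame(temperature_C = temperature_C, signal = signal),
            label = label, class = c("melt_curve", "data.frame"))
}

# Two-state van't Hoff melt with linear baselines; temperatures in deg C,
# enthalpy in kJ/mol, Tm in deg C.
two_state_signal <- function(temp_C, tm_C, dH_kJ, bn_i, bn_s, bd_i, bd_s) {
  TK <- temp_C + 273.15
  TmK <- tm_C + 273.15
  K <- exp(-dH_kJ / GAS_R_kJ * (1 / TK - 1 / TmK))
  bn <- bn_i + bn_s * temp_C
  bd <- bd_i + bd_s * temp_C
  (bn + bd * K) / (1 + K)
}

#' Fit a thermal denaturation curve
#'
#' Fits (a) the two-state van't Hoff model with linear native and denatured
#' baselines,
#' `signal(T) = (b_n(T) + b_d(T) K(T)) / (1 + K(T))` with
#' `K(T) = exp(-dH/R (1/T - 1/Tm))` (T in kelvin internally), and (b) a
#' no-transition straight line. The curve is classified `non_cooperative`
#' when the linear model wins on AIC or the fitted van't Hoff enthalpy falls
#' below `dH_floor_kJ` (default 40 kJ/mol) -- the behavior expected of an
#' isolated SAH, which unfolds without a cooperative transition -- and
#' `two_state` otherwise. If the two-state fit does not converge the class is
#' `undetermined` unless the linear model essentially explains the data.
#'
#' @param curve a [melt_curve] with at least 8 temperatures.
#' @param dH_floor_kJ enthalpy floor for calling a transition cooperative.
#' @return An object of class `melt_fit`: list with `tm_C`, `dH_kJ`, native
#'   and denatured baseline coefficients, `model_class`, `aic_two_state`,
#'   `aic_linear`, `delta_aic` (linear minus two-state), `rss`, `converged`
#'   and the `fitted` function.
#' @export
fit_melt <- function(curve, dH_floor_kJ = 40) {
  stopifnot(inherits(curve, "data.frame"),
            all(c("temperature_C", "signal") %in% names(curve)))
  tC <- curve$temperature_C; y <- curve$signal
  if (length(tC) < 8L) stop("need >= 8 temperatures spanning the transition")
  n <- length(y)
  lin <- stats::lm(y ~ tC)
  aic_lin <- stats::AIC(lin)
  # starting values: baselines from the terminal thirds, Tm at the steepest
  # signal change
  k <- max(3L, n %/% 3L)
  cf_n <- stats::coef(stats::lm(y[1:k] ~ tC[1:k]))
  cf_d <- stats::coef(stats::lm(y[(n - k + 1):n] ~ tC[(n - k + 1):n]))
  dy <- diff(y) / diff(tC)
  tm0 <- tC[which.max(abs(dy - stats::median(dy)))]
  tm0 <- min(max(tm0, min(tC) + 1), max(tC) - 1)
  dat <- data.frame(tC = tC, y = y)
  cf_n <- unname(cf_n); cf_d <- unname(cf_d)
  starts <- list(
    list(tm_C = tm0, dH_kJ = 200, bn_i = cf_n[1], bn_s = cf_n[2],
         bd_i = cf_d[1], bd_s = cf_d[2]),
    list(tm_C = mean(range(tC)), dH_kJ = 100, bn_i = cf_n[1], bn_s = cf_n[2],
         bd_i = cf_d[1], bd_s = cf_d[2]),
    list(tm_C = tm0 + 10, dH_kJ = 400, bn_i = cf_n[1], bn_s = cf_n[2],
         bd_i = cf_d[1], bd_s = cf_d[2]))
  fit <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ two_state_signal(tC, tm_C, dH_kJ, bn_i, bn_s,
                                             bd_i, bd_s),
                        data = dat, start = st,
                        lower = c(min(tC) - 20, 1, -Inf, -Inf, -Inf, -Inf),
                        upper = c(max(tC) + 20, 2000, Inf, Inf, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) ||
                        sum(stats::resid(f)^2) < sum(stats::resid(fit)^2)))
      fit <- f
  }
  tss <- sum((y - mean(y))^2)
  r2_lin <- if (tss > 0) 1 - sum(stats::resid(lin)^2) / tss else 1
  if (is.null(fit)) {
    cls <- if (is.finite(r2_lin) && r2_lin > 0.99) "non_cooperative"
           else "undetermined"
    return(structure(list(tm_C = NA_real_, dH_kJ = NA_real_,
                          native_baseline = cf_n, denat_baseline = cf_d,
                          model_class = cls, aic_two_state = NA_real_,
                          aic_linear = aic_lin, delta_aic = NA_real_,
                          rss = sum(stats::resid(lin)^2), converged = FALSE,
                          fitted = function(x) stats::predict(
                            lin, data.frame(tC = x))),
                     class = "melt_fit"))
  }
  cf <- stats::coef(fit)
  aic_ts <- stats::AIC(fit)
  tm_in_range <- cf["tm_C"] >= min(tC) && cf["tm_C"] <= max(tC)
  cls <- if ((is.finite(r2_lin) && r2_lin > 1 - 1e-9) ||
             aic_lin <= aic_ts || cf["dH_kJ"] < dH_floor_kJ || !tm_in_range)
    "non_cooperative" else "two_state"
  structure(list(tm_C = unname(cf["tm_C"]), dH_kJ = unname(cf["dH_kJ"]),
                 native_baseline = c(intercept = unname(cf["bn_i"]),
                                     slope = unname(cf["bn_s"])),
                 denat_baseline = c(intercept = unname(cf["bd_i"]),
                                    slope = unname(cf["bd_s"])),
                 model_class = cls, aic_two_state = aic_ts,
                 aic_linear = aic_lin, delta_aic = aic_lin - aic_ts,
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 fitted = local({p <- as.list(cf); function(x)
                   two_state_signal(x, p$tm_C, p$dH_kJ, p$bn_i, p$bn_s,
                                    p$bd_i, p$bd_s)})),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: class %s", x$model_class))
  if (is.finite(x$tm_C))
    cat(sprintf(", Tm = %.2f degC, dH = %.0f kJ/mol", x$tm_C, x$dH_kJ))
  cat(sprintf("\n  AIC two-state %.1f vs linear %.1f; converged: %s\n",
              x$aic_two_state, x$aic_linear, x$converged))
  invisible(x)
}

#' Melting-temperature shift between two melt fits
#'
#' @param fit_ref,fit_test [fit_melt] results; the shift is
#'   `fit_test$tm_C - fit_ref$tm_C` (e.g. DNA-bound minus free protein).
#' @return scalar delta-Tm in deg C (`NA` if either fit lacks a Tm).
#' @export
melt_shift <- function(fit_ref, fit_test) {
  if (!is.finite(fit_ref$tm_C) || !is.finite(fit_test$tm_C)) return(NA_real_)
  fit_test$tm_C - fit_ref$tm_C
}

#' Average repeated CD scans
#'
#' Optional helper mirroring instrument-side scan averaging: pointwise mean
#' of spectra sharing one wavelength grid.
#' @param spectra list of [cd_spectrum] objects on identical grids.
#' @return A [cd_spectrum] with the first spectrum's metadata.
#' @export
average_scans <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wavelength_nm
  for (s in spectra)
    if (length(s$wavelength_nm) != length(wl) || any(s$wavelength_nm != wl))
      stop("all scans must share one wavelength grid")
  m <- rowMeans(vapply(spectra, function(s) s$millideg, numeric(length(wl))))
  cd_spectrum(wl, m, MW = attr(spectra[[1L]], "MW"),
              n_residues = attr(spectra[[1L]], "n_residues"),
              path_cm = attr(spectra[[1L]], "path_cm"),
              conc_g_per_L = attr(spectra[[1L]], "conc_g_per_L"),
              label = attr(spectra[[1L]], "label"))
}
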