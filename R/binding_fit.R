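#' Cooperative (Hill) binding isotherm
#'
#' Fraction bound as a function of protein concentration:
#' \deqn{f([P]) = B_{max} [P]^h / (K_D^h + [P]^h)}
#' where `h` is the Hill coefficient, `kd_nM` the dissociation constant and
#' `bmax` the maximum binding. At `[P] = K_D` the value is `bmax/2` for any
#' `h`; the curve is monotone non-decreasing in `[P]`.
#'
#' @param conc_nM protein concentration(s), nM (>= 0).
#' @param kd_nM dissociation constant, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @param bmax maximum binding.
#' @return numeric vector of fractions bound.
#' @export
hill_fraction <- function(conc_nM, kd_nM, h = 1, bmax = 1) {
  stopifnot(kd_nM > 0, h > 0)
  x <- (conc_nM / kd_nM)^h
  ifelse(conc_nM <= 0, 0, bmax * x / (1 + x))
}

#' Build a titration series from EMSA gel-lane intensities
#'
#' Converts per-lane band intensities (free DNA plus the ladder of shifted
#' protein-DNA complexes) into fraction bound per protein concentration.
#' Background is subtracted from every band and clamped at zero. Two
#' definitions are available: `"bound-over-total"` (default; sum of shifted
#' bands over total lane signal, which uses all band information and is
#' invariant to uniform lane rescaling) and `"free-depletion"`
#' (1 - free/free_at_zero_protein). The zero-protein lane yields fraction 0
#' by construction in both modes.
#'
#' @param lanes data frame with columns `lane_id`, `protein_conc_nM`,
#'   `background`, `free`, and zero or more `complex*` columns (NA allowed
#'   for bands absent in a lane).
#' @param mode fraction-bound definition, see above.
#' @param dna_length_bp,dna_conc_nM,label optional metadata carried on the
#'   result.
#' @return A data frame of class `titration_series` with columns
#'   `protein_conc_nM` and `fraction_bound`, ordered by concentration.
#' @export
fraction_bound <- function(lanes,
                           mode = c("bound-over-total", "free-depletion"),
                           dna_length_bp = NA_integer_, dna_conc_nM = NA_real_,
                           label = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(lanes),
            all(c("protein_conc_nM", "background", "free") %in% names(lanes)))
  ccols <- grep("^complex", names(lanes), value = TRUE)
  conc <- lanes$protein_conc_nM
  if (!any(conc == 0))
    stop("lanes must include a zero-protein lane")
  sub0 <- function(v, bg) pmax(v - bg, 0)
  free <- sub0(lanes$free, lanes$background)
  shifted <- if (length(ccols)) {
    m <- as.matrix(lanes[, ccols, drop = FALSE])
    m[is.na(m)] <- 0
    rowSums(pmax(m - lanes$background, 0))
  } else rep(0, nrow(lanes))
  total <- free + shifted
  if (any(total <= 0))
    stop("empty lane: zero total signal in lane(s) ",
         paste(lanes$lane_id[total <= 0], collapse = ", "))
  if (mode == "bound-over-total") {
    frac <- shifted / total
  } else {
    f0 <- free[conc == 0]
    f0 <- mean(f0)
    if (f0 <= 0) stop("zero-protein lane has no free-DNA signal")
    frac <- 1 - free / f0
  }
  frac[conc == 0] <- 0
  out <- data.frame(protein_conc_nM = conc, fraction_bound = frac)
  out <- out[order(out$protein_conc_nM), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dna_length_bp = dna_length_bp, dna_conc_nM = dna_conc_nM,
            label = label %||% "titration", mode = mode,
            class = c("titration_series", "data.frame"))
}

#' Construct a titration series directly
#'
#' @param protein_conc_nM,fraction_bound numeric vectors of equal length.
#' @inheritParams fraction_bound
#' @param sd optional per-point standard deviation (replicate spread).
#' @param n_rep optional replicate count per point.
#' @return A `titration_series` data frame.
#' @export
titration_series <- function(protein_conc_nM, fraction_bound, sd = NULL,
                             n_rep = NULL, dna_length_bp = NA_integer_,
                             dna_conc_nM = NA_real_, label = "titration") {
  stopifnot(length(protein_conc_nM) == length(fraction_bound))
  out <- data.frame(protein_conc_nM = protein_conc_nM,
                    fraction_bound = fraction_bound)
  if (!is.null(sd)) out$sd <- sd
  if (!is.null(n_rep)) out$n_rep <- n_rep
  out <- out[order(out$protein_conc_nM), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dna_length_bp = dna_length_bp, dna_conc_nM = dna_conc_nM,
            label = label, class = c("titration_series", "data.frame"))
}

hill_start <- function(conc, frac) {
  bmax0 <- max(frac)
  # log-logit linearization for h and K_D starts: log(f/(b-f)) = h log c - h log K_D
  h0 <- 1; kd0 <- NA_real_
  pos <- conc > 0
  fr <- frac[pos] / (bmax0 * 1.05 + 1e-9)
  sel <- fr > 0.02 & fr < 0.98
  if (sum(sel) >= 2L) {
    y <- log(fr[sel] / (1 - fr[sel]))
    x <- log(conc[pos][sel])
    cf <- tryCatch(stats::coef(stats::lm(y ~ x)), error = function(e) c(NA, NA))
    if (all(is.finite(cf)) && cf[2] > 0) {
      h0 <- min(max(cf[2], 0.3), 8)
      kd0 <- exp(-cf[1] / cf[2])
    }
  }
  if (!is.finite(kd0) || kd0 <= 0) {
    half <- bmax0 / 2
    kd0 <- if (any(frac >= half) && any(frac < half))
      stats::approx(frac, conc, xout = half, ties = mean)$y
    else stats::median(conc[conc > 0])
    if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  }
  kd0 <- min(max(kd0, 1e-3), 1e6)
  c(kd_nM = kd0, h = h0, bmax = max(bmax0, 0.05))
}

#' Fit the Hill binding isotherm to a titration
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM]) of the
#' cooperative binding isotherm to fraction-bound data. Starting values are
#' taken from the data (half-maximum crossing for `K_D`, `h = 1`, `bmax` at
#' the observed maximum); parameters are bounded (`K_D` in [1e-3, 1e6] nM,
#' `h` in [0.2, 10], `bmax` in [0, 1.2]) for numerical stability. On failure
#' the fit is retried from 5 seeded random starts; if it still fails the
#' best-found parameters are returned with `converged = FALSE`.
#'
#' @param series a `titration_series` (or data frame with columns
#'   `protein_conc_nM`, `fraction_bound`, optionally `sd`).
#' @param fix_bmax fix `bmax` at this value instead of fitting it.
#' @param fix_h fix the Hill coefficient (e.g. `fix_h = 1` for the
#'   non-cooperative nested model).
#' @param weighted if `TRUE` and the series carries a positive `sd` column,
#'   use inverse-variance weights. Default unweighted.
#' @param restart_seed seed for the randomized multi-start fallback.
#' @return An object of class `hill_fit`: list with `kd_nM`, `hill_h`,
#'   `bmax`, standard errors (`se`, NA for fixed parameters), `rss`, `n`,
#'   `converged`, `fixed` and the `fitted` function.
#' @export
fit_hill <- function(series, fix_bmax = NULL, fix_h = NULL, weighted = FALSE,
                     restart_seed = 1L) {
  conc <- series$protein_conc_nM
  frac <- series$fraction_bound
  ok <- is.finite(conc) & is.finite(frac)
  conc <- conc[ok]; frac <- frac[ok]
  if (length(unique(conc[conc > 0])) < 4L)
    stop("need at least 4 distinct nonzero concentrations")
  if (all(frac <= 0)) stop("no binding detected")
  if (any(frac < -0.05) || any(frac > 1.3))
    warning("fraction-bound values outside [0, 1.05] range")
  w <- rep(1, length(conc))
  if (weighted && !is.null(series$sd)) {
    s <- series$sd[ok]
    if (all(is.finite(s)) && all(s > 0)) w <- 1 / s^2
  }
  lower <- c(kd_nM = 1e-3, h = 0.2, bmax = 0)
  upper <- c(kd_nM = 1e6, h = 10, bmax = 1.2)
  st <- hill_start(conc, frac)
  fixed <- c(bmax = !is.null(fix_bmax), h = !is.null(fix_h))
  free <- c("kd_nM", if (!fixed["h"]) "h", if (!fixed["bmax"]) "bmax")
  dat <- data.frame(conc = conc, frac = frac)

  make_formula <- function() {
    hterm <- if (fixed["h"]) deparse(fix_h) else "h"
    bterm <- if (fixed["bmax"]) deparse(fix_bmax) else "bmax"
    stats::as.formula(sprintf(
      "frac ~ %s * (conc/kd_nM)^%s / (1 + (conc/kd_nM)^%s)", bterm, hterm, hterm))
  }
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(make_formula(), data = dat, start = as.list(start),
                        lower = unname(lower[free]), upper = unname(upper[free]),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  start <- as.list(st[free])
  fit <- try_fit(start)
  if (is.null(fit)) {
    fit <- with_seed(restart_seed, {
      best <- NULL
      for (i in seq_len(5L)) {
        jit <- lapply(start, function(v) v * exp(stats::rnorm(1, 0, 0.7)))
        jit <- mapply(function(v, nm) min(max(v, lower[nm]), upper[nm]),
                      jit, free, SIMPLIFY = FALSE)
        names(jit) <- free
        f <- try_fit(jit)
        if (!is.null(f) && (is.null(best) ||
                            sum(stats::resid(f)^2) < sum(stats::resid(best)^2)))
          best <- f
      }
      best
    })
  }
  if (is.null(fit)) {
    # last resort: coarse grid to report best-found parameters, unconverged
    grid <- expand.grid(kd = exp(seq(log(1e-2), log(1e5), length.out = 60)),
                        h = c(0.5, 1, 2, 4), bmax = c(0.5, 1))
    rss <- apply(grid, 1, function(p)
      sum(w * (frac - hill_fraction(conc, p[1], p[2], p[3]))^2))
    p <- grid[which.min(rss), ]
    return(structure(list(kd_nM = p$kd, hill_h = p$h, bmax = p$bmax,
                          se = c(kd_nM = NA, h = NA, bmax = NA),
                          rss = min(rss), n = length(conc), converged = FALSE,
                          fixed = fixed,
                          fitted = function(x) hill_fraction(x, p$kd, p$h, p$bmax)),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  se_tab <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) setNames(rep(NA_real_, length(cf)),
                                                  names(cf)))
  kd <- unname(cf["kd_nM"])
  h <- if (fixed["h"]) fix_h else unname(cf["h"])
  bm <- if (fixed["bmax"]) fix_bmax else unname(cf["bmax"])
  se <- c(kd_nM = unname(se_tab["kd_nM"]),
          h = if (fixed["h"]) NA_real_ else unname(se_tab["h"]),
          bmax = if (fixed["bmax"]) NA_real_ else unname(se_tab["bmax"]))
  structure(list(kd_nM = kd, hill_h = h, bmax = bm, se = se,
                 rss = sum(w * stats::resid(fit)^2), n = length(conc),
                 converged = TRUE, fixed = fixed,
                 fitted = function(x) hill_fraction(x, kd, h, bm)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("hill_fit: K_D = %.4g nM (se %.3g), h = %.3g (se %.3g), Bmax = %.3g (se %.3g)\n",
              x$kd_nM, x$se["kd_nM"], x$hill_h, x$se["h"], x$bmax, x$se["bmax"]))
  cat(sprintf("  rss = %.4g over n = %d points; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' Average replicate titrations
#'
#' Replicates must share the same concentration grid (relative tolerance
#' 1e-6). Returns per-concentration mean and sample SD (SD is `NA`, not 0,
#' for a single replicate).
#'
#' @param series_list list of `titration_series` objects.
#' @return A `titration_series` with columns `protein_conc_nM`,
#'   `fraction_bound` (mean), `sd` and `n_rep`.
#' @export
aggregate_replicates <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  ref <- sort(series_list[[1L]]$protein_conc_nM)
  for (k in seq_along(series_list)) {
    ck <- sort(series_list[[k]]$protein_conc_nM)
    if (length(ck) != length(ref) ||
        any(abs(ck - ref) > 1e-6 * pmax(abs(ref), 1e-12))) {
      bad <- if (length(ck) == length(ref)) ck[abs(ck - ref) > 1e-6 * pmax(abs(ref), 1e-12)] else ck
      stop("replicate ", k, " concentration grid mismatch at: ",
           paste(signif(bad, 6), collapse = ", "))
    }
  }
  m <- vapply(series_list, function(s) {
    s <- s[order(s$protein_conc_nM), ]
    s$fraction_bound
  }, numeric(length(ref)))
  m <- matrix(m, nrow = length(ref))
  n <- ncol(m)
  means <- rowMeans(m)
  sds <- if (n > 1L) apply(m, 1, stats::sd) else rep(NA_real_, length(ref))
  titration_series(ref, means, sd = sds, n_rep = rep(n, length(ref)),
                   dna_length_bp = attr(series_list[[1L]], "dna_length_bp"),
                   dna_conc_nM = attr(series_list[[1L]], "dna_conc_nM"),
                   label = attr(series_list[[1L]], "label") %||% "mean")
}
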