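#' Normalize free-DNA intensities in a competition DNA-ladder titration
#'
#' For each fragment (and replicate), divides the free-DNA band intensity at
#' every protein concentration by the intensity in the zero-protein lane, so
#' the normalized free DNA starts at 1 and falls as the fragment is depleted
#' into complexes. Values above 1 from noise are kept (not clamped).
#'
#' @param ladder long-format data frame with columns `protein_conc_nM`,
#'   `fragment_bp`, `free_intensity`, and optionally `construct` and
#'   `replicate`.
#' @return The input with an added `normalized_free` column, class
#'   `ladder_titration`.
#' @export
normalize_free_dna <- function(ladder) {
  stopifnot(is.data.frame(ladder),
            all(c("protein_conc_nM", "fragment_bp", "free_intensity") %in%
                  names(ladder)))
  if (!"construct" %in% names(ladder)) ladder$construct <- "construct"
  if (!"replicate" %in% names(ladder)) ladder$replicate <- 1L
  key <- interaction(ladder$construct, ladder$replicate, ladder$fragment_bp,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(ladder, key), function(d) {
    i0 <- d$protein_conc_nM == 0
    if (!any(i0))
      stop("no zero-protein lane for fragment ", d$fragment_bp[1L])
    ref <- mean(d$free_intensity[i0])
    if (!is.finite(ref) || ref <= 0)
      stop("zero-protein intensity is 0 for fragment ", d$fragment_bp[1L])
    d$normalized_free <- d$free_intensity / ref
    d
  }))
  out <- out[order(out$construct, out$replicate, out$fragment_bp,
                   out$protein_conc_nM), ]
  rownames(out) <- NULL
  structure(out, class = c("ladder_titration", "data.frame"))
}

#' Apparent K_D per DNA fragment from ladder depletion curves
#'
#' Treats `1 - normalized_free` as fraction bound and fits the Hill isotherm
#' per fragment (and replicate). Fragments whose maximum depletion never
#' reaches `censor_threshold` (default 20%) are reported right-censored
#' (`kdapp_nM = NA`, `censored = TRUE`, bound at the largest tested
#' concentration) rather than fitted -- the behavior of an inert fragment
#' such as 10 bp DNA against a 20 bp-footprint binder.
#'
#' @param curves a `ladder_titration` from [normalize_free_dna].
#' @param censor_threshold minimum depletion required to attempt a fit.
#' @param fix_bmax optional fixed `Bmax` passed to [fit_hill].
#' @return data frame of class `selectivity_fits`: one row per
#'   construct/replicate/fragment with `kdapp_nM`, `kd_se`, `hill_h`, `bmax`,
#'   `c50_nM`, `censored`, `censor_bound_nM` and `converged`.
#' @export
kdapp_per_fragment <- function(curves, censor_threshold = 0.2,
                               fix_bmax = NULL) {
  stopifnot("normalized_free" %in% names(curves))
  key <- interaction(curves$construct, curves$replicate, curves$fragment_bp,
                     drop = TRUE)
  rows <- lapply(split(curves, key), function(d) {
    d <- d[order(d$protein_conc_nM), ]
    base <- data.frame(construct = d$construct[1L],
                       replicate = d$replicate[1L],
                       fragment_bp = d$fragment_bp[1L])
    depl <- 1 - min(d$normalized_free)
    if (depl < censor_threshold) {
      return(cbind(base, kdapp_nM = NA_real_, kd_se = NA_real_,
                   hill_h = NA_real_, bmax = NA_real_, c50_nM = NA_real_,
                   censored = TRUE,
                   censor_bound_nM = max(d$protein_conc_nM),
                   converged = NA))
    }
    ser <- titration_series(d$protein_conc_nM, 1 - d$normalized_free,
                            dna_length_bp = d$fragment_bp[1L])
    fit <- tryCatch(fit_hill(ser, fix_bmax = fix_bmax), error = function(e) e)
    if (inherits(fit, "error"))
      stop("fit failed for fragment ", d$fragment_bp[1L], " bp: ",
           conditionMessage(fit))
    cbind(base, kdapp_nM = fit$kd_nM, kd_se = unname(fit$se["kd_nM"]),
          hill_h = fit$hill_h, bmax = fit$bmax,
          c50_nM = c50_from_fit(fit), censored = FALSE,
          censor_bound_nM = NA_real_, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("selectivity_fits", "data.frame"))
}

# Invert the fitted Hill curve at normalized_free = 0.5 (fraction bound 0.5).
c50_from_fit <- function(fit) {
  if (fit$bmax <= 0.5) return(NA_real_)
  fit$kd_nM * (0.5 / (fit$bmax - 0.5))^(1 / fit$hill_h)
}

#' Protein concentration achieving 50% depletion of a fragment
#'
#' Default (`method = "fit"`): inverts the fitted Hill curve at
#' normalized free DNA = 0.5; censored where the fitted plateau never reaches
#' 50% depletion. `method = "interpolate"` reads the crossing directly off
#' the (monotone) raw depletion curve.
#'
#' @param fits a `selectivity_fits` table (for `method = "fit"`).
#' @param curves a `ladder_titration` (required for `"interpolate"`).
#' @param method `"fit"` or `"interpolate"`.
#' @return data frame with one row per construct/replicate/fragment and a
#'   `c50_nM` column (`NA` = censored).
#' @export
c50 <- function(fits = NULL, curves = NULL,
                method = c("fit", "interpolate")) {
  method <- match.arg(method)
  if (method == "fit") {
    stopifnot(!is.null(fits))
    return(fits[, c("construct", "replicate", "fragment_bp", "c50_nM")])
  }
  stopifnot(!is.null(curves), "normalized_free" %in% names(curves))
  key <- interaction(curves$construct, curves$replicate, curves$fragment_bp,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(curves, key), function(d) {
    d <- d[order(d$protein_conc_nM), ]
    nf <- d$normalized_free
    base <- data.frame(construct = d$construct[1L],
                       replicate = d$replicate[1L],
                       fragment_bp = d$fragment_bp[1L])
    if (min(nf) > 0.5) return(cbind(base, c50_nM = NA_real_))
    if (is.unsorted(rev(nf)) && any(diff(nf) > 1e-8))
      stop("non-monotone raw depletion curve for fragment ",
           d$fragment_bp[1L], " bp; use method = 'fit'")
    cross <- which(nf <= 0.5)[1L]
    if (cross == 1L) return(cbind(base, c50_nM = d$protein_conc_nM[1L]))
    x <- stats::approx(nf[(cross - 1L):cross],
                       d$protein_conc_nM[(cross - 1L):cross], xout = 0.5)$y
    cbind(base, c50_nM = x)
  }))
  rownames(out) <- NULL
  out
}

#' 40-to-50 bp selectivity slope of the apparent K_D
#'
#' Rate of change of the apparent dissociation constant between the 40 and
#' 50 bp fragments: `(kdapp(50) - kdapp(40)) / 10` nM/bp, computed per
#' replicate, negative when 50 bp is bound more tightly than 40 bp. A
#' censored K_Dapp at either length makes the replicate's slope undefined
#' (`NA`, flagged).
#'
#' @param fits a `selectivity_fits` table.
#' @param from_bp,to_bp fragment lengths defining the slope (defaults 40, 50).
#' @return list of class `selectivity_slope`: per-replicate `slopes` data
#'   frame (columns `construct`, `replicate`, `slope_nM_per_bp`, `censored`)
#'   and per-construct `summary` (mean, SD, n of uncensored slopes).
#' @export
selectivity_slope <- function(fits, from_bp = 40, to_bp = 50) {
  key <- interaction(fits$construct, fits$replicate, drop = TRUE)
  slopes <- do.call(rbind, lapply(split(fits, key), function(d) {
    a <- d[d$fragment_bp == from_bp, ]
    b <- d[d$fragment_bp == to_bp, ]
    if (nrow(a) != 1L || nrow(b) != 1L)
      stop("need exactly one ", from_bp, " and one ", to_bp,
           " bp fit per replicate")
    cens <- isTRUE(a$censored) || isTRUE(b$censored)
    data.frame(construct = d$construct[1L], replicate = d$replicate[1L],
               slope_nM_per_bp = if (cens) NA_real_ else
                 (b$kdapp_nM - a$kdapp_nM) / (to_bp - from_bp),
               censored = cens)
  }))
  rownames(slopes) <- NULL
  summ <- do.call(rbind, lapply(split(slopes, slopes$construct), function(d) {
    s <- d$slope_nM_per_bp[!d$censored]
    data.frame(construct = d$construct[1L], mean_slope = mean(s),
               sd_slope = if (length(s) > 1L) stats::sd(s) else NA_real_,
               n = length(s))
  }))
  rownames(summ) <- NULL
  structure(list(slopes = slopes, summary = summ),
            class = "selectivity_slope")
}

#' @export
print.selectivity_slope <- function(x, ...) {
  cat("40->50 bp selectivity slope (nM/bp):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare selectivity slopes across constructs by one-way ANOVA
#'
#' Omnibus one-way ANOVA on per-replicate selectivity slopes, with
#' per-construct contrasts against a reference (wild-type) construct from
#' the linear-model coefficients, and optional Tukey HSD adjusted
#' comparisons.
#'
#' @param slopes per-replicate slope data frame (columns `construct`,
#'   `slope_nM_per_bp`), e.g. `selectivity_slope(...)$slopes`.
#' @param reference reference construct for the contrasts (default: first
#'   level).
#' @param tukey if `TRUE`, include Tukey HSD results.
#' @return list of class `construct_anova`: `F`, `df`, `p`, `contrasts`
#'   (estimate, se, t, p per non-reference construct), and optionally
#'   `tukey`.
#' @export
compare_constructs <- function(slopes, reference = NULL, tukey = FALSE) {
  stopifnot(all(c("construct", "slope_nM_per_bp") %in% names(slopes)))
  d <- slopes[is.finite(slopes$slope_nM_per_bp), ]
  d$construct <- factor(d$construct)
  if (nlevels(d$construct) < 2L) stop("need >= 2 constructs")
  cnt <- table(d$construct)
  if (any(cnt < 2L))
    stop("single replicate in group(s): ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  if (!is.null(reference)) d$construct <- stats::relevel(d$construct, reference)
  fit <- stats::aov(slope_nM_per_bp ~ construct, data = d)
  tab <- summary(fit)[[1L]]
  Fval <- tab["construct", "F value"]
  pval <- tab["construct", "Pr(>F)"]
  # all-equal degenerate case: no between- or within-group variation
  if (!is.finite(Fval)) { Fval <- 0; pval <- 1 }
  lmfit <- stats::lm(slope_nM_per_bp ~ construct, data = d)
  cf <- summary(lmfit)$coefficients
  ctr <- cf[-1L, , drop = FALSE]
  contrasts <- data.frame(
    construct = sub("^construct", "", rownames(ctr)),
    estimate = ctr[, "Estimate"], se = ctr[, "Std. Error"],
    t = ctr[, "t value"], p = ctr[, "Pr(>|t|)"])
  rownames(contrasts) <- NULL
  out <- list(F = unname(Fval), df = unname(tab$Df), p = unname(pval),
              contrasts = contrasts,
              reference = levels(d$construct)[1L])
  if (tukey) out$tukey <- stats::TukeyHSD(fit)
  structure(out, class = "construct_anova")
}

#' @export
print.construct_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g (reference: %s)\n",
              x$df[1L], x$df[2L], x$F, x$p, x$reference))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Full ladder selectivity analysis
#'
#' Convenience wrapper: normalize free DNA, fit per-fragment apparent K_D
#' with censoring, and compute per-replicate 40->50 bp slopes.
#'
#' @inheritParams normalize_free_dna
#' @inheritParams kdapp_per_fragment
#' @return list of class `selectivity_result`: `curves`, `fits`, `slope`,
#'   and per-construct/fragment `kdapp_summary` (mean, SD over replicates).
#' @export
analyze_ladder <- function(ladder, censor_threshold = 0.2, fix_bmax = NULL) {
  curves <- normalize_free_dna(ladder)
  fits <- kdapp_per_fragment(curves, censor_threshold = censor_threshold,
                             fix_bmax = fix_bmax)
  key <- interaction(fits$construct, fits$fragment_bp, drop = TRUE)
  summ <- do.call(rbind, lapply(split(fits, key), function(d) {
    v <- d$kdapp_nM[!d$censored]
    data.frame(construct = d$construct[1L], fragment_bp = d$fragment_bp[1L],
               mean_kdapp_nM = if (length(v)) mean(v) else NA_real_,
               sd_kdapp_nM = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_censored = sum(d$censored), n = nrow(d))
  }))
  rownames(summ) <- NULL
  structure(list(curves = curves, fits = fits,
                 slope = selectivity_slope(fits), kdapp_summary = summ),
            class = "selectivity_result")
}
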