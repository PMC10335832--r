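#' Noise model for rendered EMSA lanes
#'
#' @param cv multiplicative band-intensity coefficient of variation
#'   (lognormal, >= 0).
#' @param bg_mean,bg_sd additive background intensity mean and SD.
#' @param ceiling saturation ceiling on intensities (default `Inf`).
#' @param seed integer seed.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, bg_mean = 0, bg_sd = 0, ceiling = Inf,
                        seed = 1L) {
  stopifnot(cv >= 0, bg_sd >= 0)
  structure(list(cv = cv, bg_mean = bg_mean, bg_sd = bg_sd, ceiling = ceiling,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Render an EMSA gel-lane table from a simulated titration
#'
#' Band k intensity is proportional to the probability of k bound monomers
#' times the DNA amount, with multiplicative lognormal band noise, additive
#' background and an optional saturation ceiling. The output is the wide
#' gel-lane table consumed by [fraction_bound]: one row per lane with columns
#' `lane_id`, `protein_conc_nM`, `background`, `free`, `complex1..K`.
#' Deterministic given the noise model's seed.
#'
#' @param titration an `occupancy_titration` from [simulate_titration].
#' @param noise a [noise_model].
#' @param dna_amount relative amount of labeled DNA (scales all bands).
#' @param scale intensity scale of a fully occupied band class.
#' @return data frame of gel lanes.
#' @export
render_emsa <- function(titration, noise = noise_model(), dna_amount = 1,
                        scale = 1000) {
  stopifnot(inherits(titration, "occupancy_titration"))
  p <- titration$p
  nlane <- nrow(p)
  kmax <- ncol(p) - 1L
  with_seed(noise$seed, {
    ideal <- scale * dna_amount * p
    fac <- if (noise$cv > 0)
      matrix(exp(stats::rnorm(length(ideal), -noise$cv^2 / 2, noise$cv)),
             nlane) else matrix(1, nlane, ncol(p))
    bg_obs <- noise$bg_mean +
      if (noise$bg_sd > 0) matrix(stats::rnorm(length(ideal), 0, noise$bg_sd),
                                  nlane) else 0
    intens <- pmin(ideal * fac + bg_obs, noise$ceiling)
    intens <- pmax(intens, 0)
    out <- data.frame(lane_id = sprintf("lane%02d", seq_len(nlane)),
                      protein_conc_nM = titration$conc_nM,
                      background = rep(noise$bg_mean, nlane))
    out$free <- intens[, 1L]
    if (kmax >= 1L) for (k in seq_len(kmax))
      out[[paste0("complex", k)]] <- intens[, k + 1L]
    out
  })
}

#' Render a multi-fragment competition DNA-ladder titration
#'
#' Simulates the 5-fragment Cy5-DNA-ladder EMSA: fragments of different
#' lengths (default 10-50 bp at 1 nM each) share one protein titration, each
#' fragment binding according to its own finite-lattice configuration (shared
#' footprint, association constant and cooperativity unless overridden).
#' Returns the long-format free-DNA table consumed by the ladder selectivity
#' analysis.
#'
#' @param fragment_lengths_bp fragment lengths, bp.
#' @param conc_grid_nM shared protein concentration grid (must include 0).
#' @param K_assoc_per_nM,footprint_bp,omega lattice parameters shared by all
#'   fragments; each may also be a named vector keyed by fragment length.
#' @param n_replicates number of replicate titrations to render.
#' @param noise a [noise_model]; replicate r uses `seed + r`.
#' @param construct construct label.
#' @return data frame with columns `construct`, `replicate`,
#'   `protein_conc_nM`, `fragment_bp`, `free_intensity`.
#' @export
render_emsa_ladder <- function(fragment_lengths_bp = c(10, 20, 30, 40, 50),
                               conc_grid_nM = c(0, 37, 75, 150, 300, 450, 600, 760),
                               K_assoc_per_nM = 0.02, footprint_bp = 20L,
                               omega = 1, n_replicates = 3L,
                               noise = noise_model(), construct = "wt") {
  stopifnot(any(conc_grid_nM == 0))
  par_for <- function(p, len) if (length(p) > 1L && !is.null(names(p)))
    unname(p[as.character(len)]) else unname(p[1L])
  rows <- list()
  for (len in fragment_lengths_bp) {
    cfg <- lattice_config(len, footprint_bp = par_for(footprint_bp, len),
                          K_assoc_per_nM = par_for(K_assoc_per_nM, len),
                          omega = par_for(omega, len),
                          conc_grid_nM = conc_grid_nM)
    tit <- simulate_titration(cfg)
    for (r in seq_len(n_replicates)) {
      nm <- noise_model(cv = noise$cv, bg_mean = noise$bg_mean,
                        bg_sd = noise$bg_sd, ceiling = noise$ceiling,
                        seed = noise$seed + 1000L * r + len)
      lanes <- render_emsa(tit, noise = nm)
      rows[[length(rows) + 1L]] <- data.frame(
        construct = construct, replicate = r,
        protein_conc_nM = conc_grid_nM, fragment_bp = len,
        free_intensity = lanes$free)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Reference MRE basis curves (deg cm^2 dmol^-1) for 100% helix and 0% helix
# (coil), 190-250 nm. Shapes follow the canonical alpha-helix bands (minima
# near 208 and 222 nm, strong positive band below 195 nm) and the coil band
# near 198 nm; each curve is rescaled so its 222 nm value is exactly the
# standard reference (-39000 helix, -3000 coil).
cd_basis <- function(wavelength_nm) {
  g <- function(l, mu, s) exp(-((l - mu) / s)^2)
  shape_h <- function(l) -39000 * g(l, 222, 9) - 33000 * g(l, 208, 7) +
    65000 * g(l, 192, 6)
  shape_c <- function(l) -19000 * g(l, 198, 9) - 2500 * g(l, 222, 25)
  list(helix = shape_h(wavelength_nm) * (-39000 / shape_h(222)),
       coil = shape_c(wavelength_nm) * (-3000 / shape_c(222)))
}

#' Simulate a CD spectrum of a partially helical protein
#'
#' Builds an MRE spectrum as a linear mix of built-in 100% helix and coil
#' basis curves (190-250 nm), converts it to observed millidegrees through
#' the inverse mean-residue-ellipticity relation, and adds optional Gaussian
#' noise. Noiseless round trip: [mre] then [fractional_helicity] at 222 nm
#' returns `helix_fraction` exactly.
#'
#' @param helix_fraction fraction helix in [0, 1].
#' @param n_residues,MW,path_cm,conc_g_per_L sample metadata used for the
#'   MRE <-> millidegree conversion.
#' @param wavelengths_nm wavelength grid (must include 222 for helicity work).
#' @param noise_mdeg additive Gaussian noise SD in millidegrees.
#' @param seed integer seed.
#' @param label sample label.
#' @return A [cd_spectrum].
#' @export
simulate_cd <- function(helix_fraction, n_residues = 90L, MW = 11000,
                        path_cm = 0.1, conc_g_per_L = 0.1,
                        wavelengths_nm = 190:250, noise_mdeg = 0, seed = 1L,
                        label = "synthetic") {
  stopifnot(helix_fraction >= 0, helix_fraction <= 1)
  basis <- cd_basis(wavelengths_nm)
  mre_curve <- helix_fraction * basis$helix + (1 - helix_fraction) * basis$coil
  m0 <- mre_curve * (n_residues - 1) * 10 * path_cm * conc_g_per_L / MW
  if (noise_mdeg > 0)
    m0 <- with_seed(seed, m0 + stats::rnorm(length(m0), 0, noise_mdeg))
  cd_spectrum(wavelengths_nm, m0, MW = MW, n_residues = n_residues,
              path_cm = path_cm, conc_g_per_L = conc_g_per_L, label = label)
}

#' Simulate a two-state thermal melt monitored at 222 nm
#'
#' Generates a melt curve from the two-state van't Hoff model with linear
#' native and denatured baselines (the same model fitted by [fit_melt]),
#' plus optional Gaussian noise.
#'
#' @param tm_C melting temperature, deg C.
#' @param dH_kJ van't Hoff enthalpy, kJ/mol.
#' @param native_intercept,native_slope native-baseline MRE at 0 deg C and
#'   slope per deg C.
#' @param denat_intercept,denat_slope denatured-baseline parameters.
#' @param temps_C temperature grid, deg C.
#' @param noise_sd additive noise SD (signal units).
#' @param seed integer seed.
#' @param label curve label.
#' @return A [melt_curve].
#' @export
simulate_melt <- function(tm_C = 45, dH_kJ = 150,
                          native_intercept = -24000, native_slope = 40,
                          denat_intercept = -6000, denat_slope = 15,
                          temps_C = seq(5, 95, by = 2), noise_sd = 0,
                          seed = 1L, label = "synthetic") {
  y <- two_state_signal(temps_C, tm_C, dH_kJ, native_intercept, native_slope,
                        denat_intercept, denat_slope)
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  melt_curve(temps_C, y, label = label)
}

#' Generate ideal or curved alpha-helix C-alpha coordinates
#'
#' Places C-alpha atoms on a helical path with the given rise, twist and
#' radius. With a finite `curvature_radius` the helix axis is bent onto a
#' circle of that radius (in the xz-plane), producing a uniformly curved
#' helix; `curvature_radius = Inf` gives the straight ideal helix.
#' Deterministic.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise_per_residue axial rise per residue, Angstrom (default 1.5).
#' @param twist_deg twist per residue, degrees (default 100, i.e. 3.6
#'   residues/turn).
#' @param radius helix radius (C-alpha distance from axis), Angstrom.
#' @param curvature_radius radius of axis curvature, Angstrom (`Inf` =
#'   straight).
#' @param chain_id,first_resno,label model metadata.
#' @return A [helix_model].
#' @export
generate_helix <- function(n_residues, rise_per_residue = 1.5,
                           twist_deg = 100, radius = 2.3,
                           curvature_radius = Inf, chain_id = "A",
                           first_resno = 1L, label = "ideal-helix") {
  stopifnot(n_residues >= 4)
  i <- seq_len(n_residues) - 1L
  theta <- i * twist_deg * pi / 180
  s <- i * rise_per_residue
  if (is.infinite(curvature_radius)) {
    xyz <- cbind(radius * cos(theta), radius * sin(theta), s)
  } else {
    Rc <- curvature_radius
    phi <- s / Rc
    # axis on a circle in the xz-plane; local frame: tangent T, normal N
    # (toward circle center), binormal B = y
    ax <- cbind(Rc * sin(phi), 0, Rc * (1 - cos(phi)))
    Tn <- cbind(cos(phi), 0, sin(phi))
    Nn <- cbind(-sin(phi), 0, cos(phi))
    Bn <- cbind(0, 1, 0)[rep(1, length(phi)), , drop = FALSE]
    xyz <- ax + radius * (cos(theta) * Nn + sin(theta) * Bn)
  }
  helix_model(resno = first_resno + i, xyz = xyz, chain_id = chain_id,
              source = label)
}

#' Generate an SAH-patterned protein sequence
#'
#' Builds a synthetic single-alpha-helix-like sequence: an underlying
#' E4K4-type repeat supplies i,i+3/i,i+4 opposite-charge (Glu-Lys) pairs,
#' `ion_pair_density` sets the fraction of positions that keep the charged
#' pattern (the rest become neutral polar residues), and
#' `basic_stripe_bias` converts positions whose helical-wheel angle falls in
#' one 120-degree sector into lysines with that probability, creating a basic
#' stripe on one face. Seeded and deterministic.
#'
#' @param length sequence length (>= 7).
#' @param ion_pair_density fraction in [0, 1] of positions retaining the
#'   charged repeat pattern.
#' @param basic_stripe_bias probability in [0, 1] of forcing Lys at positions
#'   on the stripe face.
#' @param seed integer seed.
#' @param id sequence label.
#' @param numbering_offset first-residue number.
#' @return A [protein_sequence].
#' @export
generate_sah_sequence <- function(length, ion_pair_density = 1,
                                  basic_stripe_bias = 0, seed = 1L,
                                  id = "sah-synthetic", numbering_offset = 1L) {
  stopifnot(length >= 7, ion_pair_density >= 0, ion_pair_density <= 1,
            basic_stripe_bias >= 0, basic_stripe_bias <= 1)
  with_seed(seed, {
    pattern <- rep(c("E", "E", "E", "E", "K", "K", "K", "K"),
                   length.out = length)
    neutral <- sample(c("A", "Q", "S", "T", "N"), length, replace = TRUE)
    keep <- stats::runif(length) < ion_pair_density
    res <- ifelse(keep, pattern, neutral)
    if (basic_stripe_bias > 0) {
      ang <- ((seq_len(length) - 1) * 100) %% 360
      on_face <- ang >= 300 | ang < 60  # 120-degree stripe around 0 degrees
      force_k <- on_face & stats::runif(length) < basic_stripe_bias
      res[force_k] <- "K"
    }
    protein_sequence(res, id = id, numbering_offset = numbering_offset)
  })
}
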