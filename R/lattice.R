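#' Configuration for the finite-lattice cooperative binding simulator
#'
#' Parameters of a finite one-dimensional lattice model in which protein
#' monomers with a footprint of `footprint_bp` base pairs bind
#' non-overlappingly to a DNA fragment of `L_bp` base pairs with intrinsic
#' association constant `K_assoc_per_nM` and a nearest-neighbor cooperativity
#' factor `omega` applied to each pair of abutting (directly adjacent) bound
#' monomers. This is the generative stand-in for EMSA band ladders: a DNA of
#' length L can carry at most `floor(L/footprint)` monomers, so the number of
#' shifted bands scales with fragment length.
#'
#' @param L_bp DNA fragment length, bp (>= 1).
#' @param footprint_bp monomer site size, bp (default 20).
#' @param K_assoc_per_nM intrinsic association constant per nM (> 0); the
#'   single-site dissociation constant is `1/K_assoc_per_nM`.
#' @param omega nearest-neighbor cooperativity (>= 0; 1 = non-cooperative).
#' @param conc_grid_nM protein concentration grid for titrations.
#' @param seed integer seed recorded for downstream renderers.
#' @return A list of class `lattice_config`.
#' @export
lattice_config <- function(L_bp, footprint_bp = 20L, K_assoc_per_nM = 0.02,
                           omega = 1,
                           conc_grid_nM = c(0, 9, 19, 37, 75, 150, 300, 600),
                           seed = 1L) {
  stopifnot(L_bp >= 1, footprint_bp >= 1, K_assoc_per_nM > 0, omega >= 0)
  structure(list(L_bp = as.integer(L_bp),
                 footprint_bp = as.integer(footprint_bp),
                 K_assoc_per_nM = K_assoc_per_nM, omega = omega,
                 conc_grid_nM = conc_grid_nM, seed = as.integer(seed)),
            class = "lattice_config")
}

# Configuration counts by (k ligands, a abutting pairs): matrix rows k=0..kmax,
# cols a=0..max(0,kmax-1). Exact DP over lattice positions.
lattice_counts <- function(L, m) {
  kmax <- L %/% m
  amax <- max(kmax - 1L, 0L)
  dimk <- kmax + 1L; dima <- amax + 1L
  # tot[i+1, k+1, a+1]: tilings of sites 1..i; end[...]: those with a ligand
  # ending exactly at site i
  tot <- array(0, c(L + 1L, dimk, dima))
  end <- array(0, c(L + 1L, dimk, dima))
  tot[1L, 1L, 1L] <- 1
  for (i in seq_len(L)) {
    tot[i + 1L, , ] <- tot[i, , ]
    if (i >= m) {
      for (k in seq_len(kmax)) {
        for (a in 0:amax) {
          new <- (tot[i - m + 1L, k, a + 1L] - end[i - m + 1L, k, a + 1L])
          if (a >= 1L) new <- new + end[i - m + 1L, k, a]
          if (new != 0) {
            end[i + 1L, k + 1L, a + 1L] <- end[i + 1L, k + 1L, a + 1L] + new
            tot[i + 1L, k + 1L, a + 1L] <- tot[i + 1L, k + 1L, a + 1L] + new
          }
        }
      }
    }
  }
  matrix(tot[L + 1L, , ], nrow = dimk, ncol = dima,
         dimnames = list(k = 0:kmax, a = 0:amax))
}

#' Occupancy distribution on a finite lattice at fixed free-protein
#' concentration
#'
#' Exact equilibrium distribution of the number of bound monomers computed
#' from the full partition function over all placements of non-overlapping
#' footprint-sized ligands, with statistical weight
#' `(K_assoc * [P])^k * omega^(number of abutting pairs)`. Accumulation is in
#' log space, so large concentrations or cooperativities do not overflow.
#'
#' @param config a [lattice_config].
#' @param free_ligand_nM free protein concentration, nM (scalar).
#' @return An object of class `occupancy_distribution`: list with `p`
#'   (probabilities for k = 0..k_max bound ligands), `k_max`,
#'   `mean_occupancy` and `free_ligand_nM`.
#' @export
lattice_partition <- function(config, free_ligand_nM) {
  stopifnot(inherits(config, "lattice_config"), free_ligand_nM >= 0)
  counts <- lattice_counts(config$L_bp, config$footprint_bp)
  kmax <- nrow(counts) - 1L
  x <- config$K_assoc_per_nM * free_ligand_nM
  # k = 0 term is always log(1) = 0
  logw_k <- vapply(0:kmax, function(k) {
    cts <- counts[k + 1L, ]
    a <- as.numeric(colnames(counts))
    base <- ifelse(cts > 0,
                   log(cts) + ifelse(a > 0, a * log(config$omega), 0), -Inf)
    lw <- logsumexp(base)
    if (k == 0) lw else if (x == 0) -Inf else lw + k * log(x)
  }, numeric(1))
  logZ <- logsumexp(logw_k)
  p <- exp(logw_k - logZ)
  structure(list(p = setNames(p, 0:kmax), k_max = kmax,
                 mean_occupancy = sum((0:kmax) * p),
                 free_ligand_nM = free_ligand_nM),
            class = "occupancy_distribution")
}

#' Simulate a lattice-binding titration
#'
#' Evaluates the lattice occupancy distribution along the configuration's
#' protein concentration grid. In trace-DNA mode (`dna_conc_nM = NULL`,
#' matching EMSA conditions of 1-3 nM DNA against a large protein excess)
#' free protein equals total protein. With `dna_conc_nM` set, the free-protein
#' concentration is solved per titration point from the mass balance
#' `P_total = P_free + [DNA] * E[k](P_free)` by bisection.
#'
#' @param config a [lattice_config].
#' @param dna_conc_nM DNA concentration for ligand-depletion mode, or `NULL`
#'   (default) for trace-DNA mode.
#' @return An object of class `occupancy_titration`: list with
#'   `conc_nM` (total protein grid), `free_nM`, `p` (matrix, one row per
#'   concentration, columns k = 0..k_max), `mean_occupancy`, and the config.
#' @export
simulate_titration <- function(config, dna_conc_nM = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  grid <- config$conc_grid_nM
  kmax <- config$L_bp %/% config$footprint_bp
  p <- matrix(NA_real_, length(grid), kmax + 1L,
              dimnames = list(NULL, 0:kmax))
  free <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ptot <- grid[i]
    pf <- if (is.null(dna_conc_nM) || ptot == 0) ptot else {
      f <- function(x) x + dna_conc_nM *
        lattice_partition(config, x)$mean_occupancy - ptot
      if (f(ptot) < 0) ptot else stats::uniroot(f, c(0, ptot), tol = 1e-10)$root
    }
    occ <- lattice_partition(config, pf)
    p[i, ] <- occ$p
    free[i] <- pf
  }
  structure(list(conc_nM = grid, free_nM = free, p = p,
                 mean_occupancy = drop(p %*% (0:kmax)), config = config),
            class = "occupancy_titration")
}
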