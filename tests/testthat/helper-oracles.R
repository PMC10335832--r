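# Independent oracles used to cross-check package computations.

# Brute-force enumeration of all placements of non-overlapping m-site ligands
# on an L-site lattice; returns a data frame of (k, a, count) where a is the
# number of abutting ligand pairs. Exponential -- only for small L.
enumerate_lattice <- function(L, m) {
  acc <- new.env()
  bump <- function(k, a) {
    key <- paste(k, a)
    acc[[key]] <- (acc[[key]] %||% 0) + 1
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  recur <- function(next_free, k, a, last_end) {
    bump(k, a)  # stop placing further ligands: one configuration
    if (next_free + m - 1 > L) return(invisible())
    for (s in next_free:(L - m + 1)) {
      recur(s + m, k + 1, a + as.integer(s == last_end + 1), s + m - 1)
    }
  }
  recur(1, 0, 0, -10)
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, " "))
  data.frame(k = as.integer(parts[, 1]), a = as.integer(parts[, 2]),
             count = vapply(keys, function(kk) acc[[kk]], numeric(1)),
             row.names = NULL)
}

# Occupancy probabilities from the enumeration, weight (K*P)^k * omega^a.
enumerate_occupancy <- function(L, m, K, omega, conc) {
  tab <- enumerate_lattice(L, m)
  x <- K * conc
  w <- tab$count * ifelse(tab$k == 0 & x == 0, 1, x^tab$k) * omega^tab$a
  p <- tapply(w, tab$k, sum)
  p <- p / sum(p)
  out <- numeric(max(tab$k) + 1)
  out[as.integer(names(p)) + 1] <- p
  out
}

# Coarse grid-search minimizer for the Hill isotherm: independent of the
# nonlinear least-squares route.
grid_search_hill <- function(conc, frac,
                             kd_grid = exp(seq(log(2), log(2000), length.out = 80)),
                             h_grid = seq(0.4, 5, by = 0.2),
                             bmax_grid = seq(0.7, 1.15, by = 0.05)) {
  grid <- expand.grid(kd = kd_grid, h = h_grid, bmax = bmax_grid)
  M <- t(apply(grid, 1, function(p) hill_fraction(conc, p[1], p[2], p[3])))
  rss <- rowSums((M - matrix(frac, nrow(grid), length(frac), byrow = TRUE))^2)
  as.list(grid[which.min(rss), ])
}

# Brute-force rigid-superposition RMSD: minimize over a grid of Euler-angle
# rotations, refined with a general-purpose optimizer. Independent of the
# SVD route.
rotation_grid_rmsd <- function(x, y, coarse_deg = 20) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  rot <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((yc %*% rot(ang) - xc)^2)))
  step <- coarse_deg * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                      b = seq(0, pi, by = step),
                      g = seq(0, 2 * pi - step, by = step))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt$value
}

# Shared fixture: a small noiseless gel-lane table following the Hill model.
make_hill_lanes <- function(kd = 30, h = 2, bmax = 1,
                            conc = c(0, 5, 10, 20, 40, 80, 160, 320),
                            total = 100, background = 0) {
  f <- hill_fraction(conc, kd, h, bmax)
  data.frame(lane_id = paste0("L", seq_along(conc)),
             protein_conc_nM = conc, background = background,
             free = total * (1 - f) + background,
             complex1 = total * f + background)
}
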