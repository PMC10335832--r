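#' C-alpha helix model
#'
#' @param resno strictly increasing residue numbers (author numbering).
#' @param xyz n x 3 matrix of C-alpha coordinates, Angstrom.
#' @param chain_id chain identifier.
#' @param source source label (file, generator, ...).
#' @return list of class `helix_model` with elements `resno`, `xyz`,
#'   `chain_id`, `source`.
#' @export
helix_model <- function(resno, xyz, chain_id = "A", source = "model") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(resno))
  if (length(resno) < 4L) stop("helix model needs >= 4 residues")
  if (is.unsorted(resno, strictly = TRUE))
    stop("residue numbers must be strictly increasing")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(resno = as.integer(resno), xyz = xyz,
                 chain_id = chain_id, source = source),
            class = "helix_model")
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf("helix_model [%s] chain %s: %d residues (%d-%d)\n",
              x$source, x$chain_id, length(x$resno), min(x$resno),
              max(x$resno)))
  invisible(x)
}

#' Read C-alpha models from a PDB or mmCIF file
#'
#' Extracts C-alpha traces per chain (first alternate location kept),
#' optionally restricted to a chain selection and residue range. Chain
#' breaks (gaps in residue numbering) are recorded in attribute `gaps`.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain optional character vector of chains to keep.
#' @param range optional `c(first, last)` residue-number range.
#' @return named list of [helix_model] objects, one per chain.
#' @export
read_structure <- function(path, chain = NULL, range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$elety == "CA", , drop = FALSE]
  alt_keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[alt_keep, , drop = FALSE]
  if (!is.null(chain)) {
    missing <- setdiff(chain, unique(at$chain))
    if (length(missing))
      stop("chain(s) not found: ", paste(missing, collapse = ", "))
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  if (!is.null(range))
    at <- at[at$resno >= range[1L] & at$resno <= range[2L], , drop = FALSE]
  out <- lapply(split(at, at$chain), function(d) {
    d <- d[!duplicated(d$resno), , drop = FALSE]
    d <- d[order(d$resno), , drop = FALSE]
    if (nrow(d) < 4L)
      stop("fewer than 4 C-alpha atoms in selection for chain ", d$chain[1L])
    m <- helix_model(d$resno, cbind(d$x, d$y, d$z), chain_id = d$chain[1L],
                     source = basename(path))
    gaps <- which(diff(d$resno) > 1L)
    attr(m, "gaps") <- if (length(gaps))
      data.frame(after_resno = d$resno[gaps],
                 gap_length = diff(d$resno)[gaps] - 1L) else NULL
    m
  })
  out
}

#' Write a C-alpha model as a minimal PDB file
#'
#' @param model a [helix_model].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(model, path) {
  n <- length(model$resno)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), model$chain_id, model$resno,
    model$xyz[, 1L], model$xyz[, 2L], model$xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Local helix axis by the second-difference (Kahn) construction: for C-alpha
# window i-1, i, i+1 the vector v_i = P_{i-1} - 2 P_i + P_{i+1} points from
# P_i toward the local axis; consecutive v's give the axis direction
# (v_i x v_{i+1}), the local twist angle (angle between v_i and v_{i+1})
# and the local radius r = |v| / (2 (1 - cos twist)).

#' Local helix axis from C-alpha coordinates
#'
#' Deterministic local axis construction from sliding windows of 4
#' consecutive C-alpha atoms. Returns one axis point per interior residue
#' and one axis direction and twist angle per residue step.
#'
#' @param model a [helix_model] with >= 4 residues.
#' @return list of class `helix_axis`: `points` (axis points for residues
#'   2..n-1), `directions` (unit axis directions per window), `twist_deg`
#'   (local twist per residue step), `radius` (local helix radius per
#'   window), `resno_points`, `resno_steps`.
#' @export
helix_axis <- function(model) {
  P <- model$xyz
  n <- nrow(P)
  if (n < 4L) stop("need >= 4 consecutive C-alpha atoms")
  v <- P[1:(n - 2L), , drop = FALSE] - 2 * P[2:(n - 1L), , drop = FALSE] +
    P[3:n, , drop = FALSE]                         # v for residues 2..n-1
  nv <- nrow(v)
  vn <- v / sqrt(rowSums(v^2))
  dots <- rowSums(vn[1:(nv - 1L), , drop = FALSE] *
                    vn[2:nv, , drop = FALSE])
  dots <- pmin(pmax(dots, -1), 1)
  twist <- acos(dots) * 180 / pi                   # per residue step
  dirs <- t(vapply(seq_len(nv - 1L), function(i) {
    d <- c(v[i, 2L] * v[i + 1L, 3L] - v[i, 3L] * v[i + 1L, 2L],
           v[i, 3L] * v[i + 1L, 1L] - v[i, 1L] * v[i + 1L, 3L],
           v[i, 1L] * v[i + 1L, 2L] - v[i, 2L] * v[i + 1L, 1L])
    d / sqrt(sum(d^2))
  }, numeric(3)))
  # local radius from |v| = 2 r (1 - cos twist); use adjacent twist per point
  tw_pt <- c(twist[1L], (twist[-length(twist)] + twist[-1L]) / 2, twist[length(twist)])
  tw_pt <- tw_pt[seq_len(nv)]
  r <- sqrt(rowSums(v^2)) / (2 * (1 - cos(tw_pt * pi / 180)))
  pts <- P[2:(n - 1L), , drop = FALSE] + vn * r
  structure(list(points = pts, directions = dirs, twist_deg = twist,
                 radius = r,
                 resno_points = model$resno[2:(n - 1L)],
                 resno_steps = model$resno[2:(n - 2L)]),
            class = "helix_axis")
}

#' Measure helix geometry
#'
#' Computes end-to-end length (terminal C-alpha distance), integrated axis
#' arc length (axis polyline extended by the mean axis spacing to cover the
#' terminal residues), number of helical turns (mean local twist times the
#' residue count / 360), the per-residue curvature profile (angular change
#' of the local axis direction per residue step, degrees) and the longest
#' contiguous region whose curvature exceeds `curvature_threshold`.
#'
#' @param model a [helix_model].
#' @param curvature_threshold degrees of axis bending per residue above
#'   which a residue counts as curved (default 1.5).
#' @return list of class `geometry_report`: `end_to_end_A`, `axis_arc_A`,
#'   `n_turns`, `mean_twist_deg`, `curvature` (data frame resno,
#'   curvature_deg_per_res), `curved_region` (`c(first, last)` residue
#'   numbers or `NULL`), `n_residues`.
#' @export
measure_geometry <- function(model, curvature_threshold = 1.5) {
  ax <- helix_axis(model)
  n <- length(model$resno)
  e2e <- sqrt(sum((model$xyz[n, ] - model$xyz[1L, ])^2))
  pts <- ax$points
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  mean_seg <- mean(seg)
  arc <- sum(seg) + 2 * mean_seg  # extend to cover both terminal residues
  mean_twist <- mean(ax$twist_deg)
  n_turns <- mean_twist * n / 360
  # curvature from the axis polyline smoothed over ~one helical turn
  # (4 points): the periodic wobble of single-window axis points cancels,
  # leaving the genuine axis bending per residue step
  w <- min(4L, nrow(pts) - 1L)
  ns <- nrow(pts) - w + 1L
  sm <- vapply(seq_len(ns), function(i)
    colMeans(pts[i:(i + w - 1L), , drop = FALSE]), numeric(3))
  sm <- t(sm)
  curv <- numeric(0)
  curv_resno <- integer(0)
  if (nrow(sm) >= 3L) {
    d <- diff(sm)
    d <- d / sqrt(rowSums(d^2))
    nd <- nrow(d)
    dots <- rowSums(d[1:(nd - 1L), , drop = FALSE] *
                      d[2:nd, , drop = FALSE])
    curv <- acos(pmin(pmax(dots, -1), 1)) * 180 / pi
    # smoothed point i averages axis points i..i+w-1 (residues 2..n-1);
    # the bend angle at smoothed point i+1 sits near its residue center
    centers <- ax$resno_points[seq_len(ns)] + (w - 1) / 2
    curv_resno <- as.integer(round(centers[2:(ns - 1L)]))
  }
  cprof <- data.frame(resno = curv_resno, curvature_deg_per_res = curv)
  curved_region <- NULL
  above <- curv > curvature_threshold
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    curved_region <- c(first = curv_resno[starts[best]],
                       last = curv_resno[ends[best]])
  }
  structure(list(end_to_end_A = e2e, axis_arc_A = arc, n_turns = n_turns,
                 mean_twist_deg = mean_twist, curvature = cprof,
                 curved_region = curved_region, n_residues = n,
                 chain_id = model$chain_id, source = model$source),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("geometry_report [%s chain %s]: %d residues\n",
              x$source, x$chain_id, x$n_residues))
  cat(sprintf("  end-to-end %.1f A, axis arc %.1f A, %.2f turns (mean twist %.2f deg/res)\n",
              x$end_to_end_A, x$axis_arc_A, x$n_turns, x$mean_twist_deg))
  if (!is.null(x$curved_region))
    cat(sprintf("  curved region: residues %d-%d\n",
                x$curved_region["first"], x$curved_region["last"]))
  invisible(x)
}

# Optimal least-squares rigid superposition (Kabsch, via SVD); returns the
# RMSD of y onto x after superposition on all rows.
kabsch_rmsd <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3L)
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  yr <- yc %*% R
  sqrt(mean(rowSums((yr - xc)^2)))
}

#' Pairwise superposition RMSD between C-alpha models
#'
#' Optimal rigid-body (Kabsch) superposition on the common residue numbers
#' of each model pair (optionally restricted to a range), then RMSD over the
#' superposed C-alpha positions.
#'
#' @param models list of [helix_model] objects (>= 2), optionally named.
#' @param range optional `c(first, last)` residue-number range.
#' @return symmetric matrix of class `rmsd_matrix` (Angstrom), zero
#'   diagonal; attribute `common_resno` gives the residue set used per pair
#'   count (list).
#' @export
pairwise_rmsd <- function(models, range = NULL) {
  stopifnot(length(models) >= 2L)
  labs <- names(models) %||% paste0("model", seq_along(models))
  if (is.null(names(models))) names(models) <- labs
  nm <- length(models)
  M <- matrix(0, nm, nm, dimnames = list(labs, labs))
  for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    ri <- models[[i]]$resno; rj <- models[[j]]$resno
    common <- intersect(ri, rj)
    if (!is.null(range))
      common <- common[common >= range[1L] & common <= range[2L]]
    if (length(common) < 4L)
      stop("models ", labs[i], " and ", labs[j],
           " share fewer than 4 common residues")
    xi <- models[[i]]$xyz[match(common, ri), , drop = FALSE]
    xj <- models[[j]]$xyz[match(common, rj), , drop = FALSE]
    M[i, j] <- M[j, i] <- kabsch_rmsd(xi, xj)
  }
  structure(M, class = c("rmsd_matrix", "matrix", "array"))
}
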