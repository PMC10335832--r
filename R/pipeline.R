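#' Read a delimited analysis table
#'
#' Reads tab- or comma-delimited tables with optional `#`-prefixed header
#' lines (as written by this package's writers).
#' @param path input file.
#' @param sep field separator (default tab).
#' @return data frame.
#' @export
read_table_file <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an analysis table with a provenance header
#'
#' Writes a tab-delimited table preceded by `#`-prefixed provenance lines
#' (package version, seed, arbitrary key-value pairs). Numeric columns are
#' rendered at a fixed precision so identical runs produce byte-identical
#' files.
#'
#' @param x data frame.
#' @param path output file.
#' @param provenance named list of key-value pairs to record.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(x, path, provenance = list(), digits = 10) {
  prov <- c(list(package = paste0("sahdna ",
                                  as.character(utils::packageVersion("sahdna"))),
                 written = "run"),
            provenance)
  hdr <- sprintf("# %s: %s", names(prov), vapply(prov, function(v)
    paste(as.character(v), collapse = " "), character(1)))
  xx <- as.data.frame(x)
  for (j in seq_along(xx)) if (is.numeric(xx[[j]]) && !is.integer(xx[[j]]))
    xx[[j]] <- formatC(xx[[j]], digits = digits, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(xx, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' Declarative configuration validated before execution: the analysis stage,
#' its input paths, model options and seed. Unknown options are rejected so
#' that config typos fail loudly.
#'
#' @param stage one of `"emsa_fit"`, `"ladder"`, `"cd_mre"`, `"cd_helicity"`,
#'   `"cd_melt"`, `"seq_charge"`, `"seq_pairs"`, `"seq_face"`,
#'   `"structure_geometry"`, `"structure_rmsd"`.
#' @param inputs named list of input file paths (stage dependent).
#' @param options named list of stage options (e.g. `mode`, `window`,
#'   `h_charge`, `censor_threshold`, `fix_bmax`, `chain`, `range`,
#'   `theta_u`, `theta_h`).
#' @param seed integer seed recorded in all outputs.
#' @param out_dir output directory (created if missing).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(stage, inputs = list(), options = list(), seed = 1L,
                       out_dir = ".") {
  stages <- c("emsa_fit", "ladder", "cd_mre", "cd_helicity", "cd_melt",
              "seq_charge", "seq_pairs", "seq_face", "structure_geometry",
              "structure_rmsd")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; must be one of: ",
         paste(stages, collapse = ", "))
  for (nm in names(inputs)) {
    p <- inputs[[nm]]
    if (!is.character(p) || !file.exists(p))
      stop("input path for field '", nm, "' does not exist: ", p)
  }
  structure(list(stage = stage, inputs = inputs, options = options,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Execute a configured pipeline stage
#'
#' Runs the requested stage on its inputs and writes result tables (with a
#' provenance header echoing the config and seed) into the configured output
#' directory. Deterministic: identical config and seed give byte-identical
#' outputs.
#'
#' @param config a [run_config].
#' @return list with elements `result` (the stage's R object) and `files`
#'   (paths written), invisibly returned by stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  opt <- config$options
  prov <- list(stage = config$stage, seed = config$seed)
  outfile <- function(name) file.path(config$out_dir, name)
  files <- character(0)
  result <- switch(config$stage,
    emsa_fit = {
      lanes <- read_table_file(config$inputs$lanes)
      ser <- fraction_bound(lanes, mode = opt$mode %||% "bound-over-total")
      fit <- fit_hill(ser, fix_bmax = opt$fix_bmax, fix_h = opt$fix_h)
      tab <- data.frame(label = attr(ser, "label"),
                        dna_length_bp = attr(ser, "dna_length_bp"),
                        kd_nM = fit$kd_nM, kd_se = fit$se["kd_nM"],
                        hill_h = fit$hill_h, h_se = fit$se["h"],
                        bmax = fit$bmax, rss = fit$rss, n = fit$n,
                        converged = fit$converged)
      files <- c(files, write_table_file(tab, outfile("hill_fit.tsv"), prov))
      fit
    },
    ladder = {
      ladder <- read_table_file(config$inputs$ladder)
      res <- analyze_ladder(ladder,
                            censor_threshold = opt$censor_threshold %||% 0.2,
                            fix_bmax = opt$fix_bmax)
      files <- c(files,
                 write_table_file(res$fits, outfile("ladder_fits.tsv"), prov),
                 write_table_file(res$slope$slopes,
                                  outfile("ladder_slopes.tsv"), prov),
                 write_table_file(res$kdapp_summary,
                                  outfile("ladder_kdapp_summary.tsv"), prov))
      res
    },
    cd_mre = {
      spec <- read_cd_file(config$inputs$spectrum, opt)
      m <- mre(spec)
      files <- c(files, write_table_file(m, outfile("mre.tsv"), prov))
      m
    },
    cd_helicity = {
      spec <- read_cd_file(config$inputs$spectrum, opt)
      fh <- fractional_helicity(mre222(spec),
                                theta_u = opt$theta_u %||% -3000,
                                theta_h = opt$theta_h %||% -39000)
      tab <- data.frame(label = attr(spec, "label"),
                        mre222 = mre222(spec), fractional_helicity = fh)
      files <- c(files, write_table_file(tab, outfile("helicity.tsv"), prov))
      fh
    },
    cd_melt = {
      d <- read_table_file(config$inputs$melt)
      cur <- melt_curve(d[[1L]], d[[2L]])
      fit <- fit_melt(cur, dH_floor_kJ = opt$dH_floor_kJ %||% 40)
      tab <- data.frame(tm_C = fit$tm_C, dH_kJ = fit$dH_kJ,
                        model_class = fit$model_class,
                        delta_aic = fit$delta_aic, converged = fit$converged)
      files <- c(files, write_table_file(tab, outfile("melt_fit.tsv"), prov))
      fit
    },
    seq_charge = {
      seqs <- read_protein_fasta(config$inputs$fasta,
                                 numbering_offset = opt$numbering_offset %||% 1L)
      scheme <- charge_scheme(h_charge = opt$h_charge %||% 0)
      profs <- lapply(seqs, sliding_net_charge, window = opt$window %||% 7L,
                      scheme = scheme)
      for (i in seq_along(profs))
        files <- c(files, write_table_file(
          profs[[i]], outfile(sprintf("charge_%s.tsv", names(seqs)[i])),
          c(prov, list(window = opt$window %||% 7L,
                       h_charge = opt$h_charge %||% 0))))
      profs
    },
    seq_pairs = {
      seqs <- read_protein_fasta(config$inputs$fasta,
                                 numbering_offset = opt$numbering_offset %||% 1L)
      scheme <- charge_scheme(h_charge = opt$h_charge %||% 0)
      nets <- lapply(seqs, predict_ion_pairs, scheme = scheme)
      for (i in seq_along(nets))
        files <- c(files, write_table_file(
          nets[[i]], outfile(sprintf("pairs_%s.tsv", names(seqs)[i])), prov))
      nets
    },
    seq_face = {
      seqs <- read_protein_fasta(config$inputs$fasta,
                                 numbering_offset = opt$numbering_offset %||% 1L)
      scheme <- charge_scheme(h_charge = opt$h_charge %||% 0)
      reps <- lapply(seqs, helical_face_bias, scheme = scheme,
                     sector_width_deg = opt$sector_width_deg %||% 60)
      tab <- do.call(rbind, lapply(reps, function(r)
        data.frame(id = r$id, total_charge = r$total_charge,
                   max_sector_start_deg = r$max_basic_sector$start_deg,
                   max_sector_charge = r$max_basic_sector$net_charge,
                   bias_index = r$bias_index)))
      files <- c(files, write_table_file(tab, outfile("face_bias.tsv"), prov))
      reps
    },
    structure_geometry = {
      models <- read_structure(config$inputs$structure, chain = opt$chain,
                               range = opt$range)
      geos <- lapply(models, measure_geometry,
                     curvature_threshold = opt$curvature_threshold %||% 1.5)
      tab <- do.call(rbind, lapply(geos, function(g)
        data.frame(chain = g$chain_id, n_residues = g$n_residues,
                   end_to_end_A = g$end_to_end_A, axis_arc_A = g$axis_arc_A,
                   n_turns = g$n_turns, mean_twist_deg = g$mean_twist_deg)))
      files <- c(files, write_table_file(tab, outfile("geometry.tsv"), prov))
      for (g in geos)
        files <- c(files, write_table_file(
          g$curvature, outfile(sprintf("curvature_%s.tsv", g$chain_id)), prov))
      geos
    },
    structure_rmsd = {
      models <- read_structure(config$inputs$structure, chain = opt$chain,
                               range = opt$range)
      M <- pairwise_rmsd(models, range = opt$range)
      tab <- as.data.frame(as.table(unclass(M)))
      names(tab) <- c("model_i", "model_j", "rmsd_A")
      files <- c(files, write_table_file(tab, outfile("rmsd.tsv"), prov))
      M
    })
  list(result = result, files = files)
}

read_cd_file <- function(path, opt) {
  d <- read_table_file(path)
  cd_spectrum(d[[1L]], d[[2L]], MW = opt$MW %||% NA_real_,
              n_residues = opt$n_residues %||% NA_integer_,
              path_cm = opt$path_cm %||% NA_real_,
              conc_g_per_L = opt$conc_g_per_L %||% NA_real_,
              label = opt$label %||% basename(path))
}
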