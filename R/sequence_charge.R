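AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Protein sequence with author numbering
#'
#' A light container for a one-letter amino-acid sequence, keeping the residue
#' number of the first position so that analyses report positions in the
#' protein's own numbering (e.g. 136 for the N-terminus of the yeast Cac1 KER).
#'
#' @param residues character; either a single string or a vector of one-letter
#'   codes drawn from the 20 standard amino acids.
#' @param id sequence label.
#' @param numbering_offset residue number of the first position (>= 1).
#' @return An object of class `protein_sequence`: a character vector of
#'   one-letter codes with attributes `id` and `numbering_offset`.
#' @examples
#' protein_sequence("KELKEKR", id = "toy", numbering_offset = 10)
#' @export
protein_sequence <- function(residues, id = "seq", numbering_offset = 1L) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) stop("sequence must have length >= 1")
  bad <- setdiff(unique(residues), AA1)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L)
    stop("numbering_offset must be >= 1")
  structure(residues, id = as.character(id),
            numbering_offset = numbering_offset,
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence '%s': %d aa, first residue %d\n",
              attr(x, "id"), length(x), attr(x, "numbering_offset")))
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (multi-record allowed).
#' @param numbering_offset first-residue number applied to every record
#'   (single value or vector recycled across records).
#' @return A list of [protein_sequence] objects, named by record id.
#' @export
read_protein_fasta <- function(path, numbering_offset = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE)
  offs <- rep_len(as.integer(numbering_offset), length(recs))
  out <- mapply(function(s, nm, off) protein_sequence(toupper(s), id = nm,
                                                      numbering_offset = off),
                recs, names(recs), offs, SIMPLIFY = FALSE)
  out
}

#' Per-residue charge scheme
#'
#' Assigns +1 to Lys/Arg, -1 to Asp/Glu and 0 to all other residues.
#' Histidine is neutral by default (pH ~7.4); set `h_charge` in [0, 1] to
#' count it as (partially) basic, matching figure colorings that treat His
#' as positive.
#'
#' @param h_charge charge assigned to histidine, in [0, 1]. Default 0.
#' @return Named numeric vector over the 20 standard residues, class
#'   `charge_scheme`.
#' @export
charge_scheme <- function(h_charge = 0) {
  if (!is.numeric(h_charge) || length(h_charge) != 1L ||
      h_charge < 0 || h_charge > 1)
    stop("h_charge must be a single value in [0, 1]")
  ch <- setNames(numeric(length(AA1)), AA1)
  ch[c("K", "R")] <- 1
  ch[c("D", "E")] <- -1
  ch["H"] <- h_charge
  structure(ch, class = "charge_scheme")
}

residue_charges <- function(seq, scheme) {
  seq <- as_protein_sequence(seq)
  unname(unclass(scheme)[unclass(seq)])
}

as_protein_sequence <- function(x) {
  if (inherits(x, "protein_sequence")) x else protein_sequence(x)
}

#' Sliding-window net charge along a sequence
#'
#' Computes the net charge in a sliding window of `window` residues and
#' assigns each value to the central residue of the window (the 4th residue
#' for the default window of 7), reported in the sequence's own numbering.
#'
#' @param seq a [protein_sequence] (or a string, coerced with offset 1).
#' @param window odd window length; must not exceed the sequence length.
#' @param scheme a [charge_scheme].
#' @return A data frame of class `charge_profile` with columns `position`
#'   (residue number of the window center) and `net_charge`; attributes
#'   `window` and `id`.
#' @examples
#' sliding_net_charge(protein_sequence("KELKEKR"), window = 7)
#' @export
sliding_net_charge <- function(seq, window = 7L, scheme = charge_scheme()) {
  seq <- as_protein_sequence(seq)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > length(seq)) stop("sequence too short for window")
  ch <- residue_charges(seq, scheme)
  n <- length(ch)
  nw <- n - window + 1L
  vals <- as.numeric(stats::filter(ch, rep(1, window), sides = 2))
  center0 <- (window + 1L) %/% 2L            # index of assigned residue in window
  idx <- seq.int(center0, center0 + nw - 1L) # residue indices carrying a value
  off <- attr(seq, "numbering_offset")
  out <- data.frame(position = off + idx - 1L, net_charge = vals[idx])
  structure(out, window = window, id = attr(seq, "id"),
            class = c("charge_profile", "data.frame"))
}

#' Predict i,i+3 and i,i+4 ion pairs
#'
#' Enumerates every pair of residues three or four positions apart that carry
#' opposite nonzero charges under `scheme` -- the intrahelical salt-bridge
#' geometry that stabilizes single alpha-helix (SAH) motifs. A residue may
#' participate in several pairs.
#'
#' @inheritParams sliding_net_charge
#' @return A data frame of class `ion_pair_network` with columns `pos_i`,
#'   `pos_j` (sequence numbering), `spacing` (3 or 4) and `orientation`
#'   ("acid-first" or "base-first"); attribute `participates`, a logical
#'   vector flagging residues appearing in at least one pair.
#' @export
predict_ion_pairs <- function(seq, scheme = charge_scheme()) {
  seq <- as_protein_sequence(seq)
  n <- length(seq)
  if (n < 4L) stop("sequence length must be >= 4")
  ch <- residue_charges(seq, scheme)
  off <- attr(seq, "numbering_offset")
  rows <- list()
  for (s in c(3L, 4L)) {
    if (n <= s) next
    i <- seq_len(n - s)
    keep <- ch[i] != 0 & ch[i + s] != 0 & sign(ch[i]) != sign(ch[i + s])
    if (any(keep)) {
      ii <- i[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        pos_i = off + ii - 1L, pos_j = off + ii + s - 1L, spacing = s,
        orientation = ifelse(ch[ii] < 0, "acid-first", "base-first"))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos_i = integer(), pos_j = integer(), spacing = integer(),
               orientation = character())
  out <- out[order(out$pos_i, out$spacing), , drop = FALSE]
  rownames(out) <- NULL
  part <- logical(n)
  part[c(out$pos_i, out$pos_j) - off + 1L] <- TRUE
  structure(out, participates = part, id = attr(seq, "id"),
            class = c("ion_pair_network", "data.frame"))
}

#' Helical-wheel charge face bias
#'
#' Projects residues onto a helical wheel (default 100 degrees of twist per
#' residue, i.e. 3.6 residues/turn) and quantifies how strongly charge is
#' concentrated on one face. Fixed angular bins give a partition whose sector
#' charges sum to the total net charge; a sliding sector scan (1-degree steps)
#' locates the most basic face.
#'
#' @inheritParams sliding_net_charge
#' @param twist_deg_per_residue helical twist per residue in degrees.
#' @param sector_width_deg angular sector width in degrees; for the fixed-bin
#'   partition it must divide 360.
#' @return A list of class `face_bias_report`: `sectors` (fixed-bin data frame
#'   with `start_deg`, `end_deg`, `net_charge`), `max_basic_sector` (start
#'   angle, width, net charge of the most basic sliding sector; ties broken by
#'   smallest start angle), `bias_index` (max sliding-sector charge minus the
#'   mean sliding-sector charge), `total_charge`, and the residue `angles`.
#' @export
helical_face_bias <- function(seq, scheme = charge_scheme(),
                              twist_deg_per_residue = 100,
                              sector_width_deg = 60) {
  seq <- as_protein_sequence(seq)
  ch <- residue_charges(seq, scheme)
  n <- length(ch)
  angles <- ((seq_len(n) - 1) * twist_deg_per_residue) %% 360
  if (360 %% sector_width_deg != 0)
    stop("sector_width_deg must divide 360 for the fixed-bin partition")
  starts <- seq(0, 360 - sector_width_deg, by = sector_width_deg)
  bin_charge <- vapply(starts, function(s)
    sum(ch[angles >= s & angles < s + sector_width_deg]), numeric(1))
  sectors <- data.frame(start_deg = starts,
                        end_deg = starts + sector_width_deg,
                        net_charge = bin_charge)
  # sliding scan at 1-degree resolution, wrapping across 360
  scan_starts <- 0:359
  scan_charge <- vapply(scan_starts, function(s) {
    rel <- (angles - s) %% 360
    sum(ch[rel < sector_width_deg])
  }, numeric(1))
  best <- which.max(scan_charge)  # first max = smallest start angle
  structure(list(
    sectors = sectors,
    max_basic_sector = list(start_deg = scan_starts[best],
                            width_deg = sector_width_deg,
                            net_charge = scan_charge[best]),
    bias_index = scan_charge[best] - mean(scan_charge),
    total_charge = sum(ch),
    angles = angles,
    id = attr(seq, "id")), class = "face_bias_report")
}

#' @export
print.face_bias_report <- function(x, ...) {
  cat(sprintf("face_bias_report '%s': total charge %+g\n", x$id, x$total_charge))
  cat(sprintf("  most basic sector: [%d, %d) deg, net charge %+g\n",
              x$max_basic_sector$start_deg,
              x$max_basic_sector$start_deg + x$max_basic_sector$width_deg,
              x$max_basic_sector$net_charge))
  cat(sprintf("  bias index: %.3f\n", x$bias_index))
  invisible(x)
}

#' Write a charge profile or ion-pair table to a delimited file
#'
#' Tab-delimited output with `#`-prefixed header lines recording the sequence
#' id and analysis parameters.
#' @param x a `charge_profile` or `ion_pair_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(x, path) {
  hdr <- c(sprintf("# id: %s", attr(x, "id")),
           if (!is.null(attr(x, "window")))
             sprintf("# window: %d", attr(x, "window")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
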