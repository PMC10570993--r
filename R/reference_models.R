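# Reference units: the per-spoke label-site tables that seed every simulation.
#
# A "rotational unit" (RU) holds one spoke's fluorophore attachment sites,
# each encoded by an axial position z, a radius r from the central axis, an
# in-plane angle alpha relative to the other sites, and a subcomplex tag.
# All lengths are nanometres once loaded.

#' @name npc_ru
#' @title Rotational-unit objects
#' @description An `npc_ru` is a list with elements `model_id` (character)
#'   and `sites`, a data frame with one row per fluorophore attachment site
#'   and columns `nup_name`, `terminus` (`"N"` or `"C"`), `copy` (integer
#'   copy index within the RU), `z`, `r` (nm), `alpha` (radians, in
#'   `[-pi, pi)`) and `subcomplex` (one of CR, BRCR, IR, BRNR, NR). Angles
#'   are measured counter-clockwise in the x-y plane viewed from the
#'   cytoplasmic side; the cytoplasmic side is +z.
NULL

#' The five subcomplex tags
#'
#' Cytoplasmic ring (CR), bridge CR-IR (BRCR), inner ring (IR), bridge
#' IR-NR (BRNR) and nucleoplasmic ring (NR), ordered cytoplasmic to
#' nucleoplasmic.
#' @export
SUBCOMPLEXES <- c("CR", "BRCR", "IR", "BRNR", "NR")

wrap_angle <- function(a) {
  # wrap to [-pi, pi)
  ((a + pi) %% (2 * pi)) - pi
}

validate_ru_sites <- function(sites) {
  needed <- c("nup_name", "terminus", "copy", "z", "r", "alpha", "subcomplex")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    stop("reference-unit table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(sites) < 1) stop("reference unit must contain at least one site")
  if (!all(sites$terminus %in% c("N", "C"))) {
    stop("terminus must be 'N' or 'C'")
  }
  if (!all(sites$subcomplex %in% SUBCOMPLEXES)) {
    stop("subcomplex must be one of: ", paste(SUBCOMPLEXES, collapse = ", "))
  }
  if (any(!is.finite(sites$r)) || any(sites$r <= 0)) {
    stop("all radii must be finite and > 0")
  }
  if (any(!is.finite(sites$z)) || any(!is.finite(sites$alpha))) {
    stop("z and alpha must be finite")
  }
  key <- paste(sites$nup_name, sites$terminus, sites$copy)
  if (anyDuplicated(key)) {
    stop("duplicate (nup_name, terminus, copy) rows in reference unit")
  }
  invisible(sites)
}

new_ru <- function(model_id, sites) {
  sites$alpha <- wrap_angle(sites$alpha)
  validate_ru_sites(sites)
  structure(list(model_id = model_id, sites = sites), class = "npc_ru")
}

#' Build a synthetic rotational unit
#'
#' Constructs an `npc_ru` from explicit site values, used as a self-contained
#' stand-in for label-site tables derived from pseudoatomic NPC models. All
#' lengths in nm, angles in radians.
#'
#' @param z,r,alpha numeric vectors of length `g` (one element per site).
#' @param subcomplex character vector of length `g`, values from
#'   [SUBCOMPLEXES].
#' @param nup_name,terminus site labels, recycled to length `g`.
#' @return an [npc_ru] with `model_id = "synthetic"`.
#' @examples
#' make_synthetic_ru(z = c(25, -25), r = c(53.7, 53.7), alpha = c(0, 0),
#'                   subcomplex = c("CR", "NR"))
#' @export
make_synthetic_ru <- function(z, r, alpha, subcomplex,
                              nup_name = "SynNup", terminus = "N") {
  g <- length(z)
  if (length(r) != g || length(alpha) != g || length(subcomplex) != g) {
    stop("z, r, alpha and subcomplex must all have the same length")
  }
  nup_name <- rep_len(nup_name, g)
  terminus <- rep_len(terminus, g)
  copy <- stats::ave(seq_len(g), paste(nup_name, terminus),
                     FUN = seq_along)
  sites <- data.frame(
    nup_name = nup_name, terminus = terminus, copy = as.integer(copy),
    z = as.numeric(z), r = as.numeric(r), alpha = as.numeric(alpha),
    subcomplex = subcomplex, stringsAsFactors = FALSE
  )
  new_ru("synthetic", sites)
}

#' Default two-ring synthetic reference unit
#'
#' One site on the cytoplasmic ring and one on the nucleoplasmic ring,
#' emulating a C-terminally tagged outer-ring scaffold Nup: radius 53.7 nm
#' (the fitted radius reported for Nup96 reference data) and a 50 nm
#' CR-NR distance.
#'
#' @param r ring radius, nm.
#' @param d CR-NR axial distance, nm.
#' @return an [npc_ru] with two sites.
#' @export
synthetic_tworing_ru <- function(r = 53.7, d = 50) {
  make_synthetic_ru(
    z = c(d / 2, -d / 2), r = c(r, r), alpha = c(0, 0),
    subcomplex = c("CR", "NR"), nup_name = "SynNup", terminus = "C"
  )
}

#' Load a label-site table
#'
#' Reads a comma-separated model table with a header and columns `model_id`,
#' `nup_name`, `terminus`, `copy`, `z`, `r`, `alpha`, `subcomplex`, `unit`.
#' Lengths declared in angstrom (`unit = "angstrom"`) are converted to nm
#' (divided by 10); angles are radians. Row order is preserved as band order.
#'
#' @param path path to the CSV table.
#' @return an [npc_ru] with all lengths in nm.
#' @export
load_model_table <- function(path) {
  if (!file.exists(path)) stop("model table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("model_id", "nup_name", "terminus", "copy", "z", "r",
              "alpha", "subcomplex", "unit")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("model table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(tab$unit %in% c("nm", "angstrom"))) {
    stop("unit column must be 'nm' or 'angstrom'")
  }
  scale <- ifelse(tab$unit == "angstrom", 0.1, 1)
  sites <- data.frame(
    nup_name = tab$nup_name, terminus = tab$terminus,
    copy = as.integer(tab$copy),
    z = tab$z * scale, r = tab$r * scale, alpha = tab$alpha,
    subcomplex = tab$subcomplex, stringsAsFactors = FALSE
  )
  new_ru(unique(tab$model_id)[1], sites)
}

#' Write a label-site table
#'
#' Inverse of [load_model_table()]: writes the RU in nm so that a reload
#' reproduces it exactly.
#'
#' @param ru an [npc_ru].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(ru, path) {
  tab <- cbind(model_id = ru$model_id, ru$sites, unit = "nm")
  write_csv_exact(tab, path)
  invisible(path)
}

#' Define a multichannel label selection
#'
#' Up to six (Nup, terminus) channels may be selected. With
#' `reference = TRUE` the first channel acts as the reference: the global
#' angular offset is chosen so the reference channel's mean angle is zero,
#' which makes the reference Nup's simulated variability comparable between
#' single- and multichannel runs.
#'
#' @param nup_name character vector of Nup names (one per channel).
#' @param terminus character vector, `"N"`/`"C"`, recycled.
#' @param reference logical; is the first channel the reference?
#' @return a `label_selection` object.
#' @export
label_selection <- function(nup_name, terminus = "N", reference = FALSE) {
  n <- length(nup_name)
  if (n < 1 || n > 6) stop("between 1 and 6 channels must be selected")
  terminus <- rep_len(terminus, n)
  if (!all(terminus %in% c("N", "C"))) stop("terminus must be 'N' or 'C'")
  structure(list(
    channels = data.frame(nup_name = nup_name, terminus = terminus,
                          stringsAsFactors = FALSE),
    reference_is_first = isTRUE(reference)
  ), class = "label_selection")
}

#' Resolve a label selection into band specifications
#'
#' Picks the selected sites from the rotational unit and applies the global
#' angular offset: for a single channel the arithmetic mean of the site
#' angles becomes 0; with a reference channel the reference mean becomes 0
#' and every other channel is shifted by the same amount; without a
#' reference all selected channels are pooled and the pooled mean becomes 0.
#' z, r, subcomplex and within-channel angle differences are never changed.
#'
#' @param ru an [npc_ru].
#' @param sel a [label_selection()], or a character vector of Nup names as a
#'   shorthand for a reference-free selection of N-termini.
#' @return an `npc_bands` data frame with one row (band) per selected site:
#'   columns `z`, `r`, `alpha`, `channel`, `nup_name`, `terminus`,
#'   `subcomplex`; attribute `g` is the number of bands.
#' @export
select_labels <- function(ru, sel) {
  if (is.character(sel)) sel <- label_selection(sel)
  stopifnot(inherits(ru, "npc_ru"), inherits(sel, "label_selection"))
  ch <- sel$channels
  rows <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    idx <- which(ru$sites$nup_name == ch$nup_name[i] &
                   ru$sites$terminus == ch$terminus[i])
    if (length(idx) == 0) {
      stop("no site for (", ch$nup_name[i], ", ", ch$terminus[i],
           ") in model ", ru$model_id)
    }
    sl <- ru$sites[idx, , drop = FALSE]
    rows[[i]] <- data.frame(
      z = sl$z, r = sl$r, alpha = sl$alpha, channel = i,
      nup_name = sl$nup_name, terminus = sl$terminus,
      subcomplex = sl$subcomplex, stringsAsFactors = FALSE
    )
  }
  bands <- do.call(rbind, rows)
  offset <- if (sel$reference_is_first && nrow(ch) > 1) {
    mean(bands$alpha[bands$channel == 1])
  } else {
    mean(bands$alpha)
  }
  bands$alpha <- bands$alpha - offset
  out <- bands[bands$alpha < -pi | bands$alpha >= pi, "alpha"]
  if (length(out) > 0) {
    bands$alpha <- wrap_angle(bands$alpha)
  }
  rownames(bands) <- NULL
  structure(bands, g = nrow(bands), class = c("npc_bands", "data.frame"))
}

#' Extract a rotational unit from a PDB structure (optional helper)
#'
#' Convenience wrapper around `bio3d` that reads a pseudoatomic NPC model,
#' takes the first and last resolved residue of each requested chain as the
#' N- and C-terminal attachment sites, and converts their coordinates into
#' the (z, r, alpha) encoding relative to a user-supplied central axis.
#' Requires the PDB (or mmCIF converted to PDB) file locally; it is a
#' documented utility, not part of the tested simulation core.
#'
#' @param path PDB file path.
#' @param chains character vector of chain identifiers forming one spoke.
#' @param nup_names names to assign, parallel to `chains`.
#' @param subcomplex subcomplex tags, parallel to `chains`.
#' @param center x-y position of the central axis in the model frame
#'   (angstrom), default `c(0, 0)`.
#' @return an [npc_ru] in nm with two sites (N and C) per chain.
#' @export
ru_from_pdb <- function(path, chains, nup_names, subcomplex,
                        center = c(0, 0)) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("ru_from_pdb requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  rows <- list()
  for (i in seq_along(chains)) {
    cc <- ca[ca$chain == chains[i], ]
    if (nrow(cc) == 0) stop("chain not found: ", chains[i])
    for (term in c("N", "C")) {
      at <- if (term == "N") cc[1, ] else cc[nrow(cc), ]
      dx <- at$x - center[1]
      dy <- at$y - center[2]
      rows[[length(rows) + 1]] <- data.frame(
        nup_name = nup_names[i], terminus = term, copy = 1L,
        z = at$z / 10, r = sqrt(dx^2 + dy^2) / 10, alpha = atan2(dy, dx),
        subcomplex = subcomplex[i], stringsAsFactors = FALSE
      )
    }
  }
  new_ru(basename(path), do.call(rbind, rows))
}
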