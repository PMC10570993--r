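# Experiment harness: class datasets and the radius-variability sweep.

#' Class presets of commonly observed or hypothesized NPC variability
#'
#' Eight named classes: unmodified reference NPCs, smaller radius, smaller
#' CR-NR distance, elongated NPCs, a 14 degree twist angle, 9-fold
#' symmetry, laterally shifted outer rings, and independently tilted outer
#' rings. The twist angle (14 degrees) and the deviant symmetry (9-fold)
#' follow reported observations; the remaining magnitudes are editable
#' defaults chosen to be clearly visible against the reference geometry
#' (10% radius reduction, 20 nm smaller ring distance, axis ratio 0.8,
#' 3 nm shift SD, concentration 50 for tilt).
#'
#' Each preset is a list of [simulation_config()] arguments layered over a
#' base configuration by [run_class_dataset()].
#'
#' @param base_radius reference mean radius, nm, used to derive the
#'   smaller-radius class.
#' @param base_height reference CR-NR distance, nm.
#' @return named list of parameter lists.
#' @export
npc_class_presets <- function(base_radius = 53.7, base_height = 50) {
  list(
    reference       = list(),
    smaller_radius  = list(mean_radius = 0.9 * base_radius),
    smaller_height  = list(height = base_height - 20),
    elongated       = list(q = 0.8),
    twist_14deg     = list(twist = 14 * pi / 180),
    ninefold        = list(s = 9),
    shifted         = list(shift_sd = 3),
    tilted          = list(kappa = 50)
  )
}

#' The two twist modes used for bimodality studies
#'
#' Two single-parameter classes with twist angles of 9.6 and 14 degrees,
#' the two reported twist modes, for testing whether an analysis method
#' recovers a bimodal twist distribution.
#'
#' @return named list of preset parameter lists.
#' @export
twist_mode_classes <- function() {
  list(
    twist_9p6deg = list(twist = 9.6 * pi / 180),
    twist_14deg  = list(twist = 14 * pi / 180)
  )
}

apply_preset <- function(base_args, preset) {
  args <- base_args
  args[names(preset)] <- preset
  do.call(simulation_config, args)
}

#' Simulate class datasets over a grid of deformation magnitudes
#'
#' For every class preset and every `dmag`, simulates `n` NPCs, extracts
#' features, and (optionally) writes the run to
#' `out_dir/<class>_dmag<dmag>/`. Cells derive their seeds from the master
#' seed, so the whole plan is reproducible from one integer.
#'
#' @param classes named list of preset parameter lists
#'   (default [npc_class_presets()]).
#' @param dmags deformation magnitudes to cross with the classes
#'   (default `c(0, 1, 5, 10, 15)`).
#' @param n NPCs per cell.
#' @param seed master seed.
#' @param x band specification or rotational unit (default the two-ring
#'   synthetic reference unit).
#' @param out_dir if not `NULL`, every cell is written via [write_run()].
#' @param base_args named list of [simulation_config()] arguments shared by
#'   all classes.
#' @return a manifest data frame: one row per cell with class, dmag, seed,
#'   n, output path, mean fitted radius and mean ellipse RSS.
#' @export
run_class_dataset <- function(classes = npc_class_presets(),
                              dmags = c(0, 1, 5, 10, 15),
                              n = 10, seed = 1,
                              x = synthetic_tworing_ru(),
                              out_dir = NULL, base_args = list()) {
  bands <- bands_from_input(x)
  manifest <- list()
  cell <- 0L
  for (cls in names(classes)) {
    for (dm in dmags) {
      cell <- cell + 1L
      cell_seed <- derive_seed(seed, "placement", cell)
      args <- base_args
      args$n_npcs <- n
      args$dmag <- dm
      args$seed <- cell_seed
      cfg <- apply_preset(args, classes[[cls]])
      run <- simulate_run(bands, cfg)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, sprintf("%s_dmag%g", cls, dm))
        write_run(run, path)
      }
      manifest[[cell]] <- data.frame(
        class = cls, dmag = dm, seed = cell_seed, n = n, path = path,
        mean_radius = mean(run$features$npc$radius),
        mean_ellipse_rss = mean(run$features$npc$ellipse_rss),
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  manifest
}

#' Radius-variability sweep and comparison against a real-data SD
#'
#' Sweeps the two parameters that contribute to the variability of fitted
#' NPC radii -- the per-NPC SD of the model radius (`r_sigmas`) and the
#' irregular deformation magnitude (`dmags`) -- simulating `n` NPCs per
#' cell. The per-NPC radius is the mean of the per-band 3D circle-fit radii.
#' Each cell reports the dataset mean and SD of per-NPC radii and the
#' comparison ratio [radius_sd_ratio()] against `sd_real`.
#'
#' @param r_sigmas SDs of the model radius, nm (default `c(0, 1, 2)`).
#' @param dmags deformation magnitudes, nm (default `c(1, 10, 20)`).
#' @param n NPCs per cell (default 1000).
#' @param sd_real radius SD of the real reference dataset, nm (default
#'   2.1, the reported value for good-quality Nup96 imaging).
#' @param seed master seed.
#' @param x band specification or rotational unit (default the two-ring
#'   synthetic reference unit).
#' @return data frame with one row per cell: `r_sigma`, `dmag`, `n`,
#'   `mean_radius`, `sd_radius`, `ratio`.
#' @export
run_radius_sweep <- function(r_sigmas = c(0, 1, 2), dmags = c(1, 10, 20),
                             n = 1000, sd_real = 2.1, seed = 1,
                             x = synthetic_tworing_ru()) {
  if (sd_real <= 0) stop("sd_real must be > 0")
  bands <- bands_from_input(x)
  cells <- expand.grid(r_sigma = r_sigmas, dmag = dmags,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell_seed <- derive_seed(seed, "placement", ci)
    cfg <- simulation_config(dmag = cells$dmag[ci],
                             radius_sd = cells$r_sigma[ci],
                             n_npcs = n, seed = cell_seed)
    radii <- numeric(n)
    for (i in seq_len(n)) {
      m <- simulate_npc(bands, cfg, index = i - 1L)
      xyz <- as.matrix(m$nodes[, c("x", "y", "z")])
      br <- vapply(seq_len(m$g), function(b) {
        fit_circle_3d(xyz[m$nodes$band == b, , drop = FALSE])$radius
      }, numeric(1))
      radii[i] <- mean(br)
    }
    out[[ci]] <- data.frame(
      r_sigma = cells$r_sigma[ci], dmag = cells$dmag[ci], n = n,
      mean_radius = mean(radii), sd_radius = stats::sd(radii),
      ratio = radius_sd_ratio(stats::sd(radii), sd_real)
    )
  }
  do.call(rbind, out)
}

#' Re-extract features from an exported coordinates CSV
#'
#' Groups a localization table written by [write_run()] by `npc_id` and
#' `band` and refits circles and ellipses, allowing features to be
#' recomputed from files alone (e.g. after labelling-efficiency
#' subsampling).
#'
#' @param path coordinates CSV path.
#' @param with_ellipse also fit ellipses.
#' @return data frame of per-band fits (NA rows for bands with fewer than 3
#'   localizations).
#' @export
features_from_csv <- function(path, with_ellipse = TRUE) {
  co <- utils::read.csv(path)
  needed <- c("npc_id", "band", "x_nm", "y_nm", "z_nm")
  if (!all(needed %in% names(co))) {
    stop("coordinates CSV must contain columns: ",
         paste(needed, collapse = ", "))
  }
  if ("kept" %in% names(co)) co <- co[co$kept, , drop = FALSE]
  keys <- unique(co[, c("npc_id", "band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- co$npc_id == keys$npc_id[i] & co$band == keys$band[i]
    pts <- as.matrix(co[sel, c("x_nm", "y_nm", "z_nm")])
    r <- band_fit_row(pts, with_ellipse)
    c(list(npc_id = keys$npc_id[i], scope = "band", band = keys$band[i],
           subcomplex = NA_character_), r)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
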