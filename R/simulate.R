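# Per-NPC orchestration: parameter sampling, geometric variability in fixed
# order, then force-based deformation.
#
# Order of application: symmetry -> radius -> height -> twist -> tilt ->
# shift -> (elongation + stochastic forces via springs) -> axial offsets.
# Discrete and scaling operators first, rigid motions next, force-based
# deformation last; the order matters and is fixed package-wide.

clamp_q <- function(q) min(max(q, 1e-3), 1)

#' Simulate one NPC
#'
#' Draws this NPC's parameter values (`X' ~ N(X, sd^2)` for radius, height,
#' twist and elongation ratio; symmetry is discrete and never resampled),
#' applies the geometric operators in the package's fixed order, and deforms
#' the result with correlated stochastic forces and axial offsets. All
#' randomness derives from `config$seed` and `index` through named streams,
#' so toggling one variability type does not perturb another's draws.
#'
#' @param bands an `npc_bands` specification (base symmetry 8).
#' @param config an `npc_config` from [simulation_config()].
#' @param index per-NPC counter within the run (0-based).
#' @return a deformed `npc_model` with the applied parameter values in
#'   `provenance`.
#' @export
simulate_npc <- function(bands, config, index = 0L) {
  seed <- config$seed
  if (config$s != 8) {
    bands <- change_symmetry(bands, config$s, s = 8)
  }
  base_r <- if (is.null(config$mean_radius)) mean(bands$r) else
    config$mean_radius
  base_d <- config$height
  base_t <- config$twist
  draws <- with_seed(derive_seed(seed, "params", index), {
    list(
      r = draw_parameter(base_r, config$radius_sd),
      d = if (!is.null(base_d)) draw_parameter(base_d, config$height_sd),
      theta = if (!is.null(base_t)) draw_parameter(base_t, config$twist_sd),
      q = clamp_q(draw_parameter(config$q, config$q_sd))
    )
  })
  model <- assemble(bands, config$s)
  if (!is.null(config$mean_radius) || config$radius_sd > 0) {
    model <- set_mean_radius(model, max(draws$r, 1e-3))
  }
  if (!is.null(draws$d)) {
    model <- set_height(model, max(draws$d, 1e-3))
  }
  if (!is.null(draws$theta)) {
    model <- set_twist(model, draws$theta)
  }
  if (!is.null(config$kappa)) {
    model <- with_seed(derive_seed(seed, "tilt", index),
                       apply_tilt(model, config$kappa))
  }
  if (config$shift_sd > 0) {
    model <- with_seed(derive_seed(seed, "shift", index),
                       apply_shift(model, config$shift_sd))
  }
  model <- deform_npc(model, dmag = config$dmag, omag = config$omag,
                      q = draws$q, kernel_fraction = config$kernel_fraction,
                      h = config$h, seed = seed, index = index)
  model$provenance$index <- index
  model$provenance$seed <- seed
  model
}

bands_from_input <- function(x) {
  if (inherits(x, "npc_bands")) return(x)
  if (inherits(x, "npc_ru")) {
    pairs <- unique(x$sites[, c("nup_name", "terminus")])
    sel <- label_selection(pairs$nup_name, pairs$terminus)
    return(select_labels(x, sel))
  }
  stop("input must be an npc_bands specification or an npc_ru")
}

#' Simulate a run of NPCs
#'
#' Simulates `config$n_npcs` NPCs from one band specification (or rotational
#' unit) and extracts ground-truth features for each.
#'
#' @param x an `npc_bands` specification, or an `npc_ru` (all of whose label
#'   sites are then used as one pooled selection).
#' @param config an `npc_config`.
#' @param with_ellipse fit ellipses during feature extraction (default
#'   TRUE; switch off for large radius-only sweeps).
#' @return an `npc_run`: list with `models` (list of `npc_model`),
#'   `features` (list of stacked `band`/`subcomplex`/`npc` data frames),
#'   `config` and `bands`.
#' @export
simulate_run <- function(x, config = simulation_config(),
                         with_ellipse = TRUE) {
  bands <- bands_from_input(x)
  n <- config$n_npcs
  models <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    models[[i]] <- simulate_npc(bands, config, index = i - 1L)
    feats[[i]] <- npc_features(models[[i]], npc_id = i,
                               with_ellipse = with_ellipse)
  }
  features <- list(
    band = do.call(rbind, lapply(feats, `[[`, "band")),
    subcomplex = do.call(rbind, lapply(feats, `[[`, "subcomplex")),
    npc = do.call(rbind, lapply(feats, `[[`, "npc"))
  )
  structure(list(models = models, features = features, config = config,
                 bands = bands),
            class = "npc_run")
}

#' @export
print.npc_run <- function(x, ...) {
  cat(sprintf("<npc_run> %d NPCs (g = %d, s = %d), dmag = %g nm\n",
              length(x$models), x$models[[1]]$g, x$config$s, x$config$dmag))
  invisible(x)
}
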