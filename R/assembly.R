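# Assembly of band specifications into the s-fold symmetric node cloud.

#' Assemble bands into a rotationally symmetric NPC model
#'
#' Reflects each band's label site `s` times around the central axis
#' (0, 0), with an angular offset of `2 * pi / s` between spokes. The node
#' for band `j`, spoke `k` sits at
#' `(r_j cos(alpha_j + 2 pi k / s), r_j sin(alpha_j + 2 pi k / s), z_j)`.
#'
#' @param bands an `npc_bands` data frame from [select_labels()] (or any data
#'   frame with columns `z`, `r`, `alpha`, `channel`, `subcomplex`).
#' @param s rotational symmetry, integer >= 1 (default 8). Values below 3 are
#'   rejected unless `allow_degenerate = TRUE` (useful for inspecting a
#'   single rotational unit).
#' @param allow_degenerate allow `s < 3`.
#' @return an `npc_model`: list with `nodes` (data frame: `node_id`, `band`,
#'   `spoke`, `channel`, `subcomplex`, `x`, `y`, `z`), `s`, `g`, `bands`
#'   (the input specification) and `provenance` (named list of applied
#'   parameters, filled in by the variability operators).
#' @export
assemble <- function(bands, s = 8, allow_degenerate = FALSE) {
  s <- as.integer(s)
  if (is.na(s) || s < 1 || (s < 3 && !allow_degenerate)) {
    stop("rotational symmetry s must be an integer >= 3")
  }
  g <- nrow(bands)
  if (g < 1) stop("at least one band is required")
  spoke <- rep(0:(s - 1), times = g)
  band <- rep(seq_len(g), each = s)
  theta <- bands$alpha[band] + 2 * pi * spoke / s
  nodes <- data.frame(
    node_id = seq_len(g * s),
    band = band,
    spoke = spoke,
    channel = bands$channel[band],
    subcomplex = bands$subcomplex[band],
    x = bands$r[band] * cos(theta),
    y = bands$r[band] * sin(theta),
    z = bands$z[band],
    stringsAsFactors = FALSE
  )
  structure(
    list(nodes = nodes, s = s, g = g, bands = bands,
         provenance = list(s = s)),
    class = "npc_model"
  )
}

#' Arithmetic mean radius of a model or band specification
#'
#' The mean over nodes of the lateral distance `sqrt(x^2 + y^2)` to the
#' central axis (for band specifications, the node-count-weighted mean of
#' band radii, which is identical).
#'
#' @param x an `npc_model`, `npc_bands`, or an n-by-2/3 coordinate matrix.
#' @return mean radius in nm.
#' @export
mean_radius <- function(x) {
  if (inherits(x, "npc_model")) {
    n <- x$nodes
    if (nrow(n) == 0) stop("empty model")
    return(mean(sqrt(n$x^2 + n$y^2)))
  }
  if (inherits(x, "npc_bands") || (is.data.frame(x) && "r" %in% names(x))) {
    if (nrow(x) == 0) stop("empty band specification")
    return(mean(x$r))
  }
  if (is.matrix(x)) {
    if (nrow(x) == 0) stop("empty coordinate matrix")
    return(mean(sqrt(x[, 1]^2 + x[, 2]^2)))
  }
  stop("unsupported input to mean_radius")
}

node_xyz <- function(model) {
  as.matrix(model$nodes[, c("x", "y", "z")])
}

#' @export
print.npc_model <- function(x, ...) {
  cat(sprintf("<npc_model> %d nodes: g = %d bands x s = %d spokes\n",
              nrow(x$nodes), x$g, x$s))
  cat(sprintf("  mean radius %.2f nm, subcomplexes: %s\n",
              mean_radius(x),
              paste(unique(x$nodes$subcomplex), collapse = ", ")))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects every tunable of a simulation run with validated defaults.
#' Defaults are the study conditions used throughout: 8-fold symmetry,
#' spring neighbour order `h = 2`, force-kernel width half the mean radius,
#' axial offset magnitude half the lateral one.
#'
#' @param s rotational symmetry (integer >= 3, default 8). No SD: symmetry
#'   is discrete and never resampled per NPC.
#' @param dmag magnitude of irregular lateral deformation, nm; three
#'   marginal standard deviations of the scalar force distribution
#'   (about 99.7% of sampled forces fall within `[-dmag, dmag]`).
#' @param omag axial analogue of `dmag`; default `dmag / 2`.
#' @param kernel_fraction RBF kernel width as a fraction of the mean radius
#'   (default 0.5).
#' @param h circumferential spring neighbour order (default 2): each node is
#'   connected to its `2 * h` nearest same-band neighbours.
#' @param mean_radius target mean radius, nm (`NULL`: keep the model's).
#' @param radius_sd per-NPC SD of the mean radius, nm.
#' @param height CS-NS mean-z distance `d`, nm (`NULL`: keep).
#' @param height_sd per-NPC SD of `d`, nm.
#' @param twist twist angle between cytoplasmic and nucleoplasmic side,
#'   radians (`NULL`: keep).
#' @param twist_sd per-NPC SD of the twist angle, radians.
#' @param kappa von Mises-Fisher concentration for independent CS/NS tilt;
#'   smaller values mean more tilt; `NULL` disables tilt.
#' @param shift_sd lateral shift SD per side, nm (0 disables).
#' @param q elongation ratio of short to long axis, in (0, 1]; 1 disables.
#' @param q_sd per-NPC SD of `q` (draws are clamped to (0, 1]).
#' @param n_npcs number of NPCs in a run.
#' @param labelling_efficiency probability a binding site carries a label.
#' @param expansion_factor isotropic coordinate scaling at export
#'   (expansion microscopy).
#' @param seed master seed; all randomness derives from it via
#'   [derive_seed()].
#' @return a validated `npc_config` list.
#' @export
simulation_config <- function(s = 8, dmag = 0, omag = NULL,
                              kernel_fraction = 0.5, h = 2,
                              mean_radius = NULL, radius_sd = 0,
                              height = NULL, height_sd = 0,
                              twist = NULL, twist_sd = 0,
                              kappa = NULL, shift_sd = 0,
                              q = 1, q_sd = 0,
                              n_npcs = 1, labelling_efficiency = 1,
                              expansion_factor = 1, seed = 1) {
  s <- as.integer(s)
  if (s < 3) stop("s must be >= 3")
  if (dmag < 0) stop("dmag must be >= 0")
  if (is.null(omag)) omag <- dmag / 2
  if (omag < 0) stop("omag must be >= 0")
  if (kernel_fraction <= 0) stop("kernel_fraction must be > 0")
  h <- as.integer(h)
  if (h < 0 || h > s %/% 2) stop("h must lie in 0..floor(s/2)")
  if (!is.null(mean_radius) && mean_radius <= 0) {
    stop("mean_radius must be > 0")
  }
  if (radius_sd < 0 || height_sd < 0 || twist_sd < 0 || q_sd < 0 ||
      shift_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (!is.null(height) && height <= 0) stop("height must be > 0")
  if (!is.null(kappa) && kappa <= 0) stop("kappa must be > 0")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  if (labelling_efficiency < 0 || labelling_efficiency > 1) {
    stop("labelling_efficiency must lie in [0, 1]")
  }
  if (expansion_factor <= 0) stop("expansion_factor must be > 0")
  if (n_npcs < 1) stop("n_npcs must be >= 1")
  structure(list(
    s = s, dmag = dmag, omag = omag, kernel_fraction = kernel_fraction,
    h = h, mean_radius = mean_radius, radius_sd = radius_sd,
    height = height, height_sd = height_sd,
    twist = twist, twist_sd = twist_sd,
    kappa = kappa, shift_sd = shift_sd, q = q, q_sd = q_sd,
    n_npcs = as.integer(n_npcs),
    labelling_efficiency = labelling_efficiency,
    expansion_factor = expansion_factor, seed = as.integer(seed)
  ), class = "npc_config")
}
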