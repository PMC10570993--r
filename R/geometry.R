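# Geometric variability operators.
#
# Axial variability (height, tilt, shift, twist) acts on the subcomplex
# closest to the cytoplasmic side (CS) and nucleoplasmic side (NS); bands of
# sandwiched subcomplexes receive linearly interpolated values. Lateral
# operators (radius, elongation, symmetry) never touch z; axial operators
# never change lateral radii (height changes only z).

#' Draw a per-NPC parameter value
#'
#' Samples `X' ~ N(X, sd^2)`; with `sd = 0` the input is returned unchanged.
#' Never used for the discrete rotational symmetry.
#'
#' @param x central value.
#' @param sd standard deviation, >= 0.
#' @return one draw.
#' @export
draw_parameter <- function(x, sd = 0) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(x)
  stats::rnorm(1, mean = x, sd = sd)
}

#' Split a model into cytoplasmic, nucleoplasmic and sandwiched bands
#'
#' The subcomplex with the greatest mean z is the cytoplasmic side (CS,
#' weight 1), the one with the least mean z the nucleoplasmic side (NS,
#' weight 0); bands of other subcomplexes are "sandwiched" and get a weight
#' linear in their mean z between the NS and CS subcomplex means. With only
#' one subcomplex present, axial variability is inapplicable.
#'
#' @param model an `npc_model`.
#' @return list with `applicable` (logical) and `sides`, a data frame with
#'   one row per band: `band`, `subcomplex`, `mean_z`, `w`, `side`
#'   (`"CS"`/`"NS"`/`"sandwiched"`).
#' @export
split_sides <- function(model) {
  n <- model$nodes
  sub_z <- tapply(n$z, n$subcomplex, mean)
  band_z <- tapply(n$z, n$band, mean)
  band_sub <- model$bands$subcomplex
  g <- model$g
  if (length(sub_z) < 2) {
    return(list(applicable = FALSE,
                sides = data.frame(band = seq_len(g), subcomplex = band_sub,
                                   mean_z = as.numeric(band_z[as.character(seq_len(g))]),
                                   w = NA_real_, side = NA_character_,
                                   stringsAsFactors = FALSE)))
  }
  cs_sub <- names(sub_z)[which.max(sub_z)]
  ns_sub <- names(sub_z)[which.min(sub_z)]
  z_cs <- sub_z[[cs_sub]]
  z_ns <- sub_z[[ns_sub]]
  bz <- as.numeric(band_z[as.character(seq_len(g))])
  w <- (bz - z_ns) / (z_cs - z_ns)
  side <- ifelse(band_sub == cs_sub, "CS",
                 ifelse(band_sub == ns_sub, "NS", "sandwiched"))
  w[side == "CS"] <- 1
  w[side == "NS"] <- 0
  w <- pmin(pmax(w, 0), 1)
  list(applicable = TRUE,
       sides = data.frame(band = seq_len(g), subcomplex = band_sub,
                          mean_z = bz, w = w, side = side,
                          stringsAsFactors = FALSE))
}

side_nodes <- function(model, sides, which_side) {
  bands <- sides$sides$band[sides$sides$side == which_side]
  model$nodes$band %in% bands
}

#' Measure the CS-NS height of a model
#'
#' Difference between the mean z of the cytoplasmic-side nodes and the mean
#' z of the nucleoplasmic-side nodes.
#'
#' @param model an `npc_model`.
#' @return height `d` in nm.
#' @export
measure_height <- function(model) {
  sides <- split_sides(model)
  if (!sides$applicable) {
    stop("height is undefined: only one subcomplex present")
  }
  n <- model$nodes
  mean(n$z[side_nodes(model, sides, "CS")]) -
    mean(n$z[side_nodes(model, sides, "NS")])
}

#' Set the CS-NS height
#'
#' Affinely rescales all z about the model's mean z so that the CS-NS mean-z
#' difference equals `d`. Sandwiched bands move in proportion to their
#' position between the sides; x and y are untouched. A single-subcomplex
#' model is returned unchanged with a warning.
#'
#' @param model an `npc_model`.
#' @param d target height, nm, > 0.
#' @return the modified model.
#' @export
set_height <- function(model, d) {
  if (d <= 0) stop("height d must be > 0")
  sides <- split_sides(model)
  if (!sides$applicable) {
    warning("only one subcomplex selected; height not applied")
    return(model)
  }
  cur <- measure_height(model)
  if (cur <= 0) stop("model has no axial extent to rescale")
  zbar <- mean(model$nodes$z)
  model$nodes$z <- zbar + (model$nodes$z - zbar) * (d / cur)
  model$provenance$height <- d
  model
}

circ_mean <- function(a) {
  atan2(mean(sin(a)), mean(cos(a)))
}

#' Measure the twist angle
#'
#' The twist angle is the difference between the mean cytoplasmic-side
#' angles and the mean nucleoplasmic-side angles within one spoke (circular
#' means, wrapped to `(-pi, pi]`), averaged circularly over spokes.
#' Sandwiched bands do not enter the measurement.
#'
#' @param model an `npc_model`.
#' @return twist angle in radians.
#' @export
measure_twist <- function(model) {
  sides <- split_sides(model)
  if (!sides$applicable) {
    stop("twist is undefined: only one subcomplex present")
  }
  n <- model$nodes
  cs <- side_nodes(model, sides, "CS")
  ns <- side_nodes(model, sides, "NS")
  ang <- atan2(n$y, n$x)
  per_spoke <- vapply(sort(unique(n$spoke)), function(k) {
    a_cs <- ang[cs & n$spoke == k]
    a_ns <- ang[ns & n$spoke == k]
    wrap_angle(circ_mean(a_cs) - circ_mean(a_ns))
  }, numeric(1))
  circ_mean(per_spoke)
}

#' Set the twist angle
#'
#' Rotates each band about the z-axis by `w * (theta - current)`, where `w`
#' is the band's side weight (NS 0, CS 1, sandwiched interpolated), so that
#' the measured twist equals `theta`. Radii and z are untouched.
#'
#' @param model an `npc_model`.
#' @param theta target twist angle, radians.
#' @return the modified model.
#' @export
set_twist <- function(model, theta) {
  sides <- split_sides(model)
  if (!sides$applicable) {
    warning("only one subcomplex selected; twist not applied")
    return(model)
  }
  delta <- wrap_angle(theta - measure_twist(model))
  n <- model$nodes
  for (b in seq_len(model$g)) {
    wb <- sides$sides$w[sides$sides$band == b]
    if (wb == 0) next
    idx <- n$band == b
    a <- delta * wb
    x <- n$x[idx]; y <- n$y[idx]
    n$x[idx] <- cos(a) * x - sin(a) * y
    n$y[idx] <- sin(a) * x + cos(a) * y
  }
  model$nodes <- n
  model$provenance$twist <- theta
  model
}

#' Sample unit vectors from a von Mises-Fisher distribution about +z
#'
#' Standard inversion sampler for the polar cosine; azimuth uniform.
#'
#' @param n number of draws.
#' @param kappa concentration, > 0 (smaller values mean more spread).
#' @return an `n` x 3 matrix of unit vectors.
#' @export
rvmf_z <- function(n, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  u <- stats::runif(n)
  # W = 1 + log(u + (1 - u) exp(-2 kappa)) / kappa, numerically safe form
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(pmax(w, -1), 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  cbind(s * cos(phi), s * sin(phi), w)
}

rotation_from_z <- function(v) {
  # rotation matrix taking +z onto unit vector v (about axis z x v)
  w <- min(max(v[3], -1), 1)
  ang <- acos(w)
  if (ang < 1e-15) return(diag(3))
  axis <- c(-v[2], v[1], 0)
  axis <- axis / sqrt(sum(axis^2))
  rotation_axis_angle(axis, ang)
}

rotation_axis_angle <- function(axis, angle) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c0 <- cos(angle); s0 <- sin(angle); t0 <- 1 - c0
  matrix(c(
    t0 * x * x + c0,     t0 * x * y - s0 * z, t0 * x * z + s0 * y,
    t0 * x * y + s0 * z, t0 * y * y + c0,     t0 * y * z - s0 * x,
    t0 * x * z - s0 * y, t0 * y * z + s0 * x, t0 * z * z + c0
  ), nrow = 3, byrow = TRUE)
}

scale_rotation <- function(R, frac) {
  # same-axis rotation with the angle scaled by frac (for interpolation)
  if (frac == 1) return(R)
  tr <- (sum(diag(R)) - 1) / 2
  ang <- acos(min(max(tr, -1), 1))
  if (ang < 1e-15) return(diag(3))
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  rotation_axis_angle(axis, frac * ang)
}

#' Apply independent tilt to the cytoplasmic and nucleoplasmic sides
#'
#' For each side a unit vector is drawn from a von Mises-Fisher distribution
#' with mean direction +z and concentration `kappa`; the side's bands are
#' rigidly rotated about the side centroid so that their plane normal aligns
#' with the drawn vector. Sandwiched bands receive both side rotations with
#' angles scaled by their interpolation weight. Pairwise distances within a
#' side are preserved (rigid rotation).
#'
#' @param model an `npc_model`.
#' @param kappa von Mises-Fisher concentration, > 0.
#' @return the modified model.
#' @export
apply_tilt <- function(model, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  sides <- split_sides(model)
  if (!sides$applicable) {
    warning("only one subcomplex selected; tilt not applied")
    return(model)
  }
  dirs <- rvmf_z(2, kappa) # row 1: CS, row 2: NS
  n <- model$nodes
  xyz <- as.matrix(n[, c("x", "y", "z")])
  cs_idx <- side_nodes(model, sides, "CS")
  ns_idx <- side_nodes(model, sides, "NS")
  cen <- list(CS = colMeans(xyz[cs_idx, , drop = FALSE]),
              NS = colMeans(xyz[ns_idx, , drop = FALSE]))
  R <- list(CS = rotation_from_z(dirs[1, ]), NS = rotation_from_z(dirs[2, ]))
  for (b in seq_len(model$g)) {
    wb <- sides$sides$w[sides$sides$band == b]
    idx <- n$band == b
    p <- xyz[idx, , drop = FALSE]
    if (wb > 0) {
      Rb <- scale_rotation(R$CS, wb)
      p <- sweep(sweep(p, 2, cen$CS) %*% t(Rb), 2, cen$CS, `+`)
    }
    if (wb < 1) {
      Rb <- scale_rotation(R$NS, 1 - wb)
      p <- sweep(sweep(p, 2, cen$NS) %*% t(Rb), 2, cen$NS, `+`)
    }
    xyz[idx, ] <- p
  }
  model$nodes$x <- xyz[, 1]
  model$nodes$y <- xyz[, 2]
  model$nodes$z <- xyz[, 3]
  model$provenance$kappa <- kappa
  model
}

#' Apply independent lateral shift to the two sides
#'
#' Each side is translated laterally by its own (dx, dy) draw from
#' `N(0, shift_sd^2)`; sandwiched bands are shifted by the interpolated
#' offset. z is untouched.
#'
#' @param model an `npc_model`.
#' @param shift_sd Gaussian SD per side and axis, nm, >= 0.
#' @return the modified model.
#' @export
apply_shift <- function(model, shift_sd) {
  if (shift_sd < 0) stop("shift_sd must be >= 0")
  sides <- split_sides(model)
  if (!sides$applicable) {
    warning("only one subcomplex selected; shift not applied")
    return(model)
  }
  if (shift_sd == 0) return(model)
  d_cs <- stats::rnorm(2, 0, shift_sd)
  d_ns <- stats::rnorm(2, 0, shift_sd)
  n <- model$nodes
  for (b in seq_len(model$g)) {
    wb <- sides$sides$w[sides$sides$band == b]
    idx <- n$band == b
    off <- wb * d_cs + (1 - wb) * d_ns
    n$x[idx] <- n$x[idx] + off[1]
    n$y[idx] <- n$y[idx] + off[2]
  }
  model$nodes <- n
  model$provenance$shift_sd <- shift_sd
  model
}

#' Set the mean radius
#'
#' Isotropically scales all lateral coordinates by `r_new / mean_radius`,
#' so nodes are further apart in dilated NPCs; z is untouched.
#'
#' @param model an `npc_model`.
#' @param r_new target mean radius, nm, > 0.
#' @return the modified model.
#' @export
set_mean_radius <- function(model, r_new) {
  if (r_new <= 0) stop("r_new must be > 0")
  f <- r_new / mean_radius(model)
  model$nodes$x <- model$nodes$x * f
  model$nodes$y <- model$nodes$y * f
  model$provenance$mean_radius <- r_new
  model
}

#' Elongation forces toward a random-orientation target ellipse
#'
#' Returns one scalar radial force per node pushing it toward an ellipse of
#' the same area as the circle of radius `mean_radius(model)`, with
#' short-to-long axis ratio `q` and uniformly random orientation. The force
#' is proportional to the signed radial gap between the node and the ellipse
#' at the node's azimuth; the gain `ELONGATION_GAIN` is calibrated once so
#' that relaxation under elongation forces alone reproduces an axis ratio of
#' about `q` (within 5% at `q = 0.8`) on the default spring constants.
#' Forces are added to the stochastic forces before radialization.
#'
#' @param model an `npc_model`.
#' @param q axis ratio in (0, 1]; `q = 1` gives exactly zero forces.
#' @return numeric vector of scalar forces, one per node.
#' @export
elongation_forces <- function(model, q) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  m <- nrow(model$nodes)
  if (q == 1) return(numeric(m))
  rbar <- mean_radius(model)
  a <- rbar / sqrt(q) # long semi-axis; area preserved: a * b = rbar^2
  b <- rbar * sqrt(q)
  phi0 <- stats::runif(1, 0, 2 * pi)
  n <- model$nodes
  phi <- atan2(n$y, n$x)
  r_node <- sqrt(n$x^2 + n$y^2)
  rho <- a * b / sqrt((b * cos(phi - phi0))^2 + (a * sin(phi - phi0))^2)
  ELONGATION_GAIN * (rho - r_node)
}

#' Change the rotational symmetry of a band specification
#'
#' Keeps the geodesic (arc) distance between adjacent same-band Nups
#' constant and preserves each band's offset from the mean radius: the mean
#' radius rescales as `r_bar * s_new / s`, and `r_j_new = r_bar_new +
#' (r_j - r_bar)`. z and angles are unchanged, so NPCs with 9- or 10-fold
#' symmetry have a greater diameter.
#'
#' @param bands an `npc_bands` specification.
#' @param s_new target symmetry, integer >= 3.
#' @param s current symmetry the spacing refers to (default 8).
#' @return the rescaled `npc_bands`.
#' @export
change_symmetry <- function(bands, s_new, s = 8) {
  s_new <- as.integer(s_new)
  if (s_new < 3) stop("s_new must be >= 3")
  if (s_new == s) return(bands)
  rbar <- mean(bands$r)
  rbar_new <- rbar * s_new / s
  r_new <- rbar_new + (bands$r - rbar)
  if (any(r_new <= 0)) {
    stop("symmetry change would drive a band radius below zero")
  }
  bands$r <- r_new
  bands
}
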