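# Shared fixtures: all built in code, no files needed.

tworing_bands <- function(r = 53.7, d = 50) {
  select_labels(synthetic_tworing_ru(r = r, d = d),
                label_selection("SynNup", "C"))
}

onering_bands <- function(r = 50) {
  select_labels(make_synthetic_ru(z = 0, r = r, alpha = 0,
                                  subcomplex = "CR"),
                label_selection("SynNup"))
}

threering_bands <- function() {
  ru <- make_synthetic_ru(
    z = c(25, 0, -25), r = c(53.7, 44, 53.7), alpha = c(0, 0.1, 0),
    subcomplex = c("CR", "IR", "NR")
  )
  select_labels(ru, label_selection("SynNup"))
}

# points on an exact circle of radius r in a plane rotated about a given
# axis, plus center offset
circle_points <- function(n = 8, r = 50, center = c(0, 0, 0),
                          axis = c(0, 0, 1), angle = 0, phase = 0) {
  th <- phase + 2 * pi * (0:(n - 1)) / n
  pts <- cbind(r * cos(th), r * sin(th), 0)
  R <- npcsim:::rotation_axis_angle(axis / sqrt(sum(axis^2)), angle)
  sweep(pts %*% t(R), 2, center, `+`)
}

ellipse_points <- function(n = 8, a = 55, b = 45, phi = 0,
                           center = c(0, 0, 0), axis = c(0, 0, 1),
                           angle = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  u <- a * cos(th); v <- b * sin(th)
  pts <- cbind(u * cos(phi) - v * sin(phi), u * sin(phi) + v * cos(phi), 0)
  R <- npcsim:::rotation_axis_angle(axis / sqrt(sum(axis^2)), angle)
  sweep(pts %*% t(R), 2, center, `+`)
}

# independent geometric circle-fit oracle: full nonlinear least squares over
# center (3), normal (2 angles) and radius, minimizing true 3D
# point-to-circle distances, started from the truth
oracle_circle_fit <- function(pts, start_center, start_normal, start_r) {
  obj <- function(p) {
    ctr <- p[1:3]
    nrm <- c(sin(p[4]) * cos(p[5]), sin(p[4]) * sin(p[5]), cos(p[4]))
    r <- p[6]
    d <- sweep(pts, 2, ctr)
    w <- d %*% nrm
    inpl <- d - w %*% t(nrm)
    rho <- sqrt(rowSums(inpl^2))
    sum((rho - r)^2 + w^2)
  }
  th0 <- acos(start_normal[3] / sqrt(sum(start_normal^2)))
  ph0 <- atan2(start_normal[2], start_normal[1])
  fit <- stats::optim(c(start_center, th0, ph0, start_r), obj,
                      control = list(maxit = 2000, reltol = 1e-14))
  list(radius = fit$par[6], rss = fit$value)
}
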