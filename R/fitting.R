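# Ground-truth feature extraction: 3D circle and ellipse fits.
#
# Fitting proceeds in two stages shared by both shapes: the fit plane is the
# total-least-squares plane (centroid plus the two leading principal
# directions; the normal is the direction of least variance), then the shape
# is fitted to the in-plane projections -- algebraically first, refined by
# geometric least squares. The residual sum of squares (RSS) is always the
# sum of squared shortest 3D distances from the points to the fitted curve,
# so out-of-plane irregularity counts.

fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  normal <- sv$v[, 3]
  if (normal[3] < 0 || (normal[3] == 0 && normal[1] < 0)) normal <- -normal
  e1 <- sv$v[, 1]
  e2 <- sv$v[, 2]
  # right-handed in-plane frame
  if (sum(normal * crossprod_vec(e1, e2)) < 0) e2 <- -e2
  uv <- cbind(x %*% e1, x %*% e2)
  w <- drop(x %*% normal)
  list(center = ctr, normal = normal, e1 = e1, e2 = e2, uv = uv, w = w)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Fit a 3D circle to a point set
#'
#' Total-least-squares plane, algebraic (Kasa) in-plane circle fit, then
#' geometric refinement by Gauss-Newton on the in-plane radial residuals.
#' The RSS is the sum of squared 3D point-to-circle distances.
#'
#' @param pts n-by-3 matrix (n >= 3, not collinear).
#' @return a `circle_fit`: list with `center` (3D), `normal` (unit),
#'   `radius`, `rss`.
#' @export
fit_circle_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("at least 3 points are required for a circle fit")
  pl <- fit_plane(pts)
  u <- pl$uv[, 1]; v <- pl$uv[, 2]
  if (max(abs(v)) < 1e-12 * max(1, max(abs(u)))) {
    stop("points are collinear: circle fit is degenerate")
  }
  # Kasa: u^2 + v^2 = 2 a u + 2 b v + c
  A <- cbind(2 * u, 2 * v, 1)
  rhs <- u^2 + v^2
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) {
    stop("circle fit is degenerate: ", conditionMessage(e))
  })
  a <- sol[1]; b <- sol[2]
  r <- sqrt(max(sol[3] + a^2 + b^2, .Machine$double.eps))
  # Gauss-Newton on (a, b, r)
  for (it in 1:50) {
    du <- u - a; dv <- v - b
    rho <- sqrt(du^2 + dv^2)
    res <- rho - r
    J <- cbind(-du / rho, -dv / rho, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12 * max(1, r)) break
  }
  rho <- sqrt((u - a)^2 + (v - b)^2)
  rss <- sum((rho - r)^2) + sum(pl$w^2)
  center <- pl$center + a * pl$e1 + b * pl$e2
  structure(list(center = center, normal = pl$normal, radius = r, rss = rss),
            class = "circle_fit")
}

# Shortest distance from an in-plane point to an axis-aligned ellipse
# centred at the origin with semi-axes a >= b (Eberly-style root finding on
# the orthogonality condition).
point_ellipse_dist <- function(p, q, a, b) {
  p <- abs(p); q <- abs(q)
  if (p < 1e-14 * a && q < 1e-14 * a) return(b)
  if (q < 1e-12 * b) {
    crit <- (a^2 - b^2) / a
    if (p >= crit) return(abs(p - a))
    x <- a^2 * p / (a^2 - b^2)
    y <- b * sqrt(max(0, 1 - (x / a)^2))
    return(sqrt((p - x)^2 + y^2))
  }
  f <- function(t) (a * p / (t + a^2))^2 + (b * q / (t + b^2))^2 - 1
  lo <- -b^2 + b * q
  hi <- max(a * p, b * q) + a^2
  while (f(hi) > 0) hi <- 2 * hi + a^2
  t <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  x <- a^2 * p / (t + a^2)
  y <- b^2 * q / (t + b^2)
  sqrt((p - x)^2 + (q - y)^2)
}

ellipse_geo_dists <- function(u, v, cx, cy, a, b, phi) {
  co <- cos(phi); si <- sin(phi)
  du <- u - cx; dv <- v - cy
  p <- co * du + si * dv
  q <- -si * du + co * dv
  vapply(seq_along(p), function(i) point_ellipse_dist(p[i], q[i], a, b),
         numeric(1))
}

conic_to_params <- function(cf) {
  cf <- as.numeric(cf)
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F0 <- cf[6]
  M <- matrix(c(2 * A, B, B, 2 * C), 2)
  ctr <- tryCatch(solve(M, c(-D, -E)), error = function(e) {
    stop("degenerate conic: no ellipse center")
  })
  cx <- ctr[1]; cy <- ctr[2]
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F0
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  ev <- eigen(Q, symmetric = TRUE)
  lam <- ev$values
  if (any(lam * (-Fc) <= 0)) stop("fitted conic is not an ellipse")
  ax <- sqrt(-Fc / lam) # lam ordered decreasing -> ax increasing? values desc
  # eigen returns values in decreasing order: lam[1] >= lam[2];
  # semi-axis along eigvec i is sqrt(-Fc / lam[i]); the major axis pairs
  # with the smaller eigenvalue
  a <- sqrt(-Fc / lam[2])
  b <- sqrt(-Fc / lam[1])
  vec <- ev$vectors[, 2]
  phi <- atan2(vec[2], vec[1])
  if (phi < 0) phi <- phi + pi
  list(cx = cx, cy = cy, a = a, b = b, phi = phi)
}

fit_ellipse_direct <- function(u, v) {
  # Halir & Flusser numerically stable direct least-squares ellipse fit
  d1 <- cbind(u^2, u * v, v^2)
  d2 <- cbind(u, v, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  t0 <- -tryCatch(solve(s3, t(s2)), error = function(e) {
    stop("degenerate point configuration for ellipse fit")
  })
  m <- s1 + s2 %*% t0
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution for this point set")
  a1 <- evec[, ok[1]]
  c(a1, drop(t0 %*% a1))
}

#' Fit a 3D ellipse to a point set
#'
#' Total-least-squares plane, direct (constrained conic) in-plane ellipse
#' fit, then geometric refinement of center, semi-axes and orientation by
#' minimizing the sum of squared in-plane point-to-ellipse distances. The
#' RSS is the sum of squared shortest 3D distances to the fitted ellipse.
#'
#' @param pts n-by-3 matrix, n >= 5, in non-degenerate position.
#' @return an `ellipse_fit`: list with `center` (3D), `normal`, `a` (semi
#'   major), `b` (semi minor), `phi` (orientation of the major axis within
#'   the fit plane, radians), `major_axis` (3D unit vector of the major
#'   axis), `ratio` (`b / a`), `rss`.
#' @export
fit_ellipse_3d <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 5) stop("at least 5 points are required for an ellipse fit")
  pl <- fit_plane(pts)
  # refine in scale-normalized coordinates so convergence (and therefore
  # the fit) is equivariant under a global rescaling of the input
  sc <- sqrt(mean(pl$uv[, 1]^2 + pl$uv[, 2]^2))
  if (sc <= 0) stop("degenerate point configuration for ellipse fit")
  u <- pl$uv[, 1] / sc; v <- pl$uv[, 2] / sc
  par0 <- conic_to_params(fit_ellipse_direct(u, v))
  obj <- function(p) {
    a <- p[3]; b <- p[4]
    if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) return(1e12)
    sum(ellipse_geo_dists(u, v, p[1], p[2], a, b, p[5])^2)
  }
  p0 <- c(par0$cx, par0$cy, par0$a, par0$b, par0$phi)
  if (obj(p0) > 1e-24) {
    for (restart in 1:2) {
      fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-14))
      if (fit$value < obj(p0)) p0 <- fit$par
      if (fit$convergence == 0) break
    }
  }
  d_in <- sc * ellipse_geo_dists(u, v, p0[1], p0[2], p0[3], p0[4], p0[5])
  rss <- sum(d_in^2) + sum(pl$w^2)
  center <- pl$center + sc * (p0[1] * pl$e1 + p0[2] * pl$e2)
  phi <- p0[5] %% pi
  major_axis <- cos(phi) * pl$e1 + sin(phi) * pl$e2
  structure(list(center = center, normal = pl$normal,
                 a = sc * p0[3], b = sc * p0[4], phi = phi,
                 major_axis = major_axis,
                 ratio = p0[4] / p0[3], rss = rss),
            class = "ellipse_fit")
}

fit_tilt_angle <- function(normal) {
  acos(min(max(abs(normal[3]), -1), 1))
}

band_fit_row <- function(pts, with_ellipse = TRUE) {
  out <- list(n_nodes = nrow(pts), radius = NA_real_, circle_rss = NA_real_,
              major = NA_real_, minor = NA_real_, axis_ratio = NA_real_,
              ellipse_rss = NA_real_, tilt = NA_real_,
              center_x = NA_real_, center_y = NA_real_, center_z = NA_real_)
  if (nrow(pts) >= 3) {
    cf <- tryCatch(fit_circle_3d(pts), error = function(e) NULL)
    if (!is.null(cf)) {
      out$radius <- cf$radius
      out$circle_rss <- cf$rss
      out$tilt <- fit_tilt_angle(cf$normal)
      out$center_x <- cf$center[1]
      out$center_y <- cf$center[2]
      out$center_z <- cf$center[3]
    }
  }
  if (with_ellipse && nrow(pts) >= 5) {
    ef <- tryCatch(fit_ellipse_3d(pts), error = function(e) NULL)
    if (!is.null(ef)) {
      out$major <- ef$a
      out$minor <- ef$b
      out$axis_ratio <- ef$ratio
      out$ellipse_rss <- ef$rss
    }
  }
  out
}

#' Extract ground-truth features of one NPC
#'
#' Fits a 3D circle and 3D ellipse to every band and to every present
#' subcomplex (all bands with the same tag pooled into one point set), and
#' derives the per-NPC record as the arithmetic mean of the band features.
#' Twist and height are included at NPC scope when two sides exist.
#'
#' @param model an `npc_model`.
#' @param npc_id identifier written into every row.
#' @param with_ellipse also fit ellipses (default TRUE).
#' @return list of three data frames: `band` (one row per band),
#'   `subcomplex` (one row per present subcomplex), `npc` (one row).
#'   Lengths nm, angles radians, RSS nm^2. Bands with fewer than 3 usable
#'   nodes yield an NA row, not an error.
#' @export
npc_features <- function(model, npc_id = 1L, with_ellipse = TRUE) {
  nodes <- model$nodes
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  band_rows <- lapply(seq_len(model$g), function(b) {
    r <- band_fit_row(xyz[nodes$band == b, , drop = FALSE], with_ellipse)
    c(list(npc_id = npc_id, scope = "band", band = b,
           subcomplex = model$bands$subcomplex[b]), r)
  })
  band_df <- do.call(rbind, lapply(band_rows, as.data.frame))
  sub_rows <- lapply(intersect(SUBCOMPLEXES, unique(nodes$subcomplex)),
                     function(sc) {
    r <- band_fit_row(xyz[nodes$subcomplex == sc, , drop = FALSE],
                      with_ellipse)
    c(list(npc_id = npc_id, scope = "subcomplex", band = NA_integer_,
           subcomplex = sc), r)
  })
  sub_df <- do.call(rbind, lapply(sub_rows, as.data.frame))
  sides <- split_sides(model)
  twist <- if (sides$applicable) measure_twist(model) else NA_real_
  height <- if (sides$applicable) measure_height(model) else NA_real_
  npc_df <- data.frame(
    npc_id = npc_id, scope = "npc",
    radius = mean(band_df$radius),
    circle_rss = mean(band_df$circle_rss),
    major = mean(band_df$major),
    minor = mean(band_df$minor),
    axis_ratio = mean(band_df$axis_ratio),
    ellipse_rss = mean(band_df$ellipse_rss),
    tilt = mean(band_df$tilt),
    twist = twist, height = height,
    stringsAsFactors = FALSE
  )
  list(band = band_df, subcomplex = sub_df, npc = npc_df)
}

#' Compare simulated to real radius variability
#'
#' The ratio `sd_sim / sd_real - 1`: negative values indicate too little
#' simulated variability, positive values too much.
#'
#' @param sd_sim SD of per-NPC fitted radii in the simulated dataset, nm.
#' @param sd_real SD of fitted radii reported for the real dataset, nm, > 0.
#' @return dimensionless ratio.
#' @export
radius_sd_ratio <- function(sd_sim, sd_real) {
  if (sd_real <= 0) stop("sd_real must be > 0")
  sd_sim / sd_real - 1
}
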