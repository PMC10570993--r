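# Spring systems and irregular (stochastic, distance-covariant) deformation.
#
# Each band is an independent spring system: nodes anchored to the central
# axis by radial springs (the nuclear envelope) and connected to their 2h
# nearest same-band neighbours by circumferential springs (protein-protein
# contacts). Scalar forces are drawn from a zero-mean multivariate normal
# whose covariance decays with inter-node distance (RBF kernel), made
# radial, and each band is relaxed to its static equilibrium. Axial offsets
# are sampled the same way but applied additively, without springs.

# Global stiffness scale, force units per nm. Circumferential stiffness is
# K_SPRING / rest-length (shorter springs are stiffer); the radial stiffness
# is half the weakest circumferential one. Calibrated once so that a uniform
# radial force of magnitude 10 dilates the default ring (radius 50 nm,
# s = 8, h = 2) by 2 nm.
K_SPRING <- 98.69

# Gain of the elongation force (force units per nm of radial gap to the
# target ellipse), matching the effective per-node stiffness of the
# elliptic deformation mode. Calibrated once so that relaxation under
# elongation forces alone yields a fitted axis ratio within 5% of q = 0.8
# on the default spring constants.
ELONGATION_GAIN <- 0.95

#' Build the spring system of one band
#'
#' Radial springs anchor every node to the central axis (0, 0); each node is
#' further connected to its neighbours `1..h` steps away along the band by
#' circumferential springs. Rest lengths equal the current geometry, so the
#' input state carries zero tension. Stiffness is `K_SPRING / rest length`
#' for circumferential springs (shorter springs are stiffer) and half the
#' weakest circumferential stiffness for radial springs.
#'
#' @param xy n-by-2 matrix of the band's lateral node positions (rest
#'   state), in band order (adjacent rows are circumferential neighbours).
#' @param h neighbour order, `0 <= h <= floor(n/2)`; `h = 0` keeps only
#'   radial springs.
#' @param k_scale overall stiffness scale (default `K_SPRING`).
#' @return a `spring_system` list: `rest` (positions), `radial` (data frame
#'   `i`, `k`, `l0`), `circ` (data frame `i`, `j`, `k`, `l0`), `h`.
#' @export
build_springs <- function(xy, h = 2, k_scale = K_SPRING) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  h <- as.integer(h)
  if (h < 0 || h > n %/% 2) stop("h must lie in 0..floor(n/2)")
  radii <- sqrt(rowSums(xy^2))
  if (any(radii < 1e-9)) stop("node on the central axis: springs degenerate")
  # circumferential springs: unordered pairs (i, i + h'), h' = 1..h
  circ <- NULL
  if (h > 0) {
    pairs <- do.call(rbind, lapply(seq_len(h), function(hp) {
      i <- seq_len(n)
      j <- ((i - 1 + hp) %% n) + 1
      cbind(pmin(i, j), pmax(i, j), hp)
    }))
    pairs <- pairs[!duplicated(pairs[, 1:2, drop = FALSE]), , drop = FALSE]
    l0 <- sqrt(rowSums((xy[pairs[, 1], , drop = FALSE] -
                          xy[pairs[, 2], , drop = FALSE])^2))
    circ <- data.frame(i = pairs[, 1], j = pairs[, 2], order = pairs[, 3],
                       k = k_scale / l0, l0 = l0)
  }
  # radial stiffness: half the weakest circumferential stiffness; with
  # h = 0 the first-neighbour chord defines the reference stiffness
  ref_l <- if (h > 0) max(circ$l0) else {
    2 * mean(radii) * sin(pi / n)
  }
  k_r <- 0.5 * k_scale / ref_l
  radial <- data.frame(i = seq_len(n), k = k_r, l0 = radii)
  structure(list(rest = xy, radial = radial, circ = circ, h = h),
            class = "spring_system")
}

#' Distance-covariant force covariance matrix
#'
#' The covariance between scalar forces on two nodes is an RBF kernel of
#' their distance, `exp(-d^2 / (2 sigma^2))`, scaled to variance
#' `(dmag / 3)^2` so that `dmag` covers about 99.7% (three SD) of the
#' sampling range. Distances are computed on radially equalized positions:
#' every node's lateral radius is replaced by the arithmetic mean radius
#' (angle and z kept), which preserves concentricity of bands during
#' deformation.
#'
#' @param xyz m-by-3 node positions, nm.
#' @param dmag deformation magnitude, nm, >= 0.
#' @param sigma kernel width, nm, > 0 (default half the mean radius).
#' @return the m-by-m covariance matrix `cov'` (zero matrix when
#'   `dmag = 0`), with attribute `"equalized"` holding the positions used.
#' @export
force_covariance <- function(xyz, dmag, sigma = NULL) {
  if (dmag < 0) stop("dmag must be >= 0")
  xyz <- as.matrix(xyz)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  rbar <- mean(r)
  if (is.null(sigma)) sigma <- 0.5 * rbar
  if (sigma <= 0) stop("sigma must be > 0")
  phi <- atan2(xyz[, 2], xyz[, 1])
  eq <- cbind(rbar * cos(phi), rbar * sin(phi), xyz[, 3])
  d2 <- as.matrix(stats::dist(eq))^2
  covp <- (dmag / 3)^2 * exp(-d2 / (2 * sigma^2))
  attr(covp, "equalized") <- eq
  covp
}

#' Sample scalar forces from the force covariance
#'
#' One draw from `N(0, cov')` via Cholesky factorization; a relative jitter
#' of at most 1e-10 is added to the diagonal only if factorization fails.
#'
#' @param covp covariance matrix from [force_covariance()].
#' @return numeric vector of scalar forces, one per node.
#' @export
sample_scalar_forces <- function(covp) {
  m <- nrow(covp)
  dg <- max(diag(covp))
  if (dg == 0) return(numeric(m))
  up <- tryCatch(chol(covp), error = function(e) NULL)
  if (is.null(up)) {
    up <- tryCatch(chol(covp + diag(1e-10 * dg, m)), error = function(e) NULL)
  }
  if (is.null(up)) stop("force covariance is not positive semi-definite")
  drop(crossprod(up, stats::rnorm(m)))
}

#' Turn scalar forces into radial, planar force vectors
#'
#' Each scalar force becomes a vector along the node's lateral unit vector
#' with zero z-component, so the force set is torque-free about the central
#' axis (no net rotation or flip).
#'
#' @param f scalar forces, one per node.
#' @param xyz node positions (m-by-2 or m-by-3).
#' @return m-by-3 matrix of force vectors.
#' @export
radialize <- function(f, xyz) {
  xyz <- as.matrix(xyz)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  if (any(r < 1e-9)) stop("node at the central axis: radial direction undefined")
  cbind(f * xyz[, 1] / r, f * xyz[, 2] / r, 0)
}

# topology-dependent scatter/gather helpers, cached per (n, edge set)
.npcsim_topo_cache <- new.env(parent = emptyenv())

spring_topology <- function(n, ci, cj) {
  key <- paste0(n, ":", paste(ci, cj, collapse = ","))
  hit <- .npcsim_topo_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- length(ci)
  # incidence matrix for gradient accumulation over edges
  B <- matrix(0, n, e)
  B[cbind(ci, seq_len(e))] <- 1
  B[cbind(cj, seq_len(e))] <- -1
  # triplet layout of the Hessian: radial diagonal blocks then the four
  # 2x2 blocks of every edge; positions are fixed, values change per call
  i <- seq_len(n)
  rows <- c(i, i, i + n, i + n)
  cols <- c(i, i + n, i, i + n)
  if (e > 0) {
    rows <- c(rows, ci, ci, ci + n, ci + n, cj, cj, cj + n, cj + n,
              ci, ci, ci + n, ci + n, cj, cj, cj + n, cj + n)
    cols <- c(cols, ci, ci + n, ci, ci + n, cj, cj + n, cj, cj + n,
              cj, cj + n, cj, cj + n, ci, ci + n, ci, ci + n)
  }
  idx <- (cols - 1) * (2 * n) + rows
  uidx <- sort(unique(idx))
  map <- match(idx, uidx)
  A <- matrix(0, length(uidx), length(idx))
  A[cbind(map, seq_along(idx))] <- 1
  out <- list(B = B, uidx = uidx, A = A)
  .npcsim_topo_cache[[key]] <- out
  out
}

# Total potential of one band under radial external forces.
#
# The external force on node i has fixed signed magnitude f_i and stays
# directed along the node's current lateral unit vector, contributing
# -f_i * |x_i| to the potential. This makes the potential invariant under
# rigid rotation of the band about the central axis, so the force field
# exerts no torque at any configuration -- deforming forces can never
# rotate or flip a band, which is the very reason the force field is radial.
# (A fixed force *vector* per node would instead make the unrotated
# equilibrium rotationally unstable whenever the net force pulls inward.)
spring_energy_fns <- function(springs, f_radial) {
  n <- nrow(springs$rest)
  rk <- springs$radial$k
  rl0 <- springs$radial$l0
  f <- f_radial
  has_circ <- !is.null(springs$circ)
  if (has_circ) {
    ci <- springs$circ$i
    cj <- springs$circ$j
    ck <- springs$circ$k
    cl0 <- springs$circ$l0
  } else {
    ci <- integer(0)
    cj <- integer(0)
  }
  topo <- spring_topology(n, ci, cj)
  fn <- function(p) {
    x <- p[1:n]; y <- p[(n + 1):(2 * n)]
    lr <- sqrt(x^2 + y^2)
    u <- 0.5 * sum(rk * (lr - rl0)^2) - sum(f * lr)
    if (has_circ) {
      dx <- x[ci] - x[cj]
      dy <- y[ci] - y[cj]
      lc <- sqrt(dx^2 + dy^2)
      u <- u + 0.5 * sum(ck * (lc - cl0)^2)
    }
    u
  }
  gr <- function(p) {
    x <- p[1:n]; y <- p[(n + 1):(2 * n)]
    lr <- sqrt(x^2 + y^2)
    cr <- (rk * (lr - rl0) - f) / lr
    gx <- cr * x
    gy <- cr * y
    if (has_circ) {
      dx <- x[ci] - x[cj]
      dy <- y[ci] - y[cj]
      lc <- sqrt(dx^2 + dy^2)
      cc <- ck * (lc - cl0) / lc
      gx <- gx + drop(topo$B %*% (cc * dx))
      gy <- gy + drop(topo$B %*% (cc * dy))
    }
    c(gx, gy)
  }
  hess <- function(p) {
    # per-node radial term (spring + force): w(L) = rk (L - l0) - f;
    # H = (w/L) I + (rk - w/L)/L^2 x x^T; edge blocks analogous
    x <- p[1:n]; y <- p[(n + 1):(2 * n)]
    lr <- sqrt(x^2 + y^2)
    c1 <- (rk * (lr - rl0) - f) / lr
    c2 <- (rk - c1) / lr^2
    bxx <- c1 + c2 * x^2
    bxy <- c2 * x * y
    byy <- c1 + c2 * y^2
    vals <- c(bxx, bxy, bxy, byy)
    if (has_circ) {
      dx <- x[ci] - x[cj]
      dy <- y[ci] - y[cj]
      lc <- sqrt(dx^2 + dy^2)
      c1 <- ck * (lc - cl0) / lc
      c2 <- (ck - c1) / lc^2
      bxx <- c1 + c2 * dx^2
      bxy <- c2 * dx * dy
      byy <- c1 + c2 * dy^2
      vals <- c(vals, bxx, bxy, bxy, byy, bxx, bxy, bxy, byy,
                -bxx, -bxy, -bxy, -byy, -bxx, -bxy, -bxy, -byy)
    }
    H <- matrix(0, 2 * n, 2 * n)
    H[topo$uidx] <- topo$A %*% vals
    # the rigid-rotation mode is exactly neutral (zero gradient and zero
    # curvature); penalize it so the Newton system is well conditioned --
    # the penalty is orthogonal to the gradient and cannot bias the optimum
    v <- c(-y, x)
    vn2 <- sum(v^2)
    if (vn2 > 0) {
      mu <- mean(abs(diag(H)))
      H <- H + (mu / vn2) * tcrossprod(v)
    }
    H
  }
  list(fn = fn, gr = gr, hess = hess, n = n)
}

#' Relax one band to its static equilibrium
#'
#' Minimizes the total potential (spring energy minus the work of the
#' external radial forces) over the band's lateral coordinates; z is frozen
#' during relaxation. Each external force keeps its signed magnitude and
#' stays directed along its node's current lateral unit vector, so the
#' force field is torque-free at every configuration and the band can
#' neither rotate nor flip. A damped Newton iteration (analytic gradient
#' and Hessian, Levenberg regularization, per-node step cap, monotone
#' energy decrease) follows the equilibrium a damped physical system would
#' settle into. The residual per-node net force at the solution must fall
#' below `tol` or an error is raised.
#'
#' @param springs a `spring_system` from [build_springs()].
#' @param force external forces: either a length-n vector of signed radial
#'   magnitudes (positive = outward), or an n-by-2/3 matrix of force
#'   vectors, which are projected onto the rest-state radial directions.
#' @param tol maximum allowed per-node residual net-force norm
#'   (default 1e-6).
#' @param step_cap maximum per-node displacement per Newton step, nm.
#' @param max_iter iteration budget.
#' @return n-by-2 matrix of equilibrium lateral positions, with attribute
#'   `"residual"` (the achieved maximum per-node net-force norm).
#' @export
relax <- function(springs, force, tol = 1e-6, step_cap = 3,
                  max_iter = 500) {
  n <- nrow(springs$rest)
  if (is.matrix(force) || is.data.frame(force)) {
    force <- as.matrix(force)
    lr <- sqrt(springs$rest[, 1]^2 + springs$rest[, 2]^2)
    force <- (force[, 1] * springs$rest[, 1] +
                force[, 2] * springs$rest[, 2]) / lr
  }
  if (length(force) != n || !all(is.finite(force))) {
    stop("external forces must be finite, one per node")
  }
  efn <- spring_energy_fns(springs, force)
  p <- c(springs$rest[, 1], springs$rest[, 2])
  node_norms <- function(v) sqrt(v[1:n]^2 + v[(n + 1):(2 * n)]^2)
  g <- efn$gr(p)
  resid <- max(node_norms(g))
  u <- efn$fn(p)
  iter <- 0
  lambda <- 0
  while (resid > tol && iter < max_iter) {
    iter <- iter + 1
    H <- efn$hess(p)
    scale <- mean(abs(diag(H)))
    repeat {
      step <- tryCatch(solve(H + diag(lambda, 2 * n), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        # remove any residual rigid-rotation drift (neutral mode)
        v <- c(-p[(n + 1):(2 * n)], p[1:n])
        step <- step - v * (sum(step * v) / sum(v^2))
        mx <- max(node_norms(step))
        if (mx > step_cap) step <- step * (step_cap / mx)
        u_new <- efn$fn(p + step)
        if (is.finite(u_new) && u_new <= u + 1e-12 * abs(u)) break
      }
      lambda <- if (lambda == 0) 1e-4 * scale else 10 * lambda
      if (lambda > 1e12 * scale) {
        stop("spring relaxation stalled: Levenberg damping exhausted")
      }
    }
    p <- p + step
    u <- efn$fn(p)
    g <- efn$gr(p)
    resid <- max(node_norms(g))
    lambda <- lambda / 4
  }
  if (resid > tol) {
    stop(sprintf("spring relaxation did not converge: residual %.3e > %.1e",
                 resid, tol))
  }
  out <- cbind(p[1:n], p[(n + 1):(2 * n)])
  attr(out, "residual") <- resid
  out
}

#' Sample correlated axial offsets
#'
#' Offsets are sampled exactly like scalar forces (same kernel, radially
#' equalized distances) but with magnitude `omag` and from an independent
#' random stream, and are applied additively to z without any spring
#' interaction.
#'
#' @param xyz m-by-3 node positions.
#' @param omag axial offset magnitude, nm, >= 0 (default `dmag / 2`
#'   upstream).
#' @param sigma kernel width, nm (default half the mean radius).
#' @return numeric vector of z offsets, one per node.
#' @export
sample_axial_offsets <- function(xyz, omag, sigma = NULL) {
  if (omag < 0) stop("omag must be >= 0")
  covp <- force_covariance(xyz, omag, sigma)
  sample_scalar_forces(covp)
}

#' Deform an assembled model with correlated forces and axial offsets
#'
#' Samples one scalar force field jointly over all nodes of all bands (the
#' shared covariance keeps adjacent bands from overlapping), adds elongation
#' forces when `q < 1`, radializes, relaxes each band separately against its
#' own spring system, and finally applies correlated axial offsets. All
#' randomness derives from `seed` via named streams and `index`.
#'
#' @param model an `npc_model`.
#' @param dmag lateral deformation magnitude, nm.
#' @param omag axial offset magnitude, nm (default `dmag / 2`).
#' @param q elongation axis ratio in (0, 1]; 1 disables elongation.
#' @param kernel_fraction RBF width as a fraction of the mean radius.
#' @param h circumferential neighbour order.
#' @param seed master seed.
#' @param index per-NPC counter for stream derivation.
#' @return the deformed model; `provenance` records the applied magnitudes
#'   and the maximum relaxation residual.
#' @export
deform_npc <- function(model, dmag, omag = dmag / 2, q = 1,
                       kernel_fraction = 0.5, h = 2, seed = 1, index = 0L) {
  if (dmag == 0 && q == 1 && omag == 0) {
    model$provenance$dmag <- 0
    model$provenance$omag <- 0
    return(model)
  }
  nodes <- model$nodes
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  rbar <- mean_radius(model)
  sigma <- kernel_fraction * rbar
  f <- numeric(nrow(nodes))
  if (dmag > 0) {
    covp <- force_covariance(xyz, dmag, sigma)
    f <- with_seed(derive_seed(seed, "forces", index),
                   sample_scalar_forces(covp))
  }
  if (q < 1) {
    f <- f + with_seed(derive_seed(seed, "elongation", index),
                       elongation_forces(model, q))
  }
  max_resid <- 0
  if (any(f != 0)) {
    for (b in seq_len(model$g)) {
      idx <- which(nodes$band == b)
      h_b <- min(h, length(idx) %/% 2)
      springs <- build_springs(xyz[idx, 1:2, drop = FALSE], h = h_b)
      eq <- relax(springs, f[idx])
      nodes$x[idx] <- eq[, 1]
      nodes$y[idx] <- eq[, 2]
      max_resid <- max(max_resid, attr(eq, "residual"))
    }
  }
  if (omag > 0) {
    o <- with_seed(derive_seed(seed, "axial", index), {
      sample_axial_offsets(xyz, omag, sigma)
    })
    nodes$z <- nodes$z + o
  }
  model$nodes <- nodes
  model$provenance$dmag <- dmag
  model$provenance$omag <- omag
  model$provenance$q <- q
  model$provenance$relax_residual <- max_resid
  model
}
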