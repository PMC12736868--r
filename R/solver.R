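# Quasi-static complex conduction on a layered cylindrical torso.
#
# The domain is discretized with a structured finite-volume mesh in
# cylindrical coordinates (r, theta, z). Radial grid lines are pinned to the
# muscle|fat and fat|skin interfaces so each cell holds a single tissue; the
# spherical bladder is represented by per-cell urine volume fractions with
# linear mixing of the complex conductivities. The theta and z grids are
# nonuniform, clustered around the electrode belt, and exactly
# mirror-symmetric about the anterior midline. Electrodes follow the
# complete electrode model: each gel patch is an equipotential coupled to
# the boundary cells through an effective contact impedance, with a
# prescribed net current per electrode; potentials are reported under a
# zero-mean electrode reference.
#
# The complex symmetric system K = K_re + i K_im is solved by conjugate
# gradients with unconjugated inner products (COCG), preconditioned by a
# sparse Cholesky factorization of K_re; the factorization is computed once
# per configuration and reused across all 15 right-hand sides.

mesh_dims <- function(level) {
  if (level < 1) stop("resolution level must be >= 1")
  list(n_muscle = 8 + 4 * level,
       n_fat = 1 + level,
       n_skin = 1,
       n_elec = 2 + level,        # theta cells across one electrode patch
       n_gap = 2 + level,         # theta cells in each inter-electrode gap
       n_post = 2 * (4 + level),  # theta cells over the posterior sector
       n_z_band = 2 + 2 * level,  # z cells across the electrode band
       n_z_out = 3 + level)       # z cells above/below the band (stretched)
}

# Theta edges aligned with the electrode patch boundaries: each patch arc
# and each inter-electrode gap is meshed uniformly, so patch coverage
# converges smoothly under refinement. The grid is exactly mirror-symmetric
# about the anterior midline (theta = 0).
theta_grid <- function(a, dims) {
  ar <- a$electrode_radius_m / a$outer_radius_m  # patch half-angle (rad)
  th <- sort(a$electrode_angles_deg) * pi / 180
  breaks <- c(-pi, as.vector(rbind(th - ar, th + ar)), pi)
  ncell <- integer(length(breaks) - 1)
  ncell[seq(2, 12, by = 2)] <- dims$n_elec                # the 6 patches
  ncell[seq(3, 11, by = 2)] <- dims$n_gap                 # 5 anterior gaps
  ncell[c(1, 13)] <- dims$n_post / 2                      # posterior halves
  edges <- numeric(0)
  for (s in seq_along(ncell)) {
    seg <- seq(breaks[s], breaks[s + 1], length.out = ncell[s] + 1)
    edges <- c(edges, if (s == 1) seg else seg[-1])
  }
  edges
}

# z edges: uniform across the electrode band [z0 - R, z0 + R], geometrically
# stretched towards the cylinder ends; symmetric about mid-height.
z_grid <- function(a, dims, ratio = 1.5) {
  z0 <- a$height_m / 2
  R <- a$electrode_radius_m
  band <- seq(z0 - R, z0 + R, length.out = dims$n_z_band + 1)
  w <- ratio^seq_len(dims$n_z_out)
  below <- c(0, cumsum(rev(w))) / sum(w) * (z0 - R)        # coarse -> fine
  above <- z0 + R + cumsum(w) / sum(w) * (a$height_m - z0 - R)
  c(below[-length(below)], band, above)
}

#' Discretize an anatomy into a solvable conduction model
#'
#' @param a a feasible [build_anatomy()] anatomy.
#' @param frequency_hz working frequency (Hz).
#' @param level integer mesh resolution level (>= 1); cell counts grow
#'   linearly with the level in every direction.
#' @param tissues optional named list overriding the shipped
#'   [tissue_table()] sets; names among muscle, fat_infiltrated, skin_dry,
#'   bladder_urine, electrode_gel.
#' @param conductivity_scale multiply every tissue complex conductivity
#'   (the contact impedance scales along with the gel conductivity);
#'   used for linearity checks.
#' @return a `conduction_model` carrying the assembled sparse operator.
#' @export
discretize <- function(a, frequency_hz, level = 2, tissues = NULL,
                       conductivity_scale = 1) {
  stopifnot(inherits(a, "anatomy"))
  if (!is_feasible(a)) {
    stop("infeasible anatomy: bladder intersects the subcutaneous fat shell")
  }
  if (frequency_hz <= 0) stop("frequency must be > 0")

  tis <- list(muscle = tissue_table("muscle"),
              fat_infiltrated = tissue_table("fat_infiltrated"),
              skin_dry = tissue_table("skin_dry"),
              bladder_urine = tissue_table("bladder_urine"),
              electrode_gel = tissue_table("electrode_gel"))
  if (!is.null(tissues)) tis[names(tissues)] <- tissues
  sig <- lapply(tis, function(t) {
    complex_conductivity(t, frequency_hz) * conductivity_scale
  })

  dims <- mesh_dims(level)
  r_m <- a$muscle_radius_m
  r_sf <- a$outer_radius_m - a$skin_m
  r_out <- a$outer_radius_m
  r_edges <- c(seq(0, r_m, length.out = dims$n_muscle + 1),
               seq(r_m, r_sf, length.out = dims$n_fat + 1)[-1],
               seq(r_sf, r_out, length.out = dims$n_skin + 1)[-1])
  t_edges <- theta_grid(a, dims)
  z_edges <- z_grid(a, dims)
  nr <- length(r_edges) - 1
  nt <- length(t_edges) - 1
  nz <- length(z_edges) - 1
  r_c <- (r_edges[-1] + r_edges[-(nr + 1)]) / 2
  dr <- diff(r_edges)
  dth <- diff(t_edges)
  t_c <- t_edges[-(nt + 1)] + dth / 2
  dzv <- diff(z_edges)

  region <- rep(c("muscle", "fat", "skin"),
                c(dims$n_muscle, dims$n_fat, dims$n_skin))
  sigma_r <- c(rep(sig$muscle, dims$n_muscle),
               rep(sig$fat_infiltrated, dims$n_fat),
               rep(sig$skin_dry, dims$n_skin))
  n_cells <- nr * nt * nz
  cid <- function(i, j, k) i + (j - 1) * nr + (k - 1) * nr * nt
  sigma <- rep(sigma_r, times = nt * nz)

  # bladder urine volume fractions (muscle cells only)
  frac <- bladder_fractions(r_edges, t_edges, z_edges, dims$n_muscle,
                            a$anterior_offset_m, a$bladder_radius_m,
                            a$height_m / 2)
  if (nrow(frac$cells) > 0) {
    ids <- cid(frac$cells$i, frac$cells$j, frac$cells$k)
    sigma[ids] <- frac$cells$frac * sig$bladder_urine +
      (1 - frac$cells$frac) * sig$muscle
  }

  trip <- assemble_faces(nr, nt, nz, r_edges, r_c, dr, t_edges, t_c, dth,
                         dzv, sigma, cid)

  # complete electrode model couplings
  z_contact <- a$electrode_thickness_m / sig$electrode_gel
  el <- electrode_faces(a, t_edges, z_edges, nt, nz)
  bcells <- cid(nr, el$j, el$k)
  g_el <- el$area / (z_contact + (dr[nr] / 2) / sigma[bcells])
  eidx <- n_cells + el$electrode
  n <- n_cells + 6

  ti <- c(trip$p, trip$q, trip$p, trip$q, bcells, eidx, bcells, eidx)
  tj <- c(trip$q, trip$p, trip$p, trip$q, bcells, eidx, eidx, bcells)
  tx <- c(-trip$g, -trip$g, trip$g, trip$g, g_el, g_el, -g_el, -g_el)

  # ground electrode 6 (drop its row/column); the returned potentials are
  # re-referenced to a zero mean over the 6 electrodes after each solve
  gnd <- n_cells + 6L
  keep <- ti != gnd & tj != gnd
  ti <- ti[keep]; tj <- tj[keep]; tx <- tx[keep]
  K_re <- Matrix::sparseMatrix(i = ti, j = tj, x = Re(tx),
                               dims = c(n - 1, n - 1))
  K_im <- Matrix::sparseMatrix(i = ti, j = tj, x = Im(tx),
                               dims = c(n - 1, n - 1))
  chol_re <- Matrix::Cholesky(Matrix::forceSymmetric(K_re), LDL = FALSE,
                              super = TRUE)

  structure(list(
    anatomy = a, frequency_hz = frequency_hz, level = level,
    dims = c(nr = nr, nt = nt, nz = nz), n_cells = n_cells,
    r_edges = r_edges, theta_edges = t_edges, z_edges = z_edges,
    region = region, sigma = sigma, z_contact = z_contact,
    bladder_volume_ml = frac$volume_m3 * 1e6,
    electrode_faces = el,
    K_re = K_re, K_im = K_im, chol_re = chol_re
  ), class = "conduction_model")
}

# Urine volume fraction of every muscle cell intersecting the bladder
# sphere, by midpoint subsampling with the cylindrical Jacobian weight.
bladder_fractions <- function(r_edges, t_edges, z_edges, n_muscle,
                              d_off, rb, z0, ns = 6) {
  nr_m <- n_muscle
  r1 <- r_edges[seq_len(nr_m)]
  r2 <- r_edges[seq_len(nr_m) + 1]
  nt <- length(t_edges) - 1
  nz <- length(z_edges) - 1

  cand <- expand.grid(i = seq_len(nr_m), j = seq_len(nt), k = seq_len(nz))
  cand$r1 <- r1[cand$i]; cand$r2 <- r2[cand$i]
  cand$t1 <- t_edges[cand$j]; cand$t2 <- t_edges[cand$j + 1]
  cand$z1 <- z_edges[cand$k]; cand$z2 <- z_edges[cand$k + 1]
  t_max <- if (rb >= d_off) pi else asin(rb / d_off)
  keep <- cand$r2 > d_off - rb & cand$r1 < d_off + rb &
    cand$z2 > z0 - rb & cand$z1 < z0 + rb &
    cand$t1 <= t_max & cand$t2 >= -t_max
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(cells = cand, volume_m3 = 0))
  }

  u <- (seq_len(ns) - 0.5) / ns
  g <- expand.grid(u1 = u, u2 = u, u3 = u)
  rs <- matrix(cand$r1, nrow(cand), nrow(g)) + outer(cand$r2 - cand$r1, g$u1)
  ts <- matrix(cand$t1, nrow(cand), nrow(g)) + outer(cand$t2 - cand$t1, g$u2)
  zs <- matrix(cand$z1, nrow(cand), nrow(g)) + outer(cand$z2 - cand$z1, g$u3)
  inside <- (rs * cos(ts) - d_off)^2 + (rs * sin(ts))^2 + (zs - z0)^2 <= rb^2
  cand$frac <- rowSums(rs * inside) / rowSums(rs)
  cand <- cand[cand$frac > 0, , drop = FALSE]
  v_cell <- 0.5 * (cand$r2^2 - cand$r1^2) *
    (cand$t2 - cand$t1) * (cand$z2 - cand$z1)
  list(cells = cand, volume_m3 = sum(cand$frac * v_cell))
}

# Two-point flux conductances for all interior faces (radial, angular with
# wrap-around, axial). Returns parallel vectors p, q (cell ids), g (complex).
assemble_faces <- function(nr, nt, nz, r_edges, r_c, dr, t_edges, t_c, dth,
                           dzv, sigma, cid) {
  # radial faces between (i, j, k) and (i+1, j, k)
  ii <- rep(seq_len(nr - 1), times = nt * nz)
  jj <- rep(rep(seq_len(nt), each = nr - 1), times = nz)
  kk <- rep(seq_len(nz), each = (nr - 1) * nt)
  p1 <- cid(ii, jj, kk); q1 <- cid(ii + 1, jj, kk)
  a_r <- r_edges[ii + 1] * dth[jj] * dzv[kk]
  d1 <- r_edges[ii + 1] - r_c[ii]
  d2 <- r_c[ii + 1] - r_edges[ii + 1]
  g1 <- a_r / (d1 / sigma[p1] + d2 / sigma[q1])

  # angular faces between (i, j, k) and (i, j+1, k), wrapping nt -> 1;
  # half arc-widths give the two-point distances on either side of the face
  ii <- rep(seq_len(nr), times = nt * nz)
  jj <- rep(rep(seq_len(nt), each = nr), times = nz)
  kk <- rep(seq_len(nz), each = nr * nt)
  jn <- ifelse(jj == nt, 1L, jj + 1L)
  p2 <- cid(ii, jj, kk); q2 <- cid(ii, jn, kk)
  a_t <- dr[ii] * dzv[kk]
  g2 <- a_t / (r_c[ii] * (dth[jj] / 2) / sigma[p2] +
                 r_c[ii] * (dth[jn] / 2) / sigma[q2])

  # axial faces between (i, j, k) and (i, j, k+1)
  ii <- rep(seq_len(nr), times = nt * (nz - 1))
  jj <- rep(rep(seq_len(nt), each = nr), times = nz - 1)
  kk <- rep(seq_len(nz - 1), each = nr * nt)
  p3 <- cid(ii, jj, kk); q3 <- cid(ii, jj, kk + 1)
  a_z <- r_c[ii] * dr[ii] * dth[jj]
  g3 <- a_z / ((dzv[kk] / 2) / sigma[p3] + (dzv[kk + 1] / 2) / sigma[q3])

  list(p = c(p1, p2, p3), q = c(q1, q2, q3), g = c(g1, g2, g3))
}

# Covered boundary-face areas for each circular electrode patch, by
# deterministic midpoint sampling of the disc in unrolled (arc, z)
# coordinates. The sample grid is symmetric, so mirror-image electrodes map
# onto mirror-image faces exactly.
electrode_faces <- function(a, t_edges, z_edges, nt, nz, ns = 16) {
  r_out <- a$outer_radius_m
  R <- a$electrode_radius_m
  z0 <- a$height_m / 2
  u <- -R + (seq_len(ns) - 0.5) * 2 * R / ns
  g <- expand.grid(u = u, v = u)
  g <- g[g$u^2 + g$v^2 <= R^2, ]
  da <- (2 * R / ns)^2

  out <- list()
  for (e in seq_along(a$electrode_angles_deg)) {
    th <- a$electrode_angles_deg[e] * pi / 180 + g$u / r_out
    zz <- z0 + g$v
    j <- findInterval(th, t_edges, rightmost.closed = TRUE)
    k <- findInterval(zz, z_edges, rightmost.closed = TRUE)
    ok <- j >= 1 & j <= nt & k >= 1 & k <= nz
    key <- paste(j[ok], k[ok])
    agg <- table(key)
    jk <- do.call(rbind, strsplit(names(agg), " "))
    out[[e]] <- data.frame(electrode = e,
                           j = as.integer(jk[, 1]), k = as.integer(jk[, 2]),
                           area = as.numeric(agg) * da)
  }
  do.call(rbind, out)
}

#' @export
print.conduction_model <- function(x, ...) {
  cat(sprintf(
    "<conduction_model: %d cells (%d x %d x %d), f = %g kHz, level %d>\n",
    x$n_cells, x$dims["nr"], x$dims["nt"], x$dims["nz"],
    x$frequency_hz / 1e3, x$level))
  cat(sprintf("  discretized bladder volume: %.2f mL (requested %g mL)\n",
              x$bladder_volume_ml, x$anatomy$bladder_volume_ml))
  invisible(x)
}

# Preconditioned conjugate gradients for the complex symmetric system
# (unconjugated inner products), M = Cholesky(K_re). b is real.
solve_cocg <- function(m, b, tol = 1e-12, maxit = 400) {
  matvec <- function(xr, xi) {
    list(re = as.numeric(m$K_re %*% xr - m$K_im %*% xi),
         im = as.numeric(m$K_re %*% xi + m$K_im %*% xr))
  }
  prec <- function(rr, ri) {
    complex(real = as.numeric(Matrix::solve(m$chol_re, rr)),
            imaginary = as.numeric(Matrix::solve(m$chol_re, ri)))
  }
  nb <- sqrt(sum(b^2))
  x <- complex(real = numeric(length(b)), imaginary = numeric(length(b)))
  r <- complex(real = b, imaginary = numeric(length(b)))
  z <- prec(Re(r), Im(r))
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    q <- matvec(Re(p), Im(p))
    q <- complex(real = q$re, imaginary = q$im)
    alpha <- rz / sum(p * q)
    x <- x + alpha * p
    r <- r - alpha * q
    if (sqrt(sum(Mod(r)^2)) / nb < tol) {
      return(x)
    }
    z <- prec(Re(r), Im(r))
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("COCG did not reach tol %g in %d iterations", tol, maxit))
}

#' Solve one current-carrying pair
#'
#' Drives `current` amperes between electrodes `cc[1]` (+) and `cc[2]` (-)
#' with zero net current through the remaining electrodes (complete
#' electrode model), and returns the complex electrode potentials under a
#' zero-mean reference over the six electrodes.
#'
#' @param m a `conduction_model`.
#' @param cc integer pair of distinct electrode indices in 1..6.
#' @param current injected current in A.
#' @return list with `U` (6 complex electrode potentials), `cc`, `current`,
#'   `frequency_hz`.
#' @export
solve_cc_pair <- function(m, cc, current = 1e-3) {
  stopifnot(inherits(m, "conduction_model"))
  if (length(cc) != 2 || cc[1] == cc[2] || any(cc < 1) || any(cc > 6)) {
    stop("cc must be two distinct electrode indices in 1..6")
  }
  U <- solve_electrodes(m, matrix(as.integer(cc), nrow = 2), current)[, 1]
  list(U = U, cc = as.integer(cc), current = current,
       frequency_hz = m$frequency_hz)
}

#' Solve all 15 current-carrying pairs of the six-electrode belt
#'
#' The operator is factorized once per configuration and the factorization
#' is reused across the 15 right-hand sides.
#'
#' @inheritParams solve_cc_pair
#' @return list with `U` (6 x 15 complex electrode-potential matrix, columns
#'   in lexicographic CC-pair order), `cc_pairs` (2 x 15), `current`,
#'   `frequency_hz`.
#' @export
solve_all_pairs <- function(m, current = 1e-3) {
  stopifnot(inherits(m, "conduction_model"))
  cc_pairs <- utils::combn(6, 2)
  U <- solve_electrodes(m, cc_pairs, current)
  list(U = U, cc_pairs = cc_pairs, current = current,
       frequency_hz = m$frequency_hz)
}

solve_electrodes <- function(m, cc_pairs, current) {
  n_unknown <- m$n_cells + 5L
  U <- matrix(complex(real = NA_real_), 6, ncol(cc_pairs))
  for (p in seq_len(ncol(cc_pairs))) {
    b <- numeric(n_unknown)
    cc <- cc_pairs[, p]
    if (cc[1] != 6) b[m$n_cells + cc[1]] <- current
    if (cc[2] != 6) b[m$n_cells + cc[2]] <- -current
    x <- solve_cocg(m, b)
    u <- c(x[m$n_cells + 1:5], 0 + 0i)
    U[, p] <- u - mean(u)
  }
  U
}

#' Frame voltages from solved electrode potentials
#'
#' @param sol output of [solve_all_pairs()].
#' @param frames output of [enumerate_frames()] for 6 electrodes.
#' @return named complex vector of PU differential voltages, one per frame.
#' @export
frame_voltages <- function(sol, frames = enumerate_frames(6)) {
  cc_key <- paste(sol$cc_pairs[1, ], sol$cc_pairs[2, ])
  col <- match(paste(frames$cc1, frames$cc2), cc_key)
  v <- sol$U[cbind(frames$pu1, col)] - sol$U[cbind(frames$pu2, col)]
  names(v) <- frames$frame
  v
}
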