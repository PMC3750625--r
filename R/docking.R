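# van der Waals radii (A) by element, used for grid digitization
.vdw_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, SE = 1.9, H = 1.2)

atom_radii <- function(model) {
  # reduced (united-residue) models carry their own radius column
  if (!is.null(model$radius)) return(as.numeric(model$radius))
  r <- .vdw_radii[toupper(model$elesy)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Digitize a chain model onto a docking grid
#'
#' First step of the shape-complementarity correlation algorithm: atoms
#' are rasterized onto a cubic grid. For the `static` partner the grid
#' is a soft two-zone model: voxels inside the clash zone (within
#' `radius - soft_margin` of any atom) carry the large negative
#' `core_weight`, and the contact skin — from the clash zone out to
#' `radius + surface_thickness` — carries weight 1. The `soft_margin`
#' absorbs grid quantization and coordinate noise, so grazing contacts
#' score as contacts rather than clashes. The `mobile` partner is
#' uniformly weighted 1 inside its van der Waals (or united-residue)
#' volume. A second channel accumulates residue-level partial charges.
#'
#' @param model A [chain_model()].
#' @param spacing Grid spacing (A).
#' @param surface_thickness Contact skin thickness beyond the atom
#'   radius (A).
#' @param role `"static"` or `"mobile"`.
#' @param core_weight Clash-zone weight for the static partner.
#' @param soft_margin Clash-zone shrinkage (A).
#' @param n Grid points per axis; defaults to a tight box around the
#'   model.
#' @param origin Cartesian position of the first voxel center; defaults
#'   to centering the model in the box.
#' @return Object of class `dock_grid`: list with `shape` and `charge`
#'   arrays, `spacing`, `origin`, `n`, `role`.
#' @export
discretize <- function(model, spacing = 1.0, surface_thickness = 2.0,
                       role = c("static", "mobile"), core_weight = -15,
                       soft_margin = 1.0, n = NULL, origin = NULL) {
  role <- match.arg(role)
  stopifnot(spacing > 0)
  if (!nrow(model)) stop("empty model")
  xyz <- as.matrix(model[, c("x", "y", "z")])
  rad <- atom_radii(model)
  if (is.null(n)) {
    ext <- max(apply(xyz, 2, function(v) diff(range(v)))) +
      2 * (max(rad) + surface_thickness) + 2
    n <- stats::nextn(ceiling(ext / spacing), c(2, 3, 5))
  }
  if (is.null(origin)) {
    ctr <- colMeans(xyz)
    origin <- ctr - (n - 1) / 2 * spacing
  }
  if (n > 200) stop("protein larger than maximum grid")
  idx <- sweep(xyz, 2, origin) / spacing   # 0-based fractional voxel coords
  fill <- function(radii) {
    filled <- array(FALSE, dim = c(n, n, n))
    rv <- radii / spacing
    for (a in seq_len(nrow(xyz))) {
      if (rv[a] <= 0) next
      lo <- pmax(0L, floor(idx[a, ] - rv[a]))
      hi <- pmin(n - 1L, ceiling(idx[a, ] + rv[a]))
      if (any(lo > hi)) next
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      dx2 <- (gx - idx[a, 1])^2; dy2 <- (gy - idx[a, 2])^2
      dz2 <- (gz - idx[a, 3])^2
      cube <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rv[a]^2
      filled[gx + 1L, gy + 1L, gz + 1L] <-
        filled[gx + 1L, gy + 1L, gz + 1L] | cube
    }
    filled
  }
  shape <- array(0, dim = c(n, n, n))
  if (role == "mobile") {
    shape[fill(rad)] <- 1
  } else {
    hard <- fill(pmax(rad - soft_margin, 0.1))
    # every atom center contributes a clash voxel even when the shrunken
    # radius falls below the grid resolution
    ctr_idx <- pmin(pmax(round(idx), 0L), n - 1L) + 1L
    hard[ctr_idx] <- TRUE
    grown <- fill(rad + surface_thickness)
    shape[grown & !hard] <- 1
    shape[hard] <- core_weight
  }
  charge <- array(0, dim = c(n, n, n))
  cp <- charge_points(model)
  if (nrow(cp)) {
    ci <- round(sweep(as.matrix(cp[, c("x", "y", "z")]), 2, origin) / spacing)
    keep <- apply(ci >= 0 & ci <= n - 1, 1, all)
    ci <- ci[keep, , drop = FALSE]
    q <- cp$q[keep]
    for (a in seq_along(q))
      charge[ci[a, 1] + 1L, ci[a, 2] + 1L, ci[a, 3] + 1L] <-
        charge[ci[a, 1] + 1L, ci[a, 2] + 1L, ci[a, 3] + 1L] + q[a]
  }
  structure(list(shape = shape, charge = charge, spacing = spacing,
                 origin = origin, n = n, role = role),
            class = "dock_grid")
}

# residue-level partial charge model: Lys/Arg +1, Asp/Glu -1, placed on a
# representative side-chain atom (fallback CB, then CA)
charge_points <- function(model) {
  reps <- list(LYS = c("NZ", "CB", "CA"), ARG = c("CZ", "CB", "CA"),
               ASP = c("CG", "CB", "CA"), GLU = c("CD", "CB", "CA"))
  qs <- c(LYS = 1, ARG = 1, ASP = -1, GLU = -1)
  out <- list()
  for (rn in unique(model$resno)) {
    rows <- model[model$resno == rn, , drop = FALSE]
    resid <- rows$resid[1]
    if (!resid %in% names(reps)) next
    atom <- intersect(reps[[resid]], rows$elety)[1]
    if (is.na(atom)) next
    at <- rows[rows$elety == atom, , drop = FALSE][1, ]
    out[[length(out) + 1L]] <- data.frame(x = at$x, y = at$y, z = at$z,
                                          q = unname(qs[resid]))
  }
  if (!length(out)) return(data.frame(x = numeric(), y = numeric(),
                                      z = numeric(), q = numeric()))
  do.call(rbind, out)
}

#' Shape-complementarity correlation over all translations
#'
#' Correlates the shape channels of a static and a (rotated) mobile grid
#' over every integer translation of the mobile partner, computed with
#' forward/inverse discrete Fourier transforms. Entry `[i, j, k]` of the
#' result is the score for shifting the mobile grid by
#' `(i, j, k) - 1` voxels (cyclically; shifts beyond `n/2` are negative
#' shifts).
#'
#' @param static,mobile `dock_grid`s with identical spacing and size.
#' @return 3-D numeric score array.
#' @export
shape_correlation <- function(static, mobile) {
  if (!identical(dim(static$shape), dim(mobile$shape)) ||
      static$spacing != mobile$spacing)
    stop("mismatched grids")
  fs <- stats::fft(static$shape)
  fm <- stats::fft(mobile$shape)
  Re(stats::fft(fs * Conj(fm), inverse = TRUE)) / length(fs)
}

#' Screened electrostatic interaction score
#'
#' Sum over cross-partner charge pairs of `332 qi qj / (eps(r) r)`
#' (kcal/mol for unit charges and Angstrom) with the distance-dependent
#' dielectric `eps(r) = 4 r` and distances floored at 2 A. Negative
#' values are favorable. Used to discard electrostatically repulsive
#' poses and break scoring ties, in keeping with correlation-docking
#' practice; it is not added to the shape score.
#'
#' @param static_charges,mobile_charges Data frames `(x, y, z, q)` as
#'   produced internally from the residue-level charge model (see
#'   [discretize()]).
#' @return Numeric score (arbitrary units, negative = attractive).
#' @export
electrostatic_score <- function(static_charges, mobile_charges) {
  if (!nrow(static_charges) || !nrow(mobile_charges)) return(0)
  A <- as.matrix(static_charges[, c("x", "y", "z")])
  B <- as.matrix(mobile_charges[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  r[r < 2] <- 2
  332.06 * sum(outer(static_charges$q, mobile_charges$q) / (4 * r^2))
}

# deterministic Euler rotation sweep with duplicate pruning
rotation_set <- function(step_deg) {
  step <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - 1e-9, by = step)
  betas <- seq(0, pi + 1e-9, by = step)
  betas <- betas[betas <= pi + 1e-9]
  seen <- new.env(hash = TRUE)
  rots <- list()
  angles <- list()
  for (b in betas) for (a in alphas) for (g in alphas) {
    R <- euler_to_matrix(a, b, g)
    key <- paste(round(R, 6), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    rots[[length(rots) + 1L]] <- R
    angles[[length(angles) + 1L]] <- c(a, b, g)
  }
  list(R = rots, euler = do.call(rbind, angles))
}

#' Generate rigid-body docking poses
#'
#' Sweeps a deterministic Euler-angle rotation grid; for each rotation
#' the mobile partner is re-digitized and the best-scoring translations
#' of the shape correlation are kept. Globally the top `keep` candidates
#' are retained, preferring electrostatically non-repulsive poses and
#' ranking by shape score (ties: electrostatic score, then pose id).
#' Swap-equivalent duplicate poses of a homodimer (the C2 relabelling
#' `(R, t) ~ (R', -R' t)`) are removed when `dedupe_c2` is set.
#'
#' The sweep contains no randomness: identical inputs and settings give
#' identical pose sets.
#'
#' @param static,mobile [chain_model()]s; `mobile` is rotated/translated.
#' @param spacing Grid spacing (A).
#' @param angle_step Euler sweep step (degrees).
#' @param keep Number of poses retained (default 10000).
#' @param keep_per_rotation Best translations kept per rotation.
#' @param surface_thickness,core_weight,soft_margin Passed to
#'   [discretize()].
#' @param dedupe_c2 Remove homodimer swap duplicates.
#' @param pad Extra box padding (A).
#' @return Object of class `pose_set`: list with `poses` (data frame:
#'   `id`, `alpha`, `beta`, `gamma` in degrees, `tx`, `ty`, `tz` in A,
#'   `shape`, `elec`), `static`, `mobile`, `settings`. The pose transform
#'   maps mobile coordinates `x` to `R (x - cm) + cs + t`, with `cm`,
#'   `cs` the mobile/static centroids.
#' @export
generate_poses <- function(static, mobile, spacing = 1.0, angle_step = 15,
                           keep = 10000, keep_per_rotation = 8,
                           surface_thickness = 2.0, core_weight = -15,
                           soft_margin = 1.0, dedupe_c2 = TRUE, pad = 4) {
  sxyz <- as.matrix(static[, c("x", "y", "z")])
  mxyz <- as.matrix(mobile[, c("x", "y", "z")])
  if (!nrow(sxyz) || !nrow(mxyz)) stop("empty model")
  cs <- colMeans(sxyz)
  cm <- colMeans(mxyz)
  ext_s <- max(apply(sxyz, 2, function(v) diff(range(v))))
  dm2 <- outer(rowSums(mxyz^2), rowSums(mxyz^2), "+") - 2 * mxyz %*% t(mxyz)
  diam_m <- sqrt(max(dm2))    # true diameter: rotation-proof box sizing
  n <- stats::nextn(ceiling((ext_s + diam_m + 2 * pad) / spacing), c(2, 3, 5))
  origin <- cs - (n - 1) / 2 * spacing
  sgrid <- discretize(static, spacing, surface_thickness, "static",
                      core_weight, soft_margin, n = n, origin = origin)
  fs <- stats::fft(sgrid$shape)

  mob_centered <- mobile
  mc <- sweep(mxyz, 2, cm)
  rset <- rotation_set(angle_step)
  nrot <- length(rset$R)
  s_charges <- charge_points(static)
  m_charges0 <- charge_points(mob_centered)
  mq_xyz <- if (nrow(m_charges0))
    sweep(as.matrix(m_charges0[, c("x", "y", "z")]), 2, cm) else NULL

  cand <- vector("list", nrot)
  half <- n %/% 2
  for (ri in seq_len(nrot)) {
    R <- rset$R[[ri]]
    rot_xyz <- mc %*% t(R)
    mmod <- mob_centered
    mmod$x <- rot_xyz[, 1] + cs[1]
    mmod$y <- rot_xyz[, 2] + cs[2]
    mmod$z <- rot_xyz[, 3] + cs[3]
    mgrid <- discretize(mmod, spacing, surface_thickness, "mobile",
                        n = n, origin = origin)
    C <- Re(stats::fft(fs * Conj(stats::fft(mgrid$shape)),
                       inverse = TRUE)) / n^3
    kk <- min(keep_per_rotation, length(C))
    ord <- order(C, decreasing = TRUE)[seq_len(kk)]
    sc <- C[ord]
    pos <- arrayInd(ord, dim(C)) - 1L
    pos[pos > half] <- pos[pos > half] - n
    ok <- sc > 1e-9
    if (!any(ok)) { cand[[ri]] <- NULL; next }
    cand[[ri]] <- data.frame(rot = ri, shape = sc[ok],
                             sx = pos[ok, 1], sy = pos[ok, 2], sz = pos[ok, 3])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) stop("settings yielded zero poses")
  cand$tx <- cand$sx * spacing
  cand$ty <- cand$sy * spacing
  cand$tz <- cand$sz * spacing
  cand$id <- seq_len(nrow(cand))

  # electrostatic score per candidate (pairwise on charge points)
  cand$elec <- 0
  if (!is.null(mq_xyz) && nrow(s_charges)) {
    sqx <- as.matrix(s_charges[, c("x", "y", "z")])
    sq2 <- rowSums(sqx^2)
    qq <- outer(s_charges$q, m_charges0$q)
    for (ri in unique(cand$rot)) {
      rows <- which(cand$rot == ri)
      rq <- mq_xyz %*% t(rset$R[[ri]])
      for (i in rows) {
        B <- sweep(rq, 2, cs + c(cand$tx[i], cand$ty[i], cand$tz[i]), "+")
        d2 <- pmax(outer(sq2, rowSums(B^2), "+") - 2 * sqx %*% t(B), 4)
        cand$elec[i] <- 332.06 * sum(qq / (4 * d2))
      }
    }
  }

  if (dedupe_c2) {
    k1 <- k2 <- character(nrow(cand))
    for (r in unique(cand$rot)) {
      rows <- which(cand$rot == r)
      R <- rset$R[[r]]
      rk <- paste(round(R, 3), collapse = ",")
      rk2 <- paste(round(t(R), 3), collapse = ",")
      tm <- cbind(cand$tx[rows], cand$ty[rows], cand$tz[rows])
      tm2 <- -tm %*% R                      # swap translation: -R^T t
      k1[rows] <- paste(rk, round(tm[, 1], 2), round(tm[, 2], 2),
                        round(tm[, 3], 2))
      k2[rows] <- paste(rk2, round(tm2[, 1], 2), round(tm2[, 2], 2),
                        round(tm2[, 3], 2))
    }
    key <- pmin(k1, k2)
    cand <- cand[!duplicated(key), , drop = FALSE]
  }

  # rank: non-repulsive first, then shape desc, elec asc, id asc
  ord <- order(cand$elec > 1e-9, -cand$shape, cand$elec, cand$id)
  cand <- cand[ord, , drop = FALSE]
  cand <- utils::head(cand, keep)
  euler_deg <- rset$euler[cand$rot, , drop = FALSE] * 180 / pi
  poses <- data.frame(id = cand$id, rot = cand$rot,
                      alpha = euler_deg[, 1], beta = euler_deg[, 2],
                      gamma = euler_deg[, 3],
                      tx = cand$tx, ty = cand$ty, tz = cand$tz,
                      shape = cand$shape, elec = cand$elec)
  rownames(poses) <- NULL
  structure(list(poses = poses, static = static, mobile = mobile,
                 rotations = rset$R,
                 settings = list(spacing = spacing, angle_step = angle_step,
                                 keep = keep,
                                 keep_per_rotation = keep_per_rotation,
                                 surface_thickness = surface_thickness,
                                 core_weight = core_weight,
                                 dedupe_c2 = dedupe_c2, n = n)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set>  %d poses (grid %d^3, %.1f A, %g deg sweep)\n",
              nrow(x$poses), x$settings$n, x$settings$spacing,
              x$settings$angle_step))
  invisible(x)
}

# pose transform as (R, t) acting on original mobile coordinates:
# x' = R (x - cm) + cs + t
pose_transform <- function(pose_set, i) {
  p <- pose_set$poses[i, ]
  R <- pose_set$rotations[[p$rot]]
  cm <- colMeans(as.matrix(pose_set$mobile[, c("x", "y", "z")]))
  cs <- colMeans(as.matrix(pose_set$static[, c("x", "y", "z")]))
  list(R = R, t = as.numeric(cs + c(p$tx, p$ty, p$tz) - R %*% cm))
}

#' Build the dimer complex realized by one pose
#'
#' @param pose_set A `pose_set`.
#' @param i Row index into `pose_set$poses`.
#' @return A [dimer_complex()] (static = chain A, posed mobile = chain B).
#' @export
pose_complex <- function(pose_set, i) {
  tr <- pose_transform(pose_set, i)
  b <- apply_transform(pose_set$mobile, tr$R, tr$t)
  dimer_complex(pose_set$static, b,
                provenance = paste0("pose ", pose_set$poses$id[i]))
}
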