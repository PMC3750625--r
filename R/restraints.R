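#' Define a crosslink distance restraint
#'
#' A restraint derived from an intermolecular crosslink: a set of
#' alternative residue-pair assignments (more than one encodes an
#' ambiguous identification such as K31 to K20-or-K24) and a maximum
#' cross-chain site distance. A pose satisfies the restraint when ANY
#' alternative pair, in either chain assignment, is within
#' `max_distance`.
#'
#' @param sites_a,sites_b Residue numbers on the two chains; all
#'   combinations of `sites_a` x `sites_b` are alternatives.
#' @param max_distance Maximum allowed distance (A); the BS3 C-beta
#'   convention is 21.3.
#' @param atom Site atom (default `"CB"`, falling back to CA).
#' @param origin Free-text provenance (table row / match id).
#' @param alternatives Optional explicit data frame of alternative pairs
#'   (columns `a`, `b`), e.g. the site assignments compatible with one
#'   observed peak; overrides `sites_a`/`sites_b`.
#' @return Object of class `xl_restraint`.
#' @export
restraint <- function(sites_a, sites_b, max_distance = 21.3, atom = "CB",
                      origin = "", alternatives = NULL) {
  stopifnot(max_distance > 0)
  if (is.null(alternatives)) {
    stopifnot(length(sites_a) >= 1, length(sites_b) >= 1)
    alternatives <- expand.grid(a = as.integer(sites_a),
                                b = as.integer(sites_b))
  } else {
    stopifnot(nrow(alternatives) >= 1,
              all(c("a", "b") %in% names(alternatives)))
  }
  structure(list(alternatives = alternatives, max_distance = max_distance,
                 atom = atom, origin = origin),
            class = "xl_restraint")
}

#' Read restraints from a TSV file
#'
#' Columns: `chainA_res`, `chainB_res`, `max_dist`. Ambiguous sites are
#' written `20/24`.
#'
#' @param path File path.
#' @return List of [restraint()]s.
#' @export
read_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    restraint(as.integer(strsplit(as.character(df$chainA_res[i]), "/")[[1]]),
              as.integer(strsplit(as.character(df$chainB_res[i]), "/")[[1]]),
              max_distance = df$max_dist[i],
              origin = sprintf("row %d", i))
  })
}

# cross-chain distances of every restraint alternative for every pose;
# returns list(min_dist = poses x restraints matrix of best alternative)
restraint_distances <- function(pose_set, restraints) {
  static <- pose_set$static
  mobile <- pose_set$mobile
  cm <- colMeans(as.matrix(mobile[, c("x", "y", "z")]))
  cs <- colMeans(as.matrix(static[, c("x", "y", "z")]))
  np <- nrow(pose_set$poses)
  nr <- length(restraints)
  # site coordinates once per unique residue
  sites <- unique(unlist(lapply(restraints, function(r)
    c(r$alternatives$a, r$alternatives$b))))
  atom <- restraints[[1]]$atom
  s_xyz <- vapply(sites, function(rn) site_coord(static, rn, atom), numeric(3))
  m_xyz <- vapply(sites, function(rn) site_coord(mobile, rn, atom) - cm,
                  numeric(3))
  colnames(s_xyz) <- colnames(m_xyz) <- as.character(sites)
  best <- matrix(Inf, np, nr)
  poses <- pose_set$poses
  for (r in unique(poses$rot)) {
    rows <- which(poses$rot == r)
    R <- pose_set$rotations[[r]]
    rm <- R %*% m_xyz                       # rotated mobile sites, 3 x ns
    offx <- cs[1] + poses$tx[rows]
    offy <- cs[2] + poses$ty[rows]
    offz <- cs[3] + poses$tz[rows]
    for (j in seq_len(nr)) {
      alts <- restraints[[j]]$alternatives
      dmin <- rep(Inf, length(rows))
      for (k in seq_len(nrow(alts))) {
        a <- as.character(alts$a[k]); b <- as.character(alts$b[k])
        v1 <- rm[, b] - s_xyz[, a]          # A-site on static chain
        d1 <- (v1[1] + offx)^2 + (v1[2] + offy)^2 + (v1[3] + offz)^2
        v2 <- rm[, a] - s_xyz[, b]          # swapped chain assignment
        d2 <- (v2[1] + offx)^2 + (v2[2] + offy)^2 + (v2[3] + offz)^2
        dmin <- pmin(dmin, d1, d2)
      }
      best[rows, j] <- sqrt(dmin)
    }
  }
  best
}

#' Filter poses with crosslink distance restraints
#'
#' A pose survives if and only if every restraint has at least one
#' alternative site pair within its maximum distance, measured
#' cross-chain on the posed complex. The surviving-set is independent of
#' restraint order (pure conjunction).
#'
#' @param pose_set A `pose_set` from [generate_poses()].
#' @param restraints List of [restraint()]s (empty list: all poses
#'   survive).
#' @return List with `poses` (the filtered `pose_set`) and `report`
#'   (class `filter_report`: `n_in`, `n_out`, `per_restraint`
#'   satisfaction counts, `worst_distance` per surviving pose).
#' @export
apply_restraints <- function(pose_set, restraints) {
  np <- nrow(pose_set$poses)
  if (!length(restraints)) {
    report <- structure(list(n_in = np, n_out = np,
                             per_restraint = integer(0),
                             worst_distance = rep(NA_real_, np)),
                        class = "filter_report")
    return(list(poses = pose_set, report = report))
  }
  dmat <- restraint_distances(pose_set, restraints)
  maxd <- vapply(restraints, `[[`, numeric(1), "max_distance")
  ok <- sweep(dmat, 2, maxd, "<=")
  keep <- rowSums(ok) == length(restraints)
  out <- pose_set
  out$poses <- pose_set$poses[keep, , drop = FALSE]
  rownames(out$poses) <- NULL
  worst <- apply(dmat[keep, , drop = FALSE], 1, max)
  report <- structure(list(n_in = np, n_out = sum(keep),
                           per_restraint = colSums(ok),
                           worst_distance = worst,
                           distances = dmat[keep, , drop = FALSE]),
                      class = "filter_report")
  list(poses = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report>  %d / %d poses satisfy all %d restraints\n",
              x$n_out, x$n_in, length(x$per_restraint)))
  if (length(x$per_restraint))
    cat("  per-restraint:", paste(x$per_restraint, collapse = ", "), "\n")
  invisible(x)
}

# precomputed atom/charge tables for repeated pose-energy evaluation
energy_cache <- function(static, mobile) {
  sq <- charge_points(static)
  mq <- charge_points(mobile)
  list(s_xyz = as.matrix(static[, c("x", "y", "z")]),
       s_rad = atom_radii(static),
       s_q = sq,
       m_xyz = as.matrix(mobile[, c("x", "y", "z")]),
       m_rad = atom_radii(mobile),
       m_q = mq,
       sq_xyz = as.matrix(sq[, c("x", "y", "z")]),
       mq_xyz = as.matrix(mq[, c("x", "y", "z")]),
       qq = outer(sq$q, mq$q),
       sig2 = outer(atom_radii(static), atom_radii(mobile), "+")^2,
       s2 = rowSums(as.matrix(static[, c("x", "y", "z")])^2),
       sq2 = rowSums(as.matrix(sq[, c("x", "y", "z")])^2))
}

# energy of a posed complex given full affine transform (Amat, b) on the
# mobile model; `soft` > 1 forgives grid-quantization overlap and is
# used when pre-ranking unrefined poses
complex_energy <- function(static, mobile, Amat, b, cache = NULL,
                           soft = 1.0, eps = 0.1, cutoff = 12) {
  if (is.null(cache)) cache <- energy_cache(static, mobile)
  B <- sweep(cache$m_xyz %*% t(Amat), 2, b, "+")
  d2 <- pmax(outer(cache$s2, rowSums(B^2), "+") - 2 * cache$s_xyz %*% t(B), 0)
  y <- cache$sig2 / (d2 + soft^2)
  sel <- d2 < cutoff^2
  e <- sum(eps * (y[sel]^6 - 2 * y[sel]^3))
  if (length(cache$qq)) {
    Bq <- sweep(cache$mq_xyz %*% t(Amat), 2, b, "+")
    dq2 <- pmax(outer(cache$sq2, rowSums(Bq^2), "+") -
                  2 * cache$sq_xyz %*% t(Bq), 4)
    e <- e + 332.06 * sum(cache$qq / (4 * dq2))
  }
  e
}

#' Rigid-body refinement of a docking pose
#'
#' Local minimization of the pose's six rigid-body degrees of freedom
#' (rotation vector about the posed mobile centroid plus translation)
#' under a soft-core van der Waals plus screened electrostatic
#' interaction energy. Minimization proceeds in rounds, each bounded by
#' a trust region, until the energy stops improving; the best-seen
#' configuration is always returned, so the reported energy is never
#' above the starting energy.
#'
#' @param pose_set A `pose_set`.
#' @param i Pose row index.
#' @param trust_rot Rotation bound (radians).
#' @param trust_trans Translation bound (A).
#' @param maxit Iteration budget for the optimizer per round.
#' @param max_rounds Maximum trust-region rounds.
#' @param cache Precomputed internal energy tables (optional).
#' @return List with the refined affine transform (`A`, `b`, mapping
#'   original mobile coordinates), `energy`, `energy0`, `converged` and
#'   the pose `id`.
#' @export
refine_pose <- function(pose_set, i, trust_rot = 0.35, trust_trans = 3.0,
                        maxit = 100, max_rounds = 5, cache = NULL) {
  tr <- pose_transform(pose_set, i)
  A0 <- tr$R; b0 <- tr$t
  static <- pose_set$static
  mobile <- pose_set$mobile
  if (is.null(cache)) cache <- energy_cache(static, mobile)
  e0 <- complex_energy(static, mobile, A0, b0, cache)
  e_prev <- e0
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    ctr <- colMeans(sweep(cache$m_xyz %*% t(A0), 2, b0, "+"))
    best <- list(par = rep(0, 6), value = e_prev)
    ener <- function(par) {
      Rw <- rotvec_to_matrix(par[1:3])
      Amat <- Rw %*% A0
      b <- as.numeric(Rw %*% (b0 - ctr)) + ctr + par[4:6]
      e <- complex_energy(static, mobile, Amat, b, cache)
      if (e < best$value) best <<- list(par = par, value = e)
      e
    }
    fit <- try(stats::optim(rep(0, 6), ener, method = "L-BFGS-B",
                            lower = c(rep(-trust_rot, 3), rep(-trust_trans, 3)),
                            upper = c(rep(trust_rot, 3), rep(trust_trans, 3)),
                            control = list(maxit = maxit)), silent = TRUE)
    opt_ok <- !inherits(fit, "try-error") && fit$convergence == 0
    Rw <- rotvec_to_matrix(best$par[1:3])
    A0 <- Rw %*% A0
    b0 <- as.numeric(Rw %*% (b0 - ctr)) + ctr + best$par[4:6]
    if (e_prev - best$value < 1e-3) { converged <- opt_ok; break }
    e_prev <- best$value
  }
  list(id = pose_set$poses$id[i], A = A0, b = b0,
       energy = min(e_prev, best$value), energy0 = e0,
       converged = converged)
}

#' Select the final dimer model from refined poses
#'
#' Minimal refined interaction energy wins; ties are broken by larger
#' buried interface area, then by pose id.
#'
#' @param refined List of results from [refine_pose()].
#' @param pose_set The parent `pose_set`.
#' @param tie_tol Energies closer than this are treated as tied.
#' @return A [dimer_complex()] with attributes `energy` and `pose_id`.
#' @export
select_model <- function(refined, pose_set, tie_tol = 1e-6) {
  if (!length(refined)) stop("no restraint-compatible pose to select")
  en <- vapply(refined, `[[`, numeric(1), "energy")
  ids <- vapply(refined, `[[`, numeric(1), "id")
  cand <- which(en <= min(en) + tie_tol)
  if (length(cand) > 1) {
    dasa <- vapply(cand, function(k) {
      cmplx <- refined_complex(refined[[k]], pose_set)
      interface_metrics(cmplx, n_points = 120)$delta_asa
    }, numeric(1))
    cand <- cand[order(-dasa, ids[cand])]
  }
  best <- refined[[cand[1]]]
  cmplx <- refined_complex(best, pose_set)
  attr(cmplx, "energy") <- best$energy
  attr(cmplx, "pose_id") <- best$id
  cmplx
}

refined_complex <- function(ref, pose_set) {
  b <- apply_transform(pose_set$mobile, ref$A, ref$b)
  dimer_complex(pose_set$static, b,
                provenance = paste0("refined pose ", ref$id))
}

# deterministic near-uniform unit sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (sphere-point method)
#'
#' Per-atom accessible surface by the Shrake-Rupley construction: test
#' points on each atom's solvent-expanded sphere are kept when outside
#' every neighbouring expanded sphere; the accessible fraction scales the
#' analytic sphere area.
#'
#' @param model A [chain_model()] (or any atom table).
#' @param n_points Sphere points per atom.
#' @param probe Probe radius (A), 1.4 for water.
#' @return Numeric vector of per-atom ASA (A^2).
#' @export
shrake_rupley <- function(model, n_points = 960, probe = 1.4) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  r <- atom_radii(model) + probe
  m <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  asa <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(m) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
             (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r[j]^2
      if (!any(acc)) break
    }
    asa[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  asa
}

#' Interface metrics of a dimer complex
#'
#' Buried solvent-accessible area `dASA = ASA(A) + ASA(B) - ASA(AB)`,
#' per-residue burials, interface residue lists (per-residue burial above
#' `floor`), residue contact pairs within `contact_cutoff`, and the
#' chain orientation classification.
#'
#' @param complex A [dimer_complex()].
#' @param n_points,probe Passed to [shrake_rupley()].
#' @param floor Minimum per-residue burial (A^2) to count as interface.
#' @param contact_cutoff Atom distance (A) defining residue contacts.
#' @return Object of class `interface_report`: list with `delta_asa`,
#'   `interface_A`, `interface_B` (data frames residue/burial),
#'   `n_interface` (per-chain counts), `contacts`, `orientation`.
#' @export
interface_metrics <- function(complex, n_points = 960, probe = 1.4,
                              floor = 0.1, contact_cutoff = 5) {
  A <- complex$A; B <- complex$B
  asa_a <- shrake_rupley(A, n_points, probe)
  asa_b <- shrake_rupley(B, n_points, probe)
  ab <- rbind(A, B)
  asa_ab <- shrake_rupley(ab, n_points, probe)
  na <- nrow(A)
  delta <- sum(asa_a) + sum(asa_b) - sum(asa_ab)
  burial <- function(asa_free, asa_cplx, model) {
    d <- asa_free - asa_cplx
    agg <- tapply(d, model$resno, sum)
    df <- data.frame(resno = as.integer(names(agg)), burial = as.numeric(agg))
    df[df$burial > floor, , drop = FALSE]
  }
  int_a <- burial(asa_a, asa_ab[seq_len(na)], A)
  int_b <- burial(asa_b, asa_ab[-seq_len(na)], B)
  # residue contact pairs across the interface
  Ax <- as.matrix(A[, c("x", "y", "z")]); Bx <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(Ax^2), rowSums(Bx^2), "+") - 2 * Ax %*% t(Bx)
  hit <- which(d2 < contact_cutoff^2, arr.ind = TRUE)
  contacts <- unique(data.frame(resA = A$resno[hit[, 1]],
                                resB = B$resno[hit[, 2]]))
  rownames(contacts) <- NULL
  structure(list(delta_asa = max(0, delta),
                 interface_A = int_a, interface_B = int_b,
                 n_interface = c(A = nrow(int_a), B = nrow(int_b)),
                 contacts = contacts,
                 orientation = classify_orientation(complex)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report>  dASA %.1f A^2; interface residues A: %d, B: %d; %s (%.1f deg)\n",
              x$delta_asa, x$n_interface["A"], x$n_interface["B"],
              x$orientation$label, x$orientation$angle))
  invisible(x)
}

#' Classify the relative orientation of a homodimer
#'
#' Each chain's reference vector runs from its first to its last ordered
#' C-alpha over the residue span common to both chains. The inter-chain
#' angle (degrees) labels the dimer `parallel` (< 90) or `antiparallel`.
#' Also reports the two-fold symmetry residual: the RMSD and rotation
#' angle of the optimal superposition of chain B onto chain A (a clean C2
#' dimer gives a rotation near 180 degrees).
#'
#' @param complex A [dimer_complex()].
#' @return List with `label`, `angle` (degrees), `c2_angle` (degrees),
#'   `c2_residual` (A).
#' @export
classify_orientation <- function(complex) {
  ca <- function(m) {
    v <- m[m$elety == "CA", , drop = FALSE]
    v[order(v$resno), , drop = FALSE]
  }
  a <- ca(complex$A); b <- ca(complex$B)
  shared <- intersect(a$resno, b$resno)
  if (length(shared) < 0.8 * max(nrow(a), nrow(b)))
    stop("chains too dissimilar to pair")
  a <- a[a$resno %in% shared, ]; b <- b[b$resno %in% shared, ]
  vec <- function(m) {
    v <- as.numeric(m[nrow(m), c("x", "y", "z")]) -
         as.numeric(m[1, c("x", "y", "z")])
    v / sqrt(sum(v^2))
  }
  ang <- acos(pmin(1, pmax(-1, sum(vec(a) * vec(b))))) * 180 / pi
  sp <- kabsch(as.matrix(b[, c("x", "y", "z")]),
               as.matrix(a[, c("x", "y", "z")]))
  c2_angle <- acos(pmin(1, pmax(-1, (sum(diag(sp$R)) - 1) / 2))) * 180 / pi
  list(label = if (ang < 90) "parallel" else "antiparallel",
       angle = ang, c2_angle = c2_angle, c2_residual = sp$rmsd)
}
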