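#' Fit a restraint-consistent rigid-body dimer model
#'
#' The package's central estimator. Given a static and a mobile copy of
#' a monomer plus crosslink distance restraints, it (1) generates a
#' deterministic set of shape-complementarity docking poses
#' ([generate_poses()]), (2) keeps the poses satisfying every restraint
#' ([apply_restraints()]), (3) rigid-body refines the best survivors
#' under a soft-core interaction energy ([refine_pose()]), re-checks the
#' restraints, and (4) selects the minimum-energy model
#' ([select_model()]), characterizing its interface and orientation
#' ([interface_metrics()]).
#'
#' An input without any restraint-compatible pose is a distinguished
#' outcome, not an error: the returned object has
#' `status = "no-compatible-pose"`.
#'
#' @param static,mobile [chain_model()]s (homodimer: the same monomer).
#' @param restraints List of [restraint()]s.
#' @param spacing,angle_step,keep,keep_per_rotation,dedupe_c2 Docking
#'   sweep settings, see [generate_poses()].
#' @param refine_top Number of top restraint-compatible poses refined.
#' @param compute_interface Set `FALSE` to skip interface analysis.
#' @param n_points Sphere points per atom for the interface ASA.
#' @param poses Optionally a precomputed `pose_set` (skips the sweep).
#' @return Object of class `dimer_fit`: list with `status`, `complex`,
#'   `energy`, `pose_id`, `transform` (`A`, `b`), `filter_report`,
#'   `restraints`, `restraint_distances` (of the final model),
#'   `interface`, `settings`, `call`.
#' @seealso [run_pipeline()] for the full MS-to-model pipeline.
#' @export
fit_dimer <- function(static, mobile = static, restraints = list(),
                      spacing = 1.0, angle_step = 15, keep = 10000,
                      keep_per_rotation = 4, dedupe_c2 = TRUE,
                      refine_top = 20, compute_interface = TRUE,
                      n_points = 240, poses = NULL) {
  cl <- match.call()
  if (is.null(poses))
    poses <- generate_poses(static, mobile, spacing = spacing,
                            angle_step = angle_step, keep = keep,
                            keep_per_rotation = keep_per_rotation,
                            dedupe_c2 = dedupe_c2)
  flt <- apply_restraints(poses, restraints)
  out <- list(status = "ok", poses = poses, filter_report = flt$report,
              restraints = restraints, settings = poses$settings, call = cl)
  if (!nrow(flt$poses$poses)) {
    out$status <- "no-compatible-pose"
    class(out) <- "dimer_fit"
    return(out)
  }
  surv <- flt$poses
  cache <- energy_cache(surv$static, surv$mobile)
  # pre-screen survivors by a softened interaction energy: the shape
  # rank alone can favour interpenetration, while the unsoftened energy
  # over-punishes snug placements whose overlap is grid quantization;
  # refinement then resolves both under the standard potential
  e0 <- vapply(seq_len(nrow(surv$poses)), function(i) {
    tr <- pose_transform(surv, i)
    complex_energy(surv$static, surv$mobile, tr$R, tr$t, cache, soft = 2.5)
  }, numeric(1))
  surv$poses <- surv$poses[order(e0), , drop = FALSE]
  rownames(surv$poses) <- NULL
  ntop <- min(refine_top, nrow(surv$poses))
  refined <- lapply(seq_len(ntop), function(i)
    refine_pose(surv, i, cache = cache))
  # re-check restraints after refinement; violators fall back to their
  # unrefined placement (which satisfied by construction)
  if (length(restraints)) {
    for (k in seq_along(refined)) {
      d <- refined_restraint_distances(refined[[k]], surv, restraints)
      maxd <- vapply(restraints, `[[`, numeric(1), "max_distance")
      if (any(d > maxd)) {
        tr <- pose_transform(surv, k)
        refined[[k]]$A <- tr$R
        refined[[k]]$b <- tr$t
        refined[[k]]$energy <- complex_energy(surv$static, surv$mobile,
                                              tr$R, tr$t, cache)
      }
    }
  }
  model <- select_model(refined, surv)
  best <- refined[[which(vapply(refined, `[[`, numeric(1), "id") ==
                           attr(model, "pose_id"))[1]]]
  out$complex <- model
  out$energy <- attr(model, "energy")
  out$pose_id <- attr(model, "pose_id")
  out$transform <- list(A = best$A, b = best$b)
  if (length(restraints)) {
    d <- refined_restraint_distances(best, surv, restraints)
    out$restraint_distances <- data.frame(
      origin = vapply(restraints, `[[`, character(1), "origin"),
      max_distance = vapply(restraints, `[[`, numeric(1), "max_distance"),
      distance = d)
  }
  if (compute_interface)
    out$interface <- interface_metrics(model, n_points = n_points)
  class(out) <- "dimer_fit"
  out
}

# best-alternative cross-chain restraint distances for a refined transform
refined_restraint_distances <- function(ref, pose_set, restraints) {
  static <- pose_set$static
  mobile <- pose_set$mobile
  vapply(restraints, function(r) {
    d <- Inf
    for (k in seq_len(nrow(r$alternatives))) {
      a <- r$alternatives$a[k]; b <- r$alternatives$b[k]
      pa_s <- site_coord(static, a, r$atom)
      pb_s <- site_coord(static, b, r$atom)
      pa_m <- as.numeric(ref$A %*% site_coord(mobile, a, r$atom) + ref$b)
      pb_m <- as.numeric(ref$A %*% site_coord(mobile, b, r$atom) + ref$b)
      d <- min(d, sqrt(sum((pa_s - pb_m)^2)), sqrt(sum((pb_s - pa_m)^2)))
    }
    d
  }, numeric(1))
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat("Rigid-body dimer fit (crosslink-restrained docking)\n")
  cat(sprintf("  poses: %d swept, %d restraint-compatible\n",
              x$filter_report$n_in, x$filter_report$n_out))
  if (x$status == "no-compatible-pose") {
    cat("  status: NO restraint-compatible pose\n")
    return(invisible(x))
  }
  cat(sprintf("  selected pose %d, interaction energy %.3f\n",
              x$pose_id, x$energy))
  if (!is.null(x$restraint_distances)) {
    cat("  restraint distances (A):",
        paste(sprintf("%.2f", x$restraint_distances$distance),
              collapse = ", "), "\n")
  }
  if (!is.null(x$interface))
    cat(sprintf("  interface: dASA %.0f A^2, %s (%.0f deg)\n",
                x$interface$delta_asa, x$interface$orientation$label,
                x$interface$orientation$angle))
  invisible(x)
}

#' @export
summary.dimer_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dimer_fit")
}

#' @export
print.summary.dimer_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$status != "ok") return(invisible(x))
  cat("\nSettings:\n")
  s <- f$settings
  cat(sprintf("  grid %d^3 at %.2f A, %g deg sweep, %d poses kept\n",
              s$n, s$spacing, s$angle_step, s$keep))
  if (!is.null(f$restraint_distances)) {
    cat("\nRestraints:\n")
    print(f$restraint_distances, row.names = FALSE)
  }
  if (!is.null(f$interface)) {
    cat(sprintf("\nInterface residues: chain A %d, chain B %d\n",
                f$interface$n_interface["A"], f$interface$n_interface["B"]))
    cat(sprintf("C2 residual %.2f A at %.0f deg\n",
                f$interface$orientation$c2_residual,
                f$interface$orientation$c2_angle))
  }
  invisible(x)
}

#' @export
coef.dimer_fit <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  A <- object$transform$A
  beta <- acos(pmin(1, pmax(-1, A[3, 3])))
  if (abs(sin(beta)) > 1e-8) {
    alpha <- atan2(A[2, 3], A[1, 3])
    gamma <- atan2(A[3, 2], -A[3, 1])
  } else {
    alpha <- atan2(A[2, 1], A[1, 1]); gamma <- 0
  }
  c(alpha = alpha * 180 / pi, beta = beta * 180 / pi,
    gamma = gamma * 180 / pi,
    tx = object$transform$b[1], ty = object$transform$b[2],
    tz = object$transform$b[3])
}

#' @export
fitted.dimer_fit <- function(object, ...) object$complex

#' @export
residuals.dimer_fit <- function(object, ...) {
  if (is.null(object$restraint_distances)) return(numeric(0))
  with(object$restraint_distances, distance - max_distance)
}

#' Diagnostic plot of a dimer fit
#'
#' Left: restrained cross-chain distances of the selected model against
#' the allowed maxima. Right: shape score versus electrostatic score of
#' the swept poses, survivors highlighted.
#'
#' @param x A `dimer_fit`.
#' @param ... Unused.
#' @export
plot.dimer_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$restraint_distances)) {
    rd <- x$restraint_distances
    bp <- graphics::barplot(rd$distance, names.arg = rd$origin,
                            ylab = "cross-chain distance (A)",
                            main = "restraints", las = 2,
                            ylim = c(0, max(rd$max_distance, rd$distance) * 1.2))
    graphics::segments(bp - 0.5, rd$max_distance, bp + 0.5, rd$max_distance,
                       col = "red", lwd = 2)
  } else graphics::plot.new()
  p <- x$poses$poses
  graphics::plot(p$shape, p$elec, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("grey40", 0.5),
                 xlab = "shape score", ylab = "electrostatic score",
                 main = "pose sweep")
  if (x$status == "ok")
    graphics::points(p$shape[p$id == x$pose_id], p$elec[p$id == x$pose_id],
                     col = "red", pch = 17)
  invisible(x)
}

#' Ligand RMSD between two placements of the mobile chain
#'
#' Complexes are superposed on the static chain (chain A), then the RMSD
#' of the mobile chain (chain B) is measured — the standard pose
#' similarity metric of docking assessment.
#'
#' @param complex,reference [dimer_complex()]s sharing chain layouts.
#' @param atoms Atom names used (default `"CA"`).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(complex, reference, atoms = "CA") {
  sp <- superpose(complex$A, reference$A, atoms = atoms)
  b1 <- apply_transform(complex$B, sp$R, sp$t)
  key <- function(m) {
    m <- m[m$elety %in% atoms, , drop = FALSE]
    m[order(m$resno, m$elety), , drop = FALSE]
  }
  p <- key(b1); q <- key(reference$B)
  shared <- intersect(paste(p$resno, p$elety), paste(q$resno, q$elety))
  p <- p[paste(p$resno, p$elety) %in% shared, ]
  q <- q[paste(q$resno, q$elety) %in% shared, ]
  sqrt(mean(rowSums((as.matrix(p[, c("x", "y", "z")]) -
                     as.matrix(q[, c("x", "y", "z")]))^2)))
}
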