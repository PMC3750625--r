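# --- ground-truthed synthetic structures, dimers and peak lists ---------
#
# Reduced representation: every residue gets an ideal-helix C-alpha
# (rise 1.5 A, 100 deg/residue) and a pseudo C-beta placed 1.53 A
# radially outward. Loop residues are interpolated between helix ends.
# This is enough geometry to exercise digestion-aware product
# enumeration, distance classification, grid docking, restraint
# filtering and interface analysis with known ground truth.

helix_ca <- function(n, axis_xy = c(0, 0), z0 = 0, up = TRUE,
                     radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(n) - 1
  ang <- i * twist * pi / 180
  z <- z0 + i * rise * if (up) 1 else -1
  cbind(axis_xy[1] + radius * cos(ang), axis_xy[2] + radius * sin(ang), z)
}

# assemble CA/CB chain from helix segment definitions; segs is a list of
# list(from, to, axis = c(x, y), up); gaps between segments become
# linearly interpolated coil
build_reduced_chain <- function(resnos, sequence, segs, chain = "A") {
  res <- strsplit(sequence, "")[[1]]
  stopifnot(length(res) == length(resnos))
  nres <- length(resnos)
  ca <- matrix(NA_real_, nres, 3)
  axis_xy <- matrix(NA_real_, nres, 2)
  cb_rad <- rep(2.7, nres)
  for (s in segs) {
    idx <- which(resnos >= s$from & resnos <= s$to)
    ca[idx, ] <- helix_ca(length(idx), s$axis, z0 = s$z0 %||% 0,
                          up = s$up %||% TRUE)
    axis_xy[idx, ] <- matrix(s$axis, length(idx), 2, byrow = TRUE)
    if (!is.null(s$cb_radius)) cb_rad[idx] <- s$cb_radius
  }
  # interpolate any unplaced (coil) residues between nearest placed ones
  placed <- which(!is.na(ca[, 1]))
  for (i in which(is.na(ca[, 1]))) {
    prev <- suppressWarnings(max(placed[placed < i]))
    nxt <- suppressWarnings(min(placed[placed > i]))
    if (is.infinite(prev)) ca[i, ] <- ca[nxt, ] - c(0, 0, 3.0 * (nxt - i))
    else if (is.infinite(nxt)) ca[i, ] <- ca[prev, ] + c(0, 0, 3.0 * (i - prev))
    else {
      w <- (i - prev) / (nxt - prev)
      ca[i, ] <- (1 - w) * ca[prev, ] + w * ca[nxt, ]
    }
  }
  to3 <- stats::setNames(names(aa3to1)[names(aa3to1) != "MSE"],
                         aa3to1[names(aa3to1) != "MSE"])
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    # pseudo-CB radially outward from the local helix axis (+x for coil)
    dir <- if (is.na(axis_xy[i, 1])) c(1, 0, 0) else
      c(ca[i, 1] - axis_xy[i, 1], ca[i, 2] - axis_xy[i, 2], 0)
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < 1e-6) c(1, 0, 0) else dir / nrm
    cb <- ca[i, ] + 1.53 * dir
    # united-residue contact radii: each pseudo-atom stands for several
    # heavy atoms, so radii are larger than a lone carbon's
    if (res[i] == "G") {
      rows[[i]] <- data.frame(chain = chain, resno = resnos[i], resid = "GLY",
                              elety = "CA", x = ca[i, 1], y = ca[i, 2],
                              z = ca[i, 3], elesy = "C", radius = 2.3,
                              stringsAsFactors = FALSE)
    } else {
      # tryptophan pseudo side chains are distinctly bulky
      ri <- if (res[i] == "W") 3.4 else cb_rad[i]
      rows[[i]] <- data.frame(chain = chain, resno = resnos[i],
                              resid = unname(to3[res[i]]),
                              elety = c("CA", "CB"),
                              x = c(ca[i, 1], cb[1]), y = c(ca[i, 2], cb[2]),
                              z = c(ca[i, 3], cb[3]), elesy = "C",
                              radius = c(2.3, ri),
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  chain_model(df)
}

#' Specification of a synthetic toy system
#'
#' Bundles the generator parameters: monomer size, lysine placement,
#' planted dimer transform style, and noise levels. The seed fully
#' determines every generated coordinate and peak.
#'
#' The default layout is a two-helix hairpin of 16-residue helices whose
#' planted dimer is a compact four-helix bundle (see
#' [make_true_dimer()]); that packed arrangement is the unique energy
#' optimum of the reference geometry, so ground-truth recovery is well
#' posed. The default lysines sit on the dimer interface so that
#' short-linker crosslinks genuinely report on it, and glutamates placed
#' beside them keep the interface region near charge-neutral.
#'
#' @param n_helices,helix_len Monomer layout (helices packed side by
#'   side 9 A apart, hairpin-connected).
#' @param lysines Residue positions carrying lysine.
#' @param flip Plant an antiparallel (flipped) dimer instead of a
#'   parallel one.
#' @param coord_sd Gaussian coordinate noise (A).
#' @param mz_noise_ppm Bounded m/z mass error (ppm, uniform).
#' @param n_decoys Decoy peaks added to the crosslinked list.
#' @param seed Integer random seed.
#' @return List of class `toy_spec`.
#' @export
toy_spec <- function(n_helices = 2, helix_len = 16,
                     lysines = c(2, 7, 11, 29), flip = FALSE,
                     coord_sd = 0.05, mz_noise_ppm = 20, n_decoys = 20,
                     seed = 1) {
  stopifnot(n_helices >= 1, helix_len >= 6)
  structure(list(n_helices = n_helices, helix_len = helix_len,
                 lysines = lysines, flip = flip, coord_sd = coord_sd,
                 mz_noise_ppm = mz_noise_ppm, n_decoys = n_decoys,
                 seed = as.integer(seed)), class = "toy_spec")
}

#' Short-spacer crosslinker used for the synthetic toy studies
#'
#' A glutarate-bridge NHS-ester (DSG-class) linker: bridge +98.03678 Da,
#' hydrolyzed dead-end +116.04734 Da, 7.7 A spacer. Its C-beta distance
#' limit is set to 12 A so that, on a toy domain a few helix diameters
#' across, a satisfied restraint localizes the partner chain to within
#' about one helix diameter of the planted contact face — the same kind
#' of geometric information an 11.4 A-spacer linker carries on a
#' full-size domain.
#'
#' @return A [crosslinker_spec()].
#' @export
toy_crosslinker <- function() {
  crosslinker_spec("DSG-like", "K",
                   bridge_mass_mono = 98.03678, bridge_mass_avg = 98.1,
                   deadend_mass_mono = 116.04734, deadend_mass_avg = 116.12,
                   spacer_length = 7.7, max_site_distance = 12)
}

#' Generate a toy monomer with known geometry
#'
#' Ideal-helix reduced monomer (see the package vignette): `n_helices`
#' alpha-helices of `helix_len` residues packed 9 A apart as a hairpin,
#' lysines at the requested positions (these double as tryptic cleavage
#' sites), a tyrosine at even-helix ends so chymotrypsin is exercised
#' too, and a sparse glutamate pattern that keeps the lysine-bearing
#' face near charge-neutral. Gaussian coordinate noise `coord_sd` is
#' applied with the spec's seed.
#'
#' @param spec A [toy_spec()].
#' @return List with `sequence` (character), `model` ([chain_model()]),
#'   `offset` (first residue number, always 1 here).
#' @export
make_toy_monomer <- function(spec) {
  n <- spec$n_helices * spec$helix_len
  res <- rep(c("A", "S", "T", "V", "N", "Q", "I"), length.out = n)
  # sparse acidic pattern adjacent to the lysines keeps the interface
  # region near charge-neutral, so crosslinkable lysine pairs do not
  # electrostatically forbid the packed contact they report on
  for (h in seq_len(spec$n_helices)) {
    off <- (h - 1) * spec$helix_len
    ch <- if (h %% 2 == 1) list(E = c(5, 12)) else list(E = c(7, 11))
    for (nm in names(ch))
      for (j in ch[[nm]]) if (j < spec$helix_len) res[off + j] <- nm
    end <- h * spec$helix_len
    res[end] <- if (h %% 2 == 1) "S" else "Y"   # chymotryptic site at even ends
  }
  ly <- spec$lysines[spec$lysines >= 1 & spec$lysines <= n]
  res[ly] <- "K"
  segs <- lapply(seq_len(spec$n_helices), function(h) {
    list(from = (h - 1) * spec$helix_len + 1, to = h * spec$helix_len,
         axis = c((h - 1) * 9, 0), up = (h %% 2 == 1),
         z0 = if (h %% 2 == 1) 0 else (spec$helix_len - 1) * 1.5)
  })
  seq_str <- paste(res, collapse = "")
  model <- build_reduced_chain(seq_len(n), seq_str, segs)
  if (spec$coord_sd > 0) {
    set.seed(spec$seed)
    model$x <- model$x + stats::rnorm(nrow(model), 0, spec$coord_sd)
    model$y <- model$y + stats::rnorm(nrow(model), 0, spec$coord_sd)
    model$z <- model$z + stats::rnorm(nrow(model), 0, spec$coord_sd)
  }
  list(sequence = seq_str, model = model, offset = 1L)
}

#' Plant a ground-truth dimer
#'
#' Chain B is a rigid copy of the monomer placed in the reference packed
#' arrangement of the toy hairpin: the partner turned ~168 degrees about
#' the contact normal and nested into the groove, forming a compact
#' four-helix bundle (this fixed transform is the energy-optimal packing
#' of the reference toy geometry and is built into the generator). The
#' copy is then settled by a bounded local rigid-body minimization on
#' the seed's noisy coordinates, so the planted contact is a genuine
#' energy optimum of that seed's structure. With `flip = TRUE` the
#' partner is instead turned so the chains run the opposite way before
#' being packed by a line search plus local settle, producing the
#' opposite orientation label. The return value records the exact
#' transform, the set of inter-chain lysine pairs within the
#' crosslinkable cutoff (the "true crosslinkable set"), and the true
#' orientation label.
#'
#' @param monomer Result of [make_toy_monomer()] (or any list with
#'   `model` and `sequence`).
#' @param transform Optional list `(R, t)` overriding the built-in
#'   packing.
#' @param seed Integer seed (kept for call-site uniformity; the planting
#'   itself is deterministic given the monomer coordinates).
#' @param flip Plant the opposite chain orientation.
#' @param contact_gap Clash floor: closest allowed inter-chain approach
#'   between atom centers (A).
#' @param xl_cutoff Crosslinkable C-beta cutoff (A); defaults to the toy
#'   linker's limit.
#' @return List with `complex` ([dimer_complex()]), `transform`,
#'   `true_pairs` (data frame `site1`, `site2`, `distance`),
#'   `orientation`.
#' @export
make_true_dimer <- function(monomer, transform = NULL, seed = 1,
                            flip = FALSE, contact_gap = 3.5,
                            xl_cutoff = toy_crosslinker()$max_site_distance) {
  model <- monomer$model
  if (is.null(transform)) {
    ctr <- colMeans(as.matrix(model[, c("x", "y", "z")]))
    cache <- energy_cache(model, model)
    # reference packing of the toy hairpin: a two-fold turn (axis close
    # to z) plus centroid offset, orthonormalized for safety
    A0 <- matrix(c(-0.9479, -0.0056, -0.3184,
                   -0.0087, -0.9990,  0.0436,
                   -0.3183,  0.0441,  0.9469), 3, 3)
    sv <- svd(A0)
    A0 <- sv$u %*% t(sv$v)
    tc <- c(-2.872, -9.830, -0.252)
    settle <- function(R0, t0, trust_rot, trust_trans) {
      ctr_b <- colMeans(sweep(cache$m_xyz %*% t(R0), 2, t0, "+"))
      ener <- function(par) {
        Rw <- rotvec_to_matrix(par[1:3])
        b <- as.numeric(Rw %*% (t0 - ctr_b)) + ctr_b + par[4:6]
        complex_energy(model, model, Rw %*% R0, b, cache)
      }
      fitp <- stats::optim(rep(0, 6), ener, method = "L-BFGS-B",
                           lower = c(rep(-trust_rot, 3), rep(-trust_trans, 3)),
                           upper = c(rep(trust_rot, 3), rep(trust_trans, 3)),
                           control = list(maxit = 150))
      Rw <- rotvec_to_matrix(fitp$par[1:3])
      list(R = Rw %*% R0,
           t = as.numeric(Rw %*% (t0 - ctr_b)) + ctr_b + fitp$par[4:6])
    }
    if (!flip) {
      t0 <- as.numeric(ctr - A0 %*% ctr) + tc
      transform <- settle(A0, t0, 0.15, 1.5)
    } else {
      # opposite chain direction: pre-turn the partner, then pack it by
      # a line search along the contact normal and a local settle
      R <- A0 %*% rotvec_to_matrix(c(0, pi, 0))
      dir <- tc / sqrt(sum(tc^2))
      best <- NULL
      for (d in seq(2, 60, by = 0.25)) {
        t <- as.numeric(ctr - R %*% ctr) + d * dir
        b <- apply_transform(model, R, t)
        if (min_interchain_distance(list(A = model, B = b)) < contact_gap)
          next
        e <- complex_energy(model, model, R, t, cache)
        if (is.null(best) || e < best$e) best <- list(e = e, t = t)
      }
      if (is.null(best)) stop("could not find a clash-free planted transform")
      transform <- settle(R, best$t, 0.35, 3)
    }
    b <- apply_transform(model, transform$R, transform$t)
    if (min_interchain_distance(list(A = model, B = b)) < 3.0)
      stop("settled planted transform clashes")
  } else {
    b <- apply_transform(model, transform$R, transform$t)
    if (min_interchain_distance(list(A = model, B = b)) < 1.5)
      stop("planted transform produces a clashing complex")
  }
  cmplx <- dimer_complex(model, b, provenance = "planted dimer")
  seqv <- strsplit(monomer$sequence, "")[[1]]
  kpos <- monomer$offset + which(seqv == "K") - 1L
  pairs <- expand.grid(site1 = kpos, site2 = kpos)
  pairs$distance <- mapply(function(a, bb)
    site_distance(cmplx, a, bb, "A", "B"), pairs$site1, pairs$site2)
  true_pairs <- pairs[pairs$distance <= xl_cutoff, , drop = FALSE]
  rownames(true_pairs) <- NULL
  list(complex = cmplx, transform = transform, true_pairs = true_pairs,
       orientation = classify_orientation(cmplx)$label)
}

#' Simulate crosslinked and control peak lists with ground truth
#'
#' Digests the monomer sequence, builds the control list from unmodified
#' peptide `[M+H]+` masses, and the crosslinked list from those plus the
#' products realizable on the planted dimer: looplinks whose two sites
#' fit within the linker cutoff inside one chain, and interlinks whose
#' site pair is in the dimer's true crosslinkable set. Bounded uniform ppm mass
#' noise and uniform decoy peaks are added with the given seed. The truth
#' table maps each planted product peak to its product.
#'
#' @param monomer Result of [make_toy_monomer()].
#' @param dimer Result of [make_true_dimer()].
#' @param xl A [crosslinker_spec()].
#' @param protease `"trypsin"` or `"chymotrypsin"`.
#' @param max_missed Missed cleavages for the digest.
#' @param mz_noise_ppm Bounded m/z mass error (ppm, uniform).
#' @param n_decoys Number of uniform decoy peaks.
#' @param seed Integer seed.
#' @return List with `crosslinked`, `control` (peak-list data frames)
#'   and `truth` (products with true m/z).
#' @export
simulate_observations <- function(monomer, dimer, xl = toy_crosslinker(),
                                  protease = "trypsin", max_missed = 2,
                                  mz_noise_ppm = 20, n_decoys = 20,
                                  seed = 1) {
  peps <- digest(monomer$sequence, protease, max_missed,
                 offset = monomer$offset)
  prods <- enumerate_products(peps, xl, kinds = c("looplink", "interlink"),
                              protease = protease)
  keep <- logical(nrow(prods))
  for (i in seq_len(nrow(prods))) {
    if (prods$kind[i] == "looplink") {
      d <- site_distance(dimer$complex$A, prods$site1[i], prods$site2[i])
      keep[i] <- d <= xl$max_site_distance
    } else {
      tp <- dimer$true_pairs
      keep[i] <- any((tp$site1 == prods$site1[i] & tp$site2 == prods$site2[i]) |
                     (tp$site1 == prods$site2[i] & tp$site2 == prods$site1[i]))
    }
  }
  truth <- prods[keep, , drop = FALSE]
  truth <- truth[!duplicated(truth[, c("kind", "site1", "site2")]), ,
                 drop = FALSE]
  truth$mz <- truth$mass_mono + .mass_proton
  base_mz <- vapply(unique(peps$sequence),
                    function(s) peptide_mass(s)[["mono"]] + .mass_proton,
                    numeric(1))
  set.seed(seed + 2000L)
  jitter <- function(mz)
    mz * (1 + stats::runif(length(mz), -1, 1) * mz_noise_ppm * 1e-6)
  control <- data.frame(mz = jitter(base_mz), intensity = 100)
  xmz <- c(jitter(base_mz), jitter(truth$mz))
  if (n_decoys > 0) {
    rng <- range(c(base_mz, truth$mz))
    xmz <- c(xmz, stats::runif(n_decoys, rng[1], rng[2]))
  }
  crosslinked <- data.frame(mz = xmz, intensity = 100)
  crosslinked <- crosslinked[order(crosslinked$mz), , drop = FALSE]
  control <- control[order(control$mz), , drop = FALSE]
  rownames(crosslinked) <- rownames(control) <- NULL
  list(crosslinked = crosslinked, control = control, truth = truth)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits FASTA, monomer and dimer PDB, crosslinked and control peak
#' lists, the product truth table and the true-pair table — all
#' regenerable from the seed. Filenames carry a `synthetic_` prefix.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [toy_spec()].
#' @param xl A [crosslinker_spec()].
#' @return Invisibly, the named list of file paths.
#' @export
make_fixture_files <- function(dir, spec = toy_spec(), xl = toy_crosslinker()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mono <- make_toy_monomer(spec)
  dim <- make_true_dimer(mono, seed = spec$seed, flip = spec$flip)
  obs <- simulate_observations(mono, dim, xl,
                               mz_noise_ppm = spec$mz_noise_ppm,
                               n_decoys = spec$n_decoys, seed = spec$seed)
  paths <- list(
    fasta = file.path(dir, "synthetic_monomer.fasta"),
    monomer = file.path(dir, "synthetic_monomer.pdb"),
    dimer = file.path(dir, "synthetic_dimer.pdb"),
    crosslinked = file.path(dir, "synthetic_crosslinked_peaks.txt"),
    control = file.path(dir, "synthetic_control_peaks.txt"),
    truth = file.path(dir, "synthetic_truth.tsv"),
    true_pairs = file.path(dir, "synthetic_true_pairs.tsv"))
  writeLines(c(">synthetic_monomer", mono$sequence), paths$fasta)
  write_structure(mono$model, paths$monomer)
  write_structure(dim$complex, paths$dimer)
  # peak lists use the plain headerless two-column convention
  utils::write.table(obs$crosslinked, paths$crosslinked, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(obs$control, paths$control, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(obs$truth, paths$truth)
  write_tsv(dim$true_pairs, paths$true_pairs)
  invisible(paths)
}

#' Synthetic stand-in for the integrase NTD monomer
#'
#' A 95-residue (positions 11-105) reduced four-helix model whose
#' sequence embeds the crosslink-bearing peptide segments at their
#' construct positions (lysines 20, 24, 31, 33, 34, 68, 88, 95, 104) and
#' whose fold places helices 1 and 4 on a common face, so that a
#' side-by-side parallel dimer can satisfy the experimentally observed
#' intermolecular crosslinks. It is entirely synthetic — built from
#' ideal-helix geometry, not from any deposited coordinates — and stands
#' in for the real crystallographic monomer in tests and examples when
#' the PDB file is not available (see [ntd_reference_structure()]).
#'
#' Construct numbering counts the initiator Met as residue 0, matching
#' the crosslink site labels.
#'
#' @return List with `sequence` (full construct, residues 0-105),
#'   `model` (residues 11-105), `offset` (0).
#' @export
synthetic_ntd_monomer <- function() {
  seq0 <- paste0(
    "MIENSSPYTSE",              # 0-10
    "HFHY",                     # 11-14
    "TVTDIKDLTKLGAIYDKTKKY",    # 15-35 (K20 K24 K31 K33 K34)
    "ESTVANQIDSRESTVANQIDSESTVANQDR",  # 36-65
    "S",                        # 66
    "MKALLER",                  # 67-73 (K68)
    "ESTVANQIDSAR",             # 74-85
    "TLKNITETCKACAQVNASKS")     # 86-105 (K88 K95 K104)
  res <- strsplit(seq0, "")[[1]]
  resnos <- 11:105
  segs <- list(
    list(from = 15, to = 36, axis = c(0, 0), up = TRUE, z0 = 0),
    list(from = 40, to = 60, axis = c(9, 0), up = FALSE, z0 = 30),
    list(from = 64, to = 81, axis = c(18, 0), up = TRUE, z0 = 0),
    list(from = 86, to = 105, axis = c(27, 0), up = TRUE, z0 = 0))
  model <- build_reduced_chain(resnos, paste(res[resnos + 1L], collapse = ""),
                               segs)
  list(sequence = seq0, model = model, offset = 0L)
}
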