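#' Enumerate theoretical crosslinked products
#'
#' Builds the candidate set of dead-end, looplink (intra-peptide) and
#' inter-peptide crosslink products for a set of proteolytic peptides and
#' a crosslinker. Masses follow the standard additivity rules: a dead-end
#' adds the hydrolyzed linker mass to one peptide; a looplink adds the
#' bridge mass to one peptide carrying both sites; an interlink mass is
#' the sum of both peptide masses plus the bridge.
#'
#' For tryptic peptides a reactive lysine at the peptide's C-terminal
#' cleavage position is not a valid link site: a crosslinked (modified)
#' lysine blocks cleavage, so a linked lysine must sit at a missed
#' cleavage, i.e. be internal. Inter-peptide enumeration includes a
#' peptide paired with a second copy of itself, which is how homodimer
#' self-links such as K24-K24 arise.
#'
#' @param peptides Data frame as returned by [digest()] (columns
#'   `sequence`, `start`, `end`, `missed_cleavages`).
#' @param xl A [crosslinker_spec()].
#' @param kinds Subset of `c("deadend", "looplink", "interlink")`.
#' @param protease Protease that produced the peptides; controls the
#'   C-terminal site exclusion (applied for `"trypsin"`).
#' @param protein_start Residue number of the parent protein's first
#'   residue; used only when `xl$nterm_reactive` is set.
#' @return Data frame with columns `kind`, `pep1`, `start1`, `end1`,
#'   `pep2`, `start2`, `end2`, `site1`, `site2`, `mass_mono`, `mass_avg`.
#'   Sites are in parent-protein coordinates.
#' @export
enumerate_products <- function(peptides, xl,
                               kinds = c("deadend", "looplink", "interlink"),
                               protease = "trypsin",
                               protein_start = NULL) {
  bad <- setdiff(kinds, c("deadend", "looplink", "interlink"))
  if (length(bad)) stop("unknown product kind(s): ", paste(bad, collapse = ", "))

  sites_of <- function(i) {
    res <- strsplit(peptides$sequence[i], "")[[1]]
    pos <- peptides$start[i] + which(res %in% xl$reactive_sites) - 1L
    if (protease == "trypsin")
      pos <- setdiff(pos, peptides$end[i])       # linked K blocks cleavage
    pos <- setdiff(pos, xl$excluded_sites)
    if (isTRUE(xl$nterm_reactive) && !is.null(protein_start) &&
        peptides$start[i] == protein_start)
      pos <- union(peptides$start[i], pos)
    sort(pos)
  }
  site_list <- lapply(seq_len(nrow(peptides)), sites_of)
  masses <- t(vapply(peptides$sequence, peptide_mass, numeric(2)))

  rows <- list()
  add <- function(kind, i, j, s1, s2, mono, avg) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind,
      pep1 = peptides$sequence[i], start1 = peptides$start[i], end1 = peptides$end[i],
      pep2 = if (is.na(j)) NA_character_ else peptides$sequence[j],
      start2 = if (is.na(j)) NA_integer_ else peptides$start[j],
      end2 = if (is.na(j)) NA_integer_ else peptides$end[j],
      site1 = s1, site2 = s2, mass_mono = mono, mass_avg = avg,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(peptides))) {
    ss <- site_list[[i]]
    if (!length(ss)) next
    if ("deadend" %in% kinds && !is.na(xl$deadend_mass_mono)) {
      for (s in ss)
        add("deadend", i, NA, s, NA_integer_,
            masses[i, 1] + xl$deadend_mass_mono,
            masses[i, 2] + xl$deadend_mass_avg)
    }
    if ("looplink" %in% kinds && length(ss) >= 2) {
      pairs <- utils::combn(ss, 2)
      for (k in seq_len(ncol(pairs)))
        add("looplink", i, NA, pairs[1, k], pairs[2, k],
            masses[i, 1] + xl$bridge_mass_mono,
            masses[i, 2] + xl$bridge_mass_avg)
    }
  }
  if ("interlink" %in% kinds) {
    for (i in seq_len(nrow(peptides))) {
      si <- site_list[[i]]
      if (!length(si)) next
      for (j in i:nrow(peptides)) {
        sj <- site_list[[j]]
        if (!length(sj)) next
        mono <- masses[i, 1] + masses[j, 1] + xl$bridge_mass_mono
        avg <- masses[i, 2] + masses[j, 2] + xl$bridge_mass_avg
        for (a in si) for (b in sj) {
          if (i == j && a > b) next        # unordered within a self-pair
          add("interlink", i, j, a, b, mono, avg)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(kind = character(), pep1 = character(), start1 = integer(),
                      end1 = integer(), pep2 = character(), start2 = integer(),
                      end2 = integer(), site1 = integer(), site2 = integer(),
                      mass_mono = numeric(), mass_avg = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match theoretical products against an observed peak list
#'
#' Computes theoretical m/z values `(M + z * proton) / z` for every
#' product and charge and reports every observed peak within the mass
#' tolerance.
#'
#' @param products Data frame from [enumerate_products()].
#' @param peaks Peak list data frame with columns `mz`, `intensity`.
#' @param tolerance Numeric tolerance, in `unit`.
#' @param unit `"ppm"` or `"Da"`.
#' @param charges Integer charge states to consider.
#' @param mass_type `"mono"` or `"avg"`.
#' @return Data frame of matches (product columns plus `charge`,
#'   `theo_mz`, `obs_mz`, `intensity`, `error_da`, `error_ppm`), sorted by
#'   absolute error.
#' @export
match_peaks <- function(products, peaks, tolerance, unit = c("ppm", "Da"),
                        charges = 1L, mass_type = c("mono", "avg")) {
  unit <- match.arg(unit)
  mass_type <- match.arg(mass_type)
  stopifnot(tolerance > 0)
  if (!length(charges)) stop("empty charge set")
  mass <- if (mass_type == "mono") products$mass_mono else products$mass_avg
  out <- list()
  for (z in sort(unique(as.integer(charges)))) {
    theo <- (mass + z * .mass_proton) / z
    tol_da <- if (unit == "ppm") theo * tolerance * 1e-6 else rep(tolerance, length(theo))
    for (i in seq_along(theo)) {
      hit <- which(abs(peaks$mz - theo[i]) <= tol_da[i])
      if (!length(hit)) next
      err <- peaks$mz[hit] - theo[i]
      out[[length(out) + 1L]] <- cbind(
        products[rep(i, length(hit)), , drop = FALSE],
        data.frame(charge = z, theo_mz = theo[i], obs_mz = peaks$mz[hit],
                   intensity = peaks$intensity[hit], error_da = err,
                   error_ppm = err / theo[i] * 1e6))
    }
  }
  if (!length(out)) {
    res <- cbind(products[0, , drop = FALSE],
                 data.frame(charge = integer(), theo_mz = numeric(),
                            obs_mz = numeric(), intensity = numeric(),
                            error_da = numeric(), error_ppm = numeric()))
    return(res)
  }
  res <- do.call(rbind, out)
  key <- if (unit == "ppm") abs(res$error_ppm) else abs(res$error_da)
  res <- res[order(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep only matches absent from a control peak list
#'
#' Implements the crosslinked-minus-control design: a match is retained
#' only if no peak of the unmodified control digest lies within the
#' tolerance of its observed m/z.
#'
#' @param matches Data frame from [match_peaks()].
#' @param control_peaks Control peak list (`mz`, `intensity`).
#' @param tolerance,unit As in [match_peaks()].
#' @return The retained subset of `matches`.
#' @export
differential_products <- function(matches, control_peaks, tolerance,
                                  unit = c("ppm", "Da")) {
  unit <- match.arg(unit)
  if (!nrow(matches)) return(matches)
  keep <- vapply(matches$obs_mz, function(mz) {
    tol_da <- if (unit == "ppm") mz * tolerance * 1e-6 else tolerance
    !any(abs(control_peaks$mz - mz) <= tol_da)
  }, logical(1))
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Theoretical b/y fragment ions of (crosslinked) peptides
#'
#' Generates b- and y-series fragment masses for a peptide. A crosslinked
#' site can carry a fixed mass addition (`link_delta`; for an interlink
#' this is the partner peptide mass plus the bridge mass). For a looplink
#' (`loop_sites`), backbone cleavages between the two linked residues are
#' suppressed because the crosslinker ring is not opened, and fragments
#' containing the whole ring carry the bridge mass.
#'
#' @param sequence Peptide sequence.
#' @param series Subset of `c("b", "y")`.
#' @param charges Integer charges.
#' @param link_site Position (1-based in the peptide) of a linked residue
#'   carrying `link_delta`.
#' @param link_delta Mass added at `link_site` (Da).
#' @param loop_sites Integer pair of looplinked positions within the
#'   peptide.
#' @param loop_delta Mass of the intact loop bridge (Da).
#' @return Data frame with `label`, `series`, `index`, `charge`, `mz`.
#' @export
fragment_ions <- function(sequence, series = c("b", "y"), charges = 1L,
                          link_site = NULL, link_delta = 0,
                          loop_sites = NULL, loop_delta = 0) {
  bad <- setdiff(series, c("b", "y"))
  if (length(bad)) stop("unsupported ion series: ", paste(bad, collapse = ", "))
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  rmass <- .aa_mass_table$mono[match(res, .aa_mass_table$residue)]
  if (anyNA(rmass)) stop("unknown residue letter")
  delta <- numeric(n)
  if (!is.null(link_site)) {
    stopifnot(link_site >= 1, link_site <= n)
    delta[link_site] <- delta[link_site] + link_delta
  }
  if (!is.null(loop_sites)) {
    stopifnot(length(loop_sites) == 2)
    loop_sites <- sort(as.integer(loop_sites))
    delta[loop_sites[1]] <- delta[loop_sites[1]] + loop_delta
  }
  cut_ok <- function(k) {    # cleavage after residue k allowed?
    is.null(loop_sites) || !(k >= loop_sites[1] && k < loop_sites[2])
  }
  out <- list()
  for (z in as.integer(charges)) {
    for (k in seq_len(n - 1L)) {
      if (!cut_ok(k)) next
      if ("b" %in% series) {
        neutral <- sum(rmass[1:k]) + sum(delta[1:k])
        out[[length(out) + 1L]] <- data.frame(
          label = sprintf("b%d^%d+", k, z), series = "b", index = k,
          charge = z, mz = (neutral + z * .mass_proton) / z,
          stringsAsFactors = FALSE)
      }
      if ("y" %in% series) {
        idx <- (k + 1L):n
        neutral <- sum(rmass[idx]) + sum(delta[idx]) + .mass_water_mono
        out[[length(out) + 1L]] <- data.frame(
          label = sprintf("y%d^%d+", n - k, z), series = "y", index = n - k,
          charge = z, mz = (neutral + z * .mass_proton) / z,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Read a two-column peak list
#'
#' Whitespace- or tab-separated text with one `(m/z, intensity)` pair per
#' line; `#` comments allowed. Returned sorted ascending by m/z.
#'
#' @param path File path.
#' @return Data frame with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("mz", "intensity"))
  if (any(df$mz <= 0)) stop("non-positive m/z in peak list")
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a peak list or product/match table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
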