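#' Chain model constructor
#'
#' A chain model is an atomic coordinate table for one polypeptide chain:
#' one row per atom with residue number, residue name, atom name, element
#' and Cartesian coordinates in Angstrom.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` (and optionally `elesy`).
#' @return Object of class `chain_model` (a data frame).
#' @export
chain_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
  class(atoms) <- c("chain_model", "data.frame")
  atoms
}

#' Read one chain from a PDB file
#'
#' Reads `ATOM` records (plus `HETATM` records for selenomethionine,
#' which crystallographers deposit as the modified residue MSE) of the
#' selected chain. Alternate locations beyond the first are dropped.
#'
#' @param path PDB (or mmCIF, via bio3d) file path.
#' @param chain Chain identifier, e.g. `"A"`.
#' @return A [chain_model()].
#' @export
read_chain <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & (at$type == "ATOM" |
           (at$type == "HETATM" & at$resid == "MSE")), , drop = FALSE]
  if (!nrow(at)) stop("chain ", chain, " not found in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  chain_model(at[, c("chain", "resno", "resid", "elety", "x", "y", "z", "elesy")])
}

#' Pair two chains into a dimer complex
#'
#' @param a,b Two [chain_model()]s; relabelled chain `"A"` and `"B"`.
#' @param provenance Free-text origin tag (e.g. `"asymmetric-unit pair"`
#'   or a docked pose id).
#' @return Object of class `dimer_complex`.
#' @export
dimer_complex <- function(a, b, provenance = "") {
  a$chain <- "A"; b$chain <- "B"
  structure(list(A = a, B = b, provenance = provenance),
            class = "dimer_complex")
}

#' Write a chain or complex as a PDB file
#'
#' @param x A `chain_model` or `dimer_complex`.
#' @param path Output path.
#' @export
write_structure <- function(x, path) {
  at <- if (inherits(x, "dimer_complex")) rbind(x$A, x$B) else x
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   elesy = at$elesy)
  invisible(path)
}

#' Convert selenomethionine records to methionine
#'
#' Renames every MSE residue to MET, the selenium atom SE to SD, and
#' corrects the element symbol; all other residues are untouched.
#'
#' @param model A [chain_model()].
#' @return The edited model; attribute `n_edited` counts edited residues.
#' @export
edit_mse_to_met <- function(model) {
  is_mse <- model$resid == "MSE"
  n <- length(unique(model$resno[is_mse]))
  model$resid[is_mse] <- "MET"
  se <- is_mse & model$elety %in% c("SE", "SE ")
  model$elety[se] <- "SD"
  model$elesy[se] <- "S"
  attr(model, "n_edited") <- n
  model
}

aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", MSE = "M", PHE = "F",
            PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y",
            VAL = "V")

#' One-letter sequence of a chain model
#' @param model A [chain_model()].
#' @return Named character vector (names = residue numbers).
#' @export
model_sequence <- function(model) {
  ca <- model[model$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  stats::setNames(unname(aa3to1[ca$resid]), ca$resno)
}

# resolve a link site to coordinates; CB falls back to CA (glycine, or
# truncated side chains), SG/N taken literally
site_coord <- function(model, resno, atom = "CB") {
  rows <- model[model$resno == resno, , drop = FALSE]
  if (!nrow(rows)) stop("residue ", resno, " not present in chain")
  hit <- rows[rows$elety == atom, , drop = FALSE]
  if (!nrow(hit) && atom %in% c("CB", "SG")) {
    hit <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(hit)) warning("atom ", atom, " missing in residue ", resno,
                           "; falling back to CA", call. = FALSE)
  }
  if (!nrow(hit)) stop("atom ", atom, " not found in residue ", resno,
                       " and no fallback applies")
  as.numeric(hit[1, c("x", "y", "z")])
}

#' Distance between two link sites
#'
#' Euclidean distance between the named atoms of two residues, within one
#' chain or across a dimer complex. `CB` (the crosslink-restraint
#' reference atom for lysines) falls back to `CA` when absent.
#'
#' @param x A `chain_model` or `dimer_complex`.
#' @param res1,res2 Residue numbers.
#' @param chain1,chain2 `"A"` or `"B"` (used for complexes).
#' @param atom1,atom2 Atom names (default `"CB"`).
#' @return Distance in Angstrom.
#' @export
site_distance <- function(x, res1, res2, chain1 = "A", chain2 = "A",
                          atom1 = "CB", atom2 = atom1) {
  get_model <- function(ch) {
    if (inherits(x, "dimer_complex")) x[[ch]] else x
  }
  p1 <- site_coord(get_model(chain1), res1, atom1)
  p2 <- site_coord(get_model(chain2), res2, atom2)
  sqrt(sum((p1 - p2)^2))
}

#' Classify crosslink site pairs against a monomer structure
#'
#' A pair is `monomer-compatible` when its within-chain distance fits the
#' linker's maximum productive site distance; a self-pair (identical
#' residue on both ends, e.g. K24-K24) can only arise between two chains
#' and is always `requires-intermolecular`; a pair that fits within the
#' monomer but carries independent dimer evidence (`from_dimer = TRUE`,
#' e.g. observed in the crosslinked-dimer gel band) is `ambiguous`.
#'
#' @param pairs Data frame with columns `site1`, `site2` and optionally
#'   logical `from_dimer`.
#' @param monomer A [chain_model()].
#' @param xl A [crosslinker_spec()].
#' @param atom Site atom (default `"CB"`).
#' @return `pairs` with added columns `distance` (within-chain, Angstrom;
#'   `NA` for self-pairs) and `label`.
#' @export
classify_crosslinks <- function(pairs, monomer, xl, atom = "CB") {
  n <- nrow(pairs)
  from_dimer <- if (is.null(pairs$from_dimer)) rep(FALSE, n) else pairs$from_dimer
  dist <- numeric(n)
  lab <- character(n)
  for (i in seq_len(n)) {
    if (pairs$site1[i] == pairs$site2[i]) {
      dist[i] <- NA_real_
      lab[i] <- "requires-intermolecular"
      next
    }
    dist[i] <- site_distance(monomer, pairs$site1[i], pairs$site2[i],
                             atom1 = atom)
    lab[i] <- if (dist[i] <= xl$max_site_distance) {
      if (from_dimer[i]) "ambiguous" else "monomer-compatible"
    } else "requires-intermolecular"
  }
  pairs$distance <- round(dist, 2)
  pairs$label <- lab
  pairs
}

#' Feasibility of a cysteine (or other) crosslink across a dimer
#'
#' Measures the cross-chain distance at one residue position (SG for
#' cysteines, falling back to CB/CA) and compares it with the crosslinker
#' spacer plus slack.
#'
#' @param complex A [dimer_complex()].
#' @param resno Residue number present in both chains.
#' @param spacer Crosslinker spacer arm (Angstrom).
#' @param slack Extra allowance for side-chain flexibility (Angstrom).
#' @param atom Site atom (default `"SG"`).
#' @return List with `distance` and `feasible`.
#' @export
cys_crosslink_feasible <- function(complex, resno, spacer, slack = 2,
                                   atom = "SG") {
  d <- site_distance(complex, resno, resno, "A", "B", atom1 = atom)
  list(distance = d, feasible = d <= spacer + slack)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over paired
#' atoms (matched by residue number and atom name), restricted to proper
#' rotations.
#'
#' @param mobile,reference [chain_model()]s.
#' @param atoms Atom name(s) used for pairing (default `"CA"`).
#' @return List with rotation `R` (3x3), translation `t` (length 3; the
#'   map is `x' = R x + t`), `rmsd` (Angstrom) and `n` paired atoms.
#' @export
superpose <- function(mobile, reference, atoms = "CA") {
  key <- function(m) {
    m <- m[m$elety %in% atoms, , drop = FALSE]
    m[order(m$resno, m$elety), , drop = FALSE]
  }
  ma <- key(mobile); ra <- key(reference)
  shared <- intersect(paste(ma$resno, ma$elety), paste(ra$resno, ra$elety))
  ma <- ma[paste(ma$resno, ma$elety) %in% shared, , drop = FALSE]
  ra <- ra[paste(ra$resno, ra$elety) %in% shared, , drop = FALSE]
  if (nrow(ma) < 3) stop("need at least 3 paired atoms")
  P <- as.matrix(ma[, c("x", "y", "z")])
  Q <- as.matrix(ra[, c("x", "y", "z")])
  kabsch(P, Q)
}

# Kabsch on two n x 3 point matrices; returns map P -> Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  if (s$d[2] <= 1e-8 * max(s$d[1], 1e-12))
    stop("degenerate (collinear) atom set")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fit <- sweep(Pc %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  list(R = R, t = t, rmsd = rmsd, n = nrow(P))
}

#' Apply a rigid transform to a chain model
#'
#' @param model A [chain_model()].
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation (Angstrom).
#' @return The transformed model.
#' @export
apply_transform <- function(model, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, "+")
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# z-y-z Euler rotation matrix, angles in radians
euler_to_matrix <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# rotation-vector (axis * angle) to matrix (Rodrigues)
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# minimum inter-chain atom distance of a complex (clash diagnostics)
min_interchain_distance <- function(complex) {
  A <- as.matrix(complex$A[, c("x", "y", "z")])
  B <- as.matrix(complex$B[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Load the reference monomer structure (PDB entry 3NNQ)
#'
#' The published analysis is anchored on the crystallographic monomer of
#' the integrase N-terminal domain (PDB 3NNQ, chain A, residues 11-105,
#' selenomethionines edited to methionine). PDB coordinate files are not
#' redistributed with this package; download `3NNQ.pdb` from the PDB and
#' point to it via `options(xldock.ntd_reference = "/path/to/3NNQ.pdb")`
#' or the `path` argument.
#'
#' @param path Path to the 3NNQ PDB file.
#' @param chain Chain to extract.
#' @return MSE-edited [chain_model()].
#' @export
ntd_reference_structure <- function(path = getOption("xldock.ntd_reference"),
                                    chain = "A") {
  if (is.null(path) || !file.exists(path %||% ""))
    stop("reference structure file (PDB entry 3NNQ) not available; ",
         "download it from the PDB and set ",
         "options(xldock.ntd_reference = <path>)", call. = FALSE)
  edit_mse_to_met(read_chain(path, chain))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chain_model <- function(x, ...) {
  rn <- unique(x$resno)
  cat(sprintf("<chain_model %s>  %d atoms, %d residues (%d-%d)\n",
              x$chain[1], nrow(x), length(rn), min(rn), max(rn)))
  invisible(x)
}

#' @export
print.dimer_complex <- function(x, ...) {
  cat(sprintf("<dimer_complex>  A: %d atoms, B: %d atoms  [%s]\n",
              nrow(x$A), nrow(x$B), x$provenance))
  invisible(x)
}
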