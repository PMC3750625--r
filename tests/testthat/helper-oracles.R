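# independent oracles used across the test suite

# --- elemental-composition peptide mass oracle --------------------------
# residue formulas (dehydrated) and monoisotopic element masses; summing
# elements is an independent route to the residue-mass-table summation
.elem_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

elemental_peptide_mass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)   # one water
  for (r in res) {
    f <- .residue_formula[[r]]
    counts[names(f)] <- counts[names(f)] + f
  }
  sum(counts * .elem_mass[names(counts)])
}

# --- direct-space cyclic correlation oracle -----------------------------
# score(t) = sum_x S(x + t) * M(x), cyclic in every axis
brute_correlation <- function(S, M) {
  n <- dim(S)[1]
  C <- array(0, dim(S))
  idx <- function(t) ((seq_len(n) - 1 + t) %% n) + 1
  for (tx in 0:(n - 1)) for (ty in 0:(n - 1)) for (tz in 0:(n - 1)) {
    C[tx + 1, ty + 1, tz + 1] <-
      sum(S[idx(tx), idx(ty), idx(tz)] * M)
  }
  C
}

# --- misc builders ------------------------------------------------------
random_chain <- function(n = 20, seed = 1) {
  set.seed(seed)
  chain_model(data.frame(
    chain = "A", resno = seq_len(n), resid = "ALA", elety = "CA",
    x = stats::rnorm(n, sd = 5), y = stats::rnorm(n, sd = 5),
    z = stats::rnorm(n, sd = 5), elesy = "C", stringsAsFactors = FALSE))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# manual single-pose pose_set for refinement tests
manual_pose_set <- function(static, mobile, R = diag(3), t = c(0, 0, 0)) {
  cm <- colMeans(as.matrix(mobile[, c("x", "y", "z")]))
  cs <- colMeans(as.matrix(static[, c("x", "y", "z")]))
  # pose transform is x' = R (x - cm) + cs + t_pose; solve t_pose so that
  # the full map equals x' = R x + t
  t_pose <- as.numeric(R %*% cm + t - cs)
  structure(list(
    poses = data.frame(id = 1L, rot = 1L, alpha = 0, beta = 0, gamma = 0,
                       tx = t_pose[1], ty = t_pose[2], tz = t_pose[3],
                       shape = 0, elec = 0),
    static = static, mobile = mobile, rotations = list(R),
    settings = list(spacing = 1, angle_step = 0, keep = 1,
                    keep_per_rotation = 1, surface_thickness = 2,
                    core_weight = -15, dedupe_c2 = FALSE, n = 0)),
    class = "pose_set")
}
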