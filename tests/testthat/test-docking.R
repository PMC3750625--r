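toy0 <- make_toy_monomer(toy_spec(coord_sd = 0))

test_that("FFT shape correlation equals the direct-space oracle", {
  set.seed(99)
  for (case in 1:40) {
    n <- 8
    S <- array(runif(n^3) < 0.25, dim = c(n, n, n)) * runif(1, 0.5, 2)
    M <- array(runif(n^3) < 0.25, dim = c(n, n, n)) * 1
    gs <- structure(list(shape = S, spacing = 1), class = "dock_grid")
    gm <- structure(list(shape = M, spacing = 1), class = "dock_grid")
    C <- shape_correlation(gs, gm)
    Cb <- brute_correlation(S, M)
    expect_lt(max(abs(C - Cb)) / max(abs(Cb), 1e-12), 1e-6)
  }
  for (case in 1:10) {
    n <- 16
    S <- array(runif(n^3) < 0.15, dim = c(n, n, n)) * 1
    M <- array(runif(n^3) < 0.15, dim = c(n, n, n)) * 1
    gs <- structure(list(shape = S, spacing = 1), class = "dock_grid")
    gm <- structure(list(shape = M, spacing = 1), class = "dock_grid")
    C <- shape_correlation(gs, gm)
    Cb <- brute_correlation(S, M)
    expect_lt(max(abs(C - Cb)) / max(abs(Cb), 1e-12), 1e-6)
  }
})

test_that("single-voxel grids score only at the aligning translation", {
  n <- 8
  S <- M <- array(0, dim = c(n, n, n))
  S[3, 4, 5] <- 1
  M[1, 1, 1] <- 1
  gs <- structure(list(shape = S, spacing = 1), class = "dock_grid")
  gm <- structure(list(shape = M, spacing = 1), class = "dock_grid")
  C <- shape_correlation(gs, gm)
  expect_equal(C[3, 4, 5], 1, tolerance = 1e-9)
  C[3, 4, 5] <- 0
  expect_lt(max(abs(C)), 1e-9)
})

test_that("mismatched grids are rejected", {
  gs <- structure(list(shape = array(0, c(8, 8, 8)), spacing = 1),
                  class = "dock_grid")
  gm <- structure(list(shape = array(0, c(9, 9, 9)), spacing = 1),
                  class = "dock_grid")
  expect_error(shape_correlation(gs, gm), "mismatch")
})

test_that("digitization builds a clash core inside a contact skin", {
  one <- chain_model(data.frame(chain = "A", resno = 1L, resid = "ALA",
                                elety = "CA", x = 0, y = 0, z = 0,
                                elesy = "C", stringsAsFactors = FALSE))
  g <- discretize(one, spacing = 1, role = "static")
  expect_gt(sum(g$shape == 1), 0)          # contact skin present
  expect_gt(sum(g$shape == -15), 0)        # clash zone present
  # the clash voxel sits within one voxel of the atom position
  core_pos <- which(g$shape == -15, arr.ind = TRUE)
  ctr <- (g$n + 1) / 2
  expect_true(all(abs(core_pos - ctr) <= 1))
  expect_error(discretize(one[0, ], 1), "empty")
})

test_that("interpenetration scores below surface contact", {
  m <- toy0$model
  n <- 48
  origin <- colMeans(as.matrix(m[, c("x", "y", "z")])) - (n - 1) / 2
  gs <- discretize(m, 1, role = "static", n = n, origin = origin)
  gm <- discretize(m, 1, role = "mobile", n = n, origin = origin)
  C <- shape_correlation(gs, gm)
  buried <- C[1, 1, 1]                       # zero shift: full overlap
  contact <- C[1, 12, 1]                     # shifted to a face contact
  expect_lt(buried, 0)
  expect_gt(contact, 0)
  expect_lt(buried, contact)
})

test_that("mobile filled-voxel count scales ~8x when spacing halves", {
  g2 <- discretize(toy0$model, 2, role = "mobile")
  g1 <- discretize(toy0$model, 1, role = "mobile")
  ratio <- sum(g1$shape > 0) / sum(g2$shape > 0)
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 * 1.15)
})

test_that("electrostatic score has the right sign, zero and bilinearity", {
  a <- data.frame(x = 0, y = 0, z = 0, q = 1)
  b <- data.frame(x = 10, y = 0, z = 0, q = -1)
  e <- electrostatic_score(a, b)
  expect_lt(e, 0)
  b$q <- 0
  expect_equal(electrostatic_score(a, b), 0)
  a2 <- a; b2 <- b
  a2$q <- 2; b2$q <- -2
  expect_equal(electrostatic_score(a2, b2), 4 * e, tolerance = 1e-9)
})

test_that("pose generation is deterministic and honors the retention count", {
  m <- toy0$model
  p1 <- generate_poses(m, m, spacing = 2, angle_step = 45, keep = 150,
                       keep_per_rotation = 4)
  p2 <- generate_poses(m, m, spacing = 2, angle_step = 45, keep = 150,
                       keep_per_rotation = 4)
  expect_identical(p1$poses, p2$poses)
  expect_equal(nrow(p1$poses), 150L)
  expect_false(is.unsorted(-p1$poses$shape[p1$poses$elec <= 1e-9]))
})

test_that("pose transforms reproduce the stored translation", {
  m <- toy0$model
  ps <- generate_poses(m, m, spacing = 2, angle_step = 90, keep = 20,
                       keep_per_rotation = 2)
  for (i in c(1L, nrow(ps$poses))) {
    cx <- pose_complex(ps, i)
    shift <- colMeans(as.matrix(cx$B[, c("x", "y", "z")])) -
      colMeans(as.matrix(cx$A[, c("x", "y", "z")]))
    expect_equal(as.numeric(shift),
                 as.numeric(ps$poses[i, c("tx", "ty", "tz")]),
                 tolerance = 1e-6)
  }
})
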