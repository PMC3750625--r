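toy0 <- make_toy_monomer(toy_spec(coord_sd = 0))

test_that("PDB write/read round-trips coordinates to 3 decimals", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy0$model, f)
  back <- read_chain(f, "A")
  expect_equal(nrow(back), nrow(toy0$model))
  expect_equal(back$x, toy0$model$x, tolerance = 1e-3)
  expect_equal(back$resno, toy0$model$resno)
  expect_error(read_chain(f, "Z"), "chain Z")
})

test_that("selenomethionine records are converted to methionine", {
  mse <- chain_model(data.frame(
    chain = "A", resno = rep(1:3, each = 2),
    resid = c("MSE", "MSE", "ALA", "ALA", "MSE", "MSE"),
    elety = c("CA", "SE", "CA", "CB", "CA", "SE"),
    x = 1:6, y = 1:6, z = 1:6,
    elesy = c("C", "SE", "C", "C", "C", "SE"), stringsAsFactors = FALSE))
  out <- edit_mse_to_met(mse)
  expect_equal(attr(out, "n_edited"), 2L)
  expect_false(any(out$resid == "MSE"))
  expect_equal(sum(out$elety == "SD"), 2L)
  expect_equal(sum(out$resid == "MET"), 4L)
  # idempotent on a model without MSE
  again <- edit_mse_to_met(out)
  expect_equal(attr(again, "n_edited"), 0L)
  expect_equal(again$resid, out$resid)
})

test_that("site distances are symmetric, zero on the diagonal, and metric", {
  m <- toy0$model
  expect_equal(site_distance(m, 5, 5), 0)
  set.seed(3)
  for (i in 1:20) {
    trip <- sample(unique(m$resno), 3)
    d12 <- site_distance(m, trip[1], trip[2])
    d21 <- site_distance(m, trip[2], trip[1])
    d13 <- site_distance(m, trip[1], trip[3])
    d23 <- site_distance(m, trip[2], trip[3])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("CB falls back to CA with a warning when absent", {
  m <- chain_model(data.frame(
    chain = "A", resno = c(1L, 2L), resid = c("GLY", "ALA"),
    elety = c("CA", "CA"), x = c(0, 3), y = 0, z = 0, elesy = "C",
    stringsAsFactors = FALSE))
  expect_warning(d <- site_distance(m, 1, 2), "falling back")
  expect_equal(suppressWarnings(site_distance(m, 1, 2)), 3)
  expect_error(suppressWarnings(site_distance(m, 1, 9)), "not present")
})

test_that("crosslink classification follows distance and evidence rules", {
  m <- toy0$model
  xl <- toy_crosslinker()   # 12 A limit
  pairs <- data.frame(site1 = c(2L, 2L, 2L), site2 = c(2L, 7L, 29L))
  d27 <- site_distance(m, 2, 7)
  d229 <- site_distance(m, 2, 29)
  out <- classify_crosslinks(pairs, m, xl)
  expect_equal(out$label[1], "requires-intermolecular")   # self pair
  expect_equal(out$label[2],
               if (d27 <= 12) "monomer-compatible" else "requires-intermolecular")
  expect_equal(out$label[3],
               if (d229 <= 12) "monomer-compatible" else "requires-intermolecular")
  # dimer-band evidence turns a short distance into ambiguity
  pairs$from_dimer <- TRUE
  out2 <- classify_crosslinks(pairs, m, xl)
  short <- which(!is.na(out2$distance) & out2$distance <= 12)
  expect_true(all(out2$label[short] == "ambiguous"))
})

test_that("cysteine crosslink feasibility compares distance with spacer plus slack", {
  b <- apply_transform(toy0$model, diag(3), c(0, 30, 0))
  cx <- dimer_complex(toy0$model, b)
  res <- suppressWarnings(cys_crosslink_feasible(cx, 5, spacer = 8, atom = "CB"))
  expect_equal(res$distance, 30, tolerance = 1e-6)
  expect_false(res$feasible)
  expect_true(suppressWarnings(
    cys_crosslink_feasible(cx, 5, spacer = 29, atom = "CB"))$feasible)
})

test_that("superposition recovers rigid transforms exactly", {
  m <- random_chain(25, seed = 5)
  sp0 <- superpose(m, m)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$R, diag(3), tolerance = 1e-9)

  R <- random_rotation(6)
  t <- c(4, -2, 9)
  moved <- apply_transform(m, R, t)
  sp <- superpose(moved, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-7)
  # recovered transform inverts the applied one
  expect_equal(sp$R %*% R, diag(3), tolerance = 1e-7)
})

test_that("superposition agrees with the bio3d reference on noisy point sets", {
  for (s in 1:10) {
    m <- random_chain(30, seed = s)
    R <- random_rotation(s + 50)
    noisy <- apply_transform(m, R, c(1, 2, 3))
    set.seed(s + 100)
    noisy$x <- noisy$x + rnorm(30, 0, 0.1)
    noisy$y <- noisy$y + rnorm(30, 0, 0.1)
    noisy$z <- noisy$z + rnorm(30, 0, 0.1)
    sp <- superpose(noisy, m)
    ref <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.numeric(t(as.matrix(m[, c("x", "y", "z")]))),
      mobile = as.numeric(t(as.matrix(noisy[, c("x", "y", "z")])))))
    ref_rmsd <- sqrt(mean(colSums(
      (matrix(ref, 3) - t(as.matrix(m[, c("x", "y", "z")])))^2)))
    expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("degenerate collinear atom sets are rejected", {
  m <- chain_model(data.frame(
    chain = "A", resno = 1:4, resid = "ALA", elety = "CA",
    x = 1:4, y = 0, z = 0, elesy = "C", stringsAsFactors = FALSE))
  flat <- m
  flat$x <- -flat$x
  expect_error(superpose(flat, m), "degenerate|collinear")
})

test_that("rigid transforms preserve internal distances", {
  m <- random_chain(15, seed = 9)
  R <- random_rotation(10)
  moved <- apply_transform(m, R, c(-3, 7, 1))
  d0 <- dist(as.matrix(m[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(moved[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)
})

test_that("the reference crystal structure loader explains how to supply the file", {
  old <- getOption("xldock.ntd_reference")
  on.exit(options(xldock.ntd_reference = old))
  options(xldock.ntd_reference = NULL)
  expect_error(ntd_reference_structure(), "3NNQ")
})
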