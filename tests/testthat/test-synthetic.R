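test_that("toy monomers have ideal helical geometry", {
  spec <- toy_spec(coord_sd = 0)
  mono <- make_toy_monomer(spec)
  expect_equal(nchar(mono$sequence), 32L)
  ca <- mono$model[mono$model$elety == "CA", ]
  ca1 <- ca[ca$resno <= 16, ]
  d4 <- sqrt(rowSums((as.matrix(ca1[1:12, c("x", "y", "z")]) -
                      as.matrix(ca1[5:16, c("x", "y", "z")]))^2))
  expect_true(all(abs(d4 - 6.2) < 0.5))     # i -> i+4 contact distance
  # rise along the axis: 1.5 A per residue
  expect_equal(diff(ca1$z), rep(1.5, 15), tolerance = 1e-9)
})

test_that("generation is fully determined by the seed", {
  a <- make_toy_monomer(toy_spec(seed = 7))
  b <- make_toy_monomer(toy_spec(seed = 7))
  expect_identical(a, b)
  c <- make_toy_monomer(toy_spec(seed = 8))
  expect_false(identical(a$model$x, c$model$x))

  da <- make_true_dimer(a, seed = 7)
  db <- make_true_dimer(b, seed = 7)
  expect_identical(da$transform, db$transform)

  oa <- simulate_observations(a, da, seed = 7)
  ob <- simulate_observations(b, db, seed = 7)
  expect_identical(oa, ob)
})

test_that("an i,i+3 lysine pair is looplinkable", {
  mono <- make_toy_monomer(toy_spec(lysines = c(5, 8), coord_sd = 0))
  expect_lt(site_distance(mono$model, 5, 8), 11)
})

test_that("infeasible toy specifications are rejected", {
  expect_error(toy_spec(n_helices = 0))
  expect_error(toy_spec(helix_len = 3))
})

test_that("planted dimers are clash-free and carry a true crosslinkable set", {
  mono <- make_toy_monomer(toy_spec(seed = 3))
  tru <- make_true_dimer(mono, seed = 3)
  expect_gte(xldock:::min_interchain_distance(tru$complex), 3)
  expect_gte(nrow(tru$true_pairs), 3)
  # the recorded set equals a brute-force sweep over all lysine pairs
  seqv <- strsplit(mono$sequence, "")[[1]]
  kpos <- which(seqv == "K")
  brute <- list()
  for (a in kpos) for (b in kpos) {
    d <- site_distance(tru$complex, a, b, "A", "B")
    if (d <= toy_crosslinker()$max_site_distance)
      brute[[length(brute) + 1]] <- c(a, b)
  }
  got <- apply(tru$true_pairs[, c("site1", "site2")], 1, paste, collapse = "-")
  want <- vapply(brute, paste, character(1), collapse = "-")
  expect_setequal(got, want)
})

test_that("flipped planting reverses the orientation label", {
  mono <- make_toy_monomer(toy_spec(seed = 4))
  normal <- make_true_dimer(mono, seed = 4)
  flipped <- make_true_dimer(mono, seed = 4, flip = TRUE)
  expect_false(normal$orientation == flipped$orientation)
})

test_that("noise-free observations are recovered exactly by match + differential", {
  mono <- make_toy_monomer(toy_spec(seed = 5))
  tru <- make_true_dimer(mono, seed = 5)
  obs <- simulate_observations(mono, tru, mz_noise_ppm = 0, n_decoys = 0,
                               seed = 5)
  peps <- digest(mono$sequence, "trypsin", 2)
  prods <- enumerate_products(peps, toy_crosslinker(),
                              kinds = c("looplink", "interlink"))
  m <- match_peaks(prods, obs$crosslinked, tolerance = 1, unit = "ppm")
  m <- differential_products(m, obs$control, tolerance = 1, unit = "ppm")
  # MS1 matching identifies products up to mass coincidence (site
  # assignment within a peptide needs MS/MS); compare at the peak level
  expect_setequal(round(unique(m$mass_mono), 4),
                  round(unique(obs$truth$mass_mono), 4))
  # and every true product peak is matched
  expect_true(all(round(obs$truth$mass_mono, 4) %in% round(m$mass_mono, 4)))
})

test_that("noisy observations are recovered at matched tolerance", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    mono <- make_toy_monomer(toy_spec(seed = s))
    tru <- make_true_dimer(mono, seed = s)
    obs <- simulate_observations(mono, tru, mz_noise_ppm = 20,
                                 n_decoys = 20, seed = s)
    peps <- digest(mono$sequence, "trypsin", 2)
    prods <- enumerate_products(peps, toy_crosslinker(),
                                kinds = c("looplink", "interlink"))
    m <- match_peaks(prods, obs$crosslinked, tolerance = 50, unit = "ppm")
    got <- round(unique(m$mass_mono), 4)
    want <- round(unique(obs$truth$mass_mono), 4)
    hits <- hits + sum(want %in% got)
    total <- total + length(want)
  }
  expect_gte(hits / total, 0.99)
})

test_that("fixture files land on disk and read back consistently", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_files(dir, toy_spec(seed = 2))
  expect_true(all(file.exists(unlist(paths))))
  pk <- read_peaklist(paths$crosslinked)
  expect_true(all(diff(pk$mz) >= 0))
  mono <- read_chain(paths$monomer, "A")
  expect_equal(length(unique(mono$resno)), 32L)
  both <- read_chain(paths$dimer, "B")
  expect_equal(length(unique(both$resno)), 32L)
  fa <- readLines(paths$fasta)
  expect_match(fa[1], "^>")
  expect_equal(nchar(fa[2]), 32L)
})
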