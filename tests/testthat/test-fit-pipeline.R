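test_that("configuration validation names each problem", {
  cfg <- pipeline_config()
  p <- validate_config(cfg)
  expect_true(any(grepl("structure", p)))
  expect_true(any(grepl("restraints", p)))

  cfg2 <- pipeline_config(structure = "/no/such/file.pdb",
                          restraints = list(restraint(1, 2, 12)),
                          tolerance = -1)
  p2 <- validate_config(cfg2)
  expect_true(any(grepl("does not exist", p2)))
  expect_true(any(grepl("tolerance", p2)))
  expect_error(run_pipeline(cfg2), "invalid config")
})

test_that("a complete bypass configuration validates cleanly and runs", {
  mono <- make_toy_monomer(toy_spec(seed = 6))
  tru <- make_true_dimer(mono, seed = 6)
  tp <- tru$true_pairs[order(tru$true_pairs$distance), ][1:3, ]
  rs <- lapply(seq_len(3), function(i)
    restraint(tp$site1[i], tp$site2[i], 12,
              origin = paste0(tp$site1[i], "-", tp$site2[i])))
  cfg <- pipeline_config(structure = mono$model, restraints = rs,
                         spacing = 2, angle_step = 45, keep = 500,
                         refine_top = 4)
  expect_length(validate_config(cfg), 0)
  rep <- suppressMessages(run_pipeline(cfg))
  expect_s3_class(rep, "pipeline_report")
  expect_equal(rep$status, "ok")
  expect_null(rep$matches)                      # MS stages skipped
  expect_true(all(rep$interlink_table$distance <=
                  rep$interlink_table$max_distance))
})

test_that("the MS-to-model pipeline runs end to end on generated fixtures", {
  dir <- withr::local_tempdir()
  spec <- toy_spec(seed = 9)
  paths <- make_fixture_files(dir, spec)
  cfg <- pipeline_config(
    sequence = paths$fasta, structure = paths$monomer,
    crosslinked_peaks = paths$crosslinked, control_peaks = paths$control,
    xl = toy_crosslinker(), tolerance = 50, tol_unit = "ppm",
    spacing = 2, angle_step = 45, keep = 800, refine_top = 4,
    outdir = file.path(dir, "out"))
  expect_length(validate_config(cfg), 0)
  rep <- suppressMessages(run_pipeline(cfg))
  expect_equal(rep$status, "ok")
  expect_gt(nrow(rep$matches), 0)
  expect_false(is.null(rep$looplink_table))
  expect_true(file.exists(file.path(dir, "out", "selected_dimer.pdb")))
  expect_true(file.exists(file.path(dir, "out", "matches.tsv")))

  # reproducibility: an identical configuration gives an identical model
  rep2 <- suppressMessages(run_pipeline(cfg))
  expect_equal(rep$fit$transform, rep2$fit$transform)
  expect_equal(rep$fit$energy, rep2$fit$energy)
})

test_that("restraint TSV files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chainA_res\tchainB_res\tmax_dist",
               "31\t20/24\t21.3", "24\t24\t21.3"), f)
  rs <- read_restraints(f)
  expect_length(rs, 2)
  expect_equal(nrow(rs[[1]]$alternatives), 2L)
  expect_equal(rs[[2]]$max_distance, 21.3)
})

test_that("fit accessor methods expose the transform and restraint residuals", {
  mono <- make_toy_monomer(toy_spec(seed = 10))
  tru <- make_true_dimer(mono, seed = 10)
  tp <- tru$true_pairs[order(tru$true_pairs$distance), ][1:3, ]
  rs <- lapply(seq_len(3), function(i)
    restraint(tp$site1[i], tp$site2[i], 12))
  fit <- fit_dimer(mono$model, mono$model, rs, spacing = 2,
                   angle_step = 45, keep = 500, refine_top = 4,
                   n_points = 120)
  expect_equal(fit$status, "ok")
  co <- coef(fit)
  expect_named(co, c("alpha", "beta", "gamma", "tx", "ty", "tz"))
  expect_s3_class(fitted(fit), "dimer_complex")
  expect_true(all(residuals(fit) <= 0))         # all restraints satisfied
  expect_output(print(fit), "restraint-compatible")
  expect_output(print(summary(fit)), "Settings")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("an unsatisfiable restraint set is a distinguished outcome", {
  mono <- make_toy_monomer(toy_spec(seed = 11))
  rs <- list(restraint(2, 2, max_distance = 0.5))
  fit <- fit_dimer(mono$model, mono$model, rs, spacing = 2,
                   angle_step = 60, keep = 200, refine_top = 2)
  expect_equal(fit$status, "no-compatible-pose")
  expect_null(fit$complex)
  expect_output(print(fit), "NO restraint-compatible")
})

test_that("ligand RMSD is zero for identical complexes and swap-aware checks work", {
  mono <- make_toy_monomer(toy_spec(seed = 12))
  tru <- make_true_dimer(mono, seed = 12)
  expect_equal(ligand_rmsd(tru$complex, tru$complex), 0, tolerance = 1e-9)
  sw <- dimer_complex(tru$complex$B, tru$complex$A)
  direct <- ligand_rmsd(tru$complex, tru$complex)
  swapped <- ligand_rmsd(sw, tru$complex)
  expect_lte(min(direct, swapped), direct)
})
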