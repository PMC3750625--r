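toy0 <- make_toy_monomer(toy_spec(coord_sd = 0))

small_pose_set <- function() {
  m <- toy0$model
  generate_poses(m, m, spacing = 2, angle_step = 60, keep = 300,
                 keep_per_rotation = 6)
}

test_that("zero restraints keep every pose; violations reject poses", {
  ps <- small_pose_set()
  out <- apply_restraints(ps, list())
  expect_equal(nrow(out$poses$poses), nrow(ps$poses))

  rs <- list(restraint(2, 2, max_distance = 12))
  flt <- apply_restraints(ps, rs)
  expect_lte(flt$report$n_out, flt$report$n_in)
  expect_true(all(flt$report$worst_distance <= 12))
  # a pose whose restrained distance exceeds the bound is rejected
  rs_tight <- list(restraint(2, 2, max_distance = 0.5))
  expect_equal(apply_restraints(ps, rs_tight)$report$n_out, 0L)
})

test_that("filtering is independent of restraint order", {
  ps <- small_pose_set()
  rs <- list(restraint(2, 7, 12), restraint(11, 11, 12), restraint(2, 29, 14))
  a <- apply_restraints(ps, rs)$poses$poses$id
  b <- apply_restraints(ps, rev(rs))$poses$poses$id
  expect_setequal(a, b)
})

test_that("ambiguous restraints are satisfied by any alternative pair", {
  ps <- small_pose_set()
  r_amb <- list(restraint(11, c(2, 29), 12))
  r_a <- list(restraint(11, 2, 12))
  r_b <- list(restraint(11, 29, 12))
  ids_amb <- apply_restraints(ps, r_amb)$poses$poses$id
  ids_union <- union(apply_restraints(ps, r_a)$poses$poses$id,
                     apply_restraints(ps, r_b)$poses$poses$id)
  expect_setequal(ids_amb, ids_union)
})

test_that("restraint construction validates its inputs", {
  expect_error(restraint(1, 2, max_distance = -1))
  expect_error(restraint(integer(0), 2))
  r <- restraint(31, c(20, 24), 21.3)
  expect_equal(nrow(r$alternatives), 2L)
})

test_that("two-atom refinement reaches the analytic soft-core minimum", {
  one <- function(x, r) chain_model(data.frame(
    chain = "A", resno = 1L, resid = "ALA", elety = "CA",
    x = x, y = 0, z = 0, elesy = "C", radius = r, stringsAsFactors = FALSE))
  static <- one(0, 2.0)
  mobile <- one(7.5, 2.0)    # start away from the optimum
  ps <- manual_pose_set(static, mobile)
  ref <- refine_pose(ps, 1, trust_trans = 4)
  moved <- apply_transform(mobile, ref$A, ref$b)
  d <- sqrt(sum((as.numeric(moved[1, c("x", "y", "z")]))^2))
  expect_equal(d, sqrt(4^2 - 1), tolerance = 0.05)   # sigma = 4, soft = 1
  expect_lte(ref$energy, ref$energy0)
})

test_that("refinement relieves a steric clash and never raises the energy", {
  m <- toy0$model
  clashed <- apply_transform(m, diag(3), c(0, 6, 0))  # deep overlap
  ps <- manual_pose_set(m, m, t = c(0, 6, 0))
  before <- min_interchain_distance(list(A = m, B = clashed))
  ref <- refine_pose(ps, 1)
  after_model <- apply_transform(m, ref$A, ref$b)
  after <- min_interchain_distance(list(A = m, B = after_model))
  expect_gt(after, before)
  expect_lt(ref$energy, ref$energy0)
})

test_that("model selection prefers lower energy, then larger buried area", {
  m <- toy0$model
  ps <- manual_pose_set(m, m, t = c(0, 12, 0))
  near <- list(id = 1, A = diag(3), b = c(0, 12, 0), energy = -5)
  far <- list(id = 2, A = diag(3), b = c(0, 40, 0), energy = -1)
  sel <- select_model(list(near, far), ps)
  expect_equal(attr(sel, "pose_id"), 1)
  # equal energies: the larger interface wins
  far$energy <- -5
  sel2 <- select_model(list(far, near), ps)
  expect_equal(attr(sel2, "pose_id"), 1)
  expect_error(select_model(list(), ps), "no restraint-compatible")
})

test_that("single-sphere accessible area matches the analytic value", {
  one <- chain_model(data.frame(chain = "A", resno = 1L, resid = "ALA",
                                elety = "CA", x = 0, y = 0, z = 0,
                                elesy = "C", stringsAsFactors = FALSE))
  asa <- shrake_rupley(one, n_points = 960)
  expect_equal(asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("two touching spheres bury twice the analytic cap area", {
  r <- 1.7 + 1.4
  d <- 2.5                                   # center separation < 2 r
  two <- chain_model(data.frame(
    chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
    x = c(0, d), y = 0, z = 0, elesy = "C", stringsAsFactors = FALSE))
  asa <- shrake_rupley(two, n_points = 960)
  buried <- 2 * 4 * pi * r^2 - sum(asa)
  cap_area <- 2 * pi * r * (r - d / 2)       # spherical cap height r - d/2
  expect_equal(buried, 2 * cap_area, tolerance = 0.05 * 2 * cap_area)
})

test_that("infinitely separated chains bury no area", {
  m <- toy0$model
  far <- apply_transform(m, diag(3), c(500, 0, 0))
  rep <- interface_metrics(dimer_complex(m, far), n_points = 120)
  expect_equal(rep$delta_asa, 0, tolerance = 1e-6)
  expect_equal(unname(rep$n_interface), c(0L, 0L))
})

test_that("buried area is invariant under a common rigid transform", {
  m <- toy0$model
  b <- apply_transform(m, diag(3), c(0, 11, 0))
  cx <- dimer_complex(m, b)
  rep1 <- interface_metrics(cx, n_points = 960)
  R <- random_rotation(77)
  cx2 <- dimer_complex(apply_transform(m, R, c(5, 6, 7)),
                       apply_transform(b, R, c(5, 6, 7)))
  rep2 <- interface_metrics(cx2, n_points = 960)
  expect_gt(rep1$delta_asa, 0)
  expect_lt(abs(rep1$delta_asa - rep2$delta_asa) / rep1$delta_asa, 0.005)
})

test_that("orientation classification distinguishes translation from flip", {
  m <- toy0$model
  trans <- classify_orientation(dimer_complex(m, apply_transform(m, diag(3), c(0, 30, 0))))
  expect_equal(trans$angle, 0, tolerance = 1e-6)
  expect_equal(trans$label, "parallel")

  # 180 deg about an axis perpendicular to the end-to-end vector
  Rflip <- xldock:::rotvec_to_matrix(c(0, 0, pi))
  flip <- classify_orientation(dimer_complex(m, apply_transform(m, Rflip, c(0, 40, 0))))
  expect_equal(flip$angle, 180, tolerance = 1)
  expect_equal(flip$label, "antiparallel")

  short <- m[m$resno <= 5, ]
  expect_error(classify_orientation(dimer_complex(m, short)), "dissimilar")
})
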