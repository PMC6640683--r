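test_that("unsuperposed RMSD reproduces analytic values", {
  expect_equal(rmsd_pair(c(0, 0, 0), c(3, 4, 0)), 5)
  a <- rbind(c(0, 0, 0), c(2, 0, 0))
  b <- rbind(c(0, 0, 0), c(0, 2, 0))
  expect_equal(rmsd_pair(a, b), 2)
  expect_equal(rmsd_pair(a, b), rmsd_pair(b, a))   # symmetric
  expect_equal(rmsd_pair(a, a), 0)
  expect_error(rmsd_pair(a, rbind(b, b)), "differ")
})

test_that("superposed RMSD of a rigidly moved copy vanishes", {
  set.seed(21)
  x <- matrix(rnorm(36), 12, 3)
  y <- sweep(x %*% t(rotation_matrix(c(1, 1, 0), 77)), 2, -c(1, 2, 3))
  expect_lt(rmsd_pair(x, y, superpose = TRUE), 1e-8)
})

test_that("RMSD series is zero on rigid tumbles and at its own reference", {
  s <- mini_structure(8)
  tr <- rigid_tumble(s, n_frames = 6, seed = 7)
  all_set <- select_atoms(s, class = "all")
  ser <- rmsd_series(tr, 1L, all_set)
  expect_s3_class(ser, "md_timeseries")
  expect_equal(ser$units, "A")
  expect_true(all(ser$values <= 1e-8))
  # noisy case: value at the reference frame is exactly 0
  toy <- make_toy_antibody(n_res_per_domain = 4)
  tr2 <- simulate_trajectory(toy$structure, toy$map,
                             ground_truth(fluct = fluctuation_spec(0.5),
                                          seed = 8), 5)
  ser2 <- rmsd_series(tr2, 1L, select_atoms(toy$structure, class = "all"))
  expect_equal(ser2$values[1], 0, tolerance = 1e-10)
})

test_that("RMSD series matches a direct evaluation through an independent engine", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  tr <- simulate_trajectory(toy$structure, toy$map,
                            ground_truth(fluct = fluctuation_spec(0.5),
                                         seed = 9), 8)
  all_set <- select_atoms(toy$structure, class = "all")
  ser <- rmsd_series(tr, 1L, all_set)
  ref <- frame_coords(tr, 1)
  oracle <- vapply(seq_len(8), function(f)
    bio3d_fitted_rmsd(frame_coords(tr, f), ref), numeric(1))
  expect_equal(ser$values, oracle, tolerance = 1e-8)
})

test_that("mean structure converges to the obvious answers", {
  s <- mini_structure(6)
  static <- md_trajectory(s, array(rep(s$xyz, each = 3),
                                   dim = c(3, n_atoms(s), 3)),
                          times = 1:3)
  all_set <- select_atoms(s, class = "all")
  expect_equal(mean_structure(static, all_set), s$xyz,
               tolerance = 1e-10, ignore_attr = TRUE)

  # two frames displaced symmetrically (pure translation): mean = midpoint
  shift <- c(1, -2, 3)
  coords <- array(0, dim = c(2, n_atoms(s), 3))
  coords[1, , ] <- sweep(s$xyz, 2, -shift)
  coords[2, , ] <- sweep(s$xyz, 2, shift)
  two <- md_trajectory(s, coords, times = 1:2)
  expect_equal(mean_structure(two, all_set), s$xyz,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("mean structure recovers a noisy template within Monte-Carlo error", {
  toy <- make_toy_antibody(n_res_per_domain = 6)
  sigma <- 0.5
  nf <- 200L
  tr <- simulate_trajectory(toy$structure, toy$map,
                            ground_truth(fluct = fluctuation_spec(sigma),
                                         seed = 10), nf)
  all_set <- select_atoms(toy$structure, class = "all")
  m <- mean_structure(tr, all_set)
  # the template is only defined up to a rigid motion of the mean
  f <- best_fit(m, toy$structure$xyz)
  expect_lt(max(abs(apply_fit(m, f) - toy$structure$xyz)),
            3 * sigma / sqrt(nf) * 3)
})

test_that("RMSF is zero for rigid motion and undefined for one frame", {
  s <- mini_structure(8)
  tr <- rigid_tumble(s, n_frames = 5, seed = 11)
  all_set <- select_atoms(s, class = "all")
  prof <- rmsf_profile(tr, all_set, fit_mode = "local")
  expect_true(all(prof$rmsf < 1e-8))
  expect_equal(nrow(prof), 8L)         # one record per residue
  one <- md_trajectory(s, s$xyz, times = 0.1)
  expect_error(rmsf_profile(one, all_set), "single-frame")
})

test_that("RMSF of isotropic noise approaches sqrt(3)*sigma and the direct formula", {
  toy <- make_toy_antibody(n_res_per_domain = 6)
  tr <- simulate_trajectory(toy$structure, toy$map,
                            ground_truth(fluct = fluctuation_spec(1.0),
                                         seed = 12), 600)
  all_set <- select_atoms(toy$structure, class = "all")
  prof <- rmsf_profile(tr, all_set, fit_mode = "local")
  expect_lt(max(abs(prof$rmsf / sqrt(3) - 1)), 0.10)

  # dual route: direct evaluation of the fluctuation formula on the frames
  # aligned by the package
  al <- align_trajectory(tr, all_set,
                         reference = mean_structure(tr, all_set))
  grp <- group_by_residue(toy$structure, all_set)
  oracle <- direct_rmsf(al$coords, grp$groups)
  expect_equal(prof$rmsf, unname(oracle), tolerance = 0.02)
})

test_that("multi-atom residues average their atoms in the fluctuation formula", {
  toy <- make_toy_antibody(n_res_per_domain = 4, atoms_per_residue = 4)
  tr <- simulate_trajectory(toy$structure, toy$map,
                            ground_truth(fluct = fluctuation_spec(0.8),
                                         seed = 13), 300)
  all_set <- select_atoms(toy$structure, class = "all")
  prof <- rmsf_profile(tr, all_set, fit_mode = "local")
  grp <- group_by_residue(toy$structure, all_set)
  expect_equal(nrow(prof), length(grp$groups))
  expect_lt(max(abs(prof$rmsf / (sqrt(3) * 0.8) - 1)), 0.15)
})

test_that("whole-molecule alignment inflates RMSF of a hinged arm; local fit does not", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  truth <- ground_truth(
    hinges = list(hinge_program("fab_left",
                                hinge_schedule("sinusoid", amp = 20,
                                               period = 40))),
    fluct = fluctuation_spec(0.2), seed = 14)
  tr <- simulate_trajectory(toy$structure, toy$map, truth, 80)
  arm <- region_atoms(toy$structure, toy$map, "fab_left")
  whole <- select_atoms(toy$structure, class = "all")
  local_prof <- rmsf_profile(tr, arm, fit_mode = "local")
  global_prof <- rmsf_profile(tr, arm, fit_mode = "global", fit_set = whole)
  # local fit sees only the noise floor; whole-molecule fit adds the sweep
  expect_lt(max(local_prof$rmsf), 3 * sqrt(3) * 0.2)
  expect_gt(mean(global_prof$rmsf), 2 * mean(local_prof$rmsf))
})

test_that("RMSF recovers a per-residue amplitude profile", {
  toy <- make_toy_antibody(n_res_per_domain = 6)
  spec <- fluctuation_spec(0.5, ramps = list(
    list(chain = "B", terminal = "C", length = 10L, peak = 3)))
  tr <- simulate_trajectory(toy$structure, toy$map,
                            ground_truth(fluct = spec, seed = 15), 800)
  bset <- select_atoms(toy$structure, chain = "B", class = "all")
  prof <- rmsf_profile(tr, bset, fit_mode = "local")
  sig_atom <- abtraj:::expand_sigma(toy$structure, spec)
  sig_b <- sig_atom[bset$indices]
  expect_gt(stats::cor(prof$rmsf, sqrt(3) * sig_b), 0.99)
  expect_lt(max(abs(prof$rmsf / (sqrt(3) * sig_b) - 1)), 0.12)
})

test_that("per-domain fitted RMSD never exceeds the whole-fit RMSD on the same atoms", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  truth <- ground_truth(
    hinges = list(hinge_program("fab_right",
                                hinge_schedule("linear", from = 0, to = 30))),
    fluct = fluctuation_spec(0.3), seed = 16)
  tr <- simulate_trajectory(toy$structure, toy$map, truth, 20)
  whole <- select_atoms(toy$structure, class = "all")
  for (lab in c("VH_D", "CH1_D", "CH3_B")) {
    dom <- fragment_atoms(toy$structure, toy$map, lab)
    fit_self <- rmsd_series(tr, 1L, dom, fit_set = dom)
    fit_whole <- rmsd_series(tr, 1L, dom, fit_set = whole)
    expect_true(all(fit_self$values <= fit_whole$values + 1e-8))
  }
})

test_that("window statistics summarize the steady-state interval", {
  const <- md_timeseries(1:10, rep(5, 10))
  ws <- window_stats(const, 2, 8)
  expect_equal(ws$mean, 5)
  expect_equal(ws$sd, 0)
  ser <- md_timeseries(1:3, c(1, 2, 3))
  ws2 <- window_stats(ser, 0, 10)
  expect_equal(ws2$mean, 2)
  expect_equal(ws2$sd, 1)
  expect_equal(ws2$n_points, 3L)
  expect_error(window_stats(ser, 5, 10), "no samples")
  expect_error(window_stats(ser, 3, 1), "t_start")
})

test_that("enlarging a window moves the mean by at most the range of added values", {
  set.seed(22)
  ser <- md_timeseries(1:50, cumsum(rnorm(50)))
  base <- window_stats(ser, 20, 30)
  for (lo in c(10, 15)) {
    wider <- window_stats(ser, lo, 30)
    added <- ser$values[ser$times >= lo & ser$times < 20]
    expect_lte(abs(wider$mean - base$mean), diff(range(c(added, base$mean))))
  }
})
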