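test_that("the toy antibody has four chains, 12 domains and resolved anchors", {
  toy <- make_toy_antibody()
  expect_setequal(unique(toy$structure$atoms$chain), c("A", "B", "C", "D"))
  domains <- setdiff(unique(toy$map$fragments$label),
                     c("linker_B", "linker_D"))
  expect_length(domains, 12L)
  expect_setequal(names(toy$map$regions), c("fab_left", "fab_right", "fc"))
  expect_equal(nrow(toy$map$anchors), 4L)
  expect_true(all(!is.na(toy$map$anchors$atom_index)))
})

test_that("the smallest valid molecule still supports every selection", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  expect_error(make_toy_antibody(n_res_per_domain = 3), ">= 4")
  for (rg in names(toy$map$regions)) {
    set <- region_atoms(toy$structure, toy$map, rg)
    expect_gte(length(set), 3L)
    # non-degenerate for superposition
    expect_silent(best_fit(toy$structure$xyz[set$indices, ],
                           toy$structure$xyz[set$indices, ]))
  }
})

test_that("frame-0 hinge angles reflect the construction geometry", {
  toy <- make_toy_antibody(arm_angle = 110)
  a <- angle_series(
    simulate_trajectory(toy$structure, toy$map, ground_truth(seed = 1), 1),
    toy$map)
  expect_equal(a$top$values[1], 110, tolerance = 1e-6)
  toy2 <- make_toy_antibody(arm_angle = 90)
  a2 <- angle_series(
    simulate_trajectory(toy2$structure, toy2$map, ground_truth(seed = 1), 1),
    toy2$map)
  expect_equal(a2$top$values[1], 90, tolerance = 1e-6)
})

test_that("zero noise and constant hinges give identical frames", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  tr <- simulate_trajectory(toy$structure, toy$map, ground_truth(seed = 3), 4)
  for (f in 2:4)
    expect_identical(tr$coords[f, , ], tr$coords[1, , ])
  all_set <- select_atoms(toy$structure, class = "all")
  expect_true(all(rmsd_series(tr, 1L, all_set)$values < 1e-12))
})

test_that("generation is deterministic in the seed", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  truth <- ground_truth(
    hinges = list(hinge_program("fab_left",
                                hinge_schedule("sinusoid", amp = 10,
                                               period = 7))),
    fluct = fluctuation_spec(0.4), seed = 99,
    global = list(rot_deg_per_frame = 1, drift_A_per_frame = 0.3))
  t1 <- simulate_trajectory(toy$structure, toy$map, truth, 10)
  t2 <- simulate_trajectory(toy$structure, toy$map, truth, 10)
  expect_identical(t1$coords, t2$coords)
  truth2 <- ground_truth(hinges = truth$hinges, fluct = truth$fluct,
                         seed = 100, global = truth$global)
  t3 <- simulate_trajectory(toy$structure, toy$map, truth2, 10)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("domains stay internally rigid under noise-free hinge motion", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  truth <- ground_truth(
    hinges = list(hinge_program("fab_right",
                                hinge_schedule("linear", from = 0, to = 50))),
    seed = 4)
  tr <- simulate_trajectory(toy$structure, toy$map, truth, 6)
  for (lab in c("VH_D", "CL_C", "CH2_B")) {
    idx <- fragment_atoms(toy$structure, toy$map, lab)$indices
    d0 <- as.matrix(stats::dist(matrix(tr$coords[1, idx, ], ncol = 3)))
    dN <- as.matrix(stats::dist(matrix(tr$coords[6, idx, ], ncol = 3)))
    expect_equal(dN, d0, tolerance = 1e-8)
  }
})

test_that("terminal ramps elevate amplitudes only near the chosen terminus", {
  toy <- make_toy_antibody(n_res_per_domain = 6)
  spec <- fluctuation_spec(0.5, ramps = list(
    list(chain = "B", terminal = "C", length = 8L, peak = 4)))
  sig <- abtraj:::expand_sigma(toy$structure, spec)
  a <- toy$structure$atoms
  b_max <- max(a$resid[a$chain == "B"])
  expect_equal(sig[a$chain == "B" & a$resid == b_max], 0.5 * 4)
  expect_equal(sig[a$chain == "B" & a$resid == 1], 0.5)
  expect_true(all(sig[a$chain == "A"] == 0.5))
  expect_error(
    abtraj:::expand_sigma(toy$structure,
                          fluctuation_spec(0.5, ramps = list(
                            list(chain = "B", terminal = "C",
                                 length = 1000L, peak = 2)))),
    "longer than chain")
})

test_that("ground truth sidecars round-trip through JSON", {
  truth <- ground_truth(
    hinges = list(hinge_program("fab_left",
                                hinge_schedule("linear", from = 5, to = 25),
                                axis = c(0, 1, 1))),
    fluct = fluctuation_spec(0.4, ramps = list(
      list(chain = "D", terminal = "N", length = 4L, peak = 2))),
    global = list(rot_deg_per_frame = 0.5, drift_A_per_frame = 0.1),
    seed = 7, dt = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$seed, 7L)
  expect_equal(back$dt, 0.05)
  expect_equal(back$hinges[[1]]$axis, c(0, 1, 1) / sqrt(2))
  expect_equal(schedule_angles(back$hinges[[1]]$schedule, 5),
               schedule_angles(truth$hinges[[1]]$schedule, 5))
  expect_equal(back$fluct$ramps[[1]]$peak, 2)
  expect_equal(back$global$rot_deg_per_frame, 0.5)
  # identical trajectories from the reloaded truth
  toy <- make_toy_antibody(n_res_per_domain = 4)
  expect_identical(
    simulate_trajectory(toy$structure, toy$map, truth, 5)$coords,
    simulate_trajectory(toy$structure, toy$map, back, 5)$coords)
})

test_that("generated trajectories survive a multi-model PDB round trip", {
  toy <- make_toy_antibody(n_res_per_domain = 4)
  truth <- ground_truth(fluct = fluctuation_spec(0.3), seed = 8, dt = 0.2)
  tr <- simulate_trajectory(toy$structure, toy$map, truth, 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, path)
  back <- read_trajectory(path, toy$structure, dt = 0.2)
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)
  expect_equal(back$times, tr$times)
})
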