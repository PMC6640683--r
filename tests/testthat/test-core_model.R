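test_that("structure invariants are enforced", {
  s <- mini_structure(3)
  expect_s3_class(s, "md_structure")
  expect_equal(n_atoms(s), 12L)
  bad <- s$atoms
  bad$atom_name[2] <- bad$atom_name[1]
  expect_error(md_structure(bad, s$xyz), "duplicate")
  expect_error(md_structure(s$atoms[0, ], s$xyz[0, , drop = FALSE]), "no atoms")
  xyz <- s$xyz
  xyz[1, 1] <- NaN
  expect_error(md_structure(s$atoms, xyz), "finite")
})

test_that("PDB round trip preserves chains, residue numbers and coordinates", {
  s <- mini_structure(5, chains = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_structure(path)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$resid, s$atoms$resid)
  expect_equal(s2$atoms$atom_name, s$atoms$atom_name)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("single-atom and degenerate PDB inputs behave", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(n_atoms(s), 1L)
  expect_equal(as.numeric(s$xyz), c(0, 0, 0))

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "no atoms|parse")
  expect_error(read_structure("/nonexistent/file.pdb"), "no such file")
})

test_that("altloc records resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$xyz[1, 1], 9)
})

test_that("multi-model trajectories read with synthesized times", {
  s <- mini_structure(4)
  tr <- rigid_tumble(s, n_frames = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, path)
  tr2 <- read_trajectory(path, s, dt = 0.1)
  expect_equal(n_frames(tr2), 3L)
  expect_equal(tr2$times, c(0.1, 0.2, 0.3))
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-3, ignore_attr = TRUE)

  # pairing with the wrong structure is an error
  expect_error(read_trajectory(path, mini_structure(5)), "atom count")
  expect_error(read_trajectory(path, s, dt = 0), "dt")

  # a single-frame trajectory is valid
  one <- md_trajectory(s, s$xyz, times = 0.1)
  expect_equal(n_frames(one), 1L)
  expect_error(md_trajectory(s, tr$coords, times = c(1, 1, 2)), "increasing")
})

test_that("selection grammar matches chains, residue ranges and atom classes", {
  s <- mini_structure(10, chains = c("A", "B"))
  expect_equal(length(select_atoms(s, "chain A and heavy")), 40L)
  expect_equal(length(select_atoms(s, "chain A and resid 1-3 and CA")), 3L)
  expect_equal(length(select_atoms(s, "chain A and resid 7 and backbone")), 4L)
  expect_error(select_atoms(s, "chain Z"), "empty selection")
  expect_error(select_atoms(s, "chain A and garbage 3"), "parse")
})

test_that("selection is idempotent, ordered, and chains partition the molecule", {
  s <- mini_structure(6, chains = c("A", "B", "C", "D"))
  sel <- select_atoms(s, "chain B and heavy")
  again <- atom_set(sel$indices, structure = s)
  expect_identical(sel$indices, again$indices)
  expect_false(is.unsorted(sel$indices))
  union_idx <- sort(unlist(lapply(c("A", "B", "C", "D"), function(ch)
    select_atoms(s, chain = ch, class = "all")$indices)))
  expect_identical(union_idx, select_atoms(s, class = "all")$indices)
})

test_that("hydrogens are kept but excluded from the heavy class", {
  s <- mini_structure(3, atom_names = c("N", "CA", "HA"))
  expect_equal(n_atoms(s), 9L)
  expect_equal(length(select_atoms(s, class = "heavy")), 6L)
})

test_that("domain maps load from YAML with anchors resolved", {
  toy <- make_toy_antibody()
  path <- withr::local_tempfile(fileext = ".yaml")
  frag_list <- lapply(seq_len(nrow(toy$map$fragments)), function(i)
    as.list(toy$map$fragments[i, ]))
  yaml::write_yaml(list(
    fragments = frag_list,
    regions = lapply(toy$map$regions, as.list),
    anchors = setNames(lapply(seq_len(nrow(toy$map$anchors)), function(i)
      list(chain = toy$map$anchors$chain[i],
           resid = toy$map$anchors$resid[i],
           rule = toy$map$anchors$rule[i])),
      toy$map$anchors$label)), path)
  map <- read_domain_map(path, toy$structure)
  expect_equal(nrow(map$anchors), 4L)
  expect_true(all(!is.na(map$anchors$atom_index)))
  expect_setequal(names(map$regions), c("fab_left", "fab_right", "fc"))
})

test_that("unresolvable or malformed domain maps error", {
  toy <- make_toy_antibody()
  anch <- toy$map$anchors
  anch$resid[1] <- 9999L
  expect_error(domain_map(toy$map$fragments, toy$map$regions, anch,
                          structure = toy$structure), "absent")
  expect_error(domain_map(toy$map$fragments[0, ]), "zero fragments")
  frag <- toy$map$fragments
  frag <- rbind(frag, data.frame(label = "VH_B", chain = "B",
                                 start = 2L, end = 5L))
  expect_error(domain_map(frag), "overlapping")
  expect_error(domain_map(toy$map$fragments,
                          regions = list(bad = "NOPE")), "undefined")
})

test_that("the shipped IgG domain map example parses", {
  path <- system.file("extdata", "igg_1igt_domain_map.yaml", package = "abtraj")
  expect_true(nzchar(path))
  y <- yaml::read_yaml(path)
  expect_true(length(y$fragments) >= 12L)
  expect_setequal(names(y$anchors), c("fab_left", "fab_right", "hinge", "fc"))
  expect_equal(y$anchors$fab_left$resid, 31L)
  expect_equal(y$anchors$fab_right$resid, 65L)
  expect_equal(y$anchors$hinge$resid, 225L)
  expect_equal(y$anchors$fc$resid, 442L)
})
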