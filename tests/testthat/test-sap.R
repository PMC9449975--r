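ref_480 <- build_exposure_reference(n_points = 480L, conformers = 1L)

test_that("SAP equals a naive double-loop transcription of its definition", {
  toy <- make_toy_protein(c("LEU", "GLY", "ARG", "ALA"), seed = 1)
  traj <- trajectory(toy$system, list(toy$frame))
  fast <- sap_index(traj, reference = ref_480, n_points = 240L)
  slow <- naive_sap(traj, reference = ref_480, n_points = 240L)
  expect_equal(fast$per_atom, slow, tolerance = 1e-9)
})

test_that("glycine-only neighborhoods score exactly zero", {
  toy <- make_toy_protein(rep("GLY", 4), seed = 1)
  traj <- trajectory(toy$system, list(toy$frame))
  res <- sap_index(traj, reference = ref_480, n_points = 240L)
  expect_true(all(res$per_atom == 0))
  expect_equal(res$score, 0)
})

test_that("a single isolated residue gives the one-term closed form", {
  toy <- make_toy_protein("LEU", seed = 1)
  traj <- trajectory(toy$system, list(toy$frame))
  prot <- select_group(toy$system, "protein")
  s <- shrake_rupley(toy$frame, toy$system, prot, n_points = 240L)
  saa_sc <- suppressWarnings(residue_saa(s, toy$system))[[1]]
  expected <- saa_sc / ref_480$saa_exposed[["LEU"]] * bm_scale()$values[["LEU"]]
  got <- atom_sap(traj, j = prot[toy$system$atoms$name == "CA"],
                  reference = ref_480, n_points = 240L)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("per-atom SAP is invariant to rigid-body motion", {
  toy <- make_toy_protein(c("LEU", "ARG"), seed = 1)
  traj1 <- trajectory(toy$system, list(toy$frame))
  shifted <- frame(sweep(toy$frame$coordinates, 2, c(5, -2, 1), "+"))
  traj2 <- trajectory(toy$system, list(shifted))
  r1 <- sap_index(traj1, reference = ref_480, n_points = 240L)
  r2 <- sap_index(traj2, reference = ref_480, n_points = 240L)
  expect_equal(r1$per_atom, r2$per_atom, tolerance = 1e-12)
  expect_equal(r1$per_residue, r2$per_residue, tolerance = 1e-12)
})

test_that("a vanishing neighborhood radius empties every SAP sum", {
  toy <- make_toy_protein(c("LEU", "ARG"), seed = 1)
  traj <- trajectory(toy$system, list(toy$frame))
  # under the self-inclusive convention only a side-chain atom's own area
  # survives r -> 0; with the own residue excluded every sum is empty
  res_self <- sap_index(traj, radius = 1e-6, reference = ref_480,
                        n_points = 240L, include_self = FALSE)
  expect_true(all(res_self$per_atom == 0))
  res <- sap_index(traj, radius = 1e-6, reference = ref_480, n_points = 240L)
  backbone <- !side_chain_mask(toy$system)[as.integer(names(res$per_atom))]
  expect_true(all(res$per_atom[backbone] == 0))
})

test_that("BSAP reduces to SAP when the buffer is far from the protein", {
  fx <- kinetics_fixture(2, 0)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 2,
                                    timestep = 1, unbound_mean = Inf,
                                    unbound_range = c(1.5, 2.0), seed = 8)
  sap <- sap_index(gen$trajectory, mode = "SAP", reference = ref_480,
                   n_points = 240L)
  bsap <- sap_index(gen$trajectory, mode = "BSAP", reference = ref_480,
                    n_points = 240L)
  expect_equal(bsap$per_atom, sap$per_atom, tolerance = 1e-12)
  expect_equal(bsap$score, sap$score, tolerance = 1e-12)
})

test_that("adsorbed hydrophilic buffer lowers BSAP below SAP on a hydrophobic patch", {
  toy <- make_toy_protein(rep("LEU", 5), seed = 1)
  sysb <- add_buffer_molecules(toy$system, 2, 0)
  gen <- make_adsorption_trajectory(sysb, toy$frame, n_frames = 3, timestep = 1,
                                    initial_state = "bound", bound_mean = 1e6,
                                    seed = 9)
  sap <- sap_index(gen$trajectory, mode = "SAP", reference = ref_480,
                   n_points = 240L)
  bsap <- sap_index(gen$trajectory, mode = "BSAP", reference = ref_480,
                    n_points = 240L)
  expect_lte(bsap$score, sap$score)
  # atoms in contact with the buffer are strictly reduced
  expect_lt(min(bsap$per_atom - sap$per_atom), -1e-6)
  expect_true(all(bsap$per_atom <= sap$per_atom + 1e-9))
})

test_that("the isolated buffer hydrophilicity term matches its closed form", {
  # one CB atom "protein" and one single-atom buffer molecule in contact,
  # placed far enough that neither occludes the other
  atoms <- data.frame(index = 1:2, name = c("CB", "C1"), element = "C",
                      residue_index = 1:2, residue_name = c("ALA", "HSD"),
                      chain_id = c("A", "B"), vdw_radius = 0.17,
                      group = c("protein", "buffer_neutral"),
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, data.frame(molecule_id = 1L, charge_state = 0L,
                                            atom_indices = I(list(2L))))
  f <- frame(rbind(c(0, 0, 0), c(0.39, 0, 0)))  # within 0.4, beyond occlusion? no
  traj <- trajectory(sys, list(f))
  sap_b <- sap_index(traj, mode = "SAP", reference = ref_480, n_points = 960L)
  bsap <- sap_index(traj, mode = "BSAP", reference = ref_480, n_points = 960L)
  # the buffer atom occludes here, so isolate the hydrophilicity term by
  # computing the occluded protein term explicitly
  s_b <- shrake_rupley(f, sys, 1L, context = 1:2, n_points = 960L)
  sap_occluded <- unname(s_b$area) / ref_480$saa_exposed[["ALA"]] *
    bm_scale()$values[["ALA"]]
  s_buf <- shrake_rupley(f, sys, 2L, context = 1:2, n_points = 960L)
  his_term <- bm_scale()$values[["HIS"]] * unname(s_buf$area) /
    ref_480$saa_exposed_excipient
  expect_equal(unname(bsap$per_atom), sap_occluded + his_term, tolerance = 1e-9)
  expect_lt(unname(bsap$per_atom), unname(sap_b$per_atom))
})

test_that("scores sum only the positive per-atom values", {
  expect_equal(sap_score(c(-1, -0.2, -3)), 0)
  expect_equal(sap_score(c(-1, 0.3, -3)), 0.3)
  expect_equal(sap_score(c(0.25, 0.5, -0.1)), 0.75)
  toy <- make_toy_protein(c("LEU", "ARG"), seed = 1)
  traj <- trajectory(toy$system, list(toy$frame))
  res <- sap_index(traj, reference = ref_480, n_points = 240L)
  expect_equal(res$score, sum(pmax(res$per_atom, 0)))
  expect_equal(sap_score(res), res$score)
})

test_that("non-protein atoms are rejected for SAP evaluation", {
  fx <- kinetics_fixture(1, 0)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 1,
                                    timestep = 1, seed = 1)
  buf_atom <- fx$system$buffer_molecules$atom_indices[[1]][1]
  expect_error(sap_index(gen$trajectory, atoms = buf_atom,
                         reference = ref_480), "protein")
})
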