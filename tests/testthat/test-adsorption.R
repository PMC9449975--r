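test_that("minimum-distance series match a brute-force all-pairs oracle", {
  fx <- kinetics_fixture(2, 1)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 8,
                                    timestep = 5, seed = 21)
  for (id in fx$system$buffer_molecules$molecule_id) {
    ser <- min_distance_series(gen$trajectory, id)
    expect_equal(ser$d_min, brute_min_dist_series(gen$trajectory, id),
                 tolerance = 1e-10)
  }
  expect_error(min_distance_series(gen$trajectory, 99), "no buffer molecule")
})

test_that("a static molecule at fixed distance yields a constant series", {
  fx <- kinetics_fixture(1, 0)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 5,
                                    timestep = 1, initial_state = "bound",
                                    bound_mean = 1e9,
                                    bound_range = c(0.3, 0.3 + 1e-12), seed = 1)
  ser <- min_distance_series(gen$trajectory, 1)
  expect_equal(ser$d_min, rep(0.3, 5), tolerance = 1e-6)
})

test_that("periodic wrapping keeps approach distances continuous across the boundary", {
  # single protein atom near the box face; buffer walks through the face
  atoms <- rbind(single_atom_system()$atoms,
                 data.frame(index = 2L, name = "C1", element = "C",
                            residue_index = 2L, residue_name = "HSD",
                            chain_id = "B", vdw_radius = 0.17,
                            group = "buffer_neutral", stringsAsFactors = FALSE))
  sys <- molecular_system(atoms, data.frame(molecule_id = 1L, charge_state = 0L,
                                            atom_indices = I(list(2L))))
  box <- diag(3) * 10
  xs <- seq(8, 10.5, by = 0.25)   # crosses x = 10 toward the protein image
  frames <- lapply(seq_along(xs), function(i)
    frame(rbind(c(0.5, 5, 5), c(xs[i], 5, 5)), box = box, time = i - 1))
  traj <- trajectory(sys, frames)
  d <- min_distance_series(traj, 1)$d_min
  expect_lt(max(abs(diff(d))), 0.25 + 1e-9)   # no reentry jump
  expect_equal(d[length(d)], 10.5 - 10 + 0.5 - 1, tolerance = 1e-9)  # wrapped approach
})

test_that("residence events follow the run-length definition by hand", {
  ser <- structure(list(molecule_id = 1L, times = seq(0, 50, by = 10),
                        d_min = c(0.5, 0.3, 0.3, 0.5, 0.35, 0.5)),
                   class = "min_distance_series")
  ev <- residence_events(ser, r_cut = 0.4)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$tau_r, c(20, 10))
  expect_equal(ev$start_frame, c(1L, 4L))
  expect_equal(ev$end_frame, c(2L, 4L))
  # never below the cutoff -> no events
  ser$d_min <- rep(0.6, 6)
  expect_equal(nrow(residence_events(ser)), 0L)
  # the boundary value d_min == r_cut counts as adsorbed
  ser$d_min <- c(0.5, 0.4, 0.5, 0.5, 0.5, 0.5)
  expect_equal(residence_events(ser, 0.4)$tau_r, 10)
})

test_that("event durations conserve the total adsorbed time", {
  fx <- kinetics_fixture(3, 0)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 200,
                                    timestep = 10, seed = 31)
  for (id in 1:3) {
    ser <- min_distance_series(gen$trajectory, id)
    ev <- residence_events(ser, 0.4)
    expect_equal(sum(ev$tau_r), sum(ser$d_min <= 0.4) * 10)
  }
})

test_that("detected events agree exactly with generator ground truth on the grid", {
  fx <- kinetics_fixture(3, 2)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 300,
                                    timestep = 10, align_grid = TRUE, seed = 41)
  detected <- do.call(rbind, lapply(fx$system$buffer_molecules$molecule_id,
    function(id) residence_events(min_distance_series(gen$trajectory, id))))
  expect_equal(nrow(detected), nrow(gen$events))
  expect_equal(detected$start_frame, gen$events$start_frame)
  expect_equal(detected$end_frame, gen$events$end_frame)
  expect_equal(detected$tau_r, gen$events$tau_r)
})

test_that("permanent adsorption gives S(t) identically one", {
  fx <- kinetics_fixture(2, 0)
  gen <- make_adsorption_trajectory(fx$system, fx$toy$frame, n_frames = 30,
                                    timestep = 1, initial_state = "bound",
                                    bound_mean = 1e9, seed = 2)
  sc <- survival_probability(gen$trajectory, charge_state = 0)
  expect_true(all(sc$S == 1))
})

test_that("a single finite contact gives a step-function S(t)", {
  # contact lasts exactly 3 frames from the single origin at its start
  atoms <- rbind(single_atom_system()$atoms,
                 data.frame(index = 2L, name = "C1", element = "C",
                            residue_index = 2L, residue_name = "HSD",
                            chain_id = "B", vdw_radius = 0.17,
                            group = "buffer_neutral", stringsAsFactors = FALSE))
  sys <- molecular_system(atoms, data.frame(molecule_id = 1L, charge_state = 0L,
                                            atom_indices = I(list(2L))))
  d_seq <- c(0.3, 0.3, 0.3, 0.8, 0.8, 0.8)
  frames <- lapply(seq_along(d_seq), function(i)
    frame(rbind(c(0, 0, 0), c(d_seq[i], 0, 0)), time = i - 1))
  traj <- trajectory(sys, frames)
  sc <- survival_probability(traj, charge_state = 0, multi_origin = FALSE)
  expect_equal(sc$S, c(1, 1, 1, 0, 0, 0))
})

test_that("exponential telegraph kinetics reproduce exp(-k_off t)", {
  toy <- make_toy_protein(c("ALA", "LEU", "GLY"), seed = 1)
  sysb <- add_buffer_molecules(toy$system, 15, 15)
  gen <- make_adsorption_trajectory(sysb, toy$frame, n_frames = 2000,
                                    timestep = 10, bound_mean = 100,
                                    unbound_mean = 300, align_grid = FALSE,
                                    seed = 11)
  sc <- survival_probability(gen$trajectory, r_cut = 0.4, max_lag_frames = 30)
  expect_gt(sc$n_origins, 1e4)
  expect_true(all(diff(sc$S) <= 0))
  expect_true(all(sc$S >= 0 & sc$S <= 1))
  expect_lt(max(abs(sc$S - exp(-sc$lag_times / 100))), 0.015)
})

test_that("contact counts match direct enumeration and a brute-force oracle", {
  # one buffer atom within 0.4 nm of exactly the three backbone atoms it faces
  toy <- make_toy_protein(c("ALA", "ALA"), seed = 1)
  sysb <- add_buffer_molecules(toy$system, 1, 0)
  buf_idx <- sysb$buffer_molecules$atom_indices[[1]]
  xyz <- rbind(toy$frame$coordinates, toy$frame$coordinates[2, ] + c(0, 0.35, 0))
  traj <- trajectory(sysb, list(frame(xyz)))
  counts <- contact_counts(traj, charge_state = 0, cutoff = 0.4)
  manual <- colSums(outer(buf_idx, select_group(sysb, "protein"),
    Vectorize(function(b, p) sqrt(sum((xyz[b, ] - xyz[p, ])^2)) <= 0.4)))
  res_of <- sysb$atoms$residue_index[select_group(sysb, "protein")]
  expect_equal(unname(counts), as.numeric(tapply(manual, res_of, sum)))
  # randomized fixture vs the same brute force, multiple frames
  gen <- make_adsorption_trajectory(sysb, toy$frame, n_frames = 20,
                                    timestep = 5, seed = 13)
  cc <- contact_counts(gen$trajectory, charge_state = 0, cutoff = 0.4)
  brute <- numeric(nrow(sysb$residues))
  for (f in gen$trajectory$frames) {
    for (p in select_group(sysb, "protein")) for (b in buf_idx) {
      if (brute_min_image(f$coordinates[p, ], f$coordinates[b, ], f$box) <= 0.4)
        brute[sysb$atoms$residue_index[p]] <- brute[sysb$atoms$residue_index[p]] + 1
    }
  }
  expect_equal(unname(cc), brute / 20, tolerance = 1e-12)
})

test_that("BAI closed forms, zero handling and scale invariance hold", {
  res <- bai(list("0" = c(r1 = 10, r2 = 5, r3 = 1)))[["0"]]
  expect_equal(unname(res$per_residue_bai), c(0, log(2), log(10)))
  expect_equal(res$n_max, 10)
  # N_avg = N_max e^-2 -> BAI = 2 kT
  res2 <- bai(list("0" = c(a = 10, b = 10 * exp(-2))))[["0"]]
  expect_equal(unname(res2$per_residue_bai[2]), 2)
  # shared reference across charge states
  both <- bai(list("0" = c(a = 10, b = 2), "1" = c(a = 4, b = 1)))
  expect_equal(both[["1"]]$n_max, 10)
  expect_equal(unname(both[["1"]]$per_residue_bai[1]), log(10 / 4))
  # only ratios matter
  scaled <- bai(list("0" = 7 * c(r1 = 10, r2 = 5, r3 = 1)))[["0"]]
  expect_equal(scaled$per_residue_bai, res$per_residue_bai)
  # zero-count residues are flagged, all-zero input errors
  z <- bai(list("0" = c(a = 3, b = 0)))[["0"]]
  expect_true(is.infinite(z$per_residue_bai[["b"]]))
  expect_equal(z$zero_contact_residues, "b")
  expect_error(bai(list("0" = c(a = 0, b = 0))), "zero")
})
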