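test_that("radius of gyration closed forms and scaling hold", {
  f1 <- frame(matrix(c(1, 2, 3), 1, 3))
  expect_equal(radius_of_gyration(f1, 1L), 0)
  f2 <- frame(rbind(c(0, 0, 0), c(0, 0, 1.4)))
  expect_equal(radius_of_gyration(f2, 1:2), 0.7)
  # uniform ring of equal masses -> R_g = ring radius
  n <- 2000; th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- frame(cbind(2.5 * cos(th), 2.5 * sin(th), 0))
  expect_equal(radius_of_gyration(ring, seq_len(n)), 2.5, tolerance = 1e-3)
  # translation/rotation invariance and linear scaling
  set.seed(1)
  xyz <- matrix(stats::rnorm(60), 20, 3)
  rg <- radius_of_gyration(frame(xyz), 1:20)
  expect_equal(radius_of_gyration(frame(sweep(xyz, 2, c(5, 6, 7), "+")), 1:20), rg)
  expect_equal(radius_of_gyration(frame(3 * xyz), 1:20), 3 * rg)
  expect_error(radius_of_gyration(f1, integer(0)), "empty")
})

test_that("mass weighting shifts R_g toward the heavy atoms", {
  f <- frame(rbind(c(0, 0, 0), c(0, 0, 1)))
  rg_eq <- radius_of_gyration(f, 1:2, masses = c(1, 1))
  rg_heavy <- radius_of_gyration(f, 1:2, masses = c(10, 1))
  expect_lt(rg_heavy, rg_eq)
})

test_that("four-point domain angles hit their trivial geometries", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0),      # A -> B along +x
               c(0, 1, 0), c(1, 1, 0),      # C -> D along +x (parallel)
               c(2, 1, 0),                  # D' for antiparallel
               c(0, 2, 0), c(0, 3, 0))      # C'-D' along +y (perpendicular)
  f <- frame(xyz)
  expect_equal(fab_fc_angle(f, angle_definition(1, 2, 3, 4)), 0)
  expect_equal(fab_fc_angle(f, angle_definition(1, 2, 5, 4)), pi)
  expect_equal(fab_fc_angle(f, angle_definition(1, 2, 6, 7)), pi / 2)
  # symmetric under swapping the two vectors
  d1 <- angle_definition(1, 2, 6, 7); d2 <- angle_definition(6, 7, 1, 2)
  expect_equal(fab_fc_angle(f, d1), fab_fc_angle(f, d2))
  expect_error(fab_fc_angle(f, angle_definition(1, 2, 3, 3)), "disjoint")
  expect_error(angle_definition(integer(0), 2, 3, 4), "nonempty")
  f0 <- frame(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_error(fab_fc_angle(f0, angle_definition(1, 2, 3, 4)), "zero-length")
})

test_that("surface-referenced distributions bin, average and conserve counts", {
  atoms <- rbind(single_atom_system()$atoms,
                 data.frame(index = 2L, name = "C1", element = "C",
                            residue_index = 2L, residue_name = "HSD",
                            chain_id = "B", vdw_radius = 0.17,
                            group = "buffer_neutral", stringsAsFactors = FALSE))
  sys <- molecular_system(atoms, data.frame(molecule_id = 1L, charge_state = 0L,
                                            atom_indices = I(list(2L))))
  f <- frame(rbind(c(0, 0, 0), c(0.55, 0, 0)))
  traj <- trajectory(sys, list(f))
  r <- surface_rdf(traj, 1L, 2L, bin_width = 0.1, r_max = 1)
  expect_equal(r$counts_per_width[6], 1 / 0.1)    # all mass in [0.5, 0.6)
  expect_equal(sum(r$counts_per_width != 0), 1L)
  # duplicating frames changes nothing
  traj2 <- trajectory(sys, list(f, frame(f$coordinates, time = 1)))
  expect_equal(surface_rdf(traj2, 1L, 2L, bin_width = 0.1, r_max = 1)$counts_per_width,
               r$counts_per_width)
  expect_error(surface_rdf(traj, 1L, 1L, 0.1, 1), "disjoint")
})

test_that("shell-distributed targets reproduce the generating density", {
  # targets uniform in a thick shell around one reference atom: the
  # min-distance density per width is 3 r^2 / (r2^3 - r1^3)
  n_t <- 400
  set.seed(8)
  u <- matrix(stats::rnorm(3 * n_t), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rr <- (stats::runif(n_t, 0.5^3, 1.5^3))^(1 / 3)
  atoms <- data.frame(index = seq_len(n_t + 1),
                      name = c("C", rep("C1", n_t)), element = "C",
                      residue_index = c(1L, rep(2L, n_t)),
                      residue_name = c("ALA", rep("HSD", n_t)),
                      chain_id = c("A", rep("B", n_t)), vdw_radius = 0.17,
                      group = c("protein", rep("buffer_neutral", n_t)),
                      stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, data.frame(molecule_id = 1L, charge_state = 0L,
                                            atom_indices = I(list(2:(n_t + 1)))))
  f <- frame(rbind(c(0, 0, 0), u * rr))
  traj <- trajectory(sys, list(f))
  r <- surface_rdf(traj, 1L, 2:(n_t + 1), bin_width = 0.25, r_max = 1.5)
  mids <- utils::head(r$bin_edges, -1) + 0.125
  expected <- ifelse(mids > 0.5, n_t * 3 * mids^2 / (1.5^3 - 0.5^3), 0)
  # conservation: integral equals the target count
  expect_equal(sum(r$counts_per_width) * 0.25, n_t)
  expect_lt(max(abs(r$counts_per_width - expected)) / max(expected), 0.15)
})

test_that("Green-Kubo viscosity vanishes for white noise and flips no sign", {
  set.seed(3)
  wn <- matrix(stats::rnorm(3e5), ncol = 3)
  eta_wn <- green_kubo_viscosity(wn, dt = 0.01, volume = 50, temperature = 300,
                                 t_max = 2)
  # white noise: only the lag-0 trapezoid survives, ~ sigma^2 dt / 2
  scale_ref <- green_kubo_viscosity(matrix(1, 10, 3), dt = 0.01, volume = 50,
                                    temperature = 300, t_max = 0.05)
  expect_lt(abs(eta_wn), scale_ref)   # far below a correlated signal
  expect_equal(green_kubo_viscosity(-wn, dt = 0.01, volume = 50,
                                    temperature = 300, t_max = 2), eta_wn)
  expect_error(green_kubo_viscosity(wn[, 1:2], dt = 0.01, volume = 50,
                                    temperature = 300, t_max = 2), "3 pressure")
  expect_error(green_kubo_viscosity(wn, times = c(0, 1, 2.5, 3:(nrow(wn) - 1)),
                                    volume = 50, temperature = 300, t_max = 2),
               "non-uniform")
  expect_error(green_kubo_viscosity(wn, dt = 0.01, volume = 50,
                                    temperature = 300, t_max = 1e9), "span")
})

test_that("OU pressure fixtures integrate to the analytic viscosity", {
  p <- make_ou_pressure_series(sigma = 100, tau_c = 0.5, dt = 0.01, n = 2e5,
                               seed = 5)
  eta <- green_kubo_viscosity(p, dt = 0.01, volume = 45.7, temperature = 300,
                              t_max = 5)
  analytic <- 45.7 * 100^2 * 0.5 / (1.380649e-23 * 300) * 1e-26
  expect_equal(eta, analytic, tolerance = 0.15)
})

test_that("Henderson-Hasselbalch fractions follow the closed form", {
  expect_identical(charged_fraction(6, 6), 0.5)
  expect_equal(charged_fraction(7, 6), 1 / 11)
  expect_equal(charged_fraction(-1e6, 6), 1)
  expect_equal(charged_fraction(1e6, 6), 0)
  # monotone decreasing in pH
  expect_true(all(diff(charged_fraction(seq(3, 9, 0.5), 6)) < 0))
})

test_that("buffer molecule counts split by the charged fraction", {
  expect_equal(buffer_molecule_count(0.020, 1661, 0.5),
               c(n_charged = 10L, n_neutral = 10L))
  expect_warning(z <- buffer_molecule_count(0, 100, 0.5), "small")
  expect_equal(z, c(n_charged = 0L, n_neutral = 0L))
  expect_equal(buffer_molecule_count(0.020, 1661, 1)[["n_neutral"]], 0L)
  expect_equal(sum(buffer_molecule_count(0.015, 2500, 0.37)),
               round(0.015 * 2500 * 0.602214076))
})
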