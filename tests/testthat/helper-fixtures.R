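# Fixture builders and independent oracles shared across the suite.

# A single-atom "protein" system with a given radius, for closed-form SASA.
single_atom_system <- function(radius = 0.19) {
  molecular_system(data.frame(
    index = 1L, name = "C", element = "C", residue_index = 1L,
    residue_name = "ALA", chain_id = "A", vdw_radius = radius,
    group = "protein", stringsAsFactors = FALSE))
}

# n-atom cluster with random coordinates in a small ball (seeded).
random_cluster <- function(n, radius = 0.19, spread = 0.35, seed = 1) {
  atoms <- data.frame(
    index = seq_len(n), name = "C", element = "C", residue_index = 1L,
    residue_name = "ALA", chain_id = "A", vdw_radius = radius,
    group = "protein", stringsAsFactors = FALSE)
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
  list(system = molecular_system(atoms), frame = frame(xyz))
}

# Independent Monte-Carlo SASA oracle: random points on each extended
# sphere, fraction not buried in any other extended sphere.
mc_sasa <- function(xyz, radii, probe, n_samples = 2e5, seed = 99) {
  set.seed(seed)
  ext <- radii + probe
  vapply(seq_len(nrow(xyz)), function(i) {
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * ext[i], 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_samples)
    for (j in setdiff(seq_len(nrow(xyz)), i)) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      buried <- buried | d2 < ext[j]^2
    }
    4 * pi * ext[i]^2 * mean(!buried)
  }, numeric(1))
}

# Brute-force minimum-image distance by explicit image enumeration (wide
# enough for displacements of a couple of box lengths).
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    img <- b + i * box[1, ] + j * box[2, ] + k * box[3, ]
    best <- min(best, sqrt(sum((img - a)^2)))
  }
  best
}

# Brute-force buffer-protein minimum distance per frame (all pairs, all
# images), independent of the package's vectorized path.
brute_min_dist_series <- function(traj, molecule_id) {
  sys <- traj$system
  b_idx <- sys$buffer_molecules$atom_indices[[
    match(molecule_id, sys$buffer_molecules$molecule_id)]]
  p_idx <- select_group(sys, "protein")
  vapply(traj$frames, function(f) {
    best <- Inf
    for (bi in b_idx) for (pi in p_idx) {
      d <- if (is.null(f$box)) sqrt(sum((f$coordinates[bi, ] - f$coordinates[pi, ])^2))
           else brute_min_image(f$coordinates[pi, ], f$coordinates[bi, ], f$box)
      best <- min(best, d)
    }
    best
  }, numeric(1))
}

# Naive double-loop SAP oracle: direct transcription of the per-atom sum,
# reusing shrake_rupley for the per-atom areas but with its own neighbor
# bookkeeping (plain loops, explicit distance tests).
naive_sap <- function(traj, radius = 0.5, scale = bm_scale(), reference,
                      n_points = 240L) {
  sys <- traj$system
  prot <- select_group(sys, "protein")
  sc <- which(side_chain_mask(sys))
  vals <- matrix(0, length(traj$frames), length(prot))
  for (fi in seq_along(traj$frames)) {
    f <- traj$frames[[fi]]
    sasa <- shrake_rupley(f, sys, sc, prot, n_points = n_points)
    for (jj in seq_along(prot)) {
      j <- prot[jj]
      total <- 0
      for (r in seq_len(nrow(sys$residues))) {
        ridx <- intersect(bsapkit:::residue_atom_indices(sys, r), sc)
        if (!length(ridx)) next
        saa_in <- 0; any_in <- FALSE
        for (k in ridx) {
          d <- min_image_distance(f$coordinates[j, ], f$coordinates[k, ], f$box)
          if (d <= radius) { any_in <- TRUE; saa_in <- saa_in + sasa$area[[as.character(k)]] }
        }
        if (any_in) {
          rn <- sys$residues$residue_name[r]
          total <- total + saa_in / reference$saa_exposed[[rn]] * scale$values[[rn]]
        }
      }
      vals[fi, jj] <- total
    }
  }
  out <- colMeans(vals)
  names(out) <- as.character(prot)
  out
}

# Survival curve built from an event-duration table: S(t) = P(tau_r > t),
# the event-start-origin estimator.
survival_from_events <- function(events, dt, max_lag) {
  lags <- seq(0, max_lag, by = dt)
  S <- vapply(lags, function(l) mean(events$tau_r > l), numeric(1))
  survival_curve(lags, S / S[1], n_origins = nrow(events))
}

# Small protein + single-atom buffer system used throughout kinetics tests.
kinetics_fixture <- function(n_neutral = 2, n_charged = 0) {
  toy <- make_toy_protein(c("ALA", "LEU", "GLY"), seed = 1)
  list(toy = toy,
       system = add_buffer_molecules(toy$system, n_neutral, n_charged))
}
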