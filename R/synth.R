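#' Run code with a private, seeded RNG stream
#'
#' Generators are pure functions of their seed: the caller's RNG state is
#' saved and restored, so fixture generation never perturbs a simulation
#' script's randomness.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a toy protein with idealized geometry
#'
#' Backbone (N, CA, C, O) plus a single CB pseudo-atom per side chain
#' (glycine gets none), with correct residue names so hydrophobicity and
#' exposure lookups work. Three geometries: `extended` (straight chain,
#' CA spacing 0.38 nm), `helix` (alpha-helical CA trace), `globule`
#' (seeded self-avoiding compact packing, radius ~ 0.25 N^(1/3) nm).
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param geometry `"extended"`, `"helix"` or `"globule"`.
#' @param seed integer seed (only the globule uses randomness, but the seed
#'   contract holds for all geometries).
#' @param chain_id chain identifier.
#' @return list with `system` and `frame`.
#' @examples
#' toy <- make_toy_protein(c("ALA", "GLY", "ALA"), seed = 1)
#' toy$system
#' @export
make_toy_protein <- function(sequence, geometry = c("extended", "helix", "globule"),
                             seed = 1L, chain_id = "A") {
  geometry <- match.arg(geometry)
  sequence <- toupper(sequence)
  if (!length(sequence)) stop("sequence must be nonempty")
  unknown <- setdiff(sequence, template_residues())
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  n <- length(sequence)
  ca <- with_seed(seed, {
    switch(geometry,
      extended = cbind(0.38 * (seq_len(n) - 1L), 0, 0),
      helix = {
        t <- (seq_len(n) - 1L) * 100 * pi / 180
        cbind(0.23 * cos(t), 0.23 * sin(t), 0.15 * (seq_len(n) - 1L))
      },
      globule = {
        R <- 0.25 * n^(1 / 3) + 0.2
        pos <- matrix(NA_real_, n, 3L)
        pos[1, ] <- c(0, 0, 0)
        for (i in seq_len(n)[-1]) {
          for (try in 1:500) {
            dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
            cand <- pos[i - 1L, ] + 0.38 * dir
            if (sqrt(sum(cand^2)) > R) next
            d2 <- rowSums(sweep(pos[seq_len(i - 1L), , drop = FALSE], 2L, cand)^2)
            if (all(d2 > 0.33^2)) break
            cand <- NULL
          }
          if (is.null(cand)) cand <- pos[i - 1L, ] + c(0.38, 0, 0)
          pos[i, ] <- cand
        }
        pos
      })
  })
  rows <- list(); coords <- list(); idx <- 0L
  centroid <- colMeans(ca)
  for (t in seq_len(n)) {
    res <- sequence[t]
    has_cb <- res != "GLY"
    out_dir <- ca[t, ] - centroid
    nrm <- sqrt(sum(out_dir^2))
    out_dir <- if (nrm > 1e-9) out_dir / nrm else c(0, 1, 0)
    perp <- if (geometry == "extended") c(0, (-1)^(t - 1L), 0) else out_dir
    nm <- c("N", "CA", "C", "O", if (has_cb) "CB")
    xyz <- rbind(ca[t, ] + c(-0.145, 0.045, 0),
                 ca[t, ],
                 ca[t, ] + c(0.15, 0.05, 0),
                 ca[t, ] + c(0.175, 0.17, 0.05),
                 if (has_cb) ca[t, ] + 0.153 * perp)
    el <- substr(nm, 1L, 1L)
    rows[[t]] <- data.frame(
      index = idx + seq_along(nm), name = nm, element = el,
      residue_index = t, residue_name = res, chain_id = chain_id,
      vdw_radius = vdw_radius(el), group = "protein", stringsAsFactors = FALSE)
    coords[[t]] <- xyz
    idx <- idx + length(nm)
  }
  atoms <- do.call(rbind, rows)
  list(system = molecular_system(atoms),
       frame = frame(do.call(rbind, coords), box = NULL, time = 0))
}

#' Append single-atom buffer molecules to a system
#'
#' Utility for fixtures: adds `n_neutral` + `n_charged` one-atom buffer
#' "molecules" (residue names HSD/HSP) whose positions are controlled by
#' the trajectory generator.
#' @param system a protein [molecular_system()].
#' @param n_neutral,n_charged molecule counts per charge state.
#' @return a new [molecular_system()] with buffer molecules appended.
#' @export
add_buffer_molecules <- function(system, n_neutral = 1L, n_charged = 0L) {
  a <- system$atoms
  n0 <- nrow(a)
  total <- n_neutral + n_charged
  if (total == 0L) return(system)
  state <- c(rep(0L, n_neutral), rep(1L, n_charged))
  buf <- data.frame(
    index = n0 + seq_len(total), name = "C1", element = "C",
    residue_index = max(a$residue_index) + seq_len(total),
    # CHARMM-style names: HSD = neutral, HSP = protonated histidine
    residue_name = ifelse(state == 1L, "HSP", "HSD"),
    chain_id = "B", vdw_radius = vdw_radius("C"),
    group = ifelse(state == 1L, "buffer_charged", "buffer_neutral"),
    stringsAsFactors = FALSE)
  molecular_system(rbind(a, buf),
                   data.frame(molecule_id = seq_len(total), charge_state = state,
                              atom_indices = I(as.list(n0 + seq_len(total)))))
}

dwell_sampler <- function(distribution, mean, mu) {
  switch(distribution,
    exponential = function(k) stats::rexp(k, rate = 1 / mean),
    stretched = {
      lambda <- mean / gamma(1 + 1 / mu)   # Weibull scale for the given mean
      function(k) stats::rweibull(k, shape = mu, scale = lambda)
    },
    stop("unknown dwell distribution '", distribution, "'"))
}

#' Generate an adsorption/desorption trajectory with known kinetics
#'
#' Each buffer molecule alternates between a bound state (minimum distance
#' to the protein drawn uniformly in `bound_range`) and an unbound state
#' (`unbound_range`), with dwell times drawn from the named distributions.
#' The placement geometry guarantees the drawn distance *is* the minimum
#' protein distance, so the returned ground-truth event list is an exact
#' oracle for downstream residence-event detection.
#'
#' @param system a [molecular_system()] containing buffer molecules (see
#'   [add_buffer_molecules()]).
#' @param protein_frame a [frame()] giving the (static) protein coordinates.
#' @param n_frames number of frames.
#' @param timestep frame spacing, ps.
#' @param bound_mean mean bound dwell time, ps.
#' @param unbound_mean mean unbound dwell time, ps (`Inf` disables
#'   adsorption, i.e. k_on = 0).
#' @param dwell_distribution `"exponential"` or `"stretched"` (Weibull) for
#'   the bound state; unbound dwells are always exponential.
#' @param mu stretching exponent for `"stretched"` bound dwells.
#' @param initial_state `"unbound"` or `"bound"`.
#' @param align_grid round dwell times to positive multiples of `timestep`
#'   so state changes fall on frame boundaries (exact oracle agreement).
#' @param bound_range,unbound_range distance ranges (nm) sampled for the
#'   two states; defaults keep bound strictly inside and unbound strictly
#'   outside the conventional 0.4 nm contact cutoff.
#' @param box_length cubic box edge, nm.
#' @param seed integer seed.
#' @return list with `trajectory` and `events` (data frame
#'   `molecule_id`, `start_frame`, `end_frame` (0-based), `tau_r` in ps).
#' @export
make_adsorption_trajectory <- function(system, protein_frame, n_frames = 100L,
                                       timestep = 10, bound_mean = 100,
                                       unbound_mean = 100,
                                       dwell_distribution = c("exponential", "stretched"),
                                       mu = 0.5,
                                       initial_state = c("unbound", "bound"),
                                       align_grid = TRUE,
                                       bound_range = c(0.25, 0.395),
                                       unbound_range = c(0.6, 2.0),
                                       box_length = NULL, seed = 1L) {
  dwell_distribution <- match.arg(dwell_distribution)
  initial_state <- match.arg(initial_state)
  if (is.null(system$buffer_molecules) || !nrow(system$buffer_molecules))
    stop("system has no buffer molecules")
  prot_idx <- select_group(system, "protein")
  prot_xyz <- protein_frame$coordinates[prot_idx, , drop = FALSE]
  centroid <- colMeans(prot_xyz)
  n_mol <- nrow(system$buffer_molecules)
  dirs <- fibonacci_sphere(max(n_mol, 2L))[seq_len(n_mol), , drop = FALSE]
  # anchor: protein atom with maximal projection along each direction
  anchors <- apply(dirs, 1L, function(u) prot_idx[which.max(prot_xyz %*% u)])

  span <- max(sqrt(rowSums(sweep(prot_xyz, 2L, centroid)^2)))
  L <- if (is.null(box_length)) 2 * (span + max(unbound_range)) + 2 else box_length
  box <- diag(3) * L

  total_t <- n_frames * timestep
  draw_bound <- dwell_sampler(dwell_distribution, bound_mean, mu)

  res <- with_seed(seed, {
    bound_mat <- matrix(FALSE, n_frames, n_mol)
    dist_mat <- matrix(NA_real_, n_frames, n_mol)
    for (m in seq_len(n_mol)) {
      t_cur <- 0; state <- initial_state == "bound"
      states <- logical(0); changes <- numeric(0)
      while (t_cur < total_t) {
        dwell <- if (state) draw_bound(1L)
                 else if (is.finite(unbound_mean)) stats::rexp(1L, 1 / unbound_mean)
                 else Inf
        if (align_grid && is.finite(dwell))
          dwell <- max(timestep, round(dwell / timestep) * timestep)
        states <- c(states, state); changes <- c(changes, t_cur + dwell)
        t_cur <- t_cur + dwell
        state <- !state
      }
      ft <- (seq_len(n_frames) - 1L) * timestep
      interval <- findInterval(ft, c(0, changes), left.open = TRUE,
                               rightmost.closed = FALSE)
      interval[ft == 0] <- 1L
      bound_mat[, m] <- states[pmin(interval, length(states))]
      dist_mat[, m] <- ifelse(bound_mat[, m],
                              stats::runif(n_frames, bound_range[1], bound_range[2]),
                              stats::runif(n_frames, unbound_range[1], unbound_range[2]))
    }
    list(bound = bound_mat, dist = dist_mat)
  })

  n_atoms <- nrow(system$atoms)
  frames <- vector("list", n_frames)
  shift <- L / 2 - centroid   # centre the protein in the box
  for (f in seq_len(n_frames)) {
    xyz <- matrix(NA_real_, n_atoms, 3L)
    xyz[prot_idx, ] <- prot_xyz
    for (m in seq_len(n_mol)) {
      u <- dirs[m, ]
      base <- protein_frame$coordinates[anchors[m], ] + res$dist[f, m] * u
      aidx <- system$buffer_molecules$atom_indices[[m]]
      # extra atoms of a molecule stack farther out along u
      for (j in seq_along(aidx)) xyz[aidx[j], ] <- base + (j - 1L) * 0.15 * u
    }
    other <- setdiff(seq_len(n_atoms), c(prot_idx, unlist(system$buffer_molecules$atom_indices)))
    if (length(other)) xyz[other, ] <- 0
    xyz <- sweep(xyz, 2L, shift, "+")
    frames[[f]] <- frame(xyz, box = box, time = (f - 1L) * timestep)
  }

  ev <- list(); k <- 0L
  for (m in seq_len(n_mol)) {
    r <- rle(res$bound[, m])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      k <- k + 1L
      ev[[k]] <- data.frame(molecule_id = m, start_frame = starts[i] - 1L,
                            end_frame = ends[i] - 1L,
                            tau_r = r$lengths[i] * timestep)
    }
  }
  events <- if (k) do.call(rbind, ev)
            else data.frame(molecule_id = integer(), start_frame = integer(),
                            end_frame = integer(), tau_r = numeric())
  list(trajectory = trajectory(system, frames), events = events)
}

#' Forward-generate a survival curve from the double stretched exponential
#'
#' Evaluates S(t) = A exp(-(k1 t)^mu1) + (1 - A) exp(-(k2 t)^mu2) on a time
#' grid, optionally adds Gaussian noise (S(0) stays exactly 1), and clips
#' to \[0, 1\].
#'
#' @param amplitude A in \[0, 1\].
#' @param k1,k2 rates in inverse time units of `t_grid`.
#' @param mu1,mu2 stretching exponents in (0, 1.5].
#' @param t_grid lag times (first entry must be 0).
#' @param noise_sd Gaussian noise standard deviation (0 = none).
#' @param seed integer seed for the noise.
#' @return a `survival_curve` object.
#' @export
make_survival_curve <- function(amplitude, k1, mu1, k2, mu2, t_grid,
                                noise_sd = 0, seed = 1L) {
  stopifnot(amplitude >= 0, amplitude <= 1, k1 > 0, k2 > 0,
            mu1 > 0, mu1 <= 1.5, mu2 > 0, mu2 <= 1.5)
  if (t_grid[1] != 0) stop("t_grid must start at 0")
  S <- amplitude * exp(-(k1 * t_grid)^mu1) + (1 - amplitude) * exp(-(k2 * t_grid)^mu2)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(S), 0, noise_sd))
    noise[1] <- 0
    S <- pmin(1, pmax(0, S + noise))
  }
  survival_curve(t_grid, S, n_origins = NA_integer_, strict = noise_sd == 0)
}

#' Exact-discretization Ornstein-Uhlenbeck pressure-like series
#'
#' Generates independent stationary OU components with variance `sigma^2`
#' and correlation time `tau_c`, using the exact one-step update
#' x' = x e^(-dt/tau) + sigma sqrt(1 - e^(-2 dt/tau)) xi.
#'
#' @param sigma stationary standard deviation (bar).
#' @param tau_c correlation time (ps).
#' @param dt sample spacing (ps).
#' @param n samples per component.
#' @param n_components number of independent components (default 3,
#'   mimicking the off-diagonal pressure-tensor components).
#' @param seed integer seed.
#' @return numeric matrix `n x n_components`.
#' @export
make_ou_pressure_series <- function(sigma, tau_c, dt, n, n_components = 3L, seed = 1L) {
  stopifnot(sigma > 0, tau_c > 0, dt > 0, n > 1)
  rho <- exp(-dt / tau_c)
  innov_sd <- sigma * sqrt(1 - rho^2)
  with_seed(seed, {
    out <- matrix(NA_real_, n, n_components)
    for (c_ in seq_len(n_components)) {
      x0 <- stats::rnorm(1L, 0, sigma)
      eps <- stats::rnorm(n - 1L, 0, innov_sd)
      out[, c_] <- c(x0, stats::filter(eps, rho, method = "recursive", init = x0))
    }
    out
  })
}
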