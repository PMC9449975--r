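#' Minimum buffer-protein distance time series
#'
#' For one buffer molecule, the per-frame minimum over all (buffer atom,
#' protein atom) pairs of the periodic-boundary-aware distance. This is the
#' d_min that defines adsorption: the molecule is adsorbed while
#' d_min <= r_cut.
#'
#' @param traj a [trajectory()] whose system declares buffer molecules.
#' @param molecule_id buffer molecule id (row of `system$buffer_molecules`).
#' @param pbc use minimum-image distances when the frame has a box
#'   (default `TRUE`).
#' @return object of class `min_distance_series`: list with `molecule_id`,
#'   `times` (ps), `d_min` (nm).
#' @export
min_distance_series <- function(traj, molecule_id, pbc = TRUE) {
  sys <- traj$system
  bm <- sys$buffer_molecules
  if (is.null(bm) || !molecule_id %in% bm$molecule_id)
    stop("no buffer molecule with id ", molecule_id)
  b_idx <- bm$atom_indices[[match(molecule_id, bm$molecule_id)]]
  p_idx <- select_group(sys, "protein")
  d <- vapply(traj$frames, function(f) {
    box <- if (pbc) f$box else NULL
    pbc_min_dist(f$coordinates[b_idx, , drop = FALSE],
                 f$coordinates[p_idx, , drop = FALSE], box)
  }, numeric(1))
  structure(list(molecule_id = molecule_id, times = trajectory_times(traj),
                 d_min = d),
            class = "min_distance_series")
}

#' @export
print.min_distance_series <- function(x, ...) {
  cat("<min_distance_series> molecule ", x$molecule_id, ", ",
      length(x$times), " frames, d_min in [",
      format(min(x$d_min), digits = 3), ", ", format(max(x$d_min), digits = 3),
      "] nm\n", sep = "")
  invisible(x)
}

#' Residence events from a minimum-distance series
#'
#' Maximal runs of consecutive frames with d_min <= r_cut. Departure and
#' return count as two separate events. Frames are 0-based; the duration
#' convention is tau_r = (frames in event) * timestep, with the timestep
#' taken from the series' time grid.
#'
#' @param series a [min_distance_series()].
#' @param r_cut contact cutoff in nm (default 0.4; d_min equal to r_cut
#'   counts as adsorbed).
#' @return data frame with `molecule_id`, `start_frame`, `end_frame`
#'   (0-based, inclusive) and `tau_r` (ps); zero rows when never adsorbed.
#' @export
residence_events <- function(series, r_cut = 0.4) {
  stopifnot(inherits(series, "min_distance_series"), r_cut > 0)
  inside <- series$d_min <= r_cut
  dt <- if (length(series$times) > 1L) diff(series$times)[1] else 1
  r <- rle(inside)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(molecule_id = rep(series$molecule_id, length(keep)),
             start_frame = starts[keep] - 1L,
             end_frame = ends[keep] - 1L,
             tau_r = r$lengths[keep] * dt)
}

#' Survival-curve container
#'
#' @param lag_times lag times (ps), starting at 0.
#' @param S survival probabilities in \[0, 1\] with S(0) = 1.
#' @param n_origins number of time origins averaged over (NA for synthetic
#'   curves).
#' @param strict enforce monotone nonincreasing S (synthetic noisy curves
#'   relax this).
#' @return object of class `survival_curve`.
#' @export
survival_curve <- function(lag_times, S, n_origins = NA_integer_, strict = TRUE) {
  if (length(lag_times) != length(S)) stop("lag_times and S lengths differ")
  if (abs(S[1] - 1) > 1e-12) stop("S(0) must be 1")
  if (any(S < -1e-12 | S > 1 + 1e-12)) stop("S must lie in [0, 1]")
  if (strict && any(diff(S) > 1e-12)) stop("S must be monotone nonincreasing")
  structure(list(lag_times = as.numeric(lag_times), S = as.numeric(S),
                 n_origins = n_origins),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> ", length(x$S), " lags up to ",
      x$lag_times[length(x$lag_times)], " ps",
      if (!is.na(x$n_origins)) paste0(", ", x$n_origins, " origin contacts"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., log = "") {
  graphics::plot(x$lag_times, x$S, type = "l", xlab = "lag time (ps)",
                 ylab = "S(t)", ylim = c(0, 1), log = log, ...)
  invisible(x)
}

#' Contact survival probability S(t)
#'
#' S(t) is the probability that a buffer-protein contact present at a time
#' origin is still *continuously* intact after lag t; a departure followed
#' by reattachment starts a new event and does not resurrect the old
#' contact. With `multi_origin`, every `origin_stride`-th frame that leaves
#' a full `max_lag` window serves as an origin; contacts are pooled over
#' origins and molecules, which keeps the per-lag denominator constant and
#' the estimate monotone.
#'
#' @param traj a [trajectory()] with buffer molecules.
#' @param charge_state 0, 1, or `"all"`.
#' @param r_cut contact cutoff, nm.
#' @param multi_origin average over multiple time origins (default `TRUE`).
#' @param origin_stride frames between origins.
#' @param max_lag_frames largest lag, in frames (default: half the
#'   trajectory with multiple origins, the whole of it with a single one).
#' @param pbc minimum-image distances (default `TRUE`).
#' @return a [survival_curve()].
#' @export
survival_probability <- function(traj, charge_state = "all", r_cut = 0.4,
                                 multi_origin = TRUE, origin_stride = 1L,
                                 max_lag_frames = NULL, pbc = TRUE) {
  sys <- traj$system
  bm <- sys$buffer_molecules
  if (is.null(bm)) stop("system has no buffer molecules")
  if (!identical(charge_state, "all"))
    bm <- bm[bm$charge_state == charge_state, , drop = FALSE]
  if (!nrow(bm)) stop("no buffer molecule with charge state ", charge_state)
  n_frames <- length(traj$frames)
  h <- vapply(bm$molecule_id, function(id)
    min_distance_series(traj, id, pbc = pbc)$d_min <= r_cut,
    logical(n_frames))
  h <- matrix(h, nrow = n_frames)
  if (is.null(max_lag_frames))
    max_lag_frames <- if (multi_origin) floor((n_frames - 1L) / 2L) else n_frames - 1L
  max_lag_frames <- min(max_lag_frames, n_frames - 1L)
  origins <- if (multi_origin)
    seq(1L, n_frames - max_lag_frames, by = origin_stride) else 1L
  # run length of unbroken contact from each frame, per molecule
  survived <- numeric(max_lag_frames + 1L)
  n_contacts <- 0L
  for (t0 in origins) {
    live <- which(h[t0, ])
    if (!length(live)) next
    n_contacts <- n_contacts + length(live)
    for (lag in 0:max_lag_frames) {
      live <- live[h[t0 + lag, live]]
      if (!length(live)) break
      survived[lag + 1L] <- survived[lag + 1L] + length(live)
    }
  }
  if (n_contacts == 0L) stop("no contacts to track at any time origin")
  dt <- if (n_frames > 1L) diff(trajectory_times(traj))[1] else 1
  survival_curve((0:max_lag_frames) * dt, survived / n_contacts,
                 n_origins = n_contacts)
}

#' Frame-averaged buffer contact counts per protein residue
#'
#' For each protein residue, the number of intermolecular (residue atom,
#' buffer atom) pairs within the cutoff, summed over all buffer molecules
#' of the requested charge state and averaged over frames.
#'
#' @param traj a [trajectory()] with buffer molecules.
#' @param charge_state 0, 1, or `"all"`.
#' @param cutoff pair-distance cutoff, nm (default 0.4).
#' @param pbc minimum-image distances (default `TRUE`).
#' @return named numeric vector over residue rows of `system$residues`.
#' @export
contact_counts <- function(traj, charge_state = "all", cutoff = 0.4, pbc = TRUE) {
  stopifnot(cutoff > 0)
  sys <- traj$system
  bm <- sys$buffer_molecules
  if (is.null(bm)) stop("system has no buffer molecules")
  if (!identical(charge_state, "all"))
    bm <- bm[bm$charge_state == charge_state, , drop = FALSE]
  if (!nrow(bm)) stop("no buffer molecule with charge state ", charge_state)
  b_idx <- unlist(bm$atom_indices)
  p_idx <- select_group(sys, "protein")
  res_of_atom <- integer(nrow(sys$atoms))
  for (r in seq_len(nrow(sys$residues)))
    res_of_atom[residue_atom_indices(sys, r)] <- r
  counts <- numeric(nrow(sys$residues))
  for (f in traj$frames) {
    box <- if (pbc) f$box else NULL
    dmat <- pbc_dist_matrix(f$coordinates[p_idx, , drop = FALSE],
                            f$coordinates[b_idx, , drop = FALSE], box)
    hits <- which(dmat <= cutoff, arr.ind = TRUE)
    if (nrow(hits)) {
      tab <- table(res_of_atom[p_idx[hits[, 1]]])
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] + as.integer(tab)
    }
  }
  out <- counts / length(traj$frames)
  names(out) <- as.character(seq_len(nrow(sys$residues)))
  out
}

#' Buffer Adsorption Index (BAI)
#'
#' BAI_i = -ln(N_avg_i / N_max) in units of k_B T: the relative free energy
#' of forming buffer contacts at residue i. N_max is the single largest
#' mean contact count across *all* supplied charge states, so neutral and
#' charged buffer share one energy reference; the residue attaining N_max
#' has BAI exactly 0. Residues with zero contacts get an infinite BAI and
#' are reported separately.
#'
#' @param counts_by_state named list of per-residue mean contact count
#'   vectors (as from [contact_counts()]), one entry per charge state,
#'   e.g. `list("0" = n0, "1" = n1)`.
#' @return named list of `bai_result` objects (fields `per_residue_n_avg`,
#'   `n_max`, `per_residue_bai`, `zero_contact_residues`, `charge_state`).
#' @examples
#' b <- bai(list("0" = c("1" = 10, "2" = 5, "3" = 1)))
#' b[["0"]]$per_residue_bai
#' @export
bai <- function(counts_by_state) {
  if (!length(counts_by_state)) stop("counts_by_state is empty")
  n_max <- max(unlist(counts_by_state))
  if (n_max <= 0) stop("all contact counts are zero")
  out <- lapply(names(counts_by_state), function(st) {
    n <- counts_by_state[[st]]
    b <- ifelse(n > 0, -log(n / n_max), Inf)
    names(b) <- names(n)
    structure(list(per_residue_n_avg = n, n_max = n_max, per_residue_bai = b,
                   zero_contact_residues = names(n)[n == 0],
                   charge_state = st),
              class = "bai_result")
  })
  names(out) <- names(counts_by_state)
  out
}

#' @export
print.bai_result <- function(x, ...) {
  finite <- is.finite(x$per_residue_bai)
  cat("<bai_result> charge state ", x$charge_state, ": ", sum(finite),
      " residues with contacts (mean BAI ",
      format(mean(x$per_residue_bai[finite]), digits = 3), " kT), ",
      length(x$zero_contact_residues), " without\n", sep = "")
  invisible(x)
}

#' Mean residence time from an event table
#' @param events data frame from [residence_events()] (possibly row-bound
#'   over molecules).
#' @return mean tau_r in ps, NA when there are no events.
#' @export
mean_residence_time <- function(events) {
  if (!nrow(events)) return(NA_real_)
  mean(events$tau_r)
}
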