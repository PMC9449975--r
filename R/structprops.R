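#' Radius of gyration of an atom selection
#'
#' sqrt(sum m_i |r_i - r_cm|^2 / sum m_i). Masses come from the system's
#' element table when a system is supplied; otherwise atoms are weighted
#' equally (or by `masses`).
#'
#' @param frm a [frame()].
#' @param selection integer atom indices.
#' @param system optional [molecular_system()] for element masses.
#' @param masses optional explicit masses (overrides `system`).
#' @param mass_weighted use masses (default `TRUE`); `FALSE` forces equal
#'   weights.
#' @return R_g in nm.
#' @export
radius_of_gyration <- function(frm, selection, system = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  if (!length(selection)) stop("selection is empty")
  xyz <- frm$coordinates[selection, , drop = FALSE]
  m <- if (!mass_weighted) rep(1, length(selection))
       else if (!is.null(masses)) masses
       else if (!is.null(system)) atomic_mass(system$atoms$element[selection])
       else rep(1, length(selection))
  cm <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2L, cm)^2)) / sum(m))
}

#' Define a four-point domain angle
#'
#' Each point is the (mass-weighted) center of a nonempty atom set; the
#' angle is between vectors A->B and C->D. Used for hinge angles such as
#' the Fab-Fc angle anchored on disulfide-bond cystine pairs.
#'
#' @param A,B,C,D integer atom index sets; must be nonempty and disjoint.
#' @return object of class `angle_definition`.
#' @export
angle_definition <- function(A, B, C, D) {
  sets <- list(A = A, B = B, C = C, D = D)
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("all four anchor sets must be nonempty")
  if (anyDuplicated(unlist(sets)))
    stop("anchor sets must be disjoint")
  structure(sets, class = "angle_definition")
}

#' Inter-domain angle from a four-point definition
#'
#' @param frm a [frame()].
#' @param definition an [angle_definition()].
#' @param system optional [molecular_system()] for mass-weighted centers.
#' @return angle in radians, in \[0, pi\].
#' @export
fab_fc_angle <- function(frm, definition, system = NULL) {
  stopifnot(inherits(definition, "angle_definition"))
  com <- function(idx) {
    xyz <- frm$coordinates[idx, , drop = FALSE]
    m <- if (is.null(system)) rep(1, length(idx))
         else atomic_mass(system$atoms$element[idx])
    colSums(xyz * m) / sum(m)
  }
  v1 <- com(definition$B) - com(definition$A)
  v2 <- com(definition$D) - com(definition$C)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length anchor vector")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2))))
}

#' Surface-referenced radial distribution
#'
#' For each target atom and frame, the minimum distance to any reference
#' (surface) atom is binned; bin counts are averaged over frames and
#' divided by the bin width. This is the count-per-width convention used
#' for buffer distributions around a protein surface, not a
#' volume-normalized g(r): the curve's integral equals the mean number of
#' target atoms within `r_max`.
#'
#' @param traj a [trajectory()].
#' @param reference_group,target_group disjoint integer atom index sets.
#' @param bin_width bin width, nm.
#' @param r_max histogram range, nm.
#' @param pbc minimum-image distances (default `TRUE`).
#' @return object of class `surface_rdf`: `bin_edges` (length n+1) and
#'   `counts_per_width` (length n, pairs/nm).
#' @export
surface_rdf <- function(traj, reference_group, target_group,
                        bin_width = 0.02, r_max = 3, pbc = TRUE) {
  if (!length(reference_group) || !length(target_group))
    stop("reference and target groups must be nonempty")
  if (length(intersect(reference_group, target_group)))
    stop("reference and target groups must be disjoint")
  stopifnot(bin_width > 0)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- numeric(length(edges) - 1L)
  for (f in traj$frames) {
    box <- if (pbc) f$box else NULL
    ref_xyz <- f$coordinates[reference_group, , drop = FALSE]
    for (tgt in target_group) {
      d <- sqrt(min(min_image_sq(sweep(ref_xyz, 2L, f$coordinates[tgt, ]), box)))
      if (d < edges[length(edges)]) {
        b <- findInterval(d, edges, rightmost.closed = FALSE)
        counts[b] <- counts[b] + 1
      }
    }
  }
  structure(list(bin_edges = edges,
                 counts_per_width = counts / length(traj$frames) / bin_width),
            class = "surface_rdf")
}

#' @export
print.surface_rdf <- function(x, ...) {
  cat("<surface_rdf> ", length(x$counts_per_width), " bins of ",
      diff(x$bin_edges)[1], " nm, integral ",
      format(sum(x$counts_per_width) * diff(x$bin_edges)[1], digits = 4),
      " atoms\n", sep = "")
  invisible(x)
}

#' @export
plot.surface_rdf <- function(x, ...) {
  mids <- utils::head(x$bin_edges, -1) + diff(x$bin_edges) / 2
  graphics::plot(mids, x$counts_per_width, type = "l",
                 xlab = "distance from surface (nm)", ylab = "pairs / nm", ...)
  invisible(x)
}

#' Green-Kubo shear viscosity from off-diagonal pressure components
#'
#' eta = (V / k_B T) * integral_0^t_max <P_ab(0) P_ab(t)> dt, with the
#' autocorrelation averaged over all supplied components and all time
#' origins, and trapezoidal integration. Units: pressure in bar, volume in
#' nm^3, time in ps; the result is in mPa s (1 bar^2 nm^3 ps = 1e-29
#' Pa^2 m^3 s, divided by k_B T in J).
#'
#' @param pressure_series numeric matrix (n_samples x n_components, >= 3
#'   components) of off-diagonal pressure-tensor samples, bar.
#' @param dt sample spacing, ps (alternatively give `times`).
#' @param volume box volume, nm^3.
#' @param temperature temperature, K.
#' @param t_max upper integration limit, ps; must not exceed the series
#'   span.
#' @param times optional explicit sample times (must be uniform).
#' @return viscosity in mPa s.
#' @export
green_kubo_viscosity <- function(pressure_series, dt = NULL, volume, temperature,
                                 t_max, times = NULL) {
  p <- as.matrix(pressure_series)
  if (ncol(p) < 3L) stop("need at least 3 pressure components")
  if (!is.null(times)) {
    if (length(times) != nrow(p)) stop("times length must match series")
    steps <- diff(times)
    if (max(abs(steps - steps[1])) > 1e-9 * max(abs(steps)))
      stop("non-uniform time grid")
    dt <- steps[1]
  }
  if (is.null(dt) || dt <= 0) stop("a positive dt (or uniform times) is required")
  n <- nrow(p)
  n_lag <- floor(t_max / dt)
  if (n_lag >= n) stop("t_max exceeds the series span")
  # raw (non-demeaned) autocorrelation over all time origins, via FFT
  acf_sum <- numeric(n_lag + 1L)
  pad <- stats::nextn(2L * n, 2L)
  for (c_ in seq_len(ncol(p))) {
    X <- stats::fft(c(p[, c_], numeric(pad - n)))
    s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / pad
    acf_sum <- acf_sum + s[1:(n_lag + 1L)] / (n - 0:n_lag)
  }
  corr <- acf_sum / ncol(p)   # bar^2
  integral <- sum((corr[-1] + corr[-length(corr)]) / 2) * dt   # bar^2 ps
  kB <- 1.380649e-23
  # bar^2 -> Pa^2 (1e10), nm^3 -> m^3 (1e-27), ps -> s (1e-12), Pa s -> mPa s (1e3)
  integral * volume / (kB * temperature) * 1e-26
}

#' Henderson-Hasselbalch charged fraction
#'
#' Fraction of an excipient population in the protonated (+1) state at a
#' given pH: f = 1 / (1 + 10^(pH - pKa)). At pH = pKa exactly half the
#' molecules are charged.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant of the titrating group (free
#'   histidine imidazolium: ~6).
#' @return fraction in (0, 1).
#' @examples
#' charged_fraction(6, 6)   # 0.5
#' @export
charged_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pH - pKa))
}

#' Buffer molecule counts for a simulation box
#'
#' n_total = round(c * V * N_A); the charged count is round(n_total * f)
#' and the remainder is neutral.
#'
#' @param concentration molar concentration, mol/L.
#' @param box_volume box volume, nm^3.
#' @param charged_fraction fraction of molecules in the +1 state.
#' @return named integer vector `c(n_charged, n_neutral)`.
#' @examples
#' buffer_molecule_count(0.020, 1661, 0.5)  # 10 charged, 10 neutral
#' @export
buffer_molecule_count <- function(concentration, box_volume, charged_fraction) {
  stopifnot(concentration >= 0, box_volume > 0,
            charged_fraction >= 0, charged_fraction <= 1)
  n_total <- round(concentration * box_volume * 6.02214076e23 * 1e-24)
  if (n_total == 0) warning("box too small for any buffer molecule", call. = FALSE)
  n_charged <- round(n_total * charged_fraction)
  c(n_charged = as.integer(n_charged), n_neutral = as.integer(n_total - n_charged))
}
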