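#' Read a trajectory (DCD or plain XYZ-with-box)
#'
#' Frames are taken in file order. Times come from the file where the
#' format carries them (the XYZ dialect does); otherwise they are
#' synthesized as `0, timestep, 2*timestep, ...`.
#'
#' The plain-text XYZ-with-box dialect is, per frame:
#' \preformatted{
#' <n_atoms>
#' t= <time_ps> box= <Lx> <Ly> <Lz>
#' <atom_name> <x> <y> <z>      (nm, one line per atom)
#' }
#' `box= 0 0 0` denotes a non-periodic frame. XTC is not supported; convert
#' to DCD or the XYZ dialect first.
#'
#' @param path file path.
#' @param system the [molecular_system()] the frames belong to.
#' @param format `"DCD"`, `"XYZ"`, or `"auto"` (from extension). `"XTC"`
#'   raises an informative error.
#' @param timestep frame spacing in ps used when the file has no times.
#' @param lenient if `TRUE`, a truncated final frame is dropped with a
#'   warning instead of raising an error.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, system, format = c("auto", "DCD", "XYZ", "XTC"),
                            timestep = 1, lenient = FALSE) {
  format <- match.arg(toupper(format[1]), c("AUTO", "DCD", "XYZ", "XTC"))
  if (format == "AUTO") {
    ext <- toupper(tools::file_ext(path))
    format <- if (ext %in% c("DCD", "XYZ", "XTC")) ext else "XYZ"
  }
  if (format == "XTC")
    stop("XTC is not supported (compressed binary format with no reader in ",
         "this toolkit); convert to DCD or the plain XYZ-with-box dialect")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "DCD") read_trajectory_dcd(path, system, timestep)
  else read_trajectory_xyz(path, system, timestep, lenient)
}

read_trajectory_xyz <- function(path, system, timestep, lenient) {
  lines <- readLines(path, warn = FALSE)
  n_sys <- nrow(system$atoms)
  frames <- list()
  pos <- 1L
  k <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("XYZ format error at line ", pos, ": expected atom count")
    if (n != n_sys)
      stop("atom-count mismatch: file frame has ", n, " atoms, system has ", n_sys)
    if (pos + 1L + n > length(lines)) {
      msg <- paste0("truncated frame at line ", pos, ": need ", n,
                    " atom lines, file ends early")
      if (lenient) { warning(msg, "; dropping partial frame", call. = FALSE); break }
      stop(msg, " (use lenient = TRUE to keep complete frames)")
    }
    header <- lines[pos + 1L]
    tm <- timestep * k
    m <- regmatches(header, regexec("t=\\s*([-0-9.eE+]+)", header))[[1]]
    if (length(m) == 2L) tm <- as.numeric(m[2])
    box <- NULL
    mb <- regmatches(header, regexec(
      "box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)", header))[[1]]
    if (length(mb) == 4L) {
      L <- as.numeric(mb[2:4])
      if (all(L > 0)) box <- diag(L)
    }
    al <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(al), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("XYZ format error in frame starting at line ", pos)
    k <- k + 1L
    frames[[k]] <- frame(xyz, box = box, time = tm)
    pos <- pos + 2L + n
  }
  trajectory(system, frames)
}

read_trajectory_dcd <- function(path, system, timestep) {
  xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
  n_file <- ncol(xyz) / 3L
  n_sys <- nrow(system$atoms)
  if (n_file != n_sys)
    stop("atom-count mismatch: DCD has ", n_file, " atoms, system has ", n_sys)
  cell <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)),
    error = function(e) NULL)
  frames <- vector("list", nrow(xyz))
  for (k in seq_len(nrow(xyz))) {
    coords <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10
    box <- NULL
    if (!is.null(cell) && is.matrix(cell) && ncol(cell) >= 3) {
      L <- as.numeric(cell[k, 1:3]) / 10
      if (all(is.finite(L)) && all(L > 0)) box <- diag(L)
    }
    frames[[k]] <- frame(coords, box = box, time = timestep * (k - 1L))
  }
  trajectory(system, frames)
}

#' Write a trajectory (DCD or plain XYZ-with-box)
#'
#' The DCD writer emits CHARMM-style binary with orthorhombic unit-cell
#' records (coordinates in Angstrom, the format's native unit); the XYZ
#' writer emits the plain-text dialect documented in [read_trajectory()].
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param format `"DCD"` or `"XYZ"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "DCD", "XYZ")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "DCD", "XYZ"))
  if (format == "AUTO") {
    ext <- toupper(tools::file_ext(path))
    format <- if (ext == "DCD") "DCD" else "XYZ"
  }
  if (format == "XYZ") write_trajectory_xyz(traj, path) else write_trajectory_dcd(traj, path)
  invisible(path)
}

write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- traj$system$atoms$name
  n <- length(nm)
  for (f in traj$frames) {
    L <- if (is.null(f$box)) c(0, 0, 0) else diag(f$box)
    writeLines(c(sprintf("%d", n),
                 sprintf("t= %.6f box= %.6f %.6f %.6f", f$time, L[1], L[2], L[3]),
                 sprintf("%-6s %12.6f %12.6f %12.6f", nm,
                         f$coordinates[, 1], f$coordinates[, 2], f$coordinates[, 3])),
               con)
  }
}

write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_frames <- length(traj$frames)
  n_atoms <- nrow(traj$system$atoms)
  has_cell <- !is.null(traj$frames[[1]]$box)
  rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n_frames
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L  # CHARMM version flag
  rec(function(rc) { writeChar("CORD", rc, nchars = 4, eos = NULL); writeBin(icntrl, rc, size = 4L) })
  title <- formatC("written by bsapkit", width = -80)
  rec(function(rc) { writeBin(1L, rc, size = 4L); writeChar(title, rc, nchars = 80, eos = NULL) })
  rec(function(rc) writeBin(n_atoms, rc, size = 4L))
  for (f in traj$frames) {
    xyz <- f$coordinates * 10
    if (has_cell) {
      L <- diag(f$box) * 10
      # CHARMM XTL order: a, cos(gamma), b, cos(beta), cos(alpha), c
      rec(function(rc) writeBin(c(L[1], 0, L[2], 0, 0, L[3]), rc, size = 8L))
    }
    for (k in 1:3) {
      col <- xyz[, k]
      rec(function(rc) writeBin(as.numeric(col), rc, size = 4L))
    }
  }
}
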