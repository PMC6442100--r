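#' Write a trajectory as extended XYZ
#'
#' One block per frame: bead count, then a comment line carrying the box
#' (`Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`), the column layout (`Properties=`) and
#' the frame time, then one `species x y z [vx vy vz]` row per bead.
#' Positions written are the unwrapped coordinates; values round-trip
#' through [read_xyz()] to better than 1e-6.
#'
#' @param traj A `dpd_trajectory`.
#' @param path Output file.
#' @param velocities Include velocity columns if stored (default FALSE).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, velocities = FALSE) {
  stopifnot(inherits(traj, "dpd_trajectory"))
  velocities <- velocities && !is.null(traj$velocities)
  con <- file(path, "w")
  on.exit(close(con))
  props <- if (velocities) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
  lat <- sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g"',
                 traj$box[1], traj$box[2], traj$box[3])
  for (k in seq_along(traj$times)) {
    p <- traj$positions[[k]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf('%s Properties=%s Time=%.10g', lat, props,
                       traj$times[k]), con)
    if (velocities) {
      v <- traj$velocities[[k]]
      writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                         traj$types, p[, 1], p[, 2], p[, 3],
                         v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%s %.10g %.10g %.10g",
                         traj$types, p[, 1], p[, 2], p[, 3]), con)
    }
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path File written by [write_xyz()] (or compatible).
#' @return A `dpd_trajectory` with `times`, `positions` (as stored in the
#'   file), `positions_wrapped` (wrapped into the box), `velocities` (if
#'   present), `types` and `box`. Engine-only fields (pressure, kinetic
#'   temperature) are absent.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  times <- numeric(0)
  frames <- list()
  vels <- list()
  types <- NULL
  box <- NULL
  has_vel <- FALSE
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected bead count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat)) {
      vals <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                                  "\\s+")[[1]])
      box <- vals[c(1, 5, 9)]
    }
    tm <- regmatches(comment, regexpr('Time=[-0-9.eE+]+', comment))
    times <- c(times, if (length(tm)) as.numeric(sub("Time=", "", tm)) else
      length(times))
    has_vel <- grepl("vel:R:3", comment, fixed = TRUE)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    typ <- vapply(rows, `[[`, "", 1L)
    num <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                    numeric(if (has_vel) 6L else 3L)))
    if (is.null(types)) types <- typ
    frames[[length(frames) + 1L]] <- num[, 1:3, drop = FALSE]
    if (has_vel) vels[[length(vels) + 1L]] <- num[, 4:6, drop = FALSE]
    i <- i + 2L + n
  }
  if (is.null(box)) stop("no Lattice entry found")
  wrapped <- lapply(frames, function(p)
    sweep(p, 2, box, function(x, L) x - L * floor(x / L)))
  traj <- structure(list(times = times, positions = frames,
                         positions_wrapped = wrapped,
                         velocities = if (has_vel) vels else NULL,
                         types = types, box = box,
                         kinetic_T = NULL, pressure = NULL, momentum = NULL,
                         params = NULL),
                    class = "dpd_trajectory")
  attr(traj, "unwrapped") <- TRUE   # files store unwrapped coordinates
  traj
}
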