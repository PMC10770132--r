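#' Dummy-particle state
#'
#' Snapshot of the dummy-particle scaffold used for force sensing. In
#' `restrained` mode each particle is tethered to a reference position by a
#' harmonic restraint of strength `k_pr` and the sensed force is the
#' restraint reaction; in `frozen` mode the particles are immobile and the
#' per-particle forces recorded by the dynamics are used directly.
#'
#' @param positions n x 3 matrix of current positions (Angstrom).
#' @param reference n x 3 matrix of restraint reference positions
#'   (Angstrom); required in restrained mode.
#' @param k_pr positional restraint constant (kJ mol^-1 nm^-2).
#' @param mode `"restrained"` or `"frozen"`.
#' @param forces n x 3 matrix of recorded forces (kJ mol^-1 nm^-1);
#'   required in frozen mode.
#' @return a `dummy_state`.
#' @export
dummy_state <- function(positions, reference = NULL, k_pr = 1000,
                        mode = c("restrained", "frozen"), forces = NULL) {
  mode <- match.arg(mode)
  positions <- as_xyz(positions)
  if (mode == "restrained") {
    if (is.null(reference)) stop("restrained mode requires reference positions")
    reference <- as_xyz(reference)
    stopifnot(nrow(reference) == nrow(positions), k_pr > 0)
  } else {
    if (is.null(forces)) stop("frozen mode requires recorded forces")
    forces <- as_xyz(forces)
    stopifnot(nrow(forces) == nrow(positions))
  }
  structure(list(positions = positions, reference = reference, k_pr = k_pr,
                 mode = mode, forces = forces), class = "dummy_state")
}

#' Restraint-derived dummy forces
#'
#' The force each dummy particle exerts through its positional restraint,
#' `F_i^n = -k_pr (a_i^n - A_i^n)` per axis n in (x, y, z), with the
#' displacement converted to nm so the result is in kJ mol^-1 nm^-1. In
#' frozen mode the recorded forces are returned unchanged.
#'
#' @param state a [dummy_state()].
#' @return n x 3 matrix of forces (kJ mol^-1 nm^-1).
#' @examples
#' st <- dummy_state(matrix(c(0, 0, 0.2), 1), matrix(0, 1, 3), k_pr = 1000)
#' restraint_forces(st)  # (0, 0, -20)
#' @export
restraint_forces <- function(state) {
  stopifnot(inherits(state, "dummy_state"))
  if (state$mode == "frozen") return(state$forces)
  -state$k_pr * ang_to_nm(state$positions - state$reference)
}

#' Time-averaged dummy forces
#'
#' Averages per-particle force vectors over an analysis window and reports
#' the magnitude of the mean vector (not the mean of magnitudes), so that
#' thermal noise cancels and only sustained loads survive.
#'
#' @param forces 3-d array (frame x particle x axis) of per-frame forces
#'   (kJ mol^-1 nm^-1), or a list of [dummy_state()]s passed through
#'   [restraint_forces()].
#' @param times frame times (ns).
#' @param t_a,t_b averaging window; default the full span.
#' @return data frame per particle: `fx, fy, fz` (mean components) and
#'   `mag` (magnitude of the mean vector).
#' @export
mean_dummy_force <- function(forces, times, t_a = min(times),
                             t_b = max(times)) {
  if (is.list(forces) && !is.array(forces)) {
    mats <- lapply(forces, restraint_forces)
    forces <- array(unlist(mats), dim = c(nrow(mats[[1]]), 3, length(mats)))
    forces <- aperm(forces, c(3, 1, 2))
  }
  stopifnot(length(dim(forces)) == 3L, dim(forces)[1] == length(times))
  win <- window_index(times, t_a, t_b)
  if (!length(win)) stop("empty averaging window")
  m <- apply(forces[win, , , drop = FALSE], c(2, 3), mean)
  data.frame(fx = m[, 1], fy = m[, 2], fz = m[, 3],
             mag = sqrt(rowSums(m^2)))
}

#' Polar force map
#'
#' Bins per-particle mean forces on the `(rho, z)` plane and reports the
#' per-bin mean (default) or sum of the force magnitudes; the inner and
#' outer dummy shells should be mapped separately. Empty bins are `NA`.
#'
#' @param mean_forces result of [mean_dummy_force()].
#' @param positions n x 3 dummy positions (Angstrom) matching its rows.
#' @param geom an [imm_geometry()].
#' @param binsize bin edge (Angstrom).
#' @param stat `"mean"` or `"sum"` per bin.
#' @return list with `rho_edges`, `z_edges` and `map` (rho x z matrix).
#' @export
force_map <- function(mean_forces, positions, geom, binsize = 10,
                      stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  positions <- as_xyz(positions)
  stopifnot(nrow(positions) == nrow(mean_forces))
  rz <- polar_transform(positions)
  zmax <- geom$z_flat + geom$dummy_gap
  rmax <- sqrt(2) * geom$l_flat / 2
  rho_edges <- seq(0, rmax + binsize, by = binsize)
  z_edges <- seq(-zmax - binsize, zmax + binsize, by = binsize)
  nr <- length(rho_edges) - 1L; nz <- length(z_edges) - 1L
  ri <- findInterval(rz[, 1], rho_edges, rightmost.closed = TRUE)
  zi <- findInterval(rz[, 2], z_edges, rightmost.closed = TRUE)
  lin <- (zi - 1L) * nr + ri
  sums <- tapply(mean_forces$mag, lin, sum)
  cnts <- tapply(rep(1, length(lin)), lin, sum)
  map <- matrix(NA_real_, nr, nz)
  pos <- as.integer(names(sums))
  map[pos] <- if (stat == "mean") sums / cnts else sums
  list(rho_edges = rho_edges, z_edges = z_edges, map = map, stat = stat)
}
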