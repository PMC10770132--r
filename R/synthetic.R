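#' Curvature-coupled lipid sorting model
#'
#' Defines an equilibrium lattice model of curvature-driven lipid sorting on
#' the cristae leaflet surfaces. Lattice sites are a fixed quasi-uniform
#' sampling of both leaflets; each site carries its analytic mean and
#' Gaussian curvature. A lipid of species `s` on site `x` contributes the
#' Helfrich-like site energy
#' `E_s(x) = 1/2 kappa_s a_s (H(x) - H0_s)^2 - kbar_s a_s K(x)`
#' (in units of kT), so species with negative spontaneous curvature `H0`
#' are drawn to the inner cylinder and outer junction. Species labels
#' exchange between sites of the same leaflet by Kawasaki moves
#' ([mc_sort()]); the composition is conserved exactly.
#'
#' The default species table encodes the curvature-preference ordering of
#' the mitochondrial lipids the model emulates (monoanionic cardiolipin
#' most negative, then dianionic cardiolipin, DOPE, POPE, POPC neutral):
#' `H0 = 0, -0.10, -0.15, -0.25, -0.35 nm^-1`, bending modulus 12 kT,
#' molecular areas 0.64 nm^2 (1.20 nm^2 for the cardiolipin-like species).
#' These are generator conventions chosen to produce realistic, weak
#' (few-percent) sorting signals.
#'
#' @param geom an [imm_geometry()].
#' @param species data frame with columns `name`, `fraction`, `kappa` (kT),
#'   `H0` (nm^-1), `kbar` (kT), `area` (nm^2); see
#'   [default_sorting_species()].
#' @param kT thermal energy in the units of `kappa`/`kbar` (default 1).
#' @param spacing lattice spacing (Angstrom).
#' @param sweep_ns pseudo-time per Monte Carlo sweep (ns); the default 0.8
#'   ns makes 40 ns running windows and 80 ns blocks meaningful.
#' @return a `sorting_model`.
#' @export
sorting_model <- function(geom, species = default_sorting_species(),
                          kT = 1, spacing = 8, sweep_ns = 0.8) {
  stopifnot(inherits(geom, "imm_geometry"))
  req <- c("name", "fraction", "kappa", "H0", "kbar", "area")
  miss <- setdiff(req, names(species))
  if (length(miss)) stop("species table missing: ", paste(miss, collapse = ", "))
  if (abs(sum(species$fraction) - 1) > 1e-9)
    stop("species fractions must sum to 1")
  if (any(species$kappa < 0)) stop("bending moduli must be >= 0")
  if (anyDuplicated(species$name)) stop("species names must be unique")

  inner <- leaflet_surface(geom, "inner", spacing)
  outer <- leaflet_surface(geom, "outer", spacing)
  curv_i <- analytic_curvature(geom, "inner", inner)
  curv_o <- analytic_curvature(geom, "outer", outer)
  sites <- rbind(
    data.frame(x = inner$x, y = inner$y, z = inner$z, rho = inner$rho,
               leaflet = "inner", region = inner$region,
               H = curv_i$H, K = curv_i$K, stringsAsFactors = FALSE),
    data.frame(x = outer$x, y = outer$y, z = outer$z, rho = outer$rho,
               leaflet = "outer", region = outer$region,
               H = curv_o$H, K = curv_o$K, stringsAsFactors = FALSE))
  n_inner <- nrow(inner)

  energy <- t(vapply(seq_len(nrow(species)), function(s) {
    (0.5 * species$kappa[s] * species$area[s] * (sites$H - species$H0[s])^2 -
       species$kbar[s] * species$area[s] * sites$K) / kT
  }, numeric(nrow(sites))))     # species x sites
  rownames(energy) <- species$name

  structure(list(geom = geom, species = species, kT = kT, spacing = spacing,
                 sweep_ns = sweep_ns, sites = sites, n_inner = n_inner,
                 energy = energy),
            class = "sorting_model")
}

#' @rdname sorting_model
#' @export
default_sorting_species <- function() {
  data.frame(
    name = c("POPC", "POPE", "DOPE", "CDL2", "CDL1"),
    fraction = rep(0.2, 5),
    kappa = 12,
    H0 = c(0, -0.10, -0.15, -0.25, -0.35),
    kbar = 0,
    area = c(0.64, 0.64, 0.64, 1.20, 1.20),
    stringsAsFactors = FALSE)
}

#' @export
print.sorting_model <- function(x, ...) {
  cat(sprintf("sorting_model: %d sites (%d inner / %d outer), spacing %.1f A\n",
              nrow(x$sites), x$n_inner, nrow(x$sites) - x$n_inner, x$spacing))
  print(x$species)
  invisible(x)
}

# Uniformly mixed initial labels, stratified by (leaflet, region)
# compartment: within each compartment the species counts follow the bulk
# fractions exactly (largest-remainder rounding) and are then shuffled.
# This emulates a uniformly mixed build and makes the t = 0 baseline of the
# enrichment factor free of initialisation noise, so F measures sorting
# dynamics. Uses the current RNG state (mc_sort(seed=) controls it).
initial_labels <- function(model) {
  ns <- nrow(model$species)
  lab <- integer(nrow(model$sites))
  grp <- paste(model$sites$leaflet, model$sites$region)
  for (gname in sort(unique(grp))) {
    part <- which(grp == gname)
    n <- length(part)
    cnt <- floor(model$species$fraction * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(model$species$fraction * n - cnt, decreasing = TRUE)
      cnt[extra[seq_len(rem)]] <- cnt[extra[seq_len(rem)]] + 1L
    }
    lab[part] <- sample(rep.int(seq_len(ns), cnt))
  }
  lab
}

#' Run the exchange Monte Carlo sorting dynamics
#'
#' Kawasaki (composition-conserving) exchange Monte Carlo on a
#' [sorting_model()]: each sweep attempts one label swap per site between
#' two random sites of the same leaflet, accepted by the Metropolis rule.
#' The initial configuration is a uniformly mixed shuffle, so the first
#' recorded frame is the natural baseline for enrichment factors. Runs are
#' bit-reproducible under a fixed `seed`.
#'
#' @param model a [sorting_model()].
#' @param n_sweeps number of sweeps.
#' @param record_every record a frame every this many sweeps.
#' @param seed RNG seed (integer); `NULL` uses the current RNG state.
#' @return a `sorting_run`: list with `model`, `times` (pseudo-ns),
#'   `labels` (frames x sites species-index matrix) and `acceptance`.
#' @export
mc_sort <- function(model, n_sweeps = 1500, record_every = 10, seed = NULL) {
  stopifnot(inherits(model, "sorting_model"))
  if (nrow(model$species) < 2) stop("need at least two species to exchange")
  if (!is.null(seed)) set.seed(seed)
  lab0 <- initial_labels(model)
  res <- mc_sort_kernel(lab0 - 1L, model$energy, model$n_inner,
                        as.integer(n_sweeps), as.integer(record_every))
  if (res$acceptance == 0 && length(unique(lab0)) > 1L)
    warning("no exchange was accepted: energy scale is likely misconfigured")
  structure(list(model = model, labels = res$frames,
                 times = res$frame_sweep * model$sweep_ns,
                 acceptance = res$acceptance, seed = seed),
            class = "sorting_run")
}

#' @export
print.sorting_run <- function(x, ...) {
  cat(sprintf("sorting_run: %d frames, %d sites, %.3g pseudo-ns, acceptance %.1f%%\n",
              nrow(x$labels), ncol(x$labels), max(x$times),
              100 * x$acceptance))
  invisible(x)
}

#' Label-only null control
#'
#' Builds and runs the null-control twin of the sorting model: a single
#' physical species of which a fraction (default 20%) is relabelled `TEST`
#' with identical parameters. The dynamics are those of [mc_sort()] with
#' uniform energies, so any apparent enrichment of the tracer is pure
#' sampling noise — the convergence control for the enrichment pipeline.
#'
#' @param geom an [imm_geometry()].
#' @param host parameters of the physical species: single-row data frame
#'   like one row of [default_sorting_species()] (fraction ignored).
#' @param tracer_fraction fraction relabelled as `TEST`.
#' @param ... passed to [sorting_model()] (`spacing`, `sweep_ns`, `kT`).
#' @inheritParams mc_sort
#' @return a `sorting_run` with species `host` and `TEST`.
#' @export
null_system <- function(geom, host = default_sorting_species()[1, ],
                        tracer_fraction = 0.20, n_sweeps = 1500,
                        record_every = 10, seed = NULL, ...) {
  stopifnot(tracer_fraction > 0, tracer_fraction <= 1)
  sp <- rbind(host, host)
  sp$name <- c(host$name[1], "TEST")
  sp$fraction <- c(1 - tracer_fraction, tracer_fraction)
  model <- sorting_model(geom, species = sp, ...)
  mc_sort(model, n_sweeps = n_sweeps, record_every = record_every,
          seed = seed)
}

#' Convert a sorting run to a labelled trajectory
#'
#' Re-expresses the label dynamics as lipid motion: lipids of each species
#' are assigned to the sites carrying their label at each frame (one
#' single-bead headgroup marker per lipid), which conserves the species
#' multiset exactly and lets the frame I/O and partitioning machinery
#' consume generator output like any trajectory.
#'
#' @param run a `sorting_run`.
#' @param frames frame indices to keep (default all).
#' @return a `labeled_trajectory`.
#' @export
sorting_run_trajectory <- function(run, frames = seq_len(nrow(run$labels))) {
  sites <- run$model$sites
  species <- run$model$species$name
  counts <- tabulate(run$labels[1L, ], nbins = length(species))
  lipid_species <- rep(species, counts)
  topo <- data.frame(lipid_id = seq_along(lipid_species),
                     species = lipid_species, bead = "PO4", role = "marker",
                     charge = 0, stringsAsFactors = FALSE)
  class(topo) <- c("topology", "data.frame")
  box <- c(run$model$geom$l_flat, run$model$geom$l_flat,
           2 * (run$model$geom$z_flat + run$model$geom$dummy_gap))
  frs <- lapply(frames, function(i) {
    ord <- order(run$labels[i, ])     # sites grouped by species index
    coords <- matrix(NA_real_, length(lipid_species), 3L)
    coords[, 1] <- sites$x[ord]; coords[, 2] <- sites$y[ord]
    coords[, 3] <- sites$z[ord]
    new_frame(time = run$times[i], coords = coords, box = box)
  })
  traj <- new_trajectory(topo, frs)
  label_trajectory(traj, run$model$geom)
}

#' Dummy-wall force-sensor toy model
#'
#' Overdamped Langevin toy of the constant-force force-sensor validation: a
#' layer of pusher particles, each driven by a constant load `F_app` along
#' +z, presses through a harmonic contact spring onto a wall of dummy
#' particles that are either harmonically restrained (`restrained`) or held
#' fixed with their contact forces recorded (`frozen`). At stationarity the
#' mean force sensed by the wall equals the applied load per particle,
#' with lateral components fluctuating around zero — the identity the dummy
#' force sensors rely on. Positions are emitted in Angstrom, forces in
#' kJ mol^-1 nm^-1.
#'
#' @param F_app applied load per particle (kJ mol^-1 nm^-1).
#' @param k_pr wall restraint constant (kJ mol^-1 nm^-2).
#' @param k_contact contact spring constant (kJ mol^-1 nm^-2).
#' @param n_particles number of wall (and pusher) particles.
#' @param kT thermal energy (kJ mol^-1; default 2.58, i.e. 310 K).
#' @param mobility particle mobility (nm^2 per kJ mol^-1 per time unit).
#' @param dt integration step (time units).
#' @param n_equil equilibration steps discarded before recording.
#' @param n_steps recorded production steps.
#' @param record_every record every this many steps.
#' @param mode `"restrained"` or `"frozen"`.
#' @param seed RNG seed.
#' @return a `wall_toy_sim`: list with `times`, `positions` (frames x n x 3,
#'   Angstrom), `reference` (n x 3, Angstrom), `contact_forces` (frames x n
#'   x 3, on the wall, kJ mol^-1 nm^-1), and the parameters.
#' @export
wall_toy_sim <- function(F_app, k_pr = 1000, k_contact = 1000,
                         n_particles = 25, kT = 2.58, mobility = 1,
                         dt = 2e-4, n_equil = 5000, n_steps = 20000,
                         record_every = 10, mode = c("restrained", "frozen"),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(F_app >= 0, k_pr > 0, k_contact > 0)
  if (dt * mobility * (k_pr + k_contact) > 0.5)
    stop("integration step unstable: reduce dt (need dt*mobility*(k_pr+k_contact) <= 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n <- n_particles
  side <- ceiling(sqrt(n))
  W <- cbind(rep(seq_len(side), length.out = n),
             rep(seq_len(side), each = side)[seq_len(n)], 10)  # nm
  w <- W + cbind(0, 0, rep(F_app / k_pr, n))
  p <- w + cbind(0, 0, rep(-F_app / k_contact, n))
  # contact spring (z only): force on wall = k_contact * (p_z - w_z + r0),
  # r0 chosen so the unloaded contact is force-free at p_z = w_z - r0
  r0 <- 0

  sig <- sqrt(2 * kT * mobility * dt)
  nrec <- n_steps %/% record_every
  pos <- array(NA_real_, c(nrec, n, 3))
  cfor <- array(NA_real_, c(nrec, n, 3))
  fi <- 0L
  for (step in seq_len(n_equil + n_steps)) {
    fc <- k_contact * (p[, 3] - w[, 3] + r0)   # on wall, +z
    # pusher: load + contact reaction + noise (free laterally)
    p <- p + dt * mobility * cbind(0, 0, F_app - fc) +
      matrix(rnorm(3 * n, sd = sig), n, 3)
    if (mode == "restrained") {
      w <- w + dt * mobility * (cbind(0, 0, fc) - k_pr * (w - W)) +
        matrix(rnorm(3 * n, sd = sig), n, 3)
    }
    if (step > n_equil && (step - n_equil) %% record_every == 0L) {
      fi <- fi + 1L
      pos[fi, , ] <- w
      cfor[fi, , 3] <- fc
      cfor[fi, , 1:2] <- 0
    }
  }
  structure(list(
    times = seq_len(nrec) * record_every * dt,
    positions = pos * 10,                 # nm -> Angstrom
    reference = nm_to_ang(W),
    contact_forces = cfor,
    F_app = F_app, k_pr = k_pr, k_contact = k_contact, kT = kT,
    mode = mode, dt = dt, mobility = mobility, seed = seed),
    class = "wall_toy_sim")
}

#' Sensed wall force with conservative block errors
#'
#' Per-axis mean sensed force of a [wall_toy_sim()] run — restraint-derived
#' (`-k_pr (a - A)`) in restrained mode, directly recorded contact forces in
#' frozen mode — averaged over particles and the analysis window, with a
#' standard error from a block-size scan (the plateau/maximum of the block
#' standard error over doubling block lengths, the conservative
#' Flyvbjerg-Petersen choice).
#'
#' @param sim a `wall_toy_sim`.
#' @param t_a,t_b analysis window (time units); default the full record.
#' @return list with `mean` (length-3, kJ mol^-1 nm^-1), `se` (length-3),
#'   and `sensed` (the per-frame particle-mean force series).
#' @export
wall_force_summary <- function(sim, t_a = min(sim$times),
                               t_b = max(sim$times)) {
  stopifnot(inherits(sim, "wall_toy_sim"))
  nrec <- dim(sim$positions)[1]
  if (sim$mode == "restrained") {
    disp <- sweep(sim$positions, c(2, 3), sim$reference)  # Angstrom
    fser <- -sim$k_pr * ang_to_nm(disp)
  } else {
    fser <- sim$contact_forces
  }
  pm <- apply(fser, c(1, 3), mean)       # frames x 3, particle means
  win <- window_index(sim$times, t_a, t_b)
  m <- colMeans(pm[win, , drop = FALSE])
  tt <- sim$times[win]
  span <- tt[length(tt)] - tt[1]
  se <- vapply(1:3, function(ax) {
    bls <- span / 2^(6:2)               # 64 down to 4 blocks
    max(vapply(bls, function(bl) block_error(pm[win, ax], tt, block = bl),
               numeric(1)))
  }, numeric(1))
  list(mean = m, se = se, sensed = pm)
}
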