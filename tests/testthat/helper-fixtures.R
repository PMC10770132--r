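# Shared fixtures: a small cristae geometry that keeps sampling cheap, and
# constructors for synthetic flat-bilayer frames.

small_geom <- function() {
  imm_geometry(r_cyl = 40, r_junction = 40, l_cylinder = 80, l_flat = 200)
}

# flat bilayer frame: n lipids per leaflet on a grid, marker beads at
# z = +/- half_thickness, one 12-bead lipid per marker is overkill for most
# tests, so species get the minimal single-marker topology unless full = TRUE
flat_bilayer_frame <- function(n_side = 10, box = c(80, 80, 100),
                               half_thickness = 20, species = "POPC",
                               jitter = 0, full = FALSE) {
  n <- n_side^2
  gx <- seq(box[1] / (2 * n_side), box[1] - box[1] / (2 * n_side),
            length.out = n_side)
  gr <- expand.grid(x = gx, y = gx)
  if (full) {
    topo <- make_topology(rep(species, length.out = 2 * n))
    coords <- matrix(0, nrow(topo), 3)
    for (l in unique(topo$lipid_id)) {
      up <- l <= n
      base <- c(gr$x[(l - 1) %% n + 1], gr$y[(l - 1) %% n + 1],
                if (up) half_thickness else -half_thickness)
      rows <- which(topo$lipid_id == l)
      # stack beads along z towards the mid-plane (tails inward)
      dzs <- seq(0, by = if (up) -3 else 3, length.out = length(rows))
      coords[rows, ] <- cbind(base[1], base[2], base[3] + dzs)
    }
  } else {
    topo <- data.frame(lipid_id = seq_len(2 * n),
                       species = rep(species, length.out = 2 * n),
                       bead = "PO4", role = "marker", charge = 0,
                       stringsAsFactors = FALSE)
    class(topo) <- c("topology", "data.frame")
    coords <- rbind(cbind(gr$x, gr$y, half_thickness),
                    cbind(gr$x, gr$y, -half_thickness))
  }
  if (jitter > 0) coords <- coords + rnorm(length(coords), 0, jitter)
  list(topology = topo,
       frame = immsort:::new_frame(0, coords, box))
}

# single-marker trajectory on the cristae surface from explicit marker
# positions per frame
marker_trajectory <- function(coord_list, times, species, box = c(600, 600, 600)) {
  topo <- data.frame(lipid_id = seq_along(species), species = species,
                     bead = "PO4", role = "marker", charge = 0,
                     stringsAsFactors = FALSE)
  class(topo) <- c("topology", "data.frame")
  frames <- Map(function(xyz, tm) immsort:::new_frame(tm, xyz, box),
                coord_list, times)
  immsort:::new_trajectory(topo, frames)
}

# uniform-area sphere sampling
sphere_cloud <- function(n, R) {
  z <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi); r <- sqrt(1 - z^2)
  R * cbind(r * cos(ph), r * sin(ph), z)
}

cylinder_cloud <- function(n, R, L) {
  ph <- runif(n, 0, 2 * pi)
  cbind(R * cos(ph), R * sin(ph), runif(n, -L / 2, L / 2))
}

# binary POPC/minor sorting run on a given geometry, enrichment table out
binary_enrichment <- function(minor, geom, seed, frac = 0.2,
                              n_sweeps = 1500, record_every = 10) {
  sp <- default_sorting_species()
  sp <- sp[sp$name %in% c("POPC", minor), ]
  sp$fraction <- c(1 - frac, frac)
  run <- mc_sort(sorting_model(geom, sp), n_sweeps, record_every, seed = seed)
  enrichment_factor(lipid_fraction(count_by_compartment(run)))
}

get_F <- function(enr, leaflet, region, species) {
  enr$F[enr$leaflet == leaflet & enr$region == region &
          enr$species == species]
}
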