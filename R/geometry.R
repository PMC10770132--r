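#' Parametric cristae (IMM) geometry
#'
#' Defines the double-bilayer-cylinder mid-surface used to model a
#' mitochondrial inner-membrane crista: a cylindrical tube of mid-surface
#' radius `r_cyl` and axial length `l_cylinder`, joined at each end to a flat
#' square sheet of edge `l_flat` through a tangent-continuous quarter-torus
#' junction of tube radius `r_junction`. The tube axis is `z`, the cylinder
#' mid-plane sits at `z = 0`, and the flat sheets lie at
#' `z = +/-(l_cylinder/2 + r_junction)`. Leaflet surfaces are offset by
#' `bilayer_thickness/2` from the mid-surface along the local normal; the
#' inner leaflet faces the crista lumen (tube interior and the far side of
#' each sheet), the outer leaflet faces the matrix (the slab between the
#' sheets, outside the tube).
#'
#' `l_cylinder` is by default the cylinder-proper axial extent (junctions add
#' `r_junction` on each side). Set `l_cylinder_includes_junctions = TRUE` to
#' interpret it as the full tube span including both junction arcs.
#'
#' @param r_cyl cylinder mid-surface radius, Angstrom.
#' @param r_junction junction torus tube radius, Angstrom.
#' @param l_cylinder cylinder axial length, Angstrom.
#' @param l_flat lateral edge of the flat square sheets, Angstrom.
#' @param bilayer_thickness leaflet-offset basis `t`; leaflets sit at
#'   `+/- t/2` from the mid-surface. Angstrom.
#' @param dummy_grid_spacing lateral spacing of the dummy-particle lattice,
#'   Angstrom.
#' @param dummy_gap separation between the two dummy layers bracketing the
#'   bilayer, Angstrom.
#' @param dummy_c12,dummy_c6 Lennard-Jones parameters of the repulsive
#'   dummy-tail interaction (kJ nm^12 mol^-1 and kJ nm^6 mol^-1); metadata
#'   only, not used in any computation here.
#' @param l_cylinder_includes_junctions logical; see Details.
#' @return an object of class `imm_geometry`.
#' @examples
#' geom <- imm_geometry()
#' geom
#' region_areas(geom)
#' @export
imm_geometry <- function(r_cyl = 100, r_junction = 100, l_cylinder = 300,
                         l_flat = 560, bilayer_thickness = 40,
                         dummy_grid_spacing = 5, dummy_gap = 50,
                         dummy_c12 = 0.0258, dummy_c6 = 0,
                         l_cylinder_includes_junctions = FALSE) {
  vals <- c(r_cyl = r_cyl, r_junction = r_junction, l_cylinder = l_cylinder,
            l_flat = l_flat, bilayer_thickness = bilayer_thickness,
            dummy_grid_spacing = dummy_grid_spacing, dummy_gap = dummy_gap)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry lengths must be finite and > 0")
  if (isTRUE(l_cylinder_includes_junctions)) {
    l_cylinder <- l_cylinder - 2 * r_junction
    if (l_cylinder <= 0)
      stop("l_cylinder must exceed 2*r_junction when it includes the junctions")
  }
  d <- bilayer_thickness / 2
  if (d >= r_cyl)
    stop("bilayer_thickness/2 must be smaller than r_cyl (inner leaflet radius must be positive)")
  if (l_flat < 2 * (r_cyl + r_junction))
    stop("l_flat must be at least 2*(r_cyl + r_junction) so a flat annulus exists")
  g <- list(r_cyl = r_cyl, r_junction = r_junction, l_cylinder = l_cylinder,
            l_flat = l_flat, bilayer_thickness = bilayer_thickness,
            leaflet_offset = d,
            dummy_grid_spacing = dummy_grid_spacing, dummy_gap = dummy_gap,
            dummy_c12 = dummy_c12, dummy_c6 = dummy_c6,
            # derived
            rho0 = r_cyl + r_junction,      # junction torus centre-circle radius
            z_cyl = l_cylinder / 2,         # cylinder half-length
            z_flat = l_cylinder / 2 + r_junction)  # flat sheet height
  class(g) <- "imm_geometry"
  g
}

#' @export
print.imm_geometry <- function(x, ...) {
  cat("IMM cristae geometry (double-bilayer cylinder)\n")
  cat(sprintf("  r_cyl       %8.1f A   r_junction  %8.1f A\n", x$r_cyl, x$r_junction))
  cat(sprintf("  l_cylinder  %8.1f A   l_flat      %8.1f A\n", x$l_cylinder, x$l_flat))
  cat(sprintf("  thickness   %8.1f A   leaflet offset +/- %.1f A\n",
              x$bilayer_thickness, x$leaflet_offset))
  cat(sprintf("  dummy grid  %8.1f A   dummy gap   %8.1f A\n",
              x$dummy_grid_spacing, x$dummy_gap))
  cat(sprintf("  flat sheets at z = +/- %.1f A\n", x$z_flat))
  invisible(x)
}

region_levels <- c("flat", "junction", "cylinder")
leaflet_levels <- c("inner", "outer")

#' Cylindrical-polar projection of 3D coordinates
#'
#' Maps geometry-centred Cartesian coordinates to the two-dimensional polar
#' system `(rho, z)` with `rho = sqrt(x^2 + y^2)` used for all region maps.
#'
#' @param xyz numeric matrix (n x 3) or length-3 vector of coordinates.
#' @return matrix with columns `rho`, `z`.
#' @examples
#' polar_transform(c(3, 4, 7))  # rho = 5, z = 7
#' @export
polar_transform <- function(xyz) {
  xyz <- as_xyz(xyz)
  if (any(!is.finite(xyz)))
    stop("polar_transform: coordinates must be finite")
  cbind(rho = sqrt(xyz[, 1]^2 + xyz[, 2]^2), z = xyz[, 3])
}

as_xyz <- function(xyz) {
  if (is.null(dim(xyz))) {
    if (length(xyz) != 3L) stop("expected a length-3 coordinate or an n x 3 matrix")
    xyz <- matrix(xyz, nrow = 1L)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("coordinates must have 3 columns")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  xyz
}

# Region, signed distance to the mid-surface (positive towards the outer
# leaflet / matrix side) and torus angle theta for near-surface points given
# in (rho, z). Vectorised; the workhorse behind assign_region() and
# assign_leaflets().
surface_coords_rz <- function(rho, z, geom) {
  az <- abs(z)
  region <- character(length(rho))
  sdist <- numeric(length(rho))
  theta <- rep(NA_real_, length(rho))

  cyl <- az <= geom$z_cyl
  region[cyl] <- "cylinder"
  sdist[cyl] <- rho[cyl] - geom$r_cyl

  jun <- !cyl & rho <= geom$rho0
  region[jun] <- "junction"
  dc <- sqrt((rho[jun] - geom$rho0)^2 + (az[jun] - geom$z_cyl)^2)
  sdist[jun] <- geom$r_junction - dc
  theta[jun] <- atan2(az[jun] - geom$z_cyl, geom$rho0 - rho[jun])

  fl <- !cyl & !jun
  region[fl] <- "flat"
  sdist[fl] <- geom$z_flat - az[fl]

  list(region = region, sdist = sdist, theta = theta)
}

#' Assign cristae surface regions to polar coordinates
#'
#' Partitions near-surface points into the three curvature regions of the
#' crista model: `cylinder` (|z| within the cylinder span), `junction`
#' (beyond the cylinder span with `rho <= r_cyl + r_junction`) and `flat`
#' (otherwise). Boundaries are half-open with ties going to the more curved
#' region: the cylinder owns the cylinder-junction seam, the junction owns
#' the junction-flat seam. The two symmetric halves map to the same region.
#' Points farther than `tol` from the mid-surface shell are returned as
#' `"unassigned"`.
#'
#' @param rho_z matrix with columns `rho`, `z` (e.g. from
#'   [polar_transform()]), or a 3-column coordinate matrix which is projected
#'   first.
#' @param geom an [imm_geometry()].
#' @param tol shell tolerance, Angstrom; default the bilayer thickness.
#' @return character vector in `c("flat", "junction", "cylinder",
#'   "unassigned")`.
#' @export
assign_region <- function(rho_z, geom, tol = geom$bilayer_thickness) {
  stopifnot(inherits(geom, "imm_geometry"))
  rho_z <- as.matrix(rho_z)
  if (ncol(rho_z) == 3L) rho_z <- polar_transform(rho_z)
  if (ncol(rho_z) != 2L) stop("rho_z must have 2 (rho, z) or 3 (x, y, z) columns")
  sc <- surface_coords_rz(rho_z[, 1], rho_z[, 2], geom)
  out <- sc$region
  out[abs(sc$sdist) > tol] <- "unassigned"
  out
}

# Signed-offset surface sampling shared by leaflet_surface() and
# dummy_lattice(). offset > 0 is towards the outer/matrix side.
offset_surface <- function(geom, offset, spacing, shell_label) {
  if (spacing <= 0) stop("target_spacing must be > 0")
  r_cyl_s <- geom$r_cyl + offset
  r_tor_s <- geom$r_junction - offset
  if (spacing >= min(r_cyl_s, abs(r_tor_s)))
    stop("target_spacing larger than the smallest geometric feature")
  if (r_cyl_s <= 0 || r_tor_s <= 0)
    stop("offset too large: offset surface degenerates")

  pieces <- list()

  # cylinder wall
  nz <- max(1L, round(geom$l_cylinder / spacing))
  dz <- geom$l_cylinder / nz
  zc <- seq(-geom$z_cyl + dz / 2, geom$z_cyl - dz / 2, length.out = nz)
  nphi <- max(4L, round(2 * pi * r_cyl_s / spacing))
  phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-1L]
  gph <- expand.grid(phi = phi, z = zc)
  pieces$cyl <- data.frame(
    x = r_cyl_s * cos(gph$phi), y = r_cyl_s * sin(gph$phi), z = gph$z,
    nx = cos(gph$phi), ny = sin(gph$phi), nz = 0)

  # quarter-torus junctions, top (sgn_z = +1) and bottom (-1)
  ntheta <- max(2L, round((pi / 2) * r_tor_s / spacing))
  dth <- (pi / 2) / ntheta
  thetas <- seq(dth / 2, pi / 2 - dth / 2, length.out = ntheta)
  for (sgn_z in c(1, -1)) {
    rows <- lapply(thetas, function(th) {
      rho <- geom$rho0 - r_tor_s * cos(th)
      zz <- sgn_z * (geom$z_cyl + r_tor_s * sin(th))
      nph <- max(4L, round(2 * pi * rho / spacing))
      ph <- seq(0, 2 * pi, length.out = nph + 1L)[-1L]
      data.frame(x = rho * cos(ph), y = rho * sin(ph), z = zz,
                 nx = cos(th) * cos(ph), ny = cos(th) * sin(ph),
                 nz = -sgn_z * sin(th))
    })
    pieces[[paste0("jun", sgn_z)]] <- do.call(rbind, rows)
  }

  # flat sheets with a circular hole of radius rho0
  half <- geom$l_flat / 2
  ng <- max(2L, round(geom$l_flat / spacing))
  dg <- geom$l_flat / ng
  gx <- seq(-half + dg / 2, half - dg / 2, length.out = ng)
  gf <- expand.grid(x = gx, y = gx)
  keep <- sqrt(gf$x^2 + gf$y^2) > geom$rho0
  gf <- gf[keep, , drop = FALSE]
  for (sgn_z in c(1, -1)) {
    pieces[[paste0("flat", sgn_z)]] <- data.frame(
      x = gf$x, y = gf$y, z = sgn_z * (geom$z_flat - offset),
      nx = 0, ny = 0, nz = -sgn_z)
  }

  pts <- do.call(rbind, pieces)
  rownames(pts) <- NULL
  rho <- sqrt(pts$x^2 + pts$y^2)
  sc <- surface_coords_rz(rho, pts$z, geom)
  pts$rho <- rho
  pts$region <- sc$region
  pts$theta <- sc$theta
  pts$leaflet <- shell_label
  attr(pts, "geometry") <- geom
  attr(pts, "spacing") <- spacing
  attr(pts, "offset") <- offset
  class(pts) <- c("surface_points", "data.frame")
  pts
}

#' Quasi-uniform sampling of a leaflet surface
#'
#' Samples the chosen leaflet (mid-surface offset by +/- half the bilayer
#' thickness along the local normal) at approximately `target_spacing`.
#' Each point carries its `(rho, z)` projection, region label and the
#' unit leaflet-outward normal (pointing from the bilayer mid-plane towards
#' that leaflet's aqueous side).
#'
#' @param geom an [imm_geometry()].
#' @param leaflet `"inner"` or `"outer"`.
#' @param target_spacing target point spacing, Angstrom.
#' @return a `surface_points` data frame with columns `x, y, z, nx, ny, nz,
#'   rho, region, theta, leaflet`.
#' @export
leaflet_surface <- function(geom, leaflet = c("outer", "inner"),
                            target_spacing = 8) {
  stopifnot(inherits(geom, "imm_geometry"))
  leaflet <- match.arg(leaflet)
  s <- if (leaflet == "outer") 1 else -1
  pts <- offset_surface(geom, s * geom$leaflet_offset, target_spacing, leaflet)
  # flip normals for the inner leaflet: leaflet-outward = -outward(mid)
  if (leaflet == "inner") {
    pts$nx <- -pts$nx; pts$ny <- -pts$ny; pts$nz <- -pts$nz
  }
  pts
}

#' Analytic leaflet curvature oracle
#'
#' Closed-form mean and Gaussian curvature of the cristae leaflet surfaces,
#' signed with respect to the leaflet-outward normal: on this convention the
#' outer-leaflet cylinder has H > 0, the inner-leaflet cylinder H < 0, both
#' junction leaflets have K < 0, and the flat sheets have H = K = 0.
#'
#' @param geom an [imm_geometry()].
#' @param leaflet `"inner"` or `"outer"`.
#' @param points a `surface_points` data frame (from [leaflet_surface()]) or
#'   a matrix of 3D coordinates on the leaflet surface.
#' @return data frame with columns `H` (nm^-1), `K` (nm^-2), `C1`, `C2`
#'   (nm^-1) and `region`.
#' @export
analytic_curvature <- function(geom, leaflet = c("outer", "inner"), points) {
  stopifnot(inherits(geom, "imm_geometry"))
  leaflet <- match.arg(leaflet)
  s <- if (leaflet == "outer") 1 else -1
  d <- geom$leaflet_offset
  if (inherits(points, "surface_points")) {
    rho <- points$rho; z <- points$z
  } else {
    rz <- polar_transform(as_xyz(points))
    rho <- rz[, 1]; z <- rz[, 2]
  }
  sc <- surface_coords_rz(rho, z, geom)
  region <- sc$region
  c1 <- numeric(length(rho)); c2 <- numeric(length(rho))

  cyl <- region == "cylinder"
  c1[cyl] <- s / (geom$r_cyl + s * d)   # azimuthal principal curvature
  c2[cyl] <- 0

  jun <- region == "junction"
  if (any(jun)) {
    r_t <- geom$r_junction - s * d
    th <- sc$theta[jun]
    c1[jun] <- -s / r_t                       # along the tube arc
    c2[jun] <- s * cos(th) / rho[jun]         # along the parallel circle
  }
  # flat: both zero

  bad <- !(region %in% region_levels)
  if (any(bad)) stop("analytic_curvature: point(s) not in any region")

  data.frame(H = curv_ang_to_nm((c1 + c2) / 2),
             K = gauss_ang_to_nm(c1 * c2),
             C1 = curv_ang_to_nm(c1), C2 = curv_ang_to_nm(c2),
             region = region, stringsAsFactors = FALSE)
}

#' Dummy-particle scaffold lattice
#'
#' Generates the two shells of dummy particles that bracket the bilayer at
#' `+/- dummy_gap/2` from the mid-surface, sampled at the dummy grid
#' spacing. Positions double as the restraint reference positions for force
#' sensing.
#'
#' @param geom an [imm_geometry()].
#' @param spacing lattice spacing, Angstrom; defaults to the geometry's
#'   `dummy_grid_spacing`.
#' @return a `surface_points` data frame with `leaflet` holding the shell
#'   label (`"outer"`/`"inner"` side of the bilayer).
#' @export
dummy_lattice <- function(geom, spacing = geom$dummy_grid_spacing) {
  stopifnot(inherits(geom, "imm_geometry"))
  half_gap <- geom$dummy_gap / 2
  if (half_gap >= min(geom$r_cyl, geom$r_junction))
    stop("dummy_gap/2 must be smaller than r_cyl and r_junction")
  outer <- offset_surface(geom, half_gap, spacing, "outer")
  inner <- offset_surface(geom, -half_gap, spacing, "inner")
  out <- rbind(outer, inner)
  attr(out, "geometry") <- geom
  attr(out, "spacing") <- spacing
  attr(out, "offset") <- half_gap
  class(out) <- c("surface_points", "data.frame")
  out
}

#' Closed-form region areas
#'
#' Areas of the three surface regions for the mid-surface or a surface offset
#' along the normal (a leaflet at `offset = +/- t/2`, a dummy shell at
#' `+/- dummy_gap/2`). Junction and flat areas are the summed areas of the
#' two symmetric halves.
#'
#' @param geom an [imm_geometry()].
#' @param offset signed normal offset from the mid-surface, Angstrom
#'   (positive towards the outer side).
#' @return named numeric vector (`flat`, `junction`, `cylinder`), Angstrom^2.
#' @export
region_areas <- function(geom, offset = 0) {
  stopifnot(inherits(geom, "imm_geometry"))
  r_c <- geom$r_cyl + offset
  r_t <- geom$r_junction - offset
  cyl <- 2 * pi * r_c * geom$l_cylinder
  jun <- 2 * (2 * pi * r_t * (geom$rho0 * pi / 2 - r_t))
  fl <- 2 * (geom$l_flat^2 - pi * geom$rho0^2)
  c(flat = fl, junction = jun, cylinder = cyl)
}

# leaflet-outward unit normal at arbitrary near-surface points; used to
# orient estimated normals when a geometry hint is available.
geometry_normals <- function(geom, xyz, leaflet = c("outer", "inner")) {
  leaflet <- match.arg(leaflet)
  s <- if (leaflet == "outer") 1 else -1
  xyz <- as_xyz(xyz)
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  sc <- surface_coords_rz(rho, xyz[, 3], geom)
  n <- matrix(0, nrow(xyz), 3L)
  erho <- cbind(xyz[, 1] / pmax(rho, 1e-12), xyz[, 2] / pmax(rho, 1e-12), 0)
  cyl <- sc$region == "cylinder"
  n[cyl, ] <- erho[cyl, , drop = FALSE]
  jun <- sc$region == "junction"
  if (any(jun)) {
    th <- sc$theta[jun]
    sz <- sign(xyz[jun, 3])
    n[jun, ] <- cbind(cos(th) * erho[jun, 1], cos(th) * erho[jun, 2],
                      -sz * sin(th))
  }
  fl <- sc$region == "flat"
  n[fl, 3] <- -sign(xyz[fl, 3])
  s * n
}

#' Export a surface sampling or dummy lattice as coordinates
#'
#' Writes a `surface_points` set (leaflet sampling or dummy lattice) as a
#' one-bead-per-point GRO or PDB file, for system building or
#' visualisation.
#'
#' @param points a `surface_points` data frame.
#' @param path output file (`.gro` or `.pdb`).
#' @param name residue/bead name to use (default `DUMY`).
#' @return `path`, invisibly.
#' @export
export_surface <- function(points, path, name = "DUMY") {
  stopifnot(inherits(points, "surface_points"))
  geom <- attr(points, "geometry")
  topo <- data.frame(lipid_id = seq_len(nrow(points)), species = name,
                     bead = name, role = "marker", charge = 0,
                     stringsAsFactors = FALSE)
  class(topo) <- c("topology", "data.frame")
  box <- c(geom$l_flat, geom$l_flat,
           2 * (geom$z_flat + geom$dummy_gap))
  fr <- new_frame(0, as.matrix(points[, c("x", "y", "z")]), box)
  write_frames(new_trajectory(topo, list(fr)), path)
}

#' @export
print.surface_points <- function(x, ...) {
  cat(sprintf("surface_points: %d points, spacing %.2f A, offset %+.1f A\n",
              nrow(x), attr(x, "spacing"), attr(x, "offset")))
  print(table(leaflet = x$leaflet, region = x$region))
  invisible(x)
}
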