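# Flat-bilayer structural observables used to audit dummy-particle
# artifacts: thickness, area per lipid, bond order, splay, pressure profile.

# Leaflet split for a flat bilayer: markers above/below the marker mid-plane.
flat_leaflets <- function(topology, coords) {
  mk <- marker_positions(topology, coords)
  mid <- mean(mk$xyz[, 3])
  list(marker = mk, upper = mk$xyz[, 3] >= mid)
}

#' Flat-bilayer thickness
#'
#' Phosphate-to-phosphate thickness: mean z of the upper-leaflet headgroup
#' markers minus mean z of the lower-leaflet markers.
#'
#' @param frame an `imm_frame`.
#' @param topology the bead topology.
#' @return thickness in Angstrom.
#' @export
bilayer_thickness <- function(frame, topology) {
  fl <- flat_leaflets(topology, frame$coords)
  if (!any(fl$upper) || all(fl$upper))
    stop("could not assign two leaflets from marker positions")
  mean(fl$marker$xyz[fl$upper, 3]) - mean(fl$marker$xyz[!fl$upper, 3])
}

#' Area per lipid
#'
#' `APL = box_x * box_y / n_leaflet` for a flat bilayer in an orthorhombic
#' box. With unequal leaflet populations both per-leaflet values are
#' returned.
#'
#' @inheritParams bilayer_thickness
#' @return named numeric: `upper` and `lower` APL (Angstrom^2); equal when
#'   the leaflets are balanced.
#' @export
area_per_lipid <- function(frame, topology) {
  if (any(!is.finite(frame$box[1:2]))) stop("frame has no box dimensions")
  fl <- flat_leaflets(topology, frame$coords)
  area <- frame$box[1] * frame$box[2]
  c(upper = area / sum(fl$upper), lower = area / sum(!fl$upper))
}

#' Second-rank bond order parameter
#'
#' `P2 = (3 cos^2(theta) - 1)/2` for the angle between each consecutive
#' tail-bead bond and the membrane normal, averaged over lipids and resolved
#' by bond position along the chain. 1 means aligned with the normal, -0.5
#' in-plane, 0 the magic angle (54.74 deg) or an isotropic distribution.
#'
#' @inheritParams bilayer_thickness
#' @param normal membrane normal (default z).
#' @return data frame: `chain`, `bond` (position along the chain), `P2`
#'   (lipid average), `n`.
#' @export
order_parameter_p2 <- function(frame, topology, normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  tails <- topology$role %in% c("tail", "tail_end")
  rows <- list()
  # chains identified by the trailing letter of the bead name (C1A.. C4A)
  chain_id <- sub("^C[0-9]+", "", topology$bead)
  pos_id <- suppressWarnings(as.integer(sub("^C([0-9]+).*$", "\\1",
                                            topology$bead)))
  df <- data.frame(i = seq_len(nrow(topology)), lipid = topology$lipid_id,
                   chain = chain_id, pos = pos_id)[tails, ]
  df <- df[order(df$lipid, df$chain, df$pos), ]
  same <- with(df, lipid[-1] == lipid[-nrow(df)] &
                 chain[-1] == chain[-nrow(df)])
  a <- df$i[-nrow(df)][same]; b <- df$i[-1][same]
  v <- frame$coords[b, , drop = FALSE] - frame$coords[a, , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  zero <- len < 1e-9
  if (any(zero)) warning(sum(zero), " zero-length bond(s) excluded")
  ct <- (v %*% normal) / len
  p2 <- (3 * ct^2 - 1) / 2
  key <- paste(df$chain[-nrow(df)][same], df$pos[-nrow(df)][same], sep = "-")
  agg <- tapply(p2[!zero], key[!zero], mean)
  n <- tapply(p2[!zero], key[!zero], length)
  parts <- strsplit(names(agg), "-")
  out <- data.frame(chain = vapply(parts, `[`, "", 1),
                    bond = as.integer(vapply(parts, `[`, "", 2)),
                    P2 = as.vector(agg), n = as.vector(n))
  out[order(out$chain, out$bond), ]
}

#' Lipid splay angle
#'
#' Angle between the vector from the first glycerol linker bead to the
#' terminal bead of the sn-1 chain and the leaflet normal (+z for the upper
#' leaflet, -z for the lower), in degrees.
#'
#' @inheritParams bilayer_thickness
#' @return data frame per lipid: `lipid_id`, `leaflet`, `angle` (degrees);
#'   lipids missing either bead are skipped and counted in the
#'   `n_skipped` attribute.
#' @export
splay_angle <- function(frame, topology) {
  fl <- flat_leaflets(topology, frame$coords)
  lids <- fl$marker$lipid_id
  gl <- tapply(seq_len(nrow(topology))[topology$role == "linker"],
               topology$lipid_id[topology$role == "linker"], `[`, 1L)
  snA <- topology$role == "tail_end" & grepl("A$", topology$bead)
  te <- tapply(seq_len(nrow(topology))[snA], topology$lipid_id[snA], `[`, 1L)
  keep <- lids %in% as.integer(names(gl)) & lids %in% as.integer(names(te))
  n_skipped <- sum(!keep)
  lids <- lids[keep]
  up <- fl$upper[keep]
  v <- frame$coords[te[as.character(lids)], , drop = FALSE] -
    frame$coords[gl[as.character(lids)], , drop = FALSE]
  nz <- ifelse(up, 1, -1)
  ct <- (v[, 3] * nz) / sqrt(rowSums(v^2))
  out <- data.frame(lipid_id = lids,
                    leaflet = ifelse(up, "upper", "lower"),
                    angle = acos(pmin(pmax(ct, -1), 1)) * 180 / pi)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a slab stress profile
#'
#' Reads a whitespace- or comma-separated table of per-slab stress tensor
#' diagonals: either 4 columns (`z`, `sxx`, `syy`, `szz`) or 10 columns
#' (`z` plus the full 9-component tensor in row-major order, of which the
#' diagonal is kept). Units: z in Angstrom, stress in bar.
#'
#' @param path file path.
#' @return a `stress_profile` data frame: `z`, `sxx`, `syy`, `szz`.
#' @export
read_stress_profile <- function(path) {
  tab <- data.table::fread(path, header = "auto")
  tab <- as.data.frame(tab)
  if (ncol(tab) == 4L) names(tab) <- c("z", "sxx", "syy", "szz")
  else if (ncol(tab) == 10L) {
    tab <- tab[, c(1, 2, 6, 10)]
    names(tab) <- c("z", "sxx", "syy", "szz")
  } else stop("expected 4 or 10 columns, got ", ncol(tab))
  if (any(!is.finite(as.matrix(tab)))) stop("non-finite stress entries")
  if (is.unsorted(tab$z)) stop("slabs must be ordered in z")
  class(tab) <- c("stress_profile", "data.frame")
  tab
}

#' Lateral pressure profile
#'
#' Computes the lateral and normal pressure components and the lateral
#' pressure profile `pi(z) = P_L(z) - P_N(z)` from per-slab stress tensor
#' diagonals. The default uses the standard convention
#' `P_L = -(sxx + syy)/2`; `convention = "unhalved"` reproduces the variant
#' without the 1/2 factor sometimes printed in the membrane literature.
#'
#' @param sp a [read_stress_profile()] result or equivalent data frame.
#' @param convention `"standard"` (with the 1/2) or `"unhalved"`.
#' @return data frame: `z`, `P_L`, `P_N`, `pi` (bar).
#' @export
pressure_profile <- function(sp, convention = c("standard", "unhalved")) {
  convention <- match.arg(convention)
  req <- c("z", "sxx", "syy", "szz")
  if (!all(req %in% names(sp))) stop("missing stress components")
  div <- if (convention == "standard") 2 else 1
  P_L <- -(sp$sxx + sp$syy) / div
  P_N <- -sp$szz
  data.frame(z = sp$z, P_L = P_L, P_N = P_N, pi = P_L - P_N)
}
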