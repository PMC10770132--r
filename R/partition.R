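#' Per-compartment lipid counts over time
#'
#' Counts lipids of each species in the six (leaflet x region) compartments
#' of the crista model for every frame. Symmetric top/bottom halves are
#' pooled into the three region values per leaflet. Accepts a labelled
#' trajectory ([label_trajectory()]) or a synthetic sorting run
#' ([mc_sort()]). Frames with more than 5% unassigned lipids trigger a
#' warning.
#'
#' @param x a `labeled_trajectory` or `sorting_run`.
#' @param ... unused.
#' @return a `compartment_series`: list with `times` (ns), `counts` (array
#'   frame x leaflet x region x species) and `species`.
#' @export
count_by_compartment <- function(x, ...) UseMethod("count_by_compartment")

new_compartment_series <- function(times, counts, species) {
  dimnames(counts) <- list(NULL, leaflet = leaflet_levels,
                           region = region_levels, species = species)
  structure(list(times = times, counts = counts, species = species),
            class = "compartment_series")
}

#' @export
count_by_compartment.labeled_trajectory <- function(x, ...) {
  species <- sort(unique(x$topology$species))
  nf <- length(x$frames)
  counts <- array(0L, dim = c(nf, 2L, 3L, length(species)))
  warned <- FALSE
  for (i in seq_len(nf)) {
    lp <- x$frames[[i]]$lipids
    assigned <- lp$region != "unassigned"
    if (!warned && mean(!assigned) > 0.05) {
      warning(sprintf("frame %d: %.1f%% of lipids unassigned",
                      i, 100 * mean(!assigned)))
      warned <- TRUE
    }
    lp <- lp[assigned, , drop = FALSE]
    tb <- table(factor(lp$leaflet, leaflet_levels),
                factor(lp$region, region_levels),
                factor(lp$species, species))
    counts[i, , , ] <- tb
  }
  new_compartment_series(frame_times(x), counts, species)
}

#' @export
count_by_compartment.sorting_run <- function(x, ...) {
  sites <- x$model$sites
  species <- x$model$species$name
  comp <- 3L * (match(sites$leaflet, leaflet_levels) - 1L) +
    match(sites$region, region_levels)          # 1..6
  nf <- nrow(x$labels)
  ns <- length(species)
  counts <- array(0L, dim = c(nf, 2L, 3L, ns))
  for (i in seq_len(nf)) {
    idx <- (comp - 1L) * ns + x$labels[i, ]
    tb <- tabulate(idx, nbins = 6L * ns)
    # idx layout: species fastest within compartment (leaflet-major)
    m <- matrix(tb, nrow = ns)                  # species x compartment
    counts[i, 1L, , ] <- t(m[, 1:3])
    counts[i, 2L, , ] <- t(m[, 4:6])
  }
  new_compartment_series(x$times, counts, species)
}

#' @export
print.compartment_series <- function(x, ...) {
  cat(sprintf("compartment_series: %d frames, species %s\n",
              length(x$times), paste(x$species, collapse = ", ")))
  cat("mean counts per compartment (last frame):\n")
  print(x$counts[length(x$times), , , ])
  invisible(x)
}

#' Compartmental lipid fractions
#'
#' Converts compartment counts to per-compartment species fractions
#' `LF_i = n_i / sum_i n_i` (the denominator running over the species
#' present in that compartment). Frames where a compartment is empty are
#' masked (`NaN`) for that compartment rather than set to zero.
#'
#' @param series a [count_by_compartment()] result.
#' @return an `lf_series`: list with `times`, `lf` (array frame x leaflet x
#'   region x species) and `species`.
#' @export
lipid_fraction <- function(series) {
  stopifnot(inherits(series, "compartment_series"))
  tot <- apply(series$counts, c(1, 2, 3), sum)
  lf <- sweep(series$counts, c(1, 2, 3), tot, "/")  # 0/0 -> NaN masks empties
  structure(list(times = series$times, lf = lf, species = series$species),
            class = "lf_series")
}

window_index <- function(times, t_a, t_b) {
  if (t_a >= t_b) stop("t_a must be < t_b")
  if (t_a < min(times) - 1e-9 || t_b > max(times) + 1e-9)
    stop(sprintf("window [%g, %g] outside data span [%g, %g]",
                 t_a, t_b, min(times), max(times)))
  which(times >= t_a & times <= t_b)
}

#' Enrichment/depletion factor
#'
#' The percentage-point change of a species' compartmental fraction,
#' `F = (<LF>_(ta->tb) - LF_(t=0)) * 100`, with the baseline taken from the
#' first stored frame and the average over the analysis window. Errors are
#' block-averaged standard errors of the windowed mean (default block 80
#' ns). Within each compartment the factors sum to zero across species.
#'
#' @param lf an [lipid_fraction()] result.
#' @param t_a,t_b averaging window (ns); default the final half of the
#'   trajectory.
#' @param block block length for the error estimate (ns); `NA` skips errors.
#' @return an `enrichment_result` data frame: `leaflet, region, species, F,
#'   block_error` (%), with the window and baseline stored as attributes.
#' @examples
#' # a fraction rising from a 20% baseline to a steady 25% gives F = 5
#' @export
enrichment_factor <- function(lf, t_a = NULL, t_b = NULL, block = 80) {
  stopifnot(inherits(lf, "lf_series"))
  times <- lf$times
  if (is.null(t_a)) t_a <- times[1] + (times[length(times)] - times[1]) / 2
  if (is.null(t_b)) t_b <- times[length(times)]
  win <- window_index(times, t_a, t_b)
  base <- lf$lf[1L, , , , drop = FALSE]
  rows <- list()
  for (il in 1:2) for (ir in 1:3) for (is in seq_along(lf$species)) {
    series <- lf$lf[win, il, ir, is]
    Fv <- (mean(series, na.rm = TRUE) - base[1L, il, ir, is]) * 100
    be <- if (is.na(block)) NA_real_ else
      100 * block_error(series, times[win], block = block)
    rows[[length(rows) + 1L]] <- data.frame(
      leaflet = leaflet_levels[il], region = region_levels[ir],
      species = lf$species[is], F = Fv, block_error = be,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "window") <- c(t_a = t_a, t_b = t_b)
  attr(out, "baseline") <- base[1L, , , ]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, digits = 3, ...) {
  w <- attr(x, "window")
  cat(sprintf("enrichment/depletion factors, window %.4g..%.4g ns (%% points)\n",
              w[1], w[2]))
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$block_error <- round(df$block_error, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Block-averaged standard error of a time-series mean
#'
#' Divides the series into contiguous blocks of `block` ns, drops the
#' trailing partial block, and returns `sd(block means)/sqrt(n_blocks)` -
#' the standard error of the windowed mean allowing for temporal
#' correlation up to the block length.
#'
#' @param x numeric series.
#' @param times sample times (ns), same length as `x`.
#' @param block block length (ns).
#' @return standard error (same units as `x`).
#' @export
block_error <- function(x, times, block = 80) {
  stopifnot(length(x) == length(times), block > 0)
  span <- times[length(times)] - times[1]
  nb <- floor(span / block + 1e-9)
  if (nb < 2) stop("window must contain at least 2 blocks")
  bi <- floor((times - times[1]) / block)
  keep <- bi < nb
  means <- tapply(x[keep], bi[keep], mean, na.rm = TRUE)
  sd(means) / sqrt(length(means))
}

#' Centred running mean
#'
#' Centred moving average over a `window` ns time window; near the edges the
#' effective window is truncated to the available data (no padding).
#'
#' @param x numeric series.
#' @param times sample times (ns).
#' @param window window length (ns).
#' @return smoothed series, same length as `x`.
#' @export
running_mean <- function(x, times, window = 40) {
  stopifnot(length(x) == length(times), window > 0)
  half <- window / 2
  lo <- findInterval(times - half, times, left.open = TRUE) + 1L
  hi <- findInterval(times + half, times)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  (cs[hi + 1L] - cs[lo]) / pmax(cn[hi + 1L] - cn[lo], 1L)
}

#' Thresholded spatial percent-change maps
#'
#' Bins lipid headgroup positions in the polar `(rho, z)` plane and maps,
#' per species, the time-averaged local composition percentage minus the
#' species' bulk percentage at the first frame. Magnitudes below the
#' significance `threshold` (default 1.5 percentage points, the level below
#' which a label-only control shows only noise) are set to zero; bins never
#' visited are `NA` (masked), which is distinct from zero.
#'
#' @param x a `labeled_trajectory` or `sorting_run`.
#' @param geom an [imm_geometry()].
#' @param binsize bin edge length (Angstrom) in both rho and z.
#' @param t_a,t_b averaging window (ns); default the final half.
#' @param threshold significance threshold in percentage points; 0 disables.
#' @param min_occupancy bins averaging fewer lipids per frame than this are
#'   masked as undersampled (`NA`), like empty bins; 0 disables.
#' @return a `spatial_map`: list with `rho_edges`, `z_edges`, `maps` (one
#'   rho x z matrix per species), `threshold`, `bulk0`.
#' @export
spatial_percent_change_map <- function(x, geom, binsize = 10,
                                       t_a = NULL, t_b = NULL,
                                       threshold = 1.5, min_occupancy = 0) {
  if (binsize > geom$r_junction / 4)
    stop("binsize must resolve the junction (<= r_junction/4)")
  pos <- map_positions(x)      # list(times, frames: list of df(rho,z,species))
  species <- pos$species
  times <- pos$times
  if (is.null(t_a)) t_a <- times[1] + (times[length(times)] - times[1]) / 2
  if (is.null(t_b)) t_b <- times[length(times)]
  win <- window_index(times, t_a, t_b)

  zmax <- geom$z_flat + geom$bilayer_thickness
  rmax <- sqrt(2) * geom$l_flat / 2
  rho_edges <- seq(0, rmax + binsize, by = binsize)
  z_edges <- seq(-zmax - binsize, zmax + binsize, by = binsize)
  nr <- length(rho_edges) - 1L; nz <- length(z_edges) - 1L

  f0 <- pos$frames[[1L]]
  bulk0 <- 100 * as.vector(table(factor(f0$species, species))) / nrow(f0)
  names(bulk0) <- species

  acc <- array(0, dim = c(nr, nz, length(species)))
  for (i in win) {
    fr <- pos$frames[[i]]
    ri <- findInterval(fr$rho, rho_edges, rightmost.closed = TRUE)
    zi <- findInterval(fr$z, z_edges, rightmost.closed = TRUE)
    ok <- ri >= 1 & ri <= nr & zi >= 1 & zi <= nz
    si <- match(fr$species, species)
    lin <- (si[ok] - 1L) * nr * nz + (zi[ok] - 1L) * nr + ri[ok]
    acc <- acc + array(tabulate(lin, nbins = nr * nz * length(species)),
                       dim = dim(acc))
  }
  tot <- apply(acc, c(1, 2), sum)
  undersampled <- tot < max(1, min_occupancy * length(win))
  maps <- lapply(seq_along(species), function(is) {
    m <- 100 * acc[, , is] / tot - bulk0[is]   # NaN where tot == 0
    m[undersampled] <- NA_real_
    if (threshold > 0) m[!is.na(m) & abs(m) < threshold] <- 0
    m
  })
  names(maps) <- species
  structure(list(rho_edges = rho_edges, z_edges = z_edges, maps = maps,
                 threshold = threshold, bulk0 = bulk0,
                 window = c(t_a = t_a, t_b = t_b)),
            class = "spatial_map")
}

# Unified access to per-frame (rho, z, species) marker tables.
map_positions <- function(x) {
  if (inherits(x, "sorting_run")) {
    sites <- x$model$sites
    species <- x$model$species$name
    frames <- lapply(seq_len(nrow(x$labels)), function(i)
      data.frame(rho = sites$rho, z = sites$z,
                 species = species[x$labels[i, ]],
                 stringsAsFactors = FALSE))
    list(times = x$times, frames = frames, species = species)
  } else if (inherits(x, "labeled_trajectory")) {
    species <- sort(unique(x$topology$species))
    frames <- lapply(x$frames, function(fr) {
      lp <- fr$lipids[fr$lipids$region != "unassigned", ]
      data.frame(rho = lp$rho, z = lp$z, species = lp$species,
                 stringsAsFactors = FALSE)
    })
    list(times = frame_times(x), frames = frames, species = species)
  } else stop("x must be a labeled_trajectory or sorting_run")
}

#' @export
plot.spatial_map <- function(x, species = names(x$maps)[1], ...) {
  m <- x$maps[[species]]
  rng <- max(abs(m), na.rm = TRUE)
  if (!is.finite(rng) || rng == 0) rng <- 1
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(41)
  graphics::image(x$rho_edges, x$z_edges, m, zlim = c(-rng, rng), col = pal,
                  xlab = "rho (A)", ylab = "z (A)",
                  main = sprintf("%s percent change", species), ...)
  invisible(x)
}
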