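#' Pearson correlation with validation
#'
#' Product-moment correlation of two equal-length vectors, with the sanity
#' checks the compartment-level analysis needs: at least 3 complete pairs
#' and nonzero variance in both; otherwise `NA` with a warning.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient, or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Enrichment-curvature correlation summary
#'
#' Correlates the per-compartment enrichment factors of each minor species
#' with the compartment-average mean and Gaussian curvature over the six
#' (leaflet x region) compartments — the statistic that separates
#' mean-curvature sensing from Gaussian-curvature sensing. Missing
#' compartments are dropped pairwise with `n` decremented. When a
#' [lipid_fraction()] series is supplied, a bootstrap over the frames of the
#' analysis window gives a confidence interval for each correlation,
#' reported separately from the point estimate.
#'
#' @param enr an [enrichment_factor()] result.
#' @param curv a [region_curvature_summary()] result.
#' @param species species to report; default every species except the most
#'   abundant at baseline (the "minor components").
#' @param lf optional `lf_series` for the bootstrap.
#' @param n_boot bootstrap replicates (0 = none).
#' @return a `correlation_summary` data frame: `species`, `r_mean`,
#'   `r_gauss`, `n`, and with bootstrap `r_mean_lo/hi`, `r_gauss_lo/hi`
#'   (2.5/97.5 percentiles).
#' @export
enrichment_curvature_correlation <- function(enr, curv, species = NULL,
                                             lf = NULL, n_boot = 0) {
  stopifnot(inherits(enr, "enrichment_result"))
  if (is.null(species)) {
    base <- attr(enr, "baseline")
    tot <- apply(base, 3, sum)
    species <- names(tot)[-which.max(tot)]
    if (!length(species)) species <- names(tot)
  }
  key <- function(d) paste(d$leaflet, d$region)
  rows <- lapply(species, function(sp) {
    e <- enr[enr$species == sp, ]
    m <- match(key(e), key(curv))
    H <- curv$H_mean[m]; K <- curv$K_mean[m]
    ok <- is.finite(e$F) & is.finite(H) & is.finite(K)
    data.frame(species = sp,
               r_mean = pearson_r(e$F[ok], H[ok]),
               r_gauss = pearson_r(e$F[ok], K[ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (n_boot > 0 && !is.null(lf)) {
    w <- attr(enr, "window")
    win <- window_index(lf$times, w[1], w[2])
    ci <- boot_correlation(lf, curv, species, win, n_boot)
    out <- cbind(out, ci)
  }
  class(out) <- c("correlation_summary", "data.frame")
  out
}

boot_correlation <- function(lf, curv, species, win, n_boot) {
  key <- paste(rep(leaflet_levels, each = 3), rep(region_levels, 2))
  m <- match(key, paste(curv$leaflet, curv$region))
  H <- curv$H_mean[m]; K <- curv$K_mean[m]
  base <- lf$lf[1L, , , , drop = FALSE]
  res <- array(NA_real_, dim = c(n_boot, length(species), 2))
  for (b in seq_len(n_boot)) {
    idx <- sample(win, length(win), replace = TRUE)
    for (is in seq_along(species)) {
      si <- match(species[is], lf$species)
      Fv <- numeric(6)
      kk <- 1
      for (il in 1:2) for (ir in 1:3) {
        Fv[kk] <- (mean(lf$lf[idx, il, ir, si], na.rm = TRUE) -
                     base[1L, il, ir, si]) * 100
        kk <- kk + 1
      }
      ok <- is.finite(Fv) & is.finite(H)
      if (sum(ok) >= 3 && sd(Fv[ok]) > 0) {
        res[b, is, 1] <- cor(Fv[ok], H[ok])
        res[b, is, 2] <- cor(Fv[ok], K[ok])
      }
    }
  }
  data.frame(
    r_mean_lo = apply(res[, , 1, drop = FALSE], 2, stats::quantile,
                      0.025, na.rm = TRUE),
    r_mean_hi = apply(res[, , 1, drop = FALSE], 2, stats::quantile,
                      0.975, na.rm = TRUE),
    r_gauss_lo = apply(res[, , 2, drop = FALSE], 2, stats::quantile,
                       0.025, na.rm = TRUE),
    r_gauss_hi = apply(res[, , 2, drop = FALSE], 2, stats::quantile,
                       0.975, na.rm = TRUE))
}
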