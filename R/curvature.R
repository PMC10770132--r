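#' Estimate leaflet curvature from a headgroup point cloud
#'
#' Reconstructs per-vertex mean (`H`) and Gaussian (`K`) curvature of a
#' leaflet surface sampled by lipid headgroup positions. For each point a
#' local frame is built from the covariance of its `k_neighbors` nearest
#' neighbours (normal = smallest-variance direction), the neighbourhood is
#' fitted with a quadratic Monge patch
#' `h(u,v) = (a u^2 + 2 b u v + c v^2)/2 + d u + e v + f`,
#' and `H`, `K` follow from the first and second fundamental forms of the
#' fit. The sign convention matches the analytic oracle
#' ([analytic_curvature()]): with the normal oriented leaflet-outward, a
#' cylinder seen from outside has `H = +1/(2R)`. Normals are oriented with
#' the cristae geometry when `geom_hint` is supplied, otherwise outward from
#' the cloud centroid. Vertices whose fit is rank-deficient or whose
#' residual exceeds 5x the median are flagged (and excluded from summaries),
#' never silently dropped.
#'
#' Vertices are the input points themselves (no remeshing), so curvature is
#' available per lipid for sorting correlations.
#'
#' @param points n x 3 matrix of headgroup positions (Angstrom).
#' @param geom_hint optional [imm_geometry()] used to orient normals and
#'   attach region labels.
#' @param leaflet leaflet the cloud belongs to (used with `geom_hint`).
#' @param k_neighbors number of nearest neighbours per fit (>= 6).
#' @return a `curvature_field` data frame: columns `x, y, z, rho, H` (nm^-1),
#'   `K` (nm^-2), `region`, `leaflet`, `residual`, `flagged`.
#' @examples
#' ph <- runif(500, 0, 2 * pi); ct <- runif(500, -1, 1)
#' sph <- 100 * cbind(sqrt(1 - ct^2) * cos(ph), sqrt(1 - ct^2) * sin(ph), ct)
#' cf <- estimate_curvature(sph, k_neighbors = 12)
#' mean(cf$H[!cf$flagged])  # ~ +1/10 nm^-1
#' @export
estimate_curvature <- function(points, geom_hint = NULL,
                               leaflet = c("outer", "inner"),
                               k_neighbors = 12) {
  leaflet <- match.arg(leaflet)
  pts <- as_xyz(points)
  n <- nrow(pts)
  if (k_neighbors < 6) stop("k_neighbors must be >= 6")
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 points")

  nn <- knn_indices(pts, k_neighbors)

  ref_normals <- if (!is.null(geom_hint)) {
    geometry_normals(geom_hint, pts, leaflet)
  } else {
    ctr <- colMeans(pts)
    sweep(pts, 2, ctr)
  }

  H <- numeric(n); K <- numeric(n); resid <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    nb <- pts[c(i, nn[i, ]), , drop = FALSE]
    ctr <- colMeans(nb)
    q <- sweep(nb, 2, ctr)
    ev <- eigen(crossprod(q) / nrow(q), symmetric = TRUE)
    nrm <- ev$vectors[, 3L]
    if (sum(nrm * ref_normals[i, ]) < 0) nrm <- -nrm
    e1 <- ev$vectors[, 1L]; e2 <- ev$vectors[, 2L]
    # local coordinates centred on the vertex itself
    rel <- sweep(nb, 2, pts[i, ])
    u <- rel %*% e1; v <- rel %*% e2; h <- rel %*% nrm
    X <- cbind(u^2 / 2, u * v, v^2 / 2, u, v, 1)
    fit <- lm.fit(X, as.vector(h))
    if (fit$rank < 6L) { flagged[i] <- TRUE; next }
    cf <- fit$coefficients
    a <- cf[1]; b <- cf[2]; ccf <- cf[3]; dd <- cf[4]; ee <- cf[5]
    resid[i] <- sqrt(mean(fit$residuals^2))
    E <- 1 + dd^2; Fm <- dd * ee; G <- 1 + ee^2
    w <- sqrt(1 + dd^2 + ee^2)
    L <- a / w; M <- b / w; N <- ccf / w
    den <- E * G - Fm^2
    # sign flip: h is measured along the outward normal, and the surface
    # bending away from the outward normal is positive curvature here
    H[i] <- -(E * N + G * L - 2 * Fm * M) / (2 * den)
    K[i] <- (L * N - M^2) / den
  }
  # Outliers: residual beyond 5x the median, with an absolute floor of a
  # tenth of the local patch scale so that exactly-planar neighbourhoods
  # (residual ~ 0) cannot drag the threshold to machine precision.
  patch <- stats::median(sqrt(rowSums((pts - pts[nn[, k_neighbors], ])^2)))
  medr <- stats::median(resid[!flagged])
  flagged <- flagged | resid > pmax(5 * medr, 0.1 * patch)

  rz <- polar_transform(pts)
  region <- if (!is.null(geom_hint)) assign_region(rz, geom_hint)
            else rep(NA_character_, n)
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], rho = rz[, 1],
                    H = curv_ang_to_nm(H), K = gauss_ang_to_nm(K),
                    region = region, leaflet = leaflet,
                    residual = resid, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("curvature_field", "data.frame")
  out
}

# Brute-force k-nearest neighbours, chunked to bound memory; adequate for
# the 10^3-10^4 point clouds of coarse-grained leaflets.
knn_indices <- function(pts, k, chunk = 512L) {
  n <- nrow(pts)
  out <- matrix(0L, n, k)
  sq <- rowSums(pts^2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * pts[idx, , drop = FALSE] %*% t(pts)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

#' Per-compartment curvature summary
#'
#' Averages a [estimate_curvature()] field (or an analytic sampling) over
#' the six (leaflet x region) compartments, pooling the symmetric halves.
#' Flagged vertices are excluded. Empty compartments are reported with
#' `n = 0` and `NA` means, never as zero.
#'
#' @param field a `curvature_field`, or any data frame with columns
#'   `H, K, leaflet, region` (and optionally `flagged`).
#' @return data frame with one row per (leaflet, region): `n`, `H_mean`,
#'   `H_se`, `K_mean`, `K_se`.
#' @export
region_curvature_summary <- function(field) {
  if (!all(c("H", "K", "leaflet", "region") %in% names(field)))
    stop("field must have H, K, leaflet and region columns")
  ok <- field$region %in% region_levels
  if (!is.null(field$flagged)) ok <- ok & !field$flagged
  f <- field[ok, , drop = FALSE]
  grid <- expand.grid(leaflet = leaflet_levels, region = region_levels,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- f[f$leaflet == grid$leaflet[i] & f$region == grid$region[i], ]
    n <- nrow(sub)
    data.frame(leaflet = grid$leaflet[i], region = grid$region[i], n = n,
               H_mean = if (n) mean(sub$H) else NA_real_,
               H_se = if (n > 1) sd(sub$H) / sqrt(n) else NA_real_,
               K_mean = if (n) mean(sub$K) else NA_real_,
               K_se = if (n > 1) sd(sub$K) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("curvature_summary", "data.frame")
  out
}

#' Export a curvature field
#'
#' Writes a [estimate_curvature()] field as CSV (vertex position, `rho`,
#' `z`, leaflet, region, `H`, `K`) or as an ASCII PLY mesh-less point cloud
#' with `H` and `K` as vertex properties for visualisation.
#'
#' @param field a `curvature_field`.
#' @param path output file; `.ply` selects PLY, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_curvature_field <- function(field, path) {
  if (tolower(tools::file_ext(path)) == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(field)),
             "property float x", "property float y", "property float z",
             "property float quality_H", "property float quality_K",
             "end_header")
    body <- sprintf("%.4f %.4f %.4f %.6f %.6f",
                    field$x, field$y, field$z, field$H, field$K)
    writeLines(c(hdr, body), path)
  } else {
    data.table::fwrite(field[, c("x", "y", "z", "rho", "leaflet", "region",
                                 "H", "K", "flagged")], path)
  }
  invisible(path)
}
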