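test_that("compartment counting places constructed markers correctly", {
  g <- imm_geometry()
  set.seed(21)
  # 10 POPE markers inside the cylinder (inner leaflet), 5 POPC outer flat
  ph <- runif(10, 0, 2 * pi)
  pope <- cbind(80 * cos(ph), 80 * sin(ph), runif(10, -100, 100))
  popc <- cbind(runif(5, 210, 270), 0, g$z_flat - 20)
  traj <- marker_trajectory(list(rbind(pope, popc)), times = 0,
                            species = rep(c("POPE", "POPC"), c(10, 5)))
  lab <- label_trajectory(traj, g)
  cs <- count_by_compartment(lab)
  expect_equal(cs$counts[1, "inner", "cylinder", "POPE"], 10L)
  expect_equal(cs$counts[1, "outer", "flat", "POPC"], 5L)
  expect_equal(sum(cs$counts[1, , , ]), 15)
})

test_that("counts match an independent per-lipid recount on random frames", {
  g <- imm_geometry()
  sp <- default_sorting_species()[c(1, 2), ]
  sp$fraction <- c(0.7, 0.3)
  run <- mc_sort(sorting_model(g, sp, spacing = 16), 100, 2, seed = 22)
  cs <- count_by_compartment(run)
  sites <- run$model$sites
  set.seed(23)
  for (i in sample(nrow(run$labels), 20)) {
    for (lft in c("inner", "outer")) for (reg in c("flat", "junction", "cylinder")) {
      sel <- sites$leaflet == lft & sites$region == reg
      naive <- c(sum(run$labels[i, sel] == 1), sum(run$labels[i, sel] == 2))
      expect_equal(unname(cs$counts[i, lft, reg, ]), naive)
    }
  }
  # per-frame totals conserved
  expect_true(all(apply(cs$counts, 1, sum) == nrow(sites)))
})

test_that("lipid fractions follow their definition", {
  counts <- array(0L, dim = c(1, 2, 3, 2))
  counts[1, 1, 3, ] <- c(30L, 10L)   # inner cylinder: 30 A, 10 B
  counts[1, 2, 1, ] <- c(0L, 7L)     # outer flat: single species
  cs <- immsort:::new_compartment_series(0, counts, c("A", "B"))
  lf <- lipid_fraction(cs)
  expect_equal(lf$lf[1, "inner", "cylinder", "B"], 0.25)
  expect_equal(lf$lf[1, "outer", "flat", "B"], 1.0)
  expect_true(is.nan(lf$lf[1, "inner", "flat", "A"]))  # empty masked
  # random ternary draws vs hand arithmetic
  set.seed(24)
  for (k in 1:20) {
    n <- rmultinom(1, 60, c(0.5, 0.3, 0.2))[, 1]
    counts <- array(0L, dim = c(1, 2, 3, 3))
    counts[1, 1, 2, ] <- as.integer(n)
    cs <- immsort:::new_compartment_series(0, counts, c("A", "B", "C"))
    lf <- lipid_fraction(cs)
    expect_equal(unname(lf$lf[1, "inner", "junction", ]), unname(n / sum(n)))
  }
})

# helper: an lf_series with one active compartment following a given series
lf_from_series <- function(times, values, baseline = values[1]) {
  nf <- length(times)
  lfarr <- array(NA_real_, dim = c(nf, 2, 3, 2))
  vals <- values
  vals[1] <- baseline
  lfarr[, 1, 3, 1] <- vals
  lfarr[, 1, 3, 2] <- 1 - vals
  structure(list(times = times, lf = lfarr, species = c("m", "host")),
            class = "lf_series")
}

test_that("the enrichment factor reproduces the worked 20%->25% case", {
  times <- seq(0, 1000, by = 4)
  vals <- ifelse(times < 200, 0.20 + 0.05 * times / 200, 0.25)
  lf <- lf_from_series(times, vals, baseline = 0.20)
  enr <- enrichment_factor(lf, t_a = 500, t_b = 1000, block = 80)
  expect_equal(get_F(enr, "inner", "cylinder", "m"), 5.0)
  expect_equal(get_F(enr, "inner", "cylinder", "host"), -5.0)
})

test_that("constant fractions give zero enrichment and species closure holds", {
  times <- seq(0, 800, by = 8)
  lf <- lf_from_series(times, rep(0.3, length(times)))
  enr <- enrichment_factor(lf, 400, 800)
  expect_equal(get_F(enr, "inner", "cylinder", "m"), 0)
  # closure on a random synthetic series
  set.seed(25)
  lf2 <- lf_from_series(times, pmin(pmax(0.3 + cumsum(rnorm(101, 0, 0.01)),
                                         0.05), 0.95))
  enr2 <- enrichment_factor(lf2, 400, 800)
  for (i in seq_len(nrow(enr2) / 2)) {
    comp <- enr2[enr2$leaflet == enr2$leaflet[i] &
                   enr2$region == enr2$region[i], ]
    if (all(is.finite(comp$F))) expect_lt(abs(sum(comp$F)), 1e-9)
  }
  expect_true(any(is.finite(enr2$F)))
  expect_error(enrichment_factor(lf2, 400, 2000), "outside")
})

test_that("block errors match closed forms and Monte Carlo scaling", {
  times <- seq(0.5, 1200, by = 1)
  expect_equal(block_error(rep(3, length(times)), times, 80), 0)
  expect_error(block_error(1:5, 1:5, 80), "2 blocks")
  # alternating two-level series with period << block: every block mean is
  # identical, so the error is (numerically) zero
  alt <- rep(c(1, -1), length.out = 1200)
  expect_lt(block_error(alt, times, 80), 1e-12)
  # iid unit-variance noise, 12 blocks of 100 samples: se ~ 1/sqrt(1200),
  # i.e. block means ~ N(0, 1/10), se ~ 0.1/sqrt(12); check over 200 seeds
  set.seed(26)
  ses <- replicate(200, block_error(rnorm(1200), seq_len(1200) - 0.5, 100))
  expect_equal(mean(ses), 0.1 / sqrt(12), tolerance = 0.30)
})

test_that("running means agree with a brute-force window average", {
  set.seed(27)
  times <- seq(0, 400, by = 4)
  x <- rnorm(length(times))
  rm40 <- running_mean(x, times, 40)
  brute <- sapply(seq_along(times), function(i) {
    mean(x[abs(times - times[i]) <= 20])
  })
  expect_equal(rm40, brute)
  expect_equal(running_mean(rep(2, 101), times, 40), rep(2, 101))
  # unit impulse spreads into a boxcar whose entries are the window weights
  imp <- c(rep(0, 50), 1, rep(0, 50))
  sm <- running_mean(imp, times, 40)
  expect_equal(sum(sm > 0), 11)
  expect_equal(max(sm), 1 / 11)
})

test_that("spatial maps are null for uniform mixtures and localise a spike", {
  g <- imm_geometry()
  set.seed(28)
  # uniform mixture on the outer flat sheet across two frames
  n <- 12000
  mk <- function() {
    rho <- sqrt(runif(n, g$rho0^2, 270^2))
    ph <- runif(n, 0, 2 * pi)
    cbind(rho * cos(ph), rho * sin(ph), g$z_flat - 20)
  }
  species <- rep(c("A", "B"), c(9600, 2400))
  traj <- marker_trajectory(list(mk(), mk(), mk(), mk()), 0:3, species)
  lab <- label_trajectory(traj, g)
  m <- spatial_percent_change_map(lab, g, binsize = 20, t_a = 1, t_b = 3,
                                  threshold = 1.5)
  vals <- m$maps[["B"]]
  expect_true(all(vals[!is.na(vals)] == 0))

  # constructed enrichment: 10 tracer lipids migrate from one bin to
  # another, so the destination bin rises from 20% to 30/110 = 27.3%
  res1 <- cbind(rep(210, 100), 0, g$z_flat - 20)   # bin (200, 220]
  res2 <- cbind(rep(245, 100), 0, g$z_flat - 20)   # bin (240, 260]
  movers_t0 <- cbind(rep(245, 10), 0, g$z_flat - 20)
  movers_t1 <- cbind(rep(210, 10), 0, g$z_flat - 20)
  species2 <- c(rep(c("A", "B"), c(80, 20)), rep(c("A", "B"), c(80, 20)),
                rep("B", 10))
  frames <- list(rbind(res1, res2, movers_t0),
                 rbind(res1, res2, movers_t1),
                 rbind(res1, res2, movers_t1))
  traj2 <- marker_trajectory(frames, 0:2, species2)
  lab2 <- label_trajectory(traj2, g)
  m0 <- spatial_percent_change_map(lab2, g, binsize = 20, t_a = 1, t_b = 2,
                                   threshold = 1.5)
  mb <- m0$maps[["B"]]
  bulk <- 100 * 50 / 210
  expect_equal(sum(mb != 0, na.rm = TRUE), 2)
  expect_equal(max(mb, na.rm = TRUE), 100 * 30 / 110 - bulk)
  expect_equal(min(mb, na.rm = TRUE), 20 - bulk)
})

test_that("unthresholded maps integrate back to compartment changes", {
  g <- imm_geometry()
  sp <- default_sorting_species()[c(1, 4), ]
  sp$fraction <- c(0.8, 0.2)
  run <- mc_sort(sorting_model(g, sp, spacing = 12), 300, 10, seed = 29)
  m <- spatial_percent_change_map(run, g, binsize = 10, threshold = 0)
  cs <- count_by_compartment(run)
  lf <- lipid_fraction(cs)
  enr <- enrichment_factor(lf, block = NA)
  # occupancy-weighted mean of the map over all bins of one compartment
  sites <- run$model$sites
  win <- which(run$times >= max(run$times) / 2)
  for (reg in c("cylinder", "junction")) {
    sel <- sites$region == reg
    ri <- findInterval(sites$rho[sel], m$rho_edges, rightmost.closed = TRUE)
    zi <- findInterval(sites$z[sel], m$z_edges, rightmost.closed = TRUE)
    cells <- unique(cbind(ri, zi))
    w <- numeric(nrow(cells)); v <- numeric(nrow(cells))
    for (k in seq_len(nrow(cells))) {
      inbin <- sum(ri == cells[k, 1] & zi == cells[k, 2])
      w[k] <- inbin
      v[k] <- m$maps[["CDL2"]][cells[k, 1], cells[k, 2]]
    }
    ok <- !is.na(v)
    mapped <- sum(w[ok] * v[ok]) / sum(w[ok])
    # compartment percent change pooled over both leaflets
    cnt <- cs$counts[win, , reg, , drop = FALSE]
    pooled <- 100 * sum(cnt[, , 1, "CDL2"]) / sum(cnt) - 20
    expect_equal(mapped, pooled, tolerance = 0.1)
  }
})

test_that("a label-only tracer shows no significant enrichment", {
  g <- small_geom()
  run <- null_system(g, tracer_fraction = 0.2, n_sweeps = 1200,
                     record_every = 10, seed = 30, spacing = 6)
  enr <- enrichment_factor(lipid_fraction(count_by_compartment(run)))
  tst <- enr[enr$species == "TEST", ]
  expect_true(all(abs(tst$F) < 2 * tst$block_error |
                    abs(tst$F) < 0.5))
  # host + tracer fractions always sum to one
  lf <- lipid_fraction(count_by_compartment(run))
  tot <- apply(lf$lf, c(1, 2, 3), sum)
  expect_true(all(abs(tot[is.finite(tot)] - 1) < 1e-12))
})

test_that("time reversal of a stationary series barely moves F", {
  # a stationary null run looks the same run forwards or backwards: the
  # windowed mean over the final half matches the reversed series' final
  # half (= the initial half) within combined block errors
  g <- small_geom()
  run <- null_system(g, n_sweeps = 1200, record_every = 10, seed = 31,
                     spacing = 6)
  lf <- lipid_fraction(count_by_compartment(run))
  half <- max(lf$times) / 2
  enr_f <- enrichment_factor(lf, t_a = half, t_b = max(lf$times))
  enr_r <- enrichment_factor(lf, t_a = min(lf$times), t_b = half)
  dF <- abs(enr_f$F - enr_r$F)
  tol <- 3 * sqrt(enr_f$block_error^2 + enr_r$block_error^2)
  expect_true(all(dF < pmax(tol, 0.5)))
})
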