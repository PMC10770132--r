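test_that("thickness is the marker-to-marker leaflet separation", {
  fb <- flat_bilayer_frame(n_side = 10, half_thickness = 20)
  expect_equal(bilayer_thickness(fb$frame, fb$topology), 40)
  # rigid z-translation changes nothing
  fr2 <- fb$frame
  fr2$coords[, 3] <- fr2$coords[, 3] + 13.7
  expect_equal(bilayer_thickness(fr2, fb$topology), 40)
  # noisy leaflets stay within sampling error
  set.seed(51)
  fb3 <- flat_bilayer_frame(n_side = 15, half_thickness = 20, jitter = 1)
  expect_equal(bilayer_thickness(fb3$frame, fb3$topology), 40,
               tolerance = 0.3 / 40)
})

test_that("area per lipid divides the box area per leaflet", {
  fb <- flat_bilayer_frame(n_side = 10, box = c(80, 80, 100))
  apl <- area_per_lipid(fb$frame, fb$topology)
  expect_equal(unname(apl), c(64, 64))
  fb$frame$box <- c(160, 80, 100)
  expect_equal(unname(area_per_lipid(fb$frame, fb$topology)), c(128, 128))
  # asymmetric 90/110 leaflets
  topo <- data.frame(lipid_id = 1:200, species = "POPC", bead = "PO4",
                     role = "marker", charge = 0)
  class(topo) <- c("topology", "data.frame")
  coords <- cbind(runif(200, 0, 80), runif(200, 0, 80),
                  rep(c(20, -20), c(90, 110)))
  fr <- immsort:::new_frame(0, coords, c(80, 80, 100))
  apl2 <- area_per_lipid(fr, topo)
  expect_equal(unname(round(apl2, 1)), c(71.1, 58.2))
})

test_that("bond order parameters hit the canonical angles", {
  # one lipid, two tail beads per chain: bond along z, bond in plane,
  # and one at the magic angle
  topo <- data.frame(
    lipid_id = 1, species = "X",
    bead = c("PO4", "C1A", "C2A", "C1B", "C2B", "C1C", "C2C"),
    role = c("marker", "tail", "tail_end", "tail", "tail_end",
             "tail", "tail_end"), charge = 0)
  class(topo) <- c("topology", "data.frame")
  magic <- 54.7356103 * pi / 180
  coords <- rbind(c(0, 0, 10),
                  c(0, 0, 0), c(0, 0, -4),                 # along normal
                  c(10, 0, 0), c(14, 0, 0),                # in plane
                  c(20, 0, 0), c(20 + 4 * sin(magic), 0, 4 * cos(magic)))
  fr <- immsort:::new_frame(0, coords, c(50, 50, 50))
  p2 <- order_parameter_p2(fr, topo)
  expect_equal(p2$P2[p2$chain == "A"], 1.0)
  expect_equal(p2$P2[p2$chain == "B"], -0.5)
  expect_lt(abs(p2$P2[p2$chain == "C"]), 1e-6)
})

test_that("P2 is bounded and vanishes for isotropic bonds", {
  set.seed(52)
  n <- 4000
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  topo <- data.frame(
    lipid_id = rep(seq_len(n), each = 2), species = "X",
    bead = rep(c("C1A", "C2A"), n),
    role = rep(c("tail", "tail_end"), n), charge = 0)
  class(topo) <- c("topology", "data.frame")
  base <- matrix(runif(3 * n, 0, 100), ncol = 3)
  coords <- matrix(0, 2 * n, 3)
  coords[seq(1, 2 * n, 2), ] <- base
  coords[seq(2, 2 * n, 2), ] <- base + 4 * dirs
  fr <- immsort:::new_frame(0, coords, c(100, 100, 100))
  p2 <- order_parameter_p2(fr, topo)
  expect_true(all(p2$P2 >= -0.5 & p2$P2 <= 1))
  expect_lt(abs(p2$P2[1]), 3 / sqrt(n))
})

test_that("splay angles follow the glycerol-to-terminal vector", {
  topo <- make_topology(c(POPC = 2))
  coords <- matrix(0, nrow(topo), 3)
  # the reference axis is the leaflet's water-side normal: +z upper leaflet,
  # -z lower leaflet, so a vector along that axis scores 0 degrees
  i1 <- which(topo$lipid_id == 1)
  i2 <- which(topo$lipid_id == 2)
  coords[i1, ] <- cbind(0, 0, 20 - 1.5 * (seq_along(i1) - 2))
  coords[i2, ] <- cbind(30, 0, -20 + 1.5 * (seq_along(i2) - 2))
  # place glycerol and terminal beads explicitly
  coords[i1[topo$bead[i1] == "GL1"], ] <- c(0, 0, 15)
  coords[i1[topo$bead[i1] == "C4A"], ] <- c(0, 0, 27)      # along +z
  coords[i2[topo$bead[i2] == "GL1"], ] <- c(30, 0, -15)
  coords[i2[topo$bead[i2] == "C4A"], ] <- c(30 + 12 / sqrt(2), 0,
                                            -15 - 12 / sqrt(2))  # 45 deg
  fr <- immsort:::new_frame(0, coords, c(60, 60, 100))
  sa <- splay_angle(fr, topo)
  expect_equal(sa$angle[sa$lipid_id == 1], 0, tolerance = 1e-9)
  expect_equal(sa$angle[sa$lipid_id == 2], 45, tolerance = 1e-9)
  expect_equal(sa$leaflet, c("upper", "lower"))
})

test_that("cone-distributed splay vectors average to the cone angle", {
  set.seed(53)
  n <- 400
  cone <- 25 * pi / 180
  ph <- runif(n, 0, 2 * pi)
  # vectors at fixed polar angle from -z (lower-leaflet normal is -z)
  v <- cbind(sin(cone) * cos(ph), sin(cone) * sin(ph), -cos(cone)) * 12
  topo <- data.frame(
    lipid_id = rep(seq_len(n), each = 3), species = "X",
    bead = rep(c("PO4", "GL1", "C4A"), n),
    role = rep(c("marker", "linker", "tail_end"), n), charge = 0)
  class(topo) <- c("topology", "data.frame")
  base <- cbind(runif(n, 0, 200), runif(n, 0, 200), -20)
  coords <- matrix(0, 3 * n, 3)
  gl <- cbind(base[, 1], base[, 2], base[, 3] + 3)
  coords[seq(1, 3 * n, 3), ] <- base
  coords[seq(2, 3 * n, 3), ] <- gl
  coords[seq(3, 3 * n, 3), ] <- gl + v
  # add an upper leaflet so the mid-plane sits between leaflets
  topo_u <- topo; topo_u$lipid_id <- topo_u$lipid_id + n
  coords_u <- coords; coords_u[, 3] <- -coords_u[, 3]
  full <- rbind(topo, topo_u)
  class(full) <- c("topology", "data.frame")
  fr <- immsort:::new_frame(0, rbind(coords, coords_u), c(200, 200, 100))
  sa <- splay_angle(fr, full)
  expect_equal(mean(sa$angle[sa$leaflet == "lower"]), 25, tolerance = 1 / 25)
})

test_that("pressure profiles follow the stress decomposition", {
  iso <- data.frame(z = 1:5, sxx = -3, syy = -3, szz = -3)
  pp <- pressure_profile(iso)
  expect_true(all(pp$pi == 0))
  one <- data.frame(z = 0, sxx = -1, syy = -1, szz = -2)
  pp1 <- pressure_profile(one)
  expect_equal(pp1$P_L, 1)
  expect_equal(pp1$P_N, 2)
  expect_equal(pp1$pi, -1)
  # compatibility switch reproduces the unhalved variant
  pp2 <- pressure_profile(one, convention = "unhalved")
  expect_equal(pp2$P_L, 2)
  # a force-balanced profile integrates to zero tension
  z <- seq(-30, 30, by = 1)
  lat <- -200 * exp(-(abs(z) - 15)^2 / 8) + 178.5 * exp(-z^2 / 18)
  lat <- lat - mean(lat)
  sp <- data.frame(z = z, sxx = -lat, syy = -lat, szz = 0)
  ppb <- pressure_profile(sp)
  expect_lt(abs(sum(ppb$pi)), 1e-9)
})

test_that("stress tables parse in both layouts", {
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("z,sxx,syy,szz", "0,-1,-1,-2", "1,-1,-1,-2"), p4)
  sp4 <- read_stress_profile(p4)
  expect_equal(sp4$szz, c(-2, -2))
  p10 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 -1 0 0 0 -1 0 0 0 -2", "1 -1 0 0 0 -1 0 0 0 -2"), p10)
  sp10 <- read_stress_profile(p10)
  expect_equal(sp10$sxx, c(-1, -1))
  expect_equal(sp10$szz, c(-2, -2))
})

test_that("thickness and area per lipid anti-correlate at fixed volume", {
  # volume-conserving compression series: box shrinks laterally,
  # leaflet separation grows to conserve slab volume
  boxes <- seq(90, 70, by = -5)
  th <- apl <- numeric(length(boxes))
  for (i in seq_along(boxes)) {
    half <- 0.5 * 40 * (80 / boxes[i])^2
    fb <- flat_bilayer_frame(n_side = 10, box = c(boxes[i], boxes[i], 120),
                             half_thickness = half)
    th[i] <- bilayer_thickness(fb$frame, fb$topology)
    apl[i] <- area_per_lipid(fb$frame, fb$topology)[1]
  }
  expect_lt(cor(th, apl), -0.9)
  expect_true(all(diff(th) > 0) && all(diff(apl) < 0))
})
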