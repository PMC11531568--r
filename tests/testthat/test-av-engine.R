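free_site <- function() {
  make_toy_structure(data.frame(x = 0, y = 0, z = 0, elety = "CB",
                                resid = "CYS"))$structure
}

test_that("an unobstructed site fills a ball centred on the attachment atom", {
  av <- compute_av(free_site(), "A", 1, av_parameters(10, 4.5, 3.5, 1))
  r <- sqrt(rowSums(av$points^2))
  expect_true(all(r <= 10 + 1e-9))
  expect_equal(unname(av_centroid(av)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sum(av$weights), 1, tolerance = 1e-12)
})

test_that("every AV point is within linker length and clash-free", {
  # an obstacle cluster near the site
  atoms <- rbind(
    data.frame(x = 0, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "A", resno = 1),
    data.frame(x = c(4, 5, 6), y = c(2, -1, 3), z = c(0, 2, -2),
               elety = "CA", resid = "GLY", chain = "B", resno = 1:3))
  st <- make_toy_structure(atoms)$structure
  params <- av_parameters(12, 4.5, c(3.4, 8.2, 3.0), 1)
  av <- compute_av(st, "A", 1, params)
  r <- sqrt(rowSums(av$points^2))
  expect_true(all(r <= params$linker_length + 1e-9))
  obstacles <- st$atoms[st$atoms$chain == "B", ]
  for (i in seq_len(nrow(obstacles))) {
    d <- sqrt((av$points[, 1] - obstacles$x[i])^2 +
                (av$points[, 2] - obstacles$y[i])^2 +
                (av$points[, 3] - obstacles$z[i])^2)
    min_allowed <- obstacles$vdw[i] + params$dye_radii[av$sub_av]
    expect_true(all(d >= min_allowed - 1e-9))
  }
})

test_that("grid AV statistics match a Monte-Carlo rejection-sampling oracle", {
  # wall of atoms at x = -5: far enough that the linker path is never
  # blocked, so the allowed region is exactly {|p| <= L} n {x >= x_min}
  wall <- expand.grid(x = -5, y = seq(-30, 30, 1.5), z = seq(-30, 30, 1.5))
  atoms <- rbind(
    data.frame(x = 0, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "A", resno = 1),
    data.frame(x = wall$x, y = wall$y, z = wall$z, elety = "CA",
               resid = "GLY", chain = "B", resno = seq_len(nrow(wall))))
  st <- make_toy_structure(atoms)$structure
  L <- 10; R_dye <- 3.5
  av <- compute_av(st, "A", 1, av_parameters(L, 4.5, R_dye, 1))
  # oracle: uniform samples in the ball, rejected on dye clash with the
  # wall plane (vdW C 1.70 + dye radius); wall spacing 1.5 A makes the
  # clash surface effectively planar at x = -5 + 1.7 + 3.5
  set.seed(4)
  n <- 2e6
  u <- matrix(runif(3 * n, -L, L), ncol = 3)
  u <- u[rowSums(u^2) <= L^2, ]
  keep <- apply(u, 1, function(p) {
    dy <- (p[2] - wall$y); dz <- (p[3] - wall$z)
    all((p[1] + 5)^2 + dy^2 + dz^2 >= (1.7 + R_dye)^2 |
          abs(dy) + abs(dz) > 8)   # only nearby wall atoms can clash
  })
  mc <- u[keep, ]
  expect_gt(nrow(mc), 1e5)
  expect_lt(abs(av_centroid(av)[1] - mean(mc[, 1])), 1)   # grid_spacing
  expect_lt(abs(av_centroid(av)[2] - mean(mc[, 2])), 1)
  # centroid displaced away from the wall
  expect_gt(av_centroid(av)[1], 0.5)
})

test_that("halving the grid spacing moves the mean dye position by less than the spacing", {
  atoms <- rbind(
    data.frame(x = 0, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "A", resno = 1),
    data.frame(x = 4, y = 0, z = 0, elety = "CA", resid = "GLY",
               chain = "B", resno = 1))
  st <- make_toy_structure(atoms)$structure
  av1 <- compute_av(st, "A", 1, av_parameters(10, 4.5, 3.5, 1))
  av2 <- compute_av(st, "A", 1, av_parameters(10, 4.5, 3.5, 0.5))
  expect_lt(sqrt(sum((av_centroid(av1) - av_centroid(av2))^2)), 1)
})

test_that("buried sites and missing attachment atoms are reported distinctly", {
  shell <- expand.grid(x = seq(-4, 4, 1.2), y = seq(-4, 4, 1.2),
                       z = seq(-4, 4, 1.2))
  shell <- shell[rowSums(shell^2) > 4, ]
  atoms <- rbind(
    data.frame(x = 0, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "A", resno = 1),
    data.frame(x = shell$x, y = shell$y, z = shell$z, elety = "CA",
               resid = "GLY", chain = "B", resno = seq_len(nrow(shell))))
  st <- make_toy_structure(atoms)$structure
  expect_error(compute_av(st, "A", 1, av_parameters(10, 4.5, 3.5, 1)),
               "buried")
  expect_error(compute_av(st, "A", 2, av_parameters(10, 4.5, 3.5, 1)),
               "not found")
})

test_that("pair statistics are exact for hand-enumerable AVs", {
  R0 <- 6.34
  d <- 50   # Angstrom
  a1 <- manual_av(c(0, 0, 0))
  a2 <- manual_av(c(d, 0, 0))
  s <- pair_distance_stats(a1, a2, R0)
  expect_equal(s$mean_R_nm, d / 10)
  expect_equal(s$R_E_nm, d / 10, tolerance = 1e-9)
  expect_equal(s$mean_E, 1 / (1 + (d / 10 / R0)^6), tolerance = 1e-12)

  # two-point AVs {0, d} x {0, d}: 4 pairs enumerated by hand
  b1 <- manual_av(rbind(c(0, 0, 0), c(d, 0, 0)))
  s2 <- pair_distance_stats(b1, b1, R0)
  E_d <- 1 / (1 + (d / 10 / R0)^6)
  expect_equal(s2$mean_R_nm, d / 2 / 10)
  expect_equal(s2$mean_E, (2 * 1 + 2 * E_d) / 4, tolerance = 1e-12)
  expect_equal(s2$R_E_nm, R0 * (1 / s2$mean_E - 1)^(1 / 6))
})

test_that("FRET-averaged distance is below the mean distance for spread AVs at long range", {
  # in the convex regime of E(r) (r well above R0), Jensen's inequality
  # gives <E> >= E(<r>), i.e. R_E <= mean_R
  set.seed(8)
  R0 <- 6.34
  for (rep in 1:5) {
    c1 <- matrix(rnorm(60, sd = 4), ncol = 3)
    c2 <- matrix(rnorm(60, sd = 4), ncol = 3) +
      matrix(c(110, 0, 0), 20, 3, byrow = TRUE)
    r_all <- sqrt(outer(rowSums(c1^2), rowSums(c2^2), "+") -
                    2 * c1 %*% t(c2))
    expect_gt(min(r_all) / 10, R0 * (7 / 13)^(-1 / 6) / 2)  # convexity regime
    s <- pair_distance_stats(manual_av(c1), manual_av(c2), R0)
    expect_lte(s$R_E_nm, s$mean_R_nm + 1e-9)
  }
})

test_that("pair predictions are invariant under rigid motion of the structure", {
  atoms <- rbind(
    data.frame(x = 0, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "A", resno = 1),
    data.frame(x = 40, y = 0, z = 0, elety = "CB", resid = "CYS",
               chain = "B", resno = 1))
  st <- make_toy_structure(atoms)$structure
  p <- av_parameters(10, 4.5, 3.5, 1)
  s0 <- pair_distance_stats(compute_av(st, "A", 1, p),
                            compute_av(st, "B", 1, p), 6.34)
  xyz2 <- random_rigid(as.matrix(atoms[, c("x", "y", "z")]), seed = 6)
  atoms2 <- atoms; atoms2[, c("x", "y", "z")] <- xyz2
  st2 <- make_toy_structure(atoms2)$structure
  s1 <- pair_distance_stats(compute_av(st2, "A", 1, p),
                            compute_av(st2, "B", 1, p), 6.34)
  expect_lt(abs(s0$mean_R_nm - s1$mean_R_nm), 0.05)
  expect_lt(abs(s0$mean_E - s1$mean_E), 0.01)
})

test_that("symmetric dimers give equal T-H and H-T predictions before averaging", {
  # C2-symmetric toy dimer: chains A and B related by a 180 degree rotation
  # about z; identical dye parameters on both sides
  site <- function(chain, resno, x, y) {
    data.frame(x = x, y = y, z = 0, elety = "CB", resid = "CYS",
               chain = chain, resno = resno)
  }
  atoms <- rbind(site("A", 64, 10, 5), site("A", 280, 20, -5),
                 site("B", 64, -10, -5), site("B", 280, -20, 5))
  st <- make_toy_structure(atoms)$structure
  dye <- av_parameters(10, 4.5, 3.5, 1)
  pred <- predict_pair_table(st, c("A", "B"), sites = c(H = 64, T = 280),
                             donor_params = dye, acceptor_params = dye,
                             form = "toy", max_pairs = 2e7)
  unmixed <- attr(pred, "unmixed")
  expect_equal(unmixed$`T-H`$mean_R_nm, unmixed$`H-T`$mean_R_nm,
               tolerance = 1e-6)
  expect_equal(unmixed$`T-H`$mean_E, unmixed$`H-T`$mean_E, tolerance = 1e-6)
  expect_setequal(pred$pair, c("T-T", "T-H/H-T", "H-H"))
  expect_true(all(pred$mean_R_nm > 0))
})

test_that("dye presets carry the published cylinder and ellipsoid parameters", {
  cy <- av_dye_preset("cy3b")
  at <- av_dye_preset("atto647n")
  expect_equal(cy$linker_length, 18.5)
  expect_equal(cy$dye_radii, c(3.4, 8.2, 3.0))
  expect_equal(at$linker_length, 21.0)
  expect_equal(at$dye_radii, c(7.15, 4.5, 1.5))
  expect_equal(cy$linker_width, 4.5)
  expect_error(av_parameters(10, 4.5, 3.5, grid_spacing = 3), "grid_spacing")
})
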