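# Coarse-grained tile geometry: fluorophore placement, distances,
# clashes, orientation factors and transfer efficiency.

test_that("fluorophore placement follows the helical rule", {
  hp <- helix_params()
  # opposite-sign offsets sit on opposite sides of the reference crossover
  sc <- build_scene(construct_spec(-31, 30), hp)
  expect_lt(sc$donor$position[3], 0)
  expect_gt(sc$acceptor$position[3], 0)
  dz <- abs(sc$acceptor$position[3] - sc$donor$position[3])
  expect_equal(dz, (31 + 30 + 2 * hp$fluorophore_axial_ext_bp) * hp$rise_nm_per_bp)
  # zero radial and axial extension, equal same-side offsets: pure
  # lateral separation equal to the inter-axis spacing
  hp0 <- helix_params(fluorophore_radial_nm = 0, fluorophore_axial_ext_bp = 0)
  sc0 <- build_scene(construct_spec(7, 7), hp0)
  expect_equal(pair_distance(sc0), hp0$interaxis_nm)
  # dipoles are unit vectors; flipped donor points away from the acceptor axis
  expect_equal(sqrt(sum(sc$donor$dipole^2)), 1)
  expect_equal(sqrt(sum(sc$acceptor$dipole^2)), 1)
  scf <- build_scene(construct_spec(5, 5, spinach_flipped = TRUE), hp)
  scn <- build_scene(construct_spec(5, 5), hp)
  to_axis <- function(s) c(hp$interaxis_nm - s$donor$position[1],
                           -s$donor$position[2], 0)
  expect_gt(sum(scn$donor$dipole * to_axis(scn)), 0)
  expect_lt(sum(scf$donor$dipole * to_axis(scf)), 0)
})

test_that("pair distance equals the coordinate-wise oracle and is invariant", {
  hp <- helix_params()
  set.seed(42)
  for (k in 1:20) {
    so <- sample(c(-40:-1, 1:40), 1); mo <- sample(c(-40:-1, 1:40), 1)
    sc <- build_scene(construct_spec(so, mo, spinach_flipped = k %% 2 == 0), hp)
    p <- sc$donor$position; q <- sc$acceptor$position
    oracle <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)
    expect_equal(pair_distance(sc), oracle)
    # symmetric under swapping the poses; invariant under rigid motion
    sw <- sc; sw$donor <- sc$acceptor; sw$acceptor <- sc$donor
    expect_equal(pair_distance(sw), pair_distance(sc))
    th <- runif(1, 0, 2 * pi); R <- matrix(c(cos(th), sin(th), 0,
                                             -sin(th), cos(th), 0, 0, 0, 1), 3)
    tl <- runif(3, -5, 5)
    rot <- sc
    rot$donor$position <- as.numeric(R %*% p + tl)
    rot$acceptor$position <- as.numeric(R %*% q + tl)
    expect_equal(pair_distance(rot), pair_distance(sc))
  }
  # identical positions give zero
  sc <- build_scene(construct_spec(5, 5))
  sc$acceptor$position <- sc$donor$position
  expect_equal(pair_distance(sc), 0)
})

test_that("steric clash triggers iff the sphere meets the stem cylinder", {
  sc <- build_scene(construct_spec(17, 40))
  expect_false(detect_clash(sc)$clash)  # far along z: no clash
  sc$acceptor$position <- c(0, 0, sc$donor$position[3] / 2)  # on the stem axis
  cl <- detect_clash(sc)
  expect_true(cl$clash)
  expect_equal(cl$min_separation_nm, 0)
  # a default-parameter Mango scan reproduces at least one clashing length
  scan <- distance_scan(construct_spec(17, 14), "mango", seq(14, 30, 2))
  expect_equal(nrow(scan), 9L)
  expect_true(any(scan$clash))
  expect_named(scan, c("stem_bp", "distance_nm", "clash"))
  # single-point scan equals pair_distance
  one <- distance_scan(construct_spec(17, 14), "mango", 21)
  expect_equal(one$distance_nm, pair_distance(build_scene(construct_spec(17, 21))))
})

test_that("detrended distance scans repeat roughly every helical turn", {
  sc <- distance_scan(construct_spec(17, 14), "mango", 18:70)
  res <- resid(lm(distance_nm ~ stem_bp, data = sc))
  a <- acf(res, lag.max = 20, plot = FALSE)$acf[-1]
  # first local autocorrelation peak past the short-range decay
  peak <- which.max(a[6:20]) + 5L
  expect_true(peak >= 10 && peak <= 13)
  # spacing between successive local distance minima
  d <- sc$distance_nm
  mins <- which(diff(sign(diff(d))) == 2) + 1L
  expect_true(all(diff(sc$stem_bp[mins]) >= 10 & diff(sc$stem_bp[mins]) <= 13))
})

test_that("kappa squared hits its closed-form limits and stays in [0, 4]", {
  r <- c(0, 0, 5)
  expect_equal(kappa_squared(c(0, 0, 1), c(0, 0, 1), r), 4)   # head-to-tail
  expect_equal(kappa_squared(c(1, 0, 0), c(1, 0, 0), r), 1)   # parallel, perp to r
  expect_equal(kappa_squared(c(1, 0, 0), c(0, 1, 0), r), 0)   # crossed
  expect_error(kappa_squared(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
               class = "aptafret_undefined_orientation")
  set.seed(7)
  rand_unit <- function(n) {
    m <- matrix(rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  }
  dd <- rand_unit(2000); da <- rand_unit(2000)
  k2 <- vapply(seq_len(2000),
               function(i) kappa_squared(dd[i, ], da[i, ], r), numeric(1))
  expect_true(all(k2 >= 0 & k2 <= 4))
})

test_that("Forster radius scaling laws and efficiency closed forms hold", {
  expect_equal(forster_radius(J = 2e15) / forster_radius(J = 1e15), 2^(1 / 6))
  expect_equal(forster_radius(J = 1e15, kappa2 = 0), 0)
  # constant-folded arithmetic oracle for a reference case
  J <- 1.5e15; k2 <- 2 / 3; Q <- 0.7; nr <- 1.4
  oracle <- (8.79e-5 * k2 * nr^-4 * Q * J)^(1 / 6) / 10
  expect_equal(forster_radius(J, k2, Q, nr), oracle)
  expect_gt(forster_radius(2e15, 1, 0.9, 1.33), forster_radius(1e15, 0.5, 0.5, 1.33))
  expect_error(forster_radius(1e15, Q_D = 0))

  expect_equal(fret_efficiency(5, 5), 0.5)
  expect_equal(fret_efficiency(0, 5), 1)
  expect_equal(fret_efficiency(10, 5), 1 / 65)
  rr <- seq(0.5, 15, by = 0.5)
  expect_true(all(diff(fret_efficiency(rr, 5)) < 0))
  expect_error(fret_efficiency(5, 0))
  # distance minima coincide with efficiency maxima at fixed R0
  sc <- distance_scan(construct_spec(17, 14), "mango", 18:48)
  e <- fret_efficiency(sc$distance_nm, 5)
  expect_equal(which.min(sc$distance_nm), which.max(e))
})
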