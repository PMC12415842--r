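# Rg, end-to-end, ACF/ACT, Kabsch RMSD, RMSF, hull Rh.

test_that("radius of gyration: closed forms and direct formula", {
  m <- toy_model(list(point_res(0, 0, 0), point_res(6, 0, 0)))
  expect_equal(radius_of_gyration(m, 1), 3)           # two equal masses
  # coincident atoms -> 0
  m0 <- toy_model(list(point_res(1, 1, 1), point_res(1, 1, 1)))
  expect_equal(radius_of_gyration(m0, 1), 0)
  # random cloud vs direct computation with masses
  spec <- synthetic_spec(seed = 31, chain_length = 12)
  mc <- generate_chain(spec)
  rg <- radius_of_gyration(mc, 1)
  xyz <- mc$coords[, , 1]; w <- mc$atoms$mass
  com <- colSums(xyz * w) / sum(w)
  expect_equal(rg, sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / sum(w)),
               tolerance = 1e-12)
  # unweighted differs when masses differ
  expect_false(isTRUE(all.equal(
    radius_of_gyration(mc, 1, mass_weighted = FALSE), rg)))
})

test_that("end-to-end distance uses terminal CA atoms", {
  # straight 10-bead chain at 3.8 A spacing -> 34.2
  beads <- lapply(0:9, function(k) point_res(3.8 * k, 0, 0))
  m <- toy_model(beads)
  expect_equal(end_to_end(m, 1), 34.2)
  # near-closed ring -> about one bond
  ring <- lapply(0:9, function(k) {
    a <- 2 * pi * k / 10
    point_res(10 * cos(a), 10 * sin(a), 0)
  })
  mr <- toy_model(ring)
  expect_equal(end_to_end(mr, 1),
               sqrt(sum((c(10 * cos(2 * pi * 0.9), 10 * sin(2 * pi * 0.9), 0)
                         - c(10, 0, 0))^2)), tolerance = 1e-9)
  # missing terminal CA errors
  noca <- toy_model(list(point_res(0, 0, 0, name = "CB"),
                         point_res(5, 0, 0)))
  expect_error(end_to_end(noca, 1), "CA")
})

test_that("ACF: white-noise null, AR(1) closed form, degenerate input", {
  set.seed(123)
  wn <- rnorm(1e5)
  a <- autocorrelation(wn, max_lag = 100)
  expect_equal(a$acf[1], 1)
  expect_lt(max(abs(a$acf[-1])), 0.02)
  # AR(1), phi = 0.9: ACT = (1 + phi) / (1 - phi) = 19
  phi <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
  act <- autocorrelation(x, max_lag = 2000)$act
  expect_lt(abs(act - 19) / 19, 0.2)
  expect_warning(ac <- autocorrelation(rep(2, 100)), "constant")
  expect_equal(ac$acf[1], 1)
  expect_true(all(ac$acf[-1] == 0))
})

test_that("Kabsch RMSD: rigid copy, chirality, analytic displacement", {
  set.seed(8)
  X <- matrix(rnorm(45), 15)
  R <- random_proper_rotation()
  Y <- sweep(X %*% R, 2, c(3, -2, 5), "+")
  expect_lt(kabsch_rmsd(Y, X, 1:15), 1e-9)
  # mirror image is not matched by a proper rotation
  Xm <- X; Xm[, 1] <- -Xm[, 1]
  expect_gt(kabsch_rmsd(Xm, X, 1:15), 0.1)
  # displace one atom, fit on the others: RMSD over all = a / sqrt(N)
  Y2 <- X; Y2[1, ] <- Y2[1, ] + c(1, 0, 0)
  got <- kabsch_rmsd(Y2, X, fit = 2:15, measure = 1:15)
  expect_equal(got, 1 / sqrt(15), tolerance = 1e-9)
  expect_error(kabsch_rmsd(Y, X, 1:2), "fit")
})

test_that("RMSF: static zero, single oscillating atom, frame order", {
  spec <- synthetic_spec(seed = 3, chain_length = 10, frames = 4)
  m <- generate_chain(spec)
  stat <- m
  for (f in 2:4) stat$coords[, , f] <- stat$coords[, , 1]
  ca <- select_atoms(stat, atom_name = "CA")
  expect_true(all(rmsf(stat, ca) < 1e-9))
  # one atom oscillating +/- a along x about its mean, fit on the rest:
  # RMSF of that atom = a, others 0
  a <- 0.8
  base <- matrix(c(0, 0, 0, 4, 0, 0, 4, 4, 0, 0, 4, 0, 2, 2, 3),
                 5, 3, byrow = TRUE)
  coords <- array(base, c(5, 3, 2))
  coords[5, 1, 1] <- base[5, 1] - a
  coords[5, 1, 2] <- base[5, 1] + a
  mm <- toy_model(lapply(seq_len(5), function(i)
    point_res(base[i, 1], base[i, 2], base[i, 3])))
  mm$coords <- coords
  out <- rmsf(mm, 1:5, fit = 1:4)   # fit on the static atoms
  expect_lt(max(out[1:4]), 1e-9)
  expect_equal(unname(out[5]), a, tolerance = 1e-9)
  # frame permutation leaves RMSF unchanged
  mm2 <- mm; mm2$coords <- mm$coords[, , c(2, 1)]
  expect_equal(rmsf(mm2, 1:5, fit = 1:4), out, tolerance = 1e-9)
})

test_that("rmsd_series tracks a rigid domain through a trajectory", {
  dm <- domain_map("CORE", 5, 14)
  spec <- synthetic_spec(seed = 21, chain_length = 20, frames = 3,
                         domain_map = dm, rigid_domains = "CORE")
  m <- generate_chain(spec)
  core_ca <- select_atoms(m, domain = "CORE", atom_name = "CA")
  rs <- rmsd_series(m, m$coords[, , 1], core_ca)
  expect_lt(max(rs), 1e-6)   # rigid body: exactly superposable
  all_ca <- select_atoms(m, atom_name = "CA")
  rs2 <- rmsd_series(m, m$coords[, , 1], all_ca)
  expect_gt(max(rs2[-1]), 1)
})

test_that("convex hull matches closed forms on known solids", {
  # unit cube (with interior points that must not contribute)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(5)
  pts <- rbind(cube, matrix(runif(60, 0.2, 0.8), 20))
  h <- convex_hull3d(pts)
  expect_equal(h$volume, 1, tolerance = 1e-12)
  expect_equal(h$area, 6, tolerance = 1e-12)
  expect_identical(sort(h$vertices), 1:8)
  # regular tetrahedron: V = edge^3 / (6 sqrt 2)
  tet <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                4, 3, byrow = TRUE)
  edge <- sqrt(8)
  ht <- convex_hull3d(tet)
  expect_equal(ht$volume, edge^3 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_error(convex_hull3d(cbind(1:5, (1:5) * 2, 0 * 1:5)),
               "degenerate|coplanar")
})

test_that("hull Rh: invariances, homogeneity, bounds", {
  spec <- synthetic_spec(seed = 5, chain_length = 60, frames = 1)
  m <- generate_chain(spec)
  h <- hullrad_rh(m, 1)
  expect_gt(h$rh, h$anhydrous_radius)   # hydrated + shape factor
  expect_gte(h$shape_factor, 1)
  set.seed(2)
  R <- random_proper_rotation()
  m2 <- m
  m2$coords[, , 1] <- sweep(m$coords[, , 1] %*% R, 2, c(10, -4, 2), "+")
  h2 <- hullrad_rh(m2, 1)
  expect_equal(h2$rh, h$rh, tolerance = 1e-9)
  m3 <- m; m3$coords <- m$coords * 2
  h3 <- hullrad_rh(m3, 1)
  expect_equal(h3$hull_volume, 8 * h$hull_volume, tolerance = 1e-9)
})

test_that("hull Rh agrees with the independent scipy oracle", {
  oracle <- system.file("extdata", "hullrad_oracle_synthetic.py",
                        package = "condensekit")
  for (seed in c(5, 17)) {
    m <- generate_chain(synthetic_spec(seed = seed, chain_length = 80))
    sel <- select_atoms(m, component = "protein", heavy_only = TRUE)
    h <- hullrad_rh(m, 1, sel)
    tmp <- withr::local_tempfile(fileext = ".txt")
    utils::write.table(m$coords[sel, , 1], tmp, row.names = FALSE,
                       col.names = FALSE)
    out <- system2("python", c(oracle, tmp), stdout = TRUE)
    ref <- as.numeric(strsplit(out, " ")[[1]])
    expect_equal(h$rh, ref[1], tolerance = 1e-6)
    expect_equal(h$hull_volume, ref[2], tolerance = 1e-6)
  }
})

test_that("dimension series unwraps periodic chains before measuring", {
  sl <- synthetic_spec(seed = 61, n_chains = 1, chain_length = 15,
                       frames = 2,
                       slab = list(box = c(30, 30, 60), dense_z = c(20, 40),
                                   n_water = 0, n_na = 0, n_cl = 0))
  m <- generate_slab(sl)
  ds0 <- dimension_series(m)
  # wrap all coordinates into the box: metrics must not change
  m2 <- m
  for (f in 1:2) {
    for (k in 1:3) {
      v <- m2$coords[, k, f]
      m2$coords[, k, f] <- v - m2$box[f, k] * floor(v / m2$box[f, k])
    }
  }
  ds1 <- dimension_series(m2)
  expect_equal(ds1$series$rg, ds0$series$rg, tolerance = 1e-9)
  expect_equal(ds1$series$dee, ds0$series$dee, tolerance = 1e-9)
})
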