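# Superposition, fluctuation metrics, essential dynamics and the
# free-energy landscape machinery.

test_that("Kabsch superposition matches the quaternion oracle", {
  set.seed(42)
  ref <- matrix(rnorm(150), 50, 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  # pure rotation: rmsd 0 after fit, proper rotation returned
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fit <- kabsch_superpose(ref %*% t(Rz), ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # random pair: agree with Horn's quaternion method to 1e-9
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(rnorm(150), 50, 3)
    b <- matrix(rnorm(150), 50, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 atoms")
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD after superposition never exceeds unfitted RMSD", {
  sys <- embed_protein(small_membrane(), 30, radius = 8)
  st <- simulate_frames(sys, 10, motion_model(jitter = 0.8), seed = 3)
  idx <- select_atoms(sys, "protein")
  ref <- frame_coords(st, 1)[idx, ]
  for (k in c(3, 7, 10)) {
    xyz <- frame_coords(st, k)[idx, ]
    raw <- sqrt(mean(rowSums((xyz - ref)^2)))
    expect_lte(kabsch_superpose(xyz, ref)$rmsd, raw + 1e-12)
  }
})

test_that("RMSD and Rg series have the expected closed forms", {
  sys <- embed_protein(small_membrane(), 30, radius = 8)
  frozen <- simulate_frames(sys, 5, motion_model(jitter = 0), seed = 1)
  rs <- rmsd_series(frozen, sys)
  expect_equal(rs$rmsd_nm, rep(0, 5), tolerance = 1e-12)
  expect_equal(rs$time_ps, (0:4) * 200)

  # two unit-mass points 2 A apart: Rg = 1 A = 0.1 nm
  atoms <- data.frame(id = 1:2, name = "CA", resid = 1:2, resname = "ALA",
                      chain = "P", x = c(0, 2), y = 0, z = 0, mass = 1)
  two <- molecular_system(atoms, c(10, 10, 10))
  rg <- rgyr_series(static_stream(two), two)
  expect_equal(rg$rg_nm, 0.1, tolerance = 1e-12)

  # uniform rod of length L: Rg -> L / sqrt(12)
  n <- 400; L <- 40
  rod <- data.frame(id = 1:n, name = "CA", resid = 1:n, resname = "GLY",
                    chain = "P", x = seq(0, L, length.out = n), y = 0, z = 0,
                    mass = 1)
  rodsys <- molecular_system(rod, c(50, 10, 10))
  rgr <- rgyr_series(static_stream(rodsys), rodsys)
  expect_equal(rgr$rg_nm * 10, L / sqrt(12), tolerance = 1e-2)

  expect_error(rmsd_series(frozen, sys, selection = "resname XYZ"), "empty")
})

test_that("RMSF vanishes when frozen and ranks jittered extremities highest", {
  sys <- embed_protein(small_membrane(), 30, radius = 8)
  frozen <- simulate_frames(sys, 5, motion_model(jitter = 0), seed = 1)
  rf <- rmsf(frozen, sys)
  expect_equal(rf$rmsf_nm, rep(0, 30), tolerance = 1e-12)

  # jitter only the five extremity residues: they must rank highest
  idx <- select_atoms(sys, "protein and resid 26:30")
  st <- simulate_frames(sys, 200, motion_model(jitter = 1, jitter_selection = idx),
                        seed = 5)
  rf2 <- rmsf(st, sys, superpose = FALSE)
  top5 <- rf2$resid[order(-rf2$rmsf_nm)][1:5]
  expect_setequal(top5, 26:30)
})

test_that("essential dynamics recovers a scripted one-dimensional motion", {
  # 12 static anchor atoms + 1 atom oscillating along x
  set.seed(8)
  n <- 13
  base <- cbind(runif(n, 0, 20), runif(n, 0, 20), runif(n, 0, 20))
  nf <- 60
  arr <- array(rep(base, nf), dim = c(n, 3, nf))
  amp <- sin(seq(0, 4 * pi, length.out = nf))
  arr[13, 1, ] <- base[13, 1] + 3 * amp
  atoms <- data.frame(id = 1:n, name = "CA", resid = 1:n, resname = "ALA",
                      chain = "P", x = base[, 1], y = base[, 2], z = base[, 3])
  sys <- molecular_system(atoms, c(25, 25, 25))
  st <- frame_stream(arr, sys$box)
  em <- essential_dynamics(st, sys)
  # a single dominant mode aligned with the motion axis
  expect_gt(em$values[1] / sum(em$values), 0.95)
  v1 <- matrix(em$vectors[, 1], ncol = 3, byrow = TRUE)
  # the mode is dominated by the moving atom's x (superposition of the
  # finite anchor set absorbs a small share into rigid-body compensation)
  expect_gt(abs(v1[13, 1]), 0.8)
  expect_equal(which.max(abs(em$vectors[, 1])), 3 * 13 - 2)
  # trace identity: eigenvalue sum = total positional variance
  X <- t(apply(memscape:::superposed_coords(st, 1:n), 3, function(x) as.vector(t(x))))
  expect_equal(sum(em$values), sum(apply(X, 2, stats::var)), tolerance = 1e-8)
  # projections: zero mean, variances equal to eigenvalues
  expect_equal(colMeans(em$projections), rep(0, 3 * n), tolerance = 1e-10,
               ignore_attr = TRUE)
  keep <- em$values > 1e-8
  expect_equal(apply(em$projections, 2, stats::var)[keep], em$values[keep],
               tolerance = 1e-8, ignore_attr = TRUE)

  conf <- interpolate_mode(em, 1, n_conformers = 100)
  expect_equal(dim(conf)[3], 100)
  f <- tempfile(fileext = ".pdb")
  write_structure(sys, f, frames = conf)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 100)
  expect_error(essential_dynamics(frame_stream(arr[, , 1, drop = FALSE], sys$box), sys),
               "2 frames")
})

test_that("mixture fitting recovers well-separated components", {
  # single tight cloud -> K = 1
  one <- synthetic_landscape(1, 500, seed = 3)
  m1 <- fit_density(one$points, K = 1:4, seed = 1)
  expect_equal(m1$K, 1)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-9)

  tri <- synthetic_landscape(3, 3000, seed = 7)
  m3 <- fit_density(tri$points, K = 1:6, seed = 1)
  expect_equal(m3$K, 3)
  # means within 0.05 of the generating centres (after matching)
  for (k in seq_len(3)) {
    d <- sqrt(colSums((m3$means - tri$centers[k, ])^2))
    expect_lt(min(d), 0.05)
  }
  expect_error(fit_density(tri$points[1:20, ], K = 1:6), "10 \\* K")
})

test_that("free energy is zero at the density maximum and basins are exact", {
  tri <- synthetic_landscape(3, 2000, seed = 11)
  m <- fit_density(tri$points, K = 3, seed = 1)
  fes <- free_energy_surface(m, grid = 80)
  expect_equal(min(fes$F), 0)
  expect_equal(fes$F[which.max(fes$density)], 0)

  lab <- cluster_by_density(m, tri$points, grid = 80)
  expect_equal(attr(lab, "n_clusters"), 3)
  # agreement with the naive per-point hill-climbing oracle
  g <- memscape:::landscape_grid(m, 80)
  rho <- matrix(mixture_density(m, as.matrix(expand.grid(x = g$x, y = g$y))), 80, 80)
  ix <- pmin(pmax(findInterval(tri$points[, 1], g$x, all.inside = TRUE), 1), 80)
  iy <- pmin(pmax(findInterval(tri$points[, 2], g$y, all.inside = TRUE), 1), 80)
  peaks <- naive_basins(rho, cbind(ix, iy))
  expect_equal(length(unique(peaks)), 3)
  # identical partitions (same label <-> same peak)
  expect_equal(length(unique(paste(lab, peaks))), 3)

  # K = 1: a single cluster containing every point
  m1 <- fit_density(synthetic_landscape(1, 400, seed = 2)$points, K = 1, seed = 1)
  lab1 <- cluster_by_density(m1, synthetic_landscape(1, 400, seed = 2)$points)
  expect_true(all(lab1 == 1))
})

test_that("a seven-mode landscape yields seven clusters", {
  sev <- synthetic_landscape(7, 4000, seed = 13)
  m <- fit_density(sev$points, K = 1:9, seed = 1)
  lab <- cluster_by_density(m, sev$points)
  expect_equal(attr(lab, "n_clusters"), 7)
  # every true component maps to exactly one recovered cluster
  expect_equal(length(unique(paste(sev$component, lab))), 7)
})
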