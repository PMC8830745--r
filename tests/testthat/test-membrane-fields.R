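# Leaflet assignment, thickness, deformation maps, partial densities,
# mean curvature and area per lipid.

test_that("leaflet assignment is per-frame geometry, covering cholesterol", {
  sys <- small_membrane()
  lf <- assign_leaflets(sys)
  # planar fixture: split equals construction (headgroup z sign)
  a <- sys$atoms
  heads <- a[a$name %in% c("P", "O3"), ]
  built <- ifelse(heads$z > 0, "top", "bottom")
  expect_equal(lf$leaflet[match(heads$resid, lf$resid)], built)
  expect_equal(sum(lf$leaflet == "top") + sum(lf$leaflet == "bottom"), nrow(lf))

  # move one cholesterol across the midplane: its label flips in that frame
  chl <- lf$resid[lf$resname == "CHL" & lf$leaflet == "top"][1]
  xyz <- coords(sys)
  rows <- which(a$resid == chl)
  xyz[rows, 3] <- xyz[rows, 3] - 30
  lf2 <- assign_leaflets(sys, xyz)
  expect_equal(lf2$leaflet[lf2$resid == chl], "bottom")

  flat <- sys
  flat$atoms$z <- 0
  expect_error(assign_leaflets(flat), "degenerate")
})

test_that("thickness equals the phosphate plane separation", {
  sys <- small_membrane()
  st <- static_stream(sys, n_frames = 2)
  th <- average_thickness(st, sys)
  # planes at +/-20.8: recovered within one 1-A histogram bin of 41.6
  expect_lt(abs(th$mean - 41.6), 1)
  # jittered planes (sigma = 1): still within one bin
  stj <- simulate_frames(sys, 100, motion_model(jitter = 1), seed = 2)
  thj <- average_thickness(stj, sys)
  expect_lt(abs(thj$mean - 41.6), 1)
  # symmetric fixture: thickness = 2 x top-leaflet mean |z| within a bin
  p <- select_atoms(sys, "name P and lipid")
  topz <- mean(abs(sys$atoms$z[p][sys$atoms$z[p] > 0]))
  expect_lt(abs(th$mean - 2 * topz), 1)
  # cholesterol-only system has no phosphate: error
  chl <- build_bilayer(bilayer_spec(composition = c(CHL = 8), box_xy = c(40, 40)))
  expect_error(average_thickness(static_stream(chl), chl), "no atoms")
})

test_that("deformation maps are signed outward and recover bump amplitudes", {
  sys <- small_membrane()
  st <- static_stream(sys)
  flat <- deformation_map(st, sys, "top", cell = 4)
  expect_lt(max(abs(flat$values)), 1e-9)

  A <- 2.43
  bump <- apply_deformation(sys, surface_gaussian_bump(A, 15))
  dm <- deformation_map(static_stream(bump), bump, "top", cell = 4)
  # map max near the bump amplitude (reduced only by the leaflet-mean shift)
  p <- select_atoms(sys, "name P")
  top <- sys$atoms$z[p] > 0
  shift <- mean(A * exp(-((sys$atoms$x[p][top] - 40)^2 +
                          (sys$atoms$y[p][top] - 40)^2) / 450))
  expect_equal(max(dm$values), A - shift, tolerance = 0.15)

  # the same bump pushed toward the bilayer centre on the bottom leaflet:
  # negative cells at the centre under the outward-positive convention
  pinch <- apply_deformation(sys, surface_gaussian_bump(A, 15, leaflet = "bottom",
                                                       outward = FALSE))
  dmb <- deformation_map(static_stream(pinch), pinch, "bottom", cell = 4)
  ci <- ceiling(40 / dmb$cell[1])
  expect_lt(dmb$values[ci, ci], 0)

  # symmetric pinch: top and bottom maps agree under the sign convention
  pin2 <- apply_deformation(
    apply_deformation(sys, surface_gaussian_bump(A, 15, leaflet = "top",
                                                 outward = FALSE)),
    surface_gaussian_bump(A, 15, leaflet = "bottom", outward = FALSE))
  mt <- deformation_map(static_stream(pin2), pin2, "top", cell = 8)
  mb <- deformation_map(static_stream(pin2), pin2, "bottom", cell = 8)
  expect_lt(mt$values[5, 5], 0)
  expect_lt(mb$values[5, 5], 0)
  # same field up to leaflet sampling noise
  expect_lt(sqrt(mean((mt$values - mb$values)^2)), 0.25)
})

test_that("partial densities conserve mass and see the protein footprint", {
  sys <- small_membrane()
  st <- static_stream(sys)
  pd <- partial_density(st, sys, "XY", voxel = 8)
  vol <- pd$cell[1] * pd$cell[2] * sys$box[3]
  total <- sum(sys$atoms$mass[startsWith(sys$atoms$class, "lipid:")])
  expect_equal(sum(pd$values) * vol, total, tolerance = 1e-9)
  # uniform in plane: voxel values scatter (Poisson-like) around the slab mean
  expect_lt(stats::sd(pd$values) / mean(pd$values), 0.7)

  emb <- embed_protein(sys, 30, radius = 16)
  pde <- partial_density(static_stream(emb), emb, "XY", voxel = 8)
  ci <- ceiling(40 / pde$cell[1])
  expect_equal(pde$values[ci, ci], 0)
  # annulus away from the footprint keeps its density
  expect_gt(pde$values[1, 1], 0)
  expect_error(partial_density(st, sys, voxel = 1000), "larger")
})

test_that("mean curvature matches analytic oracles", {
  dense <- build_bilayer(bilayer_spec(composition = c(POPC = 20000),
                                      box_xy = c(300, 300), min_spacing = 2),
                         seed = 2)
  flat <- mean_curvature(static_stream(dense), dense, "top", bins = 100)
  expect_lt(max(abs(flat$values)), 1e-6)

  cap <- apply_deformation(dense, surface_spherical_cap(100, r_cap = 60, taper = 60))
  Hc <- mean_curvature(static_stream(cap), cap, "top", bins = 100, q_modes = 12)
  apex <- Hc$values[50, 50]
  expect_lt(abs(apex - 0.01), 0.0005)  # 1/R within 5%

  dense155 <- build_bilayer(bilayer_spec(composition = c(POPC = 20000),
                                         box_xy = c(155, 155), min_spacing = 1),
                            seed = 2)
  A <- 5; sg <- 20
  bump <- apply_deformation(dense155, surface_gaussian_bump(A, sg))
  Hb <- mean_curvature(static_stream(bump), bump, "none", bins = 100, q_modes = 12)
  expect_lt(abs(Hb$values[50, 50] - (-A / sg^2)), 0.05 * A / sg^2)
  # leaflet convention flips the sign: outward bump on top is positive
  Hb2 <- mean_curvature(static_stream(bump), bump, "top", bins = 100, q_modes = 12)
  expect_equal(Hb2$values[50, 50], -Hb$values[50, 50])

  # linearity at small slopes: H(0.1 * surface) ~ 0.1 * H(surface) within 2%
  small <- apply_deformation(dense155, surface_gaussian_bump(A / 10, sg))
  Hs <- mean_curvature(static_stream(small), small, "none", bins = 100, q_modes = 12)
  expect_equal(Hs$values[50, 50] / (0.1 * Hb$values[50, 50]), 1, tolerance = 0.02)
})

test_that("area per lipid follows box area over leaflet count", {
  sys <- build_bilayer(bilayer_spec(composition = c(POPC = 200), box_xy = c(80, 80)),
                       seed = 1)
  apl <- area_per_lipid(static_stream(sys), sys, "top")
  expect_equal(apl$mean, 80 * 80 / 100)
  expect_false(apl$footprint_subtracted)
  # removing lipids at fixed box raises APL by the count ratio
  emb <- embed_protein(sys, 20, radius = 10)
  apl2 <- area_per_lipid(static_stream(emb), emb, "top")
  n_top <- census_totals(emb)
  expect_equal(apl2$mean / apl$mean, 100 / sum(n_top$top))
  expect_gt(apl2$mean, apl$mean)
})
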