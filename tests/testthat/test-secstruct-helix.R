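# Secondary-structure propensity, the 70% consensus rule, per-domain
# composition, and helix bend-angle flexibility.

test_that("the dihedral classifier labels canonical geometries", {
  n <- 20
  helix <- build_peptide(rep(-57, n), rep(-47, n))
  lab <- assign_ss_frame(helix)
  expect_true(all(lab[3:(n - 2)] == "H"))

  strand <- build_peptide(rep(-119, n), rep(113, n))
  labE <- assign_ss_frame(strand)
  expect_true(all(labE[3:(n - 2)] == "E"))

  # extended chain with alternating phi/psi signs: no 4-run alpha, so no H
  phi <- rep(c(-70, 70), n / 2)
  psi <- rep(c(-40, 40), n / 2)
  labC <- assign_ss_frame(build_peptide(phi, psi))
  expect_false(any(labC == "H"))
  expect_true(all(labC %in% c("C", "T")))
})

test_that("missing backbone atoms fall back to coil with a warning", {
  sys <- embed_protein(small_membrane(), 10, radius = 0)  # C-alpha only
  expect_warning(lab <- assign_ss_frame(sys), "backbone")
  expect_true(all(lab == "C"))
})

test_that("propensities sum to one and the 70% boundary is inclusive", {
  m <- emit_ss_labels(3, 5000, list(
    ss_plan(1, c(H = 0.72, C = 0.28)),
    ss_plan(2, c(H = 0.69, C = 0.31)),
    ss_plan(3, c(H = 0.70, C = 0.30))
  ), seed = 1)
  p <- propensity(m)
  expect_equal(unname(rowSums(p)), rep(1, 3))
  cs <- consensus(m)
  expect_equal(cs$label, c("H", "DYNAMIC", "H"))  # 0.72 in; 0.69 out; 0.700 in
  expect_equal(cs$max_fraction[3], 0.70)
  expect_error(propensity(m[, 0, drop = FALSE]), "no frames")
})

test_that("consensus is invariant to frame order and monotone in threshold", {
  set.seed(3)
  m <- emit_ss_labels(40, 200, list(
    ss_plan(1:20, c(H = 0.75, T = 0.25)),
    ss_plan(21:40, c(H = 0.55, C = 0.45))
  ), seed = 4)
  cs <- consensus(m)
  perm <- m[, sample(ncol(m)), drop = FALSE]
  expect_equal(consensus(perm), cs)
  # DYNAMIC fraction non-decreasing in threshold
  dyn <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9),
                function(t) mean(consensus(m, t)$label == "DYNAMIC"), numeric(1))
  expect_true(all(diff(dyn) >= 0))
})

test_that("composition_report reproduces generator-encoded global fractions", {
  # encode the global consensus make-up 41% H, 21% C, 14.34% T, 5.41% E,
  # remainder dynamic, over 10000 residues
  n <- 10000
  counts <- round(n * c(H = 0.41, C = 0.21, T = 0.1434, E = 0.0541))
  dyn <- n - sum(counts)
  bounds <- cumsum(c(0, counts, dyn))
  plans <- list(
    ss_plan((bounds[1] + 1):bounds[2], c(H = 1)),
    ss_plan((bounds[2] + 1):bounds[3], c(C = 1)),
    ss_plan((bounds[3] + 1):bounds[4], c(T = 1)),
    ss_plan((bounds[4] + 1):bounds[5], c(E = 1)),
    ss_plan((bounds[5] + 1):bounds[6], c(H = 0.5, C = 0.5))
  )
  m <- emit_ss_labels(n, 10, plans, seed = 1)
  cs <- consensus(m)
  tab <- data.frame(domain = "ALL", start = 1, end = n, color = "grey")
  rep <- composition_report(cs, tab)
  glob <- rep[rep$domain == "global", ]
  expect_equal(glob$H, 0.41)
  expect_equal(glob$C, 0.21)
  expect_equal(glob$T, 0.1434)
  expect_equal(glob$E, 0.0541)
  expect_equal(glob$DYNAMIC, 1 - 0.41 - 0.21 - 0.1434 - 0.0541)
  expect_equal(glob$H + glob$E + glob$T + glob$C + glob$DYNAMIC, 1)

  # all-H matrix: helix fraction 1 in every domain
  mh <- emit_ss_labels(100, 5, list(ss_plan(1:100, c(H = 1))), seed = 1)
  tab2 <- data.frame(domain = c("A", "B"), start = c(1, 51), end = c(50, 100),
                     color = "x")
  repH <- composition_report(consensus(mh), tab2)
  expect_equal(repH$H[repH$domain %in% c("A", "B")], c(1, 1))

  # empty domain omitted with a warning
  tab3 <- data.frame(domain = c("A", "ZZ"), start = c(1, 5000), end = c(100, 6000),
                     color = "x")
  expect_warning(rep3 <- composition_report(consensus(mh), tab3), "ZZ")
  expect_false("ZZ" %in% rep3$domain)
})

test_that("external label matrices load from CSV and DSSP letters", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("H,H,C", "E,E,E"), f)
  m <- read_label_matrix(f)
  expect_equal(dim(m), c(2, 3))
  expect_equal(m[1, 3], "C")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("G,I,S", "B,-,T"), f2)
  m2 <- read_label_matrix(f2, dssp = TRUE)
  expect_equal(as.vector(m2), c("H", "E", "H", "C", "C", "T"))
  writeLines(c("H,Q"), f2)
  expect_error(read_label_matrix(f2), "alphabet")
})

test_that("a straight helix is rigid and a kinked one flexible", {
  ca <- ideal_helix_ca(40)
  ax <- helix_axis(ca)
  bp <- bend_profile(ax)
  expect_true(all(bp$angle_deg < 1))
  expect_true(all(bp$class == "rigid"))
  # the averaged axis tracks the true axis (x = y = 0)
  expect_lt(max(abs(ax[, 1:2])), 0.6)

  # 30-degree kink at the midpoint
  kinked <- ca
  th <- 30 * pi / 180
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
               byrow = TRUE)
  mid <- kinked[20, ]
  kinked[21:40, ] <- sweep(sweep(kinked[21:40, ], 2, mid) %*% t(Ry), 2, mid, "+")
  bpk <- bend_profile(helix_axis(kinked), span = 12)
  expect_gt(max(bpk$angle_deg), 27)
  expect_lt(max(bpk$angle_deg), 33)
  expect_true("flexible" %in% bpk$class)
  expect_error(helix_axis(ca[1:4, ]), "too short")
})

test_that("bend classes follow the 15-degree boundary semantics", {
  # synthetic axis polylines with exact turn angles
  seg <- function(angle_deg, span = 4) {
    # two straight runs meeting at the given angle
    th <- angle_deg * pi / 180
    a <- cbind(seq(-8, 0, length.out = 9), 0, 0)
    d <- c(cos(th), sin(th), 0)
    b <- t(sapply(1:8, function(i) i * d))
    rbind(a, b)
  }
  cls_at <- function(angle) {
    bp <- bend_profile(seg(angle), span = 4)
    bp$class[which.max(bp$angle_deg)]
  }
  expect_equal(cls_at(25), "flexible")
  expect_equal(cls_at(10), "intermediate")
  expect_equal(cls_at(0.2), "rigid")
  # exactly 15 degrees is intermediate (boundary inclusive downward)
  bp15 <- bend_profile(seg(15), span = 1)
  expect_equal(max(bp15$angle_deg), 15, tolerance = 1e-9)
  expect_equal(bp15$class[which.max(bp15$angle_deg)], "intermediate")

  # smooth arc accumulating ~10 degrees per span: intermediate
  tharc <- seq(0, 50, by = 2.5) * pi / 180
  arc <- cbind(40 * sin(tharc), 40 * (1 - cos(tharc)), 0)
  bpa <- bend_profile(arc, span = 4)
  expect_true(all(bpa$class == "intermediate"))
  expect_equal(mean(bpa$angle_deg), 20, tolerance = 2)
})

test_that("helices are located as H-runs of at least six residues", {
  cs <- data.frame(resid = 1:30,
                   label = c(rep("H", 8), rep("C", 3), rep("H", 5),
                             rep("T", 2), rep("H", 12)))
  h <- find_helices(cs)
  expect_equal(h$start, c(1, 19))
  expect_equal(h$end, c(8, 30))
})
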