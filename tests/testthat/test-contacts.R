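# Contact-shell detection, persistence accounting, stable-residue
# filtering, type frequencies and annotation intersection.

test_that("the 5-A shell boundary is inclusive at the cutoff", {
  mk <- function(gap) {
    atoms <- data.frame(
      id = 1:4, name = c("CA", "P", "C1", "C2"), resid = c(1, 2, 2, 2),
      resname = c("ALA", "POPC", "POPC", "POPC"), chain = c("P", "L", "L", "L"),
      x = c(10, 10 + gap, 10 + gap, 10 + gap), y = 10, z = c(10, 10, 14, 18))
    molecular_system(atoms, c(40, 40, 40))
  }
  expect_equal(nrow(frame_contacts(mk(4.9))), 1)
  expect_equal(nrow(frame_contacts(mk(5.0))), 1)
  expect_equal(nrow(frame_contacts(mk(5.1))), 0)
  # minimum-image: 38 A apart across a 40 A box is a 2 A contact
  expect_equal(nrow(frame_contacts(mk(38))), 1)
})

test_that("grid-accelerated search equals brute force on random fixtures", {
  for (s in 1:100) {
    sys <- random_contact_system(seed = 1000 + s)
    g <- frame_contacts(sys, method = "grid")
    b <- frame_contacts(sys, method = "brute")
    expect_identical(g, b)
  }
})

test_that("persistence accumulates non-consecutive frames exactly", {
  sys <- embed_protein(small_membrane(), 40, radius = 10)
  lips <- sys$residues$resid[startsWith(sys$residues$class, "lipid:")]
  # two episodes for one pair (26 frames total) and one 13-frame pair
  sch <- rbind(contact_schedule(20, lips[1], 0, 16),
               contact_schedule(20, lips[1], 30, 40),
               contact_schedule(25, lips[2], 0, 13))
  st <- simulate_frames(sys, 50, motion_model(jitter = 0.3, schedule = sch),
                        seed = 8)
  tab <- persistence(st, sys, cutoff = 5)
  t1 <- tab[tab$protein_resid == 20 & tab$partner_resid == lips[1], ]
  expect_equal(t1$frames_in_contact, 26)
  expect_equal(t1$contact_time_ns, 26 * 0.2)
  t2 <- tab[tab$protein_resid == 25 & tab$partner_resid == lips[2], ]
  expect_equal(t2$frames_in_contact, 13)
  # frame-order invariance of the totals
  perm <- sample(50)
  stp <- frame_stream(st$coords[, , perm], st$box, dt = st$dt)
  tabp <- persistence(stp, sys, cutoff = 5)
  expect_equal(tabp$frames_in_contact, tab$frames_in_contact)
  # empty schedule, frozen far-apart system: empty table
  tab0 <- persistence(simulate_frames(sys, 3, motion_model(jitter = 0), seed = 1),
                      sys, cutoff = 0.5)
  expect_equal(nrow(tab0), 0)
})

test_that("contact monotonicity in cutoff and persistence threshold", {
  sys <- random_contact_system(seed = 77, n_prot = 8, n_lip = 20)
  c4 <- frame_contacts(sys, cutoff = 4)
  c6 <- frame_contacts(sys, cutoff = 6)
  key <- function(d) paste(d$protein_resid, d$partner_chain, d$partner_resid)
  expect_true(all(key(c4) %in% key(c6)))
})

test_that("stable residues obey the strict more-than-500-ns rule", {
  # synthetic contact table at dt = 200 ps
  tab <- data.frame(
    protein_resid = c(1, 2, 3),
    partner_chain = "L", partner_resid = c(101, 102, 103),
    partner_resname = c("POPC", "POPC", "PSM"),
    partner_kind = c("lipid:POPC", "lipid:POPC", "lipid:PSM"),
    frames_in_contact = c(2600, 2500, 2499),
    contact_time_ns = c(520, 500, 499.8))
  st <- stable_residues(tab, 500)
  expect_equal(st$protein_resid, 1)     # 500.0 and 499.8 are excluded
  expect_equal(st$POPC, 1)
  # designed stable residues are recovered exactly
  sys <- embed_protein(small_membrane(), 20, radius = 14)
  lips <- sys$residues$resid[startsWith(sys$residues$class, "lipid:")]
  design <- c(3, 6, 9, 12, 15, 18)
  sch <- do.call(rbind, lapply(seq_along(design), function(i)
    contact_schedule(design[i], lips[i], 0, 30)))   # 30 of 40 frames = 6 ns
  st2 <- simulate_frames(sys, 40, motion_model(jitter = 0.3, schedule = sch),
                         seed = 3)
  tab2 <- persistence(st2, sys, cutoff = 5)
  got <- stable_residues(tab2, min_time_ns = 5)     # > 5 ns = > 25 frames
  expect_setequal(got$protein_resid, design)
})

test_that("lipid-type frequencies report both tallies, count-ordered", {
  tab <- data.frame(
    protein_resid = c(1:10, 1:3),
    partner_chain = "L", partner_resid = c(101:110, 201:203),
    partner_resname = c(rep("POPC", 10), rep("PSM", 3)),
    partner_kind = c(rep("lipid:POPC", 10), rep("lipid:PSM", 3)),
    frames_in_contact = c(rep(10, 10), rep(40, 3)),
    contact_time_ns = c(rep(2, 10), rep(8, 3)))
  fr <- lipid_type_frequency(tab)
  expect_equal(fr$lipid_type, c("POPC", "PSM"))
  expect_equal(fr$partnerships, c(10, 3))
  expect_equal(fr$frame_events, c(100, 120))
  # persistence filter removes sub-threshold rows
  fr2 <- lipid_type_frequency(tab, min_time_ns = 5)
  expect_equal(fr2$lipid_type, "PSM")
  # ties break alphabetically
  tab$partner_resname[1:3] <- "CHL"
  tab$partner_kind[1:3] <- "lipid:CHL"
  fr3 <- lipid_type_frequency(tab)
  expect_equal(fr3$lipid_type, c("POPC", "CHL", "PSM"))
})

test_that("protein-protein contacts exclude sequence neighbours", {
  # an ideal helix: only i +/- 3 and i +/- 4 survive the +/- 2 exclusion
  ca <- ideal_helix_ca(12)
  atoms <- data.frame(id = 1:12, name = "CA", resid = 1:12, resname = "ALA",
                      chain = "P", x = ca[, 1] + 20, y = ca[, 2] + 20,
                      z = ca[, 3] + 10)
  sys <- molecular_system(atoms, c(40, 40, 40))
  st <- static_stream(sys, n_frames = 3)
  pp <- protein_protein_contacts(st, sys, cutoff = 6, min_time_ns = 0)
  ppAll <- protein_protein_contacts(st, sys, cutoff = 6, min_time_ns = 0,
                                    exclude_window = 0)
  expect_true(all(ppAll$n_partners >= pp$n_partners))
  # with exclusion 2, residue 1 touches only 4 and 5 (6 A reaches ~1 turn)
  expect_true(pp$n_partners[1] < ppAll$n_partners[1])
  # an isolated residue reports zero partners
  iso <- molecular_system(data.frame(id = 1:2, name = "CA", resid = c(1, 50),
                                     resname = "ALA", chain = "P",
                                     x = c(1, 30), y = 1, z = 1), c(40, 40, 40))
  ppi <- protein_protein_contacts(static_stream(iso), iso, cutoff = 5,
                                  min_time_ns = 0)
  expect_equal(ppi$n_partners, c(0, 0))
  # a permanent triad: each member has two stable partners
  tri <- molecular_system(data.frame(id = 1:3, name = "CA", resid = c(1, 10, 20),
                                     resname = "ALA", chain = "P",
                                     x = c(10, 13, 11.5), y = c(10, 10, 12.6),
                                     z = 10), c(40, 40, 40))
  stt <- static_stream(tri, n_frames = 10, dt = 200)
  ppt <- protein_protein_contacts(stt, tri, cutoff = 5, min_time_ns = 0.5)
  expect_equal(ppt$n_partners, c(2, 2, 2))
})

test_that("annotation intersection matches by position and collapses duplicates", {
  ann <- read_annotation(system.file("extdata", "abca1_variants.csv",
                                     package = "memscape"))
  expect_equal(nrow(ann), 11)
  stable <- data.frame(protein_resid = c(ann$residue_id, 2000))
  hit <- annotate_variants(stable, ann)
  expect_equal(nrow(hit), 11)
  expect_true("L694del" %in% hit$variant_label)   # deletion matched by position
  expect_equal(nrow(annotate_variants(data.frame(protein_resid = 1:5), ann)), 0)
  dup <- rbind(ann, ann)
  dup$source <- rep(c("a", "b"), each = 11)
  hit2 <- annotate_variants(stable, dup)
  expect_equal(nrow(hit2), 11)
  expect_true(all(hit2$source == "a;b"))
})
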