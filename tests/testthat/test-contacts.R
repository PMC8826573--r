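test_that("chemical roles follow the standard residue tables", {
  cx <- toy_complex()
  roles <- assignChemRoles(cx$structure)
  a <- atoms(cx$structure)
  nz <- which(a$resname == "LYS" & a$name == "NZ")
  expect_true(all(roles$cation[nz]) && all(roles$donor[nz]))
  cb <- which(a$resname == "ALA" & a$name == "CB")
  expect_true(all(roles$apolar[cb]))
  oe1 <- which(a$resname == "GLU" & a$name == "OE1")
  expect_true(all(roles$anion[oe1]) && all(roles$acceptor[oe1]))
  ## backbone N donates (except proline), backbone O accepts
  bbn <- which(a$name == "N")
  expect_true(all(roles$donor[bbn]))
  expect_true(all(roles$acceptor[a$name == "O"]))
})

test_that("hydrogen bond predicate honors distance and D-H..A angle", {
  st <- make_structure(c("OD1", "ND2", "HD1"),
                       c("ASN", "ASN", "ASN"), c("A", "B", "B"),
                       c(1, 1, 1),
                       rbind(c(2.9, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                       element = c("O", "N", "H"))
  roles <- assignChemRoles(st)
  crit <- contactCriteria(heavy_atom_fallback = FALSE)
  hits <- detectContactsFrame(st, coords(st), roles, 1L, 2:3, crit)
  expect_equal(hits$kind, "hbond")  # d = 2.9, angle 180
  ## bend the hydrogen: angle collapses below 110 degrees, bond vanishes
  st2 <- st
  st2@coords[3, ] <- c(0, 1, 0)
  hits2 <- detectContactsFrame(st2, coords(st2), roles, 1L, 2:3, crit)
  expect_false("hbond" %in% hits2$kind)
  ## under the heavy-atom fallback the distance alone decides
  hits3 <- detectContactsFrame(st2, coords(st2), roles, 1L, 2:3,
                               contactCriteria(heavy_atom_fallback = TRUE))
  expect_true("hbond" %in% hits3$kind)
})

test_that("salt bridge threshold is sharp at 4.0 A", {
  place <- function(d) {
    make_structure(c("OE1", "NZ"), c("GLU", "LYS"), c("A", "B"),
                   c(1, 1), rbind(c(0, 0, 0), c(d, 0, 0)),
                   element = c("O", "N"))
  }
  roles <- assignChemRoles(place(3.9))
  st <- place(3.9)
  expect_equal(detectContactsFrame(st, coords(st), roles, 1L, 2L)$kind,
               "saltbridge")
  st <- place(4.1)
  hits <- detectContactsFrame(st, coords(st), roles, 1L, 2L)
  expect_false("saltbridge" %in% hits$kind)
})

test_that("hydrophobic contacts respect the 4.5 A boundary", {
  place <- function(d) {
    make_structure(c("CB", "CB"), c("ALA", "ALA"), c("A", "B"),
                   c(1, 1), rbind(c(0, 0, 0), c(d, 0, 0)),
                   element = c("C", "C"))
  }
  st <- place(4.6)
  roles <- assignChemRoles(st)
  hits <- detectContactsFrame(st, coords(st), roles, 1L, 2L)
  expect_false("hydrophobic" %in% hits$kind)
  st <- place(4.4)
  expect_true("hydrophobic" %in%
                detectContactsFrame(st, coords(st), roles, 1L, 2L)$kind)
})

test_that("detector agrees exactly with brute force on random frames", {
  cx <- toy_complex()
  sim <- synthTrajectory(cx, n_frames = 55, noise_sigma = 0.4,
                         planted = standard_plants(), seed = 101)
  traj <- sim$traj
  expect_lte(nrow(atoms(traj)), 500)
  roles <- assignChemRoles(traj)
  crit <- contactCriteria(heavy_atom_fallback = FALSE)
  tab <- trajectoryContacts(traj, sim$sel_a, sim$sel_b, crit, roles)
  for (f in seq_len(nFrames(traj))) {
    mine <- tab[tab$frame == f, ]
    expect_identical(sort(paste(mine$kind, mine$ia, mine$ib)),
                     brute_force_contacts(traj@frames[, , f], roles,
                                          sim$sel_a, sim$sel_b, crit))
  }
})

test_that("swapping the domain labels transposes the contacts", {
  cx <- toy_complex()
  st <- cx$structure
  roles <- assignChemRoles(st)
  fwd <- detectContactsFrame(st, coords(st), roles, cx$sel_a, cx$sel_b)
  rev <- detectContactsFrame(st, coords(st), roles, cx$sel_b, cx$sel_a)
  expect_identical(sort(paste(fwd$kind, fwd$ia, fwd$ib)),
                   sort(paste(rev$kind, rev$ib, rev$ia)))
})

test_that("enlarging a distance threshold never removes contacts", {
  cx <- toy_complex()
  st <- cx$structure
  roles <- assignChemRoles(st)
  base <- detectContactsFrame(st, coords(st), roles, cx$sel_a, cx$sel_b,
                              contactCriteria(hydrophobic_max = 4.5))
  wide <- detectContactsFrame(st, coords(st), roles, cx$sel_a, cx$sel_b,
                              contactCriteria(hydrophobic_max = 5.5))
  bk <- base[base$kind == "hydrophobic", ]
  wk <- wide[wide$kind == "hydrophobic", ]
  expect_true(all(paste(bk$ia, bk$ib) %in% paste(wk$ia, wk$ib)))
})

test_that("trajectory scan matches per-frame detection and ground truth", {
  cx <- toy_complex()
  ## static trajectory with a permanent contact: every frame identical
  simst <- synthTrajectory(cx, n_frames = 5, noise_sigma = 0,
                           planted = standard_plants(c(saltbridge = 1)),
                           seed = 1)
  tab <- trajectoryContacts(simst$traj, simst$sel_a, simst$sel_b)
  per_frame <- split(paste(tab$kind, tab$ia, tab$ib), tab$frame)
  expect_length(per_frame, 5)
  expect_length(unique(per_frame), 1)
  ## planted contact appears exactly in the frames the generator drew
  sim <- synthTrajectory(cx, n_frames = 12, noise_sigma = 0.05,
                         planted = standard_plants(c(saltbridge = 0.5)),
                         seed = 7)
  tab2 <- trajectoryContacts(sim$traj, sim$sel_a, sim$sel_b)
  hit <- tab2$residue_a == "A:10" & tab2$residue_b == "B:10" &
    tab2$kind == "saltbridge"
  expect_identical(sort(unique(tab2$frame[hit])),
                   which(sim$truth[[1]]))
  ## an empty interface yields an empty table
  far <- assembleComplex(buildToyDomain(3, 4, "A"),
                         buildToyDomain(3, 4, "B"), dC = 60)
  simf <- synthTrajectory(far, n_frames = 2, noise_sigma = 0, seed = 1)
  tabf <- trajectoryContacts(simf$traj, simf$sel_a, simf$sel_b)
  expect_equal(nrow(tabf), 0)
})

test_that("contact ratios are frame-existence fractions in [0,1]", {
  tab <- data.frame(frame = c(1L, 1L, 3L, 5L), kind = "saltbridge",
                    subtype = NA, ia = 1L, ib = 2L,
                    atom_a = "A:1:NZ", atom_b = "B:1:OE1",
                    residue_a = "A:1", residue_b = "B:1")
  attr(tab, "frame_count") <- 10L
  ## two atom pairs in frame 1 count once
  expect_equal(contactRatio(tab, "A:1", "B:1", "saltbridge"), 0.3)
  expect_equal(contactRatio(tab, "A:1", "B:1", "hbond"), 0)
  expect_equal(contactRatio(tab, "A:9", "B:9"), 0)
  ## frame reordering is irrelevant
  expect_equal(contactRatio(tab[order(-tab$frame), ], "A:1", "B:1",
                            frame_count = 10), 0.3)
  expect_error(contactRatio(tab, "A:1", "B:1", frame_count = 0), ">= 1")
})
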