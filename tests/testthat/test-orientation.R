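test_that("inertia axis finds the long axis with a fixed sign", {
  rod <- cbind(0, 0, seq(0, 9))
  expect_equal(inertiaAxis(rod), c(0, 0, 1), tolerance = 1e-12)
  ## rotated rod: axis co-rotates
  R <- AbInterface:::.rot_about(c(1, 1, 0), 33)
  expect_equal(inertiaAxis(rod %*% R), as.vector(c(0, 0, 1) %*% R),
               tolerance = 1e-9)
  ## a flat rectangular sheet: the smallest-inertia axis lies in the
  ## sheet plane (never the normal, which has the largest eigenvalue)
  g <- as.matrix(expand.grid(x = seq(0, 10, 2), y = seq(0, 4, 1)))
  sheet <- cbind(g, 0)
  ax <- inertiaAxis(sheet, orient_vec = c(1, 0, 0))
  expect_equal(abs(sum(ax * c(0, 0, 1))), 0, tolerance = 1e-9)
  expect_equal(abs(sum(ax * c(1, 0, 0))), 1, tolerance = 1e-9)
  ## degenerate spectrum is refused
  sq <- cbind(as.matrix(expand.grid(0:3, 0:3)), 0)
  expect_error(inertiaAxis(sq), "degenerate")
})

test_that("the assembled complex measures as requested, AC2/BC2 at 90", {
  cx <- toy_complex(torsion = 90, dC = 28)
  ref <- buildReference(cx$structure, cx$sel_a, cx$sel_b)
  m <- measureFrame(ref, coords(cx$structure))
  expect_equal(unname(m), unname(cx$truth), tolerance = 1e-6)
  ## sign convention: negative torsions survive the round trip
  dom_a <- buildToyDomain(7, 6, "A")
  dom_b <- buildToyDomain(7, 6, "B")
  cx2 <- assembleComplex(dom_a, dom_b, torsion = -90, dC = 38)
  ref2 <- buildReference(cx2$structure, cx2$sel_a, cx2$sel_b)
  expect_equal(measureFrame(ref2, coords(cx2$structure))[["AB"]], -90,
               tolerance = 1e-6)
})

test_that("reference construction is an exact fixed point", {
  cx <- toy_complex()
  ref <- buildReference(cx$structure, cx$sel_a, cx$sel_b)
  ## the aligned reference's own principal axis must be +z exactly
  w <- ref@w_a
  p <- inertiaAxis(ref@ref_a, w,
                   orient_vec = ref@ref_a[ref@fit_a[length(ref@fit_a)], ] -
                     ref@ref_a[ref@fit_a[1], ])
  expect_equal(p, c(0, 0, 1), tolerance = 1e-9)
  pb <- inertiaAxis(ref@ref_b, ref@w_b,
                    orient_vec = ref@ref_b[ref@fit_b[length(ref@fit_b)], ] -
                      ref@ref_b[ref@fit_b[1], ])
  expect_equal(pb, c(0, 0, 1), tolerance = 1e-9)
})

test_that("planted rigid motions decompose into the right measures", {
  cx <- toy_complex(torsion = 90, dC = 28)
  st <- cx$structure
  ref <- buildReference(st, cx$sel_a, cx$sel_b)
  a <- atoms(st)
  w <- a$mass
  ha <- cx$sel_a[a$element[cx$sel_a] != "H"]
  hb <- cx$sel_b[a$element[cx$sel_b] != "H"]
  com_a <- colSums(coords(st)[ha, ] * w[ha]) / sum(w[ha])
  com_b <- colSums(coords(st)[hb, ] * w[hb]) / sum(w[hb])
  ch <- (com_b - com_a) / sqrt(sum((com_b - com_a)^2))
  base <- measureFrame(ref, coords(st))
  ## +25 degrees about the center axis: only AB moves, by +25
  x <- coords(st)
  R <- AbInterface:::.rot_about(ch, 25)
  xb <- sweep(x[cx$sel_b, ], 2, com_a)
  x2 <- x; x2[cx$sel_b, ] <- sweep(xb %*% R, 2, com_a, "+")
  m2 <- measureFrame(ref, x2)
  expect_equal(m2[["AB"]] - base[["AB"]], 25, tolerance = 1e-6)
  expect_equal(m2[c("AC1", "AC2", "BC1", "BC2", "dC")],
               base[c("AC1", "AC2", "BC1", "BC2", "dC")],
               tolerance = 1e-6)
  ## +5 A along the center axis: only dC moves, by +5
  x3 <- x; x3[cx$sel_b, ] <- sweep(x[cx$sel_b, ], 2, 5 * ch, "+")
  m3 <- measureFrame(ref, x3)
  expect_equal(m3[["dC"]] - base[["dC"]], 5, tolerance = 1e-6)
  expect_equal(m3[c("AB", "AC1", "AC2", "BC1", "BC2")],
               base[c("AB", "AC1", "AC2", "BC1", "BC2")],
               tolerance = 1e-6)
})

test_that("all six measures are invariant under global rigid motion", {
  cx <- toy_complex()
  ref <- buildReference(cx$structure, cx$sel_a, cx$sel_b)
  x <- coords(cx$structure)
  base <- measureFrame(ref, x)
  set.seed(42)
  for (k in 1:5) {
    R <- AbInterface:::.rot_about(stats::rnorm(3), stats::runif(1, 0, 360))
    t <- stats::rnorm(3, 0, 20)
    m <- measureFrame(ref, sweep(x %*% R, 2, t, "+"))
    expect_equal(unname(m), unname(base), tolerance = 1e-6)
  }
})

test_that("trajectory series recover planted torsions", {
  cx <- toy_complex(torsion = 90, dC = 28)
  ref <- buildReference(cx$structure, cx$sel_a, cx$sel_b)
  ## noise-free: per-frame torsions to 1e-4 degrees
  sim <- synthTrajectory(cx, n_frames = 3, noise_sigma = 0,
                         torsion_series = c(80, 90, 100), seed = 1)
  s <- measureTrajectory(sim$traj, ref)
  expect_equal(nrow(s), 3)
  expect_equal(s$AB, c(80, 90, 100), tolerance = 1e-4)
  ## a static trajectory gives a constant series
  simst <- synthTrajectory(cx, n_frames = 4, noise_sigma = 0, seed = 1)
  sst <- measureTrajectory(simst$traj, ref)
  expect_equal(max(apply(sst[, -1], 2, function(v) diff(range(v)))), 0,
               tolerance = 1e-9)
  ## 0.3 A coordinate noise: mean torsion within 2 degrees at F = 1000
  simn <- synthTrajectory(cx, n_frames = 1000, noise_sigma = 0.3,
                          seed = 17)
  sn <- measureTrajectory(simn$traj, ref)
  expect_lt(abs(mean(sn$AB) - 90), 2)
  ## domain-kind aliases rename the measures
  sa <- measureTrajectory(simst$traj, ref, aliases = "Fv")
  expect_named(sa, c("frame", "HL", "LC1", "LC2", "HC1", "HC2", "dC"))
})

test_that("Gaussian KDE integrates to one and locates the mode", {
  set.seed(9)
  x <- stats::rnorm(10000, 90, 5)
  k <- kdeDensity(x)
  trapz <- sum(diff(k$grid) *
                 (utils::head(k$density, -1) + utils::tail(k$density, -1)) / 2)
  expect_equal(trapz, 1, tolerance = 1e-3)
  expect_lt(abs(k$grid[which.max(k$density)] - 90), 0.5)
  ## smoothing monotonicity: doubling the bandwidth lowers the mode
  k2 <- kdeDensity(x, bandwidth = 2 * k$bandwidth)
  expect_lt(max(k2$density), max(k$density))
  expect_error(kdeDensity(rep(1, 5)), "bandwidth")
  ## mixture density lies between the scaled component densities
  y <- stats::rnorm(10000, 60, 5)
  bw <- k$bandwidth
  kx <- kdeDensity(x, bw); ky <- kdeDensity(y, bw)
  kxy <- kdeDensity(c(x, y), bw)
  at <- function(kd, g) stats::approx(kd$grid, kd$density, g,
                                      yleft = 0, yright = 0)$y
  g <- kxy$grid
  lo <- pmin(at(kx, g), at(ky, g))
  hi <- pmax(at(kx, g), at(ky, g))
  mid <- 0.5 * at(kx, g) + 0.5 * at(ky, g)
  expect_true(all(kxy$density >= lo - 1e-3 & kxy$density <= hi + 1e-3))
  expect_lt(max(abs(kxy$density - mid)), 2e-3)
})

test_that("Kabsch superposition is optimal and reflection-free", {
  cx <- toy_complex()
  x <- coords(cx$structure)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  R <- AbInterface:::.rot_about(c(2, -1, 1), 77)
  y <- sweep(x %*% R, 2, c(1, 2, 3), "+")
  expect_lt(superpose(y, x)$rmsd, 1e-9)
  ## displaced-point RMSD agrees with the independent bio3d fit
  set.seed(3)
  y2 <- x + matrix(stats::rnorm(length(x), 0, 0.5), nrow(x), 3)
  got <- superpose(y2, x)$rmsd
  fit <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(x)), as.vector(t(y2))))
  want <- bio3d::rmsd(as.vector(t(x)), fit)
  expect_equal(got, want, tolerance = 1e-3)  # bio3d prints 3 decimals
  ## proper rotation even when a reflection would fit better
  expect_equal(det(superpose(x[1:4, ] %*% diag(c(-1, 1, 1)),
                             x[1:4, ])$rotation), 1, tolerance = 1e-9)
})

test_that("RMSF measures internal fluctuation, not rigid-body motion", {
  cx <- toy_complex()
  st <- cx$structure
  n <- nrow(atoms(st))
  ## pure rigid-body motion: RMSF ~ 0 after superposition
  frames <- array(NA_real_, c(n, 3, 6))
  x <- coords(st)
  set.seed(11)
  for (f in 1:6) {
    R <- AbInterface:::.rot_about(stats::rnorm(3), stats::runif(1, 0, 90))
    frames[, , f] <- sweep(x %*% R, 2, stats::rnorm(3, 0, 5), "+")
  }
  tr <- structure_as_traj(st, frames)
  r0 <- computeRMSF(tr, cx$sel_a)
  expect_lt(max(r0), 1e-9)
  ## isotropic jitter of sigma: RMSF -> sqrt(3) * sigma
  sim <- synthTrajectory(cx, n_frames = 400, noise_sigma = 0.5, seed = 23)
  r1 <- computeRMSF(sim$traj, cx$sel_a)
  expect_equal(mean(r1), sqrt(3) * 0.5, tolerance = 0.08)
  expect_error(computeRMSF(structure_as_traj(st), cx$sel_a), "2 frames")
})
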