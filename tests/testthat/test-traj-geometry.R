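test_that("the membrane plane is the mean z of upper-leaflet N atoms", {
  prot <- data.frame(residue_id = 1L, x = 0, y = 0, z = 36.1)
  trj <- make_test_traj(prot, mem_z = c(20, 20, 20))
  expect_equal(membrane_plane_z(trj, 1), 20)
  trj2 <- make_test_traj(prot, mem_z = c(19, 20, 21))
  expect_equal(membrane_plane_z(trj2, 1), 20)

  # brute-force summation oracle on 500 jittered atoms
  set.seed(42)
  zz <- 20 + rnorm(500)
  trj3 <- make_test_traj(prot, mem_z = zz)
  acc <- 0
  for (z in zz) acc <- acc + z
  expect_equal(membrane_plane_z(trj3, 1), acc / 500, tolerance = 1e-12)
})

test_that("center of mass handles unit and explicit masses", {
  m <- rbind(c(1, 2, 3))
  expect_equal(com(m), c(1, 2, 3))
  m2 <- rbind(c(0, 0, 0), c(0, 0, 10))
  expect_equal(com(m2)[3], 5)
  # hand-weighted: masses 1 and 3 at z = 0 and 4 -> z = 3
  expect_equal(com(m2 * c(1, 1, 1, 1, 0, 0.4), masses = c(1, 3))[3], 3)
  expect_error(com(m2, integer(0)), "empty")
  expect_error(com(m2, masses = c(1, -1)), "positive")
})

test_that("protein height is signed and translation-consistent", {
  prot <- data.frame(residue_id = 1L, x = 0, y = 0, z = 36.1)
  trj <- make_test_traj(prot, mem_z = c(20, 20, 20))
  expect_equal(protein_height(trj, 1), 16.1)

  # rigid z-shift of the whole system leaves h unchanged
  shifted <- make_test_traj(prot, mem_z = c(20, 20, 20), n_frames = 2,
                            drift = function(k, m) m + (k - 1) * 7)
  expect_equal(protein_height(shifted, 2), protein_height(shifted, 1))

  # COM on the plane -> 0; below the plane -> negative
  trj0 <- make_test_traj(data.frame(residue_id = 1L, x = 0, y = 0, z = 20),
                         mem_z = c(20, 20))
  expect_equal(protein_height(trj0, 1), 0)
  trjn <- make_test_traj(data.frame(residue_id = 1L, x = 0, y = 0, z = 15),
                         mem_z = c(20, 20))
  expect_equal(protein_height(trjn, 1), -5)
})

test_that("in-plane translation leaves all geometry metrics unchanged", {
  sim <- make_docking_sim(height = 18, angle = 30, noise_sd = 0.3,
                          duration_ns = 0.3)
  trj <- sim$trajectory
  shifted <- trj
  shifted$coords[, 1, ] <- shifted$coords[, 1, ] + 13.7
  shifted$coords[, 2, ] <- shifted$coords[, 2, ] - 4.2
  for (k in 1:3) {
    expect_equal(protein_height(shifted, k), protein_height(trj, k))
    expect_equal(entry_height(shifted, k), entry_height(trj, k))
    expect_equal(segment_angle(shifted, k), segment_angle(trj, k),
                 tolerance = 1e-9)
  }
})

test_that("entry height composes com() of the entry residues with the plane", {
  sim <- make_docking_sim(height = 20, angle = 10, noise_sd = 0,
                          duration_ns = 0.2)
  trj <- sim$trajectory
  top <- trj$topology
  idx <- select_atoms(top, chain_tag = "PROT",
                      residue_id = c(129L, 185L, 190L))
  m <- frame_coords(trj, 1)
  expected <- unname(com(m, idx)[3]) - membrane_plane_z(trj, 1)
  expect_equal(entry_height(trj, 1), expected, tolerance = 1e-12)
  expect_equal(entry_height(trj, 1), sim$truth$h_entry[1], tolerance = 1e-9)

  expect_error(entry_height(trj, 1, segment_spec(entry = c(129L, 999L))),
               "999")
})

test_that("segment angle matches closed-form axis orientations", {
  mk <- function(dirvec) {
    n <- 11
    ctr <- t(vapply(seq_len(n), function(i) (i - 6) * 1.5 * dirvec,
                    numeric(3)))
    prot <- data.frame(residue_id = 346:356, x = ctr[, 1], y = ctr[, 2],
                       z = ctr[, 3] + 40)
    make_test_traj(prot, mem_z = c(20, 20, 20))
  }
  expect_equal(segment_angle(mk(c(0, 0, 1)), 1), 90)   # perpendicular
  expect_equal(segment_angle(mk(c(1, 0, 0)), 1), 0)    # in-plane
  expect_equal(segment_angle(mk(c(1, 0, 1) / sqrt(2)), 1), 45,
               tolerance = 1e-9)                        # dot-product form
  # the normal convention is the complement
  expect_equal(segment_angle(mk(c(1, 0, 1) / sqrt(2)), 1,
                             angle_ref = "normal"), 45, tolerance = 1e-9)
  expect_equal(segment_angle(mk(c(1, 0, 0)), 1, angle_ref = "normal"), 90)
  # endpoint-vector cross-check agrees on collinear segments
  expect_equal(segment_angle(mk(c(1, 0, 1) / sqrt(2)), 1,
                             axis_method = "endpoints"), 45,
               tolerance = 1e-9)
  # degenerate segment refused
  degen <- make_test_traj(data.frame(residue_id = 346:356, x = 1, y = 2,
                                     z = 30), mem_z = c(20, 20))
  expect_error(segment_angle(degen, 1), "degenerate")
})

test_that("contact fractions count signed z distances strictly below threshold", {
  # residue fixed 3 A above the plane in all frames -> 100%
  prot <- data.frame(residue_id = c(10L, 11L, 12L),
                     x = 0, y = 0, z = c(23, 25, 40))
  trj <- make_test_traj(prot, mem_z = c(20, 20, 20), n_frames = 5)
  ct <- contact_fractions(trj, threshold = 5)
  expect_equal(ct$f[ct$residue_id == 10L], 100)  # 3 A above
  expect_equal(ct$f[ct$residue_id == 11L], 0)    # exactly 5 A: strict "<"
  expect_equal(ct$f[ct$residue_id == 12L], 0)    # far above

  # residues below the plane count as contacts (signed convention)
  protb <- data.frame(residue_id = 1L, x = 0, y = 0, z = 12)
  trjb <- make_test_traj(protb, mem_z = c(20, 20))
  expect_equal(contact_fractions(trjb)$f, 100)

  # counting oracle: residue below plane half the frames, else at 10 A
  n_fr <- 40
  trjc <- make_test_traj(data.frame(residue_id = 1L, x = 0, y = 0, z = 0),
                         mem_z = c(20, 20), n_frames = n_fr,
                         drift = function(k, m) {
                           m[1, 3] <- if (k <= n_fr / 2) 18 else 30
                           m
                         })
  expect_equal(contact_fractions(trjc)$f, 50)

  # monotone non-decreasing in the threshold
  sim <- make_docking_sim(height = 16, angle = 10, noise_sd = 0.4,
                          duration_ns = 0.5)
  f1 <- contact_fractions(sim$trajectory, threshold = 3)$f
  f2 <- contact_fractions(sim$trajectory, threshold = 5)$f
  f3 <- contact_fractions(sim$trajectory, threshold = 8)$f
  expect_true(all(f2 >= f1) && all(f3 >= f2))

  expect_error(contact_fractions(sim$trajectory, window = c(5, 2)), "window")
  expect_error(contact_fractions(sim$trajectory, threshold = 0), "threshold")
})

test_that("series sampling respects the stride contract", {
  sim <- make_docking_sim(duration_ns = 1, frame_interval = 100)
  s <- sample_series(sim$trajectory, every = 100)
  expect_equal(nrow(s), 10L)   # 1 ns at 100 ps
  expect_equal(s$time_ns, seq(0.1, 1, by = 0.1))
  s2 <- sample_series(sim$trajectory, every = 500)
  expect_equal(nrow(s2), 2L)
  expect_error(sample_series(sim$trajectory, every = 150), "multiple")
})

test_that("Kabsch RMSD matches trivial cases and beats raw RMSD", {
  set.seed(7)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(rmsd(a, a), 0)
  b <- a + rep(c(3, -4, 12), each = 20)
  expect_equal(rmsd(a, b, superpose = TRUE), 0, tolerance = 1e-9)
  expect_equal(rmsd(a, b, superpose = FALSE), 13)  # |(3,-4,12)| = 13

  for (i in 1:5) {
    p <- matrix(rnorm(60), 20, 3)
    q <- matrix(rnorm(60), 20, 3)
    expect_lte(rmsd(p, q, superpose = TRUE),
               rmsd(p, q, superpose = FALSE) + 1e-12)
  }
  expect_error(rmsd(a, a[1:5, ]), "mismatch")
})

test_that("Kabsch RMSD agrees with rotation-search and bio3d oracles", {
  euler_rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  set.seed(99)
  for (rep in 1:3) {
    a <- matrix(rnorm(60, sd = 3), 20, 3)
    b <- sweep(a %*% euler_rot(runif(3, -pi, pi)), 2, c(1, 2, 3), "+") +
      matrix(rnorm(60, sd = 0.4), 20, 3)
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    obj <- function(ang)
      sqrt(mean(rowSums((bc %*% euler_rot(ang) - ac)^2)))
    # coarse grid then generic numeric minimisation (independent of Kabsch)
    grid <- as.matrix(expand.grid(seq(-pi, pi, length.out = 7)[-7],
                                  seq(-pi, pi, length.out = 7)[-7],
                                  seq(-pi, pi, length.out = 7)[-7]))
    vals <- apply(grid, 1, obj)
    best <- optim(grid[which.min(vals), ], obj,
                  control = list(reltol = 1e-14, maxit = 5000))$value
    r_kabsch <- rmsd(a, b, superpose = TRUE)
    expect_lt(abs(r_kabsch - best), 1e-3)
    expect_lte(r_kabsch, best + 1e-9)
    # bio3d rounds its RMSD to 3 decimals
    expect_equal(r_kabsch, bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                                       fit = TRUE),
                 tolerance = 2e-3)
  }
})

test_that("RMSF vanishes for rigid motion and reports true fluctuations", {
  set.seed(31)
  n <- 40
  prot <- data.frame(residue_id = 1:n, x = rnorm(n, sd = 4),
                     y = rnorm(n, sd = 4), z = rnorm(n, sd = 4) + 40)
  rigid <- make_test_traj(prot, n_frames = 8,
                          drift = function(k, m)
                            m + k * rep(c(1, 0, 0.5), each = nrow(m)))
  r <- rmsf(rigid)
  expect_true(all(r$rmsf < 1e-9))

  # one atom oscillating +/- d around its mean has RMSF ~ d (slightly less
  # because the rigid-body fit absorbs a 1/n share of the motion)
  d <- 0.8
  osc <- make_test_traj(prot, n_frames = 10,
                        drift = function(k, m) {
                          m[1, 3] <- m[1, 3] + d * (-1)^k
                          m
                        })
  r2 <- rmsf(osc)
  expect_equal(r2$rmsf[r2$residue_id == 1L], d, tolerance = 0.05)
  expect_true(all(r2$rmsf[-1] < 0.15))
})
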