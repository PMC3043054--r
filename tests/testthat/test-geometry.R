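# Minimum-image distances, unwrapping and Kabsch superposition.

test_that("min distance handles coincidence and direct separation", {
  m <- atom_meta(1L, 1L, "GLY", "CA")
  ion_on_atom <- ion_trajectory(0, 10, matrix(c(1, 1, 1), 1, 3),
                                list(I = matrix(c(1, 1, 1), 1, 3)), m)
  expect_equal(min_distance_series(ion_on_atom)$d, 0)
  sep <- ion_trajectory(0, 10, matrix(0, 1, 3),
                        list(I = matrix(c(0, 0, 0.5), 1, 3)), m)
  expect_equal(min_distance_series(sep)$d, 0.5)
})

test_that("min distance equals the 27-image brute-force scan", {
  set.seed(101)
  for (rep in 1:100) {
    n_at <- sample(2:40, 1)
    box <- runif(1, 2, 8)
    atoms <- matrix(runif(n_at * 3, 0, box), n_at, 3)
    # place the ion near the box edge half the time to stress wrapping
    ion <- if (rep %% 2) runif(3, 0, box) else
      c(runif(1, 0, 0.05), runif(1, box - 0.05, box), runif(1, 0, box))
    m <- atom_meta(seq_len(n_at), rep(1L, n_at), rep("GLY", n_at),
                   rep("CA", n_at))
    traj <- ion_trajectory(0, box, atoms, list(I = matrix(ion, 1, 3)), m)
    got <- min_distance_series(traj)
    want <- oracle_min_distance(atoms, ion, box)
    expect_equal(got$d, unname(want["d"]), tolerance = 1e-12)
    expect_equal(got$nearest_atom, unname(as.integer(want["idx"])))
  }
})

test_that("min distance is invariant under translation and image shifts", {
  set.seed(7)
  box <- 6
  atoms <- matrix(runif(30, 0, box), 10, 3)
  ion <- runif(3, 0, box)
  m <- atom_meta(1:10, rep(1L, 10), rep("GLY", 10), rep("CA", 10))
  base <- min_distance_series(ion_trajectory(0, box, atoms,
                                             list(I = matrix(ion, 1, 3)), m))
  shift <- runif(3, -10, 10)
  d_tr <- min_distance_series(ion_trajectory(
    0, box, sweep(atoms, 2, shift, `+`),
    list(I = matrix(ion + shift, 1, 3)), m))
  expect_equal(d_tr$d, base$d, tolerance = 1e-12)
  atoms2 <- atoms
  atoms2[3, ] <- atoms2[3, ] + c(2, -1, 3) * box  # integer box multiples
  d_im <- min_distance_series(ion_trajectory(0, box, atoms2,
                                             list(I = matrix(ion, 1, 3)), m))
  expect_equal(d_im$d, base$d, tolerance = 1e-12)
})

test_that("hydrogens are excluded by default but can be included", {
  m <- atom_meta(1:2, c(1L, 1L), c("GLY", "GLY"), c("CA", "HA"))
  pc <- rbind(c(0, 0, 1), c(0, 0, 0.2))
  traj <- ion_trajectory(0, 10, pc, list(I = matrix(0, 1, 3)), m)
  expect_equal(min_distance_series(traj)$d, 1)
  expect_equal(min_distance_series(traj, heavy_only = FALSE)$d, 0.2)
})

test_that("unwrapping removes boundary jumps and inverts by re-wrapping", {
  box <- 5
  # ion crossing the +x boundary
  xs <- cbind(seq(4.5, 5.4, by = 0.1) %% box, 1, 1)
  m <- atom_meta(1L, 1L, "GLY", "CA")
  traj <- ion_trajectory(seq_len(nrow(xs)) - 1, box,
                         matrix(0, 1, 3), list(I = xs), m)
  u <- unwrap_ion(traj)
  expect_true(all(diff(u[, 1]) > 0))            # monotone, no -5 jump
  expect_equal(max(abs(diff(u[, 1]) - 0.1)), 0, tolerance = 1e-12)
  expect_equal(wrap_coords(u, rep(box, 3)), xs, tolerance = 1e-12,
               ignore_attr = TRUE)
  # an already-continuous path is unchanged
  xc <- cbind(seq(1, 2, by = 0.1), 1, 1)
  traj2 <- ion_trajectory(seq_len(nrow(xc)) - 1, box, matrix(0, 1, 3),
                          list(I = xc), m)
  expect_equal(unwrap_ion(traj2), xc, ignore_attr = TRUE)
})

test_that("unwrapping matches the exhaustive image-search oracle", {
  set.seed(202)
  m <- atom_meta(1L, 1L, "GLY", "CA")
  for (rep in 1:100) {
    box <- runif(1, 3, 7)
    n <- sample(10:40, 1)
    path <- apply(matrix(rnorm(n * 3, sd = box / 10), n, 3), 2, cumsum)
    wrapped <- wrap_coords(path, rep(box, 3))
    traj <- ion_trajectory(seq_len(n) - 1, box, matrix(0, 1, 3),
                           list(I = wrapped), m)
    u <- unwrap_ion(traj)
    o <- oracle_unwrap(wrapped, box)
    expect_equal(u, o, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("unwrapping refuses sampling coarser than half the box", {
  m <- atom_meta(1L, 1L, "GLY", "CA")
  xs <- rbind(c(0.1, 1, 1), c(2.6, 1, 1))  # 2.5 nm jump in a 5 nm box
  traj <- ion_trajectory(0:1, 5, matrix(0, 1, 3), list(I = xs), m)
  expect_error(unwrap_ion(traj), "half the box")
})

test_that("Kabsch recovers identity and known transforms", {
  set.seed(303)
  P <- matrix(rnorm(30), 10, 3)
  id <- kabsch(P, P)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  for (rep in 1:20) {
    R <- random_rotation()
    tr <- rnorm(3)
    Q <- sweep(P %*% R, 2, tr, `+`)
    back <- kabsch(Q, P)     # must invert the applied transform
    expect_equal(apply_transform_test(Q, back), P, tolerance = 1e-10)
    expect_lt(back$rmsd, 1e-10)
    expect_equal(det(back$rotation), 1, tolerance = 1e-12)
  }
  expect_error(kabsch(cbind(1:5, 2 * (1:5), 3 * (1:5)),
                      matrix(rnorm(15), 5, 3)), "collinear|degenerate")
})

test_that("Kabsch rmsd agrees with Horn's quaternion oracle on noisy pairs", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(4:25, 1)
    P <- matrix(rnorm(n * 3), n, 3)
    Q <- sweep(P %*% random_rotation(), 2, rnorm(3), `+`) +
      matrix(rnorm(n * 3, sd = 0.1), n, 3)
    got <- kabsch(Q, P)$rmsd
    want <- oracle_horn(Q, P)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("superposition is optimal and maps the ion into the protein frame", {
  set.seed(505)
  n_at <- 8L
  ref <- matrix(rnorm(n_at * 3), n_at, 3)
  n_fr <- 5L
  pc <- array(0, dim = c(n_fr, n_at, 3))
  ion <- matrix(0, n_fr, 3)
  for (i in seq_len(n_fr)) {
    R <- random_rotation(); tr <- rnorm(3)
    pc[i, , ] <- sweep(ref %*% R, 2, tr, `+`)
    ion[i, ] <- as.numeric(c(0.5, 0.5, 0.5) %*% R + tr)
  }
  m <- atom_meta(seq_len(n_at), seq_len(n_at), rep("GLY", n_at),
                 rep("CA", n_at))
  traj <- ion_trajectory(seq_len(n_fr) - 1, 50, pc, list(I = ion), m)
  sp <- superpose_to_reference(traj, fit_selection = "heavy", ref_frame = 1)
  # the rigid companion point must be stationary in the protein frame
  expect_lt(max(abs(sweep(sp$ion, 2, sp$ion[1, ]))), 1e-8)
  # optimality: fitted rmsd never exceeds the unfitted rmsd
  for (i in 2:n_fr) {
    raw <- sqrt(mean(rowSums((pc[i, , ] - pc[1, , ])^2)))
    expect_lte(sp$transforms[[i]]$rmsd, raw + 1e-12)
  }
})
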