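# Independent brute-force oracles, deliberately written along different
# algorithmic routes than the package implementations.

# minimum-image distance by explicit enumeration of the 27 periodic images
oracle_min_image_dist <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p + c(i, j, k) * box - q
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

oracle_min_distance <- function(atoms, ion, box) {
  d <- apply(atoms, 1L, function(a) oracle_min_image_dist(a, ion, box))
  c(d = min(d), idx = which.min(d))
}

# unwrap by exhaustive image search: each frame picks the periodic image
# closest to the previous unwrapped position
oracle_unwrap <- function(x, box) {
  out <- x
  for (t in 2:nrow(x)) {
    best <- NULL; bestd <- Inf
    for (i in -3:3) for (j in -3:3) for (k in -3:3) {
      cand <- x[t, ] + c(i, j, k) * box
      dd <- sum((cand - out[t - 1L, ])^2)
      if (dd < bestd) { bestd <- dd; best <- cand }
    }
    out[t, ] <- best
  }
  out
}

# time-origin-averaged MSD by an explicit double loop over frame pairs
oracle_msd <- function(x, max_lag) {
  n <- nrow(x)
  vapply(seq_len(max_lag), function(lag) {
    s <- 0
    for (i in seq_len(n - lag)) s <- s + sum((x[i + lag, ] - x[i, ])^2)
    s / (n - lag)
  }, numeric(1))
}

# residence events by an explicit per-frame state machine with a gap counter
oracle_residence <- function(shells, dt, grace_frames, shell) {
  n <- length(shells)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (shells[i] == shell) {
      start <- i
      last_in <- i
      j <- i + 1L
      while (j <= n) {
        if (shells[j] == shell) {
          last_in <- j
        } else {
          # count the excursion; terminate if it exceeds the grace
          gap <- 0L
          k <- j
          while (k <= n && shells[k] != shell) { gap <- gap + 1L; k <- k + 1L }
          if (gap > grace_frames || k > n) break
          j <- k
          last_in <- j
          next
        }
        j <- j + 1L
      }
      events[[length(events) + 1L]] <-
        c(first = start, last = last_in,
          duration = (last_in - start + 1L) * dt)
      i <- last_in + 1L
    } else i <- i + 1L
  }
  if (length(events)) do.call(rbind, events) else
    matrix(numeric(0), 0L, 3L, dimnames = list(NULL,
                                               c("first", "last", "duration")))
}

# optimal superposition via Horn's quaternion method (eigen decomposition),
# algorithmically independent of the SVD-based Kabsch route
oracle_horn <- function(moving, reference) {
  mc <- colMeans(moving); rc <- colMeans(reference)
  A <- sweep(moving, 2L, mc); B <- sweep(reference, 2L, rc)
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4L, 4L, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
  # row-vector convention: y = x %*% t(R_col) ; rmsd after alignment
  fitted <- sweep(A %*% t(R), 2L, rc, `+`)
  sqrt(mean(rowSums((fitted - reference)^2)))
}

# small random rotation matrix from an axis-angle draw
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# tiny hand-made trajectory used across tests
make_test_traj <- function(n_frames = 3L, n_atoms = 4L, box = 5,
                           seed = 42L) {
  set.seed(seed)
  meta <- atom_meta(seq_len(n_atoms), rep(1L, n_atoms), rep("GLU", n_atoms),
                    c("CA", "CB", "OE1", "OE2")[seq_len(n_atoms)])
  pc <- array(stats::runif(n_frames * n_atoms * 3, 0, box),
              dim = c(n_frames, n_atoms, 3L))
  ion <- matrix(stats::runif(n_frames * 3, 0, box), n_frames, 3L)
  ion_trajectory(0:(n_frames - 1L), box, pc, list(ION = ion), meta)
}

write_test_pdb <- function(path, box = 50) {
  writeLines(c(
    sprintf("CRYST1 %8.3f %8.3f %8.3f  90.00  90.00  90.00 P 1           1",
            box, box, box),
    sprintf(paste0("ATOM  %5d  %-3s GLU A   1    %8.3f%8.3f%8.3f  1.00",
                   "  0.00           %s"),
            1:4, c("CA", "CB", "OE1", "OE2"), c(10, 11, 12, 13),
            rep(10, 4), rep(10, 4), c("C", "C", "O", "O")),
    paste0("HETATM    5 CA    CA A   2      20.000  20.000  20.000  1.00",
           "  0.00          CA"),
    "END"), path)
  path
}

apply_transform_test <- function(x, tr)
  sweep(x %*% tr$rotation, 2L, tr$translation, `+`)
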