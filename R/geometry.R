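# Periodic minimum-image geometry, ion unwrapping and Kabsch superposition.

# minimum-image displacement for an orthorhombic box; d and box recycle
min_image <- function(d, box) d - box * round(d / box)

#' Minimum ion-protein distance per frame
#'
#' For each frame, the minimum over protein atoms of the minimum-image
#' distance between the tracked ion and the atom — the working definition of
#' the ion's distance from the protein surface. Ties are broken toward the
#' lowest `atom_id`.
#'
#' @param traj an `ion_traj`.
#' @param ion_label which tracked ion; default first.
#' @param heavy_only exclude hydrogens (default `TRUE`).
#' @param chunk frames per vectorised block (memory/speed trade-off).
#' @return data.frame of class `"distance_series"` with columns `time`, `d`
#'   (nm) and `nearest_atom` (atom_id).
#' @export
min_distance_series <- function(traj, ion_label = NULL, heavy_only = TRUE,
                                chunk = 2000L) {
  stopifnot(inherits(traj, "ion_traj"))
  ion_label <- ion_label %||% names(traj$ion_coords)[1]
  if (!ion_label %in% names(traj$ion_coords))
    stop("unknown ion label: ", ion_label)
  keep <- if (heavy_only) which(traj$atoms$is_heavy) else
    seq_len(nrow(traj$atoms))
  if (!length(keep)) stop("no protein atoms left after hydrogen filtering")
  ids <- traj$atoms$atom_id[keep]
  x <- traj$ion_coords[[ion_label]]
  n <- n_frames(traj)
  d <- numeric(n); na <- integer(n)

  if (traj$static_protein) {
    P <- traj$protein_coords[keep, , drop = FALSE]
    m <- nrow(P)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      nb <- e - s + 1L
      # (nb*m) x 3 displacement block
      dx <- P[rep(seq_len(m), times = nb), , drop = FALSE] -
        x[rep(s:e, each = m), , drop = FALSE]
      bx <- traj$box[rep(s:e, each = m), , drop = FALSE]
      dx <- min_image(dx, bx)
      dist2 <- matrix(rowSums(dx * dx), nrow = m, ncol = nb)
      j <- max.col(-t(dist2), ties.method = "first")
      d[s:e] <- sqrt(dist2[cbind(j, seq_len(nb))])
      na[s:e] <- ids[j]
    }
  } else {
    for (i in seq_len(n)) {
      P <- protein_frame(traj, i)[keep, , drop = FALSE]
      dx <- min_image(sweep(P, 2L, x[i, ]), traj$box[rep(i, nrow(P)), ,
                                                     drop = FALSE])
      dist2 <- rowSums(dx * dx)
      j <- which.min(dist2)
      d[i] <- sqrt(dist2[j]); na[i] <- ids[j]
    }
  }
  structure(data.frame(time = traj$times, d = d, nearest_atom = na),
            class = c("distance_series", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unwrap an ion's periodic trajectory
#'
#' Rebuilds a continuous path by accumulating minimum-image inter-frame
#' displacements from the first frame. Requires that the true per-frame
#' displacement is below half the box on every axis; larger apparent jumps
#' abort with advice to sample more finely.
#'
#' @param traj an `ion_traj`.
#' @param ion_label which ion; default first.
#' @param tol fraction of the half-box treated as the safe displacement limit.
#' @return `n_frames x 3` matrix of continuous coordinates (nm).
#' @export
unwrap_ion <- function(traj, ion_label = NULL, tol = 0.999) {
  stopifnot(inherits(traj, "ion_traj"))
  ion_label <- ion_label %||% names(traj$ion_coords)[1]
  x <- traj$ion_coords[[ion_label]]
  if (is.null(x)) stop("unknown ion label: ", ion_label)
  n <- nrow(x)
  if (n == 1L) return(x)
  steps <- min_image(diff(x), traj$box[-1, , drop = FALSE])
  lim <- tol * traj$box[-1, , drop = FALSE] / 2
  if (any(abs(steps) >= lim))
    stop("inter-frame ion displacement reaches half the box; the trajectory ",
         "is sampled too coarsely to unwrap - save frames more often")
  cum <- matrix(apply(steps, 2L, cumsum), ncol = 3L)
  rbind(x[1, , drop = FALSE], x[rep(1, n - 1L), , drop = FALSE] + cum)
}

#' Re-wrap continuous coordinates into the periodic box
#'
#' Inverse of [unwrap_ion()] up to whole-box translations: maps each frame's
#' position into `[0, box)` per axis.
#'
#' @param x `n x 3` coordinate matrix (nm).
#' @param box per-frame box matrix or constant vector (nm).
#' @return wrapped `n x 3` matrix.
#' @export
wrap_coords <- function(x, box) {
  if (is.null(dim(box))) box <- matrix(box, nrow(x), 3L, byrow = TRUE)
  x - box * floor(x / box)
}

#' Kabsch rigid-body superposition
#'
#' Least-squares rotation + translation mapping `moving` onto `reference`
#' (both `n x 3`, n >= 3, non-collinear). The returned transform acts as
#' `y = x %*% R + t` on row-vector coordinates.
#'
#' @param moving,reference coordinate matrices with matching rows.
#' @return list of class `"rigid_transform"` with `rotation` (3x3, det +1),
#'   `translation` (length 3) and `rmsd` (nm).
#' @export
kabsch <- function(moving, reference) {
  stopifnot(nrow(moving) == nrow(reference), ncol(moving) == 3L)
  if (nrow(moving) < 3L) stop("need at least 3 fit atoms")
  mc <- colMeans(moving); rc <- colMeans(reference)
  A <- sweep(moving, 2L, mc); B <- sweep(reference, 2L, rc)
  if (min(svd(A)$d) < 1e-10 * max(svd(A)$d, 1e-300))
    stop("degenerate (collinear) fit atom set")
  H <- crossprod(A, B)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  t <- rc - as.numeric(mc %*% R)
  fitted <- sweep(moving %*% R, 2L, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rmsd =", format(x$rmsd), "nm\n")
  invisible(x)
}

apply_transform <- function(x, tr) sweep(x %*% tr$rotation, 2L,
                                         tr$translation, `+`)

#' Superpose a trajectory onto a reference frame
#'
#' Removes global protein rotation and translation: every frame's fit atoms
#' (C-alpha by default) are Kabsch-superposed onto the reference frame, and
#' the same rigid transform is applied to the (unwrapped) ion position, giving
#' ion coordinates in the protein-fixed frame. For a static protein this is
#' the identity and the unwrapped coordinates are returned as-is.
#'
#' @param traj an `ion_traj`.
#' @param ion_label which ion; default first.
#' @param fit_selection `"calpha"` (default), `"heavy"`, or an integer vector
#'   of atom_ids to fit on.
#' @param ref_frame index of the reference frame (default 1).
#' @return list with `ion` (`n x 3` protein-frame ion coordinates) and
#'   `transforms` (list of per-frame `rigid_transform`s).
#' @export
superpose_to_reference <- function(traj, ion_label = NULL,
                                   fit_selection = "calpha", ref_frame = 1L) {
  stopifnot(inherits(traj, "ion_traj"))
  ion_label <- ion_label %||% names(traj$ion_coords)[1]
  xu <- unwrap_ion(traj, ion_label)
  n <- n_frames(traj)
  if (traj$static_protein) {
    id <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                         rmsd = 0), class = "rigid_transform")
    return(list(ion = xu, transforms = rep(list(id), n)))
  }
  sel <- if (is.numeric(fit_selection)) {
    match(fit_selection, traj$atoms$atom_id)
  } else if (identical(fit_selection, "calpha")) {
    which(traj$atoms$atom_name == "CA" &
            traj$atoms$residue_name %in% STANDARD_AA)
  } else if (identical(fit_selection, "heavy")) {
    which(traj$atoms$is_heavy)
  } else stop("fit_selection must be 'calpha', 'heavy' or atom ids")
  if (length(sel) < 3L || anyNA(sel))
    stop("need at least 3 valid fit atoms for superposition")
  ref <- protein_frame(traj, ref_frame)[sel, , drop = FALSE]
  transforms <- vector("list", n)
  ion <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    tr <- kabsch(protein_frame(traj, i)[sel, , drop = FALSE], ref)
    transforms[[i]] <- tr
    ion[i, ] <- apply_transform(xu[i, , drop = FALSE], tr)
  }
  list(ion = ion, transforms = transforms)
}
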