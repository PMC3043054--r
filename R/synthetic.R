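# Seeded synthetic-data generators with exact ground-truth ledgers.
#
# Every generator returns its inputs and exact event bookkeeping alongside
# the data, so each downstream stage can be checked against known truth
# rather than only statistically. Reproducibility contract: identical output
# for identical (parameters, seed); independent substreams are derived from
# the master seed by an explicit integer mix, so adding one generator call
# does not perturb another.

# deterministic 31-bit substream seed from (seed, stream)
mix_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647)
  ((s * 40014 + as.double(stream) * 2082007225 + 1442695040) %%
      2147483562) + 1
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# cm^2/s -> nm^2/ps
# 1 cm^2/s = 1e14 nm^2 / 1e12 ps = 100 nm^2/ps
D_TO_NM2_PER_PS <- 100

#' Free Brownian ion trajectory
#'
#' Isotropic Gaussian steps with per-axis variance `2 D dt`; the continuous
#' path starts at the box centre and is wrapped into the periodic box for
#' the trajectory object (the unwrapped path is returned too).
#'
#' @param D diffusion coefficient, cm^2/s.
#' @param dt time step, ps.
#' @param n_steps number of steps (the trajectory has `n_steps + 1` frames).
#' @param box cubic box length, nm.
#' @param seed integer seed.
#' @return list with `trajectory` (protein-free `ion_traj`), `unwrapped`
#'   (`(n_steps+1) x 3` matrix) and `ledger` (parameters incl. the step
#'   sigma in nm).
#' @export
gen_free_diffusion <- function(D, dt = 1, n_steps = 1e5, box = 10,
                               seed = 1L) {
  if (D < 0 || dt <= 0) stop("D must be >= 0 and dt > 0")
  sigma <- sqrt(2 * D * D_TO_NM2_PER_PS * dt)
  if (sigma >= box / 2)
    stop("step sigma ", sigma, " nm reaches half the box; enlarge the box ",
         "or shorten dt")
  steps <- with_seed(mix_seed(seed, 1L),
                     matrix(stats::rnorm(3L * n_steps, sd = sigma),
                            ncol = 3L))
  x <- rbind(rep(box / 2, 3L),
             matrix(rep(box / 2, 3L), n_steps, 3L, byrow = TRUE) +
               matrix(apply(steps, 2L, cumsum), ncol = 3L))
  times <- (0:n_steps) * dt
  traj <- ion_trajectory(times, box, matrix(numeric(0), 0L, 3L),
                         list(ION = wrap_coords(x, rep(box, 3L))),
                         atom_meta(integer(0), integer(0), character(0),
                                   character(0), character(0)))
  list(trajectory = traj, unwrapped = x,
       ledger = list(D = D, dt = dt, n_steps = n_steps, box = box,
                     sigma = sigma, seed = seed))
}

#' Two-exponential residence-duration sample
#'
#' Draws `n` residence durations from the mixture
#' `w * Exp(tau_fast) + (1 - w) * Exp(tau_slow)` (means in ps). Returns the
#' continuous durations, their half-up frame discretisation (minimum one
#' frame), and optionally an in/out indicator series whose runs reproduce
#' the discretised events under [extract_residence_events()].
#'
#' @param tau_fast,tau_slow component means, ps.
#' @param weight_fast mixture weight of the fast component in `[0, 1]`.
#' @param n number of events.
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @param emit_series also build the indicator series (memory grows with the
#'   total duration; off by default).
#' @param sep_frames frames separating consecutive events in the series
#'   (must exceed the grace bridge used downstream).
#' @return list with `durations` (ps, continuous), `durations_frames`,
#'   `component` (1 = fast, 2 = slow), `series` (or `NULL`) and `ledger`.
#' @export
gen_residence_durations <- function(tau_fast, tau_slow, weight_fast = 0.5,
                                    n = 1000L, dt = 1, seed = 1L,
                                    emit_series = FALSE, sep_frames = 3L) {
  if (tau_fast <= 0 || tau_slow <= 0) stop("time constants must be > 0")
  if (weight_fast < 0 || weight_fast > 1) stop("weight_fast must be in [0,1]")
  if (n < 1L) stop("need n >= 1 events")
  comp <- with_seed(mix_seed(seed, 2L),
                    1L + (stats::runif(n) >= weight_fast))
  dur <- with_seed(mix_seed(seed, 3L),
                   stats::rexp(n, rate = 1) *
                     ifelse(comp == 1L, tau_fast, tau_slow))
  durf <- pmax(1L, as.integer(floor(dur / dt + 0.5)))
  series <- NULL
  if (emit_series) {
    series <- rep(rep(c(TRUE, FALSE), n),
                  times = as.vector(rbind(durf, sep_frames)))
  }
  list(durations = dur, durations_frames = durf, component = comp,
       series = series,
       ledger = list(tau_fast = tau_fast, tau_slow = tau_slow,
                     weight_fast = weight_fast, n = n, dt = dt, seed = seed,
                     n_fast = sum(comp == 1L), n_slow = sum(comp == 2L)))
}

# quasi-uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Overdamped Langevin ion around a rigid pseudo-protein
#'
#' Euler-Maruyama integration of an ion diffusing around a rigid sphere
#' decorated with `n_sites` labelled pseudo-residue sites. A radial Gaussian
#' well of depth `well_depth` (kT units) centred `well_center` nm above the
#' surface attracts the ion; inside `surface_zone` of the surface the
#' diffusion coefficient drops from `D_free` to `D_surface` (two-zone
#' mobility). Reflective walls keep the ion outside the sphere and inside a
#' spherical container of radius `box/2 - 0.2`, so the path never wraps and
#' surface distances are unambiguous.
#'
#' @param n_sites number of surface sites (Fibonacci lattice).
#' @param sphere_radius pseudo-protein radius, nm.
#' @param well_depth well depth in kT (0 switches the interaction off).
#' @param well_center,well_width Gaussian well centre/width above the
#'   surface, nm.
#' @param D_free,D_surface bulk and in-zone diffusion coefficients, cm^2/s.
#' @param surface_zone distance from the surface below which `D_surface`
#'   applies, nm.
#' @param dt step, ps; `n_steps` steps.
#' @param n_steps number of steps.
#' @param box cubic box length, nm.
#' @param seed integer seed.
#' @param contact_cutoff ion-site distance defining a site visit for the
#'   ledger, nm.
#' @return list with `trajectory` (`ion_traj`; sites are the protein atoms,
#'   named pseudo-Glu carboxylate oxygens), `dist_surface` (analytic
#'   distance above the sphere surface per frame, nm), `site_contact`
#'   (nearest site id within `contact_cutoff`, 0 when none), `unwrapped`
#'   ion path and `ledger` (all parameters, site coordinates, site-visit
#'   run table).
#' @export
gen_langevin_surface <- function(n_sites = 32L, sphere_radius = 1.0,
                                 well_depth = 5, well_center = 0.2,
                                 well_width = 0.12,
                                 D_free = 1.584e-5, D_surface = 0.166e-5,
                                 surface_zone = 0.35, dt = 1,
                                 n_steps = 1e5, box = 8, seed = 1L,
                                 contact_cutoff = 0.35) {
  if (well_depth < 0) stop("well_depth must be >= 0")
  Df <- D_free * D_TO_NM2_PER_PS
  Ds <- D_surface * D_TO_NM2_PER_PS
  # stability: drift per step must stay well below the well width
  fmax <- if (well_depth > 0) well_depth / well_width * exp(-0.5) else 0
  if (max(Df, Ds) * fmax * dt > 0.5 * well_width)
    stop("unstable step: D * max|dU/dd| * dt exceeds half the well width; ",
         "reduce dt")
  ctr <- rep(box / 2, 3L)
  sites <- sweep(fibonacci_sphere(n_sites, sphere_radius), 2L, ctr, `+`)
  z <- with_seed(mix_seed(seed, 4L),
                 matrix(stats::rnorm(3L * n_steps), ncol = 3L))
  x <- matrix(0, n_steps + 1L, 3L)
  # start in the bulk, halfway between surface and box edge
  x[1, ] <- ctr + c(sphere_radius + (box / 2 - sphere_radius) / 2, 0, 0)
  d_surf <- numeric(n_steps + 1L)
  pos <- x[1, ]
  wall <- 0.02          # reflective offset above the sphere, nm
  r_max <- box / 2 - 0.2  # reflective outer container radius, nm
  for (i in seq_len(n_steps)) {
    rv <- pos - ctr
    r <- sqrt(sum(rv * rv))
    d <- r - sphere_radius
    d_surf[i] <- d
    Dl <- if (d < surface_zone) Ds else Df
    drift <- 0
    if (well_depth > 0) {
      # U(d) = -depth * exp(-(d - d0)^2 / (2 w^2)), kT units
      dU <- well_depth * (d - well_center) / well_width^2 *
        exp(-(d - well_center)^2 / (2 * well_width^2))
      drift <- -Dl * dU * dt
    }
    pos <- pos + drift * rv / r + sqrt(2 * Dl * dt) * z[i, ]
    rv <- pos - ctr
    r <- sqrt(sum(rv * rv))
    if (r < sphere_radius + wall) {  # reflect radially off the inner wall
      pos <- ctr + rv / r * (2 * (sphere_radius + wall) - r)
    } else if (r > r_max) {          # reflect off the outer container
      pos <- ctr + rv / r * (2 * r_max - r)
    }
    x[i + 1L, ] <- pos
  }
  d_surf[n_steps + 1L] <- sqrt(sum((pos - ctr)^2)) - sphere_radius
  times <- (0:n_steps) * dt

  # nearest-site contact per frame (chunked), for the visit ledger
  nfr <- n_steps + 1L
  site_contact <- integer(nfr)
  chunk <- 20000L
  for (s in seq(1L, nfr, by = chunk)) {
    e <- min(s + chunk - 1L, nfr)
    d2 <- sapply(seq_len(n_sites), function(j)
      rowSums(sweep(x[s:e, , drop = FALSE], 2L, sites[j, ])^2))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
    jmin <- max.col(-d2, ties.method = "first")
    hit <- d2[cbind(seq_len(e - s + 1L), jmin)] <= contact_cutoff^2
    site_contact[s:e] <- ifelse(hit, jmin, 0L)
  }
  r <- rle(site_contact)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vi <- which(r$values > 0L)
  visits <- data.frame(site = r$values[vi], first_frame = starts[vi],
                       last_frame = ends[vi])

  meta <- atom_meta(seq_len(n_sites), seq_len(n_sites),
                    rep("GLU", n_sites), rep("OE1", n_sites),
                    rep("O", n_sites))
  traj <- ion_trajectory(times, box, sites,
                         list(ION = wrap_coords(x, rep(box, 3L))), meta)
  list(trajectory = traj, dist_surface = d_surf,
       site_contact = site_contact, unwrapped = x,
       ledger = list(n_sites = n_sites, sphere_radius = sphere_radius,
                     well_depth = well_depth, well_center = well_center,
                     well_width = well_width, D_free = D_free,
                     D_surface = D_surface, surface_zone = surface_zone,
                     dt = dt, n_steps = n_steps, box = box, seed = seed,
                     contact_cutoff = contact_cutoff, sites = sites,
                     visits = visits))
}

#' Markov surface-hopping contact generator
#'
#' Continuous-time Markov chain over `{bulk, site_1, ..., site_k}`: from the
#' bulk the ion lands on a uniformly chosen site at `arrival_rate`; from a
#' site it hops to another uniformly chosen site at `hop_rate` (total) or
#' escapes to the bulk at `escape_rate`. The continuous state path is
#' discretised to the frame grid (boundaries rounded half-up) and the exact
#' discrete bookkeeping — every site run labelled primary (arrived from
#' bulk) or secondary (site-to-site hop, with origin), pair transfer counts,
#' and the headline summary statistics — is emitted as the ledger.
#'
#' @param n_sites number of surface sites.
#' @param arrival_rate,hop_rate,escape_rate rates in 1/ps.
#' @param n_events target number of site arrivals (primary + secondary).
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @return list with `indicator` (frames x sites logical matrix, columns
#'   `site1...`), `first_shell` (logical), `times`, `state` (0 = bulk) and
#'   `ledger` (parameters, continuous path, discrete `events`, `transfers`,
#'   `summary`).
#' @export
gen_hopping_contacts <- function(n_sites = 4L, arrival_rate = 0.01,
                                 hop_rate = 0.02, escape_rate = 0.05,
                                 n_events = 200L, dt = 1, seed = 1L) {
  if (arrival_rate <= 0 || escape_rate <= 0 || hop_rate < 0)
    stop("arrival and escape rates must be > 0, hop_rate >= 0")
  if (n_sites < 1L) stop("need at least one site")
  if (n_sites == 1L && hop_rate > 0)
    stop("hopping requires at least two sites")
  seg_state <- integer(0); seg_t0 <- numeric(0); seg_t1 <- numeric(0)
  with_seed(mix_seed(seed, 5L), {
    state <- 0L; t <- 0; arrivals <- 0L
    while (arrivals < n_events || state != 0L) {
      if (state == 0L) {
        tau <- stats::rexp(1, arrival_rate)
        nxt <- sample.int(n_sites, 1L)
        arrivals <- arrivals + 1L
      } else {
        rtot <- hop_rate + escape_rate
        tau <- stats::rexp(1, rtot)
        if (stats::runif(1) < hop_rate / rtot) {
          others <- setdiff(seq_len(n_sites), state)
          nxt <- others[sample.int(length(others), 1L)]
          arrivals <- arrivals + 1L
        } else nxt <- 0L
      }
      seg_state <- c(seg_state, state)
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t + tau)
      t <- t + tau; state <- nxt
      if (arrivals >= n_events && state == 0L) {
        # close with a final bulk stretch so the last site run has an exit
        seg_state <- c(seg_state, 0L)
        seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t + 5 / arrival_rate)
        break
      }
    }
  })
  continuous <- data.frame(state = seg_state, t0 = seg_t0, t1 = seg_t1)

  # discretise: frame f (1-based) covers time (f-1)*dt; boundary rounded
  # half-up to the nearest frame
  f0 <- as.integer(floor(seg_t0 / dt + 0.5)) + 1L
  f1 <- as.integer(floor(seg_t1 / dt + 0.5))
  nfr <- max(f1)
  state_fr <- integer(nfr)
  for (i in seq_along(seg_state))
    if (f1[i] >= f0[i]) state_fr[f0[i]:f1[i]] <- seg_state[i]
  times <- (seq_len(nfr) - 1L) * dt

  r <- rle(state_fr)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  site_runs <- which(r$values > 0L)
  ev <- lapply(site_runs, function(k) {
    prev <- if (k == 1L) 0L else r$values[k - 1L]
    data.frame(site = r$values[k], first_frame = starts[k],
               last_frame = ends[k],
               classification = if (prev == 0L) "primary" else "secondary",
               origin = if (prev == 0L) NA_integer_ else prev,
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(site = integer(0), first_frame = integer(0),
               last_frame = integer(0), classification = character(0),
               origin = integer(0))

  sec <- events[events$classification == "secondary", , drop = FALSE]
  transfers <- if (nrow(sec)) {
    a <- pmin(sec$origin, sec$site); b <- pmax(sec$origin, sec$site)
    agg <- stats::aggregate(list(count = rep(1L, length(a))),
                            data.frame(site_a = a, site_b = b), sum)
    agg[order(agg$site_a, agg$site_b), , drop = FALSE]
  } else data.frame(site_a = integer(0), site_b = integer(0),
                    count = integer(0))
  rownames(transfers) <- NULL

  np <- sum(events$classification == "primary")
  ns <- sum(events$classification == "secondary")
  total_time <- nfr * dt
  summary <- list(
    n_primary = np, n_secondary = ns,
    ratio = if (np > 0L) ns / np else NA_real_,
    mean_primary_interval = if (np > 0L) total_time / np else NA_real_,
    mean_secondary_interval = if (ns > 0L) total_time / ns else NA_real_,
    mean_concurrency = if (any(state_fr > 0L)) 1 else NA_real_,
    free_fraction = mean(state_fr == 0L))

  indicator <- matrix(FALSE, nfr, n_sites,
                      dimnames = list(NULL, paste0("site", seq_len(n_sites))))
  for (j in seq_len(n_sites)) indicator[, j] <- state_fr == j

  list(indicator = indicator, first_shell = state_fr > 0L, times = times,
       state = state_fr,
       ledger = list(n_sites = n_sites, arrival_rate = arrival_rate,
                     hop_rate = hop_rate, escape_rate = escape_rate,
                     n_events = n_events, dt = dt, seed = seed,
                     continuous = continuous, events = events,
                     transfers = transfers, summary = summary,
                     total_time = total_time))
}
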