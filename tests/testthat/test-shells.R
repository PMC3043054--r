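# Shell assignment, occupancy, residence extraction, survival curves and
# exponential fitting.

test_that("shell assignment uses half-open layers with a bulk sentinel", {
  sch <- shell_scheme()
  expect_equal(assign_shells(0.30, sch), 1L)   # d < 0.35
  expect_equal(assign_shells(0.45, sch), 2L)   # 0.35 < d < 0.6
  expect_equal(assign_shells(5.0, sch), sch$bulk_index)
  # boundary value belongs to the outer shell (half-open convention)
  expect_equal(assign_shells(0.35, sch), 2L)
  expect_equal(assign_shells(0, sch), 1L)
  expect_error(shell_scheme(c(0.6, 0.35)), "increasing")
})

test_that("per-frame shell occupancy fractions sum to one", {
  set.seed(11)
  sch <- shell_scheme()
  sh <- assign_shells(runif(5000, 0, 3), sch)
  frac <- table(factor(sh, levels = seq_len(sch$bulk_index))) / 5000
  expect_equal(sum(frac), 1)
})

test_that("occupancy histogram normalises within d_max and accumulates", {
  # point mass: one bin holds 100%
  h <- occupancy_histogram(rep(0.2, 50), bin_width = 0.01)
  expect_equal(max(h$percent), 100)
  expect_equal(sum(h$percent), 100)
  # frames beyond d_max are excluded from the denominator
  h2 <- occupancy_histogram(c(rep(0.2, 50), rep(2.0, 950)), bin_width = 0.01)
  expect_equal(max(h2$percent), 100)
  # uniform draw matches direct per-bin counting exactly
  set.seed(12)
  d <- runif(2000, 0, 1.2)
  h3 <- occupancy_histogram(d, bin_width = 0.1, d_max = 1.2)
  direct <- vapply(seq_len(nrow(h3)), function(i)
    100 * sum(d >= h3$d_lo[i] & d < h3$d_hi[i]) / length(d), numeric(1))
  expect_equal(h3$percent, direct)
  expect_equal(h3$cumulative, cumsum(direct))
  expect_error(occupancy_histogram(rep(5, 10)), "no frames")
})

test_that("short excursions are bridged, longer ones terminate residence", {
  # 10 in, 2 out, 10 in at dt = 1 ps -> one 22 ps event
  sh <- c(rep(1L, 10), rep(2L, 2), rep(1L, 10), rep(9L, 5))
  ev <- extract_residence_events(sh, seq_along(sh) - 1, grace_time = 2,
                                 shell_set = 1L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 22)
  # 3 ps excursion exceeds the grace -> two 10 ps events
  sh2 <- c(rep(1L, 10), rep(2L, 3), rep(1L, 10), rep(9L, 5))
  ev2 <- extract_residence_events(sh2, seq_along(sh2) - 1, grace_time = 2,
                                  shell_set = 1L)
  expect_equal(ev2$duration, c(10, 10))
})

test_that("exit directions follow the shell entered at termination", {
  sh <- c(rep(2L, 5), rep(1L, 5), rep(2L, 5), rep(3L, 5), rep(2L, 4))
  ev <- extract_residence_events(sh, seq_along(sh) - 1, grace_time = 0)
  e2 <- ev[ev$shell == 2L, ]
  expect_identical(e2$exit_direction, c("inward", "outward", "end_of_data"))
  e1 <- ev[ev$shell == 1L, ]
  expect_identical(e1$exit_direction, "outward")
})

test_that("residence extraction matches the state-machine oracle on random series", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(30:120, 1)
    sh <- sample(1:4, n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
    g <- sample(0:3, 1)
    for (s in 1:4) {
      ev <- extract_residence_events(sh, seq_len(n) - 1, grace_time = g,
                                     shell_set = s)
      o <- oracle_residence(sh, 1, g, s)
      expect_equal(nrow(ev), nrow(o))
      if (nrow(o)) {
        expect_equal(ev$first_frame, unname(o[, "first"]))
        expect_equal(ev$last_frame, unname(o[, "last"]))
        expect_equal(ev$duration, unname(o[, "duration"]))
      }
    }
  }
})

test_that("bridging is idempotent on the event indicator series", {
  set.seed(22)
  for (rep in 1:20) {
    n <- 200L
    sh <- sample(c(1L, 9L), n, replace = TRUE, prob = c(0.6, 0.4))
    ev <- extract_residence_events(sh, seq_len(n) - 1, grace_time = 2,
                                   shell_set = 1L)
    # rebuild the indicator implied by the events (bridged gaps included)
    ind <- rep(9L, n)
    for (i in seq_len(nrow(ev))) ind[ev$first_frame[i]:ev$last_frame[i]] <- 1L
    ev2 <- extract_residence_events(ind, seq_len(n) - 1, grace_time = 2,
                                    shell_set = 1L)
    expect_equal(ev2$first_frame, ev$first_frame)
    expect_equal(ev2$last_frame, ev$last_frame)
  }
})

test_that("event durations never exceed the trajectory span", {
  set.seed(23)
  n <- 500L
  sh <- sample(1:9, n, replace = TRUE)
  ev <- extract_residence_events(sh, seq_len(n) - 1, grace_time = 2)
  for (s in unique(ev$shell))
    expect_lte(sum(ev$duration[ev$shell == s]), n * 1)
})

test_that("survival curve counts events lasting at least t", {
  sc1 <- survival_curve(5, dt = 1)
  expect_true(all(sc1$N[sc1$t <= 5] == 1))
  expect_true(all(sc1$N[sc1$t > 5] == 0))
  sc <- survival_curve(c(3, 5, 5, 9), dt = 1)
  expect_equal(sc$N[sc$t == 4], 3)
  expect_equal(sc$N[1], 4)            # N(0) = number of events
  expect_true(all(diff(sc$N) <= 0))   # non-increasing
  expect_error(survival_curve(numeric(0)), "no events")
})

test_that("noiseless single-exponential data is recovered near-exactly", {
  tg <- 0:2000
  N <- 1000 * exp(-tg / 100)
  fit <- fit_exponential(data.frame(t = tg, N = N), order = 1)
  expect_equal(fit$tau, 100, tolerance = 1e-6)
  expect_lt(fit$rel_rms_error, 1e-8)
  expect_equal(unname(coef(fit)["A1"]), 1000, tolerance = 1e-6)
})

test_that("bi-exponential fits recover mixture constants and beat order 1", {
  g <- gen_residence_durations(3.611, 212.193, 0.5, n = 1e5, seed = 31)
  sc <- survival_curve(g$durations, dt = 1)
  f2 <- fit_exponential(sc, order = 2)
  expect_lt(abs(f2$tau[2] / 212.193 - 1), 0.10)
  expect_lt(abs(f2$tau[1] / 3.611 - 1), 0.10)
  expect_lt(f2$tau[1], f2$tau[2])     # reported ascending
  f1 <- fit_exponential(sc, order = 1)
  expect_gt(f1$rel_rms_error, f2$rel_rms_error)  # nested-model property
  # points with N <= 10 are excluded from the fit
  expect_true(all(f2$data$N > 10))
  # model-object surface behaves like a classic fit
  expect_named(coef(f2), c("A1", "A2", "tau1", "tau2"))
  expect_equal(predict(f2, 0), sum(f2$A), tolerance = 1e-12)
  expect_equal(length(residuals(f2)), f2$n_retained)
})

test_that("fit is deterministic and refuses underdetermined curves", {
  g <- gen_residence_durations(2, 20, 0.5, n = 2000, seed = 32)
  sc <- survival_curve(g$durations, dt = 1)
  fa <- fit_exponential(sc, order = 2)
  fb <- fit_exponential(sc, order = 2)
  expect_identical(coef(fa), coef(fb))
  expect_error(fit_exponential(data.frame(t = 0:3, N = c(100, 50, 20, 12)),
                               order = 2), "insufficient points")
})

test_that("directional residence means split by exit direction", {
  ev <- structure(data.frame(
    shell = c(2L, 2L, 2L, 2L),
    t_start = c(0, 20, 40, 60), t_end = c(10, 25, 52, 61),
    duration = c(10, 5, 12, 1),
    first_frame = c(1L, 21L, 41L, 61L), last_frame = c(10L, 25L, 52L, 61L),
    exit_direction = c("inward", "outward", "inward", "outward")),
    class = c("residence_events", "data.frame"))
  dr <- directional_residence(ev)
  expect_equal(dr$mean_duration[dr$direction == "inward"], 11)
  expect_equal(dr$mean_duration[dr$direction == "outward"], 3)
  expect_error(directional_residence(ev[ev$exit_direction == "inward", ],
                                     "outward"), "no events")
})

test_that("an asymmetric inner barrier yields inward residence longer than outward", {
  # two-shell world: ions entering shell 2 from inside linger (slow mixture
  # component), ions passing outward leave quickly
  set.seed(33)
  durs_in <- rexp(400, 1 / 50)
  durs_out <- rexp(400, 1 / 20)
  ev <- structure(data.frame(
    shell = 2L,
    t_start = 0, t_end = 1,
    duration = c(durs_in, durs_out),
    first_frame = 1L, last_frame = 2L,
    exit_direction = rep(c("inward", "outward"), each = 400)),
    class = c("residence_events", "data.frame"))
  dr <- directional_residence(ev)
  ratio <- dr$mean_duration[dr$direction == "inward"] /
    dr$mean_duration[dr$direction == "outward"]
  expect_gt(ratio, 1)
})
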