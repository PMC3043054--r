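# Contact detection and primary/secondary encounter bookkeeping.

test_that("a parked ion yields one residue contact covering all frames", {
  n <- 50L
  m <- atom_meta(1:2, c(60L, 60L), c("GLU", "GLU"), c("OE1", "CB"))
  pc <- rbind(c(1, 1, 1), c(1.8, 1, 1))
  ion <- matrix(rep(c(1.25, 1, 1), each = n), n, 3)  # 0.25 nm from OE1
  traj <- ion_trajectory(seq_len(n) - 1, 10, pc, list(I = ion), m)
  ci <- detect_contacts(traj, cutoff = 0.35)
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$entity, "GLU60")
  expect_equal(ci$duration, 50)
})

test_that("1-frame gaps inside a contact are bridged by the grace rule", {
  ind <- matrix(c(rep(TRUE, 10), FALSE, rep(TRUE, 10)), ncol = 1,
                dimnames = list(NULL, "GLU60"))
  ci <- contacts_from_indicator(ind, 0:20, grace_time = 2)
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$duration, 21)
  ci0 <- contacts_from_indicator(ind, 0:20, grace_time = 0)
  expect_equal(nrow(ci0), 2L)
})

test_that("contact intervals match a run-length oracle on random indicators", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(40:150, 1)
    ind <- matrix(runif(n * 2) < 0.4, n, 2,
                  dimnames = list(NULL, c("A", "B")))
    g <- sample(0:2, 1)
    ci <- contacts_from_indicator(ind, seq_len(n) - 1, grace_time = g)
    for (e in c("A", "B")) {
      o <- oracle_residence(ifelse(ind[, e], 1L, 9L), 1, g, 1L)
      ce <- ci[ci$entity == e, ]
      expect_equal(nrow(ce), nrow(o))
      if (nrow(o)) {
        expect_equal(ce$first_frame, unname(o[, "first"]))
        expect_equal(ce$last_frame, unname(o[, "last"]))
      }
    }
  }
})

test_that("arrival from the bulk is primary; in-shell transfer is secondary", {
  n <- 30L
  times <- seq_len(n) - 1
  # contact with residue 60 frames 5-10, residue 54 frames 15-20
  ind <- matrix(FALSE, n, 2, dimnames = list(NULL, c("E60", "D54")))
  ind[5:10, 1] <- TRUE
  ind[15:20, 2] <- TRUE
  ci <- contacts_from_indicator(ind, times, grace_time = 0)
  # ion stays in the first shell throughout the inter-contact window
  fs_in <- rep(FALSE, n); fs_in[4:21] <- TRUE
  ce <- classify_encounters(ci, fs_in, times, grace_time = 0)
  expect_identical(ce$classification, c("primary", "secondary"))
  expect_identical(ce$origin_entity, c(NA, "E60"))
  # ion exits the first shell between the contacts -> both primary
  fs_out <- fs_in; fs_out[12:13] <- FALSE
  ce2 <- classify_encounters(ci, fs_out, times, grace_time = 0)
  expect_identical(ce2$classification, c("primary", "primary"))
  # but a <= grace exit is bridged and the transfer stays secondary
  fs_short <- fs_in; fs_short[12] <- FALSE
  ce3 <- classify_encounters(ci, fs_short, times, grace_time = 2)
  expect_identical(ce3$classification, c("primary", "secondary"))
})

test_that("a contact starting while another persists uses the same look-back", {
  n <- 30L
  times <- seq_len(n) - 1
  ind <- matrix(FALSE, n, 2, dimnames = list(NULL, c("E60", "D54")))
  ind[5:20, 1] <- TRUE
  ind[10:15, 2] <- TRUE     # starts while E60 still bound
  ci <- contacts_from_indicator(ind, times, grace_time = 0)
  fs <- rep(FALSE, n); fs[4:21] <- TRUE
  ce <- classify_encounters(ci, fs, times, grace_time = 0)
  d54 <- ce[ce$entity == "D54", ]
  expect_identical(d54$classification, "secondary")
  expect_identical(d54$origin_entity, "E60")
})

test_that("binding table aggregates time, counts and dwell; carboxylates merge", {
  # two disjoint 10 ps contacts -> 20 ps binding, 10 ps mean dwell
  ev <- structure(data.frame(
    entity = c("E60", "E60"), t_start = c(0, 30), t_end = c(10, 40),
    duration = c(10, 10), first_frame = c(1L, 31L), last_frame = c(10L, 40L),
    classification = c("primary", "secondary"),
    origin_entity = c(NA, "D54")), class = c("contact_events", "data.frame"))
  bt <- binding_table(ev)
  expect_equal(bt$binding_time, 20)
  expect_equal(bt$mean_dwell, 10)
  expect_equal(bt$primary_count, 1L)
  expect_equal(bt$secondary_count, 1L)
  # OE1 then OE2 with no gap collapse into one carboxylate contact
  m <- atom_meta(1:2, c(60L, 60L), c("GLU", "GLU"), c("OE1", "OE2"))
  pc <- rbind(c(1, 1, 1), c(1.3, 1, 1))
  ion <- rbind(matrix(rep(c(1.05, 1, 1), 5), 5, 3, byrow = TRUE),
               matrix(rep(c(1.25, 1, 1), 5), 5, 3, byrow = TRUE))
  traj <- ion_trajectory(0:9, 10, pc, list(I = ion), m)
  ci <- detect_contacts(traj, cutoff = 0.12, granularity = "sidechain_oxygen",
                        grace_time = 0)
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$entity, "GLU60:carboxylate")
  expect_equal(ci$duration, 10)
  # at atom granularity the same trajectory shows two entities
  ci2 <- detect_contacts(traj, cutoff = 0.12, granularity = "atom",
                         grace_time = 0)
  expect_setequal(ci2$entity, c("GLU60:OE1", "GLU60:OE2"))
})

test_that("transfer counts are symmetric and restrictable to named pairs", {
  ev <- structure(data.frame(
    entity = c("D54", "E60", "E65"),
    t_start = 0, t_end = 1, duration = 1,
    first_frame = 1L, last_frame = 1L,
    classification = c("secondary", "secondary", "primary"),
    origin_entity = c("E60", "D54", NA)),
    class = c("contact_events", "data.frame"))
  tc <- transfer_counts(ev)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$count, 2L)             # both directions pooled
  tcp <- transfer_counts(ev, pairs = data.frame(a = c("D54", "D58"),
                                                b = c("E60", "E65")))
  expect_equal(tcp$count[tcp$entity_a == "D54"], 2L)
  expect_equal(tcp$count[tcp$entity_a == "D58"], 0L)
  expect_equal(nrow(transfer_counts(ev[3, ])), 0L)
})

test_that("summary statistics reconcile with hand arithmetic", {
  n <- 100L
  ev <- structure(data.frame(
    entity = c("A", "B", "A"),
    t_start = c(0, 10, 50), t_end = c(10, 30, 60),
    duration = c(10, 20, 10),
    first_frame = c(1L, 11L, 51L), last_frame = c(10L, 30L, 60L),
    classification = c("primary", "secondary", "primary"),
    origin_entity = c(NA, "A", NA)),
    class = c("contact_events", "data.frame"))
  ss <- summary_stats(ev, seq_len(n) - 1, total_time = 100)
  expect_equal(ss$ratio, 0.5)
  expect_equal(ss$mean_primary_interval, 50)
  expect_equal(ss$mean_secondary_interval, 100)
  expect_equal(ss$free_fraction, 0.6)    # 40 bound frames of 100
  expect_equal(ss$mean_concurrency, 1)   # never overlapping here
  # zero secondary -> ratio 0; zero primary -> undefined ratio
  ss0 <- summary_stats(ev[ev$classification == "primary", ],
                       seq_len(n) - 1)
  expect_equal(ss0$ratio, 0)
  ssu <- summary_stats(ev[ev$classification == "secondary", ],
                       seq_len(n) - 1)
  expect_true(is.na(ssu$ratio))
})

test_that("hopping-generator bookkeeping is reproduced exactly (ledger equality)", {
  h <- gen_hopping_contacts(n_sites = 4L, arrival_rate = 0.01,
                            hop_rate = 0.02, escape_rate = 0.05,
                            n_events = 400L, seed = 62)
  ci <- contacts_from_indicator(h$indicator, h$times, grace_time = 0)
  ce <- classify_encounters(ci, h$first_shell, h$times, grace_time = 0)
  led <- h$ledger
  expect_equal(nrow(ce), nrow(led$events))
  expect_equal(sum(ce$classification == "primary"), led$summary$n_primary)
  expect_equal(sum(ce$classification == "secondary"), led$summary$n_secondary)
  # event-by-event agreement
  ord <- order(ce$first_frame)
  expect_equal(ce$first_frame[ord], led$events$first_frame)
  expect_equal(ce$last_frame[ord], led$events$last_frame)
  expect_equal(ce$entity[ord], paste0("site", led$events$site))
  sec <- led$events$classification == "secondary"
  expect_equal(ce$origin_entity[ord][sec], paste0("site",
                                                  led$events$origin[sec]))
  # binding table totals equal per-site ledger sums
  bt <- binding_table(ce)
  for (s in seq_len(4)) {
    le <- led$events[led$events$site == s, ]
    row <- bt[bt$entity == paste0("site", s), ]
    expect_equal(row$binding_time,
                 sum(le$last_frame - le$first_frame + 1L) * led$dt)
    expect_equal(row$primary_count, sum(le$classification == "primary"))
    expect_equal(row$secondary_count, sum(le$classification == "secondary"))
  }
  # transfer counts equal the ledger pair table
  tc <- transfer_counts(ce)
  expect_equal(nrow(tc), nrow(led$transfers))
  expect_equal(tc$entity_a, paste0("site", led$transfers$site_a))
  expect_equal(tc$count, led$transfers$count)
  # summary statistics identical
  ss <- summary_stats(ce, h$times, total_time = led$total_time)
  expect_equal(ss$ratio, led$summary$ratio)
  expect_equal(ss$mean_primary_interval, led$summary$mean_primary_interval)
  expect_equal(ss$mean_secondary_interval,
               led$summary$mean_secondary_interval)
  expect_equal(ss$free_fraction, led$summary$free_fraction)
  expect_equal(ss$mean_concurrency, led$summary$mean_concurrency)
})

test_that("the packaged encounter table pools to the headline ratios", {
  tab <- load_encounter_table()
  st <- summarize_encounter_table(tab, total_time_ns = 2000)
  expect_equal(round(st$ratio, 1), 0.3)
  expect_equal(round(st$mean_primary_interval_ns, 1), 1.3)
  expect_equal(round(st$mean_secondary_interval_ns), 4)
})
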