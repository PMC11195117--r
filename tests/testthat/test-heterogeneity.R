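test_that("peak matching handles identical, disjoint and mixed trains", {
  ti <- c(1, 3, 5)
  m <- match_peaks(ti, ti)
  expect_identical(nrow(m$matched), 3L)
  expect_length(m$unique_i, 0)
  expect_length(m$unique_j, 0)
  expect_equal(same_peak_fraction(m), 1)

  m0 <- match_peaks(c(1, 3, 5), c(2, 4, 6), tol = 0.67)
  expect_identical(nrow(m0$matched), 0L)
  expect_equal(same_peak_fraction(m0), 0)

  m1 <- match_peaks(c(1.0, 5.0), c(1.5, 9.0))
  expect_equal(m1$matched, cbind(time_i = 1.0, time_j = 1.5))
  expect_equal(m1$unique_i, 5.0)
  expect_equal(m1$unique_j, 9.0)
  expect_identical(nrow(m1$matched),
                   max_matching_oracle(c(1, 5), c(1.5, 9), 0.67))
})

test_that("matching is symmetric and one-to-one", {
  set.seed(11)
  for (rep in 1:20) {
    ti <- random_train(rpois(1, 4), 30, 1)
    tj <- random_train(rpois(1, 4), 30, 1)
    a <- match_peaks(ti, tj)
    b <- match_peaks(tj, ti)
    expect_identical(nrow(a$matched), nrow(b$matched))
    expect_lte(nrow(a$matched), min(length(ti), length(tj)))
    if (nrow(a$matched)) {
      expect_false(anyDuplicated(a$matched[, 1]) > 0)
      expect_false(anyDuplicated(a$matched[, 2]) > 0)
    }
  }
})

test_that("greedy matching equals brute-force optimal matching on spaced trains", {
  set.seed(12)
  for (rep in 1:100) {
    ti <- random_train(rpois(1, 4), 40, min_gap = 1.4)  # > 2 * tol
    tj <- random_train(rpois(1, 4), 40, min_gap = 1.4)
    expect_identical(nrow(match_peaks(ti, tj)$matched),
                     max_matching_oracle(ti, tj, 0.67))
  }
})

test_that("same-peak fraction uses the 2m/(n_i+n_j) convention", {
  m <- match_peaks(c(1, 5, 9), c(1.2, 5.3, 20))
  expect_identical(nrow(m$matched), 2L)
  expect_equal(same_peak_fraction(m), 4 / 6)
  expect_error(same_peak_fraction(match_peaks(numeric(0), numeric(0))),
               "undefined")
})

test_that("hierarchical aggregation equals the brute-force three-level mean", {
  pairs <- data.frame(
    axon_id = c(1, 1, 1, 2),
    bouton_i = c(1, 1, 2, 4),
    bouton_j = c(2, 3, 3, 5),
    fraction = c(0.2, 0.6, 0.4, 0.8))
  agg <- aggregate_same_fraction(pairs)
  # bouton means: b1 = .4, b2 = .3, b3 = .5, b4 = .8, b5 = .8
  # axon means: a1 = .4, a2 = .8 -> mouse = .6
  expect_equal(agg$mouse, 0.6)
  expect_equal(unname(agg$per_axon), c(0.4, 0.8))

  flat <- data.frame(axon_id = c(1, 2), bouton_i = c(1, 3),
                     bouton_j = c(2, 4), fraction = c(0.5, 0.5))
  expect_equal(aggregate_same_fraction(flat)$mouse, 0.5)
})

test_that("measured same-peak fraction converges to p_shared", {
  p <- 0.7
  cfg <- sim_config(n_axons = 3, boutons_per_axon = 2, n_frames = 4000,
                    noise_sd = 0, p_shared = p, unique_event_rate = 0,
                    frac_rm_only = 0, frac_um_only = 0, frac_both = 0,
                    shared_event_rate = 0.25, seed = 13)
  beh <- simulate_behavior(cfg, 13)
  sim <- simulate_fluorescence(cfg, beh, 13)
  ev <- detect_events_all(sim$fluor)
  expect_gt(nrow(ev), 200)
  pairs <- same_axon_pair_fractions(ev)
  measured <- aggregate_same_fraction(pairs)$mouse
  # with only shared events the expected pair fraction is p itself
  expect_equal(measured, p, tolerance = 0.12)
  # matching the ground-truth event log agrees closely (the dual
  # detection criterion may drop an occasional borderline-z event)
  tru_pairs <- same_axon_pair_fractions(
    data.frame(bouton_id = sim$truth$events$bouton_id,
               axon_id = sim$truth$events$axon_id,
               time_s = sim$truth$events$peak_time))
  expect_equal(measured, aggregate_same_fraction(tru_pairs)$mouse,
               tolerance = 0.03)
})

test_that("lowering p_shared lowers the same-peak fraction monotonically", {
  frac_at <- function(p) {
    cfg <- sim_config(n_axons = 3, boutons_per_axon = 3, n_frames = 3000,
                      noise_sd = 0, p_shared = p, unique_event_rate = 0.01,
                      frac_rm_only = 0, frac_um_only = 0, frac_both = 0,
                      shared_event_rate = 0.2, seed = 14)
    beh <- simulate_behavior(cfg, 14)
    sim <- simulate_fluorescence(cfg, beh, 14)
    pairs <- same_axon_pair_fractions(detect_events_all(sim$fluor))
    aggregate_same_fraction(pairs)$mouse
  }
  fr <- vapply(c(0.3, 0.6, 0.9), frac_at, 0)
  expect_true(all(diff(fr) > 0))
})

test_that("peaks are associated with the outcome window -330 to +670 ms", {
  bouts <- data.frame(onset = c(10, 20), label = c("RM", "UM"))
  expect_identical(label_peak_outcome(10.2, bouts), "RM")
  expect_identical(label_peak_outcome(9.5, bouts), "none")   # 0.5 s before
  expect_identical(label_peak_outcome(20.6, bouts), "UM")
  expect_identical(label_peak_outcome(9.7, bouts), "RM")     # within 330 ms
  expect_identical(label_peak_outcome(50, bouts), "none")
  # overlapping windows resolve to the nearest onset
  near <- data.frame(onset = c(10, 10.8), label = c("RM", "UM"))
  expect_identical(label_peak_outcome(10.5, near), "UM")   # both windows cover
  expect_identical(label_peak_outcome(10.2, near), "RM")
})

test_that("outcome-resolved same/unique fractions match exhaustive counts", {
  ev <- data.frame(
    bouton_id = c(1, 1, 2, 2, 1),
    axon_id = 1,
    time_s = c(10.1, 30.0, 10.3, 40.0, 20.1))
  bouts <- data.frame(onset = c(10, 20, 40), label = c("RM", "UM", "UM"))
  out <- outcome_peak_fractions(ev, bouts)
  # matched pair (10.1, 10.3) -> RM same; unique 20.1 -> UM; 40.0 -> UM;
  # 30.0 -> no outcome
  expect_equal(out$same[out$outcome == "RM"], 1)
  expect_equal(out$same[out$outcome == "UM"], 0)
  expect_equal(out$unique[out$outcome == "UM"], 1)
  expect_equal(out$n, c(1, 2), ignore_attr = TRUE)
})

test_that("axon heterogeneity is the minority fraction of selective boutons", {
  expect_equal(axon_heterogeneity(rep("RM_only", 5)), 0)
  expect_equal(axon_heterogeneity(rep(c("RM_only", "UM_only"), 3)), 0.5)
  expect_equal(axon_heterogeneity(c(rep("RM_only", 4), "UM_only")), 0.2)
  # both/none boutons do not enter
  expect_equal(axon_heterogeneity(c("RM_only", "RM_only", "both", "none",
                                    "UM_only")), 1 / 3)
  expect_true(is.na(axon_heterogeneity(c("RM_only", "both"))))
})
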