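make_track <- function(presence, positions = NULL, axon_id = NULL,
                       length_um = 50, days = c(0, 2, 4, 6, 8, 10)) {
  n <- nrow(presence)
  days <- days[seq_len(ncol(presence))]
  axon_id <- axon_id %||% rep(1L, n)
  positions <- positions %||% seq(5, by = 5, length.out = n)
  structure(list(
    axons = data.frame(axon_id = unique(axon_id), length_um = length_um,
                       group = "training"),
    boutons = data.frame(bouton_id = seq_len(n), axon_id = axon_id,
                         position_um = positions),
    presence = presence, days = days
  ), class = "bouton_track")
}

test_that("dynamics annotation assigns exactly one state per transition", {
  p <- rbind(c(TRUE, TRUE, TRUE),    # persistent throughout
             c(FALSE, TRUE, TRUE),   # formed at day 2
             c(TRUE, FALSE, TRUE))   # gap: eliminated then re-formed
  ann <- annotate_dynamics(make_track(p, days = c(0, 2, 4)))
  expect_identical(nrow(ann), 6L)
  g1 <- ann$state[ann$bouton_id == 1]
  expect_identical(g1, c("persistent", "persistent"))
  g2 <- ann$state[ann$bouton_id == 2]
  expect_identical(g2, c("formed", "persistent"))
  g3 <- ann$state[ann$bouton_id == 3]
  expect_identical(g3, c("eliminated", "formed"))
})

test_that("simulated annotations agree with the generator event log", {
  cfg <- sim_config(n_axons = 5, formation_rate = 0.12,
                    elimination_rate = 0.08, seed = 15)
  st <- simulate_structure(cfg)
  ann <- annotate_dynamics(st$track)
  changed <- ann[ann$state %in% c("formed", "eliminated"), ]
  key_ann <- paste(changed$bouton_id, changed$to_day, changed$state)
  key_log <- paste(st$truth$bouton_id, st$truth$day,
                   ifelse(st$truth$type == "formed", "formed", "eliminated"))
  expect_setequal(key_ann, key_log)
})

test_that("bookkeeping identity present(d) = present(d-2) - eliminated + formed", {
  cfg <- sim_config(n_axons = 8, formation_rate = 0.15,
                    elimination_rate = 0.1, seed = 16)
  st <- simulate_structure(cfg)
  ann <- annotate_dynamics(st$track)
  p <- st$track$presence
  for (d in 2:length(st$track$days)) {
    g <- ann[ann$to_day == st$track$days[d], ]
    expect_identical(sum(p[, d]),
                     sum(p[, d - 1]) - sum(g$state == "eliminated") +
                       sum(g$state == "formed"))
  }
})

test_that("densities and normalized densities follow the definitions", {
  p <- matrix(TRUE, 10, 3)
  d <- density_timecourse(make_track(p, length_um = 50, days = c(0, 2, 4)))
  expect_equal(d$density, rep(0.2, 3))
  expect_equal(d$norm_density, rep(1, 3))

  p2 <- rbind(matrix(TRUE, 10, 3),
              cbind(FALSE, TRUE, TRUE))   # one bouton formed at day 2
  d2 <- density_timecourse(make_track(p2, length_um = 50, days = c(0, 2, 4)))
  expect_equal(d2$norm_density, c(1, 1.1, 1.1))
})

test_that("turnover percentages are normalized to the earlier session", {
  p <- matrix(TRUE, 20, 2)
  p <- rbind(p, cbind(rep(FALSE, 2), rep(TRUE, 2)))   # 2 formed
  ann <- annotate_dynamics(make_track(p, days = c(0, 2)))
  tr <- turnover_rates(ann)
  expect_equal(tr$formation_pct, 10)    # 2 formed / 20 present
  expect_equal(tr$elimination_pct, 0)

  ann0 <- annotate_dynamics(make_track(matrix(TRUE, 5, 4),
                                       days = c(0, 2, 4, 6)))
  tr0 <- turnover_rates(ann0)
  expect_true(all(tr0$formation_pct == 0) && all(tr0$elimination_pct == 0))
})

test_that("programmed turnover rates are recovered within binomial CIs", {
  cfg <- sim_config(n_axons = 25, axon_length_um = 80, baseline_density = 0.3,
                    formation_rate = 0.08, elimination_rate = 0.06, seed = 17)
  st <- simulate_structure(cfg)
  ann <- annotate_dynamics(st$track)
  n_ref <- sum(ann$state %in% c("persistent", "eliminated"))
  ci_f <- binom.test(sum(ann$state == "formed"), n_ref)$conf.int
  ci_e <- binom.test(sum(ann$state == "eliminated"), n_ref)$conf.int
  expect_true(ci_f[1] < 0.08 && 0.08 < ci_f[2])
  expect_true(ci_e[1] < 0.06 && 0.06 < ci_e[2])
})

test_that("survival of a formed cohort follows the definitions", {
  p <- rbind(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
             c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),   # formed day 4, survives
             c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))# formed day 4, lost
  s <- survival_curve(make_track(p))
  expect_equal(s, c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_identical(attr(s, "n_formed"), 2L)

  all_live <- rbind(c(TRUE, rep(TRUE, 5)),
                    c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(survival_curve(make_track(all_live)), c(1, 1, 1),
               ignore_attr = TRUE)
  gone <- rbind(c(rep(TRUE, 6)),
                c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(survival_curve(make_track(gone)), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_error(survival_curve(make_track(matrix(TRUE, 3, 6))), "formed")
})

test_that("co-formed bouton pair distances are along-axon distances", {
  p <- rbind(c(TRUE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  tr <- make_track(p, positions = c(2, 10, 14), days = c(0, 2))
  expect_equal(sort(new_bouton_pair_distances(tr, 2)), 4)
  one <- make_track(rbind(c(TRUE, TRUE), c(FALSE, TRUE)),
                    positions = c(2, 10), days = c(0, 2))
  expect_length(new_bouton_pair_distances(one, 2), 0)
})

test_that("clustered formation yields closer pairs than uniform formation", {
  mk <- function(scale, seed) {
    cfg <- sim_config(n_axons = 40, axon_length_um = 80,
                      baseline_density = 0.3, formation_rate = 0.3,
                      elimination_rate = 0, cluster_scale_um = scale,
                      seed = seed)
    st <- simulate_structure(cfg)
    new_bouton_pair_distances(st$track, 4)
  }
  d_clust <- mk(4, 18)
  d_unif <- mk(Inf, 18)
  expect_gt(length(d_clust), 30)
  expect_lt(mean(d_clust), mean(d_unif))
  expect_lt(ks.test(d_clust, d_unif)$p.value, 0.05)
})

test_that("density correlations detect persistent axon-specific rates", {
  p <- matrix(TRUE, 9, 6)
  tr <- make_track(p, axon_id = rep(1:3, each = 3), length_um = 50)
  dens <- density_timecourse(tr)
  expect_error(density_day_correlation(dens, 4, 10), "zero variance")

  set.seed(19)
  # axon-specific densities persist across days -> strong day-to-day r
  n_ax <- 30
  base <- rpois(n_ax, 12) + 2
  dens2 <- do.call(rbind, lapply(1:n_ax, function(a)
    data.frame(axon_id = a, day = c(4, 10),
               density = (base[a] + rpois(2, 2)) / 50)))
  expect_gt(density_day_correlation(dens2, 4, 10), 0.5)
})

test_that("functional class stratifies structural rates as programmed", {
  set.seed(20)
  rates <- c(RM = 0.2, UM = 0.05)
  tracks <- lapply(1:40, function(a) {
    cls <- if (a <= 20) "RM" else "UM"
    cfg <- sim_config(n_axons = 1, axon_length_um = 80,
                      baseline_density = 0.3,
                      formation_rate = unname(rates[cls]),
                      elimination_rate = 0.05, seed = 100 + a)
    st <- simulate_structure(cfg)$track
    st$axons$axon_id <- a
    st$boutons$axon_id <- a
    st
  })
  track <- structure(list(
    axons = do.call(rbind, lapply(tracks, `[[`, "axons")),
    boutons = do.call(rbind, lapply(tracks, `[[`, "boutons")),
    presence = do.call(rbind, lapply(tracks, `[[`, "presence")),
    days = tracks[[1]]$days), class = "bouton_track")
  track$boutons$bouton_id <- seq_len(nrow(track$boutons))
  classes <- data.frame(axon_id = 1:40,
                        early_class = rep(c("RM", "UM"), each = 20),
                        late_class = rep(c("RM", "UM"), each = 20))
  j <- function_structure_join(track, classes)
  f <- j$formation_by_late
  expect_gt(f$mean[f$class == "RM"], f$mean[f$class == "UM"])
  expect_identical(sort(j$elimination_by_early$class), c("RM", "UM"))
  # single-class stratum equals the pooled value
  one <- function_structure_join(track,
    data.frame(axon_id = 1:40, early_class = "RM", late_class = "RM"))
  expect_identical(nrow(one$formation_by_late), 1L)
})
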