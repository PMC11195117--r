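test_that("concatenated matrix stacks RM over UM trial averages per bouton", {
  L <- 4
  act <- array(0, dim = c(2, 4, L))
  act[1, 1, ] <- c(1, 2, 3, 4); act[1, 2, ] <- c(3, 4, 5, 6)  # RM trials
  act[1, 3, ] <- c(0, 1, 0, 1); act[1, 4, ] <- c(0, 3, 0, 3)  # UM trials
  act[2, , ] <- 1
  tens <- make_tensor(act, c("RM", "RM", "UM", "UM"))
  cm <- build_concat_matrix(tens)
  expect_identical(dim(cm$matrix), c(8L, 2L))
  expect_equal(cm$matrix[, 1], c(2, 3, 4, 5, 0, 2, 0, 2))  # hand-stacked
  expect_equal(cm$matrix[, 2], rep(1, 8))
})

test_that("boutons missing a trial type are excluded with a record", {
  act <- array(1, dim = c(2, 2, 3))
  tens <- make_tensor(act, c("RM", "RM"))
  expect_error(build_concat_matrix(tens), "no bouton")
})

test_that("bouton embedding agrees with a direct SVD oracle up to sign", {
  set.seed(6)
  x <- matrix(rnorm(8 * 5), 8, 5)
  emb <- embed_boutons(x, k = 3)
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  oracle_scores <- sv$v[, 1:3] %*% diag(sv$d[1:3])
  for (k in 1:3) {
    same <- max(abs(emb$scores[, k] - oracle_scores[, k]))
    flip <- max(abs(emb$scores[, k] + oracle_scores[, k]))
    expect_lt(min(same, flip), 1e-10)
  }
  expect_true(all(diff(emb$explained) <= 1e-12))
  # duplicated bouton columns get identical coordinates
  emb2 <- embed_boutons(cbind(x, x[, 2]), k = 3)
  expect_equal(emb2$scores[2, ], emb2$scores[6, ], tolerance = 1e-10)
})

test_that("pure RM and pure UM responders separate in the embedding", {
  L <- 10
  bump <- sin(seq(0, pi, length.out = L))
  n_half <- 6
  rm_cols <- vapply(1:n_half, function(i) c(bump * (1 + 0.1 * i), rep(0, L)),
                    numeric(2 * L))
  um_cols <- vapply(1:n_half, function(i) c(rep(0, L), bump * (1 + 0.1 * i)),
                    numeric(2 * L))
  # the two response groups span a rank-2 space; the reduced embedding is
  # expected and sufficient for separation
  expect_warning(emb <- embed_boutons(cbind(rm_cols, um_cols), k = 3),
                 "rank-deficient")
  lab <- rep(c("RM", "UM"), each = n_half)
  # project onto the direction between group means: intervals must not overlap
  d <- colMeans(emb$scores[lab == "RM", ]) - colMeans(emb$scores[lab == "UM", ])
  proj <- emb$scores %*% d
  expect_gt(min(proj[lab == "RM"]), max(proj[lab == "UM"]))
})

test_that("segment PCA matches the eigendecomposition oracle up to sign", {
  set.seed(7)
  x <- matrix(rnorm(30), 3, 10)       # 3 boutons x 10 frames
  res <- segment_pca(x, k = 3)
  xc <- sweep(t(x), 2, colMeans(t(x)))
  eig <- eigen(crossprod(xc))
  oracle_pcs <- xc %*% eig$vectors
  for (k in 1:3) {
    same <- max(abs(res$pcs[, k] - oracle_pcs[, k]))
    flip <- max(abs(res$pcs[, k] + oracle_pcs[, k]))
    expect_lt(min(same, flip), 1e-10)
  }
  expect_equal(res$explained, eig$values / sum(eig$values), tolerance = 1e-10)

  # single bouton: PC1 is the centered trace itself (up to sign)
  one <- matrix(rnorm(20), 1, 20)
  expect_warning(r1 <- segment_pca(one, k = 3), "fewer boutons")
  cent <- as.numeric(one - mean(one))
  expect_lt(min(max(abs(r1$pcs[, 1] - cent)), max(abs(r1$pcs[, 1] + cent))),
            1e-10)

  # two perfectly correlated boutons: second component carries no variance
  two <- rbind(rnorm(15), 0)
  two[2, ] <- 2 * two[1, ]
  r2 <- segment_pca(two, k = 2)
  expect_lt(r2$explained[2], 1e-20)
})

test_that("full-rank reconstruction reproduces the centered segment", {
  set.seed(8)
  x <- matrix(rnorm(4 * 12), 4, 12)
  r <- segment_pca(x, k = 4)
  xc <- sweep(t(x), 2, colMeans(t(x)))
  expect_equal(r$pcs %*% t(r$loadings), xc, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("trajectory extraction returns frame-wise mean trajectories", {
  pcs <- matrix(rnorm(900 * 3), 900, 3)
  tr <- extract_trajectories(pcs, onsets = c(10, 20, 40),
                             labels = c("RM", "RM", "UM"), frame_rate = 15)
  expect_length(tr$trials, 3)
  expect_equal(tr$mean_rm, (tr$trials[[1]] + tr$trials[[2]]) / 2)
  expect_equal(tr$mean_um, tr$trials[[3]])
  # a single RM trial is its own mean
  tr1 <- extract_trajectories(pcs, onsets = 10, labels = "RM",
                              frame_rate = 15)
  expect_equal(tr1$mean_rm, tr1$trials[[1]])
  expect_null(tr1$mean_um)
})

test_that("selectivity index hits its defining boundary values", {
  L <- 60
  mean_rm <- cbind(sin(seq_len(L) / 5), cos(seq_len(L) / 5), seq_len(L) / L)
  mean_um <- mean_rm + 1   # separated at every frame
  on_rm <- selectivity_index(mean_rm, mean_rm, mean_um, "RM")
  expect_true(all(on_rm$index == 1))
  expect_equal(on_rm$trial_mean, 1)
  on_um <- selectivity_index(mean_um, mean_rm, mean_um, "RM")
  expect_equal(on_um$trial_mean, -1)
  # equidistant trial: index 0 at every frame
  mid <- (mean_rm + mean_um) / 2
  expect_equal(selectivity_index(mid, mean_rm, mean_um, "RM")$trial_mean, 0)
})

test_that("selectivity index is bounded and label-swap antisymmetric", {
  set.seed(9)
  for (rep in 1:10) {
    L <- 20
    t1 <- matrix(rnorm(L * 3), L, 3)
    mr <- matrix(rnorm(L * 3), L, 3)
    mu <- matrix(rnorm(L * 3), L, 3)
    a <- selectivity_index(t1, mr, mu, "RM")
    expect_true(all(a$index >= -1 & a$index <= 1, na.rm = TRUE))
    b <- selectivity_index(t1, mu, mr, "UM")  # swap means and label
    expect_equal(a$index, b$index)
    d <- selectivity_index(t1, mr, mu, "UM")  # swap label only
    expect_equal(a$index, -d$index)
  }
})

test_that("mean RM selectivity grows with programmed response gain", {
  sel_at_gain <- function(gain) {
    cfg <- sim_config(n_axons = 4, boutons_per_axon = 4, n_frames = 3000,
                      p_success = 0.6, p_iti_push = 0.5, noise_sd = 0.05,
                      response_gain = gain, frac_rm_only = 0.5,
                      frac_um_only = 0.2, frac_both = 0.1, seed = 10)
    beh <- simulate_behavior(cfg, 10)
    sim <- simulate_fluorescence(cfg, beh, 10)
    res <- analyze_session(sim$fluor, beh)
    mean(res$selectivity$selectivity[res$selectivity$label == "RM"])
  }
  sels <- vapply(c(0.1, 0.6, 1.5), sel_at_gain, 0)
  expect_true(all(diff(sels) > 0))
  expect_gt(sels[3], 0)
})
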