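test_that("correlation distance matches the direct formula", {
  m <- rbind(a = c(1, 0, 1, 0, 1, 1), b = c(1, 0, 1, 0, 1, 0),
             c = c(0, 1, 0, 1, 0, 1))
  d <- correlation_distance(m)
  r <- cor(t(m))
  expect_equal(unclass(d), 1 - r, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # r = 1 -> d = 0; r = -1 -> d = 2
  m2 <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1))
  d2 <- correlation_distance(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 2)
})

test_that("UPGMA merge sequence equals brute-force enumeration up to n = 6", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    rownames(d) <- colnames(d) <- sprintf("c%d", 1:n)
    cl <- average_linkage_cluster(d, k = 2)
    oracle <- bf_upgma(d)
    expect_equal(cl$hclust$height, oracle$heights, tolerance = 1e-12)
    expect_identical(hclust_sets(cl$hclust), oracle$sets)
  }
  # n = 2: a single merge at the pair distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  cl2 <- average_linkage_cluster(d2, k = 2)
  expect_equal(cl2$hclust$height, 0.7)
  expect_error(average_linkage_cluster(matrix(0, 1, 1)))
})

test_that("planted two-block structure is recovered exactly at a 2-cut", {
  m <- make_block_raster(n_per_block = 4, seed = 41)
  cl <- average_linkage_cluster(correlation_distance(m), k = 2)
  expect_equal(adjusted_rand_index(cl$labels, rep(1:2, each = 4)), 1)
  # silhouette cut finds the same k
  cl_auto <- average_linkage_cluster(correlation_distance(m))
  expect_equal(cl_auto$k, 2)
  td <- generics::tidy(cl)
  expect_equal(nrow(td), 8)
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
  nwk <- cluster_newick(cl)
  expect_match(nwk, ";$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("jitter surrogate preserves counts and respects magnitude bounds", {
  ev <- tibble::tibble(subject = "s1",
                       channel = rep(sprintf("ch%02d", 1:4), each = 25),
                       peak_time = runif(100, 1, 99),
                       onset = NA_real_, offset = NA_real_)
  ev$onset <- ev$peak_time - 0.01; ev$offset <- ev$peak_time + 0.01
  jt <- jitter_surrogate(ev, seed = 5, t_max = 100)
  expect_identical(table(jt$channel), table(ev$channel))
  shift <- abs(jt$peak_time - ev$peak_time)
  expect_true(all(shift >= 0.05 - 1e-12 & shift <= 0.10 + 1e-12))
  # zero jitter is the identity
  expect_equal(jitter_surrogate(ev, 0, 0, seed = 1)$peak_time, ev$peak_time)
  # boundary reflection keeps events inside the recording
  evb <- tibble::tibble(channel = "ch01", peak_time = c(0.01, 99.99))
  jb <- jitter_surrogate(evb, t_max = 100, seed = 2)
  expect_true(all(jb$peak_time >= 0 & jb$peak_time <= 100))
})

test_that("synchrony follows its contracts and drops under jitter", {
  ident <- matrix(rep(c(1, 0, 0, 1, 0), 4), 4, 5, byrow = TRUE)
  expect_equal(synchrony(ident), 1)
  set.seed(43)
  indep <- matrix(rbinom(6 * 3000, 1, 0.05), 6, 3000)
  expect_lt(abs(synchrony(indep)), 0.02)
  # single-channel or all-constant input is flagged
  cst <- matrix(0L, 3, 10)
  expect_true(is.na(synchrony(cst)))
  # jittered co-bursting rasters lose synchrony in >= 19/20 paired runs
  wins <- 0
  for (s in 1:20) {
    m <- make_cobursting_raster(n_ch = 6, n_bins = 3000, prob = 0.02, seed = s)
    ev <- raster_to_events(m)
    jt <- jitter_surrogate(ev, seed = 1000 + s, t_max = 30)
    mj <- build_raster(jt, align_times = 15, window = 15,
                       channels = rownames(m))[[1]]
    if (synchrony(mj) < synchrony(m)) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("synchrony loss grows with jitter magnitude in expectation", {
  drops <- vapply(c(0.010, 0.050, 0.100, 0.200), function(jmax) {
    mean(vapply(1:6, function(s) {
      m <- make_cobursting_raster(n_ch = 6, n_bins = 3000, prob = 0.02,
                                  seed = 100 + s)
      ev <- raster_to_events(m)
      jt <- jitter_surrogate(ev, jitter_min = 0, jitter_max = jmax,
                             seed = 2000 + s, t_max = 30)
      mj <- build_raster(jt, align_times = 15, window = 15,
                         channels = rownames(m))[[1]]
      synchrony(m) - synchrony(mj)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(drops) > -0.02))
  expect_gt(drops[4], drops[1])
})

test_that("adjusted Rand index matches brute-force pair counting", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "a", "b"), c("x", "x", "y")), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), c(1, 2, 3, 1, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(1, 1, 2, 3, 3)),
               bf_ari(c(1, 1, 2, 2, 3), c(1, 1, 2, 3, 3)), tolerance = 1e-12)
  set.seed(47)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), bf_ari(a, b), tolerance = 1e-12)
    # symmetry and label-renaming invariance
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(adjusted_rand_index(a, b),
                 adjusted_rand_index(match(a, unique(a)) + 10, b))
  }
  expect_error(adjusted_rand_index(1:3, 1:4))
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(53)
  for (i in 1:20) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("bootstrap stability is high for planted blocks and near zero for noise", {
  blocks <- lapply(1:12, function(s)
    make_block_raster(n_per_block = 4, n_bins = 300, seed = s))
  st <- bootstrap_stability(blocks, n_boot = 60, k = 2, seed = 1)
  expect_gte(st$ari_mean, 0.9)
  set.seed(61)
  noise <- lapply(1:12, function(s)
    matrix(rbinom(8 * 300, 1, 0.05), 8, 300,
           dimnames = list(sprintf("ch%02d", 1:8), NULL)))
  st0 <- bootstrap_stability(noise, n_boot = 60, k = 2, seed = 1)
  expect_lt(abs(st0$ari_mean), 0.15)
  # single replicate under a fixed seed is reproducible
  s1 <- bootstrap_stability(blocks[[1]], n_boot = 1, k = 2, seed = 7)
  s2 <- bootstrap_stability(blocks[[1]], n_boot = 1, k = 2, seed = 7)
  expect_identical(s1$ari_mean, s2$ari_mean)
  expect_error(bootstrap_stability(blocks[[1]][1:2, ], n_boot = 5))
})

test_that("recall-modulated co-bursting clusters more stably than unmodulated", {
  ari_for <- function(share, seed) {
    cfg <- sim_config(n_subjects = 1, n_channels = 8, fs = 500, n_lists = 6,
                      seed = seed, group_share = share,
                      coincidence_groups = list(coincidence_group(1:4),
                                                coincidence_group(5:8)),
                      burst_freq_range = c(80, 200))
    sim <- simulate_dataset(cfg, render_signal = FALSE)
    ev <- ground_truth_events(sim$ground_truth)
    rec <- dplyr::filter(sim$task_events, trial_type == "RECALL")
    rasters <- build_raster(ev, rec$onset, channels = sprintf("ch%02d", 1:8),
                            t_max = cfg$duration)
    bootstrap_stability(rasters, n_boot = 30, k = 2, seed = 1)$ari_mean
  }
  structured <- mean(vapply(1:3, function(s) ari_for(0.9, s), numeric(1)))
  weak <- mean(vapply(1:3, function(s) ari_for(0.15, s), numeric(1)))
  expect_gt(structured, weak)
})
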