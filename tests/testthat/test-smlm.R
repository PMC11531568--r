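jittered_emitters <- function(n_em, n_frames, sigma, side = 20000, seed = 1) {
  set.seed(seed)
  cx <- runif(n_em, 0, side); cy <- runif(n_em, 0, side)
  data.frame(
    x_nm = rep(cx, each = n_frames) + rnorm(n_em * n_frames, 0, sigma),
    y_nm = rep(cy, each = n_frames) + rnorm(n_em * n_frames, 0, sigma),
    frame = rep(seq_len(n_frames), times = n_em))
}

test_that("NeNA recovers the injected localization precision", {
  locs <- jittered_emitters(40, 60, sigma = 10, seed = 2)  # ~2,360 pairs
  sig <- as.numeric(nena_precision(locs))
  expect_lt(abs(sig - 10), 1)
  # scale equivariance: doubling the jitter doubles the estimate within 10%
  locs2 <- jittered_emitters(40, 60, sigma = 20, seed = 2)
  sig2 <- as.numeric(nena_precision(locs2))
  expect_lt(abs(sig2 / sig - 2), 0.2)
})

test_that("zero jitter collapses the NeNA estimate to zero", {
  locs <- jittered_emitters(20, 30, sigma = 0, seed = 3)
  expect_equal(as.numeric(nena_precision(locs)), 0)
  expect_error(nena_precision(locs[1:50, ]), ">= 100")
})

test_that("linking obeys the dark-frame rule", {
  two <- data.frame(x_nm = c(0, 1), y_nm = c(0, 0), frame = c(1L, 2L))
  linked <- link_localizations(two, radius = 50, max_dark_frames = 5)
  expect_equal(nrow(linked), 1L)
  expect_equal(linked$x_nm, 0.5)
  # 5 dark frames between (frames 1 and 7): linked
  gap5 <- data.frame(x_nm = c(0, 0), y_nm = c(0, 0), frame = c(1L, 7L))
  expect_equal(nrow(link_localizations(gap5, 50, 5)), 1L)
  # 6 dark frames between (frames 1 and 8): not linked
  gap6 <- data.frame(x_nm = c(0, 0), y_nm = c(0, 0), frame = c(1L, 8L))
  expect_equal(nrow(link_localizations(gap6, 50, 5)), 2L)
  # same-frame localizations are distinct emitters
  same <- data.frame(x_nm = c(0, 0), y_nm = c(0, 0), frame = c(3L, 3L))
  expect_equal(nrow(link_localizations(same, 50, 5)), 2L)
})

test_that("linking equals the brute-force transitive-closure oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    locs <- data.frame(x_nm = runif(n, 0, 300), y_nm = runif(n, 0, 300),
                       frame = sample.int(15, n, replace = TRUE))
    linked <- link_localizations(locs, radius = 60, max_dark_frames = 5)
    grp <- attr(linked, "group")
    oracle <- oracle_link_groups(locs, 60, 5)
    expect_equal(canonical_partition(grp), canonical_partition(oracle))
  }
})

test_that("linking never increases counts and merges inside the group hull", {
  set.seed(5)
  locs <- data.frame(x_nm = runif(200, 0, 500), y_nm = runif(200, 0, 500),
                     frame = sample.int(30, 200, replace = TRUE))
  linked <- link_localizations(locs, radius = 40, max_dark_frames = 5)
  expect_lte(nrow(linked), nrow(locs))
  grp <- attr(linked, "group")
  for (g in unique(grp)) {
    inside <- locs[grp == g, ]
    merged <- linked[g, ]
    expect_gte(merged$x_nm, min(inside$x_nm) - 1e-9)
    expect_lte(merged$x_nm, max(inside$x_nm) + 1e-9)
    expect_gte(merged$y_nm, min(inside$y_nm) - 1e-9)
    expect_lte(merged$y_nm, max(inside$y_nm) + 1e-9)
  }
})

test_that("DBSCAN handles coincident, isolated and empty inputs", {
  ten <- data.frame(x_nm = rep(0, 10), y_nm = rep(0, 10), frame = 1:10)
  res <- dbscan_clusters(ten, eps = 5, min_pts = 10)
  expect_equal(res$n_clusters, 1L)
  expect_true(all(res$labels == 1L))
  one <- data.frame(x_nm = 0, y_nm = 0, frame = 1L)
  expect_equal(dbscan_clusters(one, 5, 2)$labels, 0L)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      frame = integer(0))
  expect_equal(dbscan_clusters(empty, 5, 2)$n_clusters, 0L)
})

test_that("DBSCAN matches brute-force semantics on random point sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    xy <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    res <- dbscan_clusters(data.frame(x_nm = xy[, 1], y_nm = xy[, 2]),
                           eps = 30, min_pts = 4)
    oracle <- oracle_dbscan(xy, eps = 30, min_pts = 4)
    # identical core-point partition (up to relabelling)
    expect_equal(canonical_partition(res$labels[oracle$core]),
                 canonical_partition(oracle$core_labels[oracle$core]))
    # identical noise set
    expect_equal(which(res$labels == 0L),
                 which(vapply(oracle$border_options, length, 1L) == 0L &
                         seq_len(n) %in% setdiff(seq_len(n), oracle$core)))
    # border points sit in one of their eps-adjacent core clusters
    for (i in setdiff(which(res$labels > 0L), oracle$core)) {
      core_opts <- oracle$border_options[[i]]
      mapped <- unique(res$labels[oracle$core[oracle$core_labels[oracle$core] %in% core_opts]])
      expect_true(res$labels[i] %in% mapped)
    }
  }
})

test_that("DBSCAN partitions are stable under input permutation", {
  set.seed(9)
  # well-separated blobs: no border-point ambiguity
  centers <- cbind(runif(8, 0, 5000), runif(8, 0, 5000))
  xy <- do.call(rbind, lapply(1:8, function(i) {
    cbind(rnorm(20, centers[i, 1], 15), rnorm(20, centers[i, 2], 15))
  }))
  base <- dbscan_clusters(data.frame(x_nm = xy[, 1], y_nm = xy[, 2]), 60, 5)
  perm <- sample(nrow(xy))
  shuf <- dbscan_clusters(data.frame(x_nm = xy[perm, 1],
                                     y_nm = xy[perm, 2]), 60, 5)
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  expect_equal(canonical_partition(base$labels),
               canonical_partition(shuf$labels[inv]))
})

test_that("cluster density is the count per area", {
  res <- structure(list(labels = rep(1:28, each = 10), n_clusters = 28L,
                        parameters = list(eps = 20, min_pts = 10)),
                   class = "cluster_result")
  expect_equal(cluster_density(res, 10), 2.8)
  res0 <- structure(list(labels = integer(0), n_clusters = 0L,
                         parameters = list()), class = "cluster_result")
  expect_equal(cluster_density(res0, 10), 0)
  expect_error(cluster_density(res, 0), "area")
})

test_that("the full density pipeline recovers the generated cluster density", {
  fp <- field_params(area_um2 = 100, cluster_density = 3,
                     localization_precision = 10, seed = 3)
  sim <- simulate_localization_field(fp)
  res <- smlm_density_pipeline(sim$localizations, 100)
  true_density <- nrow(sim$truth) / 100
  expect_lt(abs(res$density - true_density) / true_density, 0.15)
  expect_lt(abs(res$nena_nm - 10) / 10, 0.1)
  # the published caps are applied as nm ceilings
  expect_lte(res$link_radius_nm, 0.45 * 157)
  expect_lte(res$eps_nm, 0.15 * 157)
})

test_that("an empty field yields an empty localization table", {
  fp <- field_params(area_um2 = 10, cluster_density = 0, noise_density = 0,
                     seed = 1)
  sim <- simulate_localization_field(fp)
  expect_equal(nrow(sim$localizations), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("cluster counts are Poisson with mean density times area", {
  counts <- vapply(1:40, function(s) {
    fp <- field_params(area_um2 = 50, cluster_density = 2,
                       localizations_per_cluster = 1, noise_density = 0,
                       seed = 100 + s)
    nrow(simulate_localization_field(fp)$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 40))
})

test_that("localization tables accept Picasso-style column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(`x [nm]` = c(1, 2), `y [nm]` = c(3, 4),
                       frame = c(1L, 2L), check.names = FALSE),
            f, row.names = FALSE)
  got <- read_localizations(f)
  expect_equal(got$x_nm, c(1, 2))
  expect_equal(got$y_nm, c(3, 4))
})
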