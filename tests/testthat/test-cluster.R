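# Shared fixtures: a small layout + adjacency and random subject maps.
cl_layout <- tiny_layout(5L)
cl_adj <- build_adjacency(cl_layout, 1.5)

random_maps <- function(n, k, n_e = 5L, n_t = 10L, seed = 1, shift = 0) {
  set.seed(seed)
  m <- array(rnorm(n * k * n_e * n_t), c(n, k, n_e, n_t)) + shift
  sc_maps(m, cl_layout$id[seq_len(n_e)], (seq_len(n_t) - 1) / 100)
}

test_that("pointwise RM-ANOVA matches the definitional SS oracle and t^2", {
  maps <- random_maps(6, 3, seed = 11)
  sm <- pointwise_rm_anova(maps)
  expect_equal(sm$df, c(2, 10))
  for (e in 1:5) for (ti in c(1, 4, 10)) {
    y <- maps$maps[, , e, ti]
    expect_equal(sm$stat[e, ti], oracle_rm_anova_f(y), tolerance = 1e-10)
    expect_equal(sm$p[e, ti],
                 pf(oracle_rm_anova_f(y), 2, 10, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # k = 2: F equals the squared paired t everywhere
  maps2 <- random_maps(7, 2, seed = 12)
  f2 <- pointwise_rm_anova(maps2)
  t2 <- pointwise_paired_t(maps2)
  expect_equal(f2$stat, t2$stat^2, tolerance = 1e-10)
  # identical conditions -> F = 0
  m <- random_maps(4, 3, seed = 13)
  m$maps[, 2, , ] <- m$maps[, 1, , ]
  m$maps[, 3, , ] <- m$maps[, 1, , ]
  expect_true(all(pointwise_rm_anova(m)$stat == 0))
  expect_error(pointwise_rm_anova(random_maps(1, 3)), "n >= 2")
  expect_error(pointwise_rm_anova(random_maps(6, 1)), "k >= 2")
})

test_that("pointwise paired t matches the textbook formula", {
  maps <- random_maps(9, 2, seed = 21)
  sm <- pointwise_paired_t(maps)
  expect_equal(sm$df, 8)
  for (e in 1:5) for (ti in c(2, 7)) {
    expect_equal(sm$stat[e, ti],
                 oracle_paired_t(maps$maps[, 1, e, ti],
                                 maps$maps[, 2, e, ti]),
                 tolerance = 1e-12)
  }
  # identical conditions: t = 0, p = 1
  m <- random_maps(5, 2, seed = 22)
  m$maps[, 2, , ] <- m$maps[, 1, , ]
  sm0 <- pointwise_paired_t(m)
  expect_true(all(sm0$stat == 0) && all(sm0$p == 1))
  # constant non-zero difference: zero variance path -> Inf with warning
  m$maps[, 1, , ] <- m$maps[, 2, , ] + 1
  expect_warning(smc <- pointwise_paired_t(m), "zero difference variance")
  expect_true(all(is.infinite(smc$stat)))
})

test_that("clustering matches an independent flood-fill oracle on random masks", {
  adj_rows <- erpperm:::adjacency_index_list(cl_adj, cl_layout$id)
  set.seed(33)
  for (i in 1:200) {
    mask <- matrix(runif(50) < 0.3, 5, 10)
    stat <- matrix(abs(rnorm(50)) + 1, 5, 10)
    p <- matrix(1, 5, 10)
    p[mask] <- 0.01
    sm <- stat_map(stat, p, c(2, 10), "F", cl_layout$id, (0:9) / 100)
    cl <- find_clusters(sm, 0.05, cl_adj)
    lab_mine <- matrix(0L, 5, 10)
    for (j in seq_along(cl)) lab_mine[cl[[j]]$members] <- j
    lab_oracle <- oracle_flood_fill(mask, adj_rows)
    expect_identical(oracle_cluster_summary(lab_mine, stat),
                     oracle_cluster_summary(lab_oracle, stat))
    sums <- vapply(cl, `[[`, numeric(1), "sum")
    for (j in seq_along(cl))
      expect_equal(sums[j], sum(stat[cl[[j]]$members]), tolerance = 1e-12)
    expect_true(all(diff(abs(sums)) <= 1e-12)) # sorted by |sum|
  }
  # no suprathreshold point -> empty list; isolated point -> its own cluster
  p1 <- matrix(1, 5, 10)
  sm <- stat_map(matrix(1, 5, 10), p1, c(2, 10), "F", cl_layout$id,
                 (0:9) / 100)
  expect_length(find_clusters(sm, 0.05, cl_adj), 0L)
  p1[3, 6] <- 0.01
  stat <- matrix(1, 5, 10); stat[3, 6] <- 9.5
  sm <- stat_map(stat, p1, c(2, 10), "F", cl_layout$id, (0:9) / 100)
  cl <- find_clusters(sm, 0.05, cl_adj)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$sum, 9.5)
  expect_equal(unname(cl[[1]]$members[1, ]), c(3L, 6L))
})

test_that("t-statistic clusters split by sign", {
  tv <- matrix(0, 5, 10)
  tv[2, 3:5] <- 4; tv[2, 6:7] <- -4
  p <- matrix(1, 5, 10); p[tv != 0] <- 0.01
  sm <- stat_map(tv, p, 8, "t", cl_layout$id, (0:9) / 100)
  cl <- find_clusters(sm, 0.05, cl_adj)
  expect_length(cl, 2L)
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "sum")), c(-8, 12))
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "sign")), c(-1, 1))
})

test_that("permutation null is deterministic, zero on null data, exchangeable", {
  maps <- random_maps(8, 3, seed = 41)
  n1 <- permutation_null(maps, "F", cl_adj, P = 50, seed = 9)
  n2 <- permutation_null(maps, "F", cl_adj, P = 50, seed = 9)
  expect_identical(as.numeric(n1), as.numeric(n2))
  n3 <- permutation_null(maps, "F", cl_adj, P = 50, seed = 10)
  expect_false(identical(as.numeric(n1), as.numeric(n3)))
  expect_length(n1, 50L)
  expect_true(all(n1 >= 0))
  # all-zero data -> no clusters ever
  zmaps <- maps; zmaps$maps[] <- 0
  nz <- permutation_null(zmaps, "F", cl_adj, P = 20, seed = 1)
  expect_true(all(nz == 0))
})

test_that("Monte-Carlo permutation p matches exhaustive sign-flip enumeration", {
  # n = 5 subjects, k = 2: the permutation group is the 2^5 = 32 sign flips
  adj_rows <- erpperm:::adjacency_index_list(cl_adj, cl_layout$id)
  n <- 5L
  tcrit <- qt(0.025, n - 1, lower.tail = FALSE)
  max_t_cluster <- function(dif) {
    m <- colMeans(dif); v <- apply(dif, 2, var)
    tv <- matrix(m / sqrt(v / n), 5, 10)
    best <- 0
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tv > tcrit else tv < -tcrit
      lab <- oracle_flood_fill(mask, adj_rows)
      if (max(lab) > 0)
        for (i in seq_len(max(lab)))
          best <- max(best, abs(sum(tv[lab == i])))
    }
    best
  }
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  for (inst in 1:5) {
    maps <- random_maps(n, 2, seed = 50 + inst, shift = 0)
    maps$maps[, 1, , ] <- maps$maps[, 1, , ] + 0.8 # some signal
    dif <- matrix(maps$maps[, 1, , ] - maps$maps[, 2, , ], n, 50)
    obs <- max_t_cluster(dif)
    exact <- mean(apply(flips, 1, function(s) max_t_cluster(dif * s)) >= obs - 1e-12)
    null <- permutation_null(maps, "t", cl_adj, P = 4000, seed = 7)
    mc <- (1 + sum(null >= obs - 1e-12)) / (1 + 4000)
    expect_lt(abs(mc - exact), 0.02)
  }
})

test_that("cluster p-values follow the add-one convention", {
  mk_cl <- function(s) list(list(members = cbind(1L, 1L), sum = s, sign = 1))
  null <- structure(seq_len(1000) / 10, P = 1000L, class = "permutation_null")
  res <- cluster_p_values(mk_cl(1e9), null)
  expect_equal(res$clusters[[1]]$p, 1 / 1001)
  expect_true(res$any_significant)
  res <- cluster_p_values(mk_cl(0.05), null) # |sum| below every null value
  expect_equal(res$clusters[[1]]$p, 1)
  res <- cluster_p_values(mk_cl(50.05), null) # median of the null
  expect_equal(res$clusters[[1]]$p, 0.5, tolerance = 0.01)
  expect_equal(res$min_p, res$clusters[[1]]$p)
  expect_error(cluster_p_values(mk_cl(1), numeric(0)), "empty")
})

test_that("run_cluster_test wires the stages together", {
  lay <- tiny_layout(5L)
  des <- study_design(n_subjects = 8L, trials_per_condition = 3L,
                      sampling_rate = 100, epoch_window = c(-0.1, 0.4),
                      conditions = c("A", "B", "C"))
  ep <- simulate_noise_epochs(des, noise_spec(sd_broadband = 5), lay, 3)
  res <- run_cluster_test(ep, P = 60, seed = 2, baseline = c(-0.1, 0))
  expect_s3_class(res, "cluster_test_result")
  res2 <- run_cluster_test(ep, P = 60, seed = 2, baseline = c(-0.1, 0))
  expect_identical(cluster_table(res), cluster_table(res2))
  expect_error(run_cluster_test(ep, conditions = "A"), "2 conditions")
  # strong injected effect is found
  spec <- component_spec("blob", 8, c(0.1, 0.3), lay$id[1:3], "A",
                         amplitude_sd = 0)
  res3 <- run_cluster_test(add_component(ep, spec, 1), P = 200, seed = 2,
                           baseline = c(-0.1, 0))
  expect_true(res3$any_significant)
  # F/t consistency: k = 2 pathways flag the same clusters
  maps <- condition_maps(ep, conditions = c("A", "B"))
  adj <- build_adjacency(lay)
  clf <- find_clusters(pointwise_rm_anova(maps), 0.05, adj)
  clt <- find_clusters(pointwise_paired_t(maps), 0.05, adj)
  fmem <- lapply(clf, function(cl) sort(cl$members[, 1] * 1000 + cl$members[, 2]))
  tmem <- lapply(clt, function(cl) sort(cl$members[, 1] * 1000 + cl$members[, 2]))
  expect_setequal(fmem, tmem)
})

test_that("JSON/TSV export round-trips the cluster summaries", {
  maps <- random_maps(6, 3, seed = 61, shift = 0)
  maps$maps[, 1, 2, 3:6] <- maps$maps[, 1, 2, 3:6] + 3
  res <- run_cluster_test(maps, adjacency = cl_adj, P = 50, seed = 4)
  js <- jsonlite::fromJSON(cluster_result_json(res))
  expect_equal(js$P, 50)
  expect_equal(nrow(js$clusters), length(res$clusters))
  expect_equal(js$min_p, res$min_p, tolerance = 1e-12)
  tab <- cluster_table(res)
  expect_equal(tab$sum[1], res$clusters[[1]]$sum)
})
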