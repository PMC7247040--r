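test_that("modularity matches direct evaluation of the definition", {
  # two disjoint unit edges, partitioned by component: Q = 0.5
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  dc <- dense_connectome(w)
  expect_equal(modularity_score(dc, partition(c(0, 0, 1, 1))), 0.5)

  # one community always scores exactly 0 (the null term telescopes)
  expect_equal(modularity_score(dc, partition(rep(0, 4))), 0)
  dc2 <- sbm_connectome(c(5, 5, 5), 6, 1, seed = 3)
  expect_equal(modularity_score(dc2, partition(rep(0, 15))), 0)

  # all singletons on a loop-free graph: Q = -sum(d^2) / m^2
  d <- rowSums(dc2$weights)
  m <- sum(d)
  expect_equal(modularity_score(dc2, partition(0:14)), -sum(d^2) / m^2)

  expect_error(modularity_score(dense_connectome(matrix(0, 3, 3)),
                                partition(c(0, 1, 2))), "empty graph")
  expect_error(modularity_score(dc, partition(c(0, 1))), "cover")
})

test_that("Louvain recovers planted blocks and beats trivial partitions", {
  # two clean blocks: exact recovery
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  dc <- dense_connectome(w)
  out <- louvain_communities(dc, seed = 5)
  expect_true(partitions_equivalent(out, partition(rep(0:1, each = 4))))

  # planted 4-block graph with weak inter-block noise
  planted <- partition(rep(0:3, each = 15))
  dc4 <- sbm_connectome(rep(15, 4), 8, 0.5, seed = 9)
  lv <- louvain_communities(dc4, seed = 5)
  expect_gte(ami(lv, planted), 0.9)

  # delegated optimizer validated against the independent modularity score:
  # output beats both trivial partitions
  q <- modularity_score(dc4, lv)
  expect_gte(q, modularity_score(dc4, partition(rep(0, 60))))
  expect_gte(q, modularity_score(dc4, partition(0:59)))

  # same seed reproduces bit-exactly; complete uniform graph scores >= 0
  expect_identical(as.integer(louvain_communities(dc4, seed = 5)),
                   as.integer(lv))
  kc <- dense_connectome(matrix(1, 6, 6) - diag(6))
  expect_gte(modularity_score(kc, louvain_communities(kc, seed = 1)), 0)
})

test_that("hierarchical parcellation nests and obeys the minimum-parcel rule", {
  # planted 4 super-blocks x 2 sub-blocks with intermediate-tier coupling
  sup <- partition(rep(0:3, each = 30))
  sub <- partition(rep(0:7, each = 15))
  k <- 120
  mu <- matrix(0.2, k, k)
  mu[outer(as.integer(sup), as.integer(sup), "==")] <- 2
  mu[outer(as.integer(sub), as.integer(sub), "==")] <- 8
  w <- with_seed_test(21, matrix(stats::rpois(k * k, mu), k, k))
  w[lower.tri(w, diag = TRUE)] <- 0
  w <- w + t(w)
  h <- hierarchical_parcellation(dense_connectome(w),
                                 parcellation_config(n_levels = 2, seed = 4))
  expect_true(is_nested(h))
  expect_gte(ami(h$levels[[1]], sup), 0.9)
  expect_gte(ami(h$levels[[2]], sub), 0.9)

  # every level-2 region lies inside exactly one level-1 region
  fine <- as.integer(h$levels[[2]])
  coarse <- as.integer(h$levels[[1]])
  expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))

  expect_equal(n_regions(h$levels[[1]]), 4)
  expect_equal(n_regions(h$levels[[2]]), 8)

  # parcels below the minimum fraction are copied unchanged
  dc2 <- sbm_connectome(c(40, 3), 6, 0.2, seed = 6)
  h2 <- hierarchical_parcellation(dense_connectome(dc2$weights),
                                  parcellation_config(n_levels = 2,
                                                      min_parcel_fraction = 0.2,
                                                      seed = 2))
  small <- which(tabulate(as.integer(h2$levels[[1]]) + 1L) < ceiling(0.2 * 43))
  for (r in small - 1L) {
    idx <- which(as.integer(h2$levels[[1]]) == r)
    expect_equal(length(unique(as.integer(h2$levels[[2]])[idx])), 1)
  }

  # one level, no minimum: identical to plain Louvain at the same seed
  h1 <- hierarchical_parcellation(dc2, parcellation_config(n_levels = 1,
                                                           min_parcel_fraction = 0,
                                                           seed = 8))
  expect_identical(as.integer(h1$levels[[1]]),
                   as.integer(louvain_communities(dc2, seed = 8)))
})

test_that("coarsening conserves mass and matches brute-force block sums", {
  w <- matrix(c(0, 2, 1, 0,
                2, 0, 3, 1,
                1, 3, 0, 4,
                0, 1, 4, 0), 4, byrow = TRUE)
  dc <- dense_connectome(w)
  cc <- coarsen(dc, partition(c(0, 0, 1, 1)))
  expect_equal(cc$omega, matrix(c(4, 5, 5, 8), 2))
  expect_equal(cc$region_sizes, c(2, 2))

  # all singletons reproduce W; one region gives the total mass
  expect_equal(coarsen(dc, partition(0:3))$omega, w)
  expect_equal(coarsen(dc, partition(rep(0, 4)))$omega,
               matrix(sum(w), 1, 1))

  # conservation at working scale
  dc2 <- sbm_connectome(c(20, 20, 20), 5, 1, seed = 12)
  p <- rand_partition(60, 7, 3)
  expect_equal(sum(coarsen(dc2, p)$omega), sum(dc2$weights),
               tolerance = 1e-9)

  # block-sum associativity: coarsening by the fine partition then
  # aggregating fine regions equals coarsening by the coarse partition
  coarse <- partition(rep(0:2, each = 20))
  fine <- partition(rep(0:5, each = 10))
  om_f <- coarsen(dc2, fine)$omega
  lift <- tapply(as.integer(coarse), as.integer(fine), unique)  # fine -> coarse
  mb <- membership_matrix(partition(as.integer(lift)))
  expect_equal(t(mb) %*% om_f %*% mb, coarsen(dc2, coarse)$omega,
               ignore_attr = TRUE, tolerance = 1e-12)
})
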