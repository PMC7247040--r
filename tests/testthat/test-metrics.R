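test_that("piecewise-constant approximation is the block mean", {
  w <- matrix(c(0, 2, 1, 0,
                2, 0, 3, 1,
                1, 3, 0, 4,
                0, 1, 4, 0), 4, byrow = TRUE)
  dc <- dense_connectome(w)
  g <- piecewise_constant(dc, partition(c(0, 0, 1, 1)))
  # brute-force block means over off-diagonal pairs
  expect_equal(g[1, 2], 2)            # within block 1: single pair (1,2)
  expect_equal(g[3, 4], 4)            # within block 2
  expect_equal(g[1, 3], (1 + 3 + 0 + 1) / 4)  # between blocks
  expect_equal(diag(g), rep(0, 4))

  # all-singleton partition reproduces W; block-constant input is fixed
  expect_equal(piecewise_constant(dc, partition(0:3)), w)
  wb <- matrix(3, 6, 6)
  wb[1:3, 4:6] <- 1
  wb[4:6, 1:3] <- 1
  diag(wb) <- 0
  dcb <- dense_connectome(wb)
  pb <- partition(rep(0:1, each = 3))
  expect_equal(piecewise_constant(dcb, pb), wb)
})

test_that("KL divergence is nonnegative, zero iff block-constant, and
           non-increasing under refinement", {
  wb <- matrix(3, 6, 6)
  wb[1:3, 4:6] <- 1
  wb[4:6, 1:3] <- 1
  diag(wb) <- 0
  dcb <- dense_connectome(wb)
  pb <- partition(rep(0:1, each = 3))
  expect_equal(kl_divergence(dcb, piecewise_constant(dcb, pb)), 0)

  for (s in 1:10) {
    dc <- sbm_connectome(c(12, 12, 12), 6, 1, seed = s)
    lv1 <- partition(rep(0:2, each = 12))
    lv2 <- partition(rep(0:5, each = 6))
    lv3 <- partition(rep(0:11, each = 3))
    kls <- vapply(list(lv1, lv2, lv3), function(p)
      kl_divergence(dc, piecewise_constant(dc, p)), 0)
    expect_true(all(kls >= 0))
    expect_gt(kls[1], 0)  # Poisson noise is not block-constant
    expect_lte(kls[2], kls[1])
    expect_lte(kls[3], kls[2])
  }
  expect_error(kl_divergence(dcb, matrix(0, 6, 6)), "positive")
})

test_that("mutual information matches the hand-computed contingency oracle", {
  # 2x2 table [[2,1],[1,2]], K = 6
  x <- partition(c(0, 0, 0, 1, 1, 1))
  y <- partition(c(0, 0, 1, 0, 1, 1))
  mi <- mutual_information(x, y)
  p <- matrix(c(2, 1, 1, 2) / 6, 2)
  oracle <- sum(p * log(p / outer(rowSums(p), colSums(p))))
  expect_equal(mi$mi, oracle)
  expect_equal(mi$table, matrix(c(2, 1, 1, 2), 2))

  # identical partitions: MI = H; independent second margin: MI = 0
  expect_equal(mutual_information(x, x)$mi, mi$h_x)
  expect_equal(mutual_information(x, partition(rep(0, 6)))$mi, 0)
  expect_lte(mi$mi, min(mi$h_x, mi$h_y) + 1e-12)
})

test_that("expected MI matches a Monte-Carlo permutation oracle (K <= 12)", {
  cases <- list(list(a = c(3, 3), b = c(3, 3)),
                list(a = c(4, 4, 4), b = c(6, 6)),
                list(a = c(2, 4, 6), b = c(5, 5, 2)),
                list(a = c(1, 11), b = c(6, 6)),
                list(a = c(3, 3, 3, 3), b = c(4, 4, 4)))
  for (cs in cases) {
    k <- sum(cs$a)
    expect_equal(k, sum(cs$b))
    emi <- expected_mi(cs$a, cs$b, k)
    x <- rep(seq_along(cs$a) - 1L, cs$a)
    y <- rep(seq_along(cs$b) - 1L, cs$b)
    mis <- with_seed_test(17, replicate(2e4, {
      mutual_information(partition(sample(x)), partition(y))$mi
    }))
    se <- stats::sd(mis) / sqrt(length(mis))
    expect_lt(abs(emi - mean(mis)), 3 * se + 1e-12)
    expect_lte(emi, min(entropy_oracle(cs$a), entropy_oracle(cs$b)) + 1e-12)
  }
  # a single row cluster forces MI = 0 under any table
  expect_equal(expected_mi(12, c(5, 7), 12), 0)
})

test_that("AMI is 1 exactly on relabeled copies and near 0 on noise", {
  for (s in 1:5) {
    p <- rand_partition(200, 8, s)
    expect_identical(ami(p, shuffle_labels(p, s + 10)), 1)
  }
  # independent uniform partitions of 1000 vertices into 10 clusters
  a <- rand_partition(1000, 10, 31)
  b <- rand_partition(1000, 10, 32)
  expect_lt(abs(ami(a, b)), 0.05)
  # symmetry and relabeling invariance
  x <- rand_partition(60, 4, 1)
  y <- rand_partition(60, 5, 2)
  expect_equal(ami(x, y), ami(y, x))
  expect_equal(ami(shuffle_labels(x, 9), y), ami(x, y))
  # composition of the MI and E[MI] oracles on a fixed 2x2 table
  x2 <- partition(c(0, 0, 0, 1, 1, 1))
  y2 <- partition(c(0, 0, 1, 0, 1, 1))
  mi <- mutual_information(x2, y2)
  emi <- expected_mi(c(3, 3), c(3, 3), 6)
  expect_equal(ami(x2, y2), (mi$mi - emi) / (max(mi$h_x, mi$h_y) - emi))
  # degenerate: both trivial
  expect_equal(ami(partition(rep(0, 5)), partition(rep(2, 5))), 1)
})

test_that("minimal-cover Dice follows direct set arithmetic", {
  y <- partition(rep(0:3, each = 10))
  expect_equal(dice_min_cover(1:10, y), 1)
  # |X| = 10 split 6/4 across two regions of size 10: 2*10 / (10 + 20)
  expect_equal(dice_min_cover(c(1:6, 11:14), y), 2 / 3)
  # single-region cover: closed form 2|X| / (|X| + K)
  y1 <- partition(rep(0, 40))
  expect_equal(dice_min_cover(1:10, y1), 2 * 10 / (10 + 40))
  expect_error(dice_min_cover(integer(0), y), "nonempty")
})

test_that("hemispheric symmetry scores mirrored and scrambled labelings", {
  m <- fixture_mesh(2)
  p <- planted_parcellation(m, 8, seed = 3, mirrored = TRUE)
  expect_equal(hemispheric_symmetry(p, m), 1)
  # randomizing the right hemisphere destroys symmetry
  lab <- as.integer(p)
  right <- which(m$hemisphere == "R")
  lab[right] <- with_seed_test(5, sample(lab[right]))
  expect_lt(abs(hemispheric_symmetry(partition(lab), m)), 0.1)
})

test_that("contiguity equals the independent connected-component oracle", {
  m <- fixture_mesh(1)
  p <- planted_parcellation(m, 4, seed = 2, mirrored = TRUE)
  expect_equal(contiguity(p, m), 1)
  # relabeling-invariant
  expect_equal(contiguity(shuffle_labels(p, 4), m), 1)

  # oracle: plain BFS over an adjacency list, no igraph
  adj <- adjacency_list_oracle(m)
  for (s in 1:8) {
    lab <- as.integer(perturb_hierarchy(p, m, 0.25, seed = s))
    good <- 0
    for (l in unique(lab)) {
      vs <- which(lab == l)
      if (bfs_components_oracle(vs, adj) == 1) good <- good + length(vs)
    }
    expect_equal(contiguity(partition(lab), m), good / length(lab))
  }
})

test_that("graph characteristics match closed forms on canonical graphs", {
  # complete K5 with unit weights: CC = 1, APL = 1
  k5 <- structure(list(omega = matrix(1, 5, 5) - diag(5),
                       region_sizes = rep(1L, 5)),
                  class = "coarse_connectome")
  gc5 <- graph_characteristics(k5)
  expect_equal(gc5$clustering_coefficient, 1)
  expect_equal(gc5$average_path_length, 1)

  # path 0-1-2: CC = 0, APL = (1 + 1 + 2) / 3
  pw <- matrix(0, 3, 3)
  pw[1, 2] <- pw[2, 1] <- pw[2, 3] <- pw[3, 2] <- 1
  pg <- structure(list(omega = pw, region_sizes = rep(1L, 3)),
                  class = "coarse_connectome")
  gcp <- graph_characteristics(pg)
  expect_equal(gcp$clustering_coefficient, 0)
  expect_equal(gcp$average_path_length, 4 / 3)

  # homogeneity: scaling weights keeps CC, divides path lengths
  cc <- coarsen(sbm_connectome(c(6, 6, 6), 5, 1, seed = 3),
                partition(rep(0:5, each = 3)))
  g1 <- graph_characteristics(cc)
  cc2 <- cc
  cc2$omega <- cc$omega * 7
  g2 <- graph_characteristics(cc2)
  expect_equal(g2$clustering_coefficient, g1$clustering_coefficient)
  expect_equal(g2$average_path_length, g1$average_path_length / 7)

  expect_error(graph_characteristics(
    structure(list(omega = matrix(0, 2, 2), region_sizes = c(1L, 1L)),
              class = "coarse_connectome")), "fewer than 3")
})

test_that("ensemble goodness is the mean AMI to the cohort", {
  p <- rand_partition(50, 5, 1)
  expect_equal(ensemble_goodness(p, rep(list(p), 4)), 1)
  cohort <- lapply(1:6, function(s) rand_partition(50, 5, s + 10))
  g <- ensemble_goodness(p, cohort)
  expect_lte(g, 1)
  expect_equal(g, mean(vapply(cohort, function(ci) ami(ci, p), 0)))
})
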