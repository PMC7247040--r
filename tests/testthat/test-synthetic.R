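test_that("icosphere has the exact subdivision combinatorics", {
  for (ord in 0:3) {
    m <- fixture_mesh(ord)
    expect_equal(nrow(m$positions), 2 * (10 * 4^ord + 2))
    expect_equal(nrow(m$triangles), 2 * 20 * 4^ord)
    expect_equal(nrow(mesh_adjacency(m, as = "edges")), 2 * 30 * 4^ord)
    # vertices on the unit sphere; validated two-component closed manifold
    expect_equal(sqrt(rowSums(m$positions^2)), rep(1, nrow(m$positions)))
    expect_true(validate_mesh(m))
  }
  expect_error(icosphere(8), "refused")
  expect_error(icosphere(-1), ">= 0")
})

test_that("planted Voronoi parcellations are contiguous, mirrored and full", {
  m <- fixture_mesh(2)
  for (s in 1:10) {
    p <- planted_parcellation(m, 8, seed = s, mirrored = TRUE)
    expect_equal(n_regions(p), 8)
    expect_equal(contiguity(p, m), 1)
    expect_equal(hemispheric_symmetry(p, m), 1)
  }
  p2 <- planted_parcellation(m, 7, seed = 1, mirrored = FALSE)
  expect_equal(n_regions(p2), 7)
  expect_equal(contiguity(p2, m), 1)
  expect_error(planted_parcellation(m, 4000, seed = 1), "K/2")
  expect_error(planted_parcellation(m, 7, seed = 1, mirrored = TRUE), "even")
})

test_that("planted hierarchies nest and label perturbation stays local", {
  spec <- cohort_spec(mesh_order = 2L, seed = 5L)
  m <- fixture_mesh(2)
  h <- planted_hierarchy(m, spec)
  expect_true(is_nested(h))
  expect_equal(n_regions(h$levels[[1]]), spec$n_super_regions)
  expect_equal(n_regions(h$levels[[2]]),
               spec$n_super_regions * spec$n_sub_regions)

  noisy <- perturb_hierarchy(h, m, 0.15, seed = 3)
  expect_true(is_nested(noisy))
  # permutation-invariant changed fraction: d = 2K - 2 max matched agreement
  k <- length(h$levels[[2]])
  frac_changed <- partition_distance(noisy$levels[[2]], h$levels[[2]]) / (2 * k)
  expect_lte(frac_changed, 0.15 + 1e-9)
  expect_gt(frac_changed, 0)
  # zero noise is the identity
  same <- perturb_hierarchy(h, m, 0, seed = 3)
  expect_identical(lapply(same$levels, as.integer),
                   lapply(lapply(h$levels, relabel_canonical), as.integer))
})

test_that("simulated connectomes honour the planted block intensities", {
  m <- fixture_mesh(2)
  spec0 <- cohort_spec(mesh_order = 2L, label_noise = 0, edge_noise = 0,
                       between_intensity = 0, within_intensity = 4,
                       mid_intensity = 0.0001, seed = 2L)
  h <- planted_hierarchy(m, spec0)
  w0 <- simulate_connectome(m, h, spec0, subject_seed = 7L)
  # essentially block-diagonal on the deepest planted blocks
  sub <- as.integer(h$levels[[2]])
  off_block <- w0$weights[outer(sub, sub, "!=")]
  expect_lt(mean(off_block > 0), 1e-3)

  # empirical within-block mean close to the intensity (law of large numbers)
  spec1 <- cohort_spec(mesh_order = 2L, label_noise = 0, edge_noise = 0.1,
                       within_intensity = 8, seed = 2L)
  w1 <- simulate_connectome(m, h, spec1, subject_seed = 9L)
  same <- outer(sub, sub, "==") & upper.tri(w1$weights)
  vals <- w1$weights[same]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 8), 3 * se)

  # determinism: same subject seed is bit-exact, different seeds differ
  w1b <- simulate_connectome(m, h, spec1, subject_seed = 9L)
  expect_identical(w1$weights, w1b$weights)
  w2 <- simulate_connectome(m, h, spec1, subject_seed = 10L)
  expect_false(identical(w1$weights, w2$weights))
})

test_that("cohorts are reproducible, valid, and recoverable end-to-end", {
  spec <- cohort_spec(mesh_order = 2L, n_subjects = 3L, label_noise = 0,
                      edge_noise = 0, seed = 8L)
  coh <- simulate_cohort(spec)
  expect_length(coh$connectomes, 3)
  coh2 <- simulate_cohort(spec)
  expect_identical(coh$connectomes[[2]]$weights, coh2$connectomes[[2]]$weights)

  # single noiseless subject: level-1 parcellation recovers planted blocks
  h <- hierarchical_parcellation(coh$connectomes[[1]],
                                 parcellation_config(n_levels = 2, seed = 2))
  expect_gte(ami(h$levels[[1]], coh$truth$levels[[1]]), 0.95)
})

test_that("HE consensus degrades gracefully with label noise and beats the
           median subject", {
  coh <- fixture_cohort2(n = 10L, seed = 13L)
  m <- coh$mesh
  truth <- coh$truth$levels[[2]]
  mean_recovery <- vapply(c(0.05, 0.35), function(noise) {
    mean(vapply(1:3, function(r) {
      cohort <- lapply(1:10, function(i)
        perturb_hierarchy(truth, m, noise, seed = 100 * r + i))
      ami(hard_ensemble(cohort), truth)
    }, 0))
  }, 0)
  expect_gte(mean_recovery[1], mean_recovery[2])

  cohort <- lapply(1:10, function(i) perturb_hierarchy(truth, m, 0.2, seed = i))
  he_ami <- ami(hard_ensemble(cohort), truth)
  subj_ami <- vapply(cohort, function(p) ami(p, truth), 0)
  expect_gte(he_ami, stats::median(subj_ami))
})

test_that("a cohort round trips through the on-disk layout", {
  spec <- cohort_spec(mesh_order = 1L, n_subjects = 2L, seed = 4L)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "mesh.ply")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_connectome(file.path(dir, "subject001.mtx"))
  expect_equal(back$weights, coh$connectomes[[1]]$weights, tolerance = 1e-6)
  truth <- load_labels(file.path(dir, "truth_level1.tsv"))
  expect_true(partitions_equivalent(truth, coh$truth$levels[[1]]))
})
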