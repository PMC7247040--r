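#' Experiment configuration
#'
#' @param sparsity_levels fractions of heaviest edges retained in the sweep.
#' @param n_splits number of half-sample splits for the stability harness.
#' @param n_order_perms number of cohort-order permutations for the
#'   order-stability harness.
#' @param methods consensus methods to evaluate.
#' @param levels hierarchy levels to evaluate.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(sparsity_levels = seq(0.1, 1, by = 0.1),
                              n_splits = 100L, n_order_perms = 100L,
                              methods = c("HE", "CSPA", "Average"),
                              levels = 1:3, seed = 1L) {
  stopifnot(all(sparsity_levels > 0), all(sparsity_levels <= 1),
            n_splits >= 2L)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(sparsity_levels = sparsity_levels,
                 n_splits = as.integer(n_splits),
                 n_order_perms = as.integer(n_order_perms),
                 methods = methods, levels = as.integer(levels),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Sparsity sweep: consensus quality across edge-density thresholds
#'
#' For every sparsity level, individual connectomes are thresholded to their
#' heaviest edges, parcellated hierarchically, and aggregated by each
#' requested consensus method; per method and hierarchy level the report
#' records the region count, ensemble goodness, the mean KL divergence of
#' the subjects' (sparsified) connectomes from their consensus
#' block-approximation, hemispheric symmetry and contiguity (when a mesh is
#' supplied), and weighted graph characteristics of the coarse mean
#' connectome. The intramethod similarity table holds the mean pairwise AMI
#' of each method/level's partitions across sparsity levels.
#'
#' @param connectomes nonempty list of [dense_connectome()]s.
#' @param config an [experiment_config()].
#' @param parcellation a [parcellation_config()].
#' @param mesh optional [surface_mesh()] for symmetry/contiguity.
#' @return list with data frames `report` and `intramethod`, and the
#'   consensus `partitions` (indexed by sparsity/method/level).
#' @export
sparsity_sweep <- function(connectomes, config = experiment_config(),
                           parcellation = parcellation_config(),
                           mesh = NULL) {
  if (length(connectomes) == 0L) stop("cohort must be nonempty")
  rows <- list()
  partitions <- list()
  for (q in config$sparsity_levels) {
    sparse <- lapply(connectomes, sparsify, q = q)
    indiv <- lapply(seq_along(sparse), function(i) {
      cfg_i <- parcellation
      cfg_i$seed <- derive_seed(parcellation$seed, i)
      hierarchical_parcellation(sparse[[i]], cfg_i)
    })
    mean_w <- dense_connectome(
      Reduce(`+`, lapply(sparse, `[[`, "weights")) / length(sparse))
    fits <- list()
    if ("HE" %in% config$methods) {
      fits$HE <- hierarchical_partition(lapply(config$levels, function(l)
        hard_ensemble(lapply(indiv, function(h) h$levels[[l]]))))
    }
    if ("CSPA" %in% config$methods) {
      deepest <- lapply(indiv, function(h) h$levels[[length(h$levels)]])
      fits$CSPA <- cspa(deepest, parcellation)
    }
    if ("Average" %in% config$methods) {
      fits$Average <- average_graph_parcellation(sparse, parcellation)
    }
    for (method in names(fits)) {
      for (li in seq_along(config$levels)) {
        l <- config$levels[[li]]
        cons <- fits[[method]]$levels[[li]]
        partitions[[sprintf("q%.2f_%s_L%d", q, method, l)]] <- cons
        kl <- mean(vapply(sparse, function(w)
          kl_divergence(w, piecewise_constant(w, cons)), 0))
        gch <- tryCatch(graph_characteristics(coarsen(mean_w, cons)),
                        error = function(e) list(clustering_coefficient = NA_real_,
                                                 average_path_length = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          sparsity = q, method = method, level = l,
          n_regions = n_regions(cons),
          goodness = ensemble_goodness(
            cons, lapply(indiv, function(h) h$levels[[l]])),
          kl = kl,
          symmetry = if (is.null(mesh)) NA_real_ else hemispheric_symmetry(cons, mesh),
          contiguity = if (is.null(mesh)) NA_real_ else contiguity(cons, mesh),
          clustering_coefficient = gch$clustering_coefficient,
          average_path_length = gch$average_path_length)
      }
    }
  }
  report <- do.call(rbind, rows)
  intra <- list()
  for (method in config$methods) for (l in config$levels) {
    ps <- partitions[grep(sprintf("_%s_L%d$", method, l), names(partitions))]
    if (length(ps) < 2L) next
    pairs <- utils::combn(length(ps), 2L)
    intra[[length(intra) + 1L]] <- data.frame(
      method = method, level = l,
      intramethod_similarity = mean(apply(pairs, 2, function(ij)
        ami(ps[[ij[1]]], ps[[ij[2]]]))))
  }
  list(report = report,
       intramethod = if (length(intra)) do.call(rbind, intra) else NULL,
       partitions = partitions)
}

pairwise_ami <- function(parts) {
  pairs <- utils::combn(length(parts), 2L)
  apply(pairs, 2, function(ij) ami(parts[[ij[1]]], parts[[ij[2]]]))
}

#' Split-half stability of the consensus
#'
#' Draws `n_splits` random half-samples of the cohort (halves without
#' replacement), computes one hard-ensemble consensus per split, and returns
#' all `n_splits * (n_splits - 1) / 2` unordered pairwise AMI values between
#' the split consensuses.
#'
#' @param cohort list of at least 4 partitions (individual parcellations at
#'   one hierarchy level) on a common vertex set.
#' @param config an [experiment_config()].
#' @return numeric vector of pairwise AMI values.
#' @export
split_half_stability <- function(cohort, config = experiment_config()) {
  n <- length(cohort)
  if (n < 4L) stop("split-half stability needs at least 4 subjects")
  half <- n %/% 2L
  ensembles <- lapply(seq_len(config$n_splits), function(s) {
    idx <- with_seed(derive_seed(config$seed, 7L, s), sample.int(n, half))
    hard_ensemble(cohort[idx])
  })
  pairwise_ami(ensembles)
}

#' Order-permutation stability of the hard ensemble
#'
#' The hard ensemble is order-dependent; this harness reruns it under
#' `n_order_perms` random cohort orders and returns all pairwise AMI values
#' between the resulting consensuses.
#'
#' @param cohort list of at least 2 partitions on a common vertex set.
#' @param config an [experiment_config()].
#' @return numeric vector of pairwise AMI values.
#' @export
order_permutation_stability <- function(cohort, config = experiment_config()) {
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  ensembles <- lapply(seq_len(config$n_order_perms), function(s)
    hard_ensemble(cohort, order_seed = derive_seed(config$seed, 11L, s)))
  pairwise_ami(ensembles)
}

auc_rank <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Classification harness on consensus-coarsened connectomes
#'
#' Evaluates whether the consensus-parcellated (coarse) connectomes retain
#' biologically discriminative signal. The consensus parcellation is fitted
#' by hard ensemble on one stratified half of the subjects and applied,
#' via [coarsen()], to the held-out half only; on that half an outer
#' stratified 5-fold cross-validation measures ROC AUC of an L1-penalized
#' logistic regression on the upper-triangle coarse edge weights (including
#' within-region weights), with the penalty strength chosen by inner
#' cross-validation on each outer training set. Features are standardized
#' from training data only (within [glmnet::cv.glmnet()]).
#'
#' @param connectomes list of [dense_connectome()]s.
#' @param labels binary class vector (two classes, >= 2 subjects each).
#' @param parcellation a [parcellation_config()].
#' @param level hierarchy level of the consensus used for coarsening.
#' @param n_outer,n_inner outer / inner fold counts.
#' @param seed integer seed for the half split and folds.
#' @return list with `auc` (one value per outer fold), `n_regions`,
#'   `n_features`, and the consensus `partition`.
#' @export
classification_eval <- function(connectomes, labels,
                                parcellation = parcellation_config(),
                                level = parcellation$n_levels,
                                n_outer = 5L, n_inner = 5L, seed = 1L) {
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("labels must contain exactly two classes")
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class")
  n <- length(connectomes)
  half_id <- stratified_folds(y, 2L, derive_seed(seed, 1L))
  fit_idx <- which(half_id == 1L)
  eval_idx <- which(half_id == 2L)
  indiv <- lapply(fit_idx, function(i) {
    cfg_i <- parcellation
    cfg_i$seed <- derive_seed(parcellation$seed, i)
    hierarchical_parcellation(connectomes[[i]], cfg_i)$levels[[level]]
  })
  cons <- hard_ensemble(indiv)
  feats <- t(vapply(eval_idx, function(i) {
    om <- coarsen(connectomes[[i]], cons)$omega
    om[upper.tri(om, diag = TRUE)]
  }, numeric(n_regions(cons) * (n_regions(cons) + 1) / 2)))
  ye <- y[eval_idx]
  fold <- stratified_folds(ye, n_outer, derive_seed(seed, 2L))
  aucs <- vapply(seq_len(n_outer), function(f) {
    tr <- fold != f
    cv <- with_seed(derive_seed(seed, 3L, f),
                    glmnet::cv.glmnet(feats[tr, , drop = FALSE], ye[tr],
                                      family = "binomial", alpha = 1,
                                      nfolds = n_inner, standardize = TRUE))
    pred <- stats::predict(cv, feats[!tr, , drop = FALSE], s = "lambda.min",
                           type = "response")[, 1]
    auc_rank(pred, ye[!tr])
  }, 0)
  list(auc = aucs, n_regions = n_regions(cons),
       n_features = ncol(feats), partition = cons)
}

#' Per-region minimal-cover Dice table
#'
#' Computes [dice_min_cover()] of every region of an anatomical partition
#' against a consensus partition, sorted by decreasing agreement.
#'
#' @param anatomical,ensemble partitions on a common vertex set.
#' @param path optional TSV output path (a JSON sidecar records provenance).
#' @return data frame with `region`, `size`, `cover_size`, `dice`.
#' @export
atlas_overlap_report <- function(anatomical, ensemble, path = NULL) {
  if (length(anatomical) != length(ensemble)) {
    stop("partitions must cover the same vertex set")
  }
  lab <- as.integer(relabel_canonical(anatomical))
  elab <- as.integer(ensemble)
  rows <- lapply(sort(unique(lab)), function(r) {
    idx <- which(lab == r)
    cover <- sum(elab %in% unique(elab[idx]))
    data.frame(region = r, size = length(idx), cover_size = cover,
               dice = dice_min_cover(idx, ensemble))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dice), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(path, list(kind = "atlas_overlap",
                                n_regions = nrow(out)))
  }
  out
}
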