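# Genetic-algorithm wrapper feature selection.
#
# Bit-string genomes over the feature columns are evolved against a
# k-nearest-neighbour (cosine distance) cross-validated misclassification
# rate. Tournament selection of size 2, arithmetic crossover thresholded back
# to bits, per-bit uniform mutation, and elitism.

#' Genetic-algorithm configuration
#'
#' Defaults follow the reference parameterization: population 100, 300
#' generations, crossover probability 0.8, mutation probability 0.1,
#' tournament size 2, elite count 2, and a KNN (k = 2, cosine) error fitness
#' under stratified cross-validation. The genome length always equals the
#' number of features being selected over.
#'
#' @param genome_length number of features (bits per genome).
#' @param population_size genomes per generation.
#' @param generations number of generations to evolve.
#' @param crossover_prob probability a child is produced by crossover.
#' @param mutation_prob per-bit flip probability.
#' @param tournament_size tournament size for parent selection.
#' @param elite_count best genomes copied unchanged each generation.
#' @param fitness_cv_folds stratified cross-validation folds in the fitness.
#' @param knn_k neighbours in the KNN fitness classifier.
#' @param seed integer seed.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(genome_length = 32, population_size = 100,
                      generations = 300, crossover_prob = 0.8,
                      mutation_prob = 0.1, tournament_size = 2,
                      elite_count = 2, fitness_cv_folds = 5, knn_k = 2,
                      seed = 1L) {
  stopifnot_scalar_num(crossover_prob, "crossover_prob", 0, 1)
  stopifnot_scalar_num(mutation_prob, "mutation_prob", 0, 1)
  if (elite_count >= population_size) stop("elite_count must be < population_size")
  structure(list(genome_length = as.integer(genome_length),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 elite_count = as.integer(elite_count),
                 fitness_cv_folds = as.integer(fitness_cv_folds),
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "ga_config")
}

# Cosine KNN prediction. Ties in the vote are broken towards the nearer
# neighbour, so k = 2 degenerates gracefully to 1-NN on disagreement.
.knn_cosine <- function(train_x, train_y, test_x, k) {
  nrm <- function(M) {
    n <- sqrt(rowSums(M^2))
    n[n == 0] <- 1
    M / n
  }
  sim <- tcrossprod(nrm(as.matrix(test_x)), nrm(as.matrix(train_x)))
  lev <- levels(train_y)
  out <- character(nrow(sim))
  k <- min(k, length(train_y))
  for (r in seq_len(nrow(sim))) {
    ord <- order(sim[r, ], decreasing = TRUE)[seq_len(k)]
    labs <- train_y[ord]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    out[r] <- as.character(labs[match(TRUE, as.character(labs) %in% winners)])
  }
  factor(out, levels = lev)
}

# Deterministic stratified fold assignment for a labeled table.
.stratified_folds <- function(y, nfolds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    fold
  })
}

#' KNN wrapper fitness of a feature mask
#'
#' Stratified `fitness_cv_folds`-fold cross-validated misclassification rate
#' of a cosine-distance KNN restricted to the masked feature columns. An
#' empty mask scores the worst possible fitness (1.0) rather than erroring,
#' so the search can traverse such genomes.
#'
#' @param table a `feature_table` (feature columns plus `class`).
#' @param mask logical or 0/1 vector over the feature columns.
#' @param cfg a [ga_config()].
#' @return misclassification rate in \[0, 1\]; deterministic given the seed.
#' @export
knn_fitness <- function(table, mask, cfg = ga_config()) {
  X <- as.matrix(table[, setdiff(names(table), "class"), drop = FALSE])
  y <- table$class
  mask <- as.logical(mask)
  if (!any(mask)) return(1.0)
  X <- X[, mask, drop = FALSE]
  folds <- .stratified_folds(y, cfg$fitness_cv_folds, cfg$seed)
  wrong <- 0L
  for (f in seq_len(cfg$fitness_cv_folds)) {
    te <- folds == f
    if (!any(te)) next
    pred <- .knn_cosine(X[!te, , drop = FALSE], droplevels(y[!te]),
                        X[te, , drop = FALSE], cfg$knn_k)
    wrong <- wrong + sum(as.character(pred) != as.character(y[te]))
  }
  wrong / length(y)
}

#' Run the genetic-algorithm feature search
#'
#' Evolves bit-string genomes with tournament selection, arithmetic
#' crossover (per-gene convex combination with a uniform random weight,
#' thresholded at 0.5 back to a bit), per-bit uniform mutation and elitism.
#' The initial population is uniform random bits with the all-ones genome
#' injected once, so the full feature set is always evaluated and the best
#' fitness can only improve on it.
#'
#' @param table a `feature_table` with at least 2 samples per class.
#' @param cfg a [ga_config()]; `genome_length` must equal the feature count.
#' @return an object of class `jm_selection`: `best_mask` (logical),
#'   `best_fitness`, `fitness_trajectory` (best error after initialization
#'   and after each generation; non-increasing), `selected_names`.
#' @export
ga_run <- function(table, cfg = ga_config()) {
  feats <- setdiff(names(table), "class")
  if (length(feats) != cfg$genome_length) {
    stop(sprintf("ga_run: genome_length (%d) must equal feature count (%d)",
                 cfg$genome_length, length(feats)))
  }
  y <- droplevels(table$class)
  if (nlevels(y) < 2) stop("ga_run: table must contain at least two classes")
  if (min(table(y)) < 2) stop("ga_run: every class needs >= 2 samples")
  L <- cfg$genome_length
  cache <- new.env(parent = emptyenv())
  fit1 <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- knn_fitness(table, mask, cfg)
    cache[[key]] <- val
    val
  }
  with_seed(cfg$seed, {
    pop <- matrix(stats::runif(cfg$population_size * L) < 0.5,
                  cfg$population_size, L)
    pop[1, ] <- TRUE
    fitness <- apply(pop, 1, fit1)
    traj <- min(fitness)
    for (g in seq_len(cfg$generations)) {
      ord <- order(fitness)
      newpop <- pop[ord[seq_len(cfg$elite_count)], , drop = FALSE]
      while (nrow(newpop) < cfg$population_size) {
        pick <- function() {
          cand <- sample.int(cfg$population_size, cfg$tournament_size)
          cand[which.min(fitness[cand])]
        }
        a <- pop[pick(), ]
        if (stats::runif(1) < cfg$crossover_prob) {
          b <- pop[pick(), ]
          w <- stats::runif(L)
          child <- (w * a + (1 - w) * b) >= 0.5
        } else {
          child <- a
        }
        flip <- stats::runif(L) < cfg$mutation_prob
        child <- xor(child, flip)
        newpop <- rbind(newpop, child)
      }
      pop <- newpop
      fitness <- apply(pop, 1, fit1)
      traj <- c(traj, min(fitness))
    }
    best <- which.min(fitness)
    structure(list(best_mask = as.logical(pop[best, ]),
                   best_fitness = fitness[best],
                   fitness_trajectory = traj,
                   selected_names = feats[as.logical(pop[best, ])]),
              class = "jm_selection")
  })
}

#' @export
print.jm_selection <- function(x, ...) {
  cat(sprintf("<jm_selection> %d/%d features, CV error %.4f\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness))
  cat("  ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Feature-importance profile over repeated GA runs
#'
#' For each feature, the percentage of runs whose best mask includes it --
#' the selection-frequency reading of per-feature importance.
#'
#' @param results list of `jm_selection` objects (>= 1).
#' @param names optional feature names; defaults to those of the first result.
#' @return data.frame with columns `feature` and `pct`, sorted decreasing.
#' @export
importance_profile <- function(results, names = NULL) {
  if (!length(results)) stop("importance_profile: need at least one result")
  masks <- vapply(results, function(r) as.numeric(r$best_mask),
                  numeric(length(results[[1]]$best_mask)))
  pct <- rowMeans(masks) * 100
  nm <- if (!is.null(names)) names else results[[1]]$selected_names_all
  if (is.null(nm)) {
    nm <- texture_feature_names()
    if (length(nm) != length(pct)) nm <- paste0("f", seq_along(pct))
  }
  out <- data.frame(feature = nm, pct = pct)
  out[order(-out$pct, out$feature), , drop = FALSE]
}
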