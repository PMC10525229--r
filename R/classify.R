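# Training and evaluation of the six jaw-movement classifiers, plus the
# pixel-level spectrogram labeling used for visual inspection of events.
#
# Distance/gradient based models (SVM, MLP, KNN, k-means) see z-scored
# features (scaler fit on the training split); trees and naive Bayes see raw
# features. K-means is scored as a classifier by mapping each cluster to the
# majority training label, ties broken towards the lowest class index.

.jm_kinds <- c("naive_bayes", "knn", "svm", "decision_tree", "mlp", "kmeans")

#' Classifier configuration
#'
#' @param kind one of `"naive_bayes"`, `"knn"`, `"svm"`, `"decision_tree"`,
#'   `"mlp"`, `"kmeans"`.
#' @param knn_k neighbours for the KNN classifier.
#' @param knn_metric only `"cosine"` is provided.
#' @param svm_kernel kernel for the SVM (default radial basis, C = 1).
#' @param mlp_hidden hidden layer size of the single-hidden-layer perceptron.
#' @param kmeans_k number of clusters (one per class).
#' @param seed integer seed for the stochastic fits (MLP, k-means).
#' @return an object of class `model_config`.
#' @export
model_config <- function(kind, knn_k = 2, knn_metric = "cosine",
                         svm_kernel = "radial", mlp_hidden = 32,
                         kmeans_k = 4, seed = 1L) {
  if (!(kind %in% .jm_kinds)) {
    stop("unknown classifier kind: ", kind, " (expected one of ",
         paste(.jm_kinds, collapse = ", "), ")")
  }
  if (!identical(knn_metric, "cosine")) stop("only the cosine KNN metric is provided")
  structure(list(kind = kind, knn_k = as.integer(knn_k), knn_metric = knn_metric,
                 svm_kernel = svm_kernel, mlp_hidden = as.integer(mlp_hidden),
                 kmeans_k = as.integer(kmeans_k), seed = as.integer(seed)),
            class = "model_config")
}

.split_xy <- function(table) {
  feats <- setdiff(names(table), "class")
  list(x = as.matrix(table[, feats, drop = FALSE]), y = table$class,
       features = feats)
}

.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

.apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu, "-"), 2, scaler$sd, "/")
}

#' Stratified train/test split
#'
#' Splits a feature table class-by-class so per-class proportions are
#' preserved; the default reserves two thirds for training and one third for
#' testing.
#'
#' @param table a `feature_table`.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(table, train_fraction = 2 / 3, seed = 1L) {
  stopifnot_scalar_num(train_fraction, "train_fraction", 1e-9, 1 - 1e-9)
  y <- table$class
  counts <- table(y)
  if (any(counts > 0 & counts < 2)) {
    stop("split_train_test: every present class needs >= 2 samples, got: ",
         paste(names(counts)[counts > 0 & counts < 2], collapse = ", "))
  }
  with_seed(seed, {
    tr <- logical(nrow(table))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      if (!length(idx)) next
      ntr <- max(1L, round(length(idx) * train_fraction))
      ntr <- min(ntr, length(idx) - 1L)
      tr[sample(idx, ntr)] <- TRUE
    }
    list(train = table[tr, , drop = FALSE], test = table[!tr, , drop = FALSE])
  })
}

#' Train one of the six jaw-movement classifiers
#'
#' @param kind classifier kind (see [model_config()]), or pass `cfg`.
#' @param train a `feature_table` of training rows.
#' @param cfg a [model_config()]; built from `kind` if omitted.
#' @return an object of class `jm_model`.
#' @export
train_classifier <- function(kind, train, cfg = model_config(kind)) {
  stopifnot(inherits(cfg, "model_config"))
  d <- .split_xy(train)
  x <- d$x; y <- droplevels(d$y)
  scaled <- cfg$kind %in% c("svm", "mlp", "knn", "kmeans")
  scaler <- if (scaled) .fit_scaler(x) else NULL
  xs <- if (scaled) .apply_scaler(scaler, x) else x
  fit <- switch(
    cfg$kind,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y),
    knn = list(x = xs, y = y),
    svm = e1071::svm(x = xs, y = y, kernel = cfg$svm_kernel, cost = 1,
                     scale = FALSE),
    decision_tree = {
      df <- as.data.frame(x)
      names(df) <- make.names(names(df))
      df$.class <- y
      rpart::rpart(.class ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = 0, xval = 0, minsplit = 5))
    },
    mlp = with_seed(cfg$seed,
      nnet::nnet(x = xs, y = stats::model.matrix(~ y - 1),
                 size = cfg$mlp_hidden, softmax = TRUE, maxit = 500,
                 trace = FALSE, MaxNWts = 1e5)),
    kmeans = with_seed(cfg$seed, {
      km <- stats::kmeans(xs, centers = cfg$kmeans_k, nstart = 50,
                          iter.max = 100)
      # majority training label per cluster; ties -> lowest class index
      map <- character(cfg$kmeans_k)
      for (cl in seq_len(cfg$kmeans_k)) {
        tab <- table(y[km$cluster == cl])
        map[cl] <- if (sum(tab) == 0) levels(y)[1]
                   else names(tab)[which.max(tab)]
      }
      list(centers = km$centers, map = map)
    }),
    stop("unknown classifier kind: ", cfg$kind)
  )
  structure(list(kind = cfg$kind, fit = fit, scaler = scaler,
                 levels = levels(y), features = d$features, config = cfg),
            class = "jm_model")
}

#' Predict jaw-movement classes for new feature rows
#'
#' @param object a `jm_model`.
#' @param newdata a `feature_table` or numeric matrix with the training
#'   feature columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.jm_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, object$features, drop = FALSE])
  } else {
    m <- as.matrix(newdata)
    if (!is.null(colnames(m)) && all(object$features %in% colnames(m))) {
      m <- m[, object$features, drop = FALSE]
    } else {
      m <- m[, seq_along(object$features), drop = FALSE]
      colnames(m) <- object$features
    }
    m
  }
  xs <- if (!is.null(object$scaler)) .apply_scaler(object$scaler, x) else x
  out <- switch(
    object$kind,
    naive_bayes = stats::predict(object$fit, as.data.frame(x)),
    knn = .knn_cosine(object$fit$x, object$fit$y, xs, object$config$knn_k),
    svm = stats::predict(object$fit, xs),
    decision_tree = {
      df <- as.data.frame(x)
      names(df) <- make.names(object$features)
      stats::predict(object$fit, df, type = "class")
    },
    mlp = {
      pr <- stats::predict(object$fit, xs)
      factor(object$levels[max.col(pr, ties.method = "first")],
             levels = object$levels)
    },
    kmeans = {
      cen <- object$fit$centers
      d2 <- outer(rowSums(xs^2), rep(1, nrow(cen))) - 2 * tcrossprod(xs, cen) +
        outer(rep(1, nrow(xs)), rowSums(cen^2))
      factor(object$fit$map[max.col(-d2, ties.method = "first")],
             levels = object$levels)
    }
  )
  factor(as.character(out), levels = jm_classes())
}

#' Evaluate a classifier into a per-class precision/recall/F1 report
#'
#' One-vs-rest metrics from the 4x4 confusion matrix:
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, F1 their harmonic mean,
#' as percentages rounded to 2 decimals. Totals are unweighted (macro) means
#' over the four classes. A class absent from the test set has undefined
#' recall, reported as 0 and flagged.
#'
#' @param model a `jm_model`.
#' @param test a non-empty `feature_table`.
#' @return an object of class `jm_report` with fields `per_class`
#'   (data.frame: class, precision, recall, f1, flag), `totals` and
#'   `confusion` (truth rows by prediction columns).
#' @export
evaluate <- function(model, test) {
  if (!nrow(test)) stop("evaluate: empty test table")
  truth <- factor(as.character(test$class), levels = jm_classes())
  pred <- predict(model, test)
  conf <- table(truth = truth, pred = pred)
  prec <- rec <- f1 <- numeric(4)
  flag <- character(4)
  for (k in seq_len(4)) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    flag[k] <- if (sum(conf[k, ]) == 0) "absent_from_test"
               else if (tp + fp == 0) "never_predicted" else ""
  }
  per_class <- data.frame(class = jm_classes(),
                          precision = round(100 * prec, 2),
                          recall = round(100 * rec, 2),
                          f1 = round(100 * f1, 2),
                          flag = flag)
  totals <- c(precision = round(100 * mean(prec), 2),
              recall = round(100 * mean(rec), 2),
              f1 = round(100 * mean(f1), 2))
  structure(list(kind = model$kind, per_class = per_class, totals = totals,
                 confusion = unclass(conf)),
            class = "jm_report")
}

#' @export
print.jm_report <- function(x, ...) {
  cat(sprintf("<jm_report> %s  total precision %.2f, recall %.2f, F1 %.2f\n",
              x$kind, x$totals["precision"], x$totals["recall"], x$totals["f1"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Sample patch-level texture features from labeled gray images
#'
#' Draws random fully-interior patches from each image, extracts the
#' 32-feature texture vector per patch and labels it with the image's class.
#' Used to train patch-level models for [pixel_class_map()].
#'
#' @param images list of [gray_image()].
#' @param labels class code per image.
#' @param n_per_image patches sampled per image.
#' @param patch_size odd patch edge length in pixels.
#' @param tx_cfg a [texture_config()].
#' @param seed integer seed.
#' @return a `feature_table`.
#' @export
sample_patch_features <- function(images, labels, n_per_image = 40,
                                  patch_size = 9, tx_cfg = texture_config(),
                                  seed = 1L) {
  half <- (patch_size - 1L) %/% 2L
  with_seed(seed, {
    rows <- list(); cls <- character(0)
    for (ii in seq_along(images)) {
      img <- images[[ii]]
      if (nrow(img) < patch_size || ncol(img) < patch_size) {
        stop("sample_patch_features: image smaller than patch")
      }
      rs <- sample((1L + half):(nrow(img) - half), n_per_image, replace = TRUE)
      cs <- sample((1L + half):(ncol(img) - half), n_per_image, replace = TRUE)
      for (p in seq_len(n_per_image)) {
        patch <- gray_image(unclass(img)[(rs[p] - half):(rs[p] + half),
                                         (cs[p] - half):(cs[p] + half)],
                            attr(img, "ng"))
        rows[[length(rows) + 1L]] <- extract_feature_vector(patch, tx_cfg)
        cls <- c(cls, labels[[ii]])
      }
    }
    tab <- data.frame(do.call(rbind, rows), check.names = FALSE)
    tab$class <- jm_class_factor(cls)
    structure(tab, class = c("feature_table", "data.frame"))
  })
}

#' Pixel-level class map of a spectrogram
#'
#' Slides a square patch over the gray image, extracts the texture feature
#' vector per patch and predicts a class for each patch center. Border
#' pixels, whose patch would leave the image, take the label of the nearest
#' valid center.
#'
#' @param sp a `spectrogram` or [gray_image()].
#' @param model a `jm_model` trained on patch-level texture features.
#' @param patch_size odd patch edge length (default 9).
#' @param ng gray levels used if `sp` is a spectrogram.
#' @param tx_cfg a [texture_config()].
#' @return character matrix of class codes, same dimensions as the image.
#' @export
pixel_class_map <- function(sp, model, patch_size = 9, ng = 32,
                            tx_cfg = texture_config()) {
  img <- if (inherits(sp, "gray_image")) sp else quantize(sp, ng)
  if (patch_size %% 2 != 1) stop("patch_size must be odd")
  half <- (patch_size - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  if (nr < patch_size || nc < patch_size) {
    stop(sprintf("pixel_class_map: patch %dx%d larger than image %dx%d",
                 patch_size, patch_size, nr, nc))
  }
  rs <- (1L + half):(nr - half)
  cs <- (1L + half):(nc - half)
  m <- unclass(img)
  feats <- matrix(0, length(rs) * length(cs), 32)
  k <- 0L
  for (cc in cs) for (rr in rs) {
    k <- k + 1L
    patch <- gray_image(m[(rr - half):(rr + half), (cc - half):(cc + half)],
                        attr(img, "ng"))
    feats[k, ] <- extract_feature_vector(patch, tx_cfg)
  }
  colnames(feats) <- texture_feature_names()
  pred <- predict(model, feats)
  inner <- matrix(as.character(pred), length(rs), length(cs))
  out <- matrix(NA_character_, nr, nc)
  ridx <- pmin(pmax(seq_len(nr), 1L + half), nr - half) - half
  cidx <- pmin(pmax(seq_len(nc), 1L + half), nc - half) - half
  out[] <- inner[cbind(rep(ridx, times = nc), rep(cidx, each = nr))]
  out
}
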