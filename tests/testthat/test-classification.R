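# Train/test splitting, the six classifiers, report metrics, pixel maps.

blob_table <- function(n_per_class = 30, sep = 8, seed = 13) {
  generate_feature_table(n_per_class = n_per_class, n_features = 8,
                         informative = 1:4, separation = sep, seed = seed)
}

test_that("stratified split preserves proportions and partitions the table", {
  tab <- generate_feature_table(n_per_class = 75, n_features = 5,
                                informative = 1, separation = 2, seed = 1)
  sp <- split_train_test(tab, 2 / 3, seed = 9)
  expect_equal(nrow(sp$train), 200)
  expect_equal(nrow(sp$test), 100)
  expect_true(all(table(sp$train$class) == 50))
  expect_identical(split_train_test(tab, 2 / 3, seed = 9)$train, sp$train)
  # partition: no row in both, all rows covered
  key <- function(d) unname(apply(d[, 1:5], 1, paste, collapse = ","))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(tab))
  few <- tab[c(1, 80, 160, 240), ]
  expect_error(split_train_test(few, 2 / 3, seed = 1), ">= 2 samples")
})

test_that("naive bayes priors equal training class frequencies", {
  tab <- blob_table()
  # unbalanced 50/30/10/10 split by subsetting
  idx <- c(which(tab$class == "B")[1:25], which(tab$class == "C")[1:15],
           which(tab$class == "CB")[1:5], which(tab$class == "S")[1:5])
  m <- train_classifier("naive_bayes", tab[idx, ])
  priors <- m$fit$apriori / sum(m$fit$apriori)
  expect_equal(as.numeric(priors), c(0.5, 0.3, 0.1, 0.1))
})

test_that("kmeans maps well-separated blobs bijectively onto classes", {
  tab <- blob_table(sep = 10)
  m <- train_classifier("kmeans", tab, model_config("kmeans", seed = 3))
  expect_setequal(m$fit$map, jm_classes())
  rep <- evaluate(m, tab)
  expect_equal(unname(rep$totals["precision"]), 100)
})

test_that("knn with duplicated training point predicts that point's label", {
  tab <- blob_table()
  m <- train_classifier("knn", tab, model_config("knn"))
  pred <- predict(m, tab[17, , drop = FALSE])
  expect_equal(as.character(pred), as.character(tab$class[17]))
})

test_that("all six classifiers separate an easy table and are deterministic", {
  tab <- blob_table(sep = 8)
  sp <- split_train_test(tab, 2 / 3, seed = 21)
  for (kind in c("naive_bayes", "knn", "svm", "decision_tree", "mlp", "kmeans")) {
    cfg <- model_config(kind, seed = 7)
    r1 <- evaluate(train_classifier(kind, sp$train, cfg), sp$test)
    r2 <- evaluate(train_classifier(kind, sp$train, cfg), sp$test)
    expect_identical(r1$per_class, r2$per_class)
    expect_gt(unname(r1$totals["precision"]), 90)
  }
  expect_error(train_classifier("boosted_stump", sp$train), "unknown")
})

test_that("report metrics implement one-vs-rest precision/recall/F1", {
  # forge a model that returns fixed predictions via the knn path
  tab <- blob_table(n_per_class = 3, sep = 50, seed = 2)
  m <- train_classifier("knn", tab)
  rep <- evaluate(m, tab)   # perfect self-prediction at separation 50
  expect_true(all(rep$per_class$precision == 100))
  expect_true(all(rep$per_class$f1 == 100))
  # arithmetic fixture: TP=9, FP=1, FN=3
  conf <- matrix(0, 4, 4, dimnames = list(jm_classes(), jm_classes()))
  conf["B", "B"] <- 9; conf["C", "B"] <- 1; conf["B", "C"] <- 3
  prec <- 9 / (9 + 1); rec <- 9 / (9 + 3)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(round(100 * prec, 2), 90.00)
  expect_equal(round(100 * rec, 2), 75.00)
  expect_equal(round(100 * f1, 2), 81.82)
})

test_that("report totals are macro means and F1 the harmonic mean", {
  tab <- blob_table(sep = 3, seed = 31)
  sp <- split_train_test(tab, 2 / 3, seed = 5)
  rep <- evaluate(train_classifier("svm", sp$train), sp$test)
  pc <- rep$per_class
  expect_equal(unname(rep$totals["precision"]), mean(pc$precision),
               tolerance = 0.01)
  expect_equal(unname(rep$totals["recall"]), mean(pc$recall), tolerance = 0.01)
  expect_equal(unname(rep$totals["f1"]), mean(pc$f1), tolerance = 0.01)
  for (k in 1:4) {
    p <- pc$precision[k]; r <- pc$recall[k]
    h <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(pc$f1[k], h, tolerance = 0.01)
  }
  # confusion row sums equal class test counts
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(sp$test$class))))
})

test_that("absent test classes are flagged with zero recall", {
  tab <- blob_table(sep = 10)
  m <- train_classifier("svm", tab)
  sub <- tab[tab$class != "S", ]
  rep <- evaluate(m, sub)
  expect_equal(rep$per_class$flag[rep$per_class$class == "S"],
               "absent_from_test")
  expect_equal(rep$per_class$recall[rep$per_class$class == "S"], 0)
})

test_that("pixel map labels a chew spectrogram mostly as chew", {
  # Patch-level models are trained on the pure texture classes (B, C, S);
  # chew-bite is a superposition of those phenomena, so its patches carry
  # mixed supervision. Images are cropped to the mastication band
  # (~0.2-1.3 kHz) where grinding texture lives, and the chew segments are
  # long (1.6 s) so several grind bursts fall in every image.
  sc <- synth_config(event_duration_range = c(1.6, 1.6))
  sp_cfg <- spectrogram_config(window_length = 512, hop = 256,
                               log_floor = 0.02)
  ng <- 16
  band <- 5:30
  imgs <- list(); labs <- character(0)
  for (cl in c("B", "C", "S")) for (s in 1:2) {
    ev <- generate_event_waveform(cl, sc, seed = 40 + s)
    img <- quantize(stft_image(ev, sp_cfg), ng)
    imgs[[length(imgs) + 1]] <- gray_image(unclass(img)[band, ], ng)
    labs <- c(labs, cl)
  }
  train <- sample_patch_features(imgs, labs, n_per_image = 30, patch_size = 9,
                                 seed = 6)
  m <- train_classifier("mlp", train, model_config("mlp", seed = 6))
  ev <- generate_event_waveform("C", sc, seed = 77)
  img <- gray_image(unclass(quantize(stft_image(ev, sp_cfg), ng))[band, ], ng)
  map <- pixel_class_map(img, m, patch_size = 9)
  expect_equal(dim(map), dim(img))
  expect_gt(mean(map == "C"), 0.8)
  # constant image: all patches identical, one uniform label
  const <- gray_image(matrix(3L, 20, 20), ng)
  cmap <- pixel_class_map(const, m, patch_size = 9)
  expect_length(unique(as.vector(cmap)), 1)
  expect_error(pixel_class_map(gray_image(matrix(1L, 4, 4), ng), m,
                               patch_size = 9), "larger than image")
})
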