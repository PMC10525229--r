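# Texture machinery: gray-level matrices and the 32 features.

test_that("co-occurrence matrix matches hand-enumerated fixtures", {
  cfg <- texture_config()
  # constant 2x2 image: only (1,1) pairs
  img <- gray_image(matrix(1L, 2, 2), 2)
  P <- cooccurrence_matrix(img, cfg, theta = 0)
  expect_equal(unclass(P)[1, 1], 1)
  expect_equal(sum(P), 1)
  # 4x4 checkerboard of levels 1/2: all horizontal neighbours differ
  cb <- gray_image(outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L), 2)
  P <- cooccurrence_matrix(cb, cfg, theta = 0)
  expect_equal(unclass(P), matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)
  # any image sums to 1
  withr::with_seed(7, {
    img <- random_gray(6, 5, 4)
    for (th in c(0, 45, 90, 135)) {
      expect_equal(sum(cooccurrence_matrix(img, cfg, th)), 1, tolerance = 1e-12)
    }
  })
})

test_that("co-occurrence features on closed-form fixtures", {
  cfg <- texture_config()
  # constant image at level k
  k <- 3L
  img <- gray_image(matrix(k, 4, 4), 8)
  f <- glcm_features(cooccurrence_matrix(img, cfg, 0))
  expect_equal(unname(f["Con"]), 0)
  expect_equal(unname(f["JE"]), 1)
  expect_equal(unname(f["JEnt"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["ID"]), 1)
  expect_equal(unname(f["IDMN"]), 1)
  expect_equal(unname(f["CS"]), 0)
  expect_equal(unname(f["ACor"]), k^2)
  expect_equal(unname(f["JA"]), k)
  expect_equal(unname(f["Cor"]), 1)  # degenerate convention
  expect_true(isTRUE(attr(f, "degenerate_correlation")))
  # checkerboard: two-entry matrix P(1,2)=P(2,1)=0.5
  cb <- gray_image(outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L), 2)
  f <- glcm_features(cooccurrence_matrix(cb, cfg, 0))
  expect_equal(unname(f["Con"]), 1)
  expect_equal(unname(f["ID"]), 0.5)
  expect_equal(unname(f["JE"]), 0.5)
  expect_equal(unname(f["Cor"]), -1)
})

test_that("run length matrix and features on closed-form fixtures", {
  # 4x4 constant image, horizontal runs
  img <- gray_image(matrix(2L, 4, 4), 4)
  R <- run_length_matrix(img, 0)
  expect_equal(attr(R, "NZ"), 4)
  expect_equal(attr(R, "NS"), 16)
  expect_equal(unclass(R)[2, 4], 4L)
  f <- glrlm_features(R)
  expect_equal(unname(f["SRE"]), 0.0625)
  expect_equal(unname(f["LRE"]), 16)
  expect_equal(unname(f["GLNU"]), 4)
  expect_equal(unname(f["RLNU"]), 4)
  expect_equal(unname(f["Rp"]), 0.25)
  # single row [1,1,2,2,2,1]: runs (1,2),(2,3),(1,1)
  row <- gray_image(matrix(c(1L, 1L, 2L, 2L, 2L, 1L), 1, 6), 2)
  R <- run_length_matrix(row, 0)
  expect_equal(attr(R, "NZ"), 3)
  expect_equal(unclass(R)[1, 2], 1L)
  expect_equal(unclass(R)[2, 3], 1L)
  expect_equal(unclass(R)[1, 1], 1L)
  # checkerboard: every run has length 1
  cb <- gray_image(outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L), 2)
  f <- glrlm_features(run_length_matrix(cb, 0))
  expect_equal(unname(f["SRE"]), 1)
  expect_equal(unname(f["LRE"]), 1)
  expect_equal(unname(f["Rp"]), 1)
  # pixels partition into runs: sum(count * length) = NS for every angle
  withr::with_seed(11, {
    img <- random_gray(7, 5, 3)
    for (th in c(0, 45, 90, 135)) {
      R <- run_length_matrix(img, th)
      lens <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
      expect_equal(sum(unclass(R) * lens), attr(R, "NS"))
    }
  })
})

test_that("dependence matrix and features on closed-form fixtures", {
  # constant image: diff_hist is a point mass at 0; Pdep masses at
  # dependence counts 3 (corners), 5 (edges), 8 (interior)
  img <- gray_image(matrix(1L, 4, 4), 4)
  dm <- dependence_matrix(img, texture_config())
  expect_equal(unname(dm$diff_hist["0"]), 1)
  expect_equal(unname(dm$Pdep[1, c("3", "5", "8")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(dm$Pdep), 1)
  f <- gldm_features(dm)
  expect_equal(unname(f["DE"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(f["LDE"]), 30.75)
  # single-cell distribution (2x2 constant: every pixel has dependence 3)
  # has (near) zero entropy
  one <- dependence_matrix(gray_image(matrix(1L, 2, 2), 2), texture_config())
  expect_equal(unname(one$Pdep[1, "3"]), 1)
  expect_lt(abs(gldm_features(one)["DE"]), 1e-6)
  # distributions are normalized for random images
  withr::with_seed(3, {
    img <- random_gray(6, 6, 4)
    dm <- dependence_matrix(img, texture_config())
    expect_equal(sum(dm$Pdep), 1)
    expect_equal(sum(dm$diff_hist), 1)
  })
})

test_that("all four feature groups match brute-force oracles on random images", {
  cfg <- texture_config()
  withr::with_seed(101, {
    for (rep in 1:25) {
      ng <- sample(2:5, 1)
      img <- random_gray(sample(4:10, 1), sample(4:10, 1), ng)
      m <- unclass(img)
      for (th in c(0, 45, 90, 135)) {
        expect_equal(unclass(cooccurrence_matrix(img, cfg, th)),
                     oracle_glcm(m, ng, 1, th), tolerance = 1e-12,
                     ignore_attr = TRUE)
        got <- glcm_features(cooccurrence_matrix(img, cfg, th))
        expect_equal(unname(got),
                     unname(oracle_glcm_features(oracle_glcm(m, ng, 1, th))),
                     tolerance = 1e-10)
        expect_equal(matrix(unclass(run_length_matrix(img, th)),
                            nrow = ng),
                     oracle_rlm(m, ng, th), ignore_attr = TRUE,
                     tolerance = 1e-12)
      }
      expect_equal(unname(sgldm_features(img, cfg)),
                   unname(oracle_sgldm(m, ng, 1)), tolerance = 1e-10)
      dm <- dependence_matrix(img, cfg)
      odm <- oracle_dependence(m, ng)
      expect_equal(unname(dm$Pdep), odm$Pdep, ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_equal(unname(dm$diff_hist), odm$diff_hist, tolerance = 1e-12)
      expect_equal(unname(gldm_features(dm)),
                   unname(oracle_gldm_features(odm$Pdep)), tolerance = 1e-10)
    }
  })
})

test_that("feature vector has stable names, canonical order, finite values", {
  img <- gray_image(matrix(2L, 5, 5), 4)
  v <- extract_feature_vector(img)
  expect_length(v, 32)
  expect_identical(names(v), texture_feature_names())
  expect_true(all(is.finite(v)))
  # deterministic
  expect_identical(v, extract_feature_vector(img))
})

test_that("feature invariants: probability ranges, inertia-contrast identity", {
  cfg <- texture_config()
  withr::with_seed(23, {
    for (rep in 1:10) {
      img <- random_gray(8, 8, 4)
      v <- extract_feature_vector(img, cfg)
      expect_true(v["JEnt"] >= 0 && v["Entropy"] >= 0 && v["DE"] >= 0)
      expect_true(all(v[c("JE", "ID", "IDMN", "SRE", "Rp")] > 0))
      expect_true(all(v[c("JE", "ID", "IDMN", "SRE", "Rp")] <= 1 + 1e-12))
      expect_gte(v[["LRE"]], 1)
      # SGLDM inertia over 8 angles == GLCM contrast averaged over the four
      # symmetric orientations
      expect_equal(v[["Inertia"]], v[["Con"]], tolerance = 1e-10)
    }
  })
})

test_that("angle-averaged features are invariant to 90-degree rotation", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      img <- random_gray(7, 9, 4)
      rot <- gray_image(t(unclass(img))[ncol(img):1, , drop = FALSE],
                        attr(img, "ng"))
      v1 <- extract_feature_vector(img)
      v2 <- extract_feature_vector(rot)
      expect_equal(v1, v2, tolerance = 1e-10)
    }
  })
})

test_that("degenerate displacements raise errors", {
  img <- gray_image(matrix(1L, 1, 2), 2)
  expect_error(cooccurrence_matrix(img, texture_config(), 90), "no valid")
  expect_error(run_length_matrix(img, 30), "theta")
})
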