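# Gray-level matrix texture analysis.
#
# Four matrix families are computed from a quantized time-frequency image:
#   GLCM   gray level co-occurrence matrix        -> 11 features
#   SGLDM  spatial gray level dependence method   ->  7 features
#   GLRLM  gray level run length matrix           ->  9 features
#   GLDM   gray level difference/dependence       ->  5 features
# giving the canonical 32-feature vector per event image.
#
# Conventions (fixed, documented, and mirrored by the test oracles):
# * gray levels take values 1..NG and enter formulas with those values;
# * angle theta maps to the pixel offset (drow, dcol) =
#   (-round(sin(theta)), round(cos(theta))) * d, i.e. 0 deg points along the
#   time axis and 90 deg towards higher frequencies;
# * pairs and neighbours falling outside the image are skipped (no padding);
# * entropies use log2 with an additive epsilon inside the logarithm, except
#   the SGLDM entropy which uses the natural log over nonzero cells.

#' Texture configuration
#'
#' @param d inter-pixel displacement distance in pixels.
#' @param angles angle set in degrees, multiples of 45, used by the
#'   dependence (SGLDM) estimate; co-occurrence and run-length groups use the
#'   four canonical orientations 0/45/90/135 (with symmetric counting this
#'   covers all eight directions).
#' @param symmetric_cooccurrence add the transpose when building the GLCM.
#' @param alpha gray-level tolerance when counting dependent neighbours in
#'   the dependence matrix.
#' @param epsilon additive constant inside entropy logarithms.
#' @return an object of class `texture_config`.
#' @export
texture_config <- function(d = 1,
                           angles = c(0, 45, 90, 135, 180, 225, 270, 315),
                           symmetric_cooccurrence = TRUE,
                           alpha = 0, epsilon = 2.2e-16) {
  stopifnot_scalar_num(d, "d", lower = 1)
  stopifnot_scalar_num(alpha, "alpha", lower = 0)
  stopifnot_scalar_num(epsilon, "epsilon", lower = .Machine$double.xmin)
  if (!length(angles) || !all(angles %% 45 == 0)) {
    stop("angles must be a non-empty set of multiples of 45 degrees")
  }
  structure(list(d = as.integer(d), angles = as.numeric(angles),
                 symmetric_cooccurrence = isTRUE(symmetric_cooccurrence),
                 alpha = alpha, epsilon = epsilon),
            class = "texture_config")
}

#' Canonical names of the 32 texture features
#'
#' Order: 11 co-occurrence (GLCM), 7 spatial-dependence (SGLDM), 9 run-length
#' (GLRLM), 5 dependence (GLDM) features.
#'
#' @return character vector of length 32.
#' @export
texture_feature_names <- function() {
  c("Con", "Cor", "ACor", "JA", "CP", "CS", "CT", "JE", "JEnt", "IDMN", "ID",
    "Energy", "Entropy", "Correlation", "LocalHomogeneity", "Inertia",
    "Mean", "Variance",
    "SRE", "LRE", "GLNU", "RLNU", "Rp", "LGLRE", "HGLRE", "GLV", "RV",
    "DE", "SDLGLE", "SDHGLE", "SDE", "LDE")
}

# theta (degrees) -> (drow, dcol) offset at distance d
.angle_offset <- function(theta, d) {
  rad <- theta * pi / 180
  c(dr = -round(sin(rad)) * d, dc = round(cos(rad)) * d)
}

# Ordered level pairs (a, b) at offset (dr, dc); NULL when no pair fits.
.pair_levels <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  r_lo <- max(1, 1 - dr); r_hi <- min(nr, nr - dr)
  c_lo <- max(1, 1 - dc); c_hi <- min(nc, nc - dc)
  if (r_lo > r_hi || c_lo > c_hi) return(NULL)
  r1 <- r_lo:r_hi; c1 <- c_lo:c_hi
  a <- img[r1, c1, drop = FALSE]
  b <- img[r1 + dr, c1 + dc, drop = FALSE]
  cbind(as.vector(a), as.vector(b))
}

.count_matrix <- function(pairs, ng) {
  idx <- pairs[, 1] + (pairs[, 2] - 1L) * ng
  matrix(tabulate(idx, ng * ng), ng, ng)
}

#' Gray level co-occurrence matrix
#'
#' Counts ordered level pairs at displacement `d` along `theta`, optionally
#' symmetrized by adding the transpose, and normalizes to a probability
#' matrix.
#'
#' @param img a [gray_image()].
#' @param cfg a [texture_config()].
#' @param theta angle in degrees.
#' @return an NG x NG probability matrix of class `cooccurrence_matrix` with
#'   attributes `d` and `theta`.
#' @export
cooccurrence_matrix <- function(img, cfg = texture_config(), theta = 0) {
  ng <- attr(img, "ng")
  off <- .angle_offset(theta, cfg$d)
  pairs <- .pair_levels(img, off["dr"], off["dc"])
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop(sprintf("cooccurrence_matrix: no valid pixel pairs for d=%d, theta=%g on a %dx%d image",
                 cfg$d, theta, nrow(img), ncol(img)))
  }
  M <- .count_matrix(pairs, ng)
  if (cfg$symmetric_cooccurrence) M <- M + t(M)
  P <- M / sum(M)
  structure(P, d = cfg$d, theta = theta, class = c("cooccurrence_matrix",
                                                   "matrix", "array"))
}

#' Co-occurrence (GLCM) features
#'
#' Computes the 11 co-occurrence features from a normalized matrix:
#' contrast, correlation, autocorrelation, joint average, cluster prominence,
#' cluster shade, cluster tendency, joint energy, joint entropy (log2 with
#' epsilon), inverse difference moment normalized, inverse difference.
#' On a constant image the correlation is degenerate (zero variance) and is
#' reported as 1 with attribute `degenerate_correlation = TRUE`.
#'
#' @param M normalized co-occurrence matrix (NG x NG, sums to 1).
#' @param epsilon additive constant inside the entropy logarithm.
#' @return named numeric vector of the 11 features.
#' @export
glcm_features <- function(M, epsilon = 2.2e-16) {
  P <- unclass(M)
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx2 <- sum((seq_len(ng) - mux)^2 * px)
  sigy2 <- sum((seq_len(ng) - muy)^2 * py)
  degenerate <- FALSE
  if (sigx2 <= 1e-12 || sigy2 <= 1e-12) {
    corr <- 1
    degenerate <- TRUE
  } else {
    corr <- sum((i - mux) * (j - muy) * P) / sqrt(sigx2 * sigy2)
  }
  v <- c(
    Con = sum(P * (i - j)^2),
    Cor = corr,
    ACor = sum(i * j * P),
    JA = sum(i * P),
    CP = sum((i + j - mux - muy)^4 * P),
    CS = sum((i + j - mux - muy)^3 * P),
    CT = sum((i + j - mux - muy)^2 * P),
    JE = sum(P^2),
    JEnt = -sum(P * log2(P + epsilon)),
    IDMN = sum(P / (1 + (i - j)^2 / ng^2)),
    ID = sum(P / (1 + abs(i - j)))
  )
  if (degenerate) attr(v, "degenerate_correlation") <- TRUE
  v
}

#' Spatial gray level dependence (SGLDM) features
#'
#' Estimates the directional co-occurrence distribution for each angle in
#' `cfg$angles` (unsymmetrized, one direction per angle) and averages the
#' seven features across angles: energy, entropy (natural log), correlation,
#' local homogeneity, inertia, mean and variance. The mean is
#' `sum(i * S(i,j))` -- the quantity the variance centers on. Inertia equals
#' the co-occurrence contrast for the matching displacement.
#'
#' @param img a [gray_image()].
#' @param cfg a [texture_config()].
#' @return named numeric vector of the 7 features.
#' @export
sgldm_features <- function(img, cfg = texture_config()) {
  ng <- attr(img, "ng")
  acc <- NULL
  nang <- 0L
  for (theta in cfg$angles) {
    off <- .angle_offset(theta, cfg$d)
    pairs <- .pair_levels(img, off["dr"], off["dc"])
    if (is.null(pairs) || nrow(pairs) == 0) {
      stop(sprintf("sgldm_features: no valid pixel pairs for d=%d, theta=%g",
                   cfg$d, theta))
    }
    P <- .count_matrix(pairs, ng)
    P <- P / sum(P)
    f <- .sgldm_one(P, ng)
    acc <- if (is.null(acc)) f else acc + f
    nang <- nang + 1L
  }
  acc / nang
}

.sgldm_one <- function(P, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  corr <- if (sigx <= 1e-12 || sigy <= 1e-12) 1
          else sum((i - mux) * (j - muy) * P) / (sigx * sigy)
  pos <- P > 0
  m <- sum(i * P)
  c(
    Energy = sum(P^2),
    Entropy = -sum(P[pos] * log(P[pos])),
    Correlation = corr,
    LocalHomogeneity = sum(P / (1 + (i - j)^2)),
    Inertia = sum(P * (i - j)^2),
    Mean = m,
    Variance = sum((i - m)^2 * P)
  )
}

#' Gray level run length matrix
#'
#' Counts maximal runs of equal-level pixels along direction `theta`
#' (0, 45, 90 or 135 degrees). Entry `R[i, l]` is the number of runs of
#' level `i` and length `l`.
#'
#' @param img a [gray_image()].
#' @param theta one of 0, 45, 90, 135 (degrees).
#' @return an NG x Nr count matrix of class `run_length_matrix` with
#'   attributes `NZ` (total runs), `NS` (total pixels) and `theta`; `Nr` is
#'   the longest possible run in that direction.
#' @export
run_length_matrix <- function(img, theta = 0) {
  if (!(theta %in% c(0, 45, 90, 135))) {
    stop("run_length_matrix: theta must be one of 0, 45, 90, 135 degrees")
  }
  ng <- attr(img, "ng")
  nr <- nrow(img); nc <- ncol(img)
  m <- unclass(img)
  lines <- switch(as.character(theta),
    "0" = split(t(m), rep(seq_len(nr), each = nc)),        # along rows
    "90" = split(m, rep(seq_len(nc), each = nr)),          # along columns
    "45" = split(as.vector(m), as.vector(row(m) + col(m))),
    "135" = split(as.vector(m), as.vector(row(m) - col(m)))
  )
  nrun <- switch(as.character(theta), "0" = nc, "90" = nr, min(nr, nc))
  R <- matrix(0L, ng, nrun)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    for (k in seq_along(r$lengths)) {
      R[r$values[k], r$lengths[k]] <- R[r$values[k], r$lengths[k]] + 1L
    }
  }
  structure(R, NZ = sum(R), NS = nr * nc, theta = theta,
            class = c("run_length_matrix", "matrix", "array"))
}

#' Run-length (GLRLM) features
#'
#' The nine run-length features: short/long run emphasis, gray level and run
#' length non-uniformity, run percentage, low/high gray level run emphasis,
#' gray level variance and run variance. Means for the variances are taken
#' under `p = R / NZ`.
#'
#' @param R a [run_length_matrix()].
#' @return named numeric vector of the 9 features.
#' @export
glrlm_features <- function(R) {
  NZ <- attr(R, "NZ"); NS <- attr(R, "NS")
  if (is.null(NZ) || NZ <= 0) stop("glrlm_features: empty run length matrix")
  Rm <- unclass(R)
  ng <- nrow(Rm); nrun <- ncol(Rm)
  i <- matrix(seq_len(ng), ng, nrun)
  j <- matrix(seq_len(nrun), ng, nrun, byrow = TRUE)
  p <- Rm / NZ
  mui <- sum(p * i)
  muj <- sum(p * j)
  c(
    SRE = sum(Rm / j^2) / NZ,
    LRE = sum(Rm * j^2) / NZ,
    GLNU = sum(rowSums(Rm)^2) / NZ,
    RLNU = sum(colSums(Rm)^2) / NZ,
    Rp = NZ / NS,
    LGLRE = sum(Rm / i^2) / NZ,
    HGLRE = sum(Rm * i^2) / NZ,
    GLV = sum(p * (i - mui)^2),
    RV = sum(p * (j - muj)^2)
  )
}

#' Gray level dependence matrix and difference histogram
#'
#' Two local-difference summaries of the image:
#' * `diff_hist`: the normalized histogram of absolute gray-level differences
#'   `|g(n,m) - g(n+dn, m+dm)|` pooled over the four displacement vectors
#'   `(0,d), (-d,d), (d,0), (-d,-d)` (row, column offsets);
#' * `Pdep`: the gray level dependence matrix -- the normalized count of
#'   pixels with level `i` having `j` of their 8-neighbours (Chebyshev
#'   distance 1) within `alpha` gray levels, `j = 0..8`. Neighbours outside
#'   the image are skipped.
#'
#' @param img a [gray_image()].
#' @param cfg a [texture_config()].
#' @return an object of class `dependence_matrix` with fields `Pdep` (NG x 9
#'   probability matrix, columns named by dependence count 0..8), `diff_hist`
#'   (probability vector over difference values 0..NG-1) and `alpha`.
#' @export
dependence_matrix <- function(img, cfg = texture_config()) {
  ng <- attr(img, "ng")
  d <- cfg$d
  m <- unclass(img)
  nr <- nrow(m); nc <- ncol(m)
  # pooled difference histogram over the four displacement vectors
  deltas <- list(c(0, d), c(-d, d), c(d, 0), c(-d, -d))
  counts <- numeric(ng)   # differences 0 .. ng-1
  for (dl in deltas) {
    pairs <- .pair_levels(m, dl[1], dl[2])
    if (is.null(pairs)) next
    dv <- abs(pairs[, 1] - pairs[, 2])
    counts <- counts + tabulate(dv + 1L, ng)
  }
  if (sum(counts) == 0) stop("dependence_matrix: image too small for displacement d")
  diff_hist <- counts / sum(counts)
  names(diff_hist) <- as.character(0:(ng - 1L))
  # dependence counts over the 8-neighbourhood
  dep <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r_lo <- max(1, 1 - dr); r_hi <- min(nr, nr - dr)
    c_lo <- max(1, 1 - dc); c_hi <- min(nc, nc - dc)
    if (r_lo > r_hi || c_lo > c_hi) next
    rs <- r_lo:r_hi
    cs <- c_lo:c_hi
    ok <- abs(m[rs, cs, drop = FALSE] - m[rs + dr, cs + dc, drop = FALSE]) <= cfg$alpha
    dep[rs, cs] <- dep[rs, cs] + ok
  }
  idx <- as.vector(m) + as.vector(dep) * ng
  cnt <- tabulate(idx, ng * 9L)
  Pdep <- matrix(cnt, ng, 9L) / (nr * nc)
  colnames(Pdep) <- as.character(0:8)
  structure(list(Pdep = Pdep, diff_hist = diff_hist, alpha = cfg$alpha),
            class = "dependence_matrix")
}

#' Dependence-matrix (GLDM) features
#'
#' Five features on the gray level dependence matrix `Pdep(i, j)` with
#' `i` = gray level and `j` = dependent-neighbour count: dependence entropy
#' (log2 with epsilon), small dependence low/high gray level emphasis, small
#' dependence emphasis and large dependence emphasis. Cells with dependence
#' count 0 contribute nothing to the small-dependence features (1/j^2 is
#' taken as 0 at j = 0).
#'
#' @param Dm a [dependence_matrix()].
#' @param epsilon additive constant inside the entropy logarithm.
#' @return named numeric vector of the 5 features.
#' @export
gldm_features <- function(Dm, epsilon = 2.2e-16) {
  P <- Dm$Pdep
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, 9L)
  j <- matrix(0:8, ng, 9L, byrow = TRUE)
  inv_j2 <- ifelse(j == 0, 0, 1 / j^2)
  c(
    DE = -sum(P * log2(P + epsilon)),
    SDLGLE = sum(P * inv_j2 / i^2),
    SDHGLE = sum(P * i^2 * inv_j2),
    SDE = sum(P * inv_j2),
    LDE = sum(P * j^2)
  )
}

#' Extract the canonical 32-feature texture vector
#'
#' Concatenates the four feature groups in canonical order (see
#' [texture_feature_names()]):
#' * GLCM features averaged over the orientations 0/45/90/135 with symmetric
#'   pair counting (covering all eight directions);
#' * SGLDM features averaged over `cfg$angles`;
#' * GLRLM features averaged over the four run directions;
#' * GLDM features from the 8-neighbourhood dependence matrix.
#'
#' @param img a [gray_image()].
#' @param cfg a [texture_config()].
#' @return named numeric vector of length 32; deterministic for fixed inputs.
#' @export
extract_feature_vector <- function(img, cfg = texture_config()) {
  glcm_angles <- c(0, 45, 90, 135)
  gl <- NULL
  for (th in glcm_angles) {
    f <- glcm_features(cooccurrence_matrix(img, cfg, th), cfg$epsilon)
    gl <- if (is.null(gl)) f else gl + f
  }
  gl <- gl / length(glcm_angles)
  sg <- sgldm_features(img, cfg)
  rl <- NULL
  for (th in c(0, 45, 90, 135)) {
    f <- glrlm_features(run_length_matrix(img, th))
    rl <- if (is.null(rl)) f else rl + f
  }
  rl <- rl / 4
  gd <- gldm_features(dependence_matrix(img, cfg), cfg$epsilon)
  v <- c(gl, sg, rl, gd)
  names(v) <- texture_feature_names()
  if (any(!is.finite(v))) stop("extract_feature_vector: non-finite feature value")
  v
}

#' Build a feature table from labeled event segments
#'
#' Runs each segment through the time-frequency transform, quantization and
#' texture extraction, collecting one row per event plus its class label.
#'
#' @param segments list of [event_segment()] (labeled).
#' @param sp_cfg a [spectrogram_config()].
#' @param ng number of gray levels for quantization.
#' @param tx_cfg a [texture_config()].
#' @return a `feature_table` data.frame: 32 feature columns plus `class`.
#' @export
extract_feature_table <- function(segments, sp_cfg = spectrogram_config(),
                                  ng = 32, tx_cfg = texture_config()) {
  imager <- if (sp_cfg$transform == "stft") stft_image else s_transform_image
  rows <- lapply(segments, function(seg) {
    sp <- imager(seg, sp_cfg)
    extract_feature_vector(quantize(sp, ng), tx_cfg)
  })
  X <- do.call(rbind, rows)
  tab <- data.frame(X, check.names = FALSE)
  tab$class <- jm_class_factor(vapply(segments, function(s) s$label, character(1)))
  structure(tab, class = c("feature_table", "data.frame"))
}

#' Write / read a feature table as CSV
#'
#' @param tab a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"class" %in% names(df)) stop("feature table CSV must have a 'class' column")
  df$class <- jm_class_factor(df$class)
  structure(df, class = c("feature_table", "data.frame"))
}
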