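# Brute-force reference implementations of the texture machinery, written as
# plain double/triple loops, independent of the package's vectorized code.
# These are the ground truth the texture tests compare against.

oracle_offset <- function(theta, d) {
  rad <- theta * pi / 180
  c(-round(sin(rad)) * d, round(cos(rad)) * d)  # (drow, dcol)
}

# ordered-pair count matrix at displacement (dr, dc)
oracle_pair_counts <- function(m, ng, dr, dc) {
  M <- matrix(0, ng, ng)
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m)) {
      M[m[r, c], m[r2, c2]] <- M[m[r, c], m[r2, c2]] + 1
    }
  }
  M
}

oracle_glcm <- function(m, ng, d, theta, symmetric = TRUE) {
  off <- oracle_offset(theta, d)
  M <- oracle_pair_counts(m, ng, off[1], off[2])
  if (symmetric) M <- M + t(M)
  M / sum(M)
}

oracle_glcm_features <- function(P, eps = 2.2e-16) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  con <- cor_n <- acor <- ja <- cp <- cs <- ct <- je <- jent <- idmn <- id <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    con <- con + p * (i - j)^2
    cor_n <- cor_n + (i - mux) * (j - muy) * p
    acor <- acor + i * j * p
    ja <- ja + i * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    je <- je + p^2
    jent <- jent - p * log2(p + eps)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    id <- id + p / (1 + abs(i - j))
  }
  corr <- if (sx2 <= 1e-12 || sy2 <= 1e-12) 1 else cor_n / sqrt(sx2 * sy2)
  c(Con = con, Cor = corr, ACor = acor, JA = ja, CP = cp, CS = cs, CT = ct,
    JE = je, JEnt = jent, IDMN = idmn, ID = id)
}

oracle_sgldm_one <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  en <- ent <- corn <- lh <- inr <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    en <- en + p^2
    if (p > 0) ent <- ent - p * log(p)
    corn <- corn + (i - mux) * (j - muy) * p
    lh <- lh + p / (1 + (i - j)^2)
    inr <- inr + p * (i - j)^2
  }
  corr <- if (sx <= 1e-12 || sy <= 1e-12) 1 else corn / (sx * sy)
  m <- 0
  for (i in 1:ng) for (j in 1:ng) m <- m + i * P[i, j]
  v <- 0
  for (i in 1:ng) for (j in 1:ng) v <- v + (i - m)^2 * P[i, j]
  c(Energy = en, Entropy = ent, Correlation = corr, LocalHomogeneity = lh,
    Inertia = inr, Mean = m, Variance = v)
}

oracle_sgldm <- function(m, ng, d,
                         angles = c(0, 45, 90, 135, 180, 225, 270, 315)) {
  acc <- NULL
  for (th in angles) {
    off <- oracle_offset(th, d)
    M <- oracle_pair_counts(m, ng, off[1], off[2])
    P <- M / sum(M)
    f <- oracle_sgldm_one(P)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(angles)
}

# runs scanned line by line in direction theta
oracle_rlm <- function(m, ng, theta) {
  nr <- nrow(m); nc <- ncol(m)
  step <- switch(as.character(theta),
                 "0" = c(0, 1), "90" = c(-1, 0), "45" = c(-1, 1), "135" = c(-1, -1))
  nrun <- switch(as.character(theta), "0" = nc, "90" = nr, min(nr, nc))
  R <- matrix(0, ng, nrun)
  visited <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    # start of a line: the predecessor cell lies outside the image
    pr <- r0 - step[1]; pc <- c0 - step[2]
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next
    r <- r0; c <- c0
    runlev <- m[r, c]; runlen <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      if (m[r, c] == runlev) runlen <- runlen + 1
      else {
        R[runlev, runlen] <- R[runlev, runlen] + 1
        runlev <- m[r, c]; runlen <- 1
      }
      visited[r, c] <- TRUE
      r <- r + step[1]; c <- c + step[2]
    }
    R[runlev, runlen] <- R[runlev, runlen] + 1
  }
  stopifnot(all(visited))
  R
}

oracle_glrlm_features <- function(R, ns) {
  nz <- sum(R)
  ng <- nrow(R); nrun <- ncol(R)
  sre <- lre <- lgl <- hgl <- 0
  for (i in 1:ng) for (j in 1:nrun) {
    sre <- sre + R[i, j] / j^2
    lre <- lre + R[i, j] * j^2
    lgl <- lgl + R[i, j] / i^2
    hgl <- hgl + R[i, j] * i^2
  }
  glnu <- sum(rowSums(R)^2) / nz
  rlnu <- sum(colSums(R)^2) / nz
  p <- R / nz
  mui <- 0; muj <- 0
  for (i in 1:ng) for (j in 1:nrun) { mui <- mui + p[i, j] * i; muj <- muj + p[i, j] * j }
  glv <- 0; rv <- 0
  for (i in 1:ng) for (j in 1:nrun) {
    glv <- glv + p[i, j] * (i - mui)^2
    rv <- rv + p[i, j] * (j - muj)^2
  }
  c(SRE = sre / nz, LRE = lre / nz, GLNU = glnu, RLNU = rlnu, Rp = nz / ns,
    LGLRE = lgl / nz, HGLRE = hgl / nz, GLV = glv, RV = rv)
}

oracle_dependence <- function(m, ng, d = 1, alpha = 0) {
  nr <- nrow(m); nc <- ncol(m)
  # pooled difference histogram over the four displacement vectors
  counts <- numeric(ng)
  for (dl in list(c(0, d), c(-d, d), c(d, 0), c(-d, -d))) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + dl[1]; c2 <- c + dl[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        dv <- abs(m[r, c] - m[r2, c2])
        counts[dv + 1] <- counts[dv + 1] + 1
      }
    }
  }
  diff_hist <- counts / sum(counts)
  # dependence matrix over the 8-neighbourhood
  P <- matrix(0, ng, 9)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          abs(m[r, c] - m[r2, c2]) <= alpha) dep <- dep + 1
    }
    P[m[r, c], dep + 1] <- P[m[r, c], dep + 1] + 1
  }
  list(Pdep = P / (nr * nc), diff_hist = diff_hist)
}

oracle_gldm_features <- function(Pdep, eps = 2.2e-16) {
  ng <- nrow(Pdep)
  de <- sdlgle <- sdhgle <- sde <- lde <- 0
  for (i in 1:ng) for (jj in 1:9) {
    j <- jj - 1  # dependence count
    p <- Pdep[i, jj]
    de <- de - p * log2(p + eps)
    lde <- lde + p * j^2
    if (j > 0) {
      sdlgle <- sdlgle + p / (i^2 * j^2)
      sdhgle <- sdhgle + p * i^2 / j^2
      sde <- sde + p / j^2
    }
  }
  c(DE = de, SDLGLE = sdlgle, SDHGLE = sdhgle, SDE = sde, LDE = lde)
}

# full 32-feature oracle, mirroring the documented angle-averaging scheme
oracle_feature_vector <- function(m, ng, d = 1, alpha = 0, eps = 2.2e-16) {
  gl <- NULL
  for (th in c(0, 45, 90, 135)) {
    f <- oracle_glcm_features(oracle_glcm(m, ng, d, th, symmetric = TRUE), eps)
    gl <- if (is.null(gl)) f else gl + f
  }
  gl <- gl / 4
  sg <- oracle_sgldm(m, ng, d)
  rl <- NULL
  for (th in c(0, 45, 90, 135)) {
    f <- oracle_glrlm_features(oracle_rlm(m, ng, th), nrow(m) * ncol(m))
    rl <- if (is.null(rl)) f else rl + f
  }
  rl <- rl / 4
  dm <- oracle_dependence(m, ng, d, alpha)
  gd <- oracle_gldm_features(dm$Pdep, eps)
  v <- c(gl, sg, rl, gd)
  names(v) <- texture_feature_names()
  v
}

# random test image with levels 1..ng
random_gray <- function(nr, nc, ng) {
  gray_image(matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc), ng)
}
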