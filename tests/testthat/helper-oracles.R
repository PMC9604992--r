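# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (explicit loops, full enumeration) so it shares no
# code path with the implementation it checks.

randomImage <- function(width, height, seed, blackFraction = 0.3) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n <- width * height
    px <- array(sample.int(256L, n * 3L, replace = TRUE) - 1L,
                dim = c(height, width, 3L))
    black <- sample.int(n, round(blackFraction * n))
    for (ch in 1:3) {
      m <- px[, , ch]; m[black] <- 0L; px[, , ch] <- m
    }
    RasterImage(px)
  })
}

# Per-pixel loop application of the two-filter rule.
oracleClassify <- function(image, config) {
  px <- pixelArray(image)
  h <- dim(px)[1L]; w <- dim(px)[2L]
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- px[i, j, 1L]; g <- px[i, j, 2L]; b <- px[i, j, 3L]
    if (r <= config@blackTol && g <= config@blackTol && b <= config@blackTol) {
      out[i, j] <- 0L
    } else {
      if (config@channelMode == "normalized") {
        s <- r + g + b
        r <- r / s; g <- g / s; b <- b / s
      }
      out[i, j] <- if (r >= config@redMin && g >= config@greenMin &&
                         b >= config@blueMin) 1L else 2L
    }
  }
  out
}

# Explicit-loop two-way ANOVA ICC(A,1).
oracleICCA1 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + mat[i, j]
  gm <- gm / (n * k)
  SSR <- 0
  for (i in 1:n) {
    rm <- 0; for (j in 1:k) rm <- rm + mat[i, j]; rm <- rm / k
    SSR <- SSR + k * (rm - gm)^2
  }
  SSC <- 0
  for (j in 1:k) {
    cm <- 0; for (i in 1:n) cm <- cm + mat[i, j]; cm <- cm / n
    SSC <- SSC + n * (cm - gm)^2
  }
  SST <- 0
  for (i in 1:n) for (j in 1:k) SST <- SST + (mat[i, j] - gm)^2
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Full 2^m enumeration of the signed-rank null distribution.
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  Wall <- signs %*% r
  pLess <- mean(Wall <= W + 1e-9)
  pGreater <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(pLess, pGreater))
}

# Ranks by explicit position averaging, then product-moment by loops.
oracleSpearman <- function(x, y) {
  rk <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in 1:n) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      out[i] <- less + (eq + 1) / 2
    }
    out
  }
  rx <- rk(x); ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracleOneSampleT <- function(x, mu0) {
  n <- length(x)
  m <- 0; for (v in x) m <- m + v; m <- m / n
  ss <- 0; for (v in x) ss <- ss + (v - m)^2
  s <- sqrt(ss / (n - 1))
  (m - mu0) / (s / sqrt(n))
}

# A tiny complete scan-only study: nSubjects x 6 teeth x 2 surfaces x 3
# timepoints with deterministic values (subject offset + site pattern).
tinyStudyRecords <- function(nSubjects = 4) {
  teeth <- c("16", "21", "24", "36", "41", "44")
  g <- expand.grid(timepoint = c("T1", "T2", "T3"), tooth = teeth,
                   surface = c("vestibular", "oral"),
                   subject_id = sprintf("S%02d", seq_len(nSubjects)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$method <- "scan"
  g$p_percent <- 5 +
    2 * match(g$tooth, teeth) +
    3 * (g$surface == "oral") +
    1.5 * match(g$timepoint, c("T1", "T2", "T3")) +
    0.25 * as.integer(sub("S", "", g$subject_id))
  g[, c("subject_id", "tooth", "surface", "timepoint", "method", "p_percent")]
}
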