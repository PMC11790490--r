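# Independent oracles coded from textbook formulas, kept deliberately
# separate from the package implementations they check.

# Wilson score interval, closed form
oracleWilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

# pooled two-proportion z statistic, no continuity correction
oracleZ <- function(x1, n1, x2, n2) {
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# classical Levene test (center = mean), textbook formula
oracleLevene <- function(a, b) {
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  z <- c(za, zb); g <- rep(1:2, c(length(a), length(b)))
  N <- length(z); k <- 2
  zbar <- mean(z)
  num <- (N - k) * sum(tapply(z, g, length) * (tapply(z, g, mean) - zbar)^2)
  den <- (k - 1) * sum((z - ave(z, g))^2)
  Fstat <- num / den
  list(F = Fstat, p = pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# quarter-circle midline discretized at ~1 px arc steps (vertices on the
# circle; an ideal skeleton of known total turning)
arcMidline <- function(R, span = pi / 2) {
  th <- seq(0, span, length.out = round(R * span) + 1)
  cbind(row = 55 + R * sin(th), col = 10 + R * (1 - cos(th)))
}

# assessment records with all eight criterion flags TRUE
allDeadRecords <- function(n) {
  flags <- matrix(TRUE, n, 8,
                  dimnames = list(NULL, assessmentColumns()))
  data.frame(larva_id = sprintf("larva%03d", seq_len(n)), flags)
}

# pseudo-ROI traces sampled from a movie on a patch grid (stand-in for the
# out-of-scope segmentation step when analyzing post-stun movies)
patchTraces <- function(movie, spacing = 8, radius = 1) {
  arr <- frames(movie)
  d <- dim(arr)
  centers <- expand.grid(
    r = seq(radius + 2, d[1] - radius - 1, by = spacing),
    c = seq(radius + 2, d[2] - radius - 1, by = spacing))
  t(apply(centers, 1, function(p) {
    rows <- (p[1] - radius):(p[1] + radius)
    cols <- (p[2] - radius):(p[2] + radius)
    apply(arr[rows, cols, , drop = FALSE], 3, mean)
  }))
}

# phase-lag profile of a kymograph: lag (frames) of the peak cross
# correlation between each row and a rostral reference row
kymographLags <- function(ky, probes = 6, maxLag = 15) {
  n <- nrow(ky)
  ref <- ky[round(n * 0.3), ]
  vapply(round(seq(n * 0.3, n * 0.95, length.out = probes)), function(i) {
    cc <- ccf(ky[i, ], ref, lag.max = maxLag, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }, numeric(1))
}
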