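# Independent oracles used to certify the package's implementations.
# Each is deliberately written by a different route than the code it
# checks (direct factorials vs log-gamma recurrences, exhaustive
# enumeration vs coordinate descent, bit-level decoding vs integer
# arithmetic).

# HWE exact p by direct factorial enumeration of the conditional
# distribution of heterozygote counts given allele counts (valid for
# totals <= ~80 before factorials overflow).
hweEnumOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * n - nA
  if (min(nA, nB) == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) *
      2^h * factorial(nA) * factorial(nB) / factorial(2 * n)
  }, 0)
  pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

# Exhaustive sign-pattern LASSO oracle for the objective
# (1/(2n)) RSS + lambda ||beta||_1 with an (unpenalized) intercept,
# handled by centering.  For each of the 3^p sign patterns, solves the
# equality-constrained stationarity system on the active set, keeps
# sign-consistent solutions, and returns the minimum objective attained.
lassoSignOracle <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  objective <- function(beta) {
    r <- yc - Xc %*% beta
    sum(r^2) / (2 * n) + lambda * sum(abs(beta))
  }
  best <- objective(rep(0, p))
  grid <- expand.grid(rep(list(c(-1, 0, 1)), p))
  for (k in seq_len(nrow(grid))) {
    s <- as.numeric(grid[k, ])
    A <- which(s != 0)
    if (!length(A)) next
    XA <- Xc[, A, drop = FALSE]
    bA <- tryCatch(
      solve(crossprod(XA) / n, crossprod(XA, yc) / n - lambda * s[A]),
      error = function(e) NULL)
    if (is.null(bA) || any(sign(bA) != s[A])) next
    beta <- rep(0, p); beta[A] <- bA
    best <- min(best, objective(beta))
  }
  best
}

# Brute-force greedy clumping re-implementation on a full r^2 matrix.
clumpOracle <- function(assoc, D, r2Threshold, windowKb, indexPMax,
                        memberPMax) {
  p <- nrow(assoc)
  R2 <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))^2
  R2[is.na(R2)] <- 0
  state <- rep("free", p)
  for (i in order(assoc$p, assoc$pos, assoc$id)) {
    if (state[i] != "free" || assoc$p[i] > indexPMax) next
    state[i] <- "index"
    for (j in seq_len(p)) {
      if (state[j] == "free" &&
          assoc$chrom[j] == assoc$chrom[i] &&
          abs(assoc$pos[j] - assoc$pos[i]) <= windowKb * 1000 &&
          assoc$p[j] <= memberPMax && R2[i, j] >= r2Threshold)
        state[j] <- "member"
    }
  }
  assoc$id[state != "member"]
}

# Independent PLINK .bed decoder via rawToBits (LSB-first bit pairs).
decodeBedOracle <- function(path, n, p) {
  raw <- readBin(path, "raw", file.info(path)$size)
  stopifnot(raw[1] == as.raw(0x6C), raw[2] == as.raw(0x1B),
            raw[3] == as.raw(0x01))
  body <- raw[-(1:3)]
  bytesPerSnp <- ceiling(n / 4)
  lut <- c(2, NA, 1, 0)
  out <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    bits <- as.integer(rawToBits(
      body[((j - 1) * bytesPerSnp + 1):(j * bytesPerSnp)]))
    for (i in seq_len(n)) {
      code <- bits[2 * i - 1] + 2 * bits[2 * i]
      out[i, j] <- lut[code + 1]
    }
  }
  out
}

# small random dosage GenotypeMatrix for property tests
randomGeno <- function(n, p, missingRate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.5)[rep(seq_len(p),
                                                      each = n)]),
              n, p)
  if (missingRate > 0) d[runif(n * p) < missingRate] <- NA
  GenotypeMatrix(d)
}
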