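# Independent oracles used by the tests. Each recomputes a quantity by a
# route different from the package implementation.

# Brute-force dip oracle: for each placement of the mode, minimize the band
# half-width t over all piecewise-linear nondecreasing convex-then-concave
# CDFs on the sample's knots (a jump is allowed at the mode). Each
# subproblem is a linear program solved via quadprog with a vanishing ridge.
oracle_dip <- function(x) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  F <- cumsum(tabulate(match(x, ux))) / n
  m <- length(ux)
  if (m == 1) return(1 / (2 * n))
  Fprev <- c(0, F[-m])
  best <- Inf
  for (j in 1:m) {
    nL <- j; nR <- m - j + 1
    nv <- nL + nR + 1; it <- nv
    A <- NULL; b <- NULL
    add <- function(row, rhs) { A <<- rbind(A, row); b <<- c(b, rhs) }
    zr <- function() numeric(nv)
    for (i in 1:nL) {          # left-piece boxes (lower relaxed at the mode)
      lo <- if (i < j) F[i] else Fprev[j]; hi <- Fprev[i]
      r <- zr(); r[i] <- 1; r[it] <- -1; add(r, hi)
      r <- zr(); r[i] <- -1; r[it] <- -1; add(r, -lo)
    }
    for (i in j:m) {           # right-piece boxes (upper relaxed at the mode)
      kk <- nL + (i - j + 1); lo <- F[i]; hi <- if (i == j) F[j] else Fprev[i]
      r <- zr(); r[kk] <- 1; r[it] <- -1; add(r, hi)
      r <- zr(); r[kk] <- -1; r[it] <- -1; add(r, -lo)
    }
    if (nL > 1) for (i in 1:(nL - 1)) {
      r <- zr(); r[i] <- 1; r[i + 1] <- -1; add(r, 0)
    }
    if (nR > 1) for (i in 1:(nR - 1)) {
      r <- zr(); r[nL + i] <- 1; r[nL + i + 1] <- -1; add(r, 0)
    }
    r <- zr(); r[nL] <- 1; r[nL + 1] <- -1; add(r, 0)   # jump up at the mode
    if (nL > 2) for (i in 2:(nL - 1)) {                 # convex left
      d1 <- ux[i] - ux[i - 1]; d2 <- ux[i + 1] - ux[i]
      r <- zr(); r[i - 1] <- -1 / d1; r[i] <- 1 / d1 + 1 / d2; r[i + 1] <- -1 / d2
      add(r, 0)
    }
    if (nR > 2) for (i in 2:(nR - 1)) {                 # concave right
      ii <- j + i - 1
      d1 <- ux[ii] - ux[ii - 1]; d2 <- ux[ii + 1] - ux[ii]
      r <- zr(); r[nL + i - 1] <- 1 / d1; r[nL + i] <- -(1 / d1 + 1 / d2)
      r[nL + i + 1] <- 1 / d2
      add(r, 0)
    }
    for (i in 1:(nv - 1)) {                             # 0 <= g <= 1
      r <- zr(); r[i] <- 1; add(r, 1)
      r <- zr(); r[i] <- -1; add(r, 0)
    }
    r <- zr(); r[it] <- -1; add(r, 0)                   # t >= 0
    D <- diag(1e-9, nv)
    d <- numeric(nv); d[it] <- -1
    sol <- try(quadprog::solve.QP(D, d, t(-A), -b), silent = TRUE)
    if (!inherits(sol, "try-error")) best <- min(best, sol$solution[it])
  }
  max(best, 1 / (2 * n))
}

# Exact-binomial classifier oracle built on stats::binom.test.
oracle_classify <- function(b, y, K = 2 / 3, alpha = 0.005, coverage = 10) {
  n <- b + y
  if (n == 0) return("too_rare")
  pb <- binom.test(b, n, p = K, alternative = "greater")$p.value
  py <- binom.test(y, n, p = K, alternative = "greater")$p.value
  pbg <- binom.test(b, n, p = 1 - K, alternative = "greater")$p.value
  pyg <- binom.test(y, n, p = 1 - K, alternative = "greater")$p.value
  if (pb <= alpha) "bacteria_dominated"
  else if (py <= alpha) "yeast_dominated"
  else if (pbg <= alpha && pyg <= alpha && n >= coverage) "co_dominated"
  else "too_rare"
}

# Weir-Cockerham variance components via the ANOVA mean-squares route
# (MSP/MSI/MSG on allele indicators), an algebraically different path from
# the package's direct moment formulas. g1, g2: genotype-code vectors.
oracle_fst_anova <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  y1 <- g1 / 2; y2 <- g2 / 2
  p1 <- mean(y1); p2 <- mean(y2)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  SSP <- 2 * n1 * (p1 - pbar)^2 + 2 * n2 * (p2 - pbar)^2
  MSP <- SSP / (r - 1)
  SSI <- 2 * sum((y1 - p1)^2) + 2 * sum((y2 - p2)^2)
  MSI <- SSI / (n1 + n2 - r)
  SSG <- sum(g1 == 1) / 2 + sum(g2 == 1) / 2
  MSG <- SSG / (n1 + n2)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  c <- MSG
  c(a = a, b = b, c = c)
}

# Exhaustive permutation p-value for the two-sided |log OR| test on 4+4
# samples (all C(8,4) group assignments), with the same 0.5 continuity
# correction but enumerated rather than sampled.
oracle_perm_p <- function(ga, gb) {
  pooled <- c(ga, gb)
  na <- length(ga)
  log_or <- function(a, b) {
    alt_a <- sum(a) + 0.5; ref_a <- 2 * length(a) - sum(a) + 0.5
    alt_b <- sum(b) + 0.5; ref_b <- 2 * length(b) - sum(b) + 0.5
    log((alt_a / ref_a) / (alt_b / ref_b))
  }
  obs <- abs(log_or(ga, gb))
  combos <- utils::combn(length(pooled), na)
  stats <- apply(combos, 2, function(idx) {
    abs(log_or(pooled[idx], pooled[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Closed-form chi-square upper tail for 3 degrees of freedom,
# P(X > x) = 2 (1 - Phi(sqrt(x))) + sqrt(2 x / pi) exp(-x / 2).
chisq3_sf <- function(x) {
  2 * (1 - pnorm(sqrt(x))) + sqrt(2 * x / pi) * exp(-x / 2)
}
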