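# Independent oracles, kept deliberately naive and separate from the
# package's own implementations.

# Circumradius of the circle through three 3D points, via the circumcenter
# found by solving the two perpendicular-bisector equations in the plane of
# the triangle. Returns Inf for collinear points.
oracle_circumradius <- function(p1, p2, p3) {
  u <- p2 - p1
  v <- p3 - p1
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(n^2)) < 1e-14) return(Inf)
  # circumcenter c = p1 + a*u + b*v with |c-p1| = |c-p2| = |c-p3|
  A <- rbind(c(sum(u * u), sum(u * v)),
             c(sum(u * v), sum(v * v)))
  rhs <- c(sum(u * u) / 2, sum(v * v) / 2)
  ab <- solve(A, rhs)
  center <- p1 + ab[1] * u + ab[2] * v
  sqrt(sum((center - p1)^2))
}

# Welch's heteroscedastic F* from its textbook formula.
oracle_welch <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  nj <- tapply(values, groups, length)
  mj <- tapply(values, groups, mean)
  s2 <- tapply(values, groups, var)
  wj <- nj / s2
  mw <- sum(wj * mj) / sum(wj)
  lambda <- sum((1 - wj / sum(wj))^2 / (nj - 1))
  f <- (sum(wj * (mj - mw)^2) / (k - 1)) /
    (1 + (2 * (k - 2) / (k^2 - 1)) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(statistic = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Bartlett's chi-squared statistic from its textbook formula.
oracle_bartlett <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  nj <- tapply(values, groups, length)
  s2 <- tapply(values, groups, var)
  N <- sum(nj)
  sp2 <- sum((nj - 1) * s2) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((nj - 1) * log(s2))) /
    (1 + (sum(1 / (nj - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, k - 1, lower.tail = FALSE))
}

# Balanced two-way ANOVA with interaction from raw sums of squares
# (one observation per cell combination of `a` (2 levels) x `b` (2 levels)
# with `reps` replicates folded into the case factor is NOT assumed here:
# this expects a balanced a x b layout with equal cell counts).
oracle_twoway <- function(y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  N <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); na <- tapply(y, a, length)
  mb <- tapply(y, b, mean); nb <- tapply(y, b, length)
  cell <- interaction(a, b)
  mc <- tapply(y, cell, mean); nc <- tapply(y, cell, length)
  ssa <- sum(na * (ma - gm)^2)
  ssb <- sum(nb * (mb - gm)^2)
  sscell <- sum(nc * (mc - gm)^2)
  ssab <- sscell - ssa - ssb
  sse <- sum((y - ave(y, cell))^2)
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfab <- dfa * dfb
  dfe <- N - nlevels(a) * nlevels(b)
  mse <- sse / dfe
  list(
    F_a = (ssa / dfa) / mse, p_a = pf((ssa / dfa) / mse, dfa, dfe, lower.tail = FALSE),
    F_b = (ssb / dfb) / mse, p_b = pf((ssb / dfb) / mse, dfb, dfe, lower.tail = FALSE),
    F_ab = (ssab / dfab) / mse, p_ab = pf((ssab / dfab) / mse, dfab, dfe, lower.tail = FALSE),
    dfe = dfe)
}

# Holm step-down adjustment written directly from its definition.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Two-sample KS statistic and asymptotic two-sided p value.
oracle_ks <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  D <- max(abs(Fx - Fy))
  n <- length(x) * length(y) / (length(x) + length(y))
  lam <- sqrt(n) * D
  # Kolmogorov series (same form as the classical asymptotic formula)
  kk <- 1:100
  p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lam^2))
  list(D = D, p = min(1, max(0, p)))
}

# Direct (non-separable) 3x3x3 Sobel convolution with mirror reflection.
oracle_sobel <- function(a, axis) {
  d <- dim(a)
  sm <- c(1, 2, 1); dv <- c(-1, 0, 1)
  refl <- function(i, n) {
    if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  }
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    acc <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      w <- switch(axis,
                  dv[dz + 2] * sm[dy + 2] * sm[dx + 2],
                  sm[dz + 2] * dv[dy + 2] * sm[dx + 2],
                  sm[dz + 2] * sm[dy + 2] * dv[dx + 2])
      acc <- acc + w * a[refl(z + dz, d[1]), refl(y + dy, d[2]),
                         refl(x + dx, d[3])]
    }
    out[z, y, x] <- acc
  }
  out / 32
}
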