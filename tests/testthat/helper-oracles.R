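# Independent brute-force oracles. These deliberately avoid the package's
# code paths: direct textbook formulas, exhaustive enumeration, explicit
# distance-matrix agglomeration.

# Per-gene pooled/Welch t test via stats::t.test on the detected values.
oracle_t_gene <- function(xp, xn, var_equal = TRUE) {
  tt <- stats::t.test(xp, xn, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

# Two-sided Fisher exact p by enumeration of all tables with the observed
# margins; ties in the null probabilities use the customary 1e-7 relative
# slack for floating-point equality.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Exhaustive two-sided Mann-Whitney p over all allocations of the pooled
# sample (no ties assumed).
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Log-rank chi-square from the standard O-E / V sums over event times.
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (t in ev_times) {
    at <- time >= t
    nt <- sum(at); n1t <- sum(at & g == 1L)
    dt <- sum(time == t & event == 1)
    d1t <- sum(time == t & event == 1 & g == 1L)
    OE <- OE + d1t - dt * n1t / nt
    if (nt > 1)
      V <- V + dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1)
  }
  OE^2 / V
}

# Greedy agglomeration by explicit Lance-Williams distance-matrix updates;
# returns the 2-group membership (the two clusters left before the final
# merge). `X` is samples x features. For "ward" the recursion runs on
# squared Euclidean distances (the ward.D2 convention).
oracle_two_groups <- function(X, linkage) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  if (linkage == "ward") d <- d^2
  diag(d) <- Inf
  clusters <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  while (length(clusters) > 2L) {
    k <- length(clusters)
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    i <- min(idx); j <- max(idx)
    ni <- sizes[i]; nj <- sizes[j]
    upd <- vapply(seq_len(k), function(h) {
      if (h == i || h == j) return(Inf)
      nh <- sizes[h]
      switch(linkage,
             average  = (ni * d[i, h] + nj * d[j, h]) / (ni + nj),
             complete = max(d[i, h], d[j, h]),
             single   = min(d[i, h], d[j, h]),
             ward     = ((ni + nh) * d[i, h] + (nj + nh) * d[j, h] -
                           nh * d[i, j]) / (ni + nj + nh))
    }, numeric(1))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    d[i, ] <- upd; d[, i] <- upd; d[i, i] <- Inf
    clusters[[j]] <- NULL
    sizes <- sizes[-j]
    d <- d[-j, -j, drop = FALSE]
  }
  memb <- integer(n)
  memb[clusters[[1L]]] <- 1L
  memb[clusters[[2L]]] <- 2L
  memb
}

# TRUE when two 2-group membership vectors induce the same partition.
same_partition <- function(a, b) {
  identical(a == a[1], b == b[1])
}
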