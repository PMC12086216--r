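# Independent oracles, implemented from first principles so they share no
# code path with the package functions they check.

# Adjusted Rand index by explicit O(n^2) pair counting.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  n11 <- sum(same_a[up] & same_b[up])
  n00 <- sum(!same_a[up] & !same_b[up])
  n10 <- sum(same_a[up] & !same_b[up])
  n01 <- sum(!same_a[up] & same_b[up])
  total <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# All partitions of n elements into at most k blocks, as restricted growth
# strings (each element's label <= 1 + max of previous labels).
partitions_up_to_k <- function(n, k = 3L) {
  grow <- function(prefix, mx) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (lab in seq_len(min(mx + 1L, k))) {
      out <- c(out, grow(c(prefix, lab), max(mx, lab)))
    }
    out
  }
  grow(integer(0), 0L)
}

# Benjamini-Hochberg step-up by the textbook formula
# adj_i = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (j in rev(seq_len(m))) {
    running <- min(running, ps[j] * m / j)
    adj[j] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins: sum the probabilities of tables whose
# probability does not exceed the observed one (relative tolerance 1e-7).
fisher_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  log_prob <- function(x) {
    lchoose(c1, x) + lchoose(c2, r1 - x) - lchoose(n, r1)
  }
  xs <- max(0, r1 - c2):min(r1, c1)
  lp <- vapply(xs, log_prob, 0)
  obs <- log_prob(a)
  sum(exp(lp[lp <= obs + log(1 + 1e-7)]))
}
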