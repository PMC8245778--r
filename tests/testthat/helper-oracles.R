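# Independent brute-force oracles used by the unit and acceptance tests.
# They deliberately share no code with the package internals.

# ranks by stable sort, then average within tie blocks
oracle_rank <- function(x) {
  n <- length(x)
  ord <- sort.list(x, method = "radix")  # stable
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    block <- which(x[ord] == x[ord[i]])
    r[ord[block]] <- mean(block)
    i <- max(block) + 1
  }
  r
}

# BH from the definition: explicit cumulative minimum walking down from the
# largest rank
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, (m / i) * p[ord[i]])
    q[ord[i]] <- min(running, 1)
  }
  q
}

# log-rank from hypergeometric mean/variance terms summed over event times
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  g1 <- rep(c(TRUE, FALSE), c(length(t1), length(t2)))
  O <- E <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    atrisk <- time >= tt
    n <- sum(atrisk); n1 <- sum(atrisk & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# pooled-variance two-sample t from the textbook formula
oracle_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  tt <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# build a label vector for differential scoring from explicit id sets
make_groups <- function(all_ids, high_ids, low_ids) {
  g <- data.frame(sample_id = all_ids, group = "unassigned",
                  stringsAsFactors = FALSE)
  g$group[match(high_ids, g$sample_id)] <- "CE-high"
  g$group[match(low_ids, g$sample_id)] <- "CE-low"
  g
}

# small, fast synthetic configuration for unit tests
tiny_config <- function(..., seed = 1) {
  mixture_config(n_samples = 40, n_genes = 120, n_ec_constitutive = 20,
                 n_ce_high_conditional = 6, n_ce_low_conditional = 6,
                 seed = seed, ...)
}
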