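# Independent oracles used across the suite. Each is a direct, naive
# transcription of the definition it checks, kept free of the package's own
# code paths.

# expression matrix fixture with unique ids
makeExpr <- function(values, state = "counts", prefix = c("f", "s")) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("%s%02d", prefix[1L], seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s%02d", prefix[2L], seq_len(ncol(values)))
  }
  ExpressionMatrix(values, state)
}

# naive O(N) running-sum enrichment score over a ranked weight vector
naiveEs <- function(rs, hit, weightExponent = 1) {
  N <- length(rs)
  w <- abs(rs)^weightExponent
  NR <- sum(w[hit])
  step <- numeric(N)
  step[hit] <- if (NR > 0) w[hit] / NR else 1 / sum(hit)
  step[!hit] <- -1 / (N - sum(hit))
  cs <- cumsum(step)
  maxdev <- max(0, cs)
  mindev <- min(0, cs)
  # same tie convention as the implementation: near-equal extremes go positive
  if (maxdev + 1e-12 >= -mindev) maxdev else mindev
}

# residual-orthogonalization partial correlation: correlate the residuals of
# x and y after least-squares regression on c
residualPcc <- function(x, y, c) {
  rx <- stats::resid(stats::lm(x ~ c))
  ry <- stats::resid(stats::lm(y ~ c))
  stats::cor(rx, ry)
}

# textbook two-group log-rank: observed/expected event sums over the pooled
# distinct event times, hypergeometric variance
handLogRank <- function(time, event, group1) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in times) {
    atRisk <- time >= tt
    n <- sum(atRisk)
    n1 <- sum(atRisk & group1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# a small survival cohort where the hazard jumps by `hr` above score 0
simulateStepHazard <- function(n, hr, seed) {
  set.seed(seed)
  score <- runif(n, -1, 1)
  rate <- 0.05 * ifelse(score > 0, hr, 1)
  eventTime <- rexp(n, rate)
  censTime <- rexp(n, 0.02)
  list(score = score,
       time = pmin(eventTime, censTime),
       event = as.integer(eventTime <= censTime))
}

# ranked list fixture with continuous rank scores (no ties)
makeRanked <- function(n, seed = 1) {
  set.seed(seed)
  rs <- sort(rnorm(n, sd = 2), decreasing = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), rs = rs,
             stringsAsFactors = FALSE)
}
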