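# Independent reference implementations used as oracles. These stay naive
# on purpose: per-position double loops and textbook formulas, no shared
# code with the vectorised implementation paths they check.

# double-loop center-surround scan: mean-of-8-surround subtracted from the
# center at every grid position, aggregated by direct formula evaluation
naive_profile <- function(frame, scales, gamma = 2, mode = "power") {
  M <- unclass(frame)
  m <- max(scales)
  offs <- rbind(c(0, -1), c(0, 1), c(-1, 0), c(1, 0),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  t(vapply(scales, function(k) {
    on <- off <- 0; n_on <- n_off <- 0L
    for (r in (m + 1):(nrow(M) - m)) {
      for (cc in (m + 1):(ncol(M) - m)) {
        s <- 0
        for (j in 1:8) s <- s + M[r + k * offs[j, 1], cc + k * offs[j, 2]]
        resp <- M[r, cc] - s / 8
        w <- switch(mode, power = abs(resp)^gamma, sum = abs(resp),
                    count = 1)
        if (resp > 0) { on <- on + w; n_on <- n_on + 1L }
        if (resp < 0) { off <- off + w; n_off <- n_off + 1L }
      }
    }
    c(on = on, off = off, n_on = n_on, n_off = n_off)
  }, numeric(4)))
}

# textbook one-sample t on differences
oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# brute-force sums-of-squares decomposition for a one-way repeated-measures
# design: y is an n_units x n_times matrix
oracle_rm_anova <- function(y) {
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  ss_time <- n * sum((colMeans(y) - gm)^2)
  ss_unit <- k * sum((rowMeans(y) - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_err <- ss_total - ss_time - ss_unit
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_time / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# profile columns stripped of frame metadata, for bit-identity comparisons
profile_values <- function(profile) lapply(as.data.frame(profile), identity)

# small deterministic test frame with interior structure
structured_frame <- function(w = 32, h = 32, seed = 7) {
  set.seed(seed)
  gray_frame(matrix(sample(0:255, w * h, replace = TRUE), h, w))
}
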