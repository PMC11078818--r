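# Independent reference implementations used as oracles. Each is a direct,
# naive transcription of the defining formula, sharing no code path with the
# package functions it checks.

# Harrell's C by brute-force enumeration of all sample pairs.
oracle_cindex <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # order the pair so a is the earlier observed time
      a <- if (time[i] <= time[j]) i else j
      b <- if (time[i] <= time[j]) j else i
      if (time[a] == time[b]) {
        if (event[a] == 1 && event[b] == 1) {
          # tied failure times: not usable under Harrell's rule
          next
        }
        if (event[a] + event[b] != 1) next
        # one died, one censored at the same time: the death precedes
        if (event[b] == 1) { tmp <- a; a <- b; b <- tmp }
      } else if (event[a] == 0) {
        next  # earlier time censored: ordering unknown
      }
      usable <- usable + 1
      conc <- conc + (if (scores[a] > scores[b]) 1 else if (scores[a] == scores[b]) 0.5 else 0)
    }
  }
  list(c_index = conc / usable, n_usable = usable)
}

# Log-rank chi-square by direct observed-minus-expected accumulation over
# event times (two or more groups).
oracle_logrank <- function(groups, time, event) {
  groups <- factor(groups)
  g <- nlevels(groups)
  ev_times <- sort(unique(time[event == 1]))
  O <- numeric(g); E <- numeric(g)
  V <- matrix(0, g, g)
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (k in seq_len(g)) {
      nk <- sum(at_risk & groups == levels(groups)[k])
      dk <- sum(event == 1 & time == t & groups == levels(groups)[k])
      O[k] <- O[k] + dk
      E[k] <- E[k] + d_t * nk / n_t
    }
    if (n_t > 1) {
      for (k in seq_len(g)) for (l in seq_len(g)) {
        nk <- sum(at_risk & groups == levels(groups)[k])
        nl <- sum(at_risk & groups == levels(groups)[l])
        V[k, l] <- V[k, l] + d_t * (n_t - d_t) / (n_t - 1) *
          (nk * ((k == l) * n_t - nl)) / n_t^2
      }
    }
  }
  u <- (O - E)[-1]
  stat <- as.numeric(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
  list(statistic = stat, df = g - 1,
       p = pchisq(stat, df = g - 1, lower.tail = FALSE))
}

# Cox partial log-likelihood for a single covariate, no tied event times
# (Breslow and Efron coincide), maximized by a hand-written Newton iteration
# with analytic first and second derivatives of the written likelihood.
oracle_cox_coef <- function(x, time, event, max_abs = 15) {
  derivs <- function(beta) {
    g <- 0; h <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(beta * x[risk])
      m1 <- sum(w * x[risk]) / sum(w)
      m2 <- sum(w * x[risk]^2) / sum(w)
      g <- g + x[i] - m1
      h <- h - (m2 - m1^2)
    }
    c(g = g, h = h)
  }
  beta <- 0
  for (iter in 1:200) {
    d <- derivs(beta)
    if (abs(d["h"]) < 1e-300) break
    step <- -d["g"] / d["h"]
    beta <- beta + max(min(step, 1), -1)  # damped for stability
    if (abs(beta) > max_abs) break
    if (abs(step) < 1e-13) break
  }
  list(coef = unname(beta), at_boundary = abs(beta) >= max_abs - 1e-3)
}

# Benjamini-Hochberg step-up by the direct formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Maximally selected standardized log-rank statistic by a naive per-threshold
# scan: recompute Nelson-Aalen log-rank scores from scratch and loop over
# midpoints, computing each statistic by direct summation.
oracle_cutpoint <- function(score, time, event, minprop = 0.10) {
  n <- length(score)
  a <- numeric(n)
  for (i in seq_len(n)) {
    haz <- 0
    for (t in sort(unique(time[time <= time[i]]))) {
      haz <- haz + sum(event == 1 & time == t) / sum(time >= t)
    }
    a[i] <- event[i] - haz
  }
  abar <- mean(a); ss <- sum((a - abar)^2)
  u <- sort(unique(score))
  best_stat <- -Inf; best_thr <- NA
  min_n <- ceiling(minprop * n)
  for (k in seq_len(length(u) - 1)) {
    thr <- (u[k] + u[k + 1]) / 2
    low <- score <= thr
    n1 <- sum(low)
    if (n1 < min_n || n - n1 < min_n) next
    stat <- abs(sum(a[low]) - n1 * abar) /
      sqrt(n1 * (n - n1) / (n * (n - 1)) * ss)
    if (stat > best_stat + 1e-12) { best_stat <- stat; best_thr <- thr }
  }
  list(threshold = best_thr, statistic = best_stat)
}

# DerSimonian-Laird random-effects pooling by the hand formula.
oracle_dl <- function(y, se) {
  w <- 1 / se^2
  yf <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yf)^2)
  df <- length(y) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * y) / sum(ws)
  list(pooled = pooled, se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# Mann-Whitney rank-sum AUC.
oracle_rank_auc <- function(scores_case, scores_ctrl) {
  cmp <- outer(scores_case, scores_ctrl,
               function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
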