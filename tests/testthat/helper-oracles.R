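# Independent brute-force oracles. Deliberately written as naive loops over
# the defining formulas, sharing no code with the package implementations.

# AUC as the concordance probability over all positive x negative pairs,
# ties counted one half
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over every candidate threshold (all observed
# values and midpoints, plus sentinels), rule: score >= t is positive;
# ties broken toward higher sensitivity
bf_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, u - 1e-9, min(u) - 1, max(u) + 1,
                        if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  best_j <- -Inf; best_sens <- -1; best_t <- NA
  for (t in cand) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && sens > best_sens)) {
      best_j <- j; best_sens <- sens; best_t <- t
    }
  }
  list(j = best_j, sensitivity = best_sens, threshold = best_t)
}

# sample entropy by explicit template counting
bf_sampen <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  A <- 0; B <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# mean silhouette coefficient from the pairwise-distance definition
bf_silhouette <- function(x, cl) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) sqrt(sum((x[i, ] - x[j, ])^2))))
    others <- setdiff(unique(cl), cl[i])
    b <- min(sapply(others, function(k) {
      mean(sapply(which(cl == k),
                  function(j) sqrt(sum((x[i, ] - x[j, ])^2))))
    }))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
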