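# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: naive double loops, exhaustive
# enumeration, and closed forms.

# exhaustive greedy minimal within-cluster-variance-increase agglomeration;
# heights are sqrt(2 * delta SSE) so a singleton pair merges at its
# Euclidean distance. Tie-break: lexicographically smallest pair of
# cluster-creation indices (leaves 1..n, merges n+1..).
oracle_ward <- function(x) {
  n <- nrow(x)
  sse <- function(rows) {
    if (length(rows) == 1L) return(0)
    ctr <- colMeans(x[rows, , drop = FALSE])
    sum(sweep(x[rows, , drop = FALSE], 2L, ctr)^2)
  }
  clusters <- lapply(seq_len(n), identity)   # leaf index sets
  cid <- seq_len(n)                          # creation indices
  heights <- numeric(0)
  partitions <- list()                       # membership after each merge
  for (m in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        inc <- sse(c(clusters[[a]], clusters[[b]])) -
          sse(clusters[[a]]) - sse(clusters[[b]])
        key <- c(min(cid[a], cid[b]), max(cid[a], cid[b]))
        if (is.null(best) || inc < best$inc - 1e-12 ||
            (abs(inc - best$inc) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(a = a, b = b, inc = inc, key = key)
        }
      }
    }
    heights[m] <- sqrt(2 * best$inc)
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    clusters <- clusters[-c(best$a, best$b)]
    cid <- cid[-c(best$a, best$b)]
    clusters[[length(clusters) + 1L]] <- merged
    cid[length(cid) + 1L] <- n + m
    memb <- integer(n)
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[m]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# normalise a membership vector so partitions compare up to relabelling
canon_partition <- function(memb) match(memb, unique(memb))

# pair-counting AUROC (lower score = positive prediction)
oracle_auroc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p < q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# rank-scan average precision, ties broken by id ascending
oracle_ap <- function(id, score, label) {
  ord <- order(score, id)
  lab <- as.logical(label)[ord]
  hits <- 0; s <- 0
  for (r in seq_along(lab)) {
    if (lab[r]) {
      hits <- hits + 1
      s <- s + hits / r
    }
  }
  s / sum(lab)
}

# brute-force occupancy autocorrelation, full-series <h^2> denominator
oracle_autocorr <- function(h, max_lag = length(h) - 1L) {
  f <- length(h)
  denom <- mean(h^2)
  vapply(0:max_lag, function(lag) {
    acc <- 0
    for (t0 in seq_len(f - lag)) acc <- acc + h[t0] * h[t0 + lag]
    (acc / (f - lag)) / denom
  }, double(1L))
}

# exhaustive affine-gap global alignment score; gap of length L costs
# open + L * extend
oracle_align_score <- function(a, b, mat, open = 10, extend = 1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (j <= length(cb)) {   # gap in a, consume b[j]
      cost <- extend + if (prev == "ga") 0 else open
      best <- max(best, -cost + rec(i, j + 1L, "ga"))
    }
    if (i <= length(ca)) {   # gap in b, consume a[i]
      cost <- extend + if (prev == "gb") 0 else open
      best <- max(best, -cost + rec(i + 1L, j, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# mass-weighted Rg by direct definition (explicit centre-of-mass loop)
oracle_rg <- function(frame, masses) {
  tot <- sum(masses)
  com <- c(sum(frame[, 1] * masses), sum(frame[, 2] * masses),
           sum(frame[, 3] * masses)) / tot
  acc <- 0
  for (i in seq_len(nrow(frame))) {
    acc <- acc + masses[i] * sum((frame[i, ] - com)^2)
  }
  sqrt(acc / tot)
}
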