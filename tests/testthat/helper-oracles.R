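# Independent brute-force oracles, written from the definitional formulas
# (explicit sums and loops, no calls into the package and no stats::cor /
# stats::quantile). They are deliberately slow and literal.

o_pearson <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
  }
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

o_weighted_pearson <- function(x, y, w) {
  x <- as.vector(x); y <- as.vector(y)
  w <- as.vector(w) / sum(w)
  mx <- 0; my <- 0
  for (i in seq_along(x)) { mx <- mx + w[i] * x[i]; my <- my + w[i] * y[i] }
  vx <- 0; vy <- 0; vxy <- 0
  for (i in seq_along(x)) {
    vx <- vx + w[i] * (x[i] - mx)^2
    vy <- vy + w[i] * (y[i] - my)^2
    vxy <- vxy + w[i] * (x[i] - mx) * (y[i] - my)
  }
  vxy / sqrt(vx * vy)
}

o_pcm <- function(m) {
  k <- nrow(m)
  out <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- if (i == j) 1 else o_pearson(m[i, ], m[j, ])
    }
  }
  out
}

o_dutilh <- function(pa, pb) {
  k <- nrow(pa)
  vapply(seq_len(k), function(i) {
    ref <- setdiff(seq_len(k), i)
    o_pearson(pa[i, ref], pb[i, ref])
  }, numeric(1))
}

o_essien <- function(pa, pb, nodes) {
  k <- nrow(pa)
  vapply(seq_len(k), function(i) {
    ref <- setdiff(nodes, i)
    o_pearson(pa[i, ref], pb[i, ref])
  }, numeric(1))
}

# exhaustive scan over all unordered pairs
o_ccn_nodes <- function(pa, pb, thr_a, thr_b) {
  k <- nrow(pa)
  nodes <- integer(0)
  n_edges <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (pa[i, j] > thr_a && pb[i, j] > thr_b) {
        n_edges <- n_edges + 1L
        nodes <- union(nodes, c(i, j))
      }
    }
  }
  list(nodes = sort(nodes), n_edges = n_edges)
}

# type-7 (linear interpolation) quantile by explicit sort and index
o_quantile7 <- function(s, x) {
  s <- sort(as.vector(s))
  n <- length(s)
  h <- (n - 1) * x + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

o_mean_sd <- function(v) {
  v <- as.vector(v)
  n <- length(v)
  m <- 0
  for (x in v) m <- m + x
  m <- m / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  c(mean = m, sd = sqrt(ss / (n - 1)))
}

# average ranks computed by sorting, ties averaged explicitly
o_rank <- function(v) {
  ord <- order(v)
  r <- numeric(length(v))
  i <- 1L
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[ord[j + 1L]] == v[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

o_agreement <- function(v1, v2) {
  c(pearson = o_pearson(v1, v2),
    spearman = o_pearson(o_rank(v1), o_rank(v2)))
}

# exhaustive pairwise concordance count (AUC), ties count 0.5
o_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}
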