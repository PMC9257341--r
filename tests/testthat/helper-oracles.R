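# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal possible algorithm so the package
# implementations are checked against something they share no code with.

# nearest-label expansion: for every background pixel scan ALL labeled
# pixels within `distance`, take the nearest, break ties by lower label
bf_expand <- function(mask, distance) {
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  src <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(src)) return(out)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (mask[r, c] > 0) next
      d2 <- (src[, 1] - r)^2 + (src[, 2] - c)^2
      ok <- d2 <= distance^2
      if (!any(ok)) next
      dmin <- min(d2[ok])
      cands <- mask[src[ok & d2 == dmin, , drop = FALSE]]
      out[r, c] <- min(cands)
    }
  }
  out
}

# all-pairs neighbor edges (inclusive radius)
bf_edges <- function(x, y, r) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= r^2) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# observed microenvironment percentage by direct per-cell counting
bf_observed <- function(edges, labels, a, b) {
  n_a <- sum(labels == a)
  if (n_a == 0) return(NA_real_)
  hits <- 0
  for (i in which(labels == a)) {
    nb <- c(edges$j[edges$i == i], edges$i[edges$j == i])
    if (any(labels[nb] == b)) hits <- hits + 1
  }
  hits / n_a
}

# exhaustive Otsu: search every candidate threshold for maximal
# between-class variance
bf_otsu <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  best <- -Inf; thr <- cand[1]
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best) {
      best <- bc
      thr <- t
    }
  }
  thr
}

# every distinct arrangement of a label multiset (for exact permutation
# nulls on tiny instances)
bf_label_arrangements <- function(labels) {
  uniq <- unique(labels)
  res <- list()
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (u in unique(remaining)) {
      k <- match(u, remaining)
      recurse(c(prefix, u), remaining[-k])
    }
  }
  recurse(character(), sort(labels))
  res
}

# minimum pixel-to-pixel distance between two labels of a mask
bf_min_label_distance <- function(mask, a, b) {
  pa <- which(mask == a, arr.ind = TRUE)
  pb <- which(mask == b, arr.ind = TRUE)
  sqrt(min(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}
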