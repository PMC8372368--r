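# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code with the implementation.

# all r x c tables with the given margins (small tables only)
enumerate_tables <- function(rows, cols) {
  r <- length(rows); c <- length(cols)
  fill <- function(i, remaining_rows, remaining_cols) {
    if (i == r) {
      if (all(remaining_cols >= 0) && remaining_rows[1] == sum(remaining_cols))
        return(list(matrix(remaining_cols, nrow = 1)))
      return(list())
    }
    out <- list()
    cells <- expand_cells(remaining_rows[1], remaining_cols)
    for (cell in cells) {
      rest <- fill(i + 1, remaining_rows[-1], remaining_cols - cell)
      for (m in rest) out <- c(out, list(rbind(cell, m)))
    }
    out
  }
  fill(1, rows, cols)
}

# all non-negative integer c-vectors summing to `total`, bounded by `caps`
expand_cells <- function(total, caps) {
  if (length(caps) == 1) {
    if (total <= caps) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1]))
    for (rest in expand_cells(total - v, caps[-1]))
      out <- c(out, list(c(v, rest)))
  out
}

# hypergeometric probability of a table given its margins
table_prob <- function(m) {
  exp(sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
        lgamma(sum(m) + 1) - sum(lgamma(m + 1)))
}

# two-sided Fisher p by the point-probability method, via full enumeration
enum_fisher <- function(m) {
  tabs <- enumerate_tables(rowSums(m), colSums(m))
  probs <- vapply(tabs, table_prob, 0)
  p_obs <- table_prob(m)
  list(p = sum(probs[probs <= p_obs * (1 + 1e-7)]), total = sum(probs))
}

# O(n^3) complete-linkage agglomeration, returning sorted merge heights
brute_complete_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters))
      for (j in seq_along(clusters))
        if (i < j) {
          h <- max(dm[clusters[[i]], clusters[[j]]])
          if (h < best_h) { best_h <- h; best <- c(i, j) }
        }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# product-limit survival table computed step by step
hand_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1; out <- data.frame(time = ut, survival = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[k] <- s
  }
  out
}

# majority-vote mapping of recovered cluster labels onto truth labels
match_clusters <- function(labels, truth) {
  out <- labels
  for (k in unique(labels[labels > 0])) {
    tt <- table(truth[labels == k])
    out[labels == k] <- as.integer(names(tt)[which.max(tt)])
  }
  out
}

# latent group each recovered cluster corresponds to (majority vote)
cluster_for_group <- function(labels, truth, g) {
  votes <- vapply(sort(unique(labels[labels > 0])), function(k)
    mean(truth[labels == k] == g), 0)
  sort(unique(labels[labels > 0]))[which.max(votes)]
}
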