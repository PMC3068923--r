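# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: direct combinatorial sums, exhaustive rank search,
# subset enumeration and naive agglomeration.

# hypergeometric upper tail by direct enumeration of the pmf
hyper_tail_enum <- function(k, K, N, m) {
  if (k == 0) return(1)
  j <- k:min(K, N)
  sum(choose(N, j) * choose(m - N, K - j)) / choose(m, K)
}

# BH step-up by the maximal-rank definition: reject the i* smallest
# p-values where i* = max{ i : p_(i) <= q * i / n }, searching all ranks
bh_select_brute <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  istar <- 0
  for (i in seq_len(n)) if (ps[i] <= q * i / n) istar <- i
  sel <- logical(n)
  if (istar > 0) sel[ord[seq_len(istar)]] <- TRUE
  sel
}

# Poisson-binomial pmf by enumeration over all drug subsets
poisbin_enum <- function(q) {
  D <- length(q)
  pmf <- numeric(D + 1)
  for (bits in 0:(2^D - 1)) {
    subset <- as.logical(bitwAnd(bits, 2^(0:(D - 1))))
    pr <- prod(ifelse(subset, q, 1 - q))
    n <- sum(subset)
    pmf[n + 1] <- pmf[n + 1] + pr
  }
  pmf
}

# Venn cell counts by per-element signature lookup
venn_brute <- function(sets) {
  nm <- names(sets)
  u <- unique(unlist(sets))
  sig <- vapply(u, function(e)
    paste(nm[vapply(sets, function(s) e %in% s, TRUE)], collapse = "&"), "")
  table(sig)
}

# naive O(n^3) complete-linkage agglomeration with the same documented tie
# rule: among minimum-distance pairs, lowest positions in the cluster list,
# merged cluster replacing its earlier component
complete_linkage_naive <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  cl_dist <- function(a, b) max(dmat[a, b])
  while (length(clusters) > 1) {
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- cl_dist(clusters[[i]], clusters[[j]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
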