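fake_enrichment <- function(p_J, ids = paste0("p", seq_along(p_J))) {
  structure(data.frame(pathway_id = ids, p_G = 1, p_M = 1, p_J = p_J),
            class = c("enrichment_result", "data.frame"))
}

test_that("the binary matrix keeps only drug-associated pathways", {
  enr <- list(
    d1 = fake_enrichment(c(0.01, 0.2, 0.04, 0.9)),
    d2 = fake_enrichment(c(0.02, 0.2, 0.9, 0.9)),
    d3 = fake_enrichment(c(0.9, 0.9, 0.9, 0.9))
  )
  B <- build_binary_matrix(enr, alpha = 0.05)
  expect_equal(colnames(B), c("p1", "p3"))   # union of significant sets
  expect_equal(unname(unclass(B)), rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L)),
               ignore_attr = TRUE)
  expect_equal(attr(B, "empty_drugs"), "d3")

  single <- build_binary_matrix(enr["d1"], alpha = 0.05)
  expect_equal(colnames(single), c("p1", "p3"))
  expect_warning(build_binary_matrix(list(d1 = fake_enrichment(rep(1, 3)))),
                 "no pathway significant")
})

test_that("hamming distance is a normalised mismatch proportion", {
  m <- rbind(a = c(0, 0, 0, 1), b = c(1, 1, 0, 1), c = c(0, 0, 0, 1))
  d <- as.matrix(hamming_dist(m))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(as.matrix(hamming_dist(m, normalize = FALSE))["a", "b"], 2)
})

test_that("complete linkage merges duplicates first and opposites last", {
  m <- rbind(zero = c(0, 0, 0), mid = c(1, 0, 0), one = c(1, 1, 1),
             zero2 = c(0, 0, 0))
  hc <- complete_linkage(hamming_dist(m))
  expect_equal(hc$height[1], 0)           # the duplicate pair merges at 0
  expect_equal(sort(hc$merge[1, ]), c(-4, -1))
  expect_equal(hc$height[length(hc$height)], 1)  # all-mismatch joins last
  expect_true(all(diff(hc$height) >= 0))  # monotone dendrogram
})

test_that("linkage heights match a naive O(n^3) oracle on random binary matrices", {
  set.seed(14)
  for (rep in 1:6) {
    m <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8,
                dimnames = list(paste0("d", 1:8), paste0("p", 1:12)))
    d <- hamming_dist(m)
    hc <- complete_linkage(d)
    expect_equal(hc$height, complete_linkage_naive(as.matrix(d)),
                 tolerance = 1e-12)
  }
})

test_that("linkage agrees with stats::hclust when distances are tie-free", {
  set.seed(8)
  m <- matrix(rbinom(9 * 14, 1, 0.5), nrow = 9)
  d <- stats::dist(m, method = "manhattan")
  d <- d + runif(length(d), 0, 1e-6)   # break ties
  ours <- complete_linkage(d)
  ref <- stats::hclust(d, method = "complete")
  expect_equal(ours$height, ref$height, tolerance = 1e-9)
  expect_equal(stats::cophenetic(ours), stats::cophenetic(ref),
               tolerance = 1e-9)
})

test_that("clustering is invariant to row permutation up to relabelling", {
  set.seed(31)
  m <- matrix(rbinom(7 * 10, 1, 0.45), nrow = 7,
              dimnames = list(paste0("d", 1:7), paste0("p", 1:10)))
  perm <- sample(7)
  coph1 <- as.matrix(stats::cophenetic(complete_linkage(hamming_dist(m))))
  coph2 <- as.matrix(stats::cophenetic(complete_linkage(hamming_dist(m[perm, ]))))
  dimnames(coph1) <- list(rownames(m), rownames(m))
  dimnames(coph2) <- list(rownames(m)[perm], rownames(m)[perm])
  expect_equal(coph2[rownames(coph1), colnames(coph1)], coph1,
               tolerance = 1e-12)
})

test_that("cluster_binary excludes empty drug rows and labels leaves", {
  enr <- list(d1 = fake_enrichment(c(0.01, 0.9, 0.01)),
              d2 = fake_enrichment(c(0.9, 0.01, 0.01)),
              d3 = fake_enrichment(c(0.01, 0.01, 0.9)),
              d4 = fake_enrichment(c(0.9, 0.9, 0.9)))
  B <- build_binary_matrix(enr)
  hc <- cluster_binary(B, "drugs")
  expect_setequal(hc$labels, c("d1", "d2", "d3"))
  expect_equal(nrow(hc$linkage), 2)
})

test_that("frequent pathway ranking extends through ties", {
  B <- structure(rbind(c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 1, 0)),
                 dimnames = list(paste0("d", 1:3), paste0("p", 1:4)),
                 class = c("binary_association_matrix", "matrix"))
  top <- frequent_pathways(B, top_k = 2)
  expect_equal(top$pathway_id, c("p1", "p2", "p3"))   # p3 tied with p2
  expect_equal(top$n_drugs, c(3L, 2L, 2L))
  all_tied <- frequent_pathways(B, top_k = 4)
  expect_equal(nrow(all_tied), 4)

  # sort-then-extend oracle on random column sums
  set.seed(2)
  Br <- structure(matrix(rbinom(6 * 15, 1, 0.5), nrow = 6,
                         dimnames = list(paste0("d", 1:6), paste0("q", 1:15))),
                  class = c("binary_association_matrix", "matrix"))
  k <- 5
  got <- frequent_pathways(Br, k)
  cs <- sort(colSums(unclass(Br)), decreasing = TRUE)
  expect_true(all(got$n_drugs >= cs[k]))
  expect_equal(nrow(got), sum(colSums(unclass(Br)) >= cs[k]))
})

test_that("specificity comparison splits consensus pathways correctly", {
  expect_equal(specificity_compare(c("a", "b"), c("c", "d"))$n_consensus_only, 2)
  expect_equal(specificity_compare(c("a", "b"), c("a", "b", "c"))$n_intersect, 2)
  s <- specificity_compare(c("a", "b", "c"), c("b", "z"))
  expect_equal(s$intersect, "b")
  expect_setequal(s$consensus_only, c("a", "c"))
})
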