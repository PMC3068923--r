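toy_matrix <- function(rows, samples = paste0("s", seq_len(ncol(rows))),
                       namespace = "gene") {
  colnames(rows) <- samples
  omics_matrix(rows, namespace)
}

test_that("correlation recovers identity, symmetry and the exact formula", {
  y <- stats::setNames(c(1.2, 0.3, 2.5, 1.9, 0.1), paste0("s", 1:5))
  m <- toy_matrix(rbind(f_same = y, f_neg = -y,
                        f_toy = c(0.4, 1.1, 0.2, 2.0, 0.9)))
  a <- correlate(m, y)
  expect_equal(a$r[a$feature_id == "f_same"], 1)
  expect_equal(a$r[a$feature_id == "f_neg"], -1)

  # direct sum-based Pearson formula and exact t CDF, computed by hand
  x <- c(0.4, 1.1, 0.2, 2.0, 0.9); n <- 5
  rx <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  tt <- rx * sqrt((n - 2) / (1 - rx^2))
  expect_equal(a$r[a$feature_id == "f_toy"], rx, tolerance = 1e-12)
  expect_equal(a$p[a$feature_id == "f_toy"], 2 * stats::pt(-abs(tt), n - 2),
               tolerance = 1e-12)
  expect_equal(a$n_used, rep(5L, 3))
})

test_that("zero-variance and under-sampled features are flagged and never selected", {
  y <- stats::setNames(rnorm(6), paste0("s", 1:6))
  m <- toy_matrix(rbind(flat = rep(2, 6),
                        sparse = c(1, 2, NA, NA, NA, NA),
                        ok = rnorm(6)))
  expect_warning(a <- correlate(m, y), "fewer than 3 complete pairs")
  expect_true(a$excluded[a$feature_id == "flat"])
  expect_true(a$excluded[a$feature_id == "sparse"])
  expect_false(a$excluded[a$feature_id == "ok"])
  panel <- select_significant(a, fdr_q = 0.99)
  expect_false(any(c("flat", "sparse") %in% panel$selected))
})

test_that("missing phenotype entries are handled pairwise-complete", {
  y <- stats::setNames(c(1, 2, NA, 4, 5, 6), paste0("s", 1:6))
  m <- toy_matrix(rbind(f = c(2, 4, 100, 8, 10, 12)))
  a <- correlate(m, y)
  expect_equal(a$n_used, 5L)
  expect_equal(a$r, 1)
})

test_that("BH selection matches the brute-force step-up on random lists", {
  # printed toy list: only the two smallest survive at q = 0.6
  a <- structure(data.frame(feature_id = c("a", "b", "c"),
                            r = c(0.9, -0.8, 0.1), p = c(0.01, 0.02, 0.9),
                            n_used = 10L, excluded = FALSE),
                 namespace = "gene", class = c("association_table", "data.frame"))
  panel <- select_significant(a, 0.6)
  expect_setequal(panel$selected, c("a", "b"))
  expect_equal(unname(panel$sign[c("a", "b")]), c(1, -1))

  set.seed(42)
  for (rep in 1:50) {
    n <- sample(1:20, 1)
    p <- round(runif(n), 3)
    q <- sample(c(0.05, 0.25, 0.6), 1)
    a <- structure(data.frame(feature_id = paste0("f", 1:n),
                              r = runif(n, -1, 1), p = p,
                              n_used = 10L, excluded = FALSE),
                   namespace = "gene",
                   class = c("association_table", "data.frame"))
    got <- a$feature_id %in% select_significant(a, q)$selected
    expect_equal(got, bh_select_brute(p, q))
  }
})

test_that("selection is invariant to feature order and monotone in the FDR threshold", {
  set.seed(7)
  n <- 30
  a <- structure(data.frame(feature_id = paste0("f", 1:n),
                            r = runif(n, -1, 1), p = runif(n)^2,
                            n_used = 20L, excluded = FALSE),
                 namespace = "gene", class = c("association_table", "data.frame"))
  perm <- sample(n)
  ap <- structure(a[perm, ], namespace = "gene",
                  class = c("association_table", "data.frame"))
  expect_setequal(select_significant(a, 0.4)$selected,
                  select_significant(ap, 0.4)$selected)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(q)
    length(select_significant(a, q)$selected), 0)
  expect_true(all(diff(sizes) >= 0))

  all_one <- a; all_one$p <- 1
  expect_length(select_significant(all_one, 0.6)$selected, 0)
})

test_that("on null data the selected fraction stays near or below the FDR level", {
  set.seed(11)
  fracs <- replicate(30, {
    m <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(paste0("f", 1:50), paste0("s", 1:20)))
    y <- stats::setNames(rnorm(20), colnames(m))
    a <- correlate(omics_matrix(m, "gene"), y)
    length(select_significant(a, 0.6)$selected) / 50
  })
  # mean selected fraction under the null must not exceed q (binomial slack)
  expect_lt(mean(fracs), 0.6 + 3 * sd(fracs) / sqrt(length(fracs)))
})
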