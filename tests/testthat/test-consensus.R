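test_that("exact-n counting and the majority consensus reproduce the published platinum row", {
  fab <- sets_with_exact_n(c(251, 182, 24, 6))
  ct <- build_consensus(fab$sets, fab$universe)
  expect_equal(unname(ct$exact_n), c(251L, 182L, 24L, 6L))
  expect_equal(ct$threshold, 3L)        # majority of 4 drugs
  expect_length(ct$consensus, 30L)      # 24 + 6 pathways in >= 3 drugs
})

test_that("consensus degenerates correctly for identical and disjoint sets", {
  u <- paste0("p", 1:6)
  ident <- list(d1 = u[1:4], d2 = u[1:4], d3 = u[1:4])
  ct <- build_consensus(ident, u)
  expect_equal(unname(ct$exact_n), c(0L, 0L, 4L))
  disj <- list(d1 = u[1:2], d2 = u[3:4], d3 = u[5:6])
  ct2 <- build_consensus(disj, u)
  expect_equal(unname(ct2$exact_n), c(6L, 0L, 0L))
  expect_error(build_consensus(list(d1 = "p1", d1 = "p2"), u), "duplicate")
  expect_error(build_consensus(list(d1 = "zz"), u), "outside the universe")
})

test_that("consensus set shrinks as the threshold rises", {
  set.seed(3)
  u <- paste0("p", 1:40)
  sets <- lapply(1:4, function(i) sample(u, 15))
  names(sets) <- paste0("d", 1:4)
  sizes <- vapply(1:4, function(t)
    length(build_consensus(sets, u, t)$consensus), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("venn cells match brute-force signatures and the exact-n histogram", {
  two <- list(A = c("x", "y"), B = c("u", "v", "w"))
  expect_equal(venn_partition(two), c(A = 2L, B = 3L, "A&B" = 0L))

  set.seed(9)
  for (D in 2:5) {
    u <- paste0("e", 1:25)
    sets <- stats::setNames(lapply(1:D, function(i) sample(u, sample(3:12, 1))),
                            LETTERS[1:D])
    cells <- venn_partition(sets)
    expect_equal(sum(cells), length(unique(unlist(sets))))
    brute <- venn_brute(sets)
    expect_equal(cells[names(brute)], unclass(brute)[names(brute)],
                 ignore_attr = TRUE)
    # signature-size histogram equals exact-n counts
    ct <- build_consensus(sets, u, threshold = D)
    sig_sizes <- lengths(strsplit(names(cells), "&", fixed = TRUE))
    hist_n <- vapply(1:D, function(n) sum(cells[sig_sizes == n]), 0L)
    expect_equal(unname(ct$exact_n), hist_n, ignore_attr = TRUE)
  }
})

test_that("overlap fractions reproduce the published transcript and metabolite figures", {
  # iproplatin vs tetraplatin transcript sets: 143 shared of 330
  a <- paste0("p", 1:233)
  b <- paste0("p", c(1:143, 234:330))
  expect_equal(length(intersect(a, b)), 143L)
  expect_equal(length(union(a, b)), 330L)
  expect_equal(pairwise_overlap_fraction(a, b), 43)
  # carboplatin vs cisplatin: 32 shared of 103
  a2 <- paste0("p", 1:60); b2 <- paste0("p", c(1:32, 61:103))
  expect_equal(length(union(a2, b2)), 103L)
  expect_equal(pairwise_overlap_fraction(a2, b2), 31)
  # metabolite analysis: 7 shared of 30
  a3 <- paste0("p", 1:20); b3 <- paste0("p", c(1:7, 21:30))
  expect_equal(length(union(a3, b3)), 30L)
  expect_equal(pairwise_overlap_fraction(a3, b3), 23)

  expect_equal(pairwise_overlap_fraction(a, a), 100)
  expect_warning(z <- pairwise_overlap_fraction(character(0), character(0)),
                 "both sets empty")
  expect_equal(z, 0)
  # symmetric and bounded
  expect_equal(pairwise_overlap_fraction(a, b), pairwise_overlap_fraction(b, a))
})

test_that("joint-analysis consensus gain reproduces the published +76%", {
  single <- paste0("p", 1:17)
  joint <- paste0("p", 1:30)
  g <- consensus_gain(single, joint)
  expect_equal(g$base, 17L)
  expect_equal(g$added, 13L)
  expect_equal(g$gain_pct, 76)
  expect_equal(consensus_gain(single, single[1:5])$gain_pct, 0)
  expect_true(is.na(consensus_gain(character(0), joint)$gain_pct))
})

test_that("direction consistency flags uniform and mixed sign patterns", {
  r <- rbind(m1 = c(0.4, 0.5, 0.1), m2 = c(0.4, -0.5, 0.3))
  sig <- rbind(m1 = c(TRUE, TRUE, FALSE), m2 = c(TRUE, TRUE, TRUE))
  colnames(r) <- colnames(sig) <- paste0("d", 1:3)
  dp <- direction_consistency(r, sig)
  expect_true(dp$consistent[["m1"]])
  expect_false(dp$consistent[["m2"]])
  # never-significant metabolite: verdict undefined, not inconsistent
  r2 <- rbind(m3 = c(0.2, -0.2)); sig2 <- rbind(m3 = c(FALSE, FALSE))
  expect_true(is.na(direction_consistency(r2, sig2)$consistent[["m3"]]))
})

test_that("the published metabolite panel is direction-consistent and validates the test compound", {
  panel <- platinum_metabolite_panel()
  train <- direction_consistency(panel$r[, panel$training_drugs],
                                 panel$significant[, panel$training_drugs])
  # every metabolite with >= 1 significant training association is consistent
  expect_true(all(train$consistent[!is.na(train$consistent)]))
  # taurine: significant for tetraplatin only, positive
  expect_equal(train$direction["Taurine", "tetraplatin"], 1)
  expect_equal(train$r["Taurine", "tetraplatin"], 0.45)

  v <- validate_test_compound(panel$significant[, panel$test_drug],
                              panel$r[, panel$test_drug], train)
  expect_equal(v$panel_size, 22L)
  expect_equal(v$n_significant, 19L)
  expect_equal(v$n_direction_agree, 19L)   # complete direction consistency

  # a test compound identical to a training drug agrees wherever significant
  v2 <- validate_test_compound(panel$significant[, "tetraplatin"],
                               panel$r[, "tetraplatin"], train)
  expect_equal(v2$n_direction_agree, v2$n_significant)
})
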