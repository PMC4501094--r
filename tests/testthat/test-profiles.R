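test_that("spike factors anchor at the geometric mean of stage sums", {
  equal <- setNames(rep(200, 6), STAGES)
  expect_equal(unname(normalization_factors(equal)), rep(1, 6))
  # two-stage toy: sums 100 and 400 give K = 200 and factors 2 and 0.5
  toy <- c(a = 100, b = 400)
  expect_equal(unname(normalization_factors(toy)), c(2, 0.5))
  m <- matrix(c(60, 40, 150, 250), nrow = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(normalization_factors(m)), c(2, 0.5))
  bad <- c(a = 100, b = 0)
  expect_error(normalization_factors(bad), "zero spike")
  expect_equal(unname(normalization_factors(toy, anchor = "first")),
               c(1, 0.25))
})

test_that("normalization preserves within-stage ratios to machine precision", {
  set.seed(42)
  sums <- setNames(sample(50:500, 6), STAGES)
  f <- normalization_factors(sums)
  raw <- matrix(sample(1:1000, 60, replace = TRUE), ncol = 6,
                dimnames = list(NULL, STAGES))
  norm <- sweep(raw, 2, f, `*`)
  for (s in STAGES) {
    expect_equal(norm[, s] / norm[1, s], raw[, s] / raw[1, s],
                 tolerance = 1e-12)
  }
})

test_that("positional coverage stacks spans and conserves mass", {
  f <- setNames(rep(1, 6), STAGES)
  trfs <- make_unique_reads(list(A = c(5L, 0L, 0L, 0L, 0L, 0L),
                                 B = c(2L, 0L, 0L, 0L, 0L, 0L)))
  trfs$span_start <- c(1L, 30L)
  trfs$span_end <- c(33L, 75L)
  cov <- positional_coverage(trfs, 75L, f)
  expect_equal(unname(cov[1, "egg"]), 5)
  expect_equal(unname(cov[31, "egg"]), 7)
  expect_equal(unname(cov[50, "egg"]), 2)
  expect_equal(unname(cov[34, "L1"]), 0)
  # conservation: column sums equal sum(count * span length)
  expect_equal(sum(cov[, "egg"]), 5 * 33 + 2 * 46)
  set.seed(6)
  f2 <- normalization_factors(setNames(sample(50:300, 6), STAGES))
  cov2 <- positional_coverage(trfs, 75L, f2)
  spanlen <- trfs$span_end - trfs$span_start + 1L
  for (s in STAGES) {
    expect_equal(sum(cov2[, s]), sum(trfs[[s]] * f2[[s]] * spanlen))
  }
})

test_that("heatmap rows are rescaled to their maximum", {
  f <- setNames(rep(1, 6), STAGES)
  v <- make_unique_reads(list(A = c(2L, 4L, 8L, 0L, 0L, 0L),
                              B = c(3L, 3L, 3L, 3L, 3L, 3L),
                              C = c(0L, 0L, 0L, 0L, 0L, 0L)))
  hm <- heatmap_matrix(v, f)
  expect_equal(unname(hm[1, ]), c(0.25, 0.5, 1, 0, 0, 0))
  expect_equal(unname(hm[2, ]), rep(1, 6))
  expect_equal(unname(hm[3, ]), rep(0, 6))
  expect_equal(attr(hm, "zero_rows"), 3L)
})

test_that("row clustering is deterministic and groups identical profiles", {
  m <- rbind(a = c(1, 0, 0, 0, 0, 0), b = c(0, 0, 0, 0, 0, 1),
             c = c(1, 0, 0, 0, 0, 0), d = c(5, 4, 3, 2, 1, 1))
  cl <- cluster_rows(m)
  # identical rows sit at distance zero and merge first
  d0 <- as.matrix(1 - trfscape:::uncentered_correlation(m))
  expect_equal(d0["a", "c"], 0)
  merged_first <- cl$hclust$merge[1, ]
  expect_setequal(abs(merged_first), c(1, 3))
  expect_match(cl$newick, "a")
  # permuting rows leaves the tree topology unchanged
  perm <- m[c(4, 2, 1, 3), ]
  cl2 <- cluster_rows(perm)
  expect_equal(sort(ape::read.tree(text = cl2$newick)$tip.label),
               sort(ape::read.tree(text = cl$newick)$tip.label))
  cd <- stats::cophenetic(cl$hclust)
  cd2 <- stats::cophenetic(cl2$hclust)
  nms <- rownames(m)
  expect_equal(as.matrix(cd2)[nms, nms], as.matrix(cd)[nms, nms])
  single <- cluster_rows(m[1, , drop = FALSE])
  expect_equal(single$order, 1L)
  expect_null(single$hclust)
})

test_that("expression trends follow the three qualitative patterns", {
  expect_equal(expression_trend(c(1, 2, 4, 8, 16, 32)), "increasing")
  expect_equal(expression_trend(c(32, 16, 8, 4, 2, 1)), "decreasing")
  expect_equal(expression_trend(c(100, 5, 5, 5, 5, 5)), "egg-enriched")
  expect_equal(expression_trend(c(0, 0, 0, 0, 0, 0)), "other")
  expect_equal(expression_trend(c(5, 9, 2, 8, 1, 7)), "other")
})

test_that("planted trends are recovered for nearly all abundant variants", {
  set.seed(19)
  weights <- list(increasing = 2^(0:5) / 63, decreasing = 2^(5:0) / 63,
                  `egg-enriched` = c(0.70, rep(0.06, 5)))
  n <- 300L
  planted <- sample(names(weights), n, replace = TRUE)
  hit <- vapply(planted, function(p) {
    total <- sample(50:500, 1L)
    x <- as.integer(rmultinom(1L, total, weights[[p]]))
    expression_trend(x) == p
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
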