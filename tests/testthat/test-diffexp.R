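test_that("group-mean log2FC arithmetic, antisymmetry, zero handling", {
  expect_equal(round(log2fc_from_means(5.76, 163.17), 2), 4.82)
  expect_equal(log2fc_from_means(10, 10), 0)
  m <- matrix(c(10L, 20L, 40L, 80L,
                5L, 5L, 0L, 0L), 2, 4, byrow = TRUE,
              dimnames = list(c("f1", "f2"),
                              c("a1", "a2", "b1", "b2")))
  x <- mir_counts(m)
  g <- setNames(c("A", "A", "B", "B"), colnames(m))
  fwd <- group_log2fc(x, g)
  rev <- group_log2fc(x, setNames(c("B", "B", "A", "A"), colnames(m)))
  expect_equal(fwd$log2fc[fwd$finite], -rev$log2fc[rev$finite])
  # zero group mean with pseudocount 0 -> flagged non-finite
  expect_false(fwd$finite[fwd$feature_id == "f2"])
  expect_true(is.infinite(fwd$log2fc[fwd$feature_id == "f2"]))
})

test_that("dispersion recovery: Poisson floor, NB band, prior collapse", {
  set.seed(11)
  g <- setNames(rep(c("A", "B"), each = 10), paste0("s", 1:20))
  mp <- matrix(rpois(200 * 20, 50), 200, 20,
               dimnames = list(paste0("f", 1:200), names(g)))
  dp <- estimate_dispersion(mir_counts(mp), g)
  expect_lte(dp$common_phi, 0.05)
  mn <- matrix(rnbinom(200 * 20, mu = 50, size = 1 / 0.4), 200, 20,
               dimnames = dimnames(mp))
  dn <- estimate_dispersion(mir_counts(mn), g)
  expect_gte(dn$common_phi, 0.25)
  expect_lte(dn$common_phi, 0.60)
  dinf <- estimate_dispersion(mir_counts(mn), g, prior_df = 1e9)
  expect_lt(max(abs(dinf$tagwise_phi - dinf$common_phi)), 1e-6)
})

test_that("exact test: balanced splits give p = 1; invariances hold", {
  m <- matrix(c(10L, 25L, 10L, 25L,
                3L, 8L, 3L, 8L), 2, 4, byrow = TRUE,
              dimnames = list(c("f1", "f2"),
                              c("a1", "a2", "b1", "b2")))
  x <- mir_counts(m)
  g <- setNames(c("A", "A", "B", "B"), colnames(m))
  p <- exact_test(x, g, 0.1)
  expect_equal(unname(p), c(1, 1))
  # label swap and feature reorder leave p unchanged
  set.seed(5)
  m2 <- matrix(rnbinom(40, mu = 30, size = 5), 10, 4,
               dimnames = list(paste0("f", 1:10), colnames(m)))
  x2 <- mir_counts(m2)
  p1 <- exact_test(x2, g, 0.2)
  p2 <- exact_test(x2, setNames(c("B", "B", "A", "A"), colnames(m)), 0.2)
  expect_equal(p1, p2)
  x3 <- mir_counts(m2[10:1, ])
  p3 <- exact_test(x3, g, 0.2)
  expect_equal(p3[names(p1)], p1)
  # zero total -> p = 1
  x0 <- mir_counts(rbind(m2, zero = rep(0L, 4)))
  expect_equal(unname(exact_test(x0, g, 0.2)["zero"]), 1)
})

test_that("exact test matches edgeR's small-p summation convention", {
  skip_if_not_installed("edgeR")
  set.seed(19)
  m <- matrix(rnbinom(60 * 8, mu = 40, size = 1 / 0.15), 60, 8,
              dimnames = list(paste0("f", 1:60), paste0("s", 1:8)))
  g <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  # equal library sizes so no equalization in either implementation
  x <- mir_counts(m)
  x$library_sizes <- setNames(rep(1e5, 8), colnames(m))
  ours <- exact_test(x, g, 0.15)
  theirs <- edgeR::exactTestBySmallP(
    m[, 1:4], m[, 5:8], dispersion = 0.15)
  expect_equal(unname(ours), as.numeric(theirs), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.005, 0.4, 0.02, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("strong selection applies the CPM floor and strict |log2FC| bound", {
  res <- data.frame(
    feature_id = c("lowcpm", "boundary", "up", "down"),
    mean_cpm_A = c(9.9, 100, 10, 800),
    mean_cpm_B = c(9.9, 400, 90, 100),
    mean_cpm_all = c(9.9, 250, 50, 450),
    log2fc = c(0, 2, log2(9), -3), finite = TRUE,
    fdr_bh = c(1, 1, 0.05, 0.2))
  st <- select_strong(res)
  expect_setequal(st$feature_id, c("up", "down"))  # 9.9 CPM and lfc==2 out
  expect_identical(st$direction, c("up", "down"))  # sorted by lfc desc
  expect_identical(st$significant, c(TRUE, FALSE))
  expect_identical(attr(st, "n_up"), 1L)
  expect_identical(attr(st, "n_down"), 1L)
})

test_that("concordance classification applies the category rules in order", {
  disc <- data.frame(feature_id = c("a", "b", "c", "d"),
                     log2fc = c(3.0, 3.0, -2.6, 2.2))
  val <- data.frame(feature_id = c("a", "b", "d"),
                    log2fc = c(1.0, 0.2, -1.4))
  cc <- classify_concordance(disc, val, expressed_in_validation =
                               c("a", "b", "d"))
  expect_identical(setNames(cc$category, cc$feature_id),
                   c(a = "confirmed", b = "no_difference",
                     c = "not_expressed", d = "opposite"))
  counts <- attr(cc, "category_counts")
  expect_identical(as.integer(counts[c("not_expressed", "no_difference",
                                       "confirmed", "opposite")]),
                   c(1L, 1L, 1L, 1L))
  expect_error(classify_concordance(rbind(disc, disc[1, ]), val, "a"),
               "duplicate")
})
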