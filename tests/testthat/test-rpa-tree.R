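planted_cohort <- function(seed = 42) {
  cfg <- cohort_config(seed = seed)
  generate_cohort(cfg)
}

test_that("perfectly separable data yields the single midpoint split", {
  tree <- grow_tree(data.frame(x = 1:6),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), min_split = 2)
  expect_equal(tree$root$split$feature, "x")
  expect_equal(tree$root$split$threshold, 3.5)
  leaves <- sabresponse:::tree_leaves(tree)
  expect_equal(sort(vapply(leaves, `[[`, numeric(1), "event_rate")), c(0, 1))
})

test_that("constant labels produce a root-only tree", {
  tree <- grow_tree(data.frame(x = rnorm(8)), rep(TRUE, 8))
  expect_null(tree$root$split)
  expect_equal(tree$root$event_rate, 1)
})

test_that("grown trees equal the exhaustive brute-force oracle (n <= 12)", {
  set.seed(52)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    k <- sample(1:3, 1)
    X <- as.data.frame(matrix(round(stats::rnorm(n * k), 2), n, k))
    names(X) <- paste0("f", seq_len(k))
    y <- stats::runif(n) < 0.5
    if (!any(y) || all(y)) y[1] <- !y[1]
    for (ms in c(2L, 5L)) {
      tree <- grow_tree(X, y, min_split = ms)
      expect_equal(tree_to_oracle_shape(tree), tree_oracle(X, y, ms),
                   tolerance = 1e-12)
    }
  }
})

test_that("no node smaller than min_split is ever split", {
  set.seed(53)
  check_min <- function(node, ms) {
    if (!is.null(node$split)) {
      expect_gte(node$n, ms)
      check_min(node$left, ms)
      check_min(node$right, ms)
    }
  }
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    X <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
    y <- X$a + stats::rnorm(n) > 0
    if (!any(y) || all(y)) y[1] <- !y[1]
    check_min(grow_tree(X, y, min_split = 5L)$root, 5L)
  }
})

test_that("pruning matches the exhaustive cost-complexity oracle", {
  set.seed(54)
  X <- data.frame(a = round(stats::rnorm(10), 2),
                  b = round(stats::rnorm(10), 2))
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  tree <- grow_tree(X, y, min_split = 2L)
  n_gini <- function(node) node$n * 2 * node$event_rate * (1 - node$event_rate)
  shape <- tree_to_oracle_shape(tree)
  risk <- function(node) {
    if (is.null(node$split)) return(node$n * node$gini)
    risk(node$left) + risk(node$right)
  }
  n_leaves <- function(node) {
    if (is.null(node$split)) return(1L)
    n_leaves(node$left) + n_leaves(node$right)
  }
  for (penalty in c(0.1, 0.3, 0.5, 1, 2, 5)) {
    pruned <- prune_tree(tree, penalty)$root
    achieved <- risk(pruned) + penalty * n_leaves(pruned)
    expect_equal(achieved, prune_oracle_cost(shape, penalty, n_gini),
                 tolerance = 1e-12)
  }
})

test_that("pruning identities: zero penalty is identity, huge penalty collapses", {
  X <- data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8))
  y <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  tree <- grow_tree(X, y, min_split = 2L)
  expect_equal(prune_tree(tree, 0), tree)
  total <- tree$root$n * tree$root$gini
  collapsed <- prune_tree(tree, total)
  expect_null(collapsed$root$split)
})

test_that("a planted 26-patient cohort reproduces the published two-split tree", {
  cohort <- planted_feature_cohort()
  tree <- prune_tree(grow_tree(cohort[, c("bv_pre", "dsuv_max")],
                               cohort$pcr, min_split = 5L), penalty = 1.0)
  # root splits on baseline blood volume inside the planted gap around 9.3
  expect_equal(tree$root$split$feature, "bv_pre")
  expect_gt(tree$root$split$threshold, 8.4)
  expect_lt(tree$root$split$threshold, 10.3)
  # the low-BV branch splits on SUV change inside the gap around -48.9
  low_bv <- tree$root$left
  expect_equal(low_bv$split$feature, "dsuv_max")
  expect_gt(low_bv$split$threshold, -54)
  expect_lt(low_bv$split$threshold, -44)
  # three leaves with the published sizes and event rates
  leaves <- sabresponse:::tree_leaves(tree)
  expect_equal(length(leaves), 3L)
  stats <- vapply(leaves, function(l) c(l$n, l$event_rate), numeric(2))
  expect_setequal(stats[1, ], c(6, 8, 12))
  expect_equal(sort(stats[2, ]), c(0, 2 / 8, 11 / 12))
  # every patient lands in the leaf of its own response group
  leaf_id <- predict(tree, cohort, type = "leaf")
  expect_equal(length(unique(paste(leaf_id, cohort$group))), 3L)
})

test_that("a randomly drawn planted cohort recovers the SUV-change threshold", {
  cohort <- planted_cohort()
  tree <- grow_tree(cohort[, c("bv_pre", "dsuv_max")], cohort$pcr,
                    min_split = 5L)
  # with Bernoulli labels the strongest signal is the response threshold;
  # the recovered cut lies inside the generator's gap around -48.9
  expect_equal(tree$root$split$feature, "dsuv_max")
  expect_gt(tree$root$split$threshold, -48.9 - 4.89)
  expect_lt(tree$root$split$threshold, -48.9 + 4.89)
})

test_that("greedy gains on the reconstructed cohort favour the SUV-change split", {
  # count-weighted Gini gains computed from the reconstructed margins
  # (6/8/12 patients, 0/2/11 events): the SUV-change split dominates the
  # blood-volume split, so greedy growth reproduces the published partition
  # in the opposite split order
  wg <- function(n, k) n * 2 * (k / n) * (1 - k / n)
  root <- wg(26, 13)
  gain_dsuv <- root - (wg(12, 11) + wg(14, 2))
  gain_bv <- root - (wg(20, 13) + wg(6, 0))
  expect_equal(round(gain_dsuv, 2), 7.74)
  expect_equal(round(gain_bv, 2), 3.90)
  expect_gt(gain_dsuv, gain_bv)
})

test_that("the fixed two-threshold model partitions the plane", {
  expect_equal(response_group(9.3, -60), 1L)
  expect_equal(response_group(5.0, -30), 2L)
  expect_equal(response_group(5.0, -60), 3L)
  set.seed(55)
  bv <- stats::runif(500, 0, 20)
  ds <- stats::runif(500, -100, 50)
  g <- response_group(bv, ds)
  expect_true(all(g %in% 1:3))
  expect_equal(g == 3L, bv < 9.3 & ds < -48.9)
  expect_equal(g == 1L, bv >= 9.3)
})

test_that("root split agrees with rpart's Gini split on planted cohorts", {
  # rpart applies its own cost-scaled stopping below the root, so the
  # cross-check pins down the root split: same feature, and a threshold
  # separating the same two sets of observations
  for (cohort in list(planted_feature_cohort(), planted_cohort(seed = 7))) {
    tree <- grow_tree(cohort[, c("bv_pre", "dsuv_max")], cohort$pcr,
                      min_split = 5L)
    rp <- rpart::rpart(pcr ~ bv_pre + dsuv_max, data = cohort,
                       method = "class",
                       control = rpart::rpart.control(minsplit = 5,
                                                      minbucket = 1,
                                                      cp = 0, xval = 0))
    rp_feature <- as.character(rp$frame$var[1])
    rp_threshold <- rp$splits[1, "index"]
    expect_equal(tree$root$split$feature, rp_feature)
    ours_left <- cohort[[rp_feature]] < tree$root$split$threshold
    rpart_left <- cohort[[rp_feature]] < rp_threshold
    expect_equal(ours_left, rpart_left)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(grow_tree(data.frame(x = numeric(0)), logical(0)),
               "at least 2")
  expect_error(grow_tree(data.frame(x = c(1, NA, 3)), c(TRUE, FALSE, TRUE)),
               "missing")
})
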