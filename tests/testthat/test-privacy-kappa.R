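test_that("filter similarity counts exact duplicates", {
  co <- toy_table(n = 10, seed = 6)
  sch <- toy_schema()
  # verbatim copy: every record matches
  expect_equal(filter_similarity(co, co, sch)$score, 0)
  # 2 of 10 artificial rows duplicate real rows
  art <- toy_table(n = 10, seed = 7)
  art[3, ] <- co[1, ]
  art[8, ] <- co[5, ]
  fs <- filter_similarity(co, art, sch)
  expect_equal(fs$score, 80)
  expect_identical(fs$matches$artificial_row, c(3L, 8L))
  # fully disjoint artificial rows
  art2 <- dplyr::mutate(co, age = pmin(age + 1, 95), score = score + 0.5)
  expect_equal(filter_similarity(co, art2, sch)$score, 100)
  expect_error(filter_similarity(co, co[0, ], sch), "non-empty")
})

test_that("filter similarity is invariant to row permutations", {
  co <- toy_table(n = 25, seed = 8)
  art <- dplyr::bind_rows(toy_table(n = 20, seed = 9), co[1:5, ])
  sch <- toy_schema()
  s1 <- filter_similarity(co, art, sch)$score
  set.seed(10)
  s2 <- filter_similarity(co[sample(25), ], art[sample(25), ], sch)$score
  expect_equal(s1, s2)
})

test_that("anonymization compares artificial NN distances to real leave-one-out", {
  co <- toy_table(n = 30, seed = 11)
  sch <- toy_schema()
  # a verbatim copy sits at distance zero: ratio 0, not anonymized
  an <- anonymization_degree(co, co, sch)
  expect_lt(max(an$nn_art_to_real), 1e-6)
  expect_lt(an$ratio, 1e-6)
  expect_false(an$anonymized)
  # shifting every numeric far outside the support forces ratio > 1
  far <- dplyr::mutate(co, age = 95, score = 100)
  an2 <- anonymization_degree(co, far, sch)
  expect_gt(an2$ratio, 1)
  expect_true(an2$anonymized)
  expect_error(anonymization_degree(co[1, ], co, sch), "at least 2")
})

test_that("the anonymization ratio is scale-consistent", {
  # multiplying all encoded coordinates by c > 0 rescales both distance
  # samples equally, leaving the ratio unchanged
  co <- toy_table(n = 20, seed = 12)
  art <- toy_table(n = 25, seed = 13)
  sch <- toy_schema()
  enc <- fit_transform(co, sch)
  an <- anonymization_degree(co, art, sch, encoded = enc)
  scaled <- enc
  scaled$values <- enc$values * 3
  R <- apply_transform(enc, co) * 3
  A <- apply_transform(enc, art) * 3
  D <- synthcohort:::cross_dist(A, R)
  Drr <- synthcohort:::cross_dist(R, R); diag(Drr) <- Inf
  ratio_scaled <- stats::median(apply(D, 1, min)) /
    stats::median(apply(Drr, 1, min))
  expect_equal(ratio_scaled, an$ratio, tolerance = 1e-12)
})

test_that("kappa reproduces hand-computed contingency tables", {
  truth <- rep(c("real", "artificial"), each = 50)
  expect_equal(cohen_kappa(truth, truth)$kappa, 1)
  # balanced 25/25/25/25 table: po = 0.5, pe = 0.5 -> kappa = 0
  rater <- c(rep("real", 25), rep("artificial", 25),
             rep("real", 25), rep("artificial", 25))
  k0 <- cohen_kappa(rater, truth)
  expect_equal(k0$kappa, 0)
  expect_identical(k0$interpretation, "indistinguishable")
  # the 0.2 threshold separates indistinguishable from partial agreement
  expect_identical(cohen_kappa(c(rep("real", 29), rep("artificial", 21),
                                 rep("real", 21), rep("artificial", 29)),
                               truth)$interpretation, "indistinguishable")
  expect_error(cohen_kappa(truth[1:5], truth[1:5]), "at least 10")
  expect_error(cohen_kappa(rep("real", 20), rep("real", 20)), "degenerate")
})

test_that("kappa CI is calibrated under random guessing", {
  # both rater and truth independent fair coins, n = 100, 10,000 tasks:
  # mean |kappa| < 0.02 and ~95% of intervals cover 0
  set.seed(123)
  n <- 100
  kap <- numeric(10000)
  cover <- logical(10000)
  for (i in seq_len(10000)) {
    rater <- sample(c("a", "b"), n, replace = TRUE)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    res <- cohen_kappa(rater, truth)
    kap[i] <- res$kappa
    cover[i] <- res$ci_low <= 0 && 0 <= res$ci_high
  }
  expect_lt(abs(mean(kap)), 0.02)
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("categorization sheets are balanced, blinded and keyed", {
  co <- toy_table(n = 60, seed = 14)
  art <- toy_table(n = 80, seed = 15)
  cs <- categorization_sheet(co, art, n_items = 100, seed = 2)
  expect_identical(nrow(cs$sheet), 100L)
  counts <- table(cs$key$truth)
  expect_identical(as.integer(counts[c("real", "artificial")]), c(50L, 50L))
  expect_false(".truth" %in% names(cs$sheet))
  # sheet and key share each item id exactly once
  expect_identical(sort(cs$sheet$item_id), sort(cs$key$item_id))
  expect_false(anyDuplicated(cs$sheet$item_id) > 0)
  # same seed reproduces the sheet; odd item counts are rejected
  cs2 <- categorization_sheet(co, art, n_items = 100, seed = 2)
  expect_identical(cs, cs2)
  expect_error(categorization_sheet(co, art, n_items = 99), "even")
  expect_error(categorization_sheet(co[1:10, ], art, n_items = 100), "at least")
})
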