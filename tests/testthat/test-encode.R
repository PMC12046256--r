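test_that("min-max scaling hits the endpoints and one-hot blocks are exact", {
  sch <- cohort_schema(col_numeric("x", 0, 100),
                       col_categorical("g", c("A", "B", "C")))
  tab <- validate_cohort(data.frame(x = c(0, 50, 100), g = c("A", "B", "A")), sch)
  enc <- fit_transform(tab, sch)
  expect_equal(enc$values[, "x"], c(0, 0.5, 1))
  expect_equal(unname(enc$values[, c("g.A", "g.B", "g.C")]),
               rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)))
  expect_equal(rowSums(enc$values[, c("g.A", "g.B", "g.C")]), rep(1, 3))
  expect_identical(enc$column_map$role,
                   c("scaled-numeric", "one-hot", "one-hot", "one-hot"))
})

test_that("fixture schema encodes 521 patients to a 521 x 103 design matrix", {
  enc <- fixture_encoded()
  expect_identical(dim(enc$values), c(521L, 103L))
  expect_true(all(enc$values >= 0 & enc$values <= 1))
  sch <- fixture_schema()
  expect_identical(sum(sch$kind == "numerical"), 19L)
  expect_identical(sum(sch$kind == "binary"), 60L)
  expect_identical(sum(sch$kind == "categorical"), 6L)
})

test_that("encode/decode round-trips any valid table", {
  # categorical/binary exactly; numerics to within one rounding unit
  for (seed in c(1, 2, 3)) {
    tab <- toy_table(n = 30, seed = seed)
    enc <- fit_transform(tab, toy_schema())
    back <- inverse_transform(enc)
    expect_identical(as.character(back$flag), as.character(tab$flag))
    expect_identical(as.character(back$grade), as.character(tab$grade))
    expect_equal(back$age, tab$age)
    expect_equal(back$score, tab$score, tolerance = 1e-10)
  }
})

test_that("decoding clips, thresholds and argmaxes as contracted", {
  sch <- cohort_schema(col_numeric("x", 0, 100), col_binary("b"),
                       col_categorical("g", c("A", "B", "C")))
  tab <- validate_cohort(
    data.frame(x = c(0, 100), b = c("0", "1"), g = c("A", "B")), sch)
  enc <- fit_transform(tab, sch)
  out <- inverse_transform(enc, matrix(c(
    1.3, 0.7, 0.2, 0.7, 0.1,   # x over-range, b above threshold, argmax B
    -0.2, 0.3, 0.5, 0.2, 0.3   # x under-range, b below threshold, tie A vs C
  ), nrow = 2, byrow = TRUE))
  expect_equal(out$x, c(100, 0))
  expect_identical(as.character(out$b), c("1", "0"))
  expect_identical(as.character(out$g)[1], "B")
  # argmax ties break toward the lowest-index level
  tie <- inverse_transform(enc, matrix(c(0.5, 0, 0.4, 0.4, 0.2), 1))
  expect_identical(as.character(tie$g), "A")
})

test_that("degenerate numeric columns encode as flagged constants", {
  sch <- cohort_schema(col_numeric("x", 0, 10), col_binary("b"))
  tab <- validate_cohort(data.frame(x = c(5, 5), b = c("0", "1")), sch)
  expect_warning(enc <- fit_transform(tab, sch), "constant")
  expect_equal(enc$values[, "x"], c(0, 0))
  expect_true(enc$scaler_state$degenerate[enc$scaler_state$column == "x"])
  back <- inverse_transform(enc)
  expect_equal(back$x, c(5, 5))
})

test_that("dimension mismatches are rejected", {
  enc <- fit_transform(toy_table(), toy_schema())
  expect_error(inverse_transform(enc, matrix(0, 2, 4)), "4 columns")
  expect_error(fit_transform(toy_table()[0, ], toy_schema()), "empty")
})

test_that("apply_transform reuses the stored scaler state", {
  sch <- cohort_schema(col_numeric("x", 0, 100), col_binary("b"))
  tab <- validate_cohort(data.frame(x = c(10, 20), b = c("0", "1")), sch)
  enc <- fit_transform(tab, sch)
  new <- validate_cohort(data.frame(x = 30, b = "0"), sch)
  # 30 under the (10, 20) scaler maps to 2, outside [0, 1] by design
  expect_equal(apply_transform(enc, new)[1, "x"], c(x = 2))
})

test_that("encoded matrices persist as CSV plus JSON sidecar", {
  enc <- fit_transform(toy_table(), toy_schema())
  path <- withr::local_tempfile(fileext = ".csv")
  write_encoded(enc, path)
  back <- read_encoded(path)
  expect_equal(back$values, enc$values, tolerance = 1e-12)
  expect_equal(as.data.frame(back$scaler_state), as.data.frame(enc$scaler_state))
  expect_equal(as.data.frame(back$schema), as.data.frame(enc$schema))
  # the restored template decodes identically
  expect_equal(inverse_transform(back), inverse_transform(enc))
})
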