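test_that("schema constructors enforce the column contracts", {
  expect_error(col_binary("b", c("x", "y", "z")), "exactly 2")
  expect_error(col_categorical("c", c("x", "y")), ">= 3")
  expect_error(col_numeric("n", 5, 2), "min > max")
  expect_error(cohort_schema(col_numeric("a", 0, 1), col_binary("a")),
               "duplicate")
  sch <- toy_schema()
  expect_s3_class(sch, "cohort_schema")
  expect_identical(attr(sch, "n_raw_features"), 4L)
})

test_that("encoded width counts numerics and binaries once, categoricals per level", {
  expect_identical(encoded_width(toy_schema()), 6L)
  # property: random schemas obey the width formula
  set.seed(11)
  for (rep in 1:100) {
    n_num <- sample(0:4, 1)
    n_bin <- sample(0:4, 1)
    n_cat <- sample(0:3, 1)
    lev_sizes <- if (n_cat > 0) sample(3:6, n_cat, replace = TRUE) else integer(0)
    if (n_num + n_bin + n_cat == 0) n_num <- 1
    specs <- c(
      lapply(seq_len(n_num), function(i) col_numeric(paste0("n", i), 0, 1)),
      lapply(seq_len(n_bin), function(i) col_binary(paste0("b", i))),
      lapply(seq_len(n_cat), function(i) {
        col_categorical(paste0("c", i), paste0("l", seq_len(lev_sizes[i])))
      })
    )
    sch <- cohort_schema(dplyr::bind_rows(specs))
    expect_identical(encoded_width(sch),
                     as.integer(n_num + n_bin + sum(lev_sizes)))
  }
})

test_that("validate_cohort coerces, imputes and reports", {
  sch <- toy_schema()
  raw <- data.frame(age = c("50", NA, "61"), score = c(10, 20, NA),
                    flag = c("no", "yes", NA), grade = c("A", NA, "B"))
  out <- validate_cohort(raw, sch)
  expect_identical(nrow(out), 3L)
  expect_false(anyNA(out))
  log <- attr(out, "coercion_log")
  expect_identical(sum(log$n_imputed), 4L)
  # numeric imputation is the column median (55.5 here), then integer
  # rounding half away from zero applies because age is integer-valued
  expect_identical(out$age[2], 56)
  expect_identical(as.character(out$grade[2]), "A")
})

test_that("validate_cohort rejects contract violations with addresses", {
  sch <- toy_schema()
  base <- data.frame(age = 50, score = 10, flag = "no", grade = "A")
  expect_error(validate_cohort(cbind(base, extra = 1), sch), "extra")
  expect_error(validate_cohort(base[, -2], sch), "score")
  bad_lev <- base; bad_lev$grade <- "Z"
  expect_error(validate_cohort(bad_lev, sch), "'Z'.*grade.*row 1")
  bad_num <- base; bad_num$age <- "fifty"
  expect_error(validate_cohort(bad_num, sch), "age.*row 1")
  bad_rng <- base; bad_rng$age <- 120
  expect_error(validate_cohort(bad_rng, sch), "out of range")
  # non-strict mode treats both as missing and falls back to imputation
  two <- rbind(base, base); two$grade[2] <- "Z"
  lax <- validate_cohort(two, sch, strict = FALSE)
  expect_identical(as.character(lax$grade[2]), "A")
})

test_that("empty table with a valid header validates to zero rows", {
  sch <- toy_schema()
  empty <- data.frame(age = numeric(0), score = numeric(0),
                      flag = character(0), grade = character(0))
  out <- validate_cohort(empty, sch)
  expect_identical(nrow(out), 0L)
  expect_identical(names(out), sch$name)
})

test_that("schema JSON round-trips", {
  sch <- toy_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_equal(as.data.frame(back), as.data.frame(sch))
})
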