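test_that("imputation interpolates interior gaps and extends boundaries", {
  df <- data.frame(a = c(1, NA, 3), load_score = c(NA, 5, 9))
  tab <- monitoring_table(df, "load_score")
  out <- impute_missing(tab)
  expect_equal(out$a, c(1, 2, 3))
  expect_equal(out$load_score, c(5, 5, 9))   # boundary takes nearest observed
  expect_identical(as.data.frame(impute_missing(out)), as.data.frame(out))

  allna <- monitoring_table(data.frame(a = c(NA_real_, NA_real_, 1),
                                       load_score = c(1, 2, 3)))
  expect_error(impute_missing(allna), "unimputable column 'a'")
})

test_that("min-max normalisation maps to [0,1] and inverts exactly", {
  df <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1), load_score = c(10, 20, 30))
  tab <- monitoring_table(df)
  norm <- normalize_table(tab)
  expect_equal(norm$table$a, c(0, 0.5, 1))
  expect_equal(norm$table$b, c(0, 0, 0))     # constant column maps to 0
  expect_equal(denormalize(norm$table$a, norm$scaler, "a"), df$a,
               tolerance = 1e-12)
  expect_equal(denormalize(0.5, norm$scaler, "a"), 4)
  expect_equal(denormalize(c(0, 1), norm$scaler, "load_score"), c(10, 30))

  # train-fitted scaler extrapolates beyond the fitted range
  test_df <- monitoring_table(data.frame(a = 8, b = 1, load_score = 15))
  out <- normalize_table(test_df, norm$scaler)
  expect_gt(out$table$a, 1)

  wrong <- monitoring_table(data.frame(z = 1:3, load_score = 1:3))
  expect_error(normalize_table(wrong, norm$scaler), "schema error")
})

test_that("normalise/denormalise round-trips random tables", {
  withr::with_seed(21L, {
    df <- as.data.frame(matrix(rnorm(60, 50, 20), 12, 5))
    names(df) <- c(paste0("f", 1:4), "load_score")
  })
  tab <- monitoring_table(df)
  norm <- normalize_table(tab)
  for (col in names(df))
    expect_equal(denormalize(norm$table[[col]], norm$scaler, col), df[[col]],
                 tolerance = 1e-12)
})

test_that("log transform shifts, errors on bad domains, reduces skewness", {
  df <- data.frame(a = c(0, exp(1) - 1, 3), load_score = 1:3)
  tab <- monitoring_table(df)
  out <- log_transform(tab, "a", offset = 1)
  expect_equal(out$a[1:2], c(0, 1))
  expect_error(log_transform(tab, "a", offset = 0), "domain error")
  expect_error(log_transform(tab, "zz"), "schema error")

  ln <- withr::with_seed(31L, exp(rnorm(400)))
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  tab2 <- monitoring_table(data.frame(a = ln, load_score = seq_along(ln)))
  expect_lt(abs(skew(log_transform(tab2, "a", offset = 0.001)$a)),
            abs(skew(ln)))
})

test_that("PCA selection matches a direct covariance eigen-decomposition", {
  # collinear 2-D data: one component carries all the variance
  line <- monitoring_table(data.frame(x = 1:10, y = 2 * (1:10) + 3,
                                      load_score = 1:10), "load_score")
  res <- pca_select(line, 1L)
  expect_equal(res$explained[1L], 1, tolerance = 1e-12)

  withr::with_seed(41L, {
    df <- as.data.frame(matrix(rnorm(200), 40, 5))
    names(df) <- paste0("f", 1:5)
    df$load_score <- rnorm(40)
  })
  tab <- monitoring_table(df)
  res <- pca_select(tab, 5L)
  ev <- eigen(stats::cov(as.matrix(df[paste0("f", 1:5)])))$values
  expect_equal(res$explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-10)
  # full basis reconstructs the centred data exactly
  rec <- as.matrix(res$table[paste0("PC", 1:5)]) %*% t(res$loadings)
  cent <- scale(as.matrix(df[paste0("f", 1:5)]), center = TRUE, scale = FALSE)
  expect_equal(rec, unname(cent), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_select(tab, 6L), "range error")
})

test_that("train/test split partitions rows reproducibly", {
  panel <- generate_athlete_panel(generator_config(missing_rate = 0, seed = 1L))
  sp <- split_train_test(panel, 140L, seed = 3L)
  expect_equal(nrow(sp$train), 140L)
  expect_equal(nrow(sp$test), 14L)
  key <- function(t) sort(paste(t$load_score, t$heart_rate))
  expect_identical(sort(c(key(sp$train), key(sp$test))), key(panel))
  sp2 <- split_train_test(panel, 140L, seed = 3L)
  expect_identical(as.data.frame(sp$train), as.data.frame(sp2$train))
  expect_error(split_train_test(panel, 154L), "size error")
})
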