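test_that("channel operators reproduce the worked 3x3 example", {
  m <- matrix(c(.9, .6, .4, .8, .1, .3, .7, .5, .2), 3, 3)
  img <- us_image(m)
  d <- dark_channel(img, 3)
  b <- bright_channel(img, 3)
  expect_equal(d$values[2, 2], 0.1)
  expect_equal(b$values[2, 2], 0.9)
  expect_equal(d$values, oracle_extremum(m, 3, FALSE))
  expect_equal(b$values, oracle_extremum(m, 3, TRUE))
})

test_that("all four channel operators match the nested-loop oracle exactly", {
  set.seed(11)
  for (rep in 1:50) {
    nr <- sample(3:16, 1); nc <- sample(3:16, 1)
    img <- random_image(nr, nc)
    m <- unclass(img)
    for (patch in c(1L, 3L, 5L)) {
      expect_identical(dark_channel(img, patch)$values,
                       oracle_extremum(m, patch, FALSE))
      expect_identical(bright_channel(img, patch)$values,
                       oracle_extremum(m, patch, TRUE))
      # secondary channel == oracle applied twice
      expect_identical(secondary_sparse_dark(img, patch)$values,
                       oracle_extremum(oracle_extremum(m, patch, FALSE), patch, FALSE))
      expect_identical(secondary_sparse_bright(img, patch)$values,
                       oracle_extremum(oracle_extremum(m, patch, TRUE), patch, TRUE))
    }
  }
})

test_that("constant images are fixed points and patch 1 is the identity", {
  img <- us_image(matrix(0.4, 9, 9))
  expect_true(all(dark_channel(img, 5)$values == 0.4))
  expect_true(all(bright_channel(img, 5)$values == 0.4))
  expect_true(all(secondary_sparse_dark(img, 3)$values == 0.4))
  r <- random_image(7, 7)
  expect_identical(dark_channel(r, 1)$values, unclass(r))
})

test_that("bright/dark duality holds to machine precision", {
  set.seed(12)
  for (rep in 1:10) {
    img <- random_image(12, 12)
    comp <- us_image(1 - unclass(img))
    expect_identical(bright_channel(img, 5)$values,
                     1 - dark_channel(comp, 5)$values)
    expect_identical(secondary_sparse_bright(img, 3)$values,
                     1 - secondary_sparse_dark(comp, 3)$values)
  }
})

test_that("iterated filtering equals one pass at doubled radius", {
  set.seed(13)
  img <- random_image(5, 5)
  expect_identical(secondary_sparse_dark(img, 3)$values,
                   dark_channel(img, 5)$values)
  expect_identical(secondary_sparse_bright(img, 3)$values,
                   bright_channel(img, 5)$values)
  img2 <- random_image(14, 11)
  expect_identical(secondary_sparse_dark(img2, 5)$values,
                   dark_channel(img2, 9)$values)
})

test_that("dark channel is monotone in the image", {
  set.seed(14)
  for (rep in 1:10) {
    a <- matrix(runif(100), 10, 10)
    b <- pmin(a + matrix(runif(100, 0, 0.3), 10, 10), 1)
    expect_true(all(dark_channel(us_image(a), 3)$values <=
                    dark_channel(us_image(b), 3)$values))
  }
})

test_that("channel bounds and argument-map locality hold", {
  set.seed(15)
  img <- random_image(10, 13)
  for (patch in c(3L, 5L)) {
    d <- dark_channel(img, patch)
    b <- bright_channel(img, patch)
    expect_true(all(d$values <= unclass(img)))
    expect_true(all(b$values >= unclass(img)))
    r <- (patch - 1) / 2
    expect_true(all(abs(d$arg_row - row(d$values)) <= r))
    expect_true(all(abs(d$arg_col - col(d$values)) <= r))
    s <- secondary_sparse_dark(img, patch)
    expect_true(all(abs(s$arg_row - row(s$values)) <= 2 * r))
    expect_true(all(abs(s$arg_col - col(s$values)) <= 2 * r))
    # the recorded coordinate attains the extremum
    expect_equal(unclass(img)[cbind(as.vector(d$arg_row), as.vector(d$arg_col))],
                 as.vector(d$values))
  }
})

test_that("argmin ties resolve to the first patch position in row-major order", {
  img <- us_image(matrix(0.3, 6, 6))   # everything tied
  d <- dark_channel(img, 3)
  expect_equal(d$arg_row[3, 3], 2)     # top-left of the patch around (3,3)
  expect_equal(d$arg_col[3, 3], 2)
  expect_equal(d$arg_row[1, 1], 1)
  expect_equal(d$arg_col[1, 1], 1)
})

test_that("selection operator reproduces the channel and is a 0/1 row-stochastic map", {
  set.seed(16)
  img <- random_image(9, 11)
  for (maker in list(dark_channel, bright_channel, secondary_sparse_dark)) {
    ch <- maker(img, 3)
    S <- selection_operator(ch, dim(unclass(img)))
    expect_identical(as.vector(S %*% as.vector(unclass(img))),
                     as.vector(ch$values))
    expect_true(all(Matrix::rowSums(S) == 1))
    # transpose applied to ones counts how often each pixel is selected
    counts <- as.vector(Matrix::t(S) %*% rep(1, prod(dim(unclass(img)))))
    expect_equal(sum(counts), prod(dim(unclass(img))))
    tab <- table(factor(
      (as.vector(ch$arg_col) - 1) * nrow(unclass(img)) + as.vector(ch$arg_row),
      levels = seq_len(prod(dim(unclass(img))))))
    expect_equal(counts, as.vector(tab), ignore_attr = TRUE)
  }
  expect_error(selection_operator(dark_channel(img, 3), c(5, 5)), "match")
})

test_that("blurring raises the mean secondary sparse dark channel", {
  higher <- logical(20)
  for (i in 1:20) {
    spec <- suite_specs(20, 400)[[i]]
    spec$speckle_model <- "none"
    pair <- degraded_pair(spec)
    higher[i] <- mean(secondary_sparse_dark(pair$observed, 15)$values) >=
                 mean(secondary_sparse_dark(pair$truth, 15)$values)
  }
  expect_true(all(higher))
})

test_that("even patch sizes are rejected", {
  img <- random_image(8, 8)
  expect_error(dark_channel(img, 4), "odd")
  expect_error(secondary_sparse_bright(img, 2), "odd")
})
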