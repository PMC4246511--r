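test_that("numbered, sparse and unnumbered lines follow the documented grammar", {
  expect_equal(
    format_example(1, c(0.5, 0, 1), writer_config(sparse = TRUE)),
    "1 1:0.500000 3:1.000000"
  )
  expect_equal(
    format_example(1, c(0.5, 0, 1), writer_config(sparse = FALSE)),
    "1 1:0.500000 2:0.000000 3:1.000000"
  )
  expect_equal(
    format_example(-1, 0.5, writer_config(numbered = FALSE)),
    "-1 0.500000"
  )
  expect_equal(
    format_example(0.7, c(0.1, 0.2), writer_config(numbered = FALSE)),
    "0.700000 0.100000 0.200000"
  )
  expect_equal(
    format_example(1, c(1, 2), writer_config(), comment = "pos 1"),
    "1 1:1.000000 2:2.000000 # pos 1"
  )
  expect_equal(
    format_example(2, c(0.123456789), writer_config(precision = 3)),
    "2 1:0.123"
  )
})

test_that("non-finite values and empty features are rejected by name", {
  err <- expect_error(
    format_example(1, c(0.5, NaN, 1), writer_config()),
    class = "protchar_error_domain"
  )
  expect_match(conditionMessage(err), "index 2")
  expect_error(format_example(Inf, 1, writer_config()), class = "protchar_error_domain")
  expect_error(format_example(1, numeric(0), writer_config()), class = "protchar_error_domain")
})

test_that("write_features writes one line per example and returns the count", {
  tab <- tibble::tibble(
    label = c(1, -1, 2),
    features = list(c(0.5, 0, 1), c(1, 1, 1), c(0, 0, 0.25))
  )
  path <- tempfile()
  expect_equal(write_features(tab, path), 3)
  expect_length(readLines(path), 3)
  expect_error(write_features(tab[0, ], tempfile()), class = "protchar_error_domain")
})

test_that("write -> parse -> write produces byte-identical files", {
  set.seed(21)
  tab <- tibble::tibble(
    label = c(1, 2, 3, -1),
    features = replicate(4, round(stats::runif(8), 4), simplify = FALSE)
  )
  for (cfg in list(writer_config(sparse = TRUE), writer_config(sparse = FALSE),
                   writer_config(numbered = FALSE))) {
    p1 <- tempfile()
    p2 <- tempfile()
    write_features(tab, p1, cfg)
    back <- parse_feature_file(p1)
    write_features(back, p2, cfg)
    expect_identical(readLines(p1), readLines(p2))
    expect_identical(
      unname(tools::md5sum(p1)), unname(tools::md5sum(p2))
    )
  }
})

test_that("sparse and dense serializations of the same examples parse equal", {
  tab <- tibble::tibble(label = c(1, 0), features = list(c(0.5, 0, 1), c(0, 2, 0)))
  ps <- tempfile()
  pd <- tempfile()
  write_features(tab, ps, writer_config(sparse = TRUE))
  write_features(tab, pd, writer_config(sparse = FALSE))
  expect_equal(parse_feature_file(ps)$features, parse_feature_file(pd)$features)
  expect_equal(parse_feature_file(ps)$label, parse_feature_file(pd)$label)
})

test_that("sparse parsing fills missing indices with zero up to the line maximum", {
  p <- write_tmp("1 1:0.5 3:1.0")
  got <- parse_feature_file(p)
  expect_equal(got$label, 1)
  expect_equal(got$features[[1]], c(0.5, 0, 1))

  dense <- parse_feature_file(write_tmp("0.7 0.1 0.2"))
  expect_equal(dense$label, 0.7)
  expect_equal(dense$features[[1]], c(0.1, 0.2))
})

test_that("decreasing or duplicate indices are format errors with line numbers", {
  err <- expect_error(
    parse_feature_file(write_tmp(c("1 1:1 2:2", "1 3:1 1:2"))),
    class = "protchar_error_format"
  )
  expect_match(conditionMessage(err), "line 2")
  expect_error(
    parse_feature_file(write_tmp("1 2:1 2:2")),
    class = "protchar_error_format"
  )
})

test_that("numbered-mode comments survive a round trip", {
  tab <- tibble::tibble(
    label = 1, features = list(c(1, 2)), comment = "residue 7"
  )
  p <- tempfile()
  write_features(tab, p, writer_config())
  expect_equal(parse_feature_file(p)$comment, "residue 7")
})

test_that("sparse without numbering is rejected at configuration time", {
  expect_error(writer_config(numbered = FALSE, sparse = TRUE),
    class = "protchar_error_domain")
})
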