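test_that("compositions count symbols and normalize to 1", {
  a <- aa_composition("AAAA")
  expect_equal(a$fraction[a$symbol == "A"], 1)
  expect_equal(sum(a$fraction), 1)

  b <- aa_composition("ACDC")
  expect_equal(b$fraction[b$symbol == "C"], 0.5)
  expect_equal(b$fraction[b$symbol == "A"], 0.25)
  expect_equal(b$fraction[b$symbol == "D"], 0.25)
  expect_equal(sum(b$fraction != 0), 3)

  s <- ss_composition("HHEC")
  expect_equal(s$fraction, c(0.5, 0.25, 0.25)) # (H, E, C) order
  expect_equal(ss_composition("CCCC")$fraction, c(0, 0, 1))

  expect_equal(sa_composition("bbee")$fraction, c(0.5, 0.5))
  expect_equal(sa_composition("b")$fraction, c(1, 0))
  expect_equal(sa_composition("eeee")$fraction, c(0, 1))
})

test_that("unknown residues are excluded from both sides of the composition", {
  a <- aa_composition("AXA")
  expect_equal(a$fraction[a$symbol == "A"], 1)
  expect_equal(sum(a$fraction), 1)
})

test_that("composition vectors sum to 1 within 1e-9 on random strings", {
  set.seed(42)
  for (k in 1:25) {
    expect_equal(sum(aa_composition(random_aa_string(sample(1:200, 1)))$fraction), 1,
      tolerance = 1e-9
    )
  }
})

test_that("degenerate composition inputs are domain errors", {
  expect_error(aa_composition(""), class = "protchar_error_domain")
  expect_error(aa_composition("XXX"), class = "protchar_error_domain")
  expect_error(ss_composition(""), class = "protchar_error_domain")
  expect_error(ss_composition("HHQ"), class = "protchar_error_alphabet")
})

test_that("entropy matches closed forms and rejects non-distributions", {
  expect_equal(calculate_entropy(rep(0.25, 4)), 2)
  expect_equal(calculate_entropy(c(1, 0, 0)), 0)
  expect_equal(calculate_entropy(c(0.5, 0.25, 0.25)), 1.5)
  for (K in c(2, 3, 4, 20)) {
    expect_equal(calculate_entropy(rep(1 / K, K)), log2(K), tolerance = 1e-12)
  }
  expect_error(calculate_entropy(c(0.7, -0.1, 0.4)), class = "protchar_error_domain")
  expect_error(calculate_entropy(c(0.5, 0.4)), class = "protchar_error_domain")
})

test_that("Pearson correlation matches the sum formula and flags degeneracy", {
  expect_equal(calculate_r(1:3, 1:3), 1)
  expect_equal(calculate_r(1:3, 3:1), -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  expect_equal(calculate_r(x, y), reference_pearson(x, y), tolerance = 1e-12)

  expect_error(calculate_r(1:3, 1:4), class = "protchar_error_domain")
  expect_error(
    calculate_r(c(2, 2, 2), 1:3),
    class = "protchar_error_undefined_correlation"
  )
})

test_that("cosine similarity handles orthogonality, scale invariance and zero norms", {
  expect_equal(calculate_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(calculate_cosine(c(2, 2), c(1, 1)), 1)
  expect_equal(calculate_cosine(c(1, 1), c(1, -1)), 0)
  expect_error(calculate_cosine(c(0, 0), c(1, 1)), class = "protchar_error_domain")
  expect_error(calculate_cosine(1:2, 1:3), class = "protchar_error_domain")
})

test_that("correlation and cosine agree with brute-force oracles on random pairs", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(2:30, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    expect_equal(calculate_r(x, y), reference_pearson(x, y), tolerance = 1e-12)
    expect_equal(calculate_cosine(x, y), reference_cosine(x, y), tolerance = 1e-12)
  }
})

test_that("the power mean reduces to the arithmetic mean at n = 1 and fixes constants", {
  h <- vapply(strsplit("ACDEFG", "")[[1]], hydrophobicity, numeric(1), scaled = TRUE)
  expect_equal(scaled_ordered_mean("ACDEFG", 1), mean(h))
  # constant string: M_n equals the constant for every n
  for (n in 1:4) {
    expect_equal(scaled_ordered_mean("FFFF", n), hydrophobicity("F", scaled = TRUE))
    expect_equal(scaled_ordered_mean("bbbb", n, scale = "sa2"), 0)
  }
})

test_that("the power mean is monotone non-decreasing in n", {
  set.seed(11)
  for (k in 1:20) {
    s <- random_aa_string(sample(3:50, 1))
    scale <- sample(c("hydrophobicity", "atchley1", "atchley3"), 1)
    ms <- vapply(1:4, function(n) scaled_ordered_mean(s, n, scale), numeric(1))
    expect_true(all(diff(ms) >= -1e-12))
    # brute-force cross-check at n = 2
    v <- protchar:::ordered_mean_values(s, scale)
    expect_equal(ms[[2]], reference_power_mean(v, 2), tolerance = 1e-12)
  }
  expect_gte(scaled_ordered_mean("HECC", 2, scale = "ss3"),
             scaled_ordered_mean("HECC", 1, scale = "ss3"))
})

test_that("power-mean edge cases error cleanly", {
  expect_error(scaled_ordered_mean("", 1), class = "protchar_error_domain")
  expect_error(scaled_ordered_mean("ACD", 0), class = "protchar_error_domain")
  expect_error(scaled_ordered_mean("ACD", 2, scale = "nope"), class = "protchar_error_domain")
})
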