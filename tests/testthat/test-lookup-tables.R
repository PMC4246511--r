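test_that("Atchley factors reproduce the published alanine row and zero out X", {
  # frozen transcription check against the published five-factor table
  expect_equal(unname(atchley_factors("A")), c(-0.591, -1.302, -0.733, 1.570, -0.146))
  expect_equal(unname(atchley_factors("Y")), c(0.260, 0.830, 3.097, -0.838, 1.512))
  expect_equal(unname(atchley_factors("X")), rep(0, 5))
  expect_length(atchley_factors("W"), 5)
  expect_error(atchley_factors("#"), class = "protchar_error_alphabet")
})

test_that("scaled Atchley factors hit exactly 0 and 1 at the per-dimension extremes", {
  tab <- lookup_table("atchley")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$aa
  scaled <- t(vapply(tab$aa, function(a) atchley_factors(a, scaled = TRUE), numeric(5)))
  expect_true(all(scaled >= 0 & scaled <= 1))
  for (d in 1:5) {
    # direct min-max oracle over the shipped 20x5 table
    expect_equal(unname(scaled[which.min(m[, d]), d]), 0)
    expect_equal(unname(scaled[which.max(m[, d]), d]), 1)
    expect_equal(unname(scaled[, d]), unname((m[, d] - min(m[, d])) / (max(m[, d]) - min(m[, d]))))
  }
})

test_that("hydrophobicity keeps the source scale's orientation and conventions", {
  # phenylalanine is the most hydrophobic entry, aspartate the most hydrophilic
  expect_gt(hydrophobicity("F"), hydrophobicity("D"))
  expect_equal(hydrophobicity("G"), 0) # glycine anchors the scale
  vals <- vapply(aa_alphabet(), hydrophobicity, numeric(1))
  expect_equal(hydrophobicity("X"), mean(vals))
  expect_equal(hydrophobicity("F", scaled = TRUE), 1)
  expect_equal(hydrophobicity("D", scaled = TRUE), 0)
  scaled <- vapply(aa_alphabet(), hydrophobicity, numeric(1), scaled = TRUE)
  expect_true(all(scaled >= 0 & scaled <= 1))
})

test_that("pair potentials are symmetric over all 210 unordered pairs", {
  for (fn in list(interface_contact_potential, beta_contact_potential)) {
    for (i in seq_along(aa_alphabet())) {
      for (j in i:length(aa_alphabet())) {
        a <- aa_alphabet()[[i]]
        b <- aa_alphabet()[[j]]
        expect_identical(fn(a, b), fn(b, a))
      }
    }
  }
})

test_that("scaled pair potentials span exactly [0,1] with X mapping to the table mean", {
  for (name in c("interface_contact", "beta_contact")) {
    fn <- if (name == "interface_contact") interface_contact_potential else beta_contact_potential
    # exhaustive scan oracle over the 210 shipped entries
    tab <- lookup_table(name)
    expect_equal(nrow(tab), 210)
    expect_equal(fn("X", "A"), mean(tab$value))
    expect_equal(fn("X", "X"), mean(tab$value))
    lo <- tab[which.min(tab$value), ]
    hi <- tab[which.max(tab$value), ]
    expect_equal(fn(lo$a, lo$b, scaled = TRUE), 0)
    expect_equal(fn(hi$a, hi$b, scaled = TRUE), 1)
    scaled <- mapply(fn, tab$a, tab$b, MoreArgs = list(scaled = TRUE))
    expect_true(all(scaled >= 0 & scaled <= 1))
    unscaled <- mapply(fn, tab$a, tab$b)
    expect_true(all(unscaled >= min(tab$value) & unscaled <= max(tab$value)))
  }
})

test_that("shipped tables pass their header checksums and record provenance", {
  for (name in c("atchley", "hydrophobicity", "interface_contact", "beta_contact")) {
    tab <- lookup_table(name)
    header <- attr(tab, "header")
    declared <- as.numeric(sub(".*checksum: ", "", header[grepl("checksum:", header)]))
    values <- unlist(tab[vapply(tab, is.numeric, logical(1))], use.names = FALSE)
    expect_equal(sum(values), declared, tolerance = 1e-9)
    expect_true(any(grepl("source:|SYNTHETIC", header)))
  }
  # the contact tables are constructed stand-ins and must say so
  for (name in c("interface_contact", "beta_contact")) {
    expect_true(any(grepl("SYNTHETIC", attr(lookup_table(name), "header"))))
  }
})
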