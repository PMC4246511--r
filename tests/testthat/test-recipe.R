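test_that("a window-1 hot_aa recipe is the hot vector plus one boundary bit", {
  recipe <- feature_recipe("hot_aa", window = 1)
  v <- build_residue_features(list(sequence = "A"), recipe, 1)
  expect_length(v, 21)
  expect_equal(v, c(unname(hot_encode_aa("A")), 0))
})

test_that("out-of-sequence window slots are zero-filled with the boundary bit set", {
  recipe <- feature_recipe("hot_aa", window = 3)
  v <- build_residue_features(list(sequence = "AC"), recipe, 1)
  expect_length(v, 3 * 21)
  left <- v[1:21]
  expect_equal(left, c(rep(0, 20), 1)) # slot before the sequence start
  centre <- v[22:42]
  expect_equal(centre, c(unname(hot_encode_aa("A")), 0))
  right <- v[43:63]
  expect_equal(right, c(unname(hot_encode_aa("C")), 0))
})

test_that("feature length equals window times the summed block widths plus bits", {
  widths <- c(
    hot_aa = 20, hot_ss = 3, hot_sa = 2, atchley = 5, hydrophobicity = 1,
    msa_freq = 20, information = 1
  )
  msa <- protchar:::new_anchored_msa("q", c("ACDEF", "AC-EF"))
  inputs <- list(sequence = "ACDEF", ss = "HHECC", sa = "bbeeb", msa = msa)
  set.seed(31)
  for (k in 1:10) {
    blocks <- sample(names(widths), sample(1:4, 1))
    window <- sample(c(1, 3, 5, 7), 1)
    recipe <- feature_recipe(paste(blocks, collapse = ","), window = window)
    expected <- window * sum(widths[blocks] + 1) # brute-force length count
    expect_equal(recipe$width, expected)
    v <- build_residue_features(inputs, recipe, 3)
    expect_length(v, expected)
  }
})

test_that("recipes referencing missing inputs raise configuration errors", {
  recipe <- feature_recipe("hot_aa,pssm_logodds", window = 1)
  err <- expect_error(
    build_residue_features(list(sequence = "ACD"), recipe, 1),
    class = "protchar_error_config"
  )
  expect_match(conditionMessage(err), "pssm")
  expect_error(feature_recipe("hot_aa,not_a_block"), class = "protchar_error_config")
  expect_error(feature_recipe("hot_aa,aa_composition"), class = "protchar_error_config")
  expect_error(feature_recipe("hot_aa", window = 2), class = "protchar_error_domain")
  expect_error(
    build_residue_features(list(sequence = "ACD"), feature_recipe("hot_aa"), 9),
    class = "protchar_error_domain"
  )
})

test_that("scaled per-residue blocks stay in [0,1]", {
  fx <- make_fixture(23, length = 20, msa_rows = 5, dir = tempfile())
  inputs <- list(
    sequence = fx$protein$sequence, pssm = fx$pssm, msa = fx$msa,
    ss = fx$ss_pred$symbols, sa = dssp_sa2(fx$dssp)
  )
  recipe <- feature_recipe(
    "hot_aa,hot_ss,hot_sa,atchley,hydrophobicity,pssm_logodds,pssm_freq,msa_freq,information",
    window = 3, scaled = TRUE
  )
  tab <- build_feature_table(inputs, recipe)
  expect_equal(nrow(tab), 20)
  all_vals <- unlist(tab$features)
  expect_true(all(all_vals >= 0 & all_vals <= 1))
  expect_true(all(lengths(tab$features) == recipe$width))
})

test_that("global recipes produce a single composition-based example", {
  inputs <- list(sequence = "ACDCACDC", ss = "HHHHEEEE", sa = "bbbbeeee")
  recipe <- feature_recipe(
    "aa_composition,ss_composition,sa_composition,ordered_mean:2:hydrophobicity,entropy"
  )
  expect_equal(recipe$kind, "global")
  tab <- build_feature_table(inputs, recipe)
  expect_equal(nrow(tab), 1)
  v <- tab$features[[1]]
  expect_length(v, 20 + 3 + 2 + 1 + 1)
  expect_equal(sum(v[1:20]), 1, tolerance = 1e-9) # aa composition block
  expect_equal(v[21:23], c(0.5, 0.5, 0)) # ss composition (H,E,C)
  expect_equal(v[24:25], c(0.5, 0.5)) # sa composition (b,e)
  expect_equal(v[26], scaled_ordered_mean("ACDCACDC", 2, "hydrophobicity"))
  expect_equal(v[27], calculate_entropy(aa_composition("ACDCACDC")$fraction))
})

test_that("labels attach per example and ss3_labels maps H/E/C to 1/2/3", {
  expect_equal(ss3_labels("HEC"), c(1L, 2L, 3L))
  inputs <- list(sequence = "ACD", ss = "HEC")
  recipe <- feature_recipe("hot_ss", window = 1)
  tab <- build_feature_table(inputs, recipe, labels = ss3_labels(inputs$ss))
  expect_equal(tab$label, c(1, 2, 3))
  expect_error(
    build_feature_table(inputs, recipe, labels = 1:2),
    class = "protchar_error_domain"
  )
})
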