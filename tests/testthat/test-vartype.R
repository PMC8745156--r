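test_that("the four physicochemical classes partition the 20 residues", {
  all20 <- unlist(residue_classes, use.names = FALSE)
  expect_setequal(all20, aa_alphabet)
  expect_equal(length(all20), 20)
  expect_error(residue_class("B"), "not standard")
})

test_that("variation types follow the class definitions", {
  expect_equal(variation_type("G", "D"), data.frame(from = "apolar",
                                                    to = "charged"))
  expect_equal(variation_type("Y", "D"), data.frame(from = "aromatic",
                                                    to = "charged"))
  expect_equal(variation_type("A", "V"), data.frame(from = "apolar",
                                                    to = "apolar"))
})

test_that("type matrices conserve counts and separate domains", {
  rec <- deduplicate_variants(parse_variant_table(mthfr_table1_path()))$records
  mc <- type_matrix(rec, "catalytic")
  mr <- type_matrix(rec, "regulatory")
  expect_equal(sum(mc), sum(rec$domain == "catalytic"))
  expect_equal(sum(mr), sum(rec$domain == "regulatory"))
  expect_false(isTRUE(all.equal(unclass(mc), unclass(mr))))
  # a single record lights exactly one cell
  one <- rec[variant_labels(rec) == "G387D", ]
  m1 <- type_matrix(one)
  expect_equal(sum(m1), 1)
  expect_equal(unclass(m1)["a", "c"], 1L)
  # frequencies sum to one
  expect_equal(sum(type_frequencies(mc)), 1)
  expect_error(type_frequencies(type_matrix(rec[0, ])), "all-zero")
})

test_that("chi-square of identical matrices is zero with p = 1", {
  rec <- deduplicate_variants(parse_variant_table(mthfr_table1_path()))$records
  m <- type_matrix(rec, "catalytic")
  res <- chi_square_pseudocount(m, m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 15)
})

test_that("pseudocount chi-square matches a hand-computed 2-category case", {
  # counts (10, 0) vs (0, 10), + 0.5 per cell:
  # table rows (10.5, 0.5) / (0.5, 10.5); all expected cells are 5.5,
  # X2 = 4 * 5^2 / 5.5 = 200/11, df = 1
  a <- matrix(c(10, 0), 1)
  b <- matrix(c(0, 10), 1)
  res <- chi_square_pseudocount(a, b)
  expect_equal(res$statistic, 200 / 11)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(200 / 11, 1, lower.tail = FALSE))
})

test_that("chi-square is swap-invariant and grows with disparity", {
  rec <- deduplicate_variants(parse_variant_table(mthfr_table1_path()))$records
  mc <- type_matrix(rec, "catalytic")
  mr <- type_matrix(rec, "regulatory")
  ab <- chi_square_pseudocount(mc, mr)
  ba <- chi_square_pseudocount(mr, mc)
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  # growing a single cell's disparity monotonically drops the p-value
  ps <- vapply(c(0, 5, 15, 40), function(extra) {
    m2 <- unclass(mc)
    m2[1, 1] <- m2[1, 1] + extra
    chi_square_pseudocount(mc, m2)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("background sampler is uniform on average and deterministic", {
  bg <- background_matrix(n = 160000, seed = 99)
  expect_equal(sum(bg), 1)
  expect_true(all(abs(unclass(bg) - 1 / 16) < 0.005))
  expect_identical(background_matrix(n = 1000, seed = 7),
                   background_matrix(n = 1000, seed = 7))
})

test_that("type matrix TSV round-trips and serves as background", {
  rec <- deduplicate_variants(parse_variant_table(mthfr_table1_path()))$records
  m <- type_matrix(rec, "regulatory")
  path <- tempfile(fileext = ".tsv")
  write_type_matrix(m, path)
  back <- read_type_matrix(path)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  bg <- background_matrix(path = path)
  expect_equal(unclass(bg), unclass(type_frequencies(m)),
               ignore_attr = TRUE)
})
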