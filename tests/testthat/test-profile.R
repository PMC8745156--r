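fasta_file <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

stockholm_file <- function(seqs, split_blocks = FALSE) {
  path <- tempfile(fileext = ".sto")
  if (!split_blocks) {
    body <- paste(names(seqs), unlist(seqs))
  } else {
    half <- ceiling(nchar(seqs[[1]]) / 2)
    body <- c(paste(names(seqs), substr(unlist(seqs), 1, half)),
              "",
              paste(names(seqs), substr(unlist(seqs), half + 1,
                                        nchar(seqs[[1]]))))
  }
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID toy", body, "//"), path)
  path
}

test_that("aligned FASTA and Stockholm of one alignment read identically", {
  seqs <- list(human = "ACDEFGHIKL", seq1 = "ACDE-GHIKL",
               seq2 = "ACDEFGH.KL")
  m1 <- read_msa(fasta_file(seqs))
  m2 <- read_msa(stockholm_file(seqs))
  m3 <- read_msa(stockholm_file(seqs, split_blocks = TRUE))
  expect_equal(dim(m1$ali), c(3, 10))
  expect_identical(m1$ali, m2$ali)
  expect_identical(m1$ali, m3$ali)
  expect_equal(m1$reference_id, "human")
  # gap symbols normalized
  expect_equal(unname(m1$ali["seq2", 8]), "-")
})

test_that("ragged alignments are rejected with the offending row", {
  path <- fasta_file(list(a = "ACDEFGHIKL", b = "ACD"))
  expect_error(read_msa(path), "ragged.*'b'")
})

test_that("identical ungapped rows give all-match Laplace emissions", {
  n <- 3
  msa <- read_msa(fasta_file(list(human = "ACDEFGHIKL",
                                  s1 = "ACDEFGHIKL",
                                  s2 = "ACDEFGHIKL")))
  prof <- build_profile(msa)
  expect_equal(prof$match_columns, 1:10)
  # observed residue gets (n + 1) / (n + 20), others 1 / (n + 20)
  expect_equal(unname(prof$emissions[1, "A"]), (n + 1) / (n + 20))
  expect_equal(unname(prof$emissions[1, "C"]), 1 / (n + 20))
  expect_equal(unname(rowSums(prof$emissions)), rep(1, 10))
})

test_that("hand-built 3x4 alignment reproduces hand-computed parameters", {
  msa <- read_msa(fasta_file(list(h = "ACDE", s2 = "AC-E", s3 = "GC-E")),
                  ref_start = 100)
  prof <- build_profile(msa)
  # column 3 is gapped in 2/3 rows -> insert; match columns 1, 2, 4
  expect_equal(prof$match_columns, c(1L, 2L, 4L))
  expect_equal(unname(prof$emissions[1, "A"]), 3 / 23)
  expect_equal(unname(prof$emissions[1, "G"]), 2 / 23)
  expect_equal(unname(prof$emissions[1, "C"]), 1 / 23)
  expect_equal(unname(prof$emissions[2, "C"]), 4 / 23)
  expect_equal(unname(prof$emissions[3, "E"]), 4 / 23)
  # transitions 1->2: all three sequences M->M; +1 pseudocount per outcome
  t1 <- prof$transitions[[1]]
  expect_equal(unname(t1["M", ]), c(4, 1, 1) / 6)
  expect_equal(unname(t1["D", ]), c(1, 1, 1) / 3)
  # transitions 2->4: h passes through the insert column (M->I),
  # s2 and s3 go straight M->M
  t2 <- prof$transitions[[2]]
  expect_equal(unname(t2["M", ]), c(3, 1, 2) / 6)
  # reference map: position 102 sits in the insert column
  expect_equal(prof$ref_map$position, 100:103)
  expect_equal(prof$ref_map$column, 1:4)
  expect_equal(prof$ref_map$match_state, c(1L, 2L, NA, 3L))
})

test_that("row duplication keeps match columns and shrinks smoothing", {
  msa <- read_msa(fasta_file(list(h = "ACDE", s2 = "AC-E", s3 = "GC-E")))
  ali10 <- msa$ali[rep(1:3, 10), ]
  rownames(ali10) <- paste0("r", 1:30)
  rownames(ali10)[1] <- "h"
  msa10 <- mthfrvar:::new_msa(ali10, "h")
  p1 <- build_profile(msa)
  p10 <- build_profile(msa10)
  expect_identical(p10$match_columns, p1$match_columns)
  # emissions converge toward the maximum-likelihood frequencies
  ml <- 2 / 3  # A in column 1
  expect_lt(abs(p10$emissions[1, "A"] - ml),
            abs(p1$emissions[1, "A"] - ml))
})

test_that("reference map round-trips through the alignment", {
  msa <- simulate_msa(n_seq = 20, ref_start = 336, width = 60, seed = 3)
  prof <- build_profile(msa)
  ref_row <- msa$ali[msa$reference_id, ]
  for (i in seq_len(nrow(prof$ref_map))) {
    expect_false(ref_row[prof$ref_map$column[i]] == "-")
  }
  expect_true(all(diff(prof$ref_map$position) > 0))
})

test_that("simulated regulatory alignment maps positions 336-566", {
  msa <- simulate_msa(n_seq = 50, ref_start = 336, width = 231, seed = 1)
  expect_equal(nrow(msa$ali), 50)
  prof <- build_profile(msa)
  expect_equal(range(prof$ref_map$position), c(336, 566))
  # reference residues sit in match columns throughout (the insert block
  # is gapped in the reference by construction)
  expect_true(all(!is.na(prof$ref_map$match_state)))
})

test_that("variants map onto the architecture by position", {
  rec <- deduplicate_variants(parse_variant_table(mthfr_table1_path()))$records
  msa <- simulate_msa(n_seq = 30, ref_start = 336, width = 231, seed = 2)
  prof <- build_profile(msa)
  mapped <- map_variants_to_architecture(rec, prof)
  g387 <- mapped[mapped$variant == "G387D", ]
  expect_equal(g387$domain_model, "regulatory")
  expect_equal(g387$match_state,
               prof$ref_map$match_state[prof$ref_map$position == 387])
  expect_equal(g387$type, "a>c")
  # all catalytic variants fall inside the 1-335 span
  cat_rows <- mapped[rec$domain == "catalytic", ]
  expect_true(all(cat_rows$domain_model == "catalytic"))
  expect_true(all(cat_rows$mapped))
  # a position beyond the regulatory model region is unmapped
  out <- rec[1, ]
  out$pos <- 600L
  out$domain <- "regulatory"
  expect_false(map_variants_to_architecture(out, prof)$mapped)
})

test_that("profile JSON export preserves the model", {
  msa <- read_msa(fasta_file(list(h = "ACDE", s2 = "AC-E", s3 = "GC-E")))
  prof <- build_profile(msa)
  path <- tempfile(fileext = ".json")
  write_profile_json(prof, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$match_columns), c(1, 2, 4))
  expect_equal(back$emissions[[1]]$A, 3 / 23)
  expect_equal(length(back$ref_map), 4)
})
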