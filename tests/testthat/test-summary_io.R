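test_that("fixture files parse into validated variant records", {
  crp <- read_summary_stats(crp_fixture_path("crp_gwas"))
  expect_s3_class(crp, "variant_assoc")
  expect_equal(nrow(crp), 5L)
  expect_identical(crp$variant_id[1], "rs6700896")
  expect_identical(crp$chrom[1], "1")
  expect_equal(crp$pos[1], 65862370)
  # shipped fixtures agree with the independently entered published values
  expect_equal(crp$beta, table1$beta_exposure)
  expect_equal(crp$se, table1$se_exposure)
  expect_equal(crp$pvalue, table1$p_exposure)
  t2d <- read_summary_stats(crp_fixture_path("t2dm_gwas"))
  expect_equal(t2d$beta, table1$beta_outcome)
  expect_equal(t2d$pvalue, table1$p_outcome)
  t1d <- read_summary_stats(crp_fixture_path("t1dm_gwas"))
  expect_equal(t1d$beta, table2$beta_outcome)
  paired <- read_paired_summary_stats(crp_fixture_path("crp_t2dm"))
  expect_equal(paired$beta_exposure, table1$beta_exposure)
  expect_equal(paired$beta_outcome, table1$beta_outcome)
})

test_that("empty, malformed, and invalid inputs are diagnosed by row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\tchr\tbp\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue", f)
  expect_equal(nrow(read_summary_stats(f)), 0L)

  writeLines(c("snp\tchr\tbp\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
               "rs1\t1\t100\tA\tG\t0.5\t0.1\t0.01\t1e-9",
               "rs2\t1\t200\tA\tG\t0.5\t0.2\t0\t1e-9"), f)
  expect_warning(x <- read_summary_stats(f), "row 2.*rs2.*se must be > 0")
  expect_equal(x$variant_id, "rs1")

  writeLines(c("snp\tchr\tbp\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
               "rs1\t1\t100\tA\tG\t0.5\tnot_a_number\t0.01\t1e-9"), f)
  expect_error(read_summary_stats(f), "unparseable numeric.*beta.*row\\(s\\) 1")

  expect_error(read_summary_stats(file.path(tempdir(), "absent.tsv")), "not found")
  writeLines("snp\tchr\tbp\tbeta\tse\tpvalue", f)
  expect_error(read_summary_stats(f), "missing required column")
  # missing eaf is tolerated
  writeLines(c("snp\tchr\tbp\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
               "rs1\t1\t100\tA\tG\t.\t0.1\t0.01\t1e-9"), f)
  expect_true(is.na(read_summary_stats(f)$eaf))
})

test_that("write/read round trip reproduces numeric fields bit-identically", {
  set.seed(42)
  x <- data.frame(
    variant_id = sprintf("rs%d", 1:20), chrom = "1", pos = 1:20 * 1000,
    effect_allele = "A", other_allele = "G",
    eaf = runif(20), beta = rnorm(20) * 10^runif(20, -6, 2),
    se = exp(rnorm(20)), pvalue = runif(20), stringsAsFactors = FALSE
  )
  x$eaf[3] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, f)
  y <- read_summary_stats(f)
  for (col in c("pos", "eaf", "beta", "se", "pvalue"))
    expect_identical(y[[col]], x[[col]], label = col)
})

test_that("harmonization copies, flips, and is idempotent", {
  e <- as_assoc(table1[1, ], "exposure")
  o <- as_assoc(table1[1, ], "outcome")
  h <- harmonize(e, o)
  expect_false(h$flipped)
  expect_equal(h$beta_exposure, -0.147)
  expect_equal(h$beta_outcome, -0.00995)

  # outcome reported on the swapped allele pair
  o_sw <- o
  o_sw$effect_allele <- "C"; o_sw$other_allele <- "T"
  o_sw$beta <- -o$beta; o_sw$eaf <- 1 - o$eaf
  h_sw <- harmonize(e, o_sw)
  expect_true(h_sw$flipped)
  expect_equal(h_sw$beta_outcome, -0.00995)

  # double-flip identity: the two routes agree on every shared field
  expect_equal(h_sw[, setdiff(names(h_sw), "flipped")],
               h[, setdiff(names(h), "flipped")])

  # idempotence: re-harmonizing the aligned outcome changes nothing
  o_al <- o
  o_al$beta <- h$beta_outcome
  h2 <- harmonize(e, o_al)
  expect_equal(h2, h)

  o_bad <- o
  o_bad$effect_allele <- "A"; o_bad$other_allele <- "G"
  expect_error(harmonize(e, o_bad), "incompatible allele sets")
  expect_error(harmonize(e, as_assoc(table1[2, ], "outcome")), "variant_id mismatch")
})

test_that("palindromic variants follow the requested policy", {
  e <- as_assoc(table1[1, ], "exposure")
  e$effect_allele <- "A"; e$other_allele <- "T"
  o <- as_assoc(table1[1, ], "outcome")
  o$effect_allele <- "A"; o$other_allele <- "T"
  expect_warning(h <- harmonize(e, o, "keep"), "palindromic")
  expect_equal(nrow(h), 1L)
  expect_equal(nrow(suppressWarnings(harmonize(e, o, "drop"))), 0L)
  expect_error(harmonize(e, o, "error"), "palindromic")
})

test_that("harmonize_tables matches by id and logs one-sided variants", {
  e <- as_assoc(table1, "exposure")
  o <- as_assoc(table2, "outcome")
  expect_message(h <- harmonize_tables(e, o), "rs4537545")
  expect_equal(nrow(h), 3L)
  expect_equal(h$variant_id, table2$variant_id)
  expect_equal(h$beta_outcome, table2$beta_outcome)
  dropped <- attr(h, "dropped")
  expect_setequal(dropped$variant_id, c("rs4537545", "rs4420638"))
  expect_true(all(dropped$reason == "unharmonizable"))

  # flipped outcome rows are re-aligned in the table path too
  o2 <- as_assoc(table1, "outcome")
  o2$effect_allele <- table1$other_allele
  o2$other_allele <- table1$effect_allele
  o2$beta <- -o2$beta
  h2 <- harmonize_tables(e, o2)
  expect_true(all(h2$flipped))
  expect_equal(h2$beta_outcome, table1$beta_outcome)
})
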