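test_that("taxa_table validates entries and identifiers", {
  m <- matrix(0:5, 2, 3, dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  tt <- taxa_table(m)
  expect_s3_class(tt, "taxa_table")
  expect_identical(dim(tt), c(2L, 3L))
  expect_error(taxa_table(matrix(c(-1, 0, 1, 2), 2, 2)), "negative")
  expect_error(taxa_table(matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))),
               "duplicate sample")
  expect_error(taxa_table(matrix(2, 1, 1), is_proportion = TRUE), "exceed")
})

test_that("read_taxa_table handles orientation, scaling and bad cells", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  mat <- matrix(1:12, 3, 4, dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  write.table(data.frame(id = rownames(mat), mat), tf, sep = "\t",
              quote = FALSE, row.names = FALSE)
  tt <- read_taxa_table(tf, orientation = "taxa_by_samples")
  expect_identical(dim(tt$counts), c(4L, 3L))
  expect_equal(tt$counts["s2", "t3"], mat["t3", "s2"])

  tt2 <- read_taxa_table(tf, orientation = "taxa_by_samples", scale = 100)
  expect_equal(tt2$counts["s1", "t1"], 100)

  writeLines(c("id\ts1\ts2", "t1\t1\t-2"), tf)
  expect_error(read_taxa_table(tf, orientation = "taxa_by_samples"), "negative")
  writeLines(c("id\ts1\ts2", "t1\t1\tabc"), tf)
  expect_error(read_taxa_table(tf, orientation = "taxa_by_samples"), "abc")
})

test_that("transformations are monotone and map zero to exactly zero", {
  expect_identical(log2_transform(0), 0)
  expect_equal(log2_transform(7), 3)
  expect_equal(log2_transform(1), 1)
  expect_error(log2_transform(-1), "non-negative")

  expect_identical(arcsine_sqrt_transform(0, 10), 0)
  expect_equal(arcsine_sqrt_transform(10, 10), pi / 2)
  expect_equal(arcsine_sqrt_transform(5, 10), pi / 4)
  expect_error(arcsine_sqrt_transform(11, 10), "exceeds")

  x <- sort(runif(50, 0, 20))
  expect_true(all(diff(log2_transform(x)) >= 0))
  expect_true(all(diff(arcsine_sqrt_transform(x, 20)) >= 0))
})

test_that("nonzero_proportions counts positives and ignores sample order", {
  m <- cbind(a = c(0, 0, 0, 1), b = c(2, 3, 0, 1), c = c(0, 0, 0, 0))
  rownames(m) <- paste0("s", 1:4)
  tt <- taxa_table(m)
  expect_equal(unname(nonzero_proportions(tt)), c(0.25, 0.75, 0))
  set.seed(1)
  perm <- sample(4)
  tt2 <- taxa_table(m[perm, ])
  expect_equal(nonzero_proportions(tt2), nonzero_proportions(tt))
})

test_that("build_design computes offsets, ordering and errors", {
  meta <- toy_meta(4, 2)
  meta$total_reads <- c(10, 100, 10, 100, 10, 100, 10, 100)
  spec <- model_spec(~ group, ~ 1 | subject, method = "nb")
  y <- rpois(8, 5) + 1
  d <- build_design(meta, spec, y)
  expect_equal(d$offset, log(meta$total_reads))

  spec0 <- model_spec(~ group, ~ 1 | subject, method = "nb",
                      offset_policy = "none")
  expect_equal(build_design(meta, spec0, y)$offset, rep(0, 8))

  spec_bad <- model_spec(~ bmi, ~ 1 | subject, method = "nb")
  expect_error(build_design(meta, spec_bad, y), "bmi")

  meta2 <- meta; meta2$total_reads <- NULL
  expect_error(build_design(meta2, spec, y), "total_reads")

  # proportion response forbids an offset
  expect_error(build_design(meta, spec, y, is_proportion = TRUE), "none")

  # ar1 orders samples by time within subject, contiguously by subject
  meta3 <- meta[sample(nrow(meta)), ]
  spec_ar <- model_spec(~ group, ~ 1 | subject, correlation = "ar1",
                        method = "nb", time_var = "time")
  d3 <- build_design(meta3, spec_ar, seq_len(8))
  expect_true(all(diff(match(d3$groups, unique(d3$groups))) >= 0))
  expect_true(all(tapply(d3$data$time, d3$groups, function(t) all(diff(t) >= 0))))
})

test_that("rows with missing model variables are dropped with a count", {
  meta <- toy_meta(4, 2)
  meta$age[3] <- NA
  spec <- model_spec(~ group + age, ~ 1 | subject, method = "nb")
  d <- build_design(meta, spec, rep(1, 8))
  expect_equal(d$n_dropped, 1L)
  expect_equal(length(d$y), 7L)
})

test_that("results tables round-trip through TSV at 12 significant digits", {
  tab <- data.frame(taxon = c("A", "B"), term = "group", part = "count",
                    estimate = c(pi, -exp(1) * 1e-7),
                    se = c(1 / 3, 2 / 7), pvalue = c(0.0455002638963584, 1e-12),
                    converged = TRUE, stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, tf)
  back <- read_results(tf)
  for (col in c("estimate", "se", "pvalue"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
})

test_that("model_spec rejects zero-part formulas for non-zero-inflated methods", {
  expect_error(model_spec(~ group, ~ 1 | subject, zi_fixed = ~1, method = "nb"),
               "zinb")
  expect_error(model_spec(y ~ group, ~ 1 | subject, method = "nb"), "one-sided")
})

test_that("run-config files parse as key=value pairs", {
  tf <- withr::local_tempfile()
  writeLines(c("# comment", "method = nb", "min_p=0.2"), tf)
  cfg <- read_run_config(tf)
  expect_identical(cfg$method, "nb")
  expect_identical(cfg$min_p, "0.2")
})
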