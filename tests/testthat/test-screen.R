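# a small count table with controlled per-taxon nonzero proportions
engineered_table <- function(nzp, n = 10, seed = 1) {
  set.seed(seed)
  counts <- sapply(nzp, function(p) {
    k <- round(p * n)
    c(rpois(k, 20) + 1, rep(0, n - k))[sample(n)]
  })
  colnames(counts) <- sprintf("tax%02d", seq_along(nzp))
  rownames(counts) <- paste0("s", seq_len(n))
  taxa_table(counts)
}

screen_meta <- function(n = 10, seed = 1) {
  set.seed(seed + 100)
  data.frame(sample_id = paste0("s", seq_len(n)),
             subject = rep(paste0("S", seq_len(n / 2)), each = 2),
             group = rep(rbinom(n / 2, 1, 0.5), each = 2),
             total_reads = runif(n, 1e3, 1e4), stringsAsFactors = FALSE)
}

test_that("min_p filters by strict inequality on nonzero proportion", {
  tab <- engineered_table(seq(0, 0.9, by = 0.1))
  meta <- screen_meta()
  spec <- model_spec(~ group, ~ 1 | subject, method = "lmm",
                     offset_policy = "none")
  res <- screen_taxa(tab, meta, spec, min_p = 0.2)
  expect_length(res$fits, 7L)
  expect_setequal(names(res$skipped), c("tax01", "tax02", "tax03"))
  expect_true(all(res$skipped == "filtered"))

  res0 <- screen_taxa(tab, meta, spec, min_p = 0)
  expect_length(res0$fits, 9L)  # only the all-zero taxon drops out

  expect_warning(res1 <- screen_taxa(tab, meta, spec, min_p = 1), "no taxa")
  expect_length(res1$fits, 0L)
})

test_that("sort orders the analysis by decreasing nonzero proportion", {
  tab <- engineered_table(c(0.3, 0.9, 0.6))
  meta <- screen_meta()
  spec <- model_spec(~ group, ~ 1 | subject, method = "lmm",
                     offset_policy = "none")
  res <- screen_taxa(tab, meta, spec, sort = TRUE)
  expect_identical(res$order, c("tax02", "tax03", "tax01"))
})

test_that("a failing taxon is isolated and other outputs are byte-identical", {
  tab <- engineered_table(seq(0, 0.9, by = 0.1))
  meta <- screen_meta()
  # engineer a failure: drop the covariate on exactly the rows where tax04
  # is nonzero, so that taxon is all zero after row dropping
  meta_fail <- meta
  meta_fail$group[tab$counts[, "tax04"] > 0] <- NA
  spec <- model_spec(~ group, ~ 1 | subject, method = "nb")
  res_all <- suppressWarnings(screen_taxa(tab, meta_fail, spec, min_p = 0.2))
  expect_match(res_all$skipped[["tax04"]], "^failed")

  keep <- setdiff(colnames(tab$counts), "tax04")
  tab2 <- taxa_table(tab$counts[, keep])
  res_sub <- suppressWarnings(screen_taxa(tab2, meta_fail, spec, min_p = 0.2))
  t_all <- fixed_table(res_all)
  t_keep <- t_all[t_all$taxon != "tax04", ]
  rownames(t_keep) <- NULL
  expect_identical(t_keep, fixed_table(res_sub))
})

test_that("screening is deterministic across repeated runs", {
  sim <- simulate_zinbmm(sim_truth(n_subjects = 15, p_zero = 0.3, m = 3, seed = 4))
  spec <- model_spec(~ group, ~ 1 | subject, method = "zinb")
  r1 <- screen_taxa(sim$table, sim$meta, spec)
  r2 <- screen_taxa(sim$table, sim$meta, spec)
  expect_identical(fixed_table(r1), fixed_table(r2))
})

test_that("fixed_table has one row per taxon, term and part", {
  sim <- simulate_zinbmm(sim_truth(n_subjects = 15, p_zero = 0.3, m = 2, seed = 4))
  spec <- model_spec(~ group + time, ~ 1 | subject, method = "zinb")
  res <- screen_taxa(sim$table, sim$meta, spec)
  tab <- fixed_table(res)
  n_fit <- length(res$fits)
  # 3 count terms + 1 zero-part intercept per fitted taxon
  expect_equal(nrow(tab), n_fit * 4L)
  expect_setequal(unique(tab$part), c("count", "zero"))
  expect_equal(sum(tab$part == "zero"), n_fit)
})

test_that("get_fixed slices one covariate and validates its name", {
  sim <- simulate_nbmm(sim_truth(n_subjects = 15, m = 3, seed = 2))
  spec <- model_spec(~ group + time, ~ 1 | subject, method = "nb")
  res <- screen_taxa(sim$table, sim$meta, spec)
  gf <- get_fixed(res, "group")
  expect_equal(nrow(gf), length(res$fits))
  expect_named(gf, c("taxon", "estimate", "se", "pvalue"))
  expect_error(get_fixed(res, "pregnant"), "available terms")
})

test_that("BH adjustment applies the step-up rule within each term", {
  tab <- data.frame(taxon = c("a", "b", "c"), term = "g", part = "count",
                    estimate = 1, se = 1, pvalue = c(0.01, 0.02, 0.03),
                    converged = TRUE)
  adj <- adjust_pvalues(tab, "BH")
  expect_equal(adj$adjusted, c(0.03, 0.03, 0.03))
  none <- adjust_pvalues(tab, "none")
  expect_identical(none$adjusted, none$pvalue)
  one <- adjust_pvalues(tab[1, ], "BH")
  expect_equal(one$adjusted, one$pvalue)

  # adjustment is per term: an unrelated term does not change the first
  tab2 <- rbind(tab, transform(tab, term = "h", pvalue = c(0.2, 0.5, 0.9)))
  adj2 <- adjust_pvalues(tab2, "BH")
  expect_equal(adj2$adjusted[1:3], c(0.03, 0.03, 0.03))
})
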