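test_that("window counting conserves reads and respects bins", {
  region <- list(chrom = "chr1", start = 0L, end = 400L)
  none <- window_counts(integer(0), region, 20)
  expect_equal(nrow(none), 20L)
  expect_true(all(none$count == 0L))

  reads <- rep(seq(1L, 400L, by = 10L), each = 1L)  # 40 uniform reads
  prof <- window_counts(reads, region, 20)
  expect_equal(nrow(prof), 20L)
  expect_equal(sum(prof$count), 40L)
  expect_true(all(prof$count == 2L))

  stacked <- window_counts(rep(101L, 17L), region, 20)
  expect_equal(sum(stacked$count > 0), 1L)
  expect_equal(max(stacked$count), 17L)
  expect_error(window_counts(1L, region, 0), "positive")
})

test_that("a sample tested against copies of itself yields no calls", {
  panel <- build_panel(toy_genes(), 50)
  cov <- flat_coverage(panel, 120L)
  calls <- detect_deletions(cov, list(cov, cov, cov), panel)
  expect_equal(nrow(calls), 0L)
})

test_that("reference count and grid contracts are enforced", {
  panel <- build_panel(toy_genes(), 50)
  cov <- flat_coverage(panel, 120L)
  expect_error(detect_deletions(cov, list(cov, cov), panel), "at least 3")
  shifted <- dplyr::mutate(cov, start = start + 1L)
  expect_error(detect_deletions(cov, list(cov, cov, shifted), panel),
               "same window grid")
})

test_that("an isolated zero window is not called (run too short)", {
  panel <- build_panel(toy_genes(), 50)
  ref <- flat_coverage(panel, 12L)
  test <- ref
  test$count[5] <- 0L
  calls <- detect_deletions(test, list(ref, ref, ref), panel)
  expect_equal(nrow(calls), 0L)
  # oracle: enumerate maximal zero runs and check none reaches min_run
  runs <- rle(test$count == 0L)
  expect_lt(max(runs$lengths[runs$values]), cnv_params()$min_run)
})

test_that("a multi-exon loss is called with exactly its affected targets", {
  panel <- build_panel(toy_genes(), 50)
  ref <- flat_coverage(panel, 150L)
  test <- ref
  lost <- grepl("^ALPHA_ex[12]", panel_windows(panel, 20)$target)
  test$count[lost] <- 0L
  calls <- detect_deletions(test, list(ref, ref, ref), panel)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_targets, 2L)
  expect_equal(calls$targets, "ALPHA_ex1,ALPHA_ex2")
  w <- panel_windows(panel, 20)
  expect_equal(calls$core_start, min(w$start[lost]))
  expect_equal(calls$core_end, max(w$end[lost]))
})

test_that("extra references are subsampled reproducibly with the seed", {
  panel <- build_panel(toy_genes(), 50)
  refs <- lapply(c(100L, 120L, 140L, 160L, 180L), function(k) {
    flat_coverage(panel, k)
  })
  cov <- flat_coverage(panel, 120L)
  c1 <- detect_deletions(cov, refs, panel, seed = 5)
  c2 <- detect_deletions(cov, refs, panel, seed = 5)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("breakpoint refinement brackets without widening", {
  call <- tibble::tibble(chrom = "chrX", core_start = 1000L, core_end = 2000L,
                         n_targets = 1L, targets = "G_ex1",
                         bp_upstream_start = 0L, bp_upstream_end = 1000L,
                         bp_downstream_start = 2000L,
                         bp_downstream_end = 5000L,
                         copy_state = "hemizygous_or_homozygous_loss")
  unchanged <- refine_breakpoints(call, integer(0))
  expect_equal(as.data.frame(unchanged), as.data.frame(call))

  ot <- tibble::tibble(chrom = "chrX", pos = c(700L, 900L, 2501L, 3001L))
  refined <- refine_breakpoints(call, ot)
  expect_equal(refined$bp_upstream_start, 899L)   # innermost upstream read
  expect_equal(refined$bp_downstream_end, 2500L)  # innermost downstream read
  # never widen: a read outside the current interval cannot push it out
  far <- tibble::tibble(chrom = "chrX", pos = c(10L, 9000L))
  refined2 <- refine_breakpoints(refined, far)
  expect_gte(refined2$bp_upstream_start, refined$bp_upstream_start)
  expect_lte(refined2$bp_downstream_end, refined$bp_downstream_end)
})

test_that("sex inference separates one from two X copies", {
  panel <- build_panel(toy_genes(), 50)
  female <- flat_coverage(panel, 100L)
  male <- dplyr::mutate(female,
                        count = ifelse(chrom == "chrX", 50L, count))
  expect_equal(infer_sex(female)$sex, "female")
  expect_equal(infer_sex(male)$sex, "male")
  self <- infer_sex(female, female_reference = female)
  expect_equal(self$sex, "female")
  expect_equal(self$ratio, 1)
  no_x <- dplyr::filter(female, chrom != "chrX")
  expect_error(infer_sex(no_x), "no chrX windows")
})

test_that("coverage tables round-trip through TSV", {
  panel <- build_panel(toy_genes(), 50)
  cov <- flat_coverage(panel, 77L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coverage(cov, path)
  expect_equal(as.data.frame(read_coverage(path)), as.data.frame(cov))
})
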