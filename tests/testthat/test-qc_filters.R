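test_that("validity requires both strands and the 3x coverage floor", {
  expect_false(is_valid(pile(depth = 30L, alt_fwd = 5L, alt_rev = 0L)))
  expect_true(is_valid(pile(depth = 3L, alt_fwd = 2L, alt_rev = 1L,
                            mapq = 25L, consensus_qual = 20L,
                            variant_qual = 20L)))
  expect_false(is_valid(pile(depth = 2L, alt_fwd = 1L, alt_rev = 1L)))
})

test_that("validity enforces the three quality floors inclusively", {
  base <- pile(depth = 30L, alt_fwd = 10L, alt_rev = 10L)
  expect_true(is_valid(base))
  expect_false(is_valid(dplyr::mutate(base, mapq = 24L)))
  expect_false(is_valid(dplyr::mutate(base, consensus_qual = 19L)))
  expect_false(is_valid(dplyr::mutate(base, variant_qual = 19L)))
  expect_true(is_valid(dplyr::mutate(base, mapq = 25L,
                                     consensus_qual = 20L,
                                     variant_qual = 20L)))
})

test_that("homozygosity boundary sits strictly above 80%", {
  expect_equal(call_zygosity(pile(depth = 100L, alt_fwd = 41L,
                                  alt_rev = 40L)), "homozygous")
  expect_equal(call_zygosity(pile(depth = 100L, alt_fwd = 40L,
                                  alt_rev = 40L)), "heterozygous")
  # full sweep over alt counts at fixed depth: the boundary is exact
  zyg <- vapply(0:100, function(a) {
    call_zygosity(pile(depth = 100L, alt_fwd = as.integer(ceiling(a / 2)),
                       alt_rev = as.integer(floor(a / 2))))
  }, character(1))
  expect_equal(max(which(zyg == "heterozygous")) - 1L, 80L)
  expect_equal(min(which(zyg == "homozygous")) - 1L, 81L)
})

test_that("male chrX homozygous-fraction calls are hemizygous", {
  x <- pile(chrom = "chrX", depth = 100L, alt_fwd = 48L, alt_rev = 47L)
  expect_equal(call_zygosity(x, sex = "male"), "hemizygous")
  expect_equal(call_zygosity(x, sex = "female"), "homozygous")
  auto <- pile(chrom = "chr5", depth = 100L, alt_fwd = 48L, alt_rev = 47L)
  expect_equal(call_zygosity(auto, sex = "male"), "homozygous")
  expect_error(call_zygosity(pile(depth = 0L, alt_fwd = 0L, alt_rev = 0L)),
               "depth 0")
})

test_that("zygosity is monotone in the alt fraction", {
  fracs <- seq(0.05, 1, by = 0.05)
  zyg <- vapply(fracs, function(f) {
    call_zygosity(pile(depth = 200L, alt_fwd = as.integer(100 * f),
                       alt_rev = as.integer(100 * f)))
  }, character(1))
  hom <- zyg == "homozygous"
  expect_true(all(diff(hom) >= 0))  # never homozygous -> heterozygous
})

test_that("benign removal spares clinically pathogenic variants", {
  v <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "G",
                      clinical_significance = c(NA, "pathogenic", NA))
  benign <- v[1:2, c("chrom", "pos", "ref", "alt")]
  out <- remove_known_benign(v, benign)
  expect_equal(out$pos, c(20L, 30L))
  expect_equal(remove_known_benign(v, benign[0, ]), v)
})

test_that("false-positive flag fires strictly below 25% or 8 reads", {
  expect_true(flag_probable_false_positive(
    pile(depth = 40L, alt_fwd = 4L, alt_rev = 3L)))   # 17.5%, 7 reads
  expect_false(flag_probable_false_positive(
    pile(depth = 32L, alt_fwd = 4L, alt_rev = 4L)))   # exactly 25%, 8 reads
  expect_false(flag_probable_false_positive(
    pile(depth = 40L, alt_fwd = 10L, alt_rev = 10L)))
  expect_true(flag_probable_false_positive(
    pile(depth = 20L, alt_fwd = 4L, alt_rev = 3L)))   # 35% but 7 reads
})

test_that("filters are vectorized, order-independent and idempotent", {
  withr::with_seed(42, {
    n <- 200
    p <- pile(depth = sample(0:60, n, replace = TRUE) + 3L)
    p$alt_fwd <- vapply(p$depth, function(d) sample(0:d, 1), integer(1))
    p$alt_rev <- pmin(p$depth - p$alt_fwd,
                      sample(0:20, n, replace = TRUE))
    p$mapq <- sample(20:60, n, replace = TRUE)
    ok <- is_valid(p)
    shuffle <- sample(n)
    expect_equal(is_valid(p[shuffle, ]), ok[shuffle])
    kept <- p[ok, ]
    expect_equal(is_valid(kept), rep(TRUE, nrow(kept)))
  })
})

test_that("threshold config round-trips through the key:value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# panel thresholds", "min_coverage: 5",
               "homozygous_fraction: 0.9"), path)
  t <- read_filter_config(path)
  expect_equal(t$min_coverage, 5)
  expect_equal(t$homozygous_fraction, 0.9)
  expect_equal(t$fp_min_alt_reads, 8)  # untouched default
  writeLines("not_a_key: 1", path)
  expect_error(read_filter_config(path), "unknown filter config key")
  expect_error(filter_thresholds(homozygous_fraction = 1),
               "strictly between")
})
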