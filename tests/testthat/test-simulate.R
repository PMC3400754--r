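test_that("the same seed yields byte-identical simulations", {
  spec <- simulation_spec(seed = 21, sample_id = "A", sex = "male",
                          decoy_variant_count = 40)
  expect_identical(simulate_patient(spec), simulate_patient(spec))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_patient_files(simulate_patient(spec), d1)
  write_patient_files(simulate_patient(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("implanted homozygous variants show the constructed alt fraction", {
  iv <- tibble::tibble(gene = "GENE001", category = "nonsense",
                       zygosity = "homozygous", alt_fraction = 0.98)
  sim <- simulate_patient(simulation_spec(seed = 22, implanted_variants = iv,
                                          decoy_variant_count = 10))
  imp <- sim$truth$implanted_variants
  row <- dplyr::semi_join(sim$pileup, imp, by = c("chrom", "pos"))
  expect_equal(nrow(row), 1L)
  expect_gt((row$alt_fwd + row$alt_rev) / row$depth, 0.80)
  expect_true(is_valid(row))
})

test_that("an implanted deletion zeroes its exons and drops its variants", {
  del <- list(gene = "GENE004", exon_from = 1, exon_to = 3)
  sim <- simulate_patient(simulation_spec(seed = 23, sex = "male",
                                          implanted_deletion = del,
                                          decoy_variant_count = 150))
  truth <- sim$truth$implanted_deletion
  lost <- sim$coverage$chrom == truth$chrom &
    sim$coverage$start >= truth$del_start &
    sim$coverage$end <= truth$del_end
  expect_gt(sum(lost), 0)
  expect_true(all(sim$coverage$count[lost] == 0L))
  inside <- sim$pileup$chrom == truth$chrom &
    sim$pileup$pos - 1L >= truth$del_start &
    sim$pileup$pos - 1L < truth$del_end
  expect_equal(sum(inside), 0L)
  # off-target reads never fall inside the deletion
  ot_inside <- sim$off_target$chrom == truth$chrom &
    sim$off_target$pos - 1L >= truth$del_start &
    sim$off_target$pos - 1L < truth$del_end
  expect_equal(sum(ot_inside), 0L)
  expect_error(
    simulate_patient(simulation_spec(seed = 1, implanted_deletion = list(
      gene = "GENE004", exon_from = 1, exon_to = 999))),
    "nonexistent exon")
})

test_that("male samples halve chrX coverage; cohorts share one grid", {
  specs <- lapply(1:4, function(i) {
    simulation_spec(seed = 30 + i, sample_id = paste0("S", i),
                    sex = if (i <= 2) "male" else "female",
                    decoy_variant_count = 0)
  })
  coh <- make_cohort(specs)
  grids <- lapply(coh$samples, function(s) {
    s$coverage[, c("chrom", "start", "end")]
  })
  for (g in grids[-1]) expect_equal(as.data.frame(g), as.data.frame(grids[[1]]))
  sexes <- vapply(coh$samples, function(s) infer_sex(s$coverage)$sex,
                  character(1))
  expect_equal(unname(sexes), c("male", "male", "female", "female"))
  expect_error(make_cohort(specs[1]), "at least 4")
})

test_that("GC effect induces a negative coverage-GC rank correlation", {
  big <- simulate_gene_models(n_genes = 40, seed = 77)
  sim <- simulate_patient(simulation_spec(seed = 77, gc_effect = TRUE,
                                          decoy_variant_count = 0),
                          gene_models = big)
  cov <- sim$coverage
  expect_gt(nrow(cov), 1000)
  rho <- stats::cor(cov$gc, cov$count, method = "spearman")
  expect_lt(rho, 0)
})

test_that("implants surviving their own filters reach the ranked output", {
  iv <- tibble::tibble(gene = c("GENE002", "GENE002"),
                       category = c("frameshift", "missense"),
                       zygosity = c("heterozygous", "heterozygous"),
                       alt_fraction = c(0.45, 0.52),
                       exon = c(1, 2))
  spec <- simulation_spec(seed = 41, sample_id = "T",
                          implanted_variants = iv,
                          decoy_variant_count = 60)
  sim <- simulate_patient(spec)
  joined <- dplyr::inner_join(sim$pileup, sim$annotations,
                              by = c("chrom", "pos", "ref", "alt"))
  candidates <- prepare_candidates(joined, sex = "female",
                                   benign_keys = sim$benign_keys)
  surviving <- dplyr::semi_join(sim$truth$implanted_variants, candidates,
                                by = c("chrom", "pos"))
  expect_equal(nrow(surviving), 2L)
  cls <- sim$disease_table$disease_classes[[
    which(sim$disease_table$gene == "GENE002")]]
  pat <- patient_context("T", "female", cls, "AR")
  ranked <- rank_patient(candidates, pat, sim$disease_table)
  top <- primary_candidates(ranked, "gene")[1, ]
  expect_equal(top$gene, "GENE002")
  expect_equal(top$zygosity, "compound_heterozygous")
})
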