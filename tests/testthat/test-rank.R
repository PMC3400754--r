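toy_table <- function() {
  disease_gene_table(
    gene = c("MYOA", "MYOB", "NEURO", "XLG"),
    disease_classes = list("Congenital myopathies", "Congenital myopathies",
                           "Hereditary neuropathies",
                           "Congenital myopathies"),
    inheritance_modes = list(c("AD", "AR"), "AR", "AD", "XL"))
}

test_that("recessive aggregation adds the top two het scores", {
  expect_equal(aggregate_gene_recessive(c(90, 50),
                                        rep("heterozygous", 2)), 140)
  expect_equal(aggregate_gene_recessive(90, "homozygous"), 180)
  expect_equal(aggregate_gene_recessive(c(90, 50, 40),
                                        rep("heterozygous", 3)), 140)
  expect_equal(aggregate_gene_recessive(60, "heterozygous"), 60)
  expect_error(aggregate_gene_recessive(numeric(0), character(0)), "empty")
})

test_that("recessive aggregation equals brute force on random instances", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(1:6, 1)
      scores <- sample(10:200, n, replace = TRUE)
      zyg <- sample(c("heterozygous", "homozygous", "hemizygous"), n,
                    replace = TRUE, prob = c(0.7, 0.2, 0.1))
      expect_equal(aggregate_gene_recessive(scores, zyg),
                   brute_force_gene_score(scores, zyg))
    }
  })
})

test_that("inheritance matching follows allele-configuration rules", {
  expect_false(match_inheritance("heterozygous", "AR", "AR", "female"))
  expect_true(match_inheritance(c("heterozygous", "heterozygous"),
                                "AR", "AR", "female"))
  expect_true(match_inheritance("homozygous", "AR", "AR", "female"))
  expect_true(match_inheritance("hemizygous", "XL", "XL", "male"))
  expect_false(match_inheritance("hemizygous", "XL", "XL", "female"))
  expect_true(match_inheritance("heterozygous", "XL", "XL", "female"))
  expect_true(match_inheritance("heterozygous", "AD", "AD", "male"))
  expect_false(match_inheritance("heterozygous", "AR", "AD", "female"))
  expect_true(match_inheritance("heterozygous", "AR", "unknown", "female"))
})

test_that("in-class pathogenic-weighted variants outrank out-of-class ones", {
  v <- dplyr::bind_rows(
    cand("MYOA", "synonymous", "heterozygous", pos = 10L,
         clinical_significance = "pathogenic"),
    cand("NEURO", "nonsense", "heterozygous", pos = 20L))
  pat <- patient_context("P", "female", "Congenital myopathies", "AD")
  r <- rank_patient(v, pat, toy_table())
  prim <- primary_candidates(r, level = "variant")
  expect_equal(prim$gene[1], "MYOA")
  expect_equal(prim$rank[1], 1L)
  sec <- dplyr::filter(r, list == "secondary")
  expect_equal(sec$gene, "NEURO")
})

test_that("out-of-class variants land in the secondary list, never dropped", {
  v <- cand("NEURO", "missense", "heterozygous", pos = 5L)
  pat <- patient_context("P", "female", "Congenital myopathies", "AD")
  r <- rank_patient(v, pat, toy_table())
  expect_equal(nrow(dplyr::filter(r, list == "primary")), 0L)
  expect_equal(nrow(dplyr::filter(r, list == "secondary")), 1L)
})

test_that("compound-het genes outrank single hets under AR", {
  v <- dplyr::bind_rows(
    cand("MYOB", "essential_splice", "heterozygous", pos = 10L),
    cand("MYOB", "missense", "heterozygous", pos = 20L),
    cand("MYOA", "nonsense", "heterozygous", pos = 30L))
  pat <- patient_context("P", "female", "Congenital myopathies", "AR")
  r <- rank_patient(v, pat, toy_table())
  prim <- primary_candidates(r, level = "gene")
  expect_equal(prim$gene, c("MYOB", "MYOA"))
  expect_equal(prim$score, c(140, 100))
  expect_equal(prim$zygosity[1], "compound_heterozygous")
  expect_true(prim$inheritance_compatible[1])
  expect_false(prim$inheritance_compatible[2])  # single het under AR
})

test_that("unknown inheritance emits both variant and gene views", {
  v <- dplyr::bind_rows(
    cand("MYOA", "missense", "heterozygous", pos = 1L),
    cand("MYOA", "nonsense", "heterozygous", pos = 2L))
  pat <- patient_context("P", "female", "Congenital myopathies", "unknown")
  r <- rank_patient(v, pat, toy_table())
  expect_setequal(unique(r$level), c("variant", "gene"))
  expect_true(all(r$inheritance_compatible))
})

test_that("ranking is invariant to input row order and ties break by name", {
  v <- dplyr::bind_rows(
    cand("MYOB", "missense", "heterozygous", pos = 50L),
    cand("MYOA", "missense", "heterozygous", pos = 60L),
    cand("MYOA", "nonsense", "heterozygous", pos = 70L))
  pat <- patient_context("P", "female", "Congenital myopathies", "AD")
  r1 <- rank_patient(v, pat, toy_table())
  withr::with_seed(1, {
    for (i in 1:5) {
      r2 <- rank_patient(v[sample(nrow(v)), ], pat, toy_table())
      expect_equal(as.data.frame(r2), as.data.frame(r1))
    }
  })
  # equal scores: MYOA before MYOB lexicographically
  tied <- dplyr::filter(r1, score == 50)
  expect_equal(tied$gene, c("MYOA", "MYOB"))
})

test_that("genes missing from the panel table are flagged, not fatal", {
  v <- cand("NOVEL1", "nonsense", "heterozygous", pos = 9L)
  pat <- patient_context("P", "female", "Congenital myopathies", "AD")
  r <- rank_patient(v, pat, toy_table())
  expect_false(r$in_panel_table[1])
  expect_equal(r$list[1], "secondary")
  expect_error(rank_patient(v, pat, toy_table()[0, ]), "empty")
})
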