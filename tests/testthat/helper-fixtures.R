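# Shared in-code fixtures: tiny gene models, pileup row builders, and
# brute-force oracles used by the property tests.

toy_genes <- function() {
  tibble::tribble(
    ~gene,   ~chrom,  ~strand, ~exon_number, ~start, ~end,
    "ALPHA", "chr1",  "+",     1L,           1000L,  1100L,
    "ALPHA", "chr1",  "+",     2L,           3000L,  3150L,
    "ALPHA", "chr1",  "+",     3L,           5000L,  5080L,
    "BETA",  "chr2",  "-",     1L,           200L,   420L,
    "BETA",  "chr2",  "-",     2L,           9000L,  9200L,
    "XGENE", "chrX",  "+",     1L,           4000L,  4180L)
}

pile <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                 depth = 30L, alt_fwd = 10L, alt_rev = 10L, mapq = 40L,
                 consensus_qual = 40L, variant_qual = 40L) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 depth = depth, alt_fwd = alt_fwd, alt_rev = alt_rev,
                 mapq = mapq, consensus_qual = consensus_qual,
                 variant_qual = variant_qual)
}

# Variant rows ready for rank_patient(): minimal annotated candidates.
cand <- function(gene, category, zygosity, chrom = "chr1", pos = 100L,
                 ref = "A", alt = "G", phastcons = NA_real_,
                 sift = NA_real_, polyphen = NA_real_,
                 splice_delta = NA_real_,
                 clinical_significance = NA_character_) {
  tibble::tibble(gene = gene, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, effect_category = category,
                 zygosity = zygosity, phastcons = phastcons, sift = sift,
                 polyphen = polyphen, splice_delta = splice_delta,
                 clinical_significance = clinical_significance)
}

# Independent oracle for recessive gene aggregation: enumerate every valid
# allele pair (a homozygous/hemizygous variant doubled, or two distinct
# heterozygous variants) and take the best sum; a lone heterozygous variant
# scores itself.
brute_force_gene_score <- function(scores, zygosity) {
  best <- -Inf
  n <- length(scores)
  for (i in seq_len(n)) {
    if (zygosity[i] %in% c("homozygous", "hemizygous")) {
      best <- max(best, 2 * scores[i])
    }
    for (j in seq_len(n)) {
      if (i < j && zygosity[i] == "heterozygous" &&
          zygosity[j] == "heterozygous") {
        best <- max(best, scores[i] + scores[j])
      }
    }
  }
  if (is.infinite(best)) best <- max(scores)
  best
}

# Brute-force panel membership: is 0-based position p within flank of any
# exon of the gene set?
covered_by_exons <- function(p, chrom, genes, flank) {
  any(genes$chrom == chrom & p >= genes$start - flank & p < genes$end + flank)
}

panel_covers <- function(panel, chrom, p) {
  any(panel$chrom == chrom & p >= panel$start & p < panel$end)
}

# A flat coverage grid over a toy panel for CNV tests.
flat_coverage <- function(panel, count = 100L, sample_id = "S",
                          window_nt = 20) {
  w <- paneldx::panel_windows(panel, window_nt)
  tibble::tibble(sample = sample_id, chrom = w$chrom, start = w$start,
                 end = w$end, count = rep(as.integer(count), nrow(w)))
}
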