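#' Variant filter thresholds
#'
#' The decision boundaries applied to pileup evidence before ranking. The
#' defaults are the published diagnostic values: a valid variant must be
#' seen on both strands with at least 3x total coverage, site mapping
#' quality at least 25, consensus quality at least 20 and variant (SNV or
#' indel) quality at least 20; a call is homozygous when the alternate
#' allele is carried by strictly more than 80% of reads; and a call is
#' flagged as a probable false positive when the alternate fraction is
#' strictly below 25% or the alternate read count is strictly below 8.
#'
#' @param min_coverage Minimum total read depth (default 3, inclusive).
#' @param min_mapping_quality Minimum site mapping quality (default 25,
#'   inclusive).
#' @param min_consensus_quality Minimum consensus quality (default 20,
#'   inclusive).
#' @param min_variant_quality Minimum SNV/indel quality (default 20,
#'   inclusive).
#' @param homozygous_fraction Alternate-allele fraction above which (strict
#'   `>`) a call is homozygous (default 0.80; must lie in (0, 1)).
#' @param fp_min_alt_fraction Alternate fraction below which (strict `<`) a
#'   call is flagged as probable false positive (default 0.25).
#' @param fp_min_alt_reads Alternate read count below which (strict `<`) a
#'   call is flagged (default 8).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_coverage = 3,
                              min_mapping_quality = 25,
                              min_consensus_quality = 20,
                              min_variant_quality = 20,
                              homozygous_fraction = 0.80,
                              fp_min_alt_fraction = 0.25,
                              fp_min_alt_reads = 8) {
  t <- list(min_coverage = min_coverage,
            min_mapping_quality = min_mapping_quality,
            min_consensus_quality = min_consensus_quality,
            min_variant_quality = min_variant_quality,
            homozygous_fraction = homozygous_fraction,
            fp_min_alt_fraction = fp_min_alt_fraction,
            fp_min_alt_reads = fp_min_alt_reads)
  if (any(map_dbl(t, identity) < 0)) {
    abort("all filter thresholds must be non-negative")
  }
  if (homozygous_fraction <= 0 || homozygous_fraction >= 1) {
    abort("homozygous_fraction must lie strictly between 0 and 1")
  }
  structure(t, class = "filter_thresholds")
}

check_pileup <- function(pileup) {
  pileup <- as_tibble(pileup)
  required <- c("chrom", "pos", "ref", "alt", "depth", "alt_fwd", "alt_rev",
                "mapq", "consensus_qual", "variant_qual")
  missing_cols <- setdiff(required, names(pileup))
  if (length(missing_cols) > 0) {
    abort(paste0("pileup lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- c(pileup$depth, pileup$alt_fwd, pileup$alt_rev,
              pileup$mapq, pileup$consensus_qual, pileup$variant_qual)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("pileup counts and qualities must be non-negative")
  }
  if (any(pileup$alt_fwd + pileup$alt_rev > pileup$depth, na.rm = TRUE)) {
    abort("alt_fwd + alt_rev may not exceed depth")
  }
  pileup
}

#' Variant validity filter
#'
#' A variant is valid when it is supported by at least one read on each
#' strand, total depth meets the coverage floor, and the three quality
#' floors hold. Applied per site; order-independent and idempotent.
#'
#' @param pileup Pileup tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_fwd`, `alt_rev`, `mapq`, `consensus_qual`,
#'   `variant_qual`.
#' @param thresholds A [filter_thresholds()] object.
#' @return Logical vector, one element per pileup row.
#' @examples
#' p <- tibble::tibble(chrom = "chr1", pos = 100, ref = "A", alt = "G",
#'                     depth = 3, alt_fwd = 2, alt_rev = 1, mapq = 25,
#'                     consensus_qual = 20, variant_qual = 20)
#' is_valid(p)  # TRUE: boundary case passes every floor
#' @export
is_valid <- function(pileup, thresholds = filter_thresholds()) {
  pileup <- check_pileup(pileup)
  pileup$alt_fwd >= 1 &
    pileup$alt_rev >= 1 &
    pileup$depth >= thresholds$min_coverage &
    pileup$mapq >= thresholds$min_mapping_quality &
    pileup$consensus_qual >= thresholds$min_consensus_quality &
    pileup$variant_qual >= thresholds$min_variant_quality
}

#' Call zygosity from the alternate-allele fraction
#'
#' Homozygous when the alternate fraction strictly exceeds the configured
#' fraction (default 0.80), heterozygous otherwise. For a male sample a
#' homozygous-fraction call on chrX is reported as hemizygous (one X copy);
#' female chrX calls are treated as autosomal. Pseudoautosomal regions are
#' not special-cased.
#'
#' @inheritParams is_valid
#' @param sex `"male"` or `"female"`.
#' @return Character vector: `"heterozygous"`, `"homozygous"` or
#'   `"hemizygous"`.
#' @export
call_zygosity <- function(pileup, thresholds = filter_thresholds(),
                          sex = c("female", "male")) {
  sex <- match.arg(sex)
  pileup <- check_pileup(pileup)
  if (any(pileup$depth == 0)) {
    abort("cannot call zygosity at depth 0")
  }
  frac <- (pileup$alt_fwd + pileup$alt_rev) / pileup$depth
  hom <- frac > thresholds$homozygous_fraction
  zyg <- ifelse(hom, "homozygous", "heterozygous")
  if (sex == "male") {
    on_x <- pileup$chrom %in% c("chrX", "X")
    zyg[hom & on_x] <- "hemizygous"
  }
  zyg
}

#' Remove validated benign variants
#'
#' Drops variants whose `(chrom, pos, ref, alt)` key appears in a set of
#' validated non-pathogenic polymorphisms (e.g. compiled from population
#' databases), except variants annotated as pathogenic or probably
#' pathogenic, which are always retained: healthy carriers put true
#' mutations in population databases too.
#'
#' @param variants Annotated variant tibble (must carry `chrom`, `pos`,
#'   `ref`, `alt` and optionally `clinical_significance`).
#' @param benign_keys Data frame of benign keys with columns `chrom`,
#'   `pos`, `ref`, `alt`.
#' @return The filtered variant tibble.
#' @export
remove_known_benign <- function(variants, benign_keys) {
  variants <- as_tibble(variants)
  benign_keys <- as_tibble(benign_keys)
  if (nrow(benign_keys) == 0 || nrow(variants) == 0) return(variants)
  keyed <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  benign <- keyed %in% paste(benign_keys$chrom, benign_keys$pos,
                             benign_keys$ref, benign_keys$alt)
  clin <- if ("clinical_significance" %in% names(variants)) {
    variants$clinical_significance
  } else {
    rep(NA_character_, nrow(variants))
  }
  keep_pathogenic <- !is.na(clin) &
    clin %in% c("pathogenic", "probably_pathogenic")
  variants[!benign | keep_pathogenic, , drop = FALSE]
}

#' Flag probable false positives
#'
#' A validity-passing variant is still flagged for orthogonal (Sanger)
#' confirmation when the alternate fraction is strictly below 25% or the
#' alternate read count is strictly below 8. The flag annotates; it never
#' deletes.
#'
#' @inheritParams is_valid
#' @return Logical vector, one element per pileup row.
#' @export
flag_probable_false_positive <- function(pileup,
                                         thresholds = filter_thresholds()) {
  pileup <- check_pileup(pileup)
  if (any(pileup$depth == 0)) {
    abort("cannot compute alt fraction at depth 0")
  }
  alt <- pileup$alt_fwd + pileup$alt_rev
  alt / pileup$depth < thresholds$fp_min_alt_fraction |
    alt < thresholds$fp_min_alt_reads
}

#' Read filter thresholds from a key:value config file
#'
#' Plain-text `key: value` lines (YAML-subset); unknown keys are an error,
#' missing keys keep their defaults.
#'
#' @param path Config file path.
#' @return A [filter_thresholds()] object.
#' @export
read_filter_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- map_chr(kv, ~ trimws(.x[1]))
  vals <- map_dbl(kv, ~ as.numeric(trimws(.x[2])))
  known <- names(formals(filter_thresholds))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    abort(paste0("unknown filter config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(filter_thresholds, as.list(setNames(vals, keys)))
}
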