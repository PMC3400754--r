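#' Read variant calls with pileup evidence and annotations
#'
#' Joins three sources keyed by `(chrom, pos, ref, alt)`: a VCF with the
#' variant calls, a strand-resolved pileup TSV with the supporting read
#' evidence (standard VCF depth fields are not strand-resolved, hence the
#' sidecar), and an annotation TSV carrying the per-variant scores consumed
#' by ranking (gene, effect category, conservation, protein-effect and
#' splice scores, clinical significance). Every VCF record must have pileup
#' evidence; annotations are optional per variant and missing score fields
#' stay missing (`NA`), never 0.
#'
#' @param vcf_path VCF 4.x file (plain text).
#' @param pileup_path Pileup TSV with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_fwd`, `alt_rev`, `mapq`, `consensus_qual`,
#'   `variant_qual`.
#' @param annotation_path Annotation TSV with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `effect_category`, `dbsnp_id`,
#'   `clinical_significance`, `phastcons`, `sift`, `polyphen`,
#'   `splice_delta`.
#' @return A tibble with one row per VCF record, pileup and annotation
#'   columns joined on. Annotation rows that match no VCF record are
#'   reported in a warning and attached as the `"unmatched_annotations"`
#'   attribute.
#' @export
read_variants <- function(vcf_path, pileup_path, annotation_path) {
  calls <- read_vcf_calls(vcf_path)
  pileup <- check_pileup(read_pileup(pileup_path))
  anno <- read_annotations(annotation_path)

  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  for (nm in c("calls", "pileup", "anno")) {
    d <- get(nm)
    if (anyDuplicated(key(d))) {
      dup <- key(d)[duplicated(key(d))]
      abort(paste0("duplicate ", nm, " key(s): ",
                   paste(unique(dup), collapse = ", ")))
    }
  }
  missing_ev <- setdiff(key(calls), key(pileup))
  if (length(missing_ev) > 0) {
    abort(paste0("VCF record(s) lacking pileup evidence: ",
                 paste(missing_ev, collapse = ", ")))
  }
  out <- calls |>
    inner_join(pileup, by = c("chrom", "pos", "ref", "alt")) |>
    left_join(anno, by = c("chrom", "pos", "ref", "alt"))
  unmatched <- anno[!key(anno) %in% key(calls), , drop = FALSE]
  if (nrow(unmatched) > 0) {
    warn(paste0(nrow(unmatched), " annotation row(s) match no VCF record"))
  }
  attr(out, "unmatched_annotations") <- unmatched
  out
}

read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble(chrom = fix$CHROM,
         pos = as.integer(fix$POS),
         id = ifelse(fix$ID %in% c(".", ""), NA_character_, fix$ID),
         ref = fix$REF,
         alt = fix$ALT)
}

#' @rdname read_variants
#' @export
read_pileup <- function(pileup_path) {
  readr::read_tsv(pileup_path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                          .default = "d")) |>
    mutate(pos = as.integer(.data$pos))
}

#' @rdname read_variants
#' @export
read_annotations <- function(annotation_path) {
  readr::read_tsv(annotation_path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", ref = "c", alt = "c", gene = "c",
                    effect_category = "c", dbsnp_id = "c",
                    clinical_significance = "c", .default = "d")) |>
    mutate(pos = as.integer(.data$pos))
}

#' Read a benign-variant key set from TSV
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A tibble of keys for [remove_known_benign()].
#' @export
read_benign_keys <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                          pos = "i"))
}

ranked_table_cols <- c("list", "level", "rank", "gene", "chrom", "pos",
                       "ref", "alt", "effect_category", "zygosity",
                       "score", "in_disease_class",
                       "inheritance_compatible", "in_panel_table",
                       "probable_false_positive", "variants")

#' Write and read a ranked candidate table
#'
#' TSV serialization of a ranking result. Row order is the deterministic
#' rank order produced by [rank_patient()]; missing values are written as
#' `NA` and survive a round trip as missing.
#'
#' @param candidates A ranked-candidate tibble (see [rank_patient()]).
#' @param path Destination TSV.
#' @return `path` invisibly; [read_ranked_table()] returns the tibble.
#' @export
write_ranked_table <- function(candidates, path) {
  candidates <- as_tibble(candidates)
  cols <- intersect(ranked_table_cols, names(candidates))
  readr::write_tsv(candidates[, cols], path)
  invisible(path)
}

#' @rdname write_ranked_table
#' @export
read_ranked_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    list = "c", level = "c", gene = "c", chrom = "c",
                    ref = "c", alt = "c", effect_category = "c",
                    zygosity = "c", variants = "c",
                    in_disease_class = "l", inheritance_compatible = "l",
                    in_panel_table = "l", probable_false_positive = "l",
                    .default = "d")) |>
    mutate(across(any_of(c("rank", "pos")), as.integer))
}
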