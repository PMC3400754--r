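#' Patient context for ranking
#'
#' @param sample_id Sample identifier.
#' @param sex `"male"` or `"female"`.
#' @param disease_classes Character vector of clinical disease classes; a
#'   patient whose phenotype fits several classes lists them all and every
#'   gene of every listed class is considered.
#' @param inheritance `"AD"`, `"AR"`, `"XL"` or `"unknown"` (no
#'   segregation filter).
#' @return A list of class `patient_context`.
#' @export
patient_context <- function(sample_id, sex = c("female", "male"),
                            disease_classes,
                            inheritance = c("unknown", "AD", "AR", "XL")) {
  sex <- match.arg(sex)
  inheritance <- match.arg(inheritance)
  if (length(disease_classes) == 0) {
    abort("a patient must list at least one disease class")
  }
  structure(list(sample_id = sample_id, sex = sex,
                 disease_classes = disease_classes,
                 inheritance = inheritance),
            class = "patient_context")
}

#' Build or read the gene / disease-class / inheritance table
#'
#' One row per panel gene: its disease classes and its known transmission
#' modes (AD, AR, XL). The TSV form uses semicolon-separated class and mode
#' lists.
#'
#' @param gene Character vector of gene symbols (unique).
#' @param disease_classes List of character vectors (one per gene, each
#'   non-empty), or a semicolon-separated character vector.
#' @param inheritance_modes As `disease_classes`, values among AD/AR/XL.
#' @return A tibble with list-columns `disease_classes` and
#'   `inheritance_modes`.
#' @export
disease_gene_table <- function(gene, disease_classes, inheritance_modes) {
  split_semi <- function(x) {
    if (is.list(x)) x else strsplit(as.character(x), ";", fixed = TRUE)
  }
  tbl <- tibble(gene = gene,
                disease_classes = split_semi(disease_classes),
                inheritance_modes = split_semi(inheritance_modes))
  if (anyDuplicated(tbl$gene)) abort("gene symbols must be unique")
  if (any(lengths(tbl$disease_classes) == 0)) {
    abort("every gene needs at least one disease class")
  }
  bad <- setdiff(unlist(tbl$inheritance_modes), c("AD", "AR", "XL"))
  if (length(bad) > 0) {
    abort(paste0("unknown inheritance mode(s): ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' @rdname disease_gene_table
#' @param path TSV with columns `gene`, `disease_classes`,
#'   `inheritance_modes` (semicolon-separated).
#' @export
read_disease_gene_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ccc")
  disease_gene_table(d$gene, d$disease_classes, d$inheritance_modes)
}

#' Aggregate variant scores within a gene under recessive segregation
#'
#' Under recessive segregation a diagnosis needs two mutated alleles, so
#' per-gene evidence is the best valid allele pair: a homozygous (or
#' hemizygous) variant supplies both alleles and counts twice, while two
#' distinct heterozygous variants (compound heterozygote) have their scores
#' added. With more than two heterozygous variants only the two
#' highest-scoring are summed; extra low-scoring hets are treated as noise.
#' A gene with a single heterozygous variant scores that variant alone but
#' cannot be recessive-compatible.
#'
#' @param scores Numeric vector of variant scores in one gene.
#' @param zygosity Matching character vector (`heterozygous`, `homozygous`,
#'   `hemizygous`).
#' @return The gene score (numeric scalar).
#' @export
aggregate_gene_recessive <- function(scores, zygosity) {
  if (length(scores) == 0) abort("cannot aggregate an empty variant list")
  if (length(scores) != length(zygosity)) {
    abort("scores and zygosity must have equal length")
  }
  two_allele <- zygosity %in% c("homozygous", "hemizygous")
  best <- -Inf
  if (any(two_allele)) best <- 2 * max(scores[two_allele])
  het <- sort(scores[zygosity == "heterozygous"], decreasing = TRUE)
  if (length(het) >= 2) best <- max(best, het[1] + het[2])
  if (is.infinite(best)) best <- max(scores)  # single het: its own score
  best
}

#' Match a gene's allele configuration against an inheritance mode
#'
#' Compatible when the patient's inheritance mode is among the gene's known
#' transmission modes and the observed allele configuration can produce
#' disease under that mode: AD needs at least one heterozygous variant; AR
#' needs a homozygous variant or at least two heterozygous ones (compound
#' het); XL needs a hemizygous variant in a male or a heterozygous one in a
#' female (carrier or manifesting). Unknown inheritance never filters.
#'
#' @param zygosity Character vector of the gene's variant zygosities.
#' @param gene_modes Character vector of the gene's transmission modes.
#' @param inheritance Patient inheritance (`AD`/`AR`/`XL`/`unknown`).
#' @param sex Patient sex.
#' @return Logical scalar.
#' @export
match_inheritance <- function(zygosity, gene_modes, inheritance, sex) {
  if (inheritance == "unknown") return(TRUE)
  if (!inheritance %in% gene_modes) return(FALSE)
  n_het <- sum(zygosity == "heterozygous")
  switch(inheritance,
         AD = n_het >= 1,
         AR = any(zygosity == "homozygous") || n_het >= 2,
         XL = (sex == "male" && any(zygosity == "hemizygous")) ||
              (sex == "female" && n_het >= 1))
}

#' Rank a patient's candidate variants and genes
#'
#' The core prioritization step. Input variants are assumed to have passed
#' the validity filter and benign removal; each must carry `gene`,
#' `effect_category`, `zygosity` and coordinates. All variants are scored
#' ([score_variants()]); under recessive segregation (and when inheritance
#' is unknown) per-gene compound-heterozygote aggregation is applied
#' ([aggregate_gene_recessive()]), with unknown inheritance emitting both
#' the variant-level and the gene-level view. Candidates in genes whose
#' disease classes intersect the patient's go to the primary list;
#' out-of-class candidates are demoted to a secondary list rather than
#' discarded, since informative variants are occasionally found outside a
#' strict class match. Within each list (and level) candidates are sorted
#' by score, ties broken lexicographically by gene, chromosome and
#' position, and assigned dense 1-based ranks.
#'
#' @param variants Scored or scorable variant tibble (validity-filtered,
#'   benign-removed).
#' @param patient A [patient_context()].
#' @param table A [disease_gene_table()]; must be non-empty.
#' @param config A [scoring_config()].
#' @return A tibble of class `ranked_candidates` with columns `list`
#'   (primary/secondary), `level` (variant/gene), `rank`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `effect_category`, `zygosity`, `score`,
#'   `in_disease_class`, `inheritance_compatible`, `in_panel_table`,
#'   `probable_false_positive`, `n_variants`, `variants`.
#' @export
rank_patient <- function(variants, patient, table, config = scoring_config()) {
  stopifnot(inherits(patient, "patient_context"))
  table <- as_tibble(table)
  if (nrow(table) == 0) abort("the disease-gene table is empty")
  variants <- as_tibble(variants)
  for (nm in c("gene", "effect_category", "zygosity", "chrom", "pos")) {
    if (!nm %in% names(variants)) {
      abort(paste0("variants must carry a '", nm, "' column"))
    }
  }
  if (!"score" %in% names(variants)) {
    variants <- score_variants(variants, config)
  }
  if (!"probable_false_positive" %in% names(variants)) {
    variants$probable_false_positive <-
      if (all(c("depth", "alt_fwd", "alt_rev") %in% names(variants)) &&
          nrow(variants) > 0) {
        flag_probable_false_positive(variants)
      } else {
        rep(NA, nrow(variants))
      }
  }
  if (!"ref" %in% names(variants)) variants$ref <- NA_character_
  if (!"alt" %in% names(variants)) variants$alt <- NA_character_

  gene_info <- variants |>
    distinct(.data$gene) |>
    left_join(table, by = "gene") |>
    mutate(in_panel_table = !map_lgl(.data$disease_classes, is.null),
           in_disease_class = map_lgl(.data$disease_classes, function(cl) {
             !is.null(cl) && length(intersect(cl, patient$disease_classes)) > 0
           }))

  gene_compat <- variants |>
    group_by(.data$gene) |>
    summarise(zygs = list(.data$zygosity), .groups = "drop") |>
    left_join(gene_info, by = "gene") |>
    mutate(inheritance_compatible = pmap(
      list(.data$zygs, .data$inheritance_modes),
      function(z, m) match_inheritance(z, m %||% character(),
                                       patient$inheritance, patient$sex)) |>
      map_lgl(isTRUE) | patient$inheritance == "unknown")

  variant_level <- variants |>
    left_join(select(gene_compat, "gene", "in_panel_table",
                     "in_disease_class", "inheritance_compatible"),
              by = "gene") |>
    mutate(level = "variant", n_variants = 1L,
           variants = paste0(.data$chrom, ":", .data$pos, ":",
                             .data$ref, ">", .data$alt)) |>
    select("level", "gene", "chrom", "pos", "ref", "alt",
           "effect_category", "zygosity", "score", "in_disease_class",
           "inheritance_compatible", "in_panel_table",
           "probable_false_positive", "n_variants", "variants")

  gene_level <- variants |>
    group_by(.data$gene) |>
    arrange(desc(.data$score), .data$chrom, .data$pos, .by_group = TRUE) |>
    summarise(gene_score = aggregate_gene_recessive(.data$score,
                                                    .data$zygosity),
              gene_zygosity = gene_zygosity_label(.data$score,
                                                  .data$zygosity),
              variants = paste0(.data$chrom, ":", .data$pos, ":",
                                .data$ref, ">", .data$alt, collapse = ";"),
              chrom = first(.data$chrom), pos = min(.data$pos),
              effect_category = first(.data$effect_category),
              probable_false_positive = any(.data$probable_false_positive),
              n_variants = n(),
              .groups = "drop") |>
    mutate(level = "gene", ref = NA_character_, alt = NA_character_,
           score = .data$gene_score, zygosity = .data$gene_zygosity) |>
    left_join(select(gene_compat, "gene", "in_panel_table",
                     "in_disease_class", "inheritance_compatible"),
              by = "gene") |>
    select(all_of(names(variant_level)))

  out <- switch(patient$inheritance,
                AR = gene_level,
                unknown = bind_rows(variant_level, gene_level),
                bind_rows(variant_level))
  out <- out |>
    mutate(score = as.numeric(.data$score),
           list = if_else(.data$in_disease_class, "primary", "secondary")) |>
    group_by(.data$list, .data$level) |>
    arrange(desc(.data$score), .data$gene, .data$chrom, .data$pos,
            .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    arrange(desc(.data$list == "primary"), .data$level, .data$rank) |>
    select("list", "level", "rank", everything())
  attr(out, "patient") <- patient
  class(out) <- c("ranked_candidates", class(out))
  out
}

# Label the allele configuration backing a gene-level score.
gene_zygosity_label <- function(scores, zygosity) {
  two_allele <- zygosity %in% c("homozygous", "hemizygous")
  het <- sort(scores[zygosity == "heterozygous"], decreasing = TRUE)
  best_hom <- if (any(two_allele)) 2 * max(scores[two_allele]) else -Inf
  best_pair <- if (length(het) >= 2) het[1] + het[2] else -Inf
  if (best_hom == -Inf && best_pair == -Inf) return("heterozygous")
  if (best_hom >= best_pair) {
    zyg <- zygosity[two_allele][which.max(scores[two_allele])]
    return(zyg)
  }
  "compound_heterozygous"
}

#' Extract the primary candidate list
#'
#' @param ranked A [rank_patient()] result.
#' @param level Candidate level to keep (`"gene"`, `"variant"` or both).
#' @return The primary-list rows in rank order.
#' @export
primary_candidates <- function(ranked, level = c("gene", "variant")) {
  ranked |>
    filter(.data$list == "primary", .data$level %in% !!level) |>
    arrange(.data$rank)
}
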