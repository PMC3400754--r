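#' Tidy a ranking result
#'
#' Returns the ranked candidates as a plain tibble, primary list first,
#' in rank order.
#'
#' @param x A `ranked_candidates` object from [rank_patient()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ranked_candidates <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ranked_candidates")
  out
}

#' @rdname tidy.ranked_candidates
#' @exportS3Method generics::glance
glance.ranked_candidates <- function(x, ...) {
  patient <- attr(x, "patient")
  prim <- x[x$list == "primary", , drop = FALSE]
  top <- prim[which.max(prim$score), , drop = FALSE]
  tibble(sample_id = patient$sample_id %||% NA_character_,
         inheritance = patient$inheritance %||% NA_character_,
         n_candidates = nrow(x),
         n_primary = nrow(prim),
         top_gene = if (nrow(top) > 0) top$gene else NA_character_,
         top_score = if (nrow(top) > 0) top$score else NA_integer_,
         top_compatible = if (nrow(top) > 0) top$inheritance_compatible else NA)
}

#' Tidy deletion calls
#'
#' @param x A `deletion_calls` object from [detect_deletions()].
#' @param ... Unused.
#' @return A tibble, one row per call.
#' @exportS3Method generics::tidy
tidy.deletion_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "deletion_calls")
  out
}

#' @rdname tidy.deletion_calls
#' @exportS3Method generics::glance
glance.deletion_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         n_targets = sum(x$n_targets),
         total_core_nt = sum(x$core_end - x$core_start))
}

#' Per-patient diagnostic report
#'
#' Summarises a ranking result (and optional deletion calls) as a
#' diagnosis shortlist: one row per top-ranked candidate with gene,
#' mutation, zygosity and class/inheritance match, mirroring the shape of
#' a clinical results table.
#'
#' @param ranked A [rank_patient()] result.
#' @param deletions Optional [detect_deletions()] result.
#' @param top_n Candidates reported from the primary list (default 5).
#' @return A tibble.
#' @export
report_patient <- function(ranked, deletions = NULL, top_n = 5) {
  patient <- attr(ranked, "patient")
  rows <- ranked |>
    filter(.data$list == "primary") |>
    arrange(.data$level, .data$rank) |>
    group_by(.data$level) |>
    slice_head(n = top_n) |>
    ungroup() |>
    transmute(sample_id = patient$sample_id, finding = "variant",
              gene = .data$gene, mutation = .data$variants,
              category = .data$effect_category, zygosity = .data$zygosity,
              score = as.numeric(.data$score), rank = .data$rank,
              level = .data$level,
              in_disease_class = .data$in_disease_class,
              inheritance_compatible = .data$inheritance_compatible)
  if (!is.null(deletions) && nrow(deletions) > 0) {
    del_rows <- as_tibble(deletions) |>
      transmute(sample_id = patient$sample_id, finding = "deletion",
                gene = sub("_ex.*$", "", sub(",.*$", "", .data$targets)),
                mutation = paste0(.data$chrom, ":", .data$core_start, "-",
                                  .data$core_end, " (", .data$n_targets,
                                  " targets)"),
                category = "large_deletion", zygosity = .data$copy_state,
                score = NA_real_, rank = NA_integer_, level = "gene",
                in_disease_class = NA, inheritance_compatible = NA)
    rows <- bind_rows(rows, del_rows)
  }
  rows
}
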