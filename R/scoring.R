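#' Mutation categories in decreasing order of a-priori severity
#'
#' The category ladder used for ranking: nonsense, frameshift, essential
#' splice site (the invariant consensus intronic positions), start loss,
#' stop loss, missense, predicted splice-site change (outside the consensus
#' sites), in-frame indel, synonymous coding.
#'
#' @export
effect_categories <- c("nonsense", "frameshift", "essential_splice",
                       "start_loss", "stop_loss", "missense",
                       "predicted_splice", "inframe_indel", "synonymous")

#' Variant scoring configuration
#'
#' Base scores encode the category ladder ([effect_categories]); only the
#' ordering is prescribed by diagnostic practice, the integer magnitudes
#' are package defaults and fully configurable. Scores are modulated by
#' additive bonuses: conservation (phastCons at or above
#' `phastcons_conserved`), protein-effect predictions (SIFT damaging when
#' low, PolyPhen damaging when high; applied to missense variants only),
#' and a splice bonus for synonymous or predicted-splice variants whose
#' relative splice-score loss reaches `splice_loss_threshold`. Variants
#' with pathogenic or probably-pathogenic clinical significance receive
#' `pathogenic_weight`, which must exceed any achievable unweighted score
#' so that known mutations always rise to the top.
#'
#' @param base_scores Named integer vector over [effect_categories],
#'   strictly decreasing along the ladder.
#' @param conservation_bonus Added when `phastcons >= phastcons_conserved`.
#' @param phastcons_conserved Conservation threshold in `[0, 1]`.
#' @param damaging_bonus Added once for SIFT-damaging and once for
#'   PolyPhen-damaging missense variants.
#' @param sift_damaging_max SIFT scores strictly below this are damaging
#'   (low = damaging).
#' @param polyphen_damaging_min PolyPhen scores at or above this are
#'   damaging (high = damaging).
#' @param splice_loss_threshold Relative splice-score loss that triggers
#'   the splice bonus.
#' @param splice_bonus Added to synonymous / predicted-splice variants with
#'   a qualifying splice loss.
#' @param pathogenic_weight Added for (probably) pathogenic clinical
#'   significance.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(base_scores = c(nonsense = 100L, frameshift = 95L,
                                           essential_splice = 90L,
                                           start_loss = 80L, stop_loss = 75L,
                                           missense = 50L,
                                           predicted_splice = 45L,
                                           inframe_indel = 30L,
                                           synonymous = 10L),
                           conservation_bonus = 5L,
                           phastcons_conserved = 0.95,
                           damaging_bonus = 5L,
                           sift_damaging_max = 0.05,
                           polyphen_damaging_min = 0.85,
                           splice_loss_threshold = 0.10,
                           splice_bonus = 20L,
                           pathogenic_weight = 200L) {
  if (!setequal(names(base_scores), effect_categories)) {
    abort("base_scores must name exactly the known effect categories")
  }
  ladder <- unname(base_scores[effect_categories])
  if (any(diff(ladder) >= 0)) {
    abort("base_scores must strictly decrease along the category ladder")
  }
  max_unweighted <- max(base_scores) + conservation_bonus +
    2L * damaging_bonus + splice_bonus
  if (pathogenic_weight <= max_unweighted) {
    abort(paste0("pathogenic_weight must exceed the maximum achievable ",
                 "unweighted score (", max_unweighted, ")"))
  }
  structure(list(base_scores = base_scores,
                 conservation_bonus = conservation_bonus,
                 phastcons_conserved = phastcons_conserved,
                 damaging_bonus = damaging_bonus,
                 sift_damaging_max = sift_damaging_max,
                 polyphen_damaging_min = polyphen_damaging_min,
                 splice_loss_threshold = splice_loss_threshold,
                 splice_bonus = splice_bonus,
                 pathogenic_weight = pathogenic_weight),
            class = "scoring_config")
}

#' Score annotated variants
#'
#' Computes the per-variant score: category base score plus additive
#' bonuses (conservation; SIFT/PolyPhen damaging, missense only; splice
#' loss, synonymous and predicted-splice only) plus the pathogenic weight
#' for clinically flagged variants. Missing annotation scores contribute
#' nothing: no bonus, no penalty.
#'
#' @param variants Tibble with `effect_category` and (optionally)
#'   `phastcons`, `sift`, `polyphen`, `splice_delta`,
#'   `clinical_significance` columns; missing columns are treated as
#'   all-missing.
#' @param config A [scoring_config()].
#' @return The input tibble with an integer `score` column added.
#' @export
score_variants <- function(variants, config = scoring_config()) {
  variants <- as_tibble(variants)
  if (!"effect_category" %in% names(variants)) {
    abort("variants must carry an effect_category column")
  }
  bad <- setdiff(unique(variants$effect_category), effect_categories)
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0 || any(is.na(variants$effect_category))) {
    abort(paste0("unknown effect category: ",
                 paste(c(bad, if (any(is.na(variants$effect_category))) "NA"),
                       collapse = ", ")))
  }
  col <- function(nm) {
    if (nm %in% names(variants)) variants[[nm]] else rep(NA_real_, nrow(variants))
  }
  phast <- col("phastcons"); sift <- col("sift"); poly <- col("polyphen")
  sdelta <- col("splice_delta")
  clin <- if ("clinical_significance" %in% names(variants)) {
    variants$clinical_significance
  } else rep(NA_character_, nrow(variants))

  base <- unname(config$base_scores[variants$effect_category])
  conserved <- !is.na(phast) & phast >= config$phastcons_conserved
  is_missense <- variants$effect_category == "missense"
  sift_dmg <- is_missense & !is.na(sift) & sift < config$sift_damaging_max
  poly_dmg <- is_missense & !is.na(poly) & poly >= config$polyphen_damaging_min
  spliceable <- variants$effect_category %in% c("synonymous", "predicted_splice")
  splice_hit <- spliceable & !is.na(sdelta) &
    sdelta >= config$splice_loss_threshold
  pathogenic <- !is.na(clin) & clin %in% c("pathogenic", "probably_pathogenic")

  score <- base +
    config$conservation_bonus * conserved +
    config$damaging_bonus * (sift_dmg + poly_dmg) +
    config$splice_bonus * splice_hit +
    config$pathogenic_weight * pathogenic
  variants$score <- as.integer(score)
  variants
}
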