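# Position frequency matrices for canonical splice sites, compiled from the
# classic mammalian consensus frequency tables. Donor window: 9 nt spanning
# the last 3 exonic and first 6 intronic bases (GT at intron positions
# +1/+2). Acceptor window: 23 nt spanning the last 20 intronic bases
# (polypyrimidine tract ending in AG) and the first 3 exonic bases.
donor_pfm <- function() {
  m <- matrix(c(
    # -3   -2   -1   +1   +2   +3   +4   +5   +6
    0.33, 0.61, 0.10, 0.00, 0.00, 0.53, 0.71, 0.07, 0.16,  # A
    0.37, 0.13, 0.04, 0.00, 0.00, 0.03, 0.08, 0.06, 0.16,  # C
    0.18, 0.12, 0.79, 1.00, 0.00, 0.42, 0.12, 0.81, 0.22,  # G
    0.12, 0.14, 0.07, 0.00, 1.00, 0.02, 0.09, 0.06, 0.46   # T
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

acceptor_pfm <- function() {
  tract <- c(A = 0.10, C = 0.31, G = 0.10, T = 0.49)  # polypyrimidine bias
  m <- matrix(tract, nrow = 4, ncol = 23,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[, 17] <- c(0.24, 0.31, 0.21, 0.24)  # -4
  m[, 18] <- c(0.04, 0.74, 0.01, 0.21)  # -3
  m[, 19] <- c(1.00, 0.00, 0.00, 0.00)  # -2 (invariant A)
  m[, 20] <- c(0.00, 0.00, 1.00, 0.00)  # -1 (invariant G)
  m[, 21] <- c(0.24, 0.15, 0.50, 0.11)  # +1
  m[, 22] <- c(0.28, 0.22, 0.25, 0.25)  # +2
  m[, 23] <- c(0.25, 0.25, 0.25, 0.25)  # +3
  m
}

#' Score a splice-site context with the bundled position-weight matrix
#'
#' The bundled scorer covers donor sites (9-nt window: 3 exonic + 6
#' intronic bases) and acceptor sites (23-nt window: 20 intronic + 3 exonic
#' bases), chosen by window length. The score is the geometric mean over
#' positions of the observed base's frequency relative to the most frequent
#' base at that position (pseudocount 0.001), so a perfect consensus scores
#' 1 and disrupting an invariant position (e.g. the GT donor dinucleotide)
#' collapses the score.
#'
#' @param context A single DNA string of length 9 (donor) or 23 (acceptor).
#' @return A score in `[0, 1]`.
#' @export
splice_pwm_score <- function(context) {
  context <- toupper(context)
  bases <- strsplit(context, "", fixed = TRUE)[[1]]
  pfm <- switch(as.character(length(bases)),
                "9" = donor_pfm(),
                "23" = acceptor_pfm(),
                abort("splice context must be 9 nt (donor) or 23 nt (acceptor)"))
  if (!all(bases %in% rownames(pfm))) {
    abort("splice context may only contain A/C/G/T")
  }
  eps <- 1e-3
  f <- pfm[cbind(match(bases, rownames(pfm)), seq_along(bases))]
  fmax <- apply(pfm, 2, max)
  exp(mean(log((f + eps) / (fmax + eps))))
}

#' Maximum relative splice-score loss across scorers
#'
#' Compares a reference and an alternate splice-site context under one or
#' more scoring functions and returns the worst relative loss,
#' `max(0, (score_ref - score_alt) / score_ref)`, taken over scorers (0
#' when no scorer yields a positive reference score). Scorers are pluggable
#' functions mapping a context string to a non-negative score; the bundled
#' PWM scorer is the default. External donor/acceptor tools can be plugged
#' in as additional functions.
#'
#' @param ref_context,alt_context Equal-length DNA strings windowed around
#'   the same donor (9 nt) or acceptor (23 nt) site.
#' @param scorers List of scoring functions (default: the bundled PWM).
#' @return The maximum relative loss, in `[0, 1]`.
#' @examples
#' ref <- "CAGGTAAGT"
#' alt <- "CAGATAAGT"  # GT -> AT at the invariant donor dinucleotide
#' splice_delta(ref, alt)
#' @export
splice_delta <- function(ref_context, alt_context,
                         scorers = list(splice_pwm_score)) {
  if (nchar(ref_context) != nchar(alt_context)) {
    abort("ref and alt splice contexts must have equal length")
  }
  if (length(scorers) == 0) return(0)
  losses <- map_dbl(scorers, function(f) {
    r <- f(ref_context)
    if (!is.finite(r) || r <= 0) return(0)
    max(0, (r - f(alt_context)) / r)
  })
  max(losses)
}
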