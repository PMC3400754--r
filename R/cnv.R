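#' CNV detection parameters
#'
#' Window-based deletion calling compares a test sample's fixed-width
#' window read counts against the median of (by default exactly three)
#' reference samples on the same grid, after library-size normalization.
#' The window size (20 nt) and three-reference comparison follow the
#' published design; the remaining thresholds are package defaults
#' validated by simulation and fully configurable.
#'
#' @param window_nt Window width in nucleotides (default 20).
#' @param n_references References used per test sample (default 3; chosen
#'   with a seeded RNG when more are supplied).
#' @param min_informative Minimum reference median raw count for a window
#'   to be informative (default 10).
#' @param loss_ratio Normalized test/reference ratio at or below which an
#'   informative window is a loss window (default 0.15; a hemizygous or
#'   homozygous full loss has ratio ~0).
#' @param min_run Minimum number of loss windows in a run (default 5);
#'   suppresses isolated capture-noise windows.
#' @param gap_windows Runs separated by fewer than this many non-loss
#'   windows are merged (default 3).
#' @return A list of class `cnv_params`.
#' @export
cnv_params <- function(window_nt = 20, n_references = 3, min_informative = 10,
                       loss_ratio = 0.15, min_run = 5, gap_windows = 3) {
  if (window_nt <= 0) abort("window_nt must be positive")
  if (n_references < 3) abort("at least 3 reference samples are required")
  structure(list(window_nt = window_nt, n_references = n_references,
                 min_informative = min_informative, loss_ratio = loss_ratio,
                 min_run = min_run, gap_windows = gap_windows),
            class = "cnv_params")
}

#' Count read starts in fixed-width windows
#'
#' Tiles a region with consecutive non-overlapping windows and counts the
#' reads whose start position falls in each window (a read belongs to
#' exactly one window, so counts are conserved).
#'
#' @param read_positions Integer vector of 1-based read start positions.
#' @param region A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window_nt Window width (default 20).
#' @param sample_id Sample label recorded on the profile.
#' @return A coverage tibble (`sample`, `chrom`, `start`, `end`, `count`).
#' @export
window_counts <- function(read_positions, region, window_nt = 20,
                          sample_id = "sample") {
  if (window_nt <= 0) abort("window_nt must be positive")
  region <- as.list(region)
  starts <- seq(region$start, region$end - 1L, by = window_nt)
  ends <- pmin(starts + window_nt, region$end)
  # read at 1-based position p occupies 0-based coordinate p - 1
  p0 <- read_positions - 1L
  p0 <- p0[p0 >= region$start & p0 < region$end]
  idx <- findInterval(p0, starts)
  tibble(sample = sample_id, chrom = region$chrom,
         start = as.integer(starts), end = as.integer(ends),
         count = as.integer(tabulate(idx, nbins = length(starts))))
}

check_same_grid <- function(test, refs) {
  grid <- function(d) paste(d$chrom, d$start, d$end)
  g0 <- grid(test)
  for (r in refs) {
    if (!identical(grid(r), g0)) {
      abort("coverage profiles do not share the same window grid")
    }
  }
}

coverage_total <- function(profile) {
  tot <- attr(profile, "total_mapped_reads")
  if (is.null(tot)) tot <- sum(profile$count)
  if (tot <= 0) abort("coverage profile has no mapped reads")
  tot
}

#' Detect large deletions from window coverage
#'
#' Per window, the normalized ratio is the test sample's library-normalized
#' count divided by the median library-normalized count of the reference
#' samples. Informative windows (reference median raw count at or above
#' `min_informative`) whose ratio falls at or below `loss_ratio` are loss
#' windows; runs of at least `min_run` consecutive loss windows (merging
#' runs separated by fewer than `gap_windows` windows) that overlap at
#' least one panel target become deletion calls. Each call reports the
#' affected targets, the core lost interval, and conservative breakpoint
#' intervals stretching to the nearest flanking window still showing
#' coverage (refine with [refine_breakpoints()] using off-target reads).
#'
#' @param test Coverage tibble for the test sample (`sample`, `chrom`,
#'   `start`, `end`, `count`), windows in grid order.
#' @param references List of coverage tibbles on the same grid (at least
#'   3). When more than `n_references` are supplied, exactly
#'   `n_references` are drawn with the seeded RNG.
#' @param panel A panel tibble of target intervals ([build_panel()]).
#' @param params A [cnv_params()].
#' @param seed RNG seed used only for reference selection (default 1).
#' @return A tibble of class `deletion_calls`: `chrom`, `core_start`,
#'   `core_end`, `n_targets`, `targets` (comma-separated labels),
#'   `bp_upstream_start`, `bp_upstream_end`, `bp_downstream_start`,
#'   `bp_downstream_end`, `copy_state`.
#' @export
detect_deletions <- function(test, references, panel,
                             params = cnv_params(), seed = 1) {
  test <- as_tibble(test)
  if (!is.list(references) || is.data.frame(references)) {
    abort("references must be a list of coverage tibbles")
  }
  if (length(references) < params$n_references) {
    abort(paste0("need at least ", params$n_references,
                 " reference samples, got ", length(references)))
  }
  if (length(references) > params$n_references) {
    pick <- withr::with_seed(seed,
      sample(seq_along(references), params$n_references))
    references <- references[pick]
  }
  check_same_grid(test, references)

  t_norm <- test$count / coverage_total(test)
  ref_norm <- map(references, ~ .x$count / coverage_total(.x))
  ref_norm_med <- apply(do.call(cbind, ref_norm), 1, median)
  ref_raw_med <- apply(do.call(cbind, map(references, "count")), 1, median)

  ratio <- ifelse(ref_norm_med > 0, t_norm / ref_norm_med, NA_real_)
  informative <- ref_raw_med >= params$min_informative
  loss <- informative & !is.na(ratio) & ratio <= params$loss_ratio

  calls <- list()
  for (chr in unique(test$chrom)) {
    sel <- which(test$chrom == chr)
    runs <- loss_runs(loss[sel], params$min_run, params$gap_windows)
    for (r in runs) {
      w <- test[sel[r], ]
      core_start <- min(w$start); core_end <- max(w$end)
      targets <- panel |>
        filter(.data$chrom == chr, .data$end > core_start,
               .data$start < core_end)
      if (nrow(targets) == 0) next
      before <- sel[seq_len(min(r) - 1L)]
      after <- if (max(r) < length(sel)) {
        sel[(max(r) + 1L):length(sel)]
      } else {
        integer(0)
      }
      bp_up <- if (length(before) > 0) max(test$end[before]) else 0L
      bp_down <- if (length(after) > 0) min(test$start[after]) else NA_integer_
      calls[[length(calls) + 1L]] <- tibble(
        chrom = chr, core_start = core_start, core_end = core_end,
        n_targets = nrow(targets),
        targets = paste(targets$name, collapse = ","),
        bp_upstream_start = bp_up, bp_upstream_end = core_start,
        bp_downstream_start = core_end, bp_downstream_end = bp_down,
        copy_state = "hemizygous_or_homozygous_loss")
    }
  }
  out <- if (length(calls) > 0) list_rbind(calls) else
    tibble(chrom = character(), core_start = integer(), core_end = integer(),
           n_targets = integer(), targets = character(),
           bp_upstream_start = integer(), bp_upstream_end = integer(),
           bp_downstream_start = integer(), bp_downstream_end = integer(),
           copy_state = character())
  class(out) <- c("deletion_calls", class(out))
  out
}

# Maximal runs of TRUE, merged across gaps shorter than gap_windows,
# kept when they contain at least min_run loss windows.
loss_runs <- function(loss, min_run, gap_windows) {
  r <- rle(loss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (length(idx) == 0) return(list())
  # merge adjacent loss runs separated by a short non-loss gap
  merged <- list(c(starts[idx[1]], ends[idx[1]], r$lengths[idx[1]]))
  for (i in idx[-1]) {
    last <- merged[[length(merged)]]
    gap <- starts[i] - last[2] - 1L
    if (gap < gap_windows) {
      merged[[length(merged)]] <- c(last[1], ends[i], last[3] + r$lengths[i])
    } else {
      merged[[length(merged) + 1L]] <- c(starts[i], ends[i], r$lengths[i])
    }
  }
  keep <- Filter(function(m) m[3] >= min_run, merged)
  map(keep, ~ seq(.x[1], .x[2]))
}

#' Refine deletion breakpoints with off-target reads
#'
#' Capture experiments yield sparse off-target reads; those mapping inside
#' the introns flanking a deletion bracket the true breakpoints far more
#' tightly than the exon-limited window grid. Each breakpoint interval is
#' narrowed to start (upstream) or end (downstream) at the innermost
#' off-target read still showing coverage; intervals never widen, and with
#' no informative off-target read the call is returned unchanged.
#'
#' @param calls A [detect_deletions()] result.
#' @param off_target_positions Sorted integer vector of 1-based off-target
#'   read start positions (one chromosome), or a tibble with `chrom`,
#'   `pos`.
#' @return The calls with narrowed breakpoint intervals.
#' @export
refine_breakpoints <- function(calls, off_target_positions) {
  calls <- as_tibble(calls)
  ot <- if (is.data.frame(off_target_positions)) off_target_positions else
    tibble(chrom = rep(calls$chrom[1] %||% NA_character_,
                       length(off_target_positions)),
           pos = off_target_positions)
  if (nrow(calls) == 0 || nrow(ot) == 0) return(restore_calls(calls))
  for (i in seq_len(nrow(calls))) {
    p <- sort(ot$pos[ot$chrom == calls$chrom[i]])
    up <- p[p - 1L < calls$core_start[i]]        # reads left of the lost core
    if (length(up) > 0) {
      calls$bp_upstream_start[i] <- max(calls$bp_upstream_start[i],
                                        max(up) - 1L)
    }
    down <- p[p - 1L >= calls$core_end[i]]       # reads right of the lost core
    if (length(down) > 0) {
      new_end <- min(down) - 1L
      old <- calls$bp_downstream_end[i]
      calls$bp_downstream_end[i] <- if (is.na(old)) new_end else
        min(old, new_end)
    }
  }
  restore_calls(calls)
}

restore_calls <- function(calls) {
  class(calls) <- unique(c("deletion_calls", class(calls)))
  calls
}

#' Infer sample sex from chrX coverage
#'
#' Compares per-window mean chrX coverage with per-window mean autosomal
#' coverage (or with a known-female reference profile when supplied, after
#' library-size normalization). One X copy halves the expectation, so the
#' ratio classifies as male in (0.3, 0.7], female in (0.7, 1.3], and
#' `"unclassified"` outside both bands.
#'
#' @param test Coverage tibble for the test sample.
#' @param female_reference Optional coverage tibble of a known female on
#'   the same grid.
#' @return A list with `sex` (`"male"`, `"female"` or `"unclassified"`)
#'   and `ratio`.
#' @export
infer_sex <- function(test, female_reference = NULL) {
  test <- as_tibble(test)
  on_x <- test$chrom %in% c("chrX", "X")
  if (!any(on_x)) abort("no chrX windows in the coverage profile")
  if (is.null(female_reference)) {
    if (all(on_x)) abort("no autosomal windows to normalize against")
    ratio <- mean(test$count[on_x]) / mean(test$count[!on_x])
  } else {
    check_same_grid(test, list(female_reference))
    ref_x <- female_reference$count[on_x] / coverage_total(female_reference)
    ratio <- mean(test$count[on_x] / coverage_total(test)) / mean(ref_x)
  }
  sex <- if (ratio > 0.3 && ratio <= 0.7) "male" else
    if (ratio > 0.7 && ratio <= 1.3) "female" else "unclassified"
  list(sex = sex, ratio = ratio)
}

#' Read / write window coverage tables
#'
#' TSV columns: `sample`, `chrom`, `start`, `end`, `count`.
#'
#' @param path TSV file path.
#' @return A coverage tibble ([read_coverage()]); `path` invisibly
#'   ([write_coverage()]).
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample = "c", chrom = "c",
                                          start = "i", end = "i",
                                          count = "i"))
}

#' @rdname read_coverage
#' @param coverage A coverage tibble.
#' @export
write_coverage <- function(coverage, path) {
  readr::write_tsv(as_tibble(coverage), path)
  invisible(path)
}
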