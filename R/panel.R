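#' Validate a gene-model table
#'
#' A gene model is a tidy table of exons: one row per exon with the gene
#' symbol, chromosome, strand, 1-based exon number (in transcript order) and
#' 0-based half-open genomic coordinates. All interval arithmetic in the
#' package uses BED conventions (0-based, half-open), so exon `start` is the
#' first base and `end` is one past the last.
#'
#' @param genes A data frame with columns `gene`, `chrom`, `strand`,
#'   `exon_number`, `start`, `end`.
#' @return The input as a validated tibble, sorted by gene and exon number.
#' @export
validate_gene_models <- function(genes) {
  genes <- as_tibble(genes)
  required <- c("gene", "chrom", "strand", "exon_number", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene models lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    abort("gene model strand must be '+' or '-'")
  }
  if (any(genes$start >= genes$end)) {
    abort("every exon must satisfy start < end (0-based half-open)")
  }
  dup <- genes |>
    count(.data$gene, .data$exon_number) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated exon numbers within gene(s): ",
                 paste(unique(dup$gene), collapse = ", ")))
  }
  # exons of one gene must not overlap each other once sorted
  ovl <- genes |>
    arrange(.data$gene, .data$start) |>
    group_by(.data$gene) |>
    filter(.data$start < lag(.data$end, default = -1L)) |>
    ungroup()
  if (nrow(ovl) > 0) {
    abort(paste0("overlapping exons in gene(s): ",
                 paste(unique(ovl$gene), collapse = ", ")))
  }
  arrange(genes, .data$gene, .data$exon_number)
}

#' Build capture targets from gene models
#'
#' Each exon contributes an interval extended by `flank_nt` intronic
#' nucleotides on both sides (clipped at position 0), the design rule used
#' for exon-focused diagnostic panels: all coding exons plus the intron-exon
#' boundaries. Overlapping contributions on a chromosome are merged, and a
#' merged interval's label concatenates the labels of its parts. UTRs and
#' deep introns are excluded by construction: only supplied exon intervals
#' are used.
#'
#' @param genes Gene models (see [validate_gene_models()]).
#' @param flank_nt Intronic nucleotides added on each side of every exon
#'   (default 50). Must be non-negative.
#' @param exclude Optional data frame of intervals (`chrom`, `start`, `end`)
#'   to subtract from the panel, e.g. externally computed repeat masks.
#' @return A tibble of class `panel_tbl` with columns `chrom`, `start`,
#'   `end`, `name`; sorted and non-overlapping within each chromosome.
#' @examples
#' g <- tibble::tibble(gene = "MTM1", chrom = "chrX", strand = "+",
#'                     exon_number = 1, start = 1000, end = 1100)
#' build_panel(g, flank_nt = 50)
#' @export
build_panel <- function(genes, flank_nt = 50, exclude = NULL) {
  if (length(flank_nt) != 1 || is.na(flank_nt) || flank_nt < 0) {
    abort("flank_nt must be a single non-negative number")
  }
  genes <- validate_gene_models(genes)
  if (nrow(genes) == 0) {
    return(new_panel(tibble(chrom = character(), start = integer(),
                            end = integer(), name = character()),
                     flank_nt))
  }
  raw <- genes |>
    transmute(chrom = .data$chrom,
              start = pmax(0L, as.integer(.data$start - flank_nt)),
              end = as.integer(.data$end + flank_nt),
              name = paste0(.data$gene, "_ex", .data$exon_number))
  merged <- merge_intervals(raw)
  if (!is.null(exclude)) {
    merged <- subtract_intervals(merged, as_tibble(exclude))
  }
  new_panel(merged, flank_nt)
}

new_panel <- function(tbl, flank_nt) {
  tbl <- as_tibble(tbl)
  attr(tbl, "flank_nt") <- as.integer(flank_nt)
  class(tbl) <- c("panel_tbl", class(tbl))
  tbl
}

# Merge overlapping/touching labeled intervals per chromosome.
merge_intervals <- function(tbl) {
  tbl |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(block = cumsum(.data$start > lag(cummax(.data$end), default = -1L))) |>
    group_by(.data$chrom, .data$block) |>
    summarise(start = min(.data$start), end = max(.data$end),
              name = paste(unique(.data$name), collapse = ","),
              .groups = "drop") |>
    select("chrom", "start", "end", "name") |>
    arrange(.data$chrom, .data$start)
}

# Subtract exclusion intervals (chrom/start/end) from labeled intervals.
subtract_intervals <- function(tbl, exclude) {
  if (nrow(exclude) == 0) return(tbl)
  pieces <- pmap(tbl, function(chrom, start, end, name) {
    ex <- exclude |>
      filter(.data$chrom == !!chrom, .data$end > !!start, .data$start < !!end) |>
      arrange(.data$start)
    cur <- start
    out <- list()
    for (i in seq_len(nrow(ex))) {
      if (ex$start[i] > cur) {
        out[[length(out) + 1L]] <- tibble(chrom = chrom, start = cur,
                                          end = ex$start[i], name = name)
      }
      cur <- max(cur, ex$end[i])
    }
    if (cur < end) {
      out[[length(out) + 1L]] <- tibble(chrom = chrom, start = cur,
                                        end = end, name = name)
    }
    list_rbind(out)
  })
  list_rbind(pieces)
}

#' Write a panel as a BED file
#'
#' Four-column BED (chrom, start, end, name), 0-based half-open, tab
#' separated, no header.
#'
#' @param panel A panel tibble (`chrom`, `start`, `end`, `name`).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(panel, path) {
  readr::write_tsv(as_tibble(panel)[, c("chrom", "start", "end", "name")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file as a panel
#'
#' Accepts 3- or 4-column BED. Lines with fewer than 3 fields, non-numeric
#' coordinates, or `end <= start` are rejected with the offending line
#' number.
#'
#' @param path BED file path.
#' @param flank_nt Flank recorded on the returned panel (metadata only;
#'   BED does not carry it). Default 0.
#' @return A `panel_tbl` tibble.
#' @export
read_bed <- function(path, flank_nt = 0) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- map(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("malformed BED line ", i, ": fewer than 3 fields"))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("malformed BED line ", i, ": non-numeric coordinates"))
    }
    if (end <= start) {
      abort(paste0("malformed BED line ", i, ": end <= start"))
    }
    tibble(chrom = f[1], start = start, end = end,
           name = if (length(f) >= 4) f[4] else NA_character_)
  })
  new_panel(list_rbind(rows), flank_nt)
}

#' Read gene models from a TSV file
#'
#' Expects columns `gene`, `chrom`, `strand`, `exon_number`, `start`, `end`
#' (0-based half-open exon coordinates).
#'
#' @param path TSV file path.
#' @return A validated gene-model tibble.
#' @export
read_gene_models <- function(path) {
  validate_gene_models(readr::read_tsv(path, show_col_types = FALSE))
}
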