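#' Disease classes used by the simulator
#'
#' Sixteen clinical classes spanning the neuromuscular-disorder spectrum,
#' used to label simulated panel genes.
#' @export
nmd_disease_classes <- c(
  "Congenital myopathies", "Muscular dystrophies", "Distal myopathies",
  "Other myopathies", "Myotonic syndromes", "Ion channel muscle diseases",
  "Metabolic myopathies", "Mitochondrial myopathies",
  "Congenital myasthenic syndromes", "Motor neuron diseases",
  "Hereditary neuropathies", "Hereditary ataxias", "Hereditary paraplegias",
  "Cardiomyopathies", "Malformation syndromes", "Other NMD diseases")

#' Specify a synthetic patient
#'
#' Collects everything needed to generate one patient's inputs: panel
#' geometry, sequencing depth model, implanted (true) variants and
#' deletion, and decoy variant load. Depth is drawn from a negative
#' binomial with mean `depth_mean` and size `depth_dispersion`; the
#' default mean of 138 reads mirrors typical multiplexed panel coverage
#' and the low dispersion (size 25) reflects the narrow per-exon spread of
#' well-behaved capture experiments. Male samples receive half depth on
#' chrX. With `gc_effect` enabled, each window carries a GC fraction and a
#' monotone-decreasing coverage multiplier, emulating the qualitative
#' GC-coverage anticorrelation of capture sequencing.
#'
#' @param seed Integer RNG seed; a fixed seed yields byte-identical
#'   outputs.
#' @param sample_id Sample label.
#' @param sex `"female"` or `"male"`.
#' @param n_genes Number of simulated panel genes (default 30).
#' @param depth_mean Mean window/variant read depth (default 138).
#' @param depth_dispersion Negative-binomial size parameter (default 25).
#' @param gc_effect Emulate GC-dependent coverage (default `FALSE`).
#' @param implanted_variants Optional tibble with columns `gene`,
#'   `category`, `zygosity`, `alt_fraction` and optionally `exon`,
#'   `clinical_significance`, `phastcons`, `sift`, `polyphen`,
#'   `splice_delta`; unspecified annotation scores get category-typical
#'   defaults.
#' @param implanted_deletion Optional list `(gene, exon_from, exon_to)`:
#'   all coverage windows of those exons are zeroed and overlapping
#'   variants removed.
#' @param decoy_variant_count Number of decoy (benign-like) variants
#'   scattered over the panel (default 120).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, sample_id = "S1",
                            sex = c("female", "male"), n_genes = 30,
                            depth_mean = 138, depth_dispersion = 25,
                            gc_effect = FALSE, implanted_variants = NULL,
                            implanted_deletion = NULL,
                            decoy_variant_count = 120) {
  sex <- match.arg(sex)
  if (!is.null(implanted_variants)) {
    implanted_variants <- as_tibble(implanted_variants)
    if (any(implanted_variants$alt_fraction <= 0 |
            implanted_variants$alt_fraction > 1)) {
      abort("implanted alt fractions must lie in (0, 1]")
    }
  }
  structure(list(seed = as.integer(seed), sample_id = sample_id, sex = sex,
                 n_genes = n_genes, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, gc_effect = gc_effect,
                 implanted_variants = implanted_variants,
                 implanted_deletion = implanted_deletion,
                 decoy_variant_count = decoy_variant_count),
            class = "simulation_spec")
}

#' Simulate panel gene models
#'
#' Lays out `n_genes` genes over autosomes plus chrX (roughly one gene in
#' five is X-linked so hemizygous scenarios are always testable). Exon
#' counts default to 3-30 per gene, exon lengths 80-300 nt, intron gaps
#' 2-20 kb; pass `exon_counts` to fix per-gene exon numbers (e.g. a
#' 79-exon dystrophin-like gene).
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param exon_counts Optional integer vector (length `n_genes`) of exon
#'   counts per gene.
#' @param chroms Optional character vector (length `n_genes`) fixing each
#'   gene's chromosome.
#' @return A gene-model tibble (see [validate_gene_models()]).
#' @export
simulate_gene_models <- function(n_genes = 30, seed = 1, exon_counts = NULL,
                                 chroms = NULL) {
  withr::with_seed(seed, {
    if (is.null(exon_counts)) {
      exon_counts <- sample(3:30, n_genes, replace = TRUE)
    }
    if (is.null(chroms)) {
      chroms <- ifelse(seq_len(n_genes) %% 5 == 0, "chrX",
                       paste0("chr", 1 + (seq_len(n_genes) %% 10)))
    }
    offset <- new.env(parent = emptyenv())  # next free position per chrom
    rows <- map(seq_len(n_genes), function(i) {
      n_ex <- exon_counts[i]
      chr <- chroms[i]
      base <- get0(chr, envir = offset, ifnotfound = 100000L)
      lens <- sample(80:300, n_ex, replace = TRUE)
      gaps <- sample(2000:20000, n_ex, replace = TRUE)
      starts <- as.integer(base + cumsum(gaps) + cumsum(c(0L, head(lens, -1))))
      ends <- as.integer(starts + lens)
      assign(chr, max(ends) + 50000L, envir = offset)
      tibble(gene = sprintf("GENE%03d", i), chrom = chr,
             strand = sample(c("+", "-"), 1),
             exon_number = seq_len(n_ex),
             start = starts, end = ends)
    })
    validate_gene_models(list_rbind(rows))
  })
}

#' Simulate the gene / disease-class / inheritance table
#'
#' Assigns each gene one or two disease classes and transmission modes:
#' chrX genes are X-linked, autosomal genes dominant, recessive or both.
#'
#' @param gene_models A gene-model tibble.
#' @param seed RNG seed.
#' @return A [disease_gene_table()].
#' @export
simulate_disease_table <- function(gene_models, seed = 1) {
  g <- distinct(as_tibble(gene_models), .data$gene, .data$chrom)
  withr::with_seed(seed, {
    classes <- map(seq_len(nrow(g)), function(i) {
      sample(nmd_disease_classes, sample(1:2, 1))
    })
    modes <- map(seq_len(nrow(g)), function(i) {
      if (g$chrom[i] %in% c("chrX", "X")) "XL" else
        sample(list("AD", "AR", c("AD", "AR")), 1)[[1]]
    })
    disease_gene_table(g$gene, classes, modes)
  })
}

category_defaults <- function(category) {
  switch(category,
         missense = list(phastcons = 0.99, sift = 0.01, polyphen = 0.99,
                         splice_delta = NA_real_),
         predicted_splice = list(phastcons = 0.99, sift = NA_real_,
                                 polyphen = NA_real_, splice_delta = 0.4),
         synonymous = list(phastcons = 0.5, sift = NA_real_,
                           polyphen = NA_real_, splice_delta = NA_real_),
         list(phastcons = 0.99, sift = NA_real_, polyphen = NA_real_,
              splice_delta = NA_real_))
}

ref_alt_for <- function(category) {
  switch(category,
         frameshift = list(ref = "A", alt = "AT"),
         inframe_indel = list(ref = "AGCT", alt = "A"),
         list(ref = sample(c("A", "C", "G", "T"), 1),
              alt = NA_character_)) -> ra
  if (is.na(ra$alt)) {
    ra$alt <- sample(setdiff(c("A", "C", "G", "T"), ra$ref), 1)
  }
  ra
}

#' Simulate a complete synthetic patient
#'
#' Generates every input the pipeline consumes, mutually consistent: panel
#' BED intervals; variant calls (VCF fields) with strand-resolved pileup
#' evidence and annotations; a benign-key set covering a fraction of the
#' decoys; window coverage over all panel targets (zeroed over an
#' implanted deletion, halved on male chrX); sparse intronic off-target
#' read positions (never inside a deletion); and a truth manifest
#' recording all implants, including the deletion's exact simulated
#' breakpoints.
#'
#' @param spec A [simulation_spec()].
#' @param gene_models Optional shared gene models (default: generated from
#'   `spec$seed`).
#' @param disease_table Optional shared [disease_gene_table()].
#' @return A list of class `simulated_patient` with elements `spec`,
#'   `gene_models`, `disease_table`, `panel`, `vcf`, `pileup`,
#'   `annotations`, `benign_keys`, `coverage`, `off_target`, `truth`.
#' @export
simulate_patient <- function(spec, gene_models = NULL, disease_table = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(gene_models)) {
    gene_models <- simulate_gene_models(spec$n_genes, seed = spec$seed)
  }
  if (is.null(disease_table)) {
    disease_table <- simulate_disease_table(gene_models, seed = spec$seed)
  }
  panel <- build_panel(gene_models, flank_nt = 50)

  withr::with_seed(spec$seed, {
    deletion <- resolve_deletion(spec$implanted_deletion, gene_models)
    coverage <- simulate_coverage(spec, panel, deletion)
    variants <- simulate_variant_tables(spec, gene_models, deletion)
    off_target <- simulate_off_target(gene_models, deletion)
    truth <- list(sample_id = spec$sample_id, sex = spec$sex,
                  implanted_variants = variants$implant_truth,
                  implanted_deletion = deletion)
    structure(list(spec = spec, gene_models = gene_models,
                   disease_table = disease_table, panel = panel,
                   vcf = variants$vcf, pileup = variants$pileup,
                   annotations = variants$annotations,
                   benign_keys = variants$benign_keys,
                   coverage = coverage, off_target = off_target,
                   truth = truth),
              class = "simulated_patient")
  })
}

resolve_deletion <- function(del, gene_models) {
  if (is.null(del)) return(NULL)
  ex <- gene_models |>
    filter(.data$gene == del$gene) |>
    arrange(.data$exon_number)
  if (nrow(ex) == 0) abort(paste0("deletion gene not in panel: ", del$gene))
  if (del$exon_from < 1 || del$exon_to > max(ex$exon_number) ||
      del$exon_from > del$exon_to) {
    abort("implanted deletion references a nonexistent exon range")
  }
  first <- ex[ex$exon_number == del$exon_from, ]
  last <- ex[ex$exon_number == del$exon_to, ]
  # true breakpoints fall mid-intron, outside any capture target
  del_start <- if (del$exon_from == 1) first$start - 1000L else {
    prev <- ex[ex$exon_number == del$exon_from - 1L, ]
    as.integer((prev$end + 50L + first$start - 50L) %/% 2L)
  }
  del_end <- if (del$exon_to == max(ex$exon_number)) last$end + 1000L else {
    nxt <- ex[ex$exon_number == del$exon_to + 1L, ]
    as.integer((last$end + 50L + nxt$start - 50L) %/% 2L)
  }
  list(gene = del$gene, exon_from = del$exon_from, exon_to = del$exon_to,
       chrom = ex$chrom[1], del_start = del_start, del_end = del_end)
}

simulate_coverage <- function(spec, panel, deletion) {
  windows <- panel_windows(panel, window_nt = 20)
  mu <- rep(spec$depth_mean, nrow(windows))
  if (spec$sex == "male") {
    mu[windows$chrom %in% c("chrX", "X")] <- mu[windows$chrom %in%
                                                  c("chrX", "X")] / 2
  }
  if (spec$gc_effect) {
    gc <- runif(nrow(windows), 0.3, 0.7)
    mu <- mu * (1.75 - 1.5 * gc)
    windows$gc <- gc
  }
  count <- rnbinom(nrow(windows), mu = mu, size = spec$depth_dispersion)
  if (!is.null(deletion)) {
    lost <- windows$chrom == deletion$chrom &
      windows$start >= deletion$del_start & windows$end <= deletion$del_end
    count[lost] <- 0L
  }
  windows |>
    mutate(sample = spec$sample_id, count = as.integer(count)) |>
    select("sample", everything())
}

#' Tile panel targets with fixed-width windows
#'
#' @param panel A panel tibble.
#' @param window_nt Window width (default 20).
#' @return A tibble `chrom`, `start`, `end`, `target` (one row per
#'   window, in panel order).
#' @export
panel_windows <- function(panel, window_nt = 20) {
  panel <- as_tibble(panel)
  rows <- pmap(panel[, c("chrom", "start", "end", "name")],
               function(chrom, start, end, name) {
                 s <- seq(start, end - 1L, by = window_nt)
                 tibble(chrom = chrom, start = as.integer(s),
                        end = as.integer(pmin(s + window_nt, end)),
                        target = name)
               })
  list_rbind(rows)
}

simulate_variant_tables <- function(spec, gene_models, deletion) {
  exons <- as_tibble(gene_models)
  n_decoy <- spec$decoy_variant_count
  decoys <- if (n_decoy > 0) {
    rows <- exons[sample(nrow(exons), n_decoy, replace = TRUE), ]
    hom <- runif(n_decoy) < 0.25
    tibble(gene = rows$gene, chrom = rows$chrom,
           pos = as.integer(rows$start +
                              floor(runif(n_decoy) * (rows$end - rows$start)) + 1L),
           category = sample(c("synonymous", "missense", "inframe_indel"),
                             n_decoy, replace = TRUE,
                             prob = c(0.55, 0.40, 0.05)),
           alt_fraction = ifelse(hom, runif(n_decoy, 0.85, 0.98),
                                 runif(n_decoy, 0.35, 0.60)),
           clinical_significance = NA_character_,
           phastcons = ifelse(runif(n_decoy) < 0.1, NA_real_,
                              runif(n_decoy, 0, 0.94)),
           sift = runif(n_decoy, 0.10, 1.00),
           polyphen = runif(n_decoy, 0.00, 0.80),
           splice_delta = NA_real_,
           is_implant = FALSE)
  } else {
    tibble()
  }

  implants <- spec$implanted_variants
  imp_rows <- NULL
  if (!is.null(implants) && nrow(implants) > 0) {
    imp_rows <- list_rbind(map(seq_len(nrow(implants)), function(i) {
      v <- as.list(implants[i, ])
      ex <- exons |> filter(.data$gene == v$gene)
      if (nrow(ex) == 0) abort(paste0("implant gene not in panel: ", v$gene))
      exon_number <- v$exon %||% ex$exon_number[1]
      if (is.na(exon_number)) exon_number <- ex$exon_number[1]
      e <- ex[ex$exon_number == exon_number, ]
      defs <- category_defaults(v$category)
      pick <- function(nm) {
        val <- v[[nm]]
        if (is.null(val) || is.na(val)) defs[[nm]] else val
      }
      tibble(gene = v$gene, chrom = e$chrom,
             pos = as.integer((e$start + e$end) %/% 2L + 1L + i),
             category = v$category, alt_fraction = v$alt_fraction,
             clinical_significance = v$clinical_significance %||% NA_character_,
             phastcons = pick("phastcons"), sift = pick("sift"),
             polyphen = pick("polyphen"), splice_delta = pick("splice_delta"),
             is_implant = TRUE)
    }))
  }
  all_v <- bind_rows(imp_rows, decoys)  # implants win duplicate-site dedup
  if (nrow(all_v) == 0) {
    empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character())
    return(list(vcf = empty, pileup = empty, annotations = empty,
                benign_keys = empty, implant_truth = empty))
  }
  # drop variants inside an implanted deletion (no reads remain there) and
  # collapse accidental duplicate sites
  if (!is.null(deletion)) {
    all_v <- all_v |>
      filter(!(.data$chrom == deletion$chrom &
                 .data$pos - 1L >= deletion$del_start &
                 .data$pos - 1L < deletion$del_end))
  }
  all_v <- all_v |> distinct(.data$chrom, .data$pos, .keep_all = TRUE)

  ra <- map(all_v$category, ref_alt_for)
  all_v$ref <- map_chr(ra, "ref")
  all_v$alt <- map_chr(ra, "alt")

  n <- nrow(all_v)
  depth <- pmax(10L, rnbinom(n, mu = spec$depth_mean,
                             size = spec$depth_dispersion))
  alt_n <- pmin(depth, pmax(2L, rbinom(n, depth, all_v$alt_fraction)))
  alt_fwd <- pmin(alt_n - 1L, pmax(1L, rbinom(n, alt_n, 0.5)))
  alt_rev <- alt_n - alt_fwd
  # a sliver of decoys gets failing evidence so filters have work to do
  broken <- !all_v$is_implant & runif(n) < 0.05
  alt_rev[broken] <- 0L
  pileup <- tibble(chrom = all_v$chrom, pos = all_v$pos, ref = all_v$ref,
                   alt = all_v$alt, depth = as.integer(depth),
                   alt_fwd = as.integer(alt_fwd),
                   alt_rev = as.integer(alt_rev),
                   mapq = as.integer(ifelse(!all_v$is_implant &
                                              runif(n) < 0.03,
                                            sample(10:24, n, replace = TRUE),
                                            sample(25:60, n, replace = TRUE))),
                   consensus_qual = as.integer(sample(20:60, n, replace = TRUE)),
                   variant_qual = as.integer(sample(20:60, n, replace = TRUE)))

  benign <- !all_v$is_implant & runif(n) < 0.20
  annotations <- tibble(chrom = all_v$chrom, pos = all_v$pos,
                        ref = all_v$ref, alt = all_v$alt,
                        gene = all_v$gene,
                        effect_category = all_v$category,
                        dbsnp_id = ifelse(benign,
                                          sprintf("rs%07d",
                                                  sample(1e6, n, replace = TRUE)),
                                          NA_character_),
                        clinical_significance = all_v$clinical_significance,
                        phastcons = all_v$phastcons, sift = all_v$sift,
                        polyphen = all_v$polyphen,
                        splice_delta = all_v$splice_delta)
  vcf <- tibble(chrom = all_v$chrom, pos = all_v$pos,
                id = annotations$dbsnp_id, ref = all_v$ref, alt = all_v$alt)
  implant_truth <- all_v |>
    filter(.data$is_implant) |>
    select("gene", "chrom", "pos", "ref", "alt", "category",
           "alt_fraction", "clinical_significance")
  list(vcf = vcf, pileup = pileup, annotations = annotations,
       benign_keys = vcf[benign, c("chrom", "pos", "ref", "alt")],
       implant_truth = implant_truth)
}

simulate_off_target <- function(gene_models, deletion) {
  # a few stray reads per intron; capture is exon-directed so introns see
  # only sparse off-target coverage
  introns <- as_tibble(gene_models) |>
    arrange(.data$gene, .data$exon_number) |>
    group_by(.data$gene, .data$chrom) |>
    reframe(intron_start = head(.data$end, -1) + 51L,
            intron_end = tail(.data$start, -1) - 51L) |>
    rename(start = "intron_start", end = "intron_end") |>
    filter(.data$end > .data$start)
  if (nrow(introns) == 0) {
    return(tibble(chrom = character(), pos = integer()))
  }
  n_reads <- rpois(nrow(introns), 2)
  pos <- list_rbind(map(which(n_reads > 0), function(i) {
    tibble(chrom = introns$chrom[i],
           pos = as.integer(introns$start[i] +
                              floor(runif(n_reads[i]) *
                                      (introns$end[i] - introns$start[i])) + 1L))
  }))
  if (!is.null(deletion) && nrow(pos) > 0) {
    pos <- pos |>
      filter(!(.data$chrom == deletion$chrom &
                 .data$pos - 1L >= deletion$del_start &
                 .data$pos - 1L < deletion$del_end))
  }
  arrange(pos, .data$chrom, .data$pos)
}

#' Simulate a cohort sharing one panel and window grid
#'
#' Multiplexed panel runs pool samples (classically four per lane), and
#' the deletion caller needs at least three references on the test
#' sample's grid, so a cohort of at least four samples is the smallest
#' self-contained unit.
#'
#' @param specs List of [simulation_spec()]s (at least 4).
#' @param gene_models Optional shared gene models (default: generated from
#'   the first spec's seed).
#' @param disease_table Optional shared table.
#' @return A list of class `simulated_cohort` with `gene_models`, `panel`,
#'   `disease_table` and `samples` (named list of `simulated_patient`s).
#' @export
make_cohort <- function(specs, gene_models = NULL, disease_table = NULL) {
  if (length(specs) < 4) {
    abort("a cohort needs at least 4 samples (insufficient references)")
  }
  ids <- map_chr(specs, "sample_id")
  if (anyDuplicated(ids)) abort("sample_id must be unique within a cohort")
  if (is.null(gene_models)) {
    gene_models <- simulate_gene_models(specs[[1]]$n_genes,
                                        seed = specs[[1]]$seed)
  }
  if (is.null(disease_table)) {
    disease_table <- simulate_disease_table(gene_models,
                                            seed = specs[[1]]$seed)
  }
  samples <- map(specs, simulate_patient, gene_models = gene_models,
                 disease_table = disease_table)
  names(samples) <- ids
  structure(list(gene_models = gene_models,
                 panel = samples[[1]]$panel,
                 disease_table = disease_table, samples = samples),
            class = "simulated_cohort")
}

#' Write a simulated patient's files
#'
#' Emits the on-disk forms of every simulator output: `panel.bed`,
#' `variants.vcf`, `pileup.tsv`, `annotations.tsv`, `benign.tsv`,
#' `coverage.tsv`, `offtarget.tsv`, `disease_genes.tsv` and `truth.json`.
#'
#' @param sim A [simulate_patient()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_files <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_bed(sim$panel, fp("panel.bed"))
  write_vcf(sim$vcf, fp("variants.vcf"))
  readr::write_tsv(sim$pileup, fp("pileup.tsv"))
  readr::write_tsv(sim$annotations, fp("annotations.tsv"))
  readr::write_tsv(sim$benign_keys, fp("benign.tsv"))
  write_coverage(sim$coverage, fp("coverage.tsv"))
  readr::write_tsv(sim$off_target, fp("offtarget.tsv"))
  readr::write_tsv(
    tibble(gene = sim$disease_table$gene,
           disease_classes = map_chr(sim$disease_table$disease_classes,
                                     paste, collapse = ";"),
           inheritance_modes = map_chr(sim$disease_table$inheritance_modes,
                                       paste, collapse = ";")),
    fp("disease_genes.tsv"))
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

# Minimal VCF 4.2 writer for simulator output (reading goes through vcfR).
write_vcf <- function(vcf, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=paneldx-simulator",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  vcf$chrom, vcf$pos,
                  ifelse(is.na(vcf$id), ".", vcf$id), vcf$ref, vcf$alt)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Prepare ranked-pipeline input from joined variant evidence
#'
#' Applies, in order: the validity filter ([is_valid()]), zygosity calling
#' ([call_zygosity()]) and benign removal ([remove_known_benign()]),
#' returning a tibble ready for [rank_patient()].
#'
#' @param variants Joined variant tibble (as from [read_variants()], or a
#'   simulator's `pileup` joined to its `annotations`).
#' @param sex Sample sex (for chrX hemizygosity).
#' @param benign_keys Optional benign-key tibble.
#' @param thresholds A [filter_thresholds()].
#' @return The filtered, zygosity-annotated variant tibble.
#' @export
prepare_candidates <- function(variants, sex = "female", benign_keys = NULL,
                               thresholds = filter_thresholds()) {
  variants <- as_tibble(variants)
  variants <- variants[is_valid(variants, thresholds), , drop = FALSE]
  if (nrow(variants) > 0) {
    variants$zygosity <- call_zygosity(variants, thresholds, sex)
    variants$probable_false_positive <-
      flag_probable_false_positive(variants, thresholds)
  } else {
    variants$zygosity <- character(0)
    variants$probable_false_positive <- logical(0)
  }
  if (!is.null(benign_keys)) {
    variants <- remove_known_benign(variants, benign_keys)
  }
  variants
}
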