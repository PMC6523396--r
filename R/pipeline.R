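# Orchestration: regions -> filter -> matrix -> (optional) concordance,
# collated into a deterministic run report with rendered accounting tables.

#' Packaged filter-cascade accounting table
#'
#' The published three-stage polymorphism accounting (detected, reliable,
#' after processing; totals with SNP/indel splits), distributed for
#' rendering and consistency checks.
#'
#' @return data.frame with columns `type`, `total`, `n_snp`, `n_indel`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "transgeno",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Run the downstream genotyping pipeline
#'
#' Executes transcribed-region construction, the variant filter cascade,
#' genotype-matrix analytics and (when amplicon inputs are configured)
#' cross-platform concordance, writing all stage outputs under
#' `config$out_dir` and returning a run report. Pipeline stages contain no
#' randomness: the same inputs always give the same report.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `gff3`, `chrom_sizes`, `vcf`, `metadata` (input paths); `out_dir`;
#'   optional `genome` (FASTA), `flank_bp` (default 3000),
#'   `reference_total_bp` (default: total bp of the HC loci in the GFF),
#'   `min_reads`, `neighbor_window`, `min_gap` (default 1e6),
#'   `amplicon_panel` + `amplicon_calls` + `min_mean_depth` (default 100) +
#'   `threshold` (default 90) for the concordance stage.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      tg_stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::yaml.load_file(config)
  }
  for (f in c("gff3", "chrom_sizes", "vcf", "metadata")) {
    if (is.null(config[[f]])) tg_stop("config is missing input: ", f)
    if (!file.exists(config[[f]])) {
      tg_stop("input file does not exist: ", config[[f]])
    }
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  # stage 1: transcribed regions
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  loci <- read_gene_models(config$gff3)
  flank <- config$flank_bp %||% 3000
  regions <- merge_intervals(extend_loci(loci, flank, chrom_sizes))
  hc <- loci[loci$source == "HC", , drop = FALSE]
  ref_bp <- config$reference_total_bp %||% sum(hc$end - hc$start)
  rstats <- region_stats(regions, ref_bp)
  write_regions_bed(regions, p("regions.bed"))
  if (!is.null(config$genome)) {
    Biostrings::writeXStringSet(extract_region_fasta(regions, config$genome),
                                p("regions.fa"))
  }

  # stage 2: filter cascade
  meta <- read_metadata(config$metadata)
  fcfg <- filter_config(
    min_reads = config$min_reads %||% 2,
    neighbor_window = config$neighbor_window %||% 60)
  cascade <- run_cascade(config$vcf, meta, fcfg)
  write_genotype_matrix(cascade$matrix, p("genotype_matrix.tsv"))
  write_filtered_vcf(cascade$matrix, p("filtered.vcf"))

  # stage 3: matrix analytics
  pw <- pairwise_diff(cascade$matrix)
  utils::write.table(pw$snp + pw$indel, p("pairwise.tsv"), sep = "\t",
                     quote = FALSE)
  gaps <- scan_gaps(cascade$matrix, min_len = config$min_gap %||% 1e6)
  utils::write.table(gaps, p("gaps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # stage 4: concordance (optional)
  concordance <- NULL
  if (!is.null(config$amplicon_panel) && !is.null(config$amplicon_calls)) {
    panel <- read_marker_panel(config$amplicon_panel)
    amp <- read_amplicon_calls(config$amplicon_calls)
    panel <- panel_mean_depth(panel, amp)
    gated <- depth_gate(panel, config$min_mean_depth %||% 100)
    strains <- intersect(colnames(cascade$matrix$calls),
                         unique(amp$strain_id))
    rows <- do.call(rbind, lapply(strains, function(s) {
      strain_concordance(rnaseq_panel_calls(cascade$matrix, gated, s),
                         amplicon_panel_calls(amp, s, gated),
                         gated, strain_id = s)
    }))
    concordance <- list(
      rows = rows,
      summary = summarize_concordance(rows, config$threshold %||% 90),
      n_panel = nrow(panel), n_gated = nrow(gated))
    utils::write.table(rows, p("concordance.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  report <- structure(list(
    tool = "transgeno",
    version = as.character(utils::packageVersion("transgeno")),
    config = config,
    region_stats = rstats,
    filter_report = cascade$report,
    n_pairwise_max = if (nrow(cascade$matrix$sites) > 0) {
      max(pw$snp + pw$indel)
    } else 0L,
    n_gaps = nrow(gaps),
    concordance = concordance,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  ), class = "run_report")
  json <- report
  json$region_stats <- unclass(rstats)
  json$filter_report <- unclass(cascade$report)
  if (!is.null(concordance)) {
    json$concordance <- list(rows = concordance$rows,
                             summary = unclass(concordance$summary),
                             n_panel = concordance$n_panel,
                             n_gated = concordance$n_gated)
  }
  jsonlite::write_json(json, p("report.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("transgeno run report (v", x$version, ")\n", sep = "")
  print(x$region_stats)
  print(x$filter_report)
  if (!is.null(x$concordance)) print(x$concordance$summary)
  invisible(x)
}

#' Render accounting tables from report components
#'
#' Produces the two standard layouts: the three-row filter accounting table
#' (`Type`, `Total`, `No. of SNPs`, `No. of indels`, thousands-separated)
#' and the per-strain concordance table (three rate columns to 3 decimals,
#' five count columns).
#'
#' @param filter_report a `filter_report`, or `NULL` to skip.
#' @param concordance_rows data.frame of concordance rows, or `NULL`.
#' @return list with character-rendered data.frames `table1`, `table2`.
#' @export
render_tables <- function(filter_report = NULL, concordance_rows = NULL) {
  out <- list()
  if (!is.null(filter_report)) {
    fr <- filter_report
    out$table1 <- data.frame(
      Type = c("Detected polymorphisms", "Reliable polymorphisms",
               "Polymorphisms after processing"),
      Total = fmt_thousands(c(fr$n_detected,
                              fr$n_reliable_snp + fr$n_reliable_indel,
                              fr$n_final_snp + fr$n_final_indel)),
      `No. of SNPs` = c("", fmt_thousands(fr$n_reliable_snp),
                        fmt_thousands(fr$n_final_snp)),
      `No. of indels` = c("", fmt_thousands(fr$n_reliable_indel),
                          fmt_thousands(fr$n_final_indel)),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(concordance_rows)) {
    r <- concordance_rows
    fmt_rate <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
    out$table2 <- data.frame(
      Strain = r$strain_id,
      Total = fmt_rate(r$rate_total),
      SNP = fmt_rate(r$rate_snp),
      Indel = fmt_rate(r$rate_indel),
      `True SNP` = r$true_snp, `True indel` = r$true_indel,
      `False SNP` = r$false_snp, `False indel` = r$false_indel,
      `Not detected` = r$not_detected,
      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (!is.null(filter_report)) {
    out$table2 <- data.frame(
      Strain = character(), Total = character(), SNP = character(),
      Indel = character(), `True SNP` = integer(), `True indel` = integer(),
      `False SNP` = integer(), `False indel` = integer(),
      `Not detected` = integer(), check.names = FALSE)
  }
  out
}
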