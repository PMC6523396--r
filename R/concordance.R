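# Genotype agreement evaluation: replicate RNA-Seq libraries of one strain,
# and RNA-Seq vs amplicon resequencing per strain and per marker.

# Normalize a genotype for cross-platform comparison: uppercase, unordered
# alleles; for heterozygous allele pairs sharing sequence, the common suffix
# then prefix is trimmed (keeping >=1 base) so differently anchored indel
# representations compare equal.
#' @keywords internal
normalize_gt <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.")) return(NA_character_)
    a <- toupper(strsplit(g, "[/|]")[[1]])
    if (length(a) == 1) a <- c(a, a)
    if (a[1] != a[2]) {
      while (nchar(a[1]) > 1 && nchar(a[2]) > 1 &&
             substring(a[1], nchar(a[1])) == substring(a[2], nchar(a[2]))) {
        a <- substring(a, 1, nchar(a) - 1)
      }
      while (nchar(a[1]) > 1 && nchar(a[2]) > 1 &&
             substring(a[1], 1, 1) == substring(a[2], 1, 1)) {
        a <- substring(a, 2)
      }
    }
    paste(sort(a), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Agreement between two replicate libraries of one strain
#'
#' Sites called in both libraries are compared (identical genotype = agreed);
#' sites called in exactly one library are counted separately and excluded
#' from the rate denominator.
#'
#' @param calls_lib1,calls_lib2 named character vectors of genotype strings
#'   keyed by site id (`NA` = no call).
#' @param strain_id optional label carried into the result.
#' @return list of class `replicate_agreement` with `agreed`, `disagreed`,
#'   `one_library_only`, `rate` (percent; `NA` with `rate_defined = FALSE`
#'   when no site is called in both libraries).
#' @export
replicate_agreement <- function(calls_lib1, calls_lib2, strain_id = NA) {
  keys <- union(names(calls_lib1), names(calls_lib2))
  g1 <- calls_lib1[keys]
  g2 <- calls_lib2[keys]
  called1 <- !is.na(g1)
  called2 <- !is.na(g2)
  both <- called1 & called2
  agreed <- sum(both & normalize_gt(g1) == normalize_gt(g2), na.rm = TRUE)
  disagreed <- sum(both) - agreed
  one_only <- sum(xor(called1, called2))
  total <- agreed + disagreed
  structure(list(strain_id = strain_id, agreed = agreed,
                 disagreed = disagreed, one_library_only = one_only,
                 rate = if (total > 0) 100 * agreed / total else NA_real_,
                 rate_defined = total > 0),
            class = "replicate_agreement")
}

#' Mean-depth gate for an amplicon marker panel
#'
#' @param panel data.frame with a `mean_depth` column (mean read depth per
#'   marker across strains on the amplicon platform).
#' @param min_mean_depth retention threshold; markers with mean depth
#'   strictly below it are omitted (default 100).
#' @return the retained subset of `panel`.
#' @export
depth_gate <- function(panel, min_mean_depth = 100) {
  if (nrow(panel) == 0) return(panel)
  if (!"mean_depth" %in% colnames(panel)) {
    tg_stop("panel has no mean_depth column (see panel_mean_depth())")
  }
  panel[panel$mean_depth >= min_mean_depth, , drop = FALSE]
}

#' Attach per-marker mean depths to a panel
#'
#' @param panel data.frame with `marker_id`.
#' @param amplicon_calls data.frame with `marker_id` and `depth` (one row
#'   per marker x strain call).
#' @return `panel` with a `mean_depth` column (NA where no calls exist).
#' @export
panel_mean_depth <- function(panel, amplicon_calls) {
  md <- tapply(amplicon_calls$depth, amplicon_calls$marker_id, mean)
  panel$mean_depth <- as.numeric(md[panel$marker_id])
  panel
}

#' Build a per-strain concordance row
#'
#' @param true_snp,true_indel,false_snp,false_indel,not_detected counts.
#' @param strain_id strain label.
#' @return one-row data.frame with the counts and `rate_total`, `rate_snp`,
#'   `rate_indel` in percent, rounded half-up to 3 decimals (`NA` when a
#'   denominator is zero).
#' @export
concordance_row <- function(strain_id, true_snp, true_indel, false_snp,
                            false_indel, not_detected) {
  rate <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 3)
  }
  data.frame(
    strain_id = strain_id,
    rate_total = rate(true_snp + true_indel,
                      true_snp + true_indel + false_snp + false_indel),
    rate_snp = rate(true_snp, true_snp + false_snp),
    rate_indel = rate(true_indel, true_indel + false_indel),
    true_snp = true_snp, true_indel = true_indel,
    false_snp = false_snp, false_indel = false_indel,
    not_detected = not_detected,
    stringsAsFactors = FALSE
  )
}

#' Cross-platform concordance for one strain
#'
#' Compares genotype calls at gated panel markers between the two platforms.
#' A marker where either platform lacks a call is "not detected"; otherwise
#' genotype equality (after normalization, see the methods vignette) counts
#' as true, inequality as false, stratified by the panel's SNP/indel class.
#'
#' @param rnaseq_calls,amplicon_calls named character vectors of genotype
#'   strings keyed by `marker_id` (`NA` = no call).
#' @param panel gated panel data.frame with `marker_id` and `vtype`.
#' @param strain_id strain label.
#' @return one-row data.frame (see [concordance_row()]) plus platform-wise
#'   missing counts `missing_rnaseq`, `missing_amplicon`.
#' @export
strain_concordance <- function(rnaseq_calls, amplicon_calls, panel,
                               strain_id = NA) {
  stray <- setdiff(union(names(rnaseq_calls), names(amplicon_calls)),
                   panel$marker_id)
  stray <- stray[!is.na(rnaseq_calls[stray]) | !is.na(amplicon_calls[stray])]
  if (length(stray) > 0) {
    warning("calls at marker(s) not in panel, skipped: ",
            paste(utils::head(stray, 5), collapse = ", "))
  }
  r <- normalize_gt(rnaseq_calls[panel$marker_id])
  a <- normalize_gt(amplicon_calls[panel$marker_id])
  detected <- !is.na(r) & !is.na(a)
  match_ok <- detected & r == a
  is_snp <- panel$vtype == "SNP"
  row <- concordance_row(
    strain_id,
    true_snp = sum(match_ok & is_snp),
    true_indel = sum(match_ok & !is_snp),
    false_snp = sum(detected & !match_ok & is_snp),
    false_indel = sum(detected & !match_ok & !is_snp),
    not_detected = sum(!detected)
  )
  row$missing_rnaseq <- sum(is.na(r))
  row$missing_amplicon <- sum(is.na(a))
  row
}

#' RNA-Seq genotype calls for one strain at panel markers
#'
#' Looks panel markers up in a filtered genotype matrix by (chrom, pos) and
#' renders the strain's calls as REF/ALT allele strings.
#'
#' @param gm a [genotype_matrix()].
#' @param panel data.frame with `marker_id`, `chrom`, `pos`.
#' @param strain_id strain column to extract.
#' @return named character vector keyed by `marker_id`.
#' @export
rnaseq_panel_calls <- function(gm, panel, strain_id) {
  if (!strain_id %in% colnames(gm$calls)) {
    tg_stop("strain not in genotype matrix: ", strain_id)
  }
  idx <- match(paste(panel$chrom, panel$pos),
               paste(gm$sites$chrom, gm$sites$pos))
  out <- rep(NA_character_, nrow(panel))
  hit <- !is.na(idx)
  out[hit] <- vapply(which(hit), function(k) {
    i <- idx[k]
    gt_to_alleles(gm$calls[i, strain_id], gm$sites$ref[i], gm$sites$alt[i])
  }, character(1))
  stats::setNames(out, panel$marker_id)
}

#' Summarize per-strain concordance rows
#'
#' @param rows data.frame of concordance rows (one per strain).
#' @param threshold agreement threshold in percent for the high-agreement
#'   strain count; the comparison is `rate_total >= threshold` (default 90).
#' @return list of class `concordance_summary`: `n_strains`,
#'   `mean_rate_snp` / `mean_rate_indel` (arithmetic means of the per-strain
#'   rates), `pooled_rate_snp` / `pooled_rate_indel` (from pooled counts),
#'   `min_rate_total`, `max_rate_total`, `n_at_least_threshold`.
#' @export
summarize_concordance <- function(rows, threshold = 90) {
  if (nrow(rows) == 0) tg_stop("no concordance rows to summarize")
  structure(list(
    n_strains = nrow(rows),
    mean_rate_snp = mean(rows$rate_snp, na.rm = TRUE),
    mean_rate_indel = mean(rows$rate_indel, na.rm = TRUE),
    pooled_rate_snp = 100 * sum(rows$true_snp) /
      sum(rows$true_snp + rows$false_snp),
    pooled_rate_indel = 100 * sum(rows$true_indel) /
      sum(rows$true_indel + rows$false_indel),
    min_rate_total = min(rows$rate_total, na.rm = TRUE),
    max_rate_total = max(rows$rate_total, na.rm = TRUE),
    n_at_least_threshold = sum(rows$rate_total >= threshold, na.rm = TRUE),
    threshold = threshold
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Concordance over", x$n_strains, "strains\n")
  cat(sprintf("  mean SNP rate   %.1f%%\n", round_half_up(x$mean_rate_snp, 1)))
  cat(sprintf("  mean indel rate %.1f%%\n",
              round_half_up(x$mean_rate_indel, 1)))
  cat(sprintf("  overall rate range %.1f-%.1f%%\n",
              round_half_up(x$min_rate_total, 1),
              round_half_up(x$max_rate_total, 1)))
  cat(sprintf("  strains with rate >= %s%%: %d\n", x$threshold,
              x$n_at_least_threshold))
  invisible(x)
}

#' Per-marker aggregation of cross-platform matches
#'
#' @param rnaseq_calls,amplicon_calls character matrices (markers x strains,
#'   shared dimnames) of genotype strings, `NA` = no call.
#' @return list of class `marker_summary`: `n_markers`, `n_missing_data`
#'   (markers where any strain lacks a call on either platform),
#'   `n_complete_match` (zero mismatches among strains called on both),
#'   `n_lt5_mismatch` (1-4 mismatches), plus a `per_marker` data.frame.
#' @export
marker_summary <- function(rnaseq_calls, amplicon_calls) {
  if (!identical(dimnames(rnaseq_calls), dimnames(amplicon_calls))) {
    tg_stop("call matrices must share markers x strains dimnames")
  }
  per <- data.frame(marker_id = rownames(rnaseq_calls),
                    missing_data = FALSE, mismatches = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rnaseq_calls))) {
    r <- normalize_gt(rnaseq_calls[i, ])
    a <- normalize_gt(amplicon_calls[i, ])
    per$missing_data[i] <- any(is.na(r)) || any(is.na(a))
    both <- !is.na(r) & !is.na(a)
    per$mismatches[i] <- sum(r[both] != a[both])
  }
  structure(list(
    n_markers = nrow(per),
    n_missing_data = sum(per$missing_data),
    n_complete_match = sum(per$mismatches == 0),
    n_lt5_mismatch = sum(per$mismatches >= 1 & per$mismatches < 5),
    per_marker = per
  ), class = "marker_summary")
}

#' Packaged cross-platform concordance count table
#'
#' The 38-strain contingency table (true/false/not-detected counts split by
#' SNP/indel, with the published agreement-rate cells) distributed with the
#' package for rate-reconstruction checks and summaries.
#'
#' @return data.frame with columns `strain_id`, `rate_total`, `rate_snp`,
#'   `rate_indel`, `true_snp`, `true_indel`, `false_snp`, `false_indel`,
#'   `not_detected`.
#' @export
table2_counts <- function() {
  path <- system.file("extdata", "table2_counts.tsv", package = "transgeno",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read amplicon platform calls
#'
#' TSV with columns `marker_id`, `strain_id`, `genotype` (allele strings,
#' `.` = missing), `depth`.
#'
#' @param path calls TSV.
#' @return data.frame.
#' @export
read_amplicon_calls <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  tab$genotype[tab$genotype == "."] <- NA_character_
  tab
}

#' Read a marker panel table
#'
#' TSV with columns `marker_id`, `chrom`, `pos`, `vtype`.
#'
#' @param path panel TSV.
#' @return data.frame.
#' @export
read_marker_panel <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
}

#' Amplicon calls for one strain as a named vector
#'
#' @param amplicon_calls data.frame from [read_amplicon_calls()].
#' @param strain_id strain to extract.
#' @param panel panel data.frame giving the marker universe.
#' @return named character vector keyed by `marker_id`.
#' @export
amplicon_panel_calls <- function(amplicon_calls, strain_id, panel) {
  sub <- amplicon_calls[amplicon_calls$strain_id == strain_id, , drop = FALSE]
  out <- stats::setNames(rep(NA_character_, nrow(panel)), panel$marker_id)
  hit <- sub$marker_id %in% panel$marker_id
  out[sub$marker_id[hit]] <- sub$genotype[hit]
  out
}
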