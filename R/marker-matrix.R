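# Analytics over the filtered genotype matrix: pairwise polymorphism counts,
# group-wise MAF/missingness filtering and polymorphism-free gap scanning.

#' Pairwise polymorphism counts between strains
#'
#' For every unordered strain pair, counts sites where both calls are
#' non-missing and the genotypes differ (heterozygous vs homozygous counts
#' as a difference), split into SNP and indel counts. Missing-vs-anything is
#' never a difference, so missingness cannot inflate distances.
#'
#' @param gm a [genotype_matrix()].
#' @return list with integer matrices `snp` and `indel` (strains x strains,
#'   symmetric, zero diagonal).
#' @export
pairwise_diff <- function(gm) {
  strains <- colnames(gm$calls)
  ns <- length(strains)
  snp <- matrix(0L, ns, ns, dimnames = list(strains, strains))
  indel <- snp
  is_snp <- gm$sites$vtype == "SNP"
  is_indel <- gm$sites$vtype == "INDEL"
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j <= i) next
      a <- gm$calls[, i]
      b <- gm$calls[, j]
      diffs <- !is.na(a) & !is.na(b) & a != b
      snp[i, j] <- snp[j, i] <- sum(diffs & is_snp)
      indel[i, j] <- indel[j, i] <- sum(diffs & is_indel)
    }
  }
  list(snp = snp, indel = indel)
}

# minor allele frequency over called alleles in a set of genotype strings
# (homozygote contributes 2 copies of its allele, heterozygote 1 of each)
#' @keywords internal
site_maf <- function(calls) {
  alleles <- unlist(gt_alleles(calls[!is.na(calls)]))
  if (length(alleles) == 0) return(NA_real_)
  counts <- table(alleles)
  if (length(counts) < 2) return(0)
  (sum(counts) - max(counts)) / sum(counts)
}

#' Group-wise MAF / missingness site filter
#'
#' Restricts the matrix to the strains of one group (e.g. a row type) and
#' drops every site whose minor allele frequency falls below `maf_min` or
#' whose missing-call fraction reaches `miss_max`.
#'
#' @param gm a [genotype_matrix()] with a `groups` map.
#' @param group_label group to evaluate.
#' @param maf_min minimum minor allele frequency (default 0.1; sites with
#'   MAF < `maf_min` are dropped).
#' @param miss_max maximum missing fraction (default 0.5; sites with
#'   missingness >= `miss_max` are dropped).
#' @return logical vector over the matrix's sites: `TRUE` = retained.
#' @export
group_filter <- function(gm, group_label, maf_min = 0.1, miss_max = 0.5) {
  if (is.null(gm$groups)) tg_stop("genotype matrix has no group map")
  members <- names(gm$groups)[gm$groups == group_label]
  if (length(members) == 0) tg_stop("unknown group label: ", group_label)
  if (length(members) < 2) tg_stop("group '", group_label, "' has < 2 strains")
  sub <- gm$calls[, members, drop = FALSE]
  miss_frac <- rowMeans(is.na(sub))
  maf <- apply(sub, 1, site_maf)
  maf[is.na(maf)] <- 0
  maf >= maf_min & miss_frac < miss_max
}

#' Scan for polymorphism-free gap regions
#'
#' Finds, per chromosome, every adjacent pair of markers whose positions are
#' more than `min_len` bp apart; the gap length is the difference of the two
#' flanking marker positions (endpoints exclusive). Chromosome-end gaps
#' (before the first / after the last marker) are excluded unless
#' chromosome lengths are supplied.
#'
#' @param positions named list (per chromosome) of 1-based marker positions,
#'   or a [genotype_matrix()].
#' @param min_len minimum gap length in bp; the comparison is strict
#'   (default 1,000,000, i.e. "more than 1 Mbp").
#' @param chrom_sizes optional named chromosome-length vector; when given,
#'   terminal gaps (position 0 to first marker, last marker to chromosome
#'   end) are included.
#' @return data.frame `chrom`, `left_pos`, `right_pos`, `length`, sorted by
#'   length descending.
#' @export
scan_gaps <- function(positions, min_len = 1e6, chrom_sizes = NULL) {
  if (inherits(positions, "genotype_matrix")) {
    positions <- split(positions$sites$pos, positions$sites$chrom)
  }
  rows <- list()
  for (ch in names(positions)) {
    pos <- sort(unique(positions[[ch]]))
    if (!is.null(chrom_sizes)) {
      if (!ch %in% names(chrom_sizes)) {
        tg_stop("chromosome absent from length table: ", ch)
      }
      pos <- c(0, pos, chrom_sizes[[ch]] + 1)
    }
    if (length(pos) < 2) next
    len <- diff(pos)
    hit <- which(len > min_len)
    if (length(hit) > 0) {
      rows[[ch]] <- data.frame(chrom = ch, left_pos = pos[hit],
                               right_pos = pos[hit + 1], length = len[hit],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), left_pos = numeric(),
                      right_pos = numeric(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, out$chrom, out$left_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned per-chromosome marker counts
#'
#' @param gm a [genotype_matrix()].
#' @param bin_size bin width in bp (default 10 Mbp).
#' @return data.frame `chrom`, `bin_start` (0-based), `bin_end`, `count`;
#'   bin counts sum to the matrix's site count.
#' @export
chromosome_distribution <- function(gm, bin_size = 1e7) {
  if (bin_size <= 0) tg_stop("bin_size must be > 0")
  if (nrow(gm$sites) == 0) {
    return(data.frame(chrom = character(), bin_start = numeric(),
                      bin_end = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  bin <- floor((gm$sites$pos - 1) / bin_size)
  agg <- stats::aggregate(list(count = gm$sites$pos),
                          by = list(chrom = gm$sites$chrom, bin = bin),
                          FUN = length)
  out <- data.frame(chrom = agg$chrom,
                    bin_start = agg$bin * bin_size,
                    bin_end = (agg$bin + 1) * bin_size,
                    count = agg$count, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
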