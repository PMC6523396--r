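# Transcribed-region construction: gene locus spans extended by fixed flanks,
# concatenated into a sorted, non-overlapping region set.
#
# All coordinates are 0-based half-open internally; GFF3 (1-based closed) is
# converted at the boundary, and BED output needs no conversion.

#' Read a chromosome-length table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) tg_stop("chromosome lengths must be positive")
  stats::setNames(tab$length, tab$chrom)
}

#' Read gene loci from a GFF3 file
#'
#' Extracts gene-level features and converts their 1-based closed GFF
#' coordinates to the package's 0-based half-open convention. The GFF
#' `source` column is compared against `confidence_tag` to separate
#' high-confidence (HC) annotated genes from novel, transcript-evidence loci.
#'
#' @param gff3 path to a GFF3 file.
#' @param confidence_tag GFF source value marking high-confidence genes.
#' @param feature_type feature type(s) treated as gene loci.
#' @return data.frame with columns `locus_id`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `strand`, `source` (`"HC"` or `"novel"`).
#' @export
read_gene_models <- function(gff3, confidence_tag = "HC",
                             feature_type = "gene") {
  gr <- tryCatch(
    rtracklayer::import(gff3, format = "gff3"),
    error = function(e) tg_stop("failed to parse GFF3 '", gff3, "': ",
                                conditionMessage(e))
  )
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(BiocGenerics::width(gr) < 1)) {
    tg_stop("rejected gene record with end < start")
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    # fall back to Name, then positional ids
    ids <- gr$Name %||% paste0("locus", seq_along(gr))
  }
  if (anyDuplicated(ids)) tg_stop("duplicate locus_id in gene models")
  loci <- data.frame(
    locus_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    source = ifelse(as.character(gr$source) == confidence_tag, "HC", "novel"),
    stringsAsFactors = FALSE
  )
  loci$strand[!loci$strand %in% c("+", "-")] <- "unknown"
  loci
}

#' Extend a gene locus by symmetric flanks
#'
#' Adds `flank_bp` on both sides of the locus span, clipping at the
#' chromosome origin and end. Flanks are strand-agnostic: "upstream" and
#' "downstream" extensions are the same length, so strand-unknown novel loci
#' are handled identically to annotated genes.
#'
#' @param start,end locus span, 0-based half-open (vectors allowed).
#' @param flank_bp flank length in bp added on each side (default 3000).
#' @param chrom_len chromosome length(s) in bp.
#' @return data.frame with clipped `start`, `end`.
#' @export
extend_locus <- function(start, end, flank_bp = 3000, chrom_len) {
  if (any(flank_bp < 0)) tg_stop("flank_bp must be >= 0")
  if (any(start < 0) || any(start >= end)) {
    tg_stop("invalid locus interval: require 0 <= start < end")
  }
  if (any(end > chrom_len)) {
    tg_stop("locus extends past chromosome end (chrom_len < locus end)")
  }
  data.frame(start = pmax(0, start - flank_bp),
             end = pmin(chrom_len, end + flank_bp))
}

#' Extend all loci in a gene-model table
#'
#' @param loci data.frame from [read_gene_models()].
#' @param flank_bp flank length in bp.
#' @param chrom_sizes named vector from [read_chrom_sizes()].
#' @return `loci` with `start`/`end` replaced by the flanked, clipped span.
#' @export
extend_loci <- function(loci, flank_bp = 3000, chrom_sizes) {
  missing_chrom <- setdiff(unique(loci$chrom), names(chrom_sizes))
  if (length(missing_chrom) > 0) {
    tg_stop("chromosomes absent from length table: ",
            paste(missing_chrom, collapse = ", "))
  }
  ext <- extend_locus(loci$start, loci$end, flank_bp,
                      chrom_sizes[loci$chrom])
  loci$start <- ext$start
  loci$end <- ext$end
  loci
}

#' Merge intervals into transcribed regions
#'
#' Concatenates overlapping and book-ended (touching) intervals on the same
#' chromosome into a canonical minimal set of disjoint regions, each carrying
#' the ids of its member loci. Input order is irrelevant; output is sorted by
#' (chrom, start).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `locus_id`.
#' @return data.frame with `chrom`, `start`, `end` and a `members`
#'   list-column of member locus ids.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  if (any(intervals$start < 0) || any(intervals$start >= intervals$end)) {
    tg_stop("invalid interval: require 0 <= start < end")
  }
  ids <- intervals$locus_id %||% paste0("iv", seq_len(nrow(intervals)))
  out <- lapply(sort(unique(intervals$chrom)), function(ch) {
    sel <- intervals$chrom == ch
    ir <- IRanges::IRanges(start = intervals$start[sel] + 1L,
                           end = intervals$end[sel])
    red <- IRanges::reduce(ir, min.gapwidth = 1L, with.revmap = TRUE)
    members <- lapply(S4Vectors::mcols(red)$revmap,
                      function(i) sort(ids[sel][i]))
    data.frame(chrom = ch,
               start = BiocGenerics::start(red) - 1L,
               end = BiocGenerics::end(red),
               members = I(members),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of a region set
#'
#' @param regions data.frame from [merge_intervals()].
#' @param reference_total_bp total bp of a reference region set (e.g. the
#'   high-confidence gene loci) against which coverage is compared.
#' @return object of class `region_stats` with `n_regions`, `total_bp`,
#'   `ratio_vs_reference`.
#' @export
region_stats <- function(regions, reference_total_bp) {
  if (reference_total_bp <= 0) tg_stop("reference_total_bp must be > 0")
  total <- if (nrow(regions) == 0) 0 else sum(regions$end - regions$start)
  structure(
    list(n_regions = nrow(regions),
         total_bp = total,
         ratio_vs_reference = total / reference_total_bp),
    class = "region_stats"
  )
}

#' @export
print.region_stats <- function(x, ...) {
  cat("Transcribed regions:", fmt_thousands(x$n_regions), "\n")
  cat("Total length (bp): ", fmt_thousands(x$total_bp), "\n")
  cat(sprintf("Ratio vs reference: %.2f\n", x$ratio_vs_reference))
  invisible(x)
}

#' Write regions as BED
#'
#' 0-based half-open BED with the joined member locus ids as the name column.
#'
#' @param regions data.frame from [merge_intervals()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  name <- vapply(regions$members, paste, character(1), collapse = ",")
  lines <- paste(regions$chrom, regions$start, regions$end, name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file written by [write_regions_bed()]
#'
#' @param path BED file path.
#' @return regions data.frame (same shape as [merge_intervals()] output).
#' @export
read_regions_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             members = I(strsplit(tab$name, ",", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Extract region sequences from a genome
#'
#' @param regions data.frame from [merge_intervals()].
#' @param genome a [Biostrings::DNAStringSet] or a FASTA file path.
#' @return `DNAStringSet` named `"chrom:start-end"` (half-open coordinates).
#' @export
extract_region_fasta <- function(regions, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing_chrom <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    tg_stop("chromosome(s) missing from genome FASTA: ",
            paste(missing_chrom, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, character(1)))
  names(seqs) <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  seqs
}
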