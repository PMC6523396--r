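# Sites x strains genotype container shared by the filter cascade and the
# marker analytics. Calls are stored as allele-index genotype strings
# ("0/0", "0/1", "1/1", ...) with NA for missing; allele indices refer to
# the site's REF (0) and ALT alleles (1, 2, ...).

#' Construct a genotype matrix
#'
#' @param sites data.frame with `chrom`, `pos` (1-based VCF position),
#'   `ref`, `alt` (comma-joined alternate alleles), `vtype`
#'   (`"SNP"`, `"INDEL"` or `"MULTI"`).
#' @param calls character matrix, `nrow(sites)` x strains, of genotype
#'   strings (allele indices joined by `/`), `NA` for missing; column names
#'   are strain ids.
#' @param groups optional named character vector mapping strain id to a
#'   group label (e.g. row type).
#' @param depth optional numeric matrix of per-call read depths, same shape
#'   as `calls`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, groups = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  if (nrow(sites) != nrow(calls)) {
    tg_stop("sites and calls have different numbers of rows")
  }
  if (is.null(colnames(calls))) tg_stop("calls must have strain column names")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (!is.null(depth)) depth <- as.matrix(depth)[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, calls = calls, groups = groups,
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x",
      ncol(x$calls), "strains\n")
  if (nrow(x$sites) > 0) {
    cat("  vtypes:", paste(names(table(x$sites$vtype)),
                           table(x$sites$vtype), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# --- genotype string helpers -------------------------------------------------

#' @keywords internal
gt_normalize <- function(gt) {
  gt[gt %in% c(".", "./.", ".|.", "")] <- NA_character_
  ok <- !is.na(gt)
  parts <- strsplit(gt[ok], "[/|]")
  gt[ok] <- vapply(parts, function(p) {
    if (any(p == ".")) return(NA_character_)
    paste(sort(as.integer(p)), collapse = "/")
  }, character(1))
  gt
}

#' @keywords internal
gt_alleles <- function(gt) lapply(strsplit(gt, "/", fixed = TRUE), as.integer)

#' @keywords internal
gt_has_alt <- function(gt) {
  out <- rep(FALSE, length(gt))
  ok <- !is.na(gt)
  out[ok] <- vapply(gt_alleles(gt[ok]), function(a) any(a > 0), logical(1))
  out
}

#' @keywords internal
gt_is_het <- function(gt) {
  out <- rep(FALSE, length(gt))
  ok <- !is.na(gt)
  out[ok] <- vapply(gt_alleles(gt[ok]), function(a) a[1] != a[2], logical(1))
  out
}

# allele-string rendering of an index genotype, e.g. "0/1" + (A, T) -> "A/T"
#' @keywords internal
gt_to_alleles <- function(gt, ref, alt) {
  ok <- !is.na(gt)
  alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
  gt[ok] <- vapply(gt_alleles(gt[ok]), function(a) {
    paste(alleles[a + 1L], collapse = "/")
  }, character(1))
  gt
}

#' Write a genotype matrix as TSV
#'
#' One row per site (`chrom`, `pos`, `ref`, `alt`, `vtype`), one column per
#' strain holding the genotype as REF/ALT allele strings, `.` for missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotype_matrix <- function(gm, path) {
  allele_calls <- gm$calls
  for (i in seq_len(nrow(allele_calls))) {
    allele_calls[i, ] <- gt_to_alleles(gm$calls[i, ],
                                       gm$sites$ref[i], gm$sites$alt[i])
  }
  allele_calls[is.na(allele_calls)] <- "."
  out <- cbind(gm$sites[, c("chrom", "pos", "ref", "alt", "vtype")],
               as.data.frame(allele_calls, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix TSV written by [write_genotype_matrix()]
#'
#' @param path TSV file.
#' @param groups optional strain-to-group map.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, groups = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, comment.char = "")
  sites <- data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
                      ref = tab$ref, alt = tab$alt, vtype = tab$vtype,
                      stringsAsFactors = FALSE)
  strain_cols <- setdiff(colnames(tab),
                         c("chrom", "pos", "ref", "alt", "vtype"))
  calls <- as.matrix(tab[, strain_cols, drop = FALSE])
  # convert allele strings back to index genotypes
  for (i in seq_len(nrow(calls))) {
    alleles <- c(sites$ref[i], strsplit(sites$alt[i], ",", fixed = TRUE)[[1]])
    row <- calls[i, ]
    row[row == "."] <- NA_character_
    ok <- !is.na(row)
    row[ok] <- vapply(strsplit(row[ok], "/", fixed = TRUE), function(p) {
      idx <- match(p, alleles) - 1L
      if (anyNA(idx)) tg_stop("allele not in REF/ALT set at row ", i)
      paste(sort(idx), collapse = "/")
    }, character(1))
    calls[i, ] <- row
  }
  genotype_matrix(sites, calls, groups = groups)
}
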