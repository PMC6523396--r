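# In-code fixture builders and independent brute-force oracles.

# O(n^2) all-pairs reference for the neighbour-window filter
neighbor_oracle <- function(sites, window, boundary = "le") {
  n <- nrow(sites)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(sites$pos - sites$pos[i])
    same <- sites$chrom == sites$chrom[i]
    other <- same & seq_len(n) != i
    keep[i] <- if (boundary == "le") {
      !any(other & d <= window)
    } else {
      !any(other & d < window)
    }
  }
  keep
}

# per-base boolean-mask union of intervals on toy chromosomes; returns the
# merged interval set independently of IRanges
mask_union_oracle <- function(intervals, chrom_len) {
  out <- list()
  for (ch in sort(unique(intervals$chrom))) {
    mask <- logical(chrom_len)
    sel <- intervals$chrom == ch
    for (i in which(sel)) {
      mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    hit <- which(r$values)
    if (length(hit) > 0) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[hit],
                              end = ends[hit], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# small genotype matrix from genotype-string vectors (one per strain)
make_gm <- function(..., chrom = NULL, pos = NULL, vtype = NULL,
                    groups = NULL) {
  calls <- cbind(...)
  n <- nrow(calls)
  sites <- data.frame(
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% seq(100, by = 200, length.out = n),
    ref = rep("A", n), alt = rep("T", n),
    vtype = vtype %||% rep("SNP", n),
    stringsAsFactors = FALSE)
  genotype_matrix(sites, calls, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written multi-sample VCF from a call spec; gt entries like "0/1:7"
write_mini_vcf <- function(path, chrom, pos, ref, alt, sample_cols) {
  libs <- names(sample_cols)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(libs, collapse = "\t")))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT:DP",
            vapply(sample_cols, `[`, character(1), i)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

mini_metadata <- function(strains, libraries = NULL, tissue = "shoot_root",
                          row_type = "two_row") {
  data.frame(strain_id = strains,
             library_id = libraries %||% paste0(strains, "_L1"),
             tissue = rep_len(tissue, length(strains)),
             row_type = rep_len(row_type, length(strains)),
             stringsAsFactors = FALSE)
}
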