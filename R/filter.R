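# Reliability + marker-suitability filter cascade over a merged multi-sample
# VCF. Stage order: per-call depth -> singleton -> replicate conflict ->
# multi-allele panel exclusion -> neighbour window.

#' Filter cascade configuration
#'
#' @param min_reads minimum supporting reads per call; calls below it are set
#'   to missing (default 2, i.e. "more than one read").
#' @param neighbor_window exclusion window in bp: a site with another
#'   polymorphism within this distance on the same chromosome is removed
#'   (default 60).
#' @param neighbor_boundary `"le"` removes pairs at distance exactly equal to
#'   the window (default); `"lt"` keeps them.
#' @param drop_singletons drop sites where only one strain carries a
#'   non-reference allele.
#' @param drop_conflicts drop sites where replicate libraries of one strain
#'   disagree.
#' @param drop_multiallelic exclude sites with two or more alternate alleles
#'   from the marker panel (they are still tallied).
#' @param depth_rule `"all"` applies `min_reads` to every non-missing call;
#'   `"het_only"` applies it to heterozygous calls only.
#' @param preference_tissues tissue tags, in preference order, used to pick
#'   one library per strain.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_reads = 2, neighbor_window = 60,
                          neighbor_boundary = c("le", "lt"),
                          drop_singletons = TRUE, drop_conflicts = TRUE,
                          drop_multiallelic = TRUE,
                          depth_rule = c("all", "het_only"),
                          preference_tissues = "shoot_root") {
  if (min_reads < 1) tg_stop("min_reads must be >= 1")
  if (neighbor_window < 0) tg_stop("neighbor_window must be >= 0")
  structure(list(min_reads = min_reads,
                 neighbor_window = neighbor_window,
                 neighbor_boundary = match.arg(neighbor_boundary),
                 drop_singletons = drop_singletons,
                 drop_conflicts = drop_conflicts,
                 drop_multiallelic = drop_multiallelic,
                 depth_rule = match.arg(depth_rule),
                 preference_tissues = preference_tissues),
            class = "filter_config")
}

#' Classify a variant site by its alleles
#'
#' @param ref reference allele string.
#' @param alts character vector of alternate alleles.
#' @return `"SNP"` (single alt, equal length 1), `"INDEL"` (single alt,
#'   unequal lengths) or `"MULTI"` (two or more alts).
#' @export
classify_site <- function(ref, alts) {
  alleles <- c(ref, alts)
  if (length(alts) == 0 || any(nchar(alleles) == 0)) {
    tg_stop("empty allele string")
  }
  if (any(grepl("[^ACGTacgt]", alleles))) {
    tg_stop("unsupported allele (symbolic/breakend or non-ACGT): ",
            paste(alleles[grepl("[^ACGTacgt]", alleles)], collapse = ", "))
  }
  if (length(alts) >= 2) return("MULTI")
  if (nchar(ref) == 1 && nchar(alts) == 1) "SNP" else "INDEL"
}

#' Per-call read-depth filter
#'
#' @param depth supporting read count(s).
#' @param min_reads threshold; a call with fewer reads fails (is set to
#'   missing by the cascade, not removed site-wide).
#' @return logical: `TRUE` = pass.
#' @export
depth_filter <- function(depth, min_reads = 2) {
  if (any(depth < 0, na.rm = TRUE)) tg_stop("negative read depth")
  depth >= min_reads
}

#' Singleton filter over one site's strain calls
#'
#' A site is unreliable for genotyping if at most one strain carries the
#' non-reference allele among non-missing calls (this also rejects
#' monomorphic and all-missing sites).
#'
#' @param strain_calls character vector of genotype strings (one per strain,
#'   `NA` missing).
#' @return logical: `TRUE` = pass. On failure the reason is attached as
#'   attribute `"reason"` (`"no data"`, `"monomorphic"` or `"singleton"`).
#' @export
singleton_filter <- function(strain_calls) {
  if (all(is.na(strain_calls))) {
    return(structure(FALSE, reason = "no data"))
  }
  n_alt <- sum(gt_has_alt(strain_calls))
  if (n_alt == 0) return(structure(FALSE, reason = "monomorphic"))
  if (n_alt == 1) return(structure(FALSE, reason = "singleton"))
  TRUE
}

#' Replicate-conflict filter over one site's library calls
#'
#' Fails when any strain with two or more libraries has two non-missing,
#' unequal genotype calls at the site. Strains with a single library are
#' vacuously consistent.
#'
#' @param lib_calls character vector of genotype strings, one per library.
#' @param lib_strain character vector of the strain each library belongs to.
#' @return logical: `TRUE` = pass.
#' @export
conflict_filter <- function(lib_calls, lib_strain) {
  for (s in unique(lib_strain[duplicated(lib_strain)])) {
    g <- lib_calls[lib_strain == s]
    g <- g[!is.na(g)]
    if (length(unique(g)) > 1) return(FALSE)
  }
  TRUE
}

#' Neighbour-window filter
#'
#' Removes every site that has another polymorphism within `window` bp on the
#' same chromosome — both members of a too-close pair are dropped, leaving
#' markers whose flanking sequence is polymorphism-free (suitable for assay
#' or primer design). Implemented as a single sweep over the
#' position-sorted site list: a site survives iff its distance to both the
#' previous and the next site on the chromosome exceeds the window.
#'
#' @param sites data.frame with `chrom` and `pos`; sorted internally.
#' @param window exclusion distance in bp.
#' @param boundary `"le"`: distance exactly `window` removes (default);
#'   `"lt"`: only strictly closer pairs remove.
#' @return logical vector (aligned to the input rows): `TRUE` = retained.
#' @export
neighbor_filter <- function(sites, window = 60, boundary = c("le", "lt")) {
  boundary <- match.arg(boundary)
  n <- nrow(sites)
  if (n == 0) return(logical(0))
  ord <- order(sites$chrom, sites$pos)
  chrom <- sites$chrom[ord]
  pos <- sites$pos[ord]
  d_prev <- c(Inf, ifelse(chrom[-1] == chrom[-n], diff(pos), Inf))
  d_next <- c(d_prev[-1], Inf)
  keep_sorted <- if (boundary == "le") {
    d_prev > window & d_next > window
  } else {
    d_prev >= window & d_next >= window
  }
  keep <- logical(n)
  keep[ord] <- keep_sorted
  keep
}

#' Pick one library per strain
#'
#' Deterministic choice: the first library whose tissue tag matches the
#' preference list (in preference order), else the lexicographically
#' smallest library id.
#'
#' @param libraries data.frame with `library_id` and `tissue` for one strain.
#' @param preference_tissues tissue tags in preference order.
#' @return the selected `library_id`.
#' @export
select_library <- function(libraries, preference_tissues = "shoot_root") {
  if (nrow(libraries) == 0) tg_stop("strain has no libraries")
  for (tis in preference_tissues) {
    hit <- libraries$library_id[libraries$tissue == tis]
    if (length(hit) > 0) return(sort(hit)[1])
  }
  sort(libraries$library_id)[1]
}

#' Read sample metadata
#'
#' TSV with columns `strain_id`, `library_id`, `tissue`, `row_type`.
#'
#' @param path metadata file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
  need <- c("strain_id", "library_id", "tissue", "row_type")
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0) {
    tg_stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$library_id)) tg_stop("duplicate library_id in metadata")
  meta
}

# Parse a merged multi-sample VCF into site table + per-library genotype and
# depth matrices. Depth is per-sample DP; if only AD exists its sum is used.
#' @keywords internal
read_vcf_calls <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0 || ncol(vcf@gt) < 2) {
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   vtype = character()),
                gt = matrix(character(), 0, 0),
                depth = matrix(numeric(), 0, 0)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fmt <- unique(vcf@gt[, "FORMAT"])
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    depth <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  } else if (any(grepl("(^|:)AD(:|$)", fmt))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    depth <- apply(ad, c(1, 2), function(x) {
      if (is.na(x)) NA_real_ else sum(as.numeric(strsplit(x, ",")[[1]]))
    })
  } else {
    tg_stop("VCF has neither DP nor AD per-sample depth fields")
  }
  gt <- matrix(gt_normalize(gt), nrow = n, dimnames = dimnames(gt))
  vtype <- vapply(seq_len(n), function(i) {
    classify_site(fix[i, "REF"],
                  strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
  }, character(1))
  list(sites = data.frame(chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          vtype = vtype, stringsAsFactors = FALSE),
       gt = gt, depth = depth)
}

#' Run the full filter cascade on a merged multi-sample VCF
#'
#' Stages, in order: (1) per-call depth — failing calls become missing;
#' (2) singleton — sites with at most one alt-carrying strain are dropped;
#' (3) replicate conflict — sites where a strain's libraries disagree are
#' dropped; (4) multi-allele sites are excluded from the marker panel;
#' (5) neighbour window — sites with a close-by polymorphism are dropped.
#' Sites that are homozygous-reference across all samples never enter the
#' cascade. One library per strain (chosen by [select_library()]) provides
#' the genotype; the conflict check uses all libraries.
#'
#' @param vcf_path merged multi-sample VCF (plain or bgzipped).
#' @param metadata data.frame from [read_metadata()]; every VCF sample
#'   column must appear as a `library_id`.
#' @param config a [filter_config()].
#' @return list with `matrix` (surviving-site [genotype_matrix()]),
#'   `report` (a `filter_report`), and `stages` (named list of logical
#'   survivor masks over the detected sites, for auditing).
#' @export
run_cascade <- function(vcf_path, metadata, config = filter_config()) {
  calls <- read_vcf_calls(vcf_path)
  libs <- colnames(calls$gt)
  unknown <- setdiff(libs, metadata$library_id)
  if (length(unknown) > 0) {
    tg_stop("VCF sample(s) absent from metadata: ",
            paste(unknown, collapse = ", "))
  }
  meta <- metadata[match(libs, metadata$library_id), , drop = FALSE]
  strains <- sort(unique(meta$strain_id))

  gt <- calls$gt
  depth <- calls$depth
  sites <- calls$sites

  if (nrow(sites) == 0) {
    report <- structure(list(n_detected = 0L, n_multi = 0L,
                             n_reliable_snp = 0L, n_reliable_indel = 0L,
                             n_final_snp = 0L, n_final_indel = 0L),
                        class = "filter_report")
    strains <- sort(unique(metadata$strain_id))
    empty_calls <- matrix(NA_character_, 0, length(strains),
                          dimnames = list(NULL, strains))
    groups <- stats::setNames(
      metadata$row_type[match(strains, metadata$strain_id)], strains)
    return(list(matrix = genotype_matrix(sites, empty_calls,
                                         groups = groups),
                report = report,
                stages = list(detected = logical(0), singleton = logical(0),
                              conflict = logical(0), panel = logical(0),
                              final = logical(0))))
  }

  if (any(depth < 0, na.rm = TRUE)) tg_stop("negative read depth in VCF")
  if (any(!is.na(gt) & (is.na(depth) | depth == 0))) {
    tg_stop("non-missing genotype with zero/absent read depth")
  }

  # detected = polymorphic sites (>=1 alt-carrying call pre-filter)
  detected <- if (nrow(gt) == 0) logical(0) else {
    rowSums(matrix(gt_has_alt(gt), nrow = nrow(gt))) > 0
  }
  sites <- sites[detected, , drop = FALSE]
  gt <- gt[detected, , drop = FALSE]
  depth <- depth[detected, , drop = FALSE]
  n_detected <- nrow(sites)
  n_multi <- sum(sites$vtype == "MULTI")

  # stage 1: depth -> missing
  low <- !is.na(gt) & !depth_filter(depth, config$min_reads)
  if (config$depth_rule == "het_only") {
    low <- low & matrix(gt_is_het(gt), nrow = nrow(gt))
  }
  gt[low] <- NA_character_

  # one library per strain
  pick <- vapply(strains, function(s) {
    select_library(meta[meta$strain_id == s, , drop = FALSE],
                   config$preference_tissues)
  }, character(1))
  sgt <- gt[, match(pick, libs), drop = FALSE]
  colnames(sgt) <- strains

  # stage 2: singleton (also drops sites left monomorphic/no-data by stage 1)
  keep_singleton <- if (config$drop_singletons) {
    apply(sgt, 1, function(r) isTRUE(singleton_filter(r)))
  } else {
    apply(sgt, 1, function(r) sum(gt_has_alt(r)) > 0)
  }

  # stage 3: replicate conflict across all libraries
  keep_conflict <- keep_singleton
  if (config$drop_conflicts && any(duplicated(meta$strain_id))) {
    idx <- which(keep_singleton)
    ok <- vapply(idx, function(i) conflict_filter(gt[i, ], meta$strain_id),
                 logical(1))
    keep_conflict[idx] <- ok
  }

  n_reliable_snp <- sum(keep_conflict & sites$vtype == "SNP")
  n_reliable_indel <- sum(keep_conflict & sites$vtype == "INDEL")

  # stage 4: multi-allele panel exclusion
  keep_panel <- keep_conflict
  if (config$drop_multiallelic) keep_panel <- keep_panel & sites$vtype != "MULTI"

  # stage 5: neighbour window (positions of panel candidates only)
  keep_final <- keep_panel
  if (any(keep_panel)) {
    nb <- neighbor_filter(sites[keep_panel, , drop = FALSE],
                          config$neighbor_window, config$neighbor_boundary)
    keep_final[keep_panel] <- nb
  }

  report <- structure(
    list(n_detected = n_detected,
         n_multi = n_multi,
         n_reliable_snp = n_reliable_snp,
         n_reliable_indel = n_reliable_indel,
         n_final_snp = sum(keep_final & sites$vtype == "SNP"),
         n_final_indel = sum(keep_final & sites$vtype == "INDEL")),
    class = "filter_report")

  groups <- stats::setNames(
    meta$row_type[match(strains, meta$strain_id)], strains)
  sdepth <- depth[, match(pick, libs), drop = FALSE]
  colnames(sdepth) <- strains
  gm <- genotype_matrix(sites[keep_final, , drop = FALSE],
                        sgt[keep_final, , drop = FALSE], groups = groups,
                        depth = sdepth[keep_final, , drop = FALSE])
  list(matrix = gm, report = report,
       stages = list(detected = rep(TRUE, n_detected),
                     singleton = keep_singleton,
                     conflict = keep_conflict,
                     panel = keep_panel,
                     final = keep_final))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade report\n")
  cat(sprintf("  Detected polymorphisms       %12s\n",
              fmt_thousands(x$n_detected)))
  cat(sprintf("  Multi-allele loci            %12s\n",
              fmt_thousands(x$n_multi)))
  cat(sprintf("  Reliable polymorphisms       %12s  (SNP %s, indel %s)\n",
              fmt_thousands(x$n_reliable_snp + x$n_reliable_indel),
              fmt_thousands(x$n_reliable_snp),
              fmt_thousands(x$n_reliable_indel)))
  cat(sprintf("  Polymorphisms after processing %10s  (SNP %s, indel %s)\n",
              fmt_thousands(x$n_final_snp + x$n_final_indel),
              fmt_thousands(x$n_final_snp), fmt_thousands(x$n_final_indel)))
  invisible(x)
}

#' Write surviving sites as a minimal VCF
#'
#' One sample column per strain (the library selected by the cascade),
#' `GT:DP` format. The result is itself valid cascade input, so the filter
#' can be re-run on its own output.
#'
#' @param gm a [genotype_matrix()] (with per-call depths, as produced by
#'   [run_cascade()]).
#' @param path output VCF path.
#' @export
write_filtered_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(colnames(gm$calls), collapse = "\t"))), con)
  if (nrow(gm$sites) > 0) {
    gtcols <- gm$calls
    if (!is.null(gm$depth)) {
      gtcols[] <- paste0(gm$calls, ":", gm$depth)
    } else {
      gtcols[] <- paste0(gm$calls, ":.")
    }
    gtcols[is.na(gm$calls)] <- "./.:."
    lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                   gm$sites$alt, ".", "PASS", ".", "GT:DP",
                   apply(gtcols, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
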