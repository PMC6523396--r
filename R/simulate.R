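# Deterministic synthetic-data generator: genome, gene models, multi-sample
# VCF with planted variants, replicate libraries and amplicon call tables,
# plus a planted-truth manifest used as the oracle in parameter-recovery
# tests. Emulates the statistical structure of low-coverage RNA-Seq
# genotyping of inbred strains at toy scale; it does not simulate reads,
# alignment, linkage disequilibrium or population structure.

#' Simulation configuration
#'
#' Planted variant categories: `clean` markers are polymorphic in at least
#' two strains with depth >= 2 and no neighbour within the exclusion window
#' (they should survive the filter cascade); `singleton` sites have exactly
#' one alt-carrying strain; `close_pair` sites come in pairs spaced
#' `close_pair_spacing` bp apart (inside a 60-bp window); `multiallelic`
#' sites carry two alternate alleles.
#'
#' @param seed RNG seed; every generator derives its stream from it.
#' @param n_chrom,chrom_len chromosome count and length (bp).
#' @param n_loci gene loci placed, split evenly over chromosomes.
#' @param locus_len_range min/max locus length (bp).
#' @param hc_fraction fraction of loci tagged as high-confidence genes.
#' @param n_strains inbred strains; `n_replicate_strains` of them get a
#'   second (replicate) library.
#' @param n_replicate_strains strains with two libraries.
#' @param n_clean,n_singletons,n_close_pairs,n_multiallelic planted counts
#'   (`n_close_pairs` counts pairs, i.e. 2 sites each).
#' @param close_pair_spacing bp between the members of a close pair.
#' @param indel_fraction fraction of planted biallelic sites that are
#'   1-3-bp indels (left-normalized at generation).
#' @param het_rate probability an alt-carrying call is heterozygous
#'   (inbred material: low).
#' @param missing_rate per-call no-call probability.
#' @param depth_mu,depth_size negative-binomial depth model (overdispersed
#'   RNA-Seq coverage proxy); realized depth is `2 + rnbinom(mu - 2, size)`
#'   so planted calls always meet the 2-read floor.
#' @param single_read_het_rate probability a heterozygous call is assigned
#'   a single supporting read (exercises the depth rule).
#' @param replicate_discordance_rate probability a replicate-library call
#'   differs from the strain's primary call.
#' @param amplicon_n_markers amplicon panel size (drawn from clean markers).
#' @param amplicon_frac_low_depth fraction of panel markers given a mean
#'   depth below 100 (the published panel had 11/384).
#' @param amplicon_error_rate,amplicon_missing_rate per-call genotype flip /
#'   drop probabilities on the amplicon platform.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_len = 200000L,
                       n_loci = 40, locus_len_range = c(1500, 4000),
                       hc_fraction = 0.7,
                       n_strains = 12, n_replicate_strains = 4,
                       n_clean = 60, n_singletons = 10,
                       n_close_pairs = 6, n_multiallelic = 5,
                       close_pair_spacing = 40,
                       indel_fraction = 0.2,
                       het_rate = 0.02, missing_rate = 0.05,
                       depth_mu = 20, depth_size = 5,
                       single_read_het_rate = 0,
                       replicate_discordance_rate = 0.09,
                       amplicon_n_markers = 48,
                       amplicon_frac_low_depth = 11 / 384,
                       amplicon_error_rate = 0.08,
                       amplicon_missing_rate = 0.1) {
  cfg <- as.list(environment())
  rates <- c(cfg$het_rate, cfg$missing_rate, cfg$replicate_discordance_rate,
             cfg$amplicon_error_rate, cfg$amplicon_missing_rate,
             cfg$amplicon_frac_low_depth, cfg$single_read_het_rate,
             cfg$indel_fraction, cfg$hc_fraction)
  if (any(rates < 0 | rates > 1)) tg_stop("rates must lie in [0, 1]")
  if (cfg$n_replicate_strains > cfg$n_strains) {
    tg_stop("n_replicate_strains exceeds n_strains")
  }
  if (cfg$depth_mu < 2) tg_stop("depth_mu must be >= 2")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome
#'
#' Uniform-base random chromosomes, reproducible under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a `DNAStringSet` named `chr1`, `chr2`, ...)
#'   and `chrom_sizes` (named vector).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(cfg$n_chrom))
  list(genome = genome,
       chrom_sizes = stats::setNames(rep(cfg$chrom_len, cfg$n_chrom),
                                     names(genome)))
}

#' Simulate gene models
#'
#' Places non-overlapping gene loci evenly over the chromosomes (with random
#' jitter) and tags a fraction as high-confidence.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return data.frame of loci (`locus_id`, `chrom`, `start` 0-based, `end`,
#'   `strand`, `source`).
#' @export
simulate_annotation <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  chroms <- names(sim$chrom_sizes)
  per_chrom <- rep(cfg$n_loci %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_loci %% cfg$n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  rows <- list()
  k <- 0L
  for (ci in seq_along(chroms)) {
    n <- per_chrom[ci]
    if (n == 0) next
    slot <- sim$chrom_sizes[ci] %/% n
    len <- sample(seq(cfg$locus_len_range[1], cfg$locus_len_range[2]), n,
                  replace = TRUE)
    if (any(len + 2 > slot)) {
      tg_stop("loci cannot fit: reduce n_loci or locus length")
    }
    start <- (seq_len(n) - 1L) * slot +
      vapply(slot - len - 1L, function(m) sample.int(m, 1), integer(1))
    for (i in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        locus_id = sprintf("locus%03d", k), chrom = chroms[ci],
        start = start[i], end = start[i] + len[i],
        strand = sample(c("+", "-"), 1),
        source = if (stats::runif(1) < cfg$hc_fraction) "HC" else "novel",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write gene models as GFF3
#'
#' @param loci data.frame from [simulate_annotation()].
#' @param path output file.
#' @export
write_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             paste(loci$chrom, loci$source, "gene", loci$start + 1L, loci$end,
                   ".", loci$strand, ".", paste0("ID=", loci$locus_id),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# draw a flipped genotype different from g, over allele indices 0..n_alt
#' @keywords internal
flip_gt <- function(g, n_alt = 1) {
  pool <- c("0/0", paste0("0/", seq_len(n_alt)),
            paste0(seq_len(n_alt), "/", seq_len(n_alt)))
  sample(setdiff(pool, g), 1)
}

#' Simulate a multi-sample VCF with planted variants
#'
#' Plants `clean`, `singleton`, `close_pair` and `multiallelic` variant
#' sites inside the gene loci (minimum 150 bp between planted features, so
#' only close-pair members fall inside each other's 60-bp window), assigns
#' inbred per-strain genotypes, injects heterozygosity and missingness,
#' draws overdispersed read depths, and duplicates replicate strains'
#' calls into second libraries with discordance flips.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @param loci data.frame from [simulate_annotation()].
#' @return list of class `sim_truth`: `variants` (with `category`),
#'   `truth_gt` (site x strain index genotypes, the planted truth),
#'   `lib_calls` / `lib_depth` (site x library realized calls),
#'   `metadata` (library table).
#' @export
simulate_strain_vcf <- function(cfg, sim, loci) {
  set.seed(cfg$seed + 2L)
  spacing <- 150L
  # candidate slots inside loci
  slots <- list()
  for (i in seq_len(nrow(loci))) {
    lo <- loci$start[i] + 10L
    hi <- loci$end[i] - 60L  # headroom for close-pair partners and deletions
    if (hi - lo < spacing) next
    p <- seq(lo, hi, by = spacing)
    slots[[i]] <- data.frame(chrom = loci$chrom[i], pos = p + 1L,
                             stringsAsFactors = FALSE)
  }
  slots <- do.call(rbind, slots)
  n_single <- cfg$n_clean + cfg$n_singletons + cfg$n_multiallelic +
    cfg$n_close_pairs
  if (nrow(slots) < n_single) {
    tg_stop("planted counts exceed capacity: ", n_single, " sites needed, ",
            nrow(slots), " slots available")
  }
  take <- slots[sort(sample.int(nrow(slots), n_single)), , drop = FALSE]
  cat_vec <- sample(c(rep("clean", cfg$n_clean),
                      rep("singleton", cfg$n_singletons),
                      rep("multiallelic", cfg$n_multiallelic),
                      rep("close_pair", cfg$n_close_pairs)))
  take$category <- cat_vec
  # each close_pair anchor gains a partner inside the window
  partners <- take[take$category == "close_pair", , drop = FALSE]
  if (nrow(partners) > 0) {
    partners$pos <- partners$pos + cfg$close_pair_spacing
    take <- rbind(take, partners)
  }
  take <- take[order(take$chrom, take$pos), , drop = FALSE]

  strains <- sprintf("S%02d", seq_len(cfg$n_strains))
  genome_chr <- lapply(sim$genome, as.character)

  n_sites <- nrow(take)
  ref <- character(n_sites)
  alt <- character(n_sites)
  vtype <- character(n_sites)
  truth <- matrix("0/0", n_sites, cfg$n_strains,
                  dimnames = list(NULL, strains))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_sites)) {
    seq_ch <- genome_chr[[take$chrom[i]]]
    b <- substr(seq_ch, take$pos[i], take$pos[i])
    cat_i <- take$category[i]
    if (cat_i == "multiallelic") {
      alts <- sample(setdiff(bases, b), 2)
      ref[i] <- b
      alt[i] <- paste(alts, collapse = ",")
      vtype[i] <- "MULTI"
    } else if (stats::runif(1) < cfg$indel_fraction) {
      if (stats::runif(1) < 0.5) {  # insertion
        ref[i] <- b
        alt[i] <- paste0(b, paste(sample(bases, sample(1:3, 1),
                                         replace = TRUE), collapse = ""))
      } else {                      # deletion
        k <- sample(1:3, 1)
        ref[i] <- substr(seq_ch, take$pos[i], take$pos[i] + k)
        alt[i] <- b
      }
      vtype[i] <- "INDEL"
    } else {
      ref[i] <- b
      alt[i] <- sample(setdiff(bases, b), 1)
      vtype[i] <- "SNP"
    }
    # planted genotypes
    n_alt_strains <- if (cat_i == "singleton") 1L else {
      sample(2:max(2, cfg$n_strains - 2), 1)
    }
    carriers <- sample.int(cfg$n_strains, n_alt_strains)
    if (cat_i == "multiallelic") {
      half <- seq_len(ceiling(n_alt_strains / 2))
      truth[i, carriers[half]] <- "1/1"
      if (n_alt_strains > length(half)) {
        truth[i, carriers[-half]] <- "2/2"
      }
    } else {
      truth[i, carriers] <- "1/1"
    }
    # heterozygote injection (inbred material: rare)
    for (s in carriers) {
      if (stats::runif(1) < cfg$het_rate) {
        g <- strsplit(truth[i, s], "/")[[1]]
        truth[i, s] <- paste0("0/", g[2])
      }
    }
  }

  variants <- data.frame(chrom = take$chrom, pos = take$pos, ref = ref,
                         alt = alt, vtype = vtype, category = take$category,
                         stringsAsFactors = FALSE)

  # libraries: one shoot_root library per strain, replicate strains get a
  # second (spike) library
  rep_strains <- strains[seq_len(cfg$n_replicate_strains)]
  metadata <- data.frame(
    strain_id = c(strains, rep_strains),
    library_id = c(paste0(strains, "_L1"), paste0(rep_strains, "_L2")),
    tissue = c(rep("shoot_root", cfg$n_strains),
               rep("spike", length(rep_strains))),
    row_type = c(ifelse(seq_len(cfg$n_strains) %% 2 == 1,
                        "two_row", "six_row"),
                 ifelse(match(rep_strains, strains) %% 2 == 1,
                        "two_row", "six_row")),
    stringsAsFactors = FALSE)

  libs <- metadata$library_id
  lib_calls <- matrix(NA_character_, n_sites, length(libs),
                      dimnames = list(NULL, libs))
  lib_depth <- matrix(0, n_sites, length(libs), dimnames = list(NULL, libs))
  n_alt_alleles <- ifelse(vtype == "MULTI", 2L, 1L)

  for (j in seq_along(libs)) {
    s <- metadata$strain_id[j]
    is_replicate <- metadata$tissue[j] == "spike"
    g <- truth[, s]
    if (is_replicate && cfg$replicate_discordance_rate > 0) {
      flips <- stats::runif(n_sites) < cfg$replicate_discordance_rate
      for (i in which(flips)) g[i] <- flip_gt(g[i], n_alt_alleles[i])
    }
    miss <- stats::runif(n_sites) < cfg$missing_rate
    g[miss] <- NA_character_
    d <- 2 + stats::rnbinom(n_sites, mu = cfg$depth_mu - 2,
                            size = cfg$depth_size)
    if (cfg$single_read_het_rate > 0) {
      het <- !is.na(g) & gt_is_het(g)
      d[het & stats::runif(n_sites) < cfg$single_read_het_rate] <- 1
    }
    d[is.na(g)] <- 0
    lib_calls[, j] <- g
    lib_depth[, j] <- d
  }

  # contract: clean (and close-pair, multiallelic) sites keep >= 2 alt
  # carriers and >= 1 called site overall; singletons keep their single
  # carrier. Restore primary-library calls where missingness broke this.
  for (i in seq_len(n_sites)) {
    need <- if (variants$category[i] == "singleton") 1L else 2L
    carriers <- which(gt_has_alt(truth[i, ]))
    protect <- strains[carriers[seq_len(min(need, length(carriers)))]]
    for (s in protect) {
      lib <- paste0(s, "_L1")
      if (is.na(lib_calls[i, lib])) {
        lib_calls[i, lib] <- truth[i, s]
        lib_depth[i, lib] <- 2 + stats::rnbinom(1, mu = cfg$depth_mu - 2,
                                                size = cfg$depth_size)
      }
    }
  }

  structure(list(variants = variants, truth_gt = truth,
                 lib_calls = lib_calls, lib_depth = lib_depth,
                 metadata = metadata, strains = strains),
            class = "sim_truth")
}

#' Write simulated calls as a multi-sample VCF
#'
#' @param truth a `sim_truth` from [simulate_strain_vcf()].
#' @param chrom_sizes named chromosome-length vector (contig headers).
#' @param path output VCF path.
#' @export
write_sim_vcf <- function(truth, chrom_sizes, path) {
  libs <- colnames(truth$lib_calls)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(chrom_sizes), ",length=",
                  chrom_sizes, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(libs, collapse = "\t")))
  body <- vapply(seq_len(nrow(truth$variants)), function(i) {
    g <- truth$lib_calls[i, ]
    d <- truth$lib_depth[i, ]
    samp <- ifelse(is.na(g), "./.:.", paste0(g, ":", d))
    paste(c(truth$variants$chrom[i], truth$variants$pos[i], ".",
            truth$variants$ref[i], truth$variants$alt[i], ".", "PASS", ".",
            "GT:DP", samp), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate an amplicon validation panel and call table
#'
#' Draws panel markers from the planted clean set, assigns per-marker mean
#' depths with a configurable fraction below the 100x gate, and realizes
#' per-strain observed genotypes with flip and drop noise.
#'
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` from [simulate_strain_vcf()].
#' @return list with `panel` (marker_id, chrom, pos, vtype, plus the planted
#'   `mean_depth`) and `calls` (marker_id, strain_id, genotype as allele
#'   strings, depth), and `true_calls` (markers x strains allele-string
#'   truth).
#' @export
simulate_amplicon <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  clean <- which(truth$variants$category == "clean")
  n_panel <- min(cfg$amplicon_n_markers, length(clean))
  pick <- sort(sample(clean, n_panel))
  panel <- data.frame(
    marker_id = sprintf("M%03d", seq_len(n_panel)),
    chrom = truth$variants$chrom[pick],
    pos = truth$variants$pos[pick],
    vtype = truth$variants$vtype[pick],
    stringsAsFactors = FALSE)
  n_low <- round(cfg$amplicon_frac_low_depth * n_panel)
  depth <- sample(100:2000, n_panel, replace = TRUE)
  if (n_low > 0) {
    depth[sample.int(n_panel, n_low)] <- sample(35:99, n_low, replace = TRUE)
  }
  panel$mean_depth <- depth

  strains <- truth$strains
  true_calls <- matrix(NA_character_, n_panel, length(strains),
                       dimnames = list(panel$marker_id, strains))
  rows <- vector("list", n_panel * length(strains))
  k <- 0L
  for (m in seq_len(n_panel)) {
    i <- pick[m]
    for (s in strains) {
      g <- truth$truth_gt[i, s]
      true_calls[m, s] <- gt_to_alleles(g, truth$variants$ref[i],
                                        truth$variants$alt[i])
      obs <- g
      if (stats::runif(1) < cfg$amplicon_error_rate) obs <- flip_gt(obs)
      geno <- if (stats::runif(1) < cfg$amplicon_missing_rate) "." else {
        gt_to_alleles(obs, truth$variants$ref[i], truth$variants$alt[i])
      }
      k <- k + 1L
      rows[[k]] <- data.frame(marker_id = panel$marker_id[m], strain_id = s,
                              genotype = geno, depth = depth[m],
                              stringsAsFactors = FALSE)
    }
  }
  list(panel = panel, calls = do.call(rbind, rows), true_calls = true_calls)
}

#' Generate a complete fixture bundle on disk
#'
#' Runs every generator under the config seed and writes FASTA, chrom-sizes
#' TSV, GFF3, VCF, metadata TSV, amplicon panel/calls TSVs and the
#' planted-truth manifest (JSON) into `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisible list of the in-memory objects plus a `paths` manifest.
#' @export
simulate_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  sim <- simulate_genome(cfg)
  loci <- simulate_annotation(cfg, sim)
  truth <- simulate_strain_vcf(cfg, sim, loci)
  amp <- simulate_amplicon(cfg, truth)

  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  utils::write.table(data.frame(names(sim$chrom_sizes), sim$chrom_sizes),
                     p("chrom.sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gff3(loci, p("genes.gff3"))
  write_sim_vcf(truth, sim$chrom_sizes, p("calls.vcf"))
  utils::write.table(truth$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(amp$panel, p("amplicon_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(amp$calls, p("amplicon_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(cfg), variants = truth$variants,
                   truth_gt = as.data.frame(truth$truth_gt))
  jsonlite::write_json(manifest, p("sim_truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(list(sim = sim, loci = loci, truth = truth, amplicon = amp,
                 paths = list(genome = p("genome.fa"),
                              chrom_sizes = p("chrom.sizes"),
                              gff3 = p("genes.gff3"),
                              vcf = p("calls.vcf"),
                              metadata = p("metadata.tsv"),
                              panel = p("amplicon_panel.tsv"),
                              amplicon_calls = p("amplicon_calls.tsv"),
                              truth = p("sim_truth.json"))))
}
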