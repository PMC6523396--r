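test_that("sites classify as SNP, indel or multi-allele", {
  expect_equal(classify_site("A", "G"), "SNP")
  expect_equal(classify_site("A", "AT"), "INDEL")
  expect_equal(classify_site("AT", "A"), "INDEL")
  expect_equal(classify_site("A", c("G", "T")), "MULTI")
  expect_error(classify_site("A", "<DEL>"), "unsupported allele")
  expect_error(classify_site("A", character(0)), "empty")
})

test_that("depth rule is a strict more-than-one-read boundary", {
  expect_false(depth_filter(1, min_reads = 2))
  expect_true(depth_filter(2, min_reads = 2))
  expect_error(depth_filter(-1), "negative")
})

test_that("singleton filter needs at least two alt-carrying strains", {
  calls <- c("1/1", rep("0/0", 9))
  expect_false(singleton_filter(calls))
  expect_equal(attr(singleton_filter(calls), "reason"), "singleton")
  expect_true(singleton_filter(c("1/1", "0/1", rep("0/0", 8))))
  expect_false(singleton_filter(rep("0/0", 10)))  # monomorphic
  expect_equal(attr(singleton_filter(rep(NA_character_, 4)), "reason"),
               "no data")
})

test_that("conflict filter flags within-strain replicate disagreement", {
  expect_true(conflict_filter(c("1/1", "1/1"), c("s1", "s1")))
  expect_false(conflict_filter(c("1/1", "0/0"), c("s1", "s1")))
  expect_true(conflict_filter(c("1/1"), c("s1")))          # vacuous
  expect_true(conflict_filter(c("1/1", NA), c("s1", "s1")))  # missing ignored
  # cross-checked against a brute-force scan of all library pairs
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    strain <- sample(c("a", "b", "c"), n, replace = TRUE)
    g <- sample(c("0/0", "0/1", "1/1", NA), n, replace = TRUE)
    brute <- TRUE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (strain[i] == strain[j] && !is.na(g[i]) && !is.na(g[j]) &&
          g[i] != g[j]) brute <- FALSE
    }
    expect_equal(conflict_filter(g, strain), brute)
  }
})

test_that("neighbour filter drops both members at the 60-bp boundary", {
  s <- data.frame(chrom = "chr1", pos = c(100, 161))
  expect_equal(neighbor_filter(s, 60), c(TRUE, TRUE))    # distance 61
  s2 <- data.frame(chrom = "chr1", pos = c(100, 160))
  expect_equal(neighbor_filter(s2, 60), c(FALSE, FALSE)) # distance 60
  expect_equal(neighbor_filter(s2, 60, boundary = "lt"), c(TRUE, TRUE))
  s3 <- data.frame(chrom = c("chr1", "chr2"), pos = c(100, 100))
  expect_equal(neighbor_filter(s3, 60), c(TRUE, TRUE))
})

test_that("neighbour sweep equals the all-pairs oracle on random site sets", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    s <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    pos = sample.int(2000, n))
    w <- sample(c(0, 10, 60, 100), 1)
    expect_equal(neighbor_filter(s, w), neighbor_oracle(s, w))
    expect_equal(neighbor_filter(s, w, "lt"), neighbor_oracle(s, w, "lt"))
  }
})

test_that("library selection prefers the common tissue, then lexicographic id", {
  libs <- data.frame(library_id = c("lib2", "lib1"),
                     tissue = c("shoot_root", "spike"))
  expect_equal(select_library(libs, "shoot_root"), "lib2")
  expect_equal(select_library(libs[1, ], "shoot_root"), "lib2")
  no_match <- data.frame(library_id = c("libB", "libA"),
                         tissue = c("spike", "spike"))
  expect_equal(select_library(no_match, "shoot_root"), "libA")
})

test_that("cascade applies depth, singleton, conflict and neighbour stages", {
  vcf <- tempfile(fileext = ".vcf")
  # sites: 1 clean, 2 singleton, 3 low-depth-carrier, 4+5 close pair,
  # 6 conflict between s1's libraries, 7 multiallelic
  write_mini_vcf(
    vcf,
    chrom = rep("chr1", 7),
    pos = c(100, 300, 500, 700, 745, 900, 1100),
    ref = rep("A", 7),
    alt = c("T", "T", "T", "T", "T", "T", "G,T"),
    sample_cols = list(
      s1a = c("1/1:9", "0/0:9", "0/0:9", "1/1:9", "1/1:9", "1/1:9", "1/1:9"),
      s1b = c("1/1:9", "0/0:9", "0/0:9", "1/1:9", "1/1:9", "0/0:9", "1/1:9"),
      s2a = c("1/1:9", "1/1:9", "1/1:1", "1/1:9", "1/1:9", "1/1:9", "2/2:9"),
      s3a = c("0/0:9", "0/0:9", "1/1:2", "0/0:9", "0/0:9", "0/0:9", "0/0:9")))
  meta <- data.frame(strain_id = c("s1", "s1", "s2", "s3"),
                     library_id = c("s1a", "s1b", "s2a", "s3a"),
                     tissue = c("shoot_root", "spike", "shoot_root",
                                "shoot_root"),
                     row_type = "two_row")
  res <- run_cascade(vcf, meta)
  expect_equal(res$report$n_detected, 7)
  expect_equal(res$report$n_multi, 1)
  # survivors: only site 100 (500 loses its single surviving carrier to the
  # depth rule -> singleton; 300 singleton; 700/745 neighbour pair; 900
  # conflict; 1100 multiallelic)
  expect_equal(res$matrix$sites$pos, 100)
  expect_equal(unname(res$matrix$calls[1, ]), c("1/1", "1/1", "0/0"))
  # stage masks are monotone
  st <- res$stages
  expect_true(all(st$conflict <= st$singleton))
  expect_true(all(st$panel <= st$conflict))
  expect_true(all(st$final <= st$panel))
  # report consistency
  expect_lte(res$report$n_final_snp, res$report$n_reliable_snp)
  expect_lte(res$report$n_final_indel, res$report$n_reliable_indel)
})

test_that("cascade errors on unmapped samples and depthless genotypes", {
  vcf <- tempfile(fileext = ".vcf")
  write_mini_vcf(vcf, "chr1", 100, "A", "T",
                 list(sX = "1/1:5", sY = "1/1:5"))
  expect_error(run_cascade(vcf, mini_metadata("sX", "sX")), "sY")
  vcf2 <- tempfile(fileext = ".vcf")
  write_mini_vcf(vcf2, "chr1", 100, "A", "T",
                 list(sX = "1/1:0", sY = "1/1:5"))
  expect_error(run_cascade(vcf2, mini_metadata(c("sX", "sY"), c("sX", "sY"))),
               "zero/absent read depth")
})

test_that("empty VCF produces a zero report and empty panel", {
  vcf <- tempfile(fileext = ".vcf")
  write_mini_vcf(vcf, character(0), integer(0), character(0), character(0),
                 list(sA = character(0), sB = character(0)))
  res <- run_cascade(vcf, mini_metadata(c("sA", "sB"), c("sA", "sB")))
  expect_equal(res$report$n_detected, 0)
  expect_equal(res$report$n_final_snp + res$report$n_final_indel, 0)
  expect_equal(nrow(res$matrix$sites), 0)
})

test_that("re-running the cascade on its own output changes nothing", {
  cfg <- sim_config(seed = 5, het_rate = 0, missing_rate = 0,
                    replicate_discordance_rate = 0)
  b <- simulate_bundle(cfg, tempfile("idem"))
  res1 <- run_cascade(b$paths$vcf, b$truth$metadata)
  vcf2 <- tempfile(fileext = ".vcf")
  write_filtered_vcf(res1$matrix, vcf2)
  strains <- colnames(res1$matrix$calls)
  res2 <- run_cascade(vcf2, mini_metadata(strains, strains))
  expect_equal(res2$matrix$sites, res1$matrix$sites)
  expect_equal(res2$matrix$calls, res1$matrix$calls)
  expect_equal(res2$report$n_final_snp, res1$report$n_final_snp)
  expect_equal(res2$report$n_final_indel, res1$report$n_final_indel)
})

test_that("noise-free planted fixtures are recovered exactly", {
  cfg <- sim_config(seed = 17, het_rate = 0, missing_rate = 0,
                    replicate_discordance_rate = 0)
  b <- simulate_bundle(cfg, tempfile("clean"))
  res <- run_cascade(b$paths$vcf, b$truth$metadata)
  truth <- b$truth$variants
  clean <- truth[truth$category == "clean", ]
  expect_setequal(paste(res$matrix$sites$chrom, res$matrix$sites$pos),
                  paste(clean$chrom, clean$pos))
  # genotypes survive unaltered
  idx <- match(paste(res$matrix$sites$chrom, res$matrix$sites$pos),
               paste(truth$chrom, truth$pos))
  expect_equal(unname(res$matrix$calls),
               unname(b$truth$truth_gt[idx, colnames(res$matrix$calls)]))
})
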