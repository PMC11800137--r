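test_that("rarity filter passes the reported frequencies and fails common alleles", {
  cfg <- filter_config()
  expect_equal(maf_filter(c(ExAC_AF = 3.295e-05, gnomAD_AF = 1.589e-05,
                            KG1000_AF = 1.997e-04), cfg), "pass")
  expect_equal(maf_filter(c(gnomAD_AF = 0.01), cfg), "fail")
  # one common database entry fails the variant even if others are rare
  expect_equal(maf_filter(c(ExAC_AF = 1e-05, gnomAD_AF = 0.002), cfg), "fail")
  # boundary: a frequency equal to the threshold is not rare
  expect_equal(maf_filter(c(ExAC_AF = 0.001), cfg), "fail")
  expect_equal(maf_filter(numeric(0), cfg), "pass_flagged")
  expect_equal(maf_filter(c(ExAC_AF = NA_real_), cfg), "pass_flagged")
  strict <- filter_config(missing_af_policy = "fail")
  expect_equal(maf_filter(numeric(0), strict), "fail")
})

test_that("consequence filter is a whitelist", {
  cfg <- filter_config()
  expect_true(consequence_filter("missense", cfg))
  expect_true(consequence_filter("stop_gain", cfg))
  expect_false(consequence_filter("synonymous", cfg))
  expect_false(consequence_filter("other", cfg))
  expect_false(consequence_filter(NA_character_, cfg))
})

test_that("segregation filter delegates to the pedigree check", {
  ped <- ped_wgs7()
  cfg <- filter_config()
  expect_true(segregation_filter(geno_wgs7(), ped, cfg)$segregates)
  bad <- geno_wgs7(); bad["II-2"] <- 1
  expect_false(segregation_filter(bad, ped, cfg)$segregates)
  allmiss <- setNames(rep(NA_real_, 7), names(geno_wgs7()))
  expect_false(segregation_filter(allmiss, ped, cfg)$segregates)
})

test_that("known-gene screen reports without excluding", {
  ann <- read_annotation_table(extdata("candidates7_synthetic.tsv"))
  cfg <- filter_config()
  expect_equal(nrow(known_gene_screen(ann, cfg)), 0L)
  ann2 <- ann
  ann2$gene[2] <- "PSEN1"
  hits <- known_gene_screen(ann2, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene, "PSEN1")
  expect_equal(nrow(known_gene_screen(ann[integer(0), ], cfg)), 0L)
})

test_that("cascade keeps all seven in-study candidates and logs a conserving funnel", {
  vset <- read_vcf(extdata("candidates7_synthetic.vcf"))
  ann <- read_annotation_table(extdata("candidates7_synthetic.tsv"))
  ped <- ped_wgs7()
  res <- apply_cascade(join_annotations(vset, ann), vset$geno, ped,
                       filter_config())
  expect_equal(nrow(res$survivors), 7L)
  expect_equal(res$funnel$stage, c("consequence", "rarity", "segregation"))
  expect_equal(res$funnel$n_in, res$funnel$n_pass + res$funnel$n_fail)
  expect_equal(res$funnel$n_in[-1], res$funnel$n_pass[-3])
})

test_that("cascade on an empty input yields an empty funnel of zeros", {
  vset <- read_vcf_lines(vcf_header(c("II-1", "II-2")))
  ped <- ped_wgs7()
  res <- apply_cascade(join_annotations(vset, NULL), vset$geno, ped,
                       filter_config())
  expect_equal(nrow(res$survivors), 0L)
  expect_equal(res$funnel$n_in, c(0L, 0L, 0L))
  expect_equal(res$funnel$n_pass, c(0L, 0L, 0L))
})

test_that("a hand-checked toy set filters to exactly the expected survivors", {
  ped <- ped_wgs7()
  samples <- names(geno_wgs7())
  seg_geno <- geno_wgs7()                     # co-segregates
  bad_geno <- geno_wgs7(); bad_geno["II-2"] <- 1  # II-2 violates
  ann <- data.frame(
    chrom = "1", pos = 1:5 * 100L, ref = "A", alt = "G",
    consequence = c("missense", "synonymous", "missense", "missense",
                    "missense"),
    ExAC_AF = c(1e-05, 1e-05, 0.05, 1e-05, 1e-05),
    stringsAsFactors = FALSE
  )
  ann$key <- variant_key(ann)
  geno <- rbind(seg_geno, seg_geno, seg_geno, bad_geno, seg_geno)
  colnames(geno) <- samples
  res <- apply_cascade(ann, geno, ped, filter_config())
  # row 1 and row 5 survive: row 2 synonymous, row 3 common, row 4 violates
  expect_equal(res$survivor_idx, c(1L, 5L))
  expect_equal(res$funnel$n_fail, c(1L, 1L, 1L))
  expect_equal(res$funnel$n_in, c(5L, 4L, 3L))
})

test_that("funnel conservation holds on randomized inputs", {
  ped <- ped_wgs7()
  samples <- ped$individual_id
  set.seed(99)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    ann <- data.frame(
      chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
      consequence = sample(c("missense", "synonymous", "other", NA), n,
                           replace = TRUE),
      ExAC_AF = sample(c(1e-05, 0.01, NA), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ann$key <- variant_key(ann)
    geno <- matrix(sample(c(0:2, NA), n * 7, replace = TRUE), nrow = n,
                   dimnames = list(NULL, samples))
    res <- apply_cascade(ann, geno, ped, filter_config())
    expect_equal(res$funnel$n_in, res$funnel$n_pass + res$funnel$n_fail)
    expect_equal(res$funnel$n_in[-1], res$funnel$n_pass[-3])
    expect_equal(nrow(res$survivors), res$funnel$n_pass[3])
  }
})

test_that("lowering the MAF threshold never increases survivors", {
  ped <- ped_wgs7()
  samples <- ped$individual_id
  set.seed(123)
  n <- 60L
  ann <- data.frame(
    chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
    consequence = "missense",
    ExAC_AF = stats::rbeta(n, 0.4, 20),
    stringsAsFactors = FALSE
  )
  ann$key <- variant_key(ann)
  geno <- matrix(rep(geno_wgs7(), each = n), nrow = n,
                 dimnames = list(NULL, names(geno_wgs7())))
  thresholds <- c(0.1, 0.01, 0.001, 1e-04, 1e-05)
  survivors <- vapply(thresholds, function(th) {
    nrow(apply_cascade(ann, geno, ped,
                       filter_config(maf_threshold = th))$survivors)
  }, integer(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("per-variant verdicts do not depend on input order", {
  vset <- read_vcf(extdata("candidates7_synthetic.vcf"))
  ann <- read_annotation_table(extdata("candidates7_synthetic.tsv"))
  ped <- ped_wgs7()
  joined <- join_annotations(vset, ann)
  set.seed(5)
  perm <- sample(nrow(joined))
  res1 <- apply_cascade(joined, vset$geno, ped, filter_config())
  res2 <- apply_cascade(joined[perm, ], vset$geno[perm, , drop = FALSE], ped,
                        filter_config())
  expect_setequal(res1$survivors$key, res2$survivors$key)
})

test_that("filter config loads from JSON and YAML", {
  j <- tempfile(fileext = ".json")
  writeLines('{"maf_threshold": 0.01, "known_genes": ["MAPT"]}', j)
  cfg <- read_filter_config(j)
  expect_equal(cfg$maf_threshold, 0.01)
  expect_equal(cfg$known_genes, "MAPT")
  expect_equal(cfg$min_informative, 2L)  # defaults retained

  y <- tempfile(fileext = ".yaml")
  writeLines(c("maf_threshold: 0.005", "min_informative: 3"), y)
  cfg2 <- read_filter_config(y)
  expect_equal(cfg2$maf_threshold, 0.005)
  expect_equal(cfg2$min_informative, 3L)
})
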