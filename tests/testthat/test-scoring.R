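test_that("criterion evaluation uses strict inequalities and flags missing", {
  sift <- criterion("SIFT", "numeric_below", 0.05)
  expect_equal(evaluate_criterion(list(SIFT = 0.049), sift), "satisfied")
  expect_equal(evaluate_criterion(list(SIFT = 0.05), sift), "unsatisfied")
  expect_equal(evaluate_criterion(list(SIFT = NA), sift), "missing")
  expect_equal(evaluate_criterion(list(), sift), "missing")

  cadd <- criterion("CADD_phred", "numeric_above", 20)
  expect_equal(evaluate_criterion(list(CADD_phred = 20), cadd), "unsatisfied")
  expect_equal(evaluate_criterion(list(CADD_phred = 20.01), cadd), "satisfied")

  mt <- criterion("MutationTaster", "label_in", damaging_labels = c("A", "D"))
  expect_equal(evaluate_criterion(list(MutationTaster = "A"), mt), "satisfied")
  expect_equal(evaluate_criterion(list(MutationTaster = "N"), mt), "unsatisfied")

  # type mismatches are typed errors naming the tool
  expect_error(evaluate_criterion(list(MutationTaster = 0.5), mt),
               "MutationTaster.*numeric")
  expect_error(evaluate_criterion(list(SIFT = "damaging"), sift),
               "SIFT.*label")
})

test_that("criterion and registry constructors enforce their contracts", {
  expect_error(criterion("X", "numeric_below"), "threshold")
  expect_error(criterion("X", "label_in"), "damaging_labels")
  expect_error(criterion("X", "numeric_above", 1, weight = 0), "positive")
  expect_error(criteria_set(criterion("A", "numeric_above", 1),
                            criterion("A", "numeric_below", 2)),
               "duplicate")
  cs <- default_criteria()
  expect_length(cs, 14L)
  expect_equal(attr(cs, "max_score"), 14)
})

test_that("cumulative score sums satisfied weights; missing contributes zero", {
  cs <- default_criteria()
  all_damaging <- list(
    SIFT = 0.001, PolyPhen2 = 0.99, CADD_phred = 25, CADD_raw = 3,
    `GERP++RS` = 5, `M-CAP` = 0.1, LoFtool = 0.1, Condel = "deleterious",
    DANN = "D", FATHMM = "D", LRT = "D", MetaLR = "D",
    MutationTaster = "A", PROVEAN = "D"
  )
  res <- damaging_score(all_damaging, cs)
  expect_equal(res$score, 14)
  expect_equal(res$n_tools_deleterious, 14L)
  expect_true(all(res$breakdown == "satisfied"))

  none <- damaging_score(list(), cs)
  expect_equal(none$score, 0)
  expect_true(all(none$breakdown == "missing"))
  expect_equal(count_deleterious_tools(all_damaging, cs), 14L)
  expect_equal(count_deleterious_tools(list(), cs), 0L)
})

test_that("score equals an independent per-criterion re-evaluation on 1,000 random profiles", {
  # a mixed registry incl. non-unit weights, both numeric kinds, labels
  cs <- criteria_set(
    criterion("SIFT", "numeric_below", 0.05, weight = 2),
    criterion("PolyPhen2", "numeric_above", 0.8),
    criterion("CADD_phred", "numeric_above", 20, weight = 1.5),
    criterion("FATHMM", "label_in", damaging_labels = "D"),
    criterion("MutationTaster", "label_in", damaging_labels = c("A", "D"),
              weight = 3)
  )
  set.seed(2024)
  for (i in 1:1000) {
    prof <- random_profile(cs)
    got <- damaging_score(prof, cs)
    want <- oracle_score(prof, cs)
    expect_equal(got$score, want$score)
    expect_equal(got$n_tools_deleterious, want$n_tools_deleterious)
    expect_true(got$score >= 0 && got$score <= attr(cs, "max_score"))
  }
})

test_that("flipping one criterion to satisfied raises the score by exactly its weight", {
  cs <- default_criteria()
  benign <- list(
    SIFT = 0.9, PolyPhen2 = 0.1, CADD_phred = 5, CADD_raw = 0,
    `GERP++RS` = 0, `M-CAP` = 0.001, LoFtool = 0.9, Condel = "neutral",
    DANN = "T", FATHMM = "T", LRT = "N", MetaLR = "T",
    MutationTaster = "N", PROVEAN = "N"
  )
  damaging_value <- list(
    SIFT = 0.001, PolyPhen2 = 0.99, CADD_phred = 30, CADD_raw = 4,
    `GERP++RS` = 5.5, `M-CAP` = 0.5, LoFtool = 0.01, Condel = "deleterious",
    DANN = "D", FATHMM = "D", LRT = "D", MetaLR = "D",
    MutationTaster = "A", PROVEAN = "D"
  )
  base <- damaging_score(benign, cs)$score
  for (cr in cs) {
    prof <- benign
    prof[[cr$tool]] <- damaging_value[[cr$tool]]
    expect_equal(damaging_score(prof, cs)$score, base + cr$weight)
  }
})

test_that("vectorized scoring matches the scalar path", {
  ann <- read_annotation_table(extdata("candidates7_synthetic.tsv"))
  cs <- read_criteria(extdata("criteria20_synthetic.json"))
  scored <- score_variants(ann, cs)
  for (i in seq_len(nrow(ann))) {
    single <- damaging_score(as.list(ann[i, ]), cs)
    expect_equal(scored$score[i], single$score)
    expect_equal(scored$n_tools_deleterious[i], single$n_tools_deleterious)
  }
})

test_that("ranking is a dense permutation with the documented tie-breaks", {
  df <- data.frame(
    chrom = c("2", "1", "3", "1"), pos = c(10L, 20L, 30L, 5L),
    score = c(5, 5, 9, 2), CADD_phred = c(22, 25, 30, 10),
    key = letters[1:4], stringsAsFactors = FALSE
  )
  ranked <- rank_variants(df)
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$key, c("c", "b", "a", "d"))  # tie on 5 broken by CADD 25 > 22
  # rank 1 attains the maximum score
  expect_equal(ranked$score[1], max(df$score))
  # permutation
  expect_setequal(ranked$key, df$key)
  # exact duplicates share a dense rank
  dup <- rank_variants(data.frame(chrom = "1", pos = 7L, score = 3,
                                  CADD_phred = 12, key = c("x", "y")))
  expect_equal(dup$rank, c(1L, 1L))
  # empty input
  empty <- rank_variants(df[integer(0), ])
  expect_equal(nrow(empty), 0L)
})

test_that("criteria registry loads from JSON with derived max score", {
  cs <- read_criteria(extdata("criteria20_synthetic.json"))
  expect_length(cs, 14L)
  expect_equal(attr(cs, "max_score"), 20)
  expect_equal(cs$SIFT$weight, 2)
  expect_equal(cs$MutationTaster$damaging_labels, c("A", "D"))

  y <- tempfile(fileext = ".yaml")
  writeLines(c("- tool: SIFT", "  kind: numeric_below", "  threshold: 0.05",
               "- tool: LRT", "  kind: label_in",
               "  damaging_labels: [D]", "  weight: 2"), y)
  cs2 <- read_criteria(y)
  expect_equal(attr(cs2, "max_score"), 3)
})
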