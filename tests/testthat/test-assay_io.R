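test_that("read_assays parses delimited files and enforces the contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,replicate,fitness",
               "ID11,1,15.2", "A,1,19.1", "A,2,18.7"), f)
  x <- read_assays(f)
  expect_equal(nrow(x), 3L)
  expect_equal(length(unique(x$genotype)), 2L)
  expect_type(x$fitness, "double")

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genotype\treplicate\tfitness", "B\t1\t18.9"), ft)
  expect_equal(read_assays(ft)$genotype, "B")

  bad <- withr::local_tempfile()
  writeLines(c("genotype,replicate,fitness", "A,1,19.1", "B,1,abc"), bad)
  expect_error(read_assays(bad), "row 2")

  noc <- withr::local_tempfile()
  writeLines(c("genotype,rep,fitness", "A,1,19.1"), noc)
  expect_error(read_assays(noc), "missing required column")

  dup <- withr::local_tempfile()
  writeLines(c("genotype,replicate,fitness", "A,1,19.1", "A,1,18.0"), dup)
  expect_error(read_assays(dup), "duplicated")
})

test_that("write/read round trip reproduces records exactly", {
  assays <- generate_assays(generator_config(), seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_assays(assays, f)
  back <- read_assays(f)
  expect_equal(back$genotype, assays$genotype)
  expect_equal(back$fitness, assays$fitness, tolerance = 1e-12)
})

test_that("summarize_assays computes n, mean and SE with the n-1 SD", {
  x <- data.frame(genotype = c("A", "A", "B", "B", "B"),
                  replicate = c(1, 2, 1, 2, 3),
                  fitness = c(2, 4, 5, 5, 5))
  s <- summarize_assays(x)
  expect_equal(s$genotype, c("A", "B"))  # lexicographic
  expect_equal(s$mean, c(3, 5))
  expect_equal(s$se, c(1, 0))            # sd{2,4}/sqrt(2) = 1
  expect_equal(sum(s$n), nrow(x))        # conservation

  one <- data.frame(genotype = "C", replicate = 1, fitness = 7)
  expect_warning(s1 <- summarize_assays(one), "single replicate")
  expect_true(is.na(s1$se))
})

test_that("effect_table computes effects relative to the wild type", {
  fx <- id11_fixture()
  eff <- fx$effects
  expect_equal(eff$effect[eff$genotype == "ID11"], 0)
  expect_equal(eff$effect[eff$genotype == "AB"], 3.47)
  expect_equal(eff$effect[eff$genotype == "G"], 5.84)
  expect_equal(eff$first[eff$genotype == "AB"], "A")
  expect_equal(eff$second[eff$genotype == "AB"], "B")
  expect_equal(attr(eff, "wild_type_mean"), 15.19)

  # double whose letters are not both singles
  s <- data.frame(genotype = c("WT", "A", "AZ"), n = c(2, 2, 2),
                  mean = c(10, 11, 12))
  expect_error(effect_table(s, wild_type = "WT"), "decompose")
  expect_error(effect_table(s[1:2, ], wild_type = "X"), "not present")
})

test_that("effects are invariant to a constant fitness shift", {
  assays <- generate_assays(generator_config(), seed = 3)
  e1 <- effect_table(summarize_assays(assays))
  assays$fitness <- assays$fitness + 2.5
  e2 <- effect_table(summarize_assays(assays))
  expect_equal(e1$effect, e2$effect, tolerance = 1e-12)
  # one summary per distinct genotype
  expect_equal(nrow(e1), length(unique(assays$genotype)))
})
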