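# Metrics, census comparison, and parts-versus-totals validation.

test_that("N50 follows its definition", {
  expect_identical(assemblyMetrics(10)$n50_bp, 10)
  expect_identical(assemblyMetrics(c(5, 4, 3, 2, 1))$n50_bp, 4)
  expect_identical(assemblyMetrics(c(1, 1, 1, 1))$n50_bp, 1)
  set.seed(17)
  for (i in 1:50) {
    lens <- sample.int(1e5, sample(1:40, 1))
    expect_equal(assemblyMetrics(lens)$n50_bp, brute_n50(lens))
  }
  m <- assemblyMetrics(Assembly(c(c1 = "ACGTNNNNNNNNNNAC")))
  expect_identical(m$effective_bp, 6)
  expect_identical(m$gaps_placeholder10, 1)
  expect_error(assemblyMetrics(c(0, 5)), "positive")
})

test_that("compareCensuses is a signed new-minus-old difference", {
  a <- data.frame(seq_id = c("c1", "Total"), total_length = c(100, 100),
                  gap_length = c(10, 10), effective_length = c(90, 90),
                  gap_number = c(3, 3))
  b <- data.frame(seq_id = c("c1", "Total"), total_length = c(98, 98),
                  gap_length = c(4, 4), effective_length = c(94, 94),
                  gap_number = c(1, 1))
  d <- compareCensuses(a, b)
  expect_identical(d$total_length, c(-2, -2))
  expect_identical(d$gap_length, c(-6, -6))
  expect_identical(d$effective_length, c(4, 4))
  # antisymmetry
  d2 <- compareCensuses(b, a)
  for (col in names(d)[-1]) expect_identical(d[[col]], -d2[[col]])
  expect_error(compareCensuses(a, b[1, ]), "different sequence sets")
})

test_that("the published pseudomolecule difference row is reproduced", {
  cen <- read_fixture("pseudomolecule_census.tsv")
  v4 <- cen[cen$version == "v4.0", -2]
  v5 <- cen[cen$version == "v5.0", -2]
  names(v4)[1] <- names(v5)[1] <- "seq_id"
  d <- compareCensuses(v4, v5)
  tot <- d[d$seq_id == "Total", ]
  expect_equal(tot$total_length, -3773173)
  expect_equal(tot$gap_length, -13466762)
  expect_equal(tot$effective_length, 9693589)
  expect_equal(tot$gap_number, -38899)
})

test_that("validateTotals passes the bundled census tables", {
  # transposable-element classes: element and bp columns exact, percentage
  # column within printed rounding (0.01)
  te <- read_fixture("te_classes.tsv")
  vals <- c(stats::setNames(te$elements, paste0("n:", te$class)),
            stats::setNames(te$sequence_length_bp, paste0("bp:", te$class)),
            stats::setNames(te$genome_pct, paste0("pct:", te$class)))
  parts <- te$class[te$group == "interspersed"]
  rel <- function(prefix, total, parts, tol = 0)
    list(total = paste0(prefix, total), parts = paste0(prefix, parts),
         tolerance = tol)
  relations <- list(
    rel("n:", "Total interspersed", parts),
    rel("bp:", "Total interspersed", parts),
    rel("pct:", "Total interspersed", parts, tol = 0.01),
    rel("n:", "Total", c("Total interspersed", "Low complexity",
                         "Simple repeat")),
    rel("bp:", "Total", c("Total interspersed", "Low complexity",
                          "Simple repeat")),
    rel("pct:", "Total", c("Total interspersed", "Low complexity",
                           "Simple repeat"), tol = 0.01))
  expect_identical(nrow(validateTotals(vals, relations)), 0L)
  # a deliberately corrupted cell yields exactly one violation naming it
  bad <- vals
  bad["n:LTR/Gypsy"] <- bad["n:LTR/Gypsy"] + 1
  v <- validateTotals(bad, relations)
  expect_identical(nrow(v), 1L)
  expect_identical(v$total_label, "n:Total interspersed")
  expect_identical(v$difference, -1)
})

test_that("intact LTR-retrotransposon chromosome counts sum to the totals", {
  ltr <- read_fixture("intact_ltr_rt_counts.tsv")
  chroms <- ltr$pseudomolecule[ltr$pseudomolecule != "Total"]
  for (col in names(ltr)[-1]) {
    vals <- stats::setNames(ltr[[col]], ltr$pseudomolecule)
    expect_identical(
      nrow(validateTotals(vals, list(list(total = "Total",
                                          parts = chroms)))), 0L)
  }
  expect_identical(ltr$copia_v5[ltr$pseudomolecule == "Total"], 15296L)
})

test_that("gene and resistance-gene tables are internally consistent", {
  gene <- read_fixture("gene_annotation_summary.tsv")
  for (col in c("v4_HC", "v4_LC", "v5_HC", "v5_LC")) {
    vals <- stats::setNames(gene[[col]], gene$metric)
    expect_identical(nrow(validateTotals(vals, list(
      list(total = "total_genes",
           parts = c("single_exon_genes", "multi_exon_genes"))))), 0L)
  }
  rga <- read_fixture("rga_counts.tsv")
  cats <- c("NBS", "CNL", "TNL", "CN", "TN", "NL", "RLP", "RLK", "TM-CC")
  for (i in 1:2) {
    vals <- c(unlist(rga[i, cats]), total = rga$total[i])
    expect_identical(nrow(validateTotals(vals, list(
      list(total = "total", parts = cats)))), 0L)
  }
  expect_identical(rga$total, c(1921L, 2243L))
  expect_error(validateTotals(c(a = 1), list(list(total = "a",
                                                  parts = "zzz"))),
               "unknown label")
})

test_that("pseudomolecule census rows obey the effective-length identity", {
  cen <- read_fixture("pseudomolecule_census.tsv")
  expect_true(all(cen$total_length - cen$gap_length == cen$effective_length))
  for (ver in c("v4.0", "v5.0")) {
    x <- cen[cen$version == ver, ]
    for (col in c("total_length", "gap_length", "effective_length",
                  "gap_number"))
      expect_identical(sum(x[[col]][x$pseudomolecule != "Total"]),
                       x[[col]][x$pseudomolecule == "Total"])
  }
})
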