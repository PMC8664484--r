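# Synthetic-data generator contracts.

test_that("genome generation is deterministic, N-free, and validates input", {
  tr1 <- generateGenome(1, n_chrom = 2, chrom_length = 2e4)
  tr2 <- generateGenome(1, n_chrom = 2, chrom_length = 2e4)
  expect_identical(as.character(truthGenome(tr1)),
                   as.character(truthGenome(tr2)))
  expect_identical(unname(Biostrings::width(truthGenome(tr1))),
                   c(20000L, 20000L))
  expect_false(any(grepl("N", as.character(truthGenome(tr1)), fixed = TRUE)))
  tr3 <- generateGenome(2, n_chrom = 2, chrom_length = 2e4)
  expect_false(identical(as.character(truthGenome(tr1)),
                         as.character(truthGenome(tr3))))
  expect_error(generateGenome(1, chrom_length = 5000), "10 kb")
  expect_error(generateGenome(1, chrom_length = 2e4, repeat_fraction = 1.2),
               "repeat_fraction")
  expect_error(generateGenome(1, chrom_length = 2e4,
                              tandem_block_rate = -1), "tandem_block_rate")
})

test_that("tandem block counts follow the requested Poisson rate", {
  # sum of per-seed counts over 60 independent 1-Mb genomes at 10 blocks/Mb
  # ~ Poisson(600); require the central 99% interval
  counts <- vapply(1:60, function(s) {
    tr <- generateGenome(s, n_chrom = 1, chrom_length = 1e6,
                         tandem_block_rate = 10)
    sum(tr@features$type == "tandem_block")
  }, 0L)
  lim <- qpois(c(0.005, 0.995), 600)
  expect_gte(sum(counts), lim[1])
  expect_lte(sum(counts), lim[2])
})

test_that("fragmentAssembly honours the placeholder mix and registers truth", {
  tr <- generateGenome(7, n_chrom = 1, chrom_length = 1e5,
                       tandem_block_rate = 0)
  fa <- fragmentAssembly(tr, placeholder_mix = c("10" = 1),
                         gap_rate = 60, sized_gap_rate = 0)
  gr <- gapRanges(fa$assembly)
  expect_gt(length(gr), 0)
  expect_true(all(gr$gap_length == 10L))
  expect_true(all(gr$klass == "placeholder10"))
  # registry and gap truth agree exactly: positions, lengths, classes
  gt <- fa$truth@gap_truth
  o <- order(gt$start)
  expect_identical(gt$start[o], BiocGenerics::start(gr))
  expect_identical(gt$end[o], BiocGenerics::end(gr))
  expect_identical(gt$klass[o], gr$klass)
  # segment layout tiles the draft around the gaps
  lay <- fa$truth@segment_layout
  expect_true(all(lay$seq_end >= lay$seq_start))
  expect_error(fragmentAssembly(tr, placeholder_mix = c("10" = 0.5)),
               "sum to 1")
})

test_that("planted flank duplication lengthens the draft by the copy", {
  tr <- generateGenome(11, n_chrom = 1, chrom_length = 1e5,
                       tandem_block_rate = 0)
  base <- fragmentAssembly(tr, seed = 99L)
  dup <- fragmentAssembly(tr, seed = 99L, error_plan = list(
    list(kind = "flank_duplication", dup_length = 2000)))
  d <- sum(Biostrings::width(assemblySeqs(dup$assembly))) -
    sum(Biostrings::width(assemblySeqs(base$assembly)))
  expect_identical(d, 2000L + 10L)  # duplicate copy plus the artifact 10-N
  pe <- dup$truth@planted_errors
  expect_identical(pe$kind, "flank_duplication")
})

test_that("planted inversion emits the reverse complement of the segment", {
  tr <- generateGenome(13, n_chrom = 1, chrom_length = 3e5)
  base <- fragmentAssembly(tr, seed = 5L)
  inv <- fragmentAssembly(tr, seed = 5L,
                          error_plan = list(list(kind = "inversion")))
  lay <- inv$truth@segment_layout
  flipped <- lay[lay$orientation == "-", , drop = FALSE]
  expect_gt(nrow(flipped), 0)
  r <- flipped[1, ]
  seg <- substr(as.character(assemblySeqs(inv$assembly)[[r$seq_id]]),
                r$seq_start, r$seq_end)
  src <- substr(as.character(truthGenome(tr)[[r$source_chrom]]),
                r$source_start, r$source_end)
  expect_identical(seg, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(src))))
  # invalid error plans are parameter errors
  expect_error(fragmentAssembly(tr, error_plan = list(list(kind = "bogus"))),
               "kind")
  expect_error(fragmentAssembly(tr, error_plan = list(
    list(kind = "flank_duplication", chrom = "chr1", position = 9e9))),
    "outside genome")
})

test_that("simulated contigs are exact truth substrings at zero noise", {
  tr <- generateGenome(3, n_chrom = 1, chrom_length = 1e5)
  ct <- simulateContigs(tr, n50_target = 2e4, coverage = 1L)
  g <- as.character(truthGenome(tr))
  for (i in seq_len(nrow(ct$placements))) {
    p <- ct$placements[i, ]
    s <- substr(g[[p$source_chrom]], p$source_start, p$source_end)
    cseq <- as.character(ct$contigs[[p$contig_id]])
    if (p$orientation == "-")
      cseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cseq)))
    expect_identical(cseq, s)
  }
  expect_error(simulateContigs(tr, error_rate = 0.2), "error_rate")
})

test_that("chimera_rate = 1 records a junction in every contig", {
  tr <- generateGenome(3, n_chrom = 2, chrom_length = 5e4)
  ct <- simulateContigs(tr, n50_target = 2e4, chimera_rate = 1,
                        coverage = 1L)
  expect_identical(sort(unique(ct$chimeras$contig_id)),
                   sort(names(ct$contigs)))
})

test_that("realized contig N50 tracks the target", {
  tr <- generateGenome(17, n_chrom = 2, chrom_length = 5e5)
  ct <- simulateContigs(tr, n50_target = 5e4, coverage = 3L)
  n50 <- assemblyMetrics(Biostrings::width(ct$contigs))$n50_bp
  expect_gt(n50, 5e4 * 0.75)
  expect_lt(n50, 5e4 * 1.25)
})

test_that("noiseless optical simulation equals the in-silico digest", {
  tr <- generateGenome(19, n_chrom = 1, chrom_length = 1e5)
  m <- simulateOpticalMap(tr)[[1]]
  d <- digestSequence(as.character(truthGenome(tr)[[1]]),
                      map_id = mapId(m))
  expect_identical(mapLabels(m), mapLabels(d))
  expect_identical(length(m), length(d))
})

test_that("opposite-strand sites within the fragile window break the map", {
  # site [51..57] forward, site [101..107] reverse: 50 bp apart
  s <- paste0(strrep("A", 50), "GCTCTTC", strrep("A", 43), "GAAGAGC",
              strrep("A", 2000), "GCTCTTC", strrep("C", 3000),
              "GCTCTTC", strrep("A", 2000))
  maps <- simulateOpticalMap(stats::setNames(s, "frag"), resolution = 0,
                             fragile_window = 100)
  expect_identical(length(maps), 2L)
  expect_identical(names(maps), c("frag_1", "frag_2"))
  # without fragility, a single map
  one <- simulateOpticalMap(stats::setNames(s, "frag"), resolution = 0)
  expect_identical(length(one), 1L)
})

test_that("fragment sizing noise has the half-normal mean error", {
  # |relative error| for N(0, cv^2) has mean cv * sqrt(2/pi)
  tr <- generateGenome(23, n_chrom = 1, chrom_length = 2e5)
  truth_map <- simulateOpticalMap(tr)[[1]]
  tf <- c(mapLabels(truth_map)[1], fragments(truth_map))
  errs <- numeric(0)
  for (s in 1:800) {
    nm <- simulateOpticalMap(tr, sizing_cv = 0.05, seed = s)[[1]]
    nf <- c(mapLabels(nm)[1], fragments(nm))
    errs <- c(errs, abs(nf - tf) / tf)
  }
  expect_gt(length(errs), 1e4)
  expect_equal(mean(errs), 0.05 * sqrt(2 / pi), tolerance = 0.05)
})
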