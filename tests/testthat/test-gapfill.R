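# Contig placement, gap filling, duplication collapse, lift-over.

test_that("placeContigs recovers truth placements at zero noise", {
  w <- make_world(seed = 51, n_chrom = 1, chrom_length = 1e5, coverage = 1L)
  pl <- placeContigs(w$assembly, w$contigs)
  expect_gt(nrow(pl), 0)
  expect_true(all(pl$identity == 1))
  # a contig interior to a segment maps exactly to its truth locus
  tp <- w$contig_truth
  lay <- w$truth@segment_layout
  for (i in seq_len(nrow(tp))) {
    inside <- any(lay$source_start <= tp$source_start[i] &
                  lay$source_end >= tp$source_end[i] &
                  lay$orientation == "+")
    if (!inside) next
    hit <- pl[pl$contig_id == tp$contig_id[i], , drop = FALSE]
    expect_gt(nrow(hit), 0)
  }
})

test_that("foreign and reverse-complement contigs behave as specified", {
  w <- make_world(seed = 53, n_chrom = 1, chrom_length = 5e4, coverage = 1L)
  a <- w$assembly
  set.seed(1)
  foreign <- paste(sample(c("A", "C", "G", "T"), 3e4, TRUE), collapse = "")
  pl <- placeContigs(a, c(alien = foreign))
  expect_identical(nrow(pl[pl$aligned_bp > 500, ]), 0L)
  s <- as.character(assemblySeqs(a)[[1]])
  loc <- substr(s, 10001, 30000)
  if (!grepl("N", loc)) {
    rcc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(loc)))
    pl2 <- placeContigs(a, c(rc = rcc))
    expect_true(all(pl2$orientation == "-"))
  }
  expect_warning(placeContigs(a, Biostrings::DNAStringSet()), "empty")
})

test_that("PAF round trip preserves the placement table", {
  w <- make_world(seed = 53, n_chrom = 1, chrom_length = 5e4, coverage = 1L)
  pl <- placeContigs(w$assembly, w$contigs)
  f <- tempfile(fileext = ".paf")
  writePAF(pl, stats::setNames(Biostrings::width(w$contigs),
                               names(w$contigs)),
           stats::setNames(Biostrings::width(assemblySeqs(w$assembly)),
                           names(w$assembly)), f)
  back <- readPAF(f)
  for (col in c("contig_id", "seq_id", "contig_start", "contig_end",
                "seq_start", "seq_end", "orientation", "aligned_bp"))
    expect_equal(back[[col]], pl[[col]])
  unlink(f)
})

test_that("spanned gaps close exactly and the census drops by that count", {
  w <- make_world(seed = 55, n_chrom = 1, chrom_length = 2e5)
  pl <- placeContigs(w$assembly, w$contigs)
  before <- gapCensus(w$assembly)
  fg <- fillGaps(w$assembly, pl, w$contigs)
  after <- gapCensus(fg$assembly)
  k <- fg$summary$gaps_closed
  expect_gt(k, 0)
  expect_identical(after$gap_number[after$seq_id == "Total"],
                   before$gap_number[before$seq_id == "Total"] - k)
  # filling only ever grows the effective length
  expect_gte(after$effective_length[after$seq_id == "Total"],
             before$effective_length[before$seq_id == "Total"])
  # zero-noise patch equals the truth exactly
  expect_identical(as.character(assemblySeqs(fg$assembly)),
                   as.character(truthGenome(w$truth)))
})

test_that("a gap with no spanning contig is left intact", {
  w <- make_world(seed = 57, n_chrom = 1, chrom_length = 1e5)
  gr <- gapRanges(w$assembly)
  g1 <- BiocGenerics::start(gr)[1]
  # drop every contig near the first gap so nothing can anchor both flanks
  gt <- w$truth@gap_truth
  src <- gt[gt$start == g1, ]
  tp <- w$contig_truth
  bad <- tp$contig_id[tp$source_chrom == src$source_chrom &
                      tp$source_start < src$source_end + 600 &
                      tp$source_end > src$source_start - 600]
  keep <- setdiff(names(w$contigs), bad)
  pl <- placeContigs(w$assembly, w$contigs[keep])
  fg <- fillGaps(w$assembly, pl, w$contigs[keep])
  grn <- gapRanges(fg$assembly)
  expect_true(any(grn$gap_length == src$emitted_n))
  expect_false(any(fg$closed$gap_start == g1))
})

test_that("fillGaps never touches a base outside its edits", {
  w <- make_world(seed = 59, n_chrom = 1, chrom_length = 1e5)
  pl <- placeContigs(w$assembly, w$contigs)
  fg <- fillGaps(w$assembly, pl, w$contigs)
  old <- as.character(assemblySeqs(w$assembly))[[1]]
  new <- as.character(assemblySeqs(fg$assembly))[[1]]
  ed <- editTable(fg$log)
  # walk unedited stretches base by base via the lift-over
  cuts <- sort(c(1, ed$old_start - 1, ed$old_end + 1, nchar(old)))
  for (i in seq(1, length(cuts) - 1, by = 2)) {
    a <- cuts[i]; b <- cuts[i + 1]
    if (b < a) next
    lift <- liftover(fg$log, names(w$assembly)[1], c(a, b))
    expect_identical(substr(new, lift$position[1], lift$position[2]),
                     substr(old, a, b))
  }
})

test_that("filling with error-bearing contigs stays above 99% identity", {
  tr <- generateGenome(61, n_chrom = 1, chrom_length = 2e5)
  fa <- fragmentAssembly(tr)
  ct <- simulateContigs(tr, n50_target = 4e4, error_rate = 0.005,
                        coverage = 4L)
  pl <- placeContigs(fa$assembly, ct$contigs)
  fg <- fillGaps(fa$assembly, pl, ct$contigs, min_identity = 0.9)
  expect_gt(fg$summary$gaps_closed, 0)
  truth <- as.character(truthGenome(tr))[[1]]
  patched <- as.character(assemblySeqs(fg$assembly))[[1]]
  # identity over replaced intervals, located in truth coordinates
  gt <- fa$truth@gap_truth
  mism <- 0; tot <- 0
  for (i in seq_len(nrow(fg$closed))) {
    src <- gt[gt$start == fg$closed$gap_start[i], ]
    lift <- liftover(fg$log, src$seq_id, c(src$start - 1, src$end + 1))
    a <- lift$position[1] + 1; b <- lift$position[2] - 1
    x <- strsplit(substr(patched, a, b), "")[[1]]
    y <- strsplit(substr(truth, src$source_start, src$source_end), "")[[1]]
    if (length(x) != length(y)) next
    mism <- mism + sum(x != y); tot <- tot + length(x)
  }
  expect_gt(tot, 0)
  expect_gte(1 - mism / tot, 0.99)
})

test_that("collapse removes a planted duplication and nothing else", {
  tr <- generateGenome(11, n_chrom = 1, chrom_length = 1e5,
                       tandem_block_rate = 0)
  base <- fragmentAssembly(tr, seed = 71L)
  dup <- fragmentAssembly(tr, seed = 71L, error_plan = list(
    list(kind = "flank_duplication", dup_length = 2000)))
  co <- collapseDuplicationArtifacts(dup$assembly)
  expect_identical(nrow(co$collapsed), 1L)
  expect_identical(co$collapsed$overlap_bp, 2000)
  expect_identical(co$collapsed$removed_bp, 2010)
  expect_identical(as.character(assemblySeqs(co$assembly)),
                   as.character(assemblySeqs(base$assembly)))
  # collapse only ever shortens the total length
  expect_lt(sum(Biostrings::width(assemblySeqs(co$assembly))),
            sum(Biostrings::width(assemblySeqs(dup$assembly))))
  # gaps with unrelated flanks are untouched
  co2 <- collapseDuplicationArtifacts(base$assembly)
  expect_identical(nrow(co2$collapsed), 0L)
  expect_identical(as.character(assemblySeqs(co2$assembly)),
                   as.character(assemblySeqs(base$assembly)))
})

test_that("published census deltas move in the collapse/fill directions", {
  cen <- read_fixture("pseudomolecule_census.tsv")
  tot <- cen[cen$pseudomolecule == "Total", ]
  d <- tot[tot$version == "v5.0", -(1:2)] - tot[tot$version == "v4.0", -(1:2)]
  # total length decreased, effective length increased, gaps decreased
  expect_identical(unname(unlist(d)),
                   c(-3773173, -13466762, 9693589, -38899))
})

test_that("liftover follows the piecewise-affine bookkeeping", {
  # constructed log: one fill replacing 10 bp at 101-110 with 25 bp
  seqs <- list(chrA = strrep("A", 1000))
  log <- gapsmith:::.build_editlog(seqs, list(chrA = list(list(
    kind = "fill", old_start = 101, old_end = 110, new_length = 25,
    provenance = "ctg1"))))
  expect_identical(liftover(log, "chrA", 100)$position, 100)   # before: fixed
  expect_identical(liftover(log, "chrA", 105)$position, 101)   # inside: start
  expect_identical(liftover(log, "chrA", 111)$position, 126)   # after: +15
  expect_identical(liftover(log, "chrA", 1000)$position, 1015)
  # round trip on unedited coordinates
  back <- liftover(log, "chrA", 126, direction = "new2old")
  expect_identical(back$position, 111)
  expect_error(liftover(log, "nope", 1), "unknown sequence")
  expect_error(liftover(log, "chrA", 1001), "outside")
})

test_that("a collapsed copy lifts onto the retained copy", {
  seqs <- list(chrA = strrep("A", 1000))
  log <- gapsmith:::.build_editlog(seqs, list(chrA = list(list(
    kind = "collapse", old_start = 191, old_end = 300, new_length = 0,
    provenance = "overlap", copy_len = 100))))
  # removed left copy at 191-290 maps onto retained copy (new 191-290
  # corresponds to old 301-400)
  expect_identical(liftover(log, "chrA", 191)$position, 191)
  expect_identical(liftover(log, "chrA", 250)$position, 250)
  expect_identical(liftover(log, "chrA", 295)$position, 191)  # gap: point
  expect_identical(liftover(log, "chrA", 301)$position, 191)  # retained copy
  expect_identical(liftover(log, "chrA", 500)$position, 390)
})

test_that("GFF3 features over unedited regions survive a round trip", {
  w <- make_world(seed = 63, n_chrom = 1, chrom_length = 1e5)
  pl <- placeContigs(w$assembly, w$contigs)
  fg <- fillGaps(w$assembly, pl, w$contigs)
  gr <- gapRanges(w$assembly)
  sid <- names(w$assembly)[1]
  # features placed between gaps, clear of every edited interval
  ed <- editTable(fg$log)
  set.seed(2)
  starts <- seq(2000, Biostrings::width(assemblySeqs(w$assembly))[1] - 3000,
                by = 7000)
  feats <- GenomicRanges::GRanges(sid, IRanges::IRanges(starts, starts + 499))
  hit <- IRanges::overlapsAny(feats, GenomicRanges::GRanges(
    ed$seq_id, IRanges::IRanges(ed$old_start, ed$old_end)))
  feats <- feats[!hit]
  feats$ID <- sprintf("gene%03d", seq_along(feats))
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  rtracklayer::export(feats, f1, format = "gff3")
  lifted <- liftoverRanges(fg$log, rtracklayer::import(f1))
  # lift back and re-export: byte-identical GFF3
  restored <- GenomicRanges::GRanges(
    liftover(fg$log, sid, BiocGenerics::start(lifted),
             direction = "new2old")$seq_id,
    IRanges::IRanges(
      liftover(fg$log, sid, BiocGenerics::start(lifted),
               direction = "new2old")$position,
      liftover(fg$log, sid, BiocGenerics::end(lifted),
               direction = "new2old")$position))
  restored$ID <- lifted$ID
  rtracklayer::export(restored, f2, format = "gff3")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})
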