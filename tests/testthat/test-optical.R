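# Chimera detection, placement validation, and edit application.

test_that("a fixture chimeric contig splits at the planted junction", {
  tr <- generateGenome(21, n_chrom = 2, chrom_length = 8e5)
  g <- as.character(truthGenome(tr))
  junction_bp <- 200000
  chim <- paste0(substr(g[["chr1"]], 100001, 100000 + junction_bp),
                 substr(g[["chr2"]], 400001, 600000))
  cm <- simulateOpticalMap(stats::setNames(chim, "chimera"))[[1]]
  refs <- simulateOpticalMap(tr)
  p <- alignParams(seed = 3)
  ch <- detectChimeras(cm, refs, p)
  expect_identical(nrow(ch), 1L)
  expect_setequal(c(ch$left_ref, ch$right_ref), c("chr1", "chr2"))
  # breakpoint within one label of the planted junction
  lab <- mapLabels(cm)
  i <- ch$split_index
  lo <- if (i > 1) lab[i - 1] else 0
  hi <- if (i + 2 <= length(lab)) lab[i + 2] else length(cm)
  expect_gte(junction_bp, lo)
  expect_lte(junction_bp, hi)
})

test_that("consistent and unalignable contigs yield no splits", {
  tr <- generateGenome(21, n_chrom = 2, chrom_length = 8e5)
  g <- as.character(truthGenome(tr))
  refs <- simulateOpticalMap(tr)
  p <- alignParams(seed = 3)
  clean <- simulateOpticalMap(
    stats::setNames(substr(g[["chr1"]], 100001, 400000), "clean"))[[1]]
  expect_identical(nrow(detectChimeras(clean, refs, p)), 0L)
  set.seed(8)
  junk <- LabelMap("junk", 2e5, sort(runif(30, 1, 2e5)))
  r <- detectChimeras(junk, refs, p)
  expect_identical(nrow(r), 0L)
  expect_true(attr(r, "unaligned"))
})

test_that("an error-free draft yields an empty conflict list", {
  tr <- generateGenome(5, n_chrom = 2, chrom_length = 6e5)
  fa <- fragmentAssembly(tr)
  maps <- simulateOpticalMap(tr)
  vp <- validatePlacements(fa$assembly, maps, alignParams(seed = 7))
  expect_identical(nrow(vp$conflicts), 0L)
})

test_that("a planted inversion is recovered as exactly one misoriented call", {
  tr <- generateGenome(45, n_chrom = 2, chrom_length = 8e5)
  fa <- fragmentAssembly(tr, error_plan = list(list(kind = "inversion")))
  pe <- fa$truth@planted_errors
  maps <- simulateOpticalMap(tr)
  vp <- validatePlacements(fa$assembly, maps, alignParams(seed = 7))
  expect_identical(nrow(vp$conflicts), 1L)
  expect_identical(vp$conflicts$kind, "misoriented")
  expect_identical(vp$conflicts$seq_id, pe$chrom)
  expect_identical(vp$conflicts$scaffold, pe$scaffold)
})

test_that("a planted misplacement is recovered with its home chromosome", {
  tr <- generateGenome(47, n_chrom = 2, chrom_length = 8e5)
  fa <- fragmentAssembly(tr, error_plan = list(list(kind = "misplacement")))
  pe <- fa$truth@planted_errors
  from <- sub("from=([^;]+);.*", "\\1", pe$detail)
  maps <- simulateOpticalMap(tr)
  vp <- validatePlacements(fa$assembly, maps, alignParams(seed = 7))
  expect_identical(nrow(vp$conflicts), 1L)
  expect_identical(vp$conflicts$kind, "misplaced")
  expect_identical(vp$conflicts$seq_id, pe$chrom)      # where it sits now
  expect_identical(vp$conflicts$target_seq, from)      # where it belongs
})

test_that("applyEdits with no edits is the identity", {
  tr <- generateGenome(49, n_chrom = 1, chrom_length = 1e5)
  fa <- fragmentAssembly(tr)
  out <- applyEdits(fa$assembly, NULL)
  expect_identical(as.character(assemblySeqs(out$assembly)),
                   as.character(assemblySeqs(fa$assembly)))
  L <- Biostrings::width(assemblySeqs(fa$assembly))[1]
  lift <- liftover(out$log, names(fa$assembly)[1], c(1, 500, L))
  expect_identical(lift$position, c(1, 500, L))
})

test_that("a flip edit reverse-complements exactly its scaffold", {
  tr <- generateGenome(45, n_chrom = 2, chrom_length = 8e5)
  fa <- fragmentAssembly(tr, error_plan = list(list(kind = "inversion")))
  maps <- simulateOpticalMap(tr)
  vp <- validatePlacements(fa$assembly, maps, alignParams(seed = 7))
  out <- applyEdits(fa$assembly, vp$edits)
  e <- vp$edits[1, ]
  old <- substr(as.character(assemblySeqs(fa$assembly)[[e$seq_id]]),
                e$start, e$end)
  new <- substr(as.character(assemblySeqs(out$assembly)[[e$seq_id]]),
                e$start, e$end)
  expect_identical(new, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(old))))
  # moves/flips neither create nor destroy sequence: base counts are
  # conserved up to strand (a flip exchanges A<->T and C<->G)
  count_bases <- function(x) {
    f <- colSums(Biostrings::alphabetFrequency(x))
    c(AT = unname(f["A"] + f["T"]), CG = unname(f["C"] + f["G"]),
      N = unname(f["N"]), other = unname(sum(f) - f["A"] - f["C"] -
                                           f["G"] - f["T"] - f["N"]))
  }
  expect_identical(count_bases(assemblySeqs(out$assembly)),
                   count_bases(assemblySeqs(fa$assembly)))
})

test_that("overlapping edits are a conflict error naming the pair", {
  tr <- generateGenome(49, n_chrom = 1, chrom_length = 1e5)
  fa <- fragmentAssembly(tr)
  ed <- data.frame(kind = c("flip", "flip"),
                   seq_id = rep(names(fa$assembly)[1], 2),
                   start = c(1, 50), end = c(1000, 1500),
                   target_seq = NA, target_index = NA, revcomp = TRUE)
  expect_error(applyEdits(fa$assembly, ed), "overlap")
})

test_that("correcting a planted misplacement restores the truth layout", {
  tr <- generateGenome(47, n_chrom = 2, chrom_length = 8e5)
  base <- fragmentAssembly(tr, seed = 31L)
  bad <- fragmentAssembly(tr, seed = 31L,
                          error_plan = list(list(kind = "misplacement")))
  maps <- simulateOpticalMap(tr)
  vp <- validatePlacements(bad$assembly, maps, alignParams(seed = 7))
  out <- applyEdits(bad$assembly, vp$edits)
  expect_identical(as.character(assemblySeqs(out$assembly)),
                   as.character(assemblySeqs(base$assembly)))
})
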