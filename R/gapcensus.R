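# Gap discovery, classification, and per-sequence census.

.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Find maximal N-runs in a DNA sequence
#'
#' Scans a sequence for maximal runs of `N` (case-insensitive) and returns
#' them in order. Ambiguity codes other than `N` are legal input but are not
#' gaps. Any character outside the IUPAC DNA alphabet is a format error that
#' names the first offending position.
#'
#' @param sequence A single character string, [Biostrings::DNAString], or a
#'   length-one [Biostrings::DNAStringSet].
#' @return A data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `length`; zero rows if the sequence has no Ns.
#' @examples
#' findNRuns("ACGTNNNNNNNNNNACGT")  # one 10-bp run at 5..14
#' findNRuns("NNACGTNN")            # two boundary runs
#' @export
findNRuns <- function(sequence) {
  s <- .as_single_string(sequence)
  bad <- regexpr(sprintf("[^%s%s]", .IUPAC_CHARS, tolower(.IUPAC_CHARS)), s)
  if (bad != -1L)
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ", bad)
  m <- gregexpr("[Nn]+", s)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(), length = integer()))
  st <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(start = st, end = st + len - 1L, length = len)
}

.as_single_string <- function(x) {
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x[[1L]]))
  }
  if (is(x, "DNAString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' Classify a gap by its N count
#'
#' Placeholder gaps carry a conventional N count that encodes provenance, not
#' span: 10 Ns link contigs from the short-read assembler, 100 Ns come from
#' hybrid scaffolding, and 1000 Ns join adjacent (super-)scaffolds. Any other
#' length is a sized gap whose N count estimates the true span. A real gap
#' whose span happens to be exactly 10/100/1000 bp is indistinguishable from
#' a placeholder; classification is by length only.
#'
#' @param length Integer vector of gap lengths (bp), all `>= 1`.
#' @return Character vector: `"placeholder10"`, `"placeholder100"`,
#'   `"placeholder1000"`, or `"sized"`.
#' @examples
#' classifyGap(c(10, 100, 1000, 237))
#' @export
classifyGap <- function(length) {
  stopifnot(all(length >= 1))
  out <- rep("sized", length(length))
  out[length == 10] <- "placeholder10"
  out[length == 100] <- "placeholder100"
  out[length == 1000] <- "placeholder1000"
  out
}

#' Construct an Assembly from sequences
#'
#' Builds the gap registry by scanning every sequence for N-runs and
#' classifying each run with [classifyGap()].
#'
#' @param seqs A named [Biostrings::DNAStringSet], a named character vector,
#'   or the path to a FASTA file.
#' @return An [Assembly-class] object.
#' @examples
#' a <- Assembly(c(chrA = "ACGTNNNNNNNNNNACGT"))
#' gapRanges(a)
#' @export
Assembly <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readDNAStringSet(seqs)
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  stopifnot(is(seqs, "DNAStringSet"))
  if (is.null(names(seqs))) stop("assembly sequences must be named")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  runs <- lapply(as.character(seqs), findNRuns)
  n <- vapply(runs, nrow, 0L)
  gr <- GRanges(
    seqnames = rep(names(seqs), n),
    ranges = IRanges(
      start = unlist(lapply(runs, `[[`, "start"), use.names = FALSE),
      end = unlist(lapply(runs, `[[`, "end"), use.names = FALSE)
    )
  )
  gr$gap_length <- BiocGenerics::width(gr)
  gr$klass <- if (length(gr)) classifyGap(gr$gap_length) else character()
  new("Assembly", seqs = seqs, gaps = gr)
}

#' Per-sequence gap census
#'
#' Computes, for every sequence, the total length, summed gap length, the
#' effective length (total minus Ns, i.e. the length of the assembly without
#' Ns), and the gap count, plus a `Total` row summing all columns.
#'
#' @param assembly An [Assembly-class] object.
#' @return A data.frame with columns `seq_id`, `total_length`, `gap_length`,
#'   `effective_length`, `gap_number`; the final row is `Total`.
#' @examples
#' a <- Assembly(c(chr1 = "ACGTNNNNNNNNNNACGT", chr2 = "ACGT"))
#' gapCensus(a)
#' @export
gapCensus <- function(assembly) {
  stopifnot(is(assembly, "Assembly"))
  ids <- names(assembly@seqs)
  if (any(Biostrings::width(assembly@seqs) == 0))
    stop("assembly sequences must be non-empty")
  total <- as.numeric(Biostrings::width(assembly@seqs))
  g <- assembly@gaps
  gl <- gn <- setNames(numeric(length(ids)), ids)
  if (length(g)) {
    by_gl <- tapply(as.numeric(g$gap_length),
                    as.character(GenomicRanges::seqnames(g)), sum)
    by_gn <- table(as.character(GenomicRanges::seqnames(g)))
    gl[names(by_gl)] <- by_gl
    gn[names(by_gn)] <- by_gn
  }
  out <- data.frame(
    seq_id = ids, total_length = total, gap_length = as.numeric(gl),
    effective_length = total - as.numeric(gl), gap_number = as.numeric(gn),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rbind(out, data.frame(
    seq_id = "Total", total_length = sum(out$total_length),
    gap_length = sum(out$gap_length),
    effective_length = sum(out$effective_length),
    gap_number = sum(out$gap_number)
  ))
}

#' Write an assembly gap registry as AGP v2.1
#'
#' Emits alternating component (`W`) and gap (`N`) lines, 1-based inclusive.
#' Placeholder-10 gaps are written with gap type `contig`, other gaps with
#' gap type `scaffold`; all are `linkage yes`.
#'
#' @param assembly An [Assembly-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAGP <- function(assembly, path) {
  stopifnot(is(assembly, "Assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  g <- assembly@gaps
  for (sid in names(assembly@seqs)) {
    L <- Biostrings::width(assembly@seqs)[match(sid, names(assembly@seqs))]
    gi <- g[as.character(GenomicRanges::seqnames(g)) == sid]
    gi <- gi[order(BiocGenerics::start(gi))]
    bounds <- rbind(
      cbind(c(1, BiocGenerics::end(gi) + 1),
            c(BiocGenerics::start(gi) - 1, L))
    )
    part <- 0L
    comp <- 0L
    for (i in seq_len(nrow(bounds))) {
      b1 <- bounds[i, 1]; b2 <- bounds[i, 2]
      if (b2 >= b1) {
        part <- part + 1L; comp <- comp + 1L
        writeLines(paste(sid, b1, b2, part, "W",
          sprintf("%s_part%03d", sid, comp), 1, b2 - b1 + 1, "+",
          sep = "\t"), con)
      }
      if (i <= length(gi)) {
        part <- part + 1L
        gt <- if (gi$klass[i] == "placeholder10") "contig" else "scaffold"
        writeLines(paste(sid, BiocGenerics::start(gi)[i],
          BiocGenerics::end(gi)[i], part, "N", gi$gap_length[i], gt, "yes",
          "na", sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read an AGP v2.1 file
#'
#' @param path AGP file path.
#' @return A list with data.frames `components` (W lines) and `gaps`
#'   (N/U lines, with a `klass` column from [classifyGap()]).
#' @export
readAGP <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  type <- vapply(f, `[[`, "", 5L)
  comp <- f[type == "W"]
  gaps <- f[type %in% c("N", "U")]
  components <- data.frame(
    seq_id = vapply(comp, `[[`, "", 1L),
    start = as.numeric(vapply(comp, `[[`, "", 2L)),
    end = as.numeric(vapply(comp, `[[`, "", 3L)),
    component_id = vapply(comp, `[[`, "", 6L),
    orientation = vapply(comp, `[[`, "", 9L)
  )
  gapdf <- data.frame(
    seq_id = vapply(gaps, `[[`, "", 1L),
    start = as.numeric(vapply(gaps, `[[`, "", 2L)),
    end = as.numeric(vapply(gaps, `[[`, "", 3L)),
    gap_length = as.numeric(vapply(gaps, `[[`, "", 6L)),
    gap_type = vapply(gaps, `[[`, "", 7L)
  )
  gapdf$klass <- if (nrow(gapdf)) classifyGap(gapdf$gap_length) else character()
  list(components = components, gaps = gapdf)
}

#' Write a census table as TSV
#'
#' @param census A data.frame from [gapCensus()] or [compareCensuses()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCensusTsv <- function(census, path) {
  write.table(census, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write assembly sequences as FASTA
#'
#' @param assembly An [Assembly-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAssemblyFasta <- function(assembly, path) {
  writeXStringSet(assembly@seqs, path)
  invisible(path)
}
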