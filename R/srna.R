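# Small-RNA read classification: size profiles, hc-siRNA attribution to TE
# superfamilies, tRNA-derived-fragment classes with nine positional bins,
# and polycistronic pre-miRNA grouping.

#' Size profile of a small-RNA read set
#'
#' Two histograms over the trimmed length range 18-34 nt: all reads, and
#' distinct sequences (each unique sequence counted once per length). The
#' distinct histogram separates abundance-driven peaks (a few highly
#' expressed 21-nt miRNAs) from diversity-driven peaks (many distinct 24-nt
#' heterochromatic siRNAs).
#'
#' @param reads data.frame with `length` (nt) and, for the distinct
#'   histogram, `sequence`.
#' @return data.frame with `length` (18..34), `total`, `distinct`.
#' @export
sizeProfile <- function(reads) {
  lens <- 18:34
  if (is.null(reads) || nrow(reads) == 0L)
    return(data.frame(length = lens, total = 0L, distinct = 0L))
  if (any(reads$length < 18L | reads$length > 34L))
    .stopf("read lengths must be within the 18-34 nt trim bounds")
  tot <- table(factor(reads$length, levels = lens))
  dis <- if ("sequence" %in% names(reads)) {
    u <- unique(reads[, c("length", "sequence")])
    table(factor(u$length, levels = lens))
  } else tot
  data.frame(length = lens, total = as.integer(tot),
             distinct = as.integer(dis))
}

#' Count heterochromatic siRNA candidates per TE superfamily and length
#'
#' Only reads 21-24 nt long whose alignment overlaps a transposable-element
#' feature are counted; the category is the TE superfamily. Reads outside
#' the length window or off any TE are excluded. Counts are independent of
#' read input order.
#'
#' @param reads data.frame with `read_id`, `seq_id`, `start`, `end`,
#'   `length` (genomic alignment, 1-based inclusive).
#' @param te_annotation A GFF3 file path or a
#'   [GenomicRanges::GRanges] of TE features carrying a superfamily
#'   attribute (metadata column `superfamily`, or `Superfamily`).
#' @return data.frame of counts: `superfamily`, `length` (21..24), `count`.
#' @export
classifyHcSirna <- function(reads, te_annotation) {
  te <- te_annotation
  if (is.character(te))
    te <- rtracklayer::import(te, format = "gff3")
  stopifnot(is(te, "GRanges"))
  sup <- mcols(te)$superfamily
  if (is.null(sup)) sup <- mcols(te)$Superfamily
  if (is.null(sup)) .stopf("TE annotation lacks a superfamily attribute")
  sup <- as.character(sup)
  keep <- reads$length >= 21L & reads$length <= 24L
  r <- reads[keep, , drop = FALSE]
  sups <- sort(unique(sup))
  grid <- expand.grid(superfamily = sups, length = 21:24,
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  if (nrow(r)) {
    rg <- GRanges(r$seq_id, IRanges(r$start, r$end))
    ov <- findOverlaps(rg, te)
    if (length(ov)) {
      # one count per read per classification: first overlapping feature
      first <- !duplicated(S4Vectors::queryHits(ov))
      qh <- S4Vectors::queryHits(ov)[first]
      sh <- S4Vectors::subjectHits(ov)[first]
      tab <- table(factor(sup[sh], levels = sups),
                   factor(r$length[qh], levels = 21:24))
      grid$count <- as.integer(
        tab[cbind(match(grid$superfamily, rownames(tab)),
                  match(as.character(grid$length), colnames(tab)))])
    }
  }
  grid
}

#' Classify tRNA-derived fragments and assign positional bins
#'
#' A read aligned to a mature tRNA is a 5-tRF when it starts at the first
#' nucleotide, a 3-tRF when it ends at the last, and an i-tRF otherwise;
#' a read spanning the full molecule takes the 5-tRF label (declared
#' precedence). The 5' start position is allocated to one of nine bins,
#' `ceiling(9 * start / trna_length)`, reflecting typical cleavage
#' positions.
#'
#' @param start,end 1-based alignment coordinates on the mature tRNA
#'   (vectors).
#' @param trna_length tRNA length(s), recycled.
#' @return data.frame with `trf_class` (`"5-tRF"`, `"i-tRF"`, `"3-tRF"`)
#'   and `bin` (1..9).
#' @examples
#' trfClassify(1, 19, 76)    # 5-tRF, bin 1
#' trfClassify(30, 55, 76)   # i-tRF, bin 4
#' @export
trfClassify <- function(start, end, trna_length) {
  n <- max(length(start), length(end), length(trna_length))
  start <- rep_len(start, n); end <- rep_len(end, n)
  trna_length <- rep_len(trna_length, n)
  if (any(start < 1 | end > trna_length | start > end))
    .stopf("alignment outside tRNA bounds")
  cls <- ifelse(start == 1L, "5-tRF",
                ifelse(end == trna_length, "3-tRF", "i-tRF"))
  data.frame(trf_class = cls,
             bin = as.integer(ceiling(9 * start / trna_length)))
}

#' Group pre-miRNA loci into potential polycistrons
#'
#' Single-linkage clustering of same-sequence loci: two neighbouring loci
#' join one cluster iff they are separated by fewer than `max_sep`
#' intervening nucleotides (strictly; `start[i+1] - end[i] - 1 < max_sep`
#' on 1-based inclusive coordinates). Clusters of two or more loci are
#' flagged as potential polycistronic units.
#'
#' @param loci data.frame with `seq_id`, `start`, `end` (1-based
#'   inclusive); an optional `locus_id` column is carried through.
#' @param max_sep Separation threshold in nt (default 3000, strict `<`).
#' @return The input with `cluster` (id, unique across sequences) and
#'   `polycistronic` (logical) columns, sorted by sequence and start.
#' @examples
#' polycistronGroup(data.frame(seq_id = "chr1", start = c(1, 3100),
#'                             end = c(100, 3200)))  # 2999 nt apart: one cluster
#' @export
polycistronGroup <- function(loci, max_sep = 3000) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(loci)))
  if (nrow(loci) == 0L) {
    loci$cluster <- integer(); loci$polycistronic <- logical()
    return(loci)
  }
  o <- order(loci$seq_id, loci$start)
  x <- loci[o, , drop = FALSE]
  newclust <- c(TRUE, x$seq_id[-1L] != x$seq_id[-nrow(x)] |
                  (x$start[-1L] - x$end[-nrow(x)] - 1) >= max_sep)
  x$cluster <- cumsum(newclust)
  sz <- table(x$cluster)
  x$polycistronic <- as.integer(sz[as.character(x$cluster)]) >= 2L
  rownames(x) <- NULL
  x
}

#' Read a BED-like small-RNA alignment TSV
#'
#' Columns: `read_id`, `seq_id`, `start`, `end`, `strand`, `length`, and
#' optionally `sequence` and `target_class`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readSrnaTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
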