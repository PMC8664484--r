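# S4 class definitions for the central data objects.

#' Assembly: named sequences with an N-gap registry
#'
#' Holds an ordered set of named DNA sequences (pseudomolecules, scaffolds)
#' together with the registry of their N-run gaps, classified into the
#' placeholder taxonomy (10/100/1000-N placeholders versus sized gaps).
#' The registry is derived from the sequence content and is kept in sync by
#' the constructor; editing operations always return a fresh object.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of the assembly sequences.
#' @slot gaps A [GenomicRanges::GRanges] of N-runs (1-based, inclusive) with
#'   metadata columns `klass` (one of `"placeholder10"`, `"placeholder100"`,
#'   `"placeholder1000"`, `"sized"`) and `gap_length`.
#'
#' @seealso [Assembly()] for construction from sequences or a FASTA file.
#' @exportClass Assembly
setClass("Assembly",
  slots = c(seqs = "DNAStringSet", gaps = "GRanges")
)

setValidity("Assembly", function(object) {
  sl <- setNames(Biostrings::width(object@seqs), names(object@seqs))
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    return("sequences must have unique names")
  g <- object@gaps
  if (length(g)) {
    bad <- !(as.character(GenomicRanges::seqnames(g)) %in% names(sl))
    if (any(bad)) return("gap registry references unknown sequence")
    lim <- sl[as.character(GenomicRanges::seqnames(g))]
    if (any(BiocGenerics::start(g) < 1) || any(BiocGenerics::end(g) > lim))
      return("gap registry range outside sequence bounds")
    if (is.null(g$klass)) return("gap registry lacks a 'klass' column")
  }
  TRUE
})

#' SyntheticTruth: a generated genome with known layout and planted errors
#'
#' The ground truth behind a synthetic benchmark: the true genome, the tiling
#' of each draft scaffold by truth intervals, the registry of true gap spans
#' hidden behind emitted N-runs, and the planted assembly errors
#' (misplacement, inversion, flank duplication) with their coordinates.
#' Regenerating with the same seed reproduces byte-identical output.
#'
#' @slot genome A [Biostrings::DNAStringSet], the truth chromosomes.
#' @slot segment_layout data.frame tiling each draft sequence with truth
#'   intervals: `seq_id`, `seq_start`, `seq_end`, `source_chrom`,
#'   `source_start`, `source_end`, `orientation`, `scaffold`.
#' @slot gap_truth data.frame of emitted gaps: `seq_id`, `start`, `end`,
#'   `klass`, `emitted_n`, `true_span`, `source_chrom`, `source_start`,
#'   `source_end` (the truth interval the gap hides; zero-width for
#'   artifact gaps).
#' @slot planted_errors data.frame: `kind` (`"misplacement"`, `"inversion"`,
#'   `"flank_duplication"`, `"chimeric_contig"`), plus coordinates.
#' @slot features data.frame of generator features (tandem blocks, repeat
#'   copies) with truth coordinates.
#' @slot seed integer seed the object was generated from.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(
    genome = "DNAStringSet",
    segment_layout = "data.frame",
    gap_truth = "data.frame",
    planted_errors = "data.frame",
    features = "data.frame",
    seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  lay <- object@segment_layout
  if (nrow(lay)) {
    need <- c("seq_id", "seq_start", "seq_end", "source_chrom",
              "source_start", "source_end", "orientation", "scaffold")
    if (!all(need %in% names(lay))) return("segment_layout missing columns")
    if (any(lay$seq_end < lay$seq_start)) return("segment_layout bad interval")
  }
  pe <- object@planted_errors
  if (nrow(pe) && !all(pe$kind %in%
      c("misplacement", "inversion", "flank_duplication", "chimeric_contig")))
    return("unknown planted error kind")
  TRUE
})

#' LabelMap: ordered nick-site label positions along one sequence
#'
#' An optical map (or in-silico digest) of a single sequence or consensus
#' contig: strictly increasing label positions in bp within `[0, length]`.
#' Successive label spacings are the map's fragment lengths; ordered-map
#' alignment compares these fragment-length sequences, not bases.
#'
#' @slot map_id character scalar naming the map.
#' @slot length numeric, the mapped molecule length in bp.
#' @slot labels numeric vector of strictly increasing label positions (bp).
#'
#' @seealso [digestSequence()], [mapAlign()], [fragments()]
#' @exportClass LabelMap
setClass("LabelMap",
  slots = c(map_id = "character", length = "numeric", labels = "numeric")
)

setValidity("LabelMap", function(object) {
  if (length(object@map_id) != 1L) return("map_id must be a single name")
  if (length(object@length) != 1L || object@length <= 0)
    return("length must be a positive scalar")
  lab <- object@labels
  if (length(lab)) {
    if (any(diff(lab) <= 0)) return("labels must be strictly increasing")
    if (lab[1L] < 0 || lab[length(lab)] > object@length)
      return("labels must lie within [0, length]")
  }
  TRUE
})

#' AlignParams: scoring and significance parameters for ordered-map alignment
#'
#' Houses the aligner's scoring constants and the permutation-null
#' significance settings. The historical vendor pipeline expressed alignment
#' cutoffs as P-values of a proprietary statistic; here significance is
#' re-grounded in a permutation null over shuffled reference fragment orders,
#' so the cutoff is `alpha = 1/(n_permutations + 1)`: significant means the
#' observed score beats every permuted score.
#'
#' @slot v numeric, sizing-variance scale in bp; the pair cost is
#'   `(x - y)^2 / (v * (x + y) + 1)` for merged interval lengths `x`, `y`.
#' @slot B numeric, per-matched-pair bonus.
#' @slot p_miss numeric, penalty per interior label merged over.
#' @slot max_merge integer, maximum fragments merged into one pair interval.
#' @slot min_matched_labels integer, minimum matched labels for significance.
#' @slot n_permutations integer, permutation-null size.
#' @slot alpha numeric, significance level (informational).
#' @slot seed integer, seed for the permutation stream (required).
#'
#' @seealso [alignParams()], [mapAlign()]
#' @exportClass AlignParams
setClass("AlignParams",
  slots = c(
    v = "numeric", B = "numeric", p_miss = "numeric", max_merge = "integer",
    min_matched_labels = "integer", n_permutations = "integer",
    alpha = "numeric", seed = "integer"
  )
)

setValidity("AlignParams", function(object) {
  for (s in c("v", "B", "p_miss")) if (methods::slot(object, s) <= 0)
    return(paste(s, "must be positive"))
  if (object@max_merge < 1L) return("max_merge must be >= 1")
  if (object@min_matched_labels < 2L) return("min_matched_labels must be >= 2")
  if (object@n_permutations < 0L) return("n_permutations must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a scalar integer seed is required")
  TRUE
})

#' MapAlignment: one query-to-reference ordered-map alignment
#'
#' The best monotone pairing of query labels to reference labels, in the
#' better of the two orientations. `pairs` holds matched label indices
#' (query orientation is the original map; for `-` alignments the query was
#' reversed before matching and indices refer to the reversed label order).
#' Labels absorbed between successive pairs are merge events; labels outside
#' the aligned block are reported as missed (end overhangs).
#'
#' @slot query_id,ref_id character, map names.
#' @slot orientation `"+"` or `"-"`.
#' @slot pairs data.frame with columns `q`, `r`: matched label indices,
#'   strictly increasing in both columns.
#' @slot score,sizing_cost numeric.
#' @slot n_merges integer, interior labels merged over (both maps).
#' @slot missed_query,missed_ref integer, unaligned labels outside the
#'   aligned block.
#' @slot significant logical, permutation-null verdict.
#' @slot n_perm_ge integer, permuted scores >= observed.
#'
#' @exportClass MapAlignment
setClass("MapAlignment",
  slots = c(
    query_id = "character", ref_id = "character", orientation = "character",
    pairs = "data.frame", score = "numeric", sizing_cost = "numeric",
    n_merges = "integer", missed_query = "integer", missed_ref = "integer",
    significant = "logical", n_perm_ge = "integer"
  )
)

setValidity("MapAlignment", function(object) {
  if (!object@orientation %in% c("+", "-")) return("orientation must be +/-")
  p <- object@pairs
  if (nrow(p) > 1L && (any(diff(p$q) <= 0) || any(diff(p$r) <= 0)))
    return("pairs must be strictly increasing in both indices")
  TRUE
})

#' EditLog: ordered assembly edits with a cumulative lift-over table
#'
#' Records every edit applied to an assembly (gap fills, duplication
#' collapses, segment moves and flips) and the resulting piecewise-affine
#' monotone coordinate map. The map is bijective outside edited intervals;
#' positions inside a replaced N-run map to the replacement start and
#' positions inside a collapsed duplicate copy map to the retained copy.
#'
#' @slot edits data.frame, one row per edit: `kind` (`"fill"`, `"collapse"`,
#'   `"move"`, `"flip"`), `seq_id`, `old_start`, `old_end`, `new_length`,
#'   `provenance`.
#' @slot blocks data.frame, the lift-over table: `seq_id`, `old_start`,
#'   `old_end`, `new_seq`, `new_start`, `strand`, `type` (`"affine"` maps
#'   positions one-to-one; `"copy"` maps a removed duplicate copy onto the
#'   retained copy, forward direction only; `"point"` maps the whole old
#'   interval to `new_start`).
#' @slot seqlengths_old,seqlengths_new named numeric vectors.
#'
#' @seealso [liftover()], [liftoverRanges()]
#' @exportClass EditLog
setClass("EditLog",
  slots = c(
    edits = "data.frame", blocks = "data.frame",
    seqlengths_old = "numeric", seqlengths_new = "numeric"
  )
)

setValidity("EditLog", function(object) {
  b <- object@blocks
  if (nrow(b)) {
    need <- c("seq_id", "old_start", "old_end", "new_seq", "new_start",
              "strand", "type")
    if (!all(need %in% names(b))) return("blocks missing columns")
    if (!all(b$type %in% c("affine", "copy", "point")))
      return("bad block type")
  }
  TRUE
})
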