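# LabelMap construction, in-silico nick-site digestion, and simplified
# CMAP-style TSV interchange.

#' Construct a LabelMap
#'
#' @param map_id Map name.
#' @param length Molecule length in bp.
#' @param labels Strictly increasing label positions (bp) in `[0, length]`.
#' @return A [LabelMap-class].
#' @export
LabelMap <- function(map_id, length, labels) {
  new("LabelMap", map_id = as.character(map_id), length = as.numeric(length),
      labels = as.numeric(labels))
}

# motif occurrences on both strands; positions are motif starts on forward
# coordinates (the nick offset within the site is unknown and cancels in
# fragment arithmetic as long as the convention is consistent)
.nick_sites <- function(sequence, motif) {
  if (grepl("[^ACGTacgt]", motif)) .stopf("motif must contain only A/C/G/T")
  s <- DNAString(sequence)
  fwd <- BiocGenerics::start(matchPattern(motif, s, fixed = TRUE))
  rcm <- as.character(reverseComplement(DNAString(motif)))
  rev <- BiocGenerics::start(matchPattern(rcm, s, fixed = TRUE))
  if (identical(rcm, toupper(motif))) rev <- integer(0)  # palindromic motif
  pos <- c(fwd, rev)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  o <- order(pos)
  data.frame(pos = pos[o], strand = strand[o])
}

# single-linkage clusters of labels closer than `resolution`, each replaced
# by its cluster midpoint (mean of extremes)
.merge_labels <- function(pos, resolution) {
  if (length(pos) < 2L || resolution <= 0) return(as.numeric(pos))
  grp <- cumsum(c(1, as.integer(diff(pos) >= resolution)))
  as.numeric(tapply(pos, grp, function(p) (min(p) + max(p)) / 2))
}

#' In-silico nick-site digest of a sequence
#'
#' Labels every occurrence of `motif` on the forward strand and of its
#' reverse complement (positions reported as motif starts on forward
#' coordinates, 1-based), then merges labels closer than `resolution` to
#' their cluster midpoint. N-runs match no motif and so yield no labels.
#'
#' @param sequence Character, [Biostrings::DNAString], or length-one
#'   [Biostrings::DNAStringSet].
#' @param motif Recognition site (A/C/G/T only, length `>= 4`).
#' @param resolution Merge distance in bp (`0` disables merging).
#' @param map_id Name for the resulting map.
#' @return A [LabelMap-class].
#' @examples
#' s <- paste0(strrep("A", 500), "GCTCTTC", strrep("A", 500))
#' mapLabels(digestSequence(s, resolution = 0))  # one label at 501
#' @export
digestSequence <- function(sequence, motif = "GCTCTTC", resolution = 1000,
                           map_id = "digest") {
  if (nchar(motif) < 4) .stopf("motif length must be >= 4")
  s <- .as_single_string(sequence)
  sites <- .nick_sites(s, motif)
  LabelMap(map_id, nchar(s), .merge_labels(sites$pos, resolution))
}

#' Write label maps as simplified CMAP-style TSV
#'
#' One row per label: `map_id`, `map_length`, `n_labels`, `site_id`,
#' `label_position`. Maps without labels emit a single row with `site_id` 0.
#'
#' @param maps A [LabelMap-class] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeLabelMaps <- function(maps, path) {
  if (is(maps, "LabelMap")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    n <- length(m@labels)
    if (n == 0L)
      return(data.frame(map_id = m@map_id, map_length = m@length,
                        n_labels = 0L, site_id = 0L,
                        label_position = NA_real_))
    data.frame(map_id = m@map_id, map_length = m@length, n_labels = n,
               site_id = seq_len(n), label_position = m@labels)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read label maps from simplified CMAP-style TSV
#'
#' @param path File written by [writeLabelMaps()].
#' @return A named list of [LabelMap-class] objects.
#' @export
readLabelMaps <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$map_id), function(g) {
    lab <- g$label_position[g$n_labels > 0L]
    LabelMap(g$map_id[1L], g$map_length[1L], sort(lab[!is.na(lab)]))
  })
  out[unique(d$map_id)]
}
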