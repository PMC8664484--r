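# Gap closing from contig placements, duplication-artifact collapse, and
# coordinate lift-over.

#' Place contigs on an assembly by unique k-mer anchors
#'
#' Anchors are exact k-mers occurring exactly once in the whole assembly.
#' Anchors sharing a (sequence, diagonal) are chained into ungapped blocks,
#' split where successive anchors are farther apart than `max_spacing`,
#' extended outward while bases match, and reported when they reach
#' `min_block` bp at `min_identity` ungapped identity. Both contig
#' orientations are tried; contig coordinates are reported on the original
#' (forward) contig. A contig spanning a gap whose emitted N count differs
#' from the true span yields one block per flank (different diagonals),
#' which is exactly what [fillGaps()] consumes.
#'
#' @param assembly An [Assembly-class].
#' @param contigs A [Biostrings::DNAStringSet] or named character vector.
#' @param anchor_k Anchor k-mer size (`>= 15`, `<= 32`).
#' @param min_block Minimum reported block length (bp).
#' @param min_identity Ungapped identity floor.
#' @param max_spacing Anchor chaining distance (bp).
#' @return A data.frame of placements, 1-based inclusive: `contig_id`,
#'   `seq_id`, `contig_start`, `contig_end`, `seq_start`, `seq_end`,
#'   `orientation`, `identity`, `aligned_bp`, `n_anchors`.
#' @export
placeContigs <- function(assembly, contigs, anchor_k = 31L, min_block = 200L,
                         min_identity = 0.97, max_spacing = 5000L) {
  stopifnot(is(assembly, "Assembly"))
  if (anchor_k < 15L) .stopf("anchor_k must be >= 15")
  if (is.character(contigs)) contigs <- DNAStringSet(contigs)
  if (length(contigs) == 0L) {
    warning("empty contig set; no placements")
    return(data.frame(contig_id = character(), seq_id = character(),
                      contig_start = numeric(), contig_end = numeric(),
                      seq_start = numeric(), seq_end = numeric(),
                      orientation = character(), identity = numeric(),
                      aligned_bp = numeric(), n_anchors = integer()))
  }
  cpp_place_contigs(names(assembly@seqs), as.character(assembly@seqs),
                    names(contigs), as.character(contigs),
                    as.integer(anchor_k), as.integer(min_block),
                    min_identity, as.integer(max_spacing))
}

#' Read a minimal 12-column PAF into a placement table
#'
#' @param path PAF file (query/target names, lengths, 0-based half-open
#'   intervals, strand, residue matches, alignment length, quality).
#' @return A placement data.frame as from [placeContigs()] (without
#'   `n_anchors`).
#' @export
readPAF <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 12L]
  gv <- function(i) vapply(f, `[[`, "", i)
  nv <- function(i) as.numeric(gv(i))
  data.frame(
    contig_id = gv(1L), seq_id = gv(6L),
    contig_start = nv(3L) + 1, contig_end = nv(4L),
    seq_start = nv(8L) + 1, seq_end = nv(9L),
    orientation = gv(5L),
    identity = nv(10L) / pmax(nv(11L), 1),
    aligned_bp = nv(11L), n_anchors = NA_integer_)
}

#' Write a placement table as minimal PAF
#'
#' @param placements data.frame from [placeContigs()].
#' @param contig_lengths,seq_lengths Named lengths (bp).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePAF <- function(placements, contig_lengths, seq_lengths, path) {
  p <- placements
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
    p$contig_id, as.integer(contig_lengths[p$contig_id]),
    as.integer(p$contig_start - 1), as.integer(p$contig_end),
    p$orientation, p$seq_id, as.integer(seq_lengths[p$seq_id]),
    as.integer(p$seq_start - 1), as.integer(p$seq_end),
    as.integer(round(p$identity * p$aligned_bp)),
    as.integer(p$aligned_bp), 60L)
  writeLines(lines, path)
  invisible(path)
}

# assemble an EditLog from per-sequence edit lists
# each edit: list(kind, old_start, old_end, new_length, provenance,
#                 copy_len [collapse only])
.build_editlog <- function(seqs_old, seq_edits) {
  blocks <- list(); edrows <- list()
  new_len <- vapply(seqs_old, nchar, 0)
  for (sid in names(seqs_old)) {
    L <- nchar(seqs_old[[sid]])
    eds <- seq_edits[[sid]]
    if (!is.null(eds) && length(eds))
      eds <- eds[order(vapply(eds, `[[`, 0, "old_start"))]
    co <- 1; cn <- 1
    for (e in eds) {
      a <- e$old_start; b <- e$old_end
      if (a > co) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          seq_id = sid, old_start = co, old_end = a - 1, new_seq = sid,
          new_start = cn, strand = "+", type = "affine")
        cn <- cn + (a - co)
      }
      if (e$kind == "fill") {
        blocks[[length(blocks) + 1L]] <- data.frame(
          seq_id = sid, old_start = a, old_end = b, new_seq = sid,
          new_start = cn, strand = "+", type = "point")
        cn <- cn + e$new_length
      } else if (e$kind == "collapse") {
        # removed interval = duplicate left copy + the gap; positions in the
        # left copy map onto the retained right copy, which begins at cn
        Lc <- e$copy_len
        blocks[[length(blocks) + 1L]] <- data.frame(
          seq_id = sid, old_start = a, old_end = a + Lc - 1, new_seq = sid,
          new_start = cn, strand = "+", type = "copy")
        blocks[[length(blocks) + 1L]] <- data.frame(
          seq_id = sid, old_start = a + Lc, old_end = b, new_seq = sid,
          new_start = cn, strand = "+", type = "point")
      } else .stopf("unknown edit kind '%s'", e$kind)
      edrows[[length(edrows) + 1L]] <- data.frame(
        kind = e$kind, seq_id = sid, old_start = a, old_end = b,
        new_length = e$new_length, provenance = e$provenance)
      co <- b + 1
    }
    if (co <= L) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        seq_id = sid, old_start = co, old_end = L, new_seq = sid,
        new_start = cn, strand = "+", type = "affine")
      cn <- cn + (L - co + 1)
    }
    new_len[sid] <- cn - 1
  }
  new("EditLog",
      edits = if (length(edrows)) do.call(rbind, edrows) else
        data.frame(kind = character(), seq_id = character(),
                   old_start = numeric(), old_end = numeric(),
                   new_length = numeric(), provenance = character()),
      blocks = do.call(rbind, blocks),
      seqlengths_old = vapply(seqs_old, nchar, 0),
      seqlengths_new = new_len)
}

#' Close N-gaps with flank-anchored contig sequence
#'
#' A gap is closed iff a single contig anchors both flanks: one placement
#' block per flank with at least `min_anchor_bp` aligned, ending/starting
#' within `max_edge_distance` of the gap edge, same contig and orientation,
#' and collinear in contig coordinates. The contig subsequence between the
#' anchor ends then replaces the assembly interval between them (which
#' contains the N-run). Placeholder gaps accept any implied span `>= 1`;
#' sized gaps additionally require the implied span to be within
#' `span_tolerance` (relative) of the emitted N count. Competing contigs are
#' ranked by total anchored bp, then mean identity, then contig id; a tie on
#' all keys is an error demanding explicit resolution. A gap is closed
#' entirely or left intact; partial shrinkage is never performed.
#'
#' @param assembly An [Assembly-class].
#' @param placements data.frame from [placeContigs()] or [readPAF()], in
#'   current assembly coordinates.
#' @param contigs The contig sequences ([Biostrings::DNAStringSet] or named
#'   character).
#' @param min_anchor_bp,max_edge_distance,min_identity,span_tolerance
#'   Anchoring thresholds (defaults 500 bp, 100 bp, 0.99, 0.5).
#' @return A list: `assembly` (patched), `log` ([EditLog-class]), `closed`
#'   (per-gap table of filled gaps), `summary` (closed count, replaced bp,
#'   net length change, remaining gap count).
#' @export
fillGaps <- function(assembly, placements, contigs, min_anchor_bp = 500,
                     max_edge_distance = 100, min_identity = 0.99,
                     span_tolerance = 0.5) {
  stopifnot(is(assembly, "Assembly"))
  if (is.character(contigs)) contigs <- DNAStringSet(contigs)
  cstr <- as.character(contigs)
  seqs <- as.character(assembly@seqs)
  g <- assembly@gaps
  pl <- placements[placements$aligned_bp >= min_anchor_bp &
                   placements$identity >= min_identity, , drop = FALSE]
  seq_edits <- setNames(vector("list", length(seqs)), names(seqs))
  closed <- list()
  for (sid in names(seqs)) {
    gi <- g[as.character(GenomicRanges::seqnames(g)) == sid]
    gi <- gi[order(BiocGenerics::start(gi), decreasing = TRUE)]
    ps <- pl[pl$seq_id == sid, , drop = FALSE]
    if (!length(gi) || !nrow(ps)) next
    guard <- Inf  # left edge of the last accepted replacement
    for (k in seq_along(gi)) {
      g1 <- BiocGenerics::start(gi)[k]; g2 <- BiocGenerics::end(gi)[k]
      klass <- gi$klass[k]
      lc <- ps[ps$seq_end >= g1 - 1 - max_edge_distance &
               ps$seq_end <= g1 - 1 & ps$seq_start < g1 - 1, , drop = FALSE]
      rc <- ps[ps$seq_start >= g2 + 1 &
               ps$seq_start <= g2 + 1 + max_edge_distance &
               ps$seq_end > g2 + 1, , drop = FALSE]
      if (!nrow(lc) || !nrow(rc)) next
      cand <- merge(lc, rc, by = c("contig_id", "orientation"),
                    suffixes = c(".l", ".r"))
      if (!nrow(cand)) next
      ok <- logical(nrow(cand)); rep_len <- numeric(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (cand$orientation[i] == "+") {
          rl <- cand$contig_start.r[i] - cand$contig_end.l[i] - 1
        } else {
          rl <- cand$contig_start.l[i] - cand$contig_end.r[i] - 1
        }
        if (is.na(rl) || rl < 0) next
        slack <- (g1 - 1 - cand$seq_end.l[i]) + (cand$seq_start.r[i] - g2 - 1)
        implied <- rl - slack
        rep_len[i] <- rl
        ok[i] <- if (klass == "sized") {
          abs(implied - (g2 - g1 + 1)) <= span_tolerance * (g2 - g1 + 1)
        } else implied >= 1
      }
      cand <- cand[ok, , drop = FALSE]; rep_len <- rep_len[ok]
      if (!nrow(cand)) next
      key_bp <- cand$aligned_bp.l + cand$aligned_bp.r
      key_id <- (cand$identity.l + cand$identity.r) / 2
      o <- order(-key_bp, -key_id, cand$contig_id)
      if (nrow(cand) > 1L) {
        a <- o[1L]; b <- o[2L]
        if (key_bp[a] == key_bp[b] && key_id[a] == key_id[b] &&
            cand$contig_id[a] == cand$contig_id[b])
          .stopf("tie between candidate fills at %s:%d-%d; resolve explicitly",
                 sid, g1, g2)
      }
      w <- o[1L]
      old_a <- cand$seq_end.l[w] + 1; old_b <- cand$seq_start.r[w] - 1
      if (old_b >= guard) next  # overlaps a previously accepted fill
      if (cand$orientation[w] == "+") {
        repl <- substr(cstr[[cand$contig_id[w]]],
                       cand$contig_end.l[w] + 1, cand$contig_start.r[w] - 1)
      } else {
        repl <- .revcomp(substr(cstr[[cand$contig_id[w]]],
                                cand$contig_end.r[w] + 1,
                                cand$contig_start.l[w] - 1))
      }
      guard <- old_a
      seq_edits[[sid]] <- c(seq_edits[[sid]], list(list(
        kind = "fill", old_start = old_a, old_end = old_b,
        new_length = nchar(repl), provenance = cand$contig_id[w],
        replacement = repl)))
      closed[[length(closed) + 1L]] <- data.frame(
        seq_id = sid, gap_start = g1, gap_end = g2, klass = klass,
        contig_id = cand$contig_id[w], orientation = cand$orientation[w],
        replaced_old_bp = old_b - old_a + 1, replacement_bp = nchar(repl))
    }
  }
  new_seqs <- seqs
  for (sid in names(seq_edits)) {
    eds <- seq_edits[[sid]]
    if (is.null(eds)) next
    # right-to-left so earlier coordinates stay valid during patching
    eds <- eds[order(vapply(eds, `[[`, 0, "old_start"), decreasing = TRUE)]
    s <- new_seqs[[sid]]
    for (e in eds)
      s <- paste0(substr(s, 1, e$old_start - 1), e$replacement,
                  substr(s, e$old_end + 1, nchar(s)))
    new_seqs[[sid]] <- s
  }
  log <- .build_editlog(seqs, seq_edits)
  out <- Assembly(new_seqs)
  closed_df <- if (length(closed)) do.call(rbind, closed) else
    data.frame(seq_id = character(), gap_start = numeric(),
               gap_end = numeric(), klass = character(),
               contig_id = character(), orientation = character(),
               replaced_old_bp = numeric(), replacement_bp = numeric())
  list(assembly = out, log = log, closed = closed_df,
       summary = data.frame(
         gaps_closed = nrow(closed_df),
         replaced_bp = sum(closed_df$replacement_bp),
         net_length_change = sum(vapply(new_seqs, nchar, 0)) -
           sum(vapply(seqs, nchar, 0)),
         gaps_remaining = length(out@gaps)))
}

#' Collapse duplication artifacts flanking placeholder gaps
#'
#' At tandem repeats, erroneous scaffold assembly can duplicate the region
#' around a placeholder gap: the sequence left of the gap ends with the same
#' near-identical copy that begins the sequence right of the gap. For each
#' placeholder gap, the best overlap between the left-flank window's suffix
#' and the right-flank window's prefix is computed; when a near-identical
#' overlap of at least `min_overlap` bp abuts the gap on both sides, the gap
#' and one copy of the overlap are removed, shortening the sequence by
#' overlap length + gap length.
#'
#' @param assembly An [Assembly-class].
#' @param window Flank window examined on each side (bp).
#' @param min_overlap Minimum duplicate-copy length (bp).
#' @param min_identity Identity floor for the overlap.
#' @return A list: `assembly` (patched), `log` ([EditLog-class]),
#'   `collapsed` (per-gap table).
#' @export
collapseDuplicationArtifacts <- function(assembly, window = 25000,
                                         min_overlap = 1000,
                                         min_identity = 0.99) {
  stopifnot(is(assembly, "Assembly"))
  seqs <- as.character(assembly@seqs)
  g <- assembly@gaps
  seq_edits <- setNames(vector("list", length(seqs)), names(seqs))
  collapsed <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    gi <- g[as.character(GenomicRanges::seqnames(g)) == sid &
            startsWith(g$klass, "placeholder")]
    gi <- gi[order(BiocGenerics::start(gi), decreasing = TRUE)]
    guard <- Inf
    for (k in seq_along(gi)) {
      g1 <- BiocGenerics::start(gi)[k]; g2 <- BiocGenerics::end(gi)[k]
      lw <- substr(s, max(1, g1 - window), g1 - 1)
      rw <- substr(s, g2 + 1, min(nchar(s), g2 + window))
      ov <- cpp_best_overlap(lw, rw, 31L, as.integer(min_overlap),
                             min_identity, 200L)
      L <- ov$length
      if (L == 0) next
      old_a <- g1 - L; old_b <- g2
      if (old_a < 1 || old_b >= guard) next
      guard <- old_a
      seq_edits[[sid]] <- c(seq_edits[[sid]], list(list(
        kind = "collapse", old_start = old_a, old_end = old_b,
        new_length = 0, provenance = "overlap", copy_len = L)))
      collapsed[[length(collapsed) + 1L]] <- data.frame(
        seq_id = sid, gap_start = g1, gap_end = g2, klass = gi$klass[k],
        overlap_bp = L, identity = ov$identity,
        removed_bp = old_b - old_a + 1)
    }
  }
  new_seqs <- seqs
  for (sid in names(seq_edits)) {
    eds <- seq_edits[[sid]]
    if (is.null(eds)) next
    eds <- eds[order(vapply(eds, `[[`, 0, "old_start"), decreasing = TRUE)]
    s <- new_seqs[[sid]]
    for (e in eds)
      s <- paste0(substr(s, 1, e$old_start - 1),
                  substr(s, e$old_end + 1, nchar(s)))
    new_seqs[[sid]] <- s
  }
  log <- .build_editlog(seqs, seq_edits)
  list(assembly = Assembly(new_seqs), log = log,
       collapsed = if (length(collapsed)) do.call(rbind, collapsed) else
         data.frame(seq_id = character(), gap_start = numeric(),
                    gap_end = numeric(), klass = character(),
                    overlap_bp = numeric(), identity = numeric(),
                    removed_bp = numeric()))
}

#' Lift positions through an edit log
#'
#' Positions outside edited intervals map bijectively (with strand for
#' flipped segments); positions inside a collapsed duplicate copy map to the
#' corresponding position in the retained copy; positions inside a replaced
#' N-run map to the replacement start. The reverse direction uses only the
#' bijective blocks, so positions inside inserted replacement sequence have
#' no pre-image and return `NA`.
#'
#' @param log An [EditLog-class].
#' @param seq_id Sequence name (in old coordinates for `old2new`, new
#'   coordinates for `new2old`).
#' @param position Numeric vector of positions.
#' @param direction `"old2new"` (default) or `"new2old"`.
#' @return A data.frame with columns `seq_id`, `position` (NA where no
#'   image exists).
#' @export
liftover <- function(log, seq_id, position, direction = c("old2new",
                                                          "new2old")) {
  stopifnot(is(log, "EditLog"))
  direction <- match.arg(direction)
  b <- log@blocks
  if (direction == "old2new") {
    if (!seq_id %in% names(log@seqlengths_old))
      .stopf("unknown sequence '%s'", seq_id)
    if (any(position < 1 | position > log@seqlengths_old[seq_id]))
      .stopf("position outside original sequence '%s'", seq_id)
    bb <- b[b$seq_id == seq_id, , drop = FALSE]
    out_seq <- rep(NA_character_, length(position))
    out_pos <- rep(NA_real_, length(position))
    for (i in seq_along(position)) {
      p <- position[i]
      hit <- bb[bb$old_start <= p & p <= bb$old_end, , drop = FALSE]
      if (!nrow(hit)) next
      h <- hit[1L, ]
      out_seq[i] <- h$new_seq
      out_pos[i] <- if (h$type == "point") h$new_start
        else if (h$strand == "+") h$new_start + (p - h$old_start)
        else h$new_start + (h$old_end - p)
    }
    return(data.frame(seq_id = out_seq, position = out_pos))
  }
  if (!seq_id %in% names(log@seqlengths_new))
    .stopf("unknown sequence '%s'", seq_id)
  bb <- b[b$new_seq == seq_id & b$type == "affine", , drop = FALSE]
  bb$new_end <- bb$new_start + (bb$old_end - bb$old_start)
  out_seq <- rep(NA_character_, length(position))
  out_pos <- rep(NA_real_, length(position))
  for (i in seq_along(position)) {
    p <- position[i]
    hit <- bb[bb$new_start <= p & p <= bb$new_end, , drop = FALSE]
    if (!nrow(hit)) next
    h <- hit[1L, ]
    out_seq[i] <- h$seq_id
    out_pos[i] <- if (h$strand == "+") h$old_start + (p - h$new_start)
      else h$old_end - (p - h$new_start)
  }
  data.frame(seq_id = out_seq, position = out_pos)
}

#' Lift a GRanges through an edit log
#'
#' Start and end are lifted independently (`old2new`); ranges whose ends map
#' to different sequences or lose their orientation are dropped with a
#' warning. Minus-strand blocks swap start and end.
#'
#' @param log An [EditLog-class].
#' @param gr A [GenomicRanges::GRanges] in old coordinates.
#' @return A [GenomicRanges::GRanges] in new coordinates.
#' @export
liftoverRanges <- function(log, gr) {
  stopifnot(is(gr, "GRanges"))
  sids <- as.character(GenomicRanges::seqnames(gr))
  ns <- character(length(gr)); a <- numeric(length(gr))
  bpos <- numeric(length(gr))
  for (i in seq_along(gr)) {
    l1 <- liftover(log, sids[i], BiocGenerics::start(gr)[i])
    l2 <- liftover(log, sids[i], BiocGenerics::end(gr)[i])
    if (is.na(l1$position) || is.na(l2$position) ||
        !identical(l1$seq_id, l2$seq_id)) {
      ns[i] <- NA_character_
      next
    }
    ns[i] <- l1$seq_id
    a[i] <- min(l1$position, l2$position)
    bpos[i] <- max(l1$position, l2$position)
  }
  keep <- !is.na(ns)
  if (any(!keep)) warning(sum(!keep), " range(s) dropped in lift-over")
  out <- GRanges(ns[keep], IRanges(a[keep], bpos[keep]))
  mcols(out) <- mcols(gr)[keep, , drop = FALSE]
  out
}
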