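# Mis-assembly detection against optical maps and correction of scaffold
# placement/orientation.

# scaffold intervals: maximal runs between placeholder-1000 joins
.scaffolds <- function(assembly) {
  g <- assembly@gaps
  out <- list()
  for (sid in names(assembly@seqs)) {
    L <- Biostrings::width(assembly@seqs)[match(sid, names(assembly@seqs))]
    j <- g[as.character(GenomicRanges::seqnames(g)) == sid &
           g$klass == "placeholder1000"]
    j <- j[order(BiocGenerics::start(j))]
    starts <- c(1, BiocGenerics::end(j) + 1)
    ends <- c(BiocGenerics::start(j) - 1, L)
    keep <- ends >= starts
    out[[sid]] <- data.frame(
      seq_id = sid, scaffold = seq_len(sum(keep)),
      start = starts[keep], end = ends[keep])
  }
  do.call(rbind, out)
}

# indices of a longest strictly-increasing subsequence (first optimum)
.lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  best <- integer(n); prev <- integer(n); len <- 0L
  for (i in seq_len(n)) {
    lo <- 1L; hi <- len
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (x[best[mid]] < x[i]) lo <- mid + 1L else hi <- mid - 1L
    }
    prev[i] <- if (lo > 1L) best[lo - 1L] else 0L
    best[lo] <- i
    if (lo > len) len <- lo
  }
  out <- integer(len)
  k <- best[len]
  for (j in rev(seq_len(len))) { out[j] <- k; k <- prev[k] }
  out
}

# query label indices in original orientation for a MapAlignment
.orig_q_idx <- function(aln, nq) {
  if (aln@orientation == "+") aln@pairs$q else sort(nq + 1L - aln@pairs$q)
}

.best_significant <- function(qmap, refs, params) {
  best <- NULL
  for (r in refs) {
    if (length(r@labels) < 2L) next
    a <- tryCatch(mapAlign(qmap, r, params), error = function(e) NULL)
    if (is.null(a) || !a@significant) next
    if (is.null(best) || a@score > best@score) best <- a
  }
  best
}

# best score over refs and orientations, no permutation test (fast scan)
.best_score_fast <- function(qmap, refs, params) {
  best <- -Inf; best_ref <- NA_character_
  for (r in refs) {
    if (length(r@labels) < 2L) next
    for (lab in list(qmap@labels, .reorient(qmap))) {
      s <- cpp_mapalign_dp(lab, r@labels, params@v, params@B,
                           params@p_miss, params@max_merge, FALSE)$score
      if (s > best) { best <- s; best_ref <- r@map_id }
    }
  }
  list(score = best, ref = best_ref)
}

.submap <- function(contig, idx, tag) {
  lab <- contig@labels[idx]
  LabelMap(paste0(contig@map_id, tag), diff(range(lab)) + 2000,
           lab - lab[1L] + 1000)
}

#' Detect chimeric map contigs
#'
#' A chimeric consensus map joins fragments from unlinked loci. Detection
#' uses a split-gain criterion: for candidate breakpoints the contig is cut
#' in two and each part is aligned on its own; if the combined score exceeds
#' the unsplit score by more than `min_gain` and the two parts align
#' inconsistently (different reference, different orientation, or an implied
#' coordinate jump beyond `tol_bp`), the contig is reported with the
#' breakpoint between the two aligned blocks. An intact contig never gains
#' from splitting (it only forfeits a pair bonus), so the criterion is
#' robust even where repeats let a glocal alignment creep across the
#' junction.
#'
#' @param contig A [LabelMap-class].
#' @param refs A list of reference [LabelMap-class] objects.
#' @param params An [AlignParams-class].
#' @param tol_bp Coordinate-jump tolerance on the same reference (bp).
#' @param min_gain Minimum combined-score gain over the unsplit alignment
#'   (default `3 * B`).
#' @return A data.frame of split points (`contig_id`, `split_index`,
#'   `split_position`, `left_ref`, `right_ref`); zero rows when the contig
#'   is consistent. The attribute `unaligned` is `TRUE` when no part of the
#'   contig aligns significantly.
#' @export
detectChimeras <- function(contig, refs, params, tol_bp = 5e4,
                           min_gain = 3 * params@B) {
  stopifnot(is(contig, "LabelMap"), length(refs) >= 1L)
  empty <- data.frame(contig_id = character(), split_index = integer(),
                      split_position = numeric(), left_ref = character(),
                      right_ref = character())
  nq <- length(contig@labels)
  full <- .best_significant(contig, refs, params)
  if (is.null(full)) {
    attr(empty, "unaligned") <- TRUE
    return(empty)
  }
  mm <- max(3L, params@min_matched_labels)
  if (nq < 2L * mm) return(empty)
  cand <- seq(mm, nq - mm)
  # coarse scan, then refine around the best split
  step <- max(1L, (nq - 2L * mm) %/% 24L)
  scan <- unique(c(seq(cand[1L], cand[length(cand)], by = step),
                   cand[length(cand)]))
  gain <- function(s) {
    l <- .best_score_fast(.submap(contig, 1:s, "_L"), refs, params)
    r <- .best_score_fast(.submap(contig, (s + 1L):nq, "_R"), refs, params)
    l$score + r$score - full@score
  }
  g <- vapply(scan, gain, 0)
  s0 <- scan[which.max(g)]
  fine <- cand[cand >= s0 - step & cand <= s0 + step]
  gf <- vapply(fine, gain, 0)
  s <- fine[which.max(gf)]
  if (max(gf) < min_gain) return(empty)
  left <- .best_significant(.submap(contig, 1:s, "_L"), refs, params)
  right <- .best_significant(.submap(contig, (s + 1L):nq, "_R"), refs,
                             params)
  if (is.null(left) || is.null(right)) return(empty)
  inconsistent <- left@ref_id != right@ref_id ||
    left@orientation != right@orientation
  if (!inconsistent) {
    ref_map <- refs[[match(left@ref_id, vapply(refs, mapId, ""))]]
    dref <- abs(ref_map@labels[right@pairs$r[1L]] -
                ref_map@labels[left@pairs$r[nrow(left@pairs)]])
    dq <- abs(contig@labels[s + 1L] - contig@labels[s])
    inconsistent <- abs(dref - dq) > tol_bp
  }
  if (!inconsistent) return(empty)
  data.frame(contig_id = contig@map_id, split_index = s,
             split_position = (contig@labels[s] + contig@labels[s + 1L]) / 2,
             left_ref = left@ref_id, right_ref = right@ref_id)
}

#' Validate scaffold placements against optical maps
#'
#' Each assembly segment between 1000-N joins is digested in silico and
#' aligned to every optical map. A segment whose best significant alignment
#' is inconsistent with its current coordinates yields one conflict: on a
#' different chromosome's consensus map (`misplaced`, with a move proposal),
#' oriented against its chromosome's majority (`misoriented`, with a flip
#' proposal), or out of positional order on its own map (`misplaced`, with
#' an in-chromosome move). Segments with too few labels or no significant
#' alignment are left unassessed.
#'
#' @param assembly An [Assembly-class].
#' @param maps List of reference [LabelMap-class] optical maps.
#' @param params An [AlignParams-class].
#' @param motif,resolution Digest settings; must match how `maps` were made.
#' @return A list: `conflicts` (data.frame of conflicts), `edits`
#'   (data.frame consumable by [applyEdits()]), `segments` (per-scaffold
#'   alignment summary).
#' @export
validatePlacements <- function(assembly, maps, params, motif = "GCTCTTC",
                               resolution = 1000) {
  stopifnot(is(assembly, "Assembly"))
  scafs <- .scaffolds(assembly)
  seqs <- as.character(assembly@seqs)
  rec <- scafs
  rec$map_id <- NA_character_
  rec$orientation <- NA_character_
  rec$ref_pos <- NA_real_
  rec$score <- NA_real_
  for (i in seq_len(nrow(scafs))) {
    s <- substr(seqs[[scafs$seq_id[i]]], scafs$start[i], scafs$end[i])
    qm <- digestSequence(s, motif, resolution,
                         map_id = sprintf("%s_s%d", scafs$seq_id[i],
                                          scafs$scaffold[i]))
    if (length(qm@labels) < max(2L, params@min_matched_labels)) next
    best <- .best_significant(qm, maps, params)
    if (is.null(best)) next
    rec$map_id[i] <- best@ref_id
    rec$orientation[i] <- best@orientation
    ref_map <- maps[[match(best@ref_id, vapply(maps, mapId, ""))]]
    rec$ref_pos[i] <- ref_map@labels[best@pairs$r[1L]]
    rec$score[i] <- best@score
  }
  # consensus map per chromosome: the map most of its assessed scaffolds
  # align to (scaffold count, ties broken by aligned bp) -- counting, not
  # bp-weighting, so one large misplaced scaffold cannot outvote its host
  cons <- vapply(split(rec, rec$seq_id), function(g) {
    g <- g[!is.na(g$map_id), , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    n <- table(g$map_id)
    bp <- tapply(g$end - g$start + 1, g$map_id, sum)
    o <- order(-as.integer(n[names(bp)]), -bp)
    names(bp)[o[1L]]
  }, "")
  map_owner <- setNames(names(cons), cons)   # map_id -> chromosome

  conflicts <- list(); edits <- list()
  add <- function(kind, row, edit_kind, target_seq, target_index, revcomp) {
    conflicts[[length(conflicts) + 1L]] <<- data.frame(
      seq_id = row$seq_id, scaffold = row$scaffold, start = row$start,
      end = row$end, kind = kind, target_seq = target_seq,
      target_index = target_index, revcomp = revcomp)
    if (!is.na(edit_kind))
      edits[[length(edits) + 1L]] <<- data.frame(
        kind = edit_kind, seq_id = row$seq_id, start = row$start,
        end = row$end, target_seq = target_seq,
        target_index = target_index, revcomp = revcomp)
  }
  for (sid in unique(rec$seq_id)) {
    g <- rec[rec$seq_id == sid, , drop = FALSE]
    ok <- !is.na(g$map_id)
    misplaced <- ok & g$map_id != cons[sid]
    for (i in which(misplaced)) {
      tgt <- unname(map_owner[g$map_id[i]])
      if (is.na(tgt) || !length(tgt)) {
        # the aligned map is claimed by no chromosome: report, no edit
        add("misplaced", g[i, ], NA_character_, NA_character_,
            NA_integer_, g$orientation[i] == "-")
        next
      }
      # insertion ordinal among ALL target scaffolds: right after the last
      # assessed scaffold that precedes the block on the map (unassessed
      # scaffolds keep their physical position)
      tg <- rec[rec$seq_id == tgt & !is.na(rec$ref_pos) &
                rec$map_id == g$map_id[i], , drop = FALSE]
      prev <- tg$scaffold[tg$ref_pos < g$ref_pos[i]]
      idx <- if (length(prev)) max(prev) + 1L else 1L
      add("misplaced", g[i, ], "move", tgt, idx, g$orientation[i] == "-")
    }
    # within-chromosome checks against the consensus map, whose forward
    # orientation is the canonical frame
    h <- g[ok & g$map_id == cons[sid], , drop = FALSE]
    if (!nrow(h)) next
    flip <- h$orientation == "-"
    for (i in which(flip))
      add("misoriented", h[i, ], "flip", NA_character_, NA_integer_, TRUE)
    # positional order: scaffolds off the longest increasing run are moved
    keep <- .lis(h$ref_pos)
    out_of_order <- setdiff(seq_len(nrow(h)), keep)
    out_of_order <- out_of_order[!flip[out_of_order]]
    for (i in out_of_order) {
      ok_rows <- setdiff(keep, i)
      prev <- h$scaffold[ok_rows][h$ref_pos[ok_rows] < h$ref_pos[i]]
      idx <- if (length(prev)) max(prev) + 1L else 1L
      # the piece is removed from the same list before re-insertion
      if (h$scaffold[i] < idx) idx <- idx - 1L
      add("misplaced", h[i, ], "move", sid, idx, FALSE)
    }
  }
  list(
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
      data.frame(seq_id = character(), scaffold = integer(),
                 start = numeric(), end = numeric(), kind = character(),
                 target_seq = character(), target_index = integer(),
                 revcomp = logical()),
    edits = if (length(edits)) do.call(rbind, edits) else
      data.frame(kind = character(), seq_id = character(),
                 start = numeric(), end = numeric(),
                 target_seq = character(), target_index = integer(),
                 revcomp = logical()),
    segments = rec)
}

#' Apply placement/orientation edits to an assembly
#'
#' Applies `flip` (reverse-complement in place) and `move` (relocate a
#' scaffold, optionally flipping) edits. Every edit interval must coincide
#' with a scaffold (a maximal segment between 1000-N joins); overlapping
#' edits are a conflict error naming the offending pair. 1000-N joins are
#' re-emitted at the new junctions and a lift-over table records old-to-new
#' coordinates.
#'
#' @param assembly An [Assembly-class].
#' @param edits data.frame as produced by [validatePlacements()]`$edits`.
#' @return A list: `assembly` (revised [Assembly-class]), `log`
#'   ([EditLog-class]).
#' @export
applyEdits <- function(assembly, edits) {
  stopifnot(is(assembly, "Assembly"))
  seqs <- as.character(assembly@seqs)
  scafs <- .scaffolds(assembly)
  if (is.null(edits) || nrow(edits) == 0L) {
    log <- .editlog_identity(seqs)
    return(list(assembly = assembly, log = log))
  }
  # overlap check
  if (nrow(edits) > 1L) {
    for (i in seq_len(nrow(edits) - 1L)) for (j in (i + 1L):nrow(edits)) {
      if (edits$seq_id[i] == edits$seq_id[j] &&
          edits$start[i] <= edits$end[j] && edits$start[j] <= edits$end[i])
        .stopf("conflicting edits %d and %d overlap on %s", i, j,
               edits$seq_id[i])
    }
  }
  # scaffold piece lists, keyed by chromosome
  pieces <- lapply(split(scafs, scafs$seq_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) list(
      src_seq = g$seq_id[i], src_start = g$start[i], src_end = g$end[i],
      revcomp = FALSE))
  })
  pieces <- pieces[names(seqs)]
  locate <- function(sid, a, b) {
    pl <- pieces[[sid]]
    for (i in seq_along(pl))
      if (pl[[i]]$src_seq == sid && pl[[i]]$src_start == a &&
          pl[[i]]$src_end == b) return(i)
    .stopf("edit interval %s:%d-%d does not match a scaffold", sid, a, b)
  }
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$kind == "flip") {
      at <- locate(e$seq_id, e$start, e$end)
      pieces[[e$seq_id]][[at]]$revcomp <-
        !pieces[[e$seq_id]][[at]]$revcomp
    } else if (e$kind == "move") {
      at <- locate(e$seq_id, e$start, e$end)
      p <- pieces[[e$seq_id]][[at]]
      if (isTRUE(e$revcomp)) p$revcomp <- !p$revcomp
      pieces[[e$seq_id]][[at]] <- NULL
      tgt <- e$target_seq
      idx <- min(max(1L, e$target_index), length(pieces[[tgt]]) + 1L)
      pieces[[tgt]] <- append(pieces[[tgt]], list(p), after = idx - 1L)
    } else .stopf("unknown edit kind '%s'", e$kind)
  }
  # emit and build lift-over
  join <- strrep("N", 1000L)
  new_seqs <- character(0)
  blocks <- list()
  for (sid in names(pieces)) {
    parts <- character(0)
    at <- 1
    for (p in pieces[[sid]]) {
      s <- substr(seqs[[p$src_seq]], p$src_start, p$src_end)
      if (p$revcomp) s <- .revcomp(s)
      if (length(parts)) {
        parts <- c(parts, join)
        at <- at + 1000
      }
      parts <- c(parts, s)
      blocks[[length(blocks) + 1L]] <- data.frame(
        seq_id = p$src_seq, old_start = p$src_start, old_end = p$src_end,
        new_seq = sid, new_start = at,
        strand = if (p$revcomp) "-" else "+", type = "affine")
      at <- at + nchar(s)
    }
    new_seqs[sid] <- paste(parts, collapse = "")
  }
  # old separator gaps: point-map to the junction following their left
  # neighbour's image (or to the start of the image chromosome)
  bl <- do.call(rbind, blocks)
  for (sid in names(seqs)) {
    sc <- scafs[scafs$seq_id == sid, , drop = FALSE]
    sc <- sc[order(sc$start), , drop = FALSE]
    gapruns <- data.frame(start = c(1, sc$end + 1),
                          end = c(sc$start - 1, nchar(seqs[[sid]])))
    gapruns <- gapruns[gapruns$end >= gapruns$start, , drop = FALSE]
    for (gi in seq_len(nrow(gapruns))) {
      prev <- sc[sc$end == gapruns$start[gi] - 1L, , drop = FALSE]
      tgt <- if (nrow(prev)) {
        img <- bl[bl$seq_id == sid & bl$old_start == prev$start[1L], ,
                  drop = FALSE]
        c(img$new_seq[1L],
          img$new_start[1L] + (img$old_end[1L] - img$old_start[1L]) + 1)
      } else c(sid, 1)
      blocks[[length(blocks) + 1L]] <- data.frame(
        seq_id = sid, old_start = gapruns$start[gi],
        old_end = gapruns$end[gi], new_seq = tgt[1L],
        new_start = as.numeric(tgt[2L]), strand = "+", type = "point")
    }
  }
  ed <- edits
  ed$old_start <- ed$start; ed$old_end <- ed$end
  ed$new_length <- ed$end - ed$start + 1
  ed$provenance <- "optical"
  log <- new("EditLog",
    edits = ed[, c("kind", "seq_id", "old_start", "old_end", "new_length",
                   "provenance")],
    blocks = do.call(rbind, blocks),
    seqlengths_old = vapply(seqs, nchar, 0),
    seqlengths_new = vapply(new_seqs, nchar, 0))
  list(assembly = Assembly(new_seqs), log = log)
}

.editlog_identity <- function(seqs) {
  blocks <- do.call(rbind, lapply(names(seqs), function(sid) data.frame(
    seq_id = sid, old_start = 1, old_end = nchar(seqs[[sid]]),
    new_seq = sid, new_start = 1, strand = "+", type = "affine")))
  new("EditLog",
      edits = data.frame(kind = character(), seq_id = character(),
                         old_start = numeric(), old_end = numeric(),
                         new_length = numeric(), provenance = character()),
      blocks = blocks,
      seqlengths_old = vapply(seqs, nchar, 0),
      seqlengths_new = vapply(seqs, nchar, 0))
}
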