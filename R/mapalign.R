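# Ordered-map alignment by dynamic programming with permutation-null
# significance.

#' Ordered-map alignment parameters
#'
#' Defaults follow nick-site optical-map scales: sizing variance scale
#' `v = 200` bp, match bonus `B = 5`, miss penalty `p_miss = 3`, up to
#' `max_merge = 3` fragments merged per pair, and at least 9 matched labels
#' for a call. The historical vendor aligner's P-value cutoffs belong to a
#' proprietary test statistic, so significance here is a permutation null:
#' an alignment is significant only if its score exceeds the best score on
#' all `n_permutations` shuffles of the reference fragment order
#' (`alpha = 1/(n_permutations + 1)`).
#'
#' @param seed Integer seed for the permutation stream (required).
#' @param v,B,p_miss,max_merge,min_matched_labels,n_permutations See slots
#'   of [AlignParams-class].
#' @return An [AlignParams-class].
#' @export
alignParams <- function(seed, v = 200, B = 5, p_miss = 3, max_merge = 3L,
                        min_matched_labels = 9L, n_permutations = 100L) {
  new("AlignParams", v = v, B = B, p_miss = p_miss,
      max_merge = as.integer(max_merge),
      min_matched_labels = as.integer(min_matched_labels),
      n_permutations = as.integer(n_permutations),
      alpha = 1 / (n_permutations + 1), seed = as.integer(seed))
}

# DP in one orientation; query labels already oriented
.dp_one <- function(qlab, rlab, params, traceback = TRUE) {
  cpp_mapalign_dp(qlab, rlab, params@v, params@B, params@p_miss,
                  params@max_merge, traceback)
}

.reorient <- function(m) rev(m@length - m@labels)

#' Align two label maps
#'
#' Dynamic program over monotone label pairings: a matched pair earns bonus
#' `B` minus a sizing cost `(x - y)^2 / (v (x + y) + 1)` on the merged
#' interval lengths, and every interior label merged over costs `p_miss`.
#' Both query orientations are tried (ties prefer `+`). Significance is
#' assessed against `n_permutations` shuffles of the reference fragment
#' order: significant iff the observed score beats every permuted score and
#' at least `min_matched_labels` labels are matched.
#'
#' @param query,ref [LabelMap-class] objects with `>= 2` labels each.
#' @param params An [AlignParams-class].
#' @return A [MapAlignment-class].
#' @examples
#' m <- LabelMap("m", 1e5, c(1, 2.2, 3.1, 5, 7.7, 9) * 1e4)
#' aln <- mapAlign(m, m, alignParams(seed = 1, min_matched_labels = 4))
#' aln
#' @export
mapAlign <- function(query, ref, params) {
  stopifnot(is(query, "LabelMap"), is(ref, "LabelMap"),
            is(params, "AlignParams"))
  if (length(query@labels) < 2L || length(ref@labels) < 2L)
    .stopf("alignment error: both maps need >= 2 labels")
  fw <- .dp_one(query@labels, ref@labels, params)
  rv <- .dp_one(.reorient(query), ref@labels, params)
  use_rev <- rv$score > fw$score
  best <- if (use_rev) rv else fw
  nq <- length(query@labels); nr <- length(ref@labels)
  qidx <- best$q; ridx <- best$r
  dmerge <- 0L
  if (length(qidx) > 1L)
    dmerge <- sum(diff(qidx) - 1L) + sum(diff(ridx) - 1L)
  missed_q <- (qidx[1L] - 1L) + (nq - qidx[length(qidx)])
  missed_r <- (ridx[1L] - 1L) + (nr - ridx[length(ridx)])

  n_ge <- 0L
  significant <- FALSE
  if (params@n_permutations > 0L) {
    rfrag <- diff(ref@labels)
    base <- ref@labels[1L]
    scores <- .with_seed(params@seed, {
      vapply(seq_len(params@n_permutations), function(i) {
        pf <- rfrag[sample.int(length(rfrag))]
        plab <- c(base, base + cumsum(pf))
        max(.dp_one(query@labels, plab, params, traceback = FALSE)$score,
            .dp_one(.reorient(query), plab, params,
                    traceback = FALSE)$score)
      }, 0)
    })
    n_ge <- sum(scores >= best$score)
    significant <- n_ge == 0L && length(qidx) >= params@min_matched_labels
  } else {
    significant <- length(qidx) >= params@min_matched_labels
  }
  new("MapAlignment",
      query_id = query@map_id, ref_id = ref@map_id,
      orientation = if (use_rev) "-" else "+",
      pairs = data.frame(q = qidx, r = ridx),
      score = best$score, sizing_cost = best$sizing_cost,
      n_merges = as.integer(dmerge), missed_query = as.integer(missed_q),
      missed_ref = as.integer(missed_r), significant = significant,
      n_perm_ge = as.integer(n_ge))
}

#' Write map alignments as TSV
#'
#' One row per alignment with summary fields; matched pairs are serialized
#' as comma-separated index lists.
#'
#' @param alignments A [MapAlignment-class] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeMapAlignments <- function(alignments, path) {
  if (is(alignments, "MapAlignment")) alignments <- list(alignments)
  rows <- lapply(alignments, function(a) data.frame(
    query_id = a@query_id, ref_id = a@ref_id, orientation = a@orientation,
    n_pairs = nrow(a@pairs), score = a@score, sizing_cost = a@sizing_cost,
    n_merges = a@n_merges, missed_query = a@missed_query,
    missed_ref = a@missed_ref, significant = a@significant,
    q_idx = paste(a@pairs$q, collapse = ","),
    r_idx = paste(a@pairs$r, collapse = ",")))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
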