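# Assembly metrics, before/after census comparison, and parts-versus-totals
# validation of annotation census tables.

#' Assembly contiguity metrics
#'
#' N50 is the length of the smallest member of the minimal set of largest
#' sequences that jointly cover at least half the total.
#'
#' @param x A numeric vector of sequence lengths, or an [Assembly-class]
#'   (which also contributes effective length and gap counts by class).
#' @return A one-row data.frame: `n_sequences`, `total_bp`, `effective_bp`,
#'   `n50_bp`, `max_bp`, and `gaps_*` count columns when `x` is an
#'   [Assembly-class] (`NA` otherwise).
#' @examples
#' assemblyMetrics(c(5, 4, 3, 2, 1))$n50_bp  # 4
#' @export
assemblyMetrics <- function(x) {
  gapcols <- setNames(rep(NA_real_, 5L),
    c("gaps_placeholder10", "gaps_placeholder100", "gaps_placeholder1000",
      "gaps_sized", "effective_bp"))
  if (is(x, "Assembly")) {
    lens <- as.numeric(Biostrings::width(x@seqs))
    tab <- table(factor(x@gaps$klass,
      levels = c("placeholder10", "placeholder100", "placeholder1000",
                 "sized")))
    gapcols[1:4] <- as.numeric(tab)
    gapcols["effective_bp"] <- sum(lens) - sum(as.numeric(x@gaps$gap_length))
  } else {
    lens <- as.numeric(x)
  }
  if (length(lens) == 0L || any(lens <= 0))
    .stopf("sequence lengths must be positive")
  srt <- sort(lens, decreasing = TRUE)
  n50 <- srt[which(cumsum(srt) >= sum(srt) / 2)[1L]]
  data.frame(n_sequences = length(lens), total_bp = sum(lens),
             effective_bp = gapcols[["effective_bp"]], n50_bp = n50,
             max_bp = max(lens),
             gaps_placeholder10 = gapcols[[1L]],
             gaps_placeholder100 = gapcols[[2L]],
             gaps_placeholder1000 = gapcols[[3L]],
             gaps_sized = gapcols[[4L]], row.names = NULL)
}

#' Difference table between two censuses
#'
#' Computes `new - old` for every numeric column, per sequence and for the
#' `Total` row, so a decrease prints as a negative number. Both censuses
#' must cover the same sequence set.
#'
#' @param old,new data.frames from [gapCensus()] (or any table with a
#'   `seq_id` column and numeric columns).
#' @return A data.frame of per-row differences.
#' @examples
#' a <- data.frame(seq_id = c("c1", "Total"), total_length = c(100, 100),
#'                 gap_length = c(10, 10))
#' b <- data.frame(seq_id = c("c1", "Total"), total_length = c(98, 98),
#'                 gap_length = c(4, 4))
#' compareCensuses(a, b)
#' @export
compareCensuses <- function(old, new) {
  if (!setequal(old$seq_id, new$seq_id))
    .stopf("censuses cover different sequence sets")
  m <- match(old$seq_id, new$seq_id)
  num <- names(old)[vapply(old, is.numeric, TRUE)]
  out <- data.frame(seq_id = old$seq_id)
  for (cn in num) out[[cn]] <- new[[cn]][m] - old[[cn]]
  out
}

#' Validate declared totals against their parts
#'
#' Checks every declared part-of relation: the value labelled `total` must
#' equal the sum of the values labelled in `parts`, within `tolerance`
#' (absolute; use 0 for integer columns, a small tolerance for percentage
#' columns affected by printed rounding).
#'
#' @param values A named numeric vector, or a data.frame with `label` and
#'   `value` columns.
#' @param relations A list of relations, each a list with `total` (label),
#'   `parts` (labels), and optional `tolerance` overriding the default.
#' @param tolerance Default absolute tolerance.
#' @return A data.frame of violations (`total_label`, `expected`,
#'   `observed`, `difference`); zero rows when every relation holds.
#' @export
validateTotals <- function(values, relations, tolerance = 0) {
  if (is.data.frame(values))
    values <- setNames(values$value, values$label)
  bad <- list()
  for (rel in relations) {
    labs <- c(rel$total, rel$parts)
    unknown <- setdiff(labs, names(values))
    if (length(unknown))
      .stopf("unknown label(s) in relation: %s",
             paste(unknown, collapse = ", "))
    tol <- if (!is.null(rel$tolerance)) rel$tolerance else tolerance
    expected <- sum(values[rel$parts])
    observed <- values[[rel$total]]
    if (abs(observed - expected) > tol + 1e-12)
      bad[[length(bad) + 1L]] <- data.frame(
        total_label = rel$total, expected = expected, observed = observed,
        difference = observed - expected)
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(total_label = character(), expected = numeric(),
               observed = numeric(), difference = numeric())
}

#' Path to a bundled census-table fixture
#'
#' The package ships the published pseudomolecule, transposable-element,
#' LTR-retrotransposon, gene-annotation, and resistance-gene census tables
#' as plain TSV under `extdata/` for worked examples and
#' parts-versus-totals validation.
#'
#' @param name File name under `extdata` (listed when empty).
#' @return File path (or vector of available names).
#' @export
censusFixture <- function(name = "") {
  if (!nzchar(name))
    return(dir(system.file("extdata", package = "gapsmith")))
  f <- system.file("extdata", name, package = "gapsmith")
  if (!nzchar(f)) .stopf("no fixture '%s'", name)
  f
}
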