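# Gene-model evidence grading: HC/LC/REP decision tree over best BLAST hits
# against a curated protein database (UniMag), a Poaceae protein database
# (UniPoa), and a hypothetical-TE-protein database (PTREP), plus the
# BUSCO-style completeness summary.

.EV_DBS <- c("UniMag", "UniPoa", "PTREP")

#' Is a best hit significant?
#'
#' A hit is significant iff its E-value is strictly below `evalue_max` and
#' the database-appropriate coverage is strictly above `coverage_min`:
#' subject coverage for the protein databases (UniMag, UniPoa), query
#' coverage for the transposon database (PTREP). The source text's
#' "E-value below 10e-10" is read as 1e-10 by default; the literal reading
#' (10 x 10^-10 = 1e-9) is available by passing `evalue_max = 1e-9`.
#'
#' @param hit A list or one-row data.frame with `evalue`, `query_coverage`,
#'   `subject_coverage` (percent, 0-100).
#' @param database One of `"UniMag"`, `"UniPoa"`, `"PTREP"`.
#' @param evalue_max E-value cutoff (strict `<`).
#' @param coverage_min Coverage cutoff in percent (strict `>`).
#' @return Logical scalar.
#' @examples
#' significantHit(list(evalue = 1e-12, query_coverage = 50,
#'                     subject_coverage = 98), "UniMag")
#' @export
significantHit <- function(hit, database, evalue_max = 1e-10,
                           coverage_min = 95) {
  database <- match.arg(database, .EV_DBS)
  cov <- if (database == "PTREP") hit$query_coverage else hit$subject_coverage
  if (is.null(cov) || length(cov) != 1L || is.na(cov))
    .stopf("missing %s coverage for %s hit",
           if (database == "PTREP") "query" else "subject", database)
  ev <- hit$evalue
  if (is.null(ev) || is.na(ev)) .stopf("missing evalue for %s hit", database)
  ev < evalue_max && cov > coverage_min
}

# per-database evidence state: "absent" (no hit), "insig" (hit below
# thresholds), or "sig"
.db_state <- function(rec, db, evalue_max, coverage_min) {
  pre <- c(UniMag = "um", UniPoa = "up", PTREP = "pt")[[db]]
  ev <- rec[[paste0(pre, "_evalue")]]
  if (is.null(ev) || is.na(ev)) return("absent")
  hit <- list(evalue = ev,
              query_coverage = rec[[paste0(pre, "_qcov")]],
              subject_coverage = rec[[paste0(pre, "_scov")]])
  if (significantHit(hit, db, evalue_max, coverage_min)) "sig" else "insig"
}

#' Grade one protein's evidence record
#'
#' Decision tree (evaluated in order; "hit" means significant hit, "no hit"
#' means no hit at all):
#' \itemize{
#'   \item HC1: complete, UniMag hit with both subject and query coverage
#'     above the threshold.
#'   \item HC2: complete, no UniMag hit, UniPoa hit, no PTREP hit.
#'   \item REP: complete, no UniMag hit, PTREP hit (evaluated before the
#'     no-hit LC fallback: the repeat tag overrides completeness-based LC).
#'   \item LC1: incomplete, a UniMag or UniPoa hit, no PTREP hit.
#'   \item LC2: complete, no hit in any database.
#' }
#' Evidence shapes the rules leave silent (for instance a complete protein
#' whose only UniMag hit is below coverage) are `unclassified`, never
#' silently HC or LC.
#'
#' @param rec A list or one-row data.frame with `protein_id`, `complete`
#'   (logical), and per-database best-hit fields `um_evalue`, `um_qcov`,
#'   `um_scov`, `up_evalue`, `up_qcov`, `up_scov`, `pt_evalue`, `pt_qcov`,
#'   `pt_scov` (`NA` = no hit).
#' @param evalue_max,coverage_min Thresholds, see [significantHit()].
#' @return A list with `label` (`"HC"`, `"LC"`, `"REP"`, `"unclassified"`)
#'   and `rule_id` (which branch fired).
#' @export
gradeProtein <- function(rec, evalue_max = 1e-10, coverage_min = 95) {
  um <- .db_state(rec, "UniMag", evalue_max, coverage_min)
  up <- .db_state(rec, "UniPoa", evalue_max, coverage_min)
  pt <- .db_state(rec, "PTREP", evalue_max, coverage_min)
  complete <- isTRUE(as.logical(rec$complete))
  # the HC UniMag clause demands both coverages above threshold
  um_full <- um == "sig" && !is.na(rec$um_qcov) &&
    rec$um_qcov > coverage_min
  if (complete && um_full)
    return(list(label = "HC", rule_id = "HC1"))
  if (complete && um == "absent" && up == "sig" && pt == "absent")
    return(list(label = "HC", rule_id = "HC2"))
  if (complete && um == "absent" && pt == "sig")
    return(list(label = "REP", rule_id = "REP"))
  if (!complete && (um == "sig" || up == "sig") && pt == "absent")
    return(list(label = "LC", rule_id = "LC1"))
  if (complete && um == "absent" && up == "absent" && pt == "absent")
    return(list(label = "LC", rule_id = "LC2"))
  list(label = "unclassified", rule_id = "U0")
}

#' Grade a set of evidence records
#'
#' @param records data.frame, one row per protein (see [gradeProtein()]);
#'   an optional `seq_id` column groups the summary per sequence.
#' @param evalue_max,coverage_min Thresholds, see [significantHit()].
#' @return A list: `grades` (per-protein data.frame with `label`,
#'   `rule_id`), `summary` (counts of HC/LC/REP/unclassified per `seq_id`
#'   plus a `Total` row).
#' @export
gradeSet <- function(records, evalue_max = 1e-10, coverage_min = 95) {
  labs <- c("HC", "LC", "REP", "unclassified")
  if (is.null(records) || nrow(records) == 0L) {
    tot <- as.data.frame(as.list(setNames(rep(0L, 4L), labs)))
    tot <- cbind(data.frame(seq_id = "Total"), tot)
    return(list(
      grades = data.frame(protein_id = character(), label = character(),
                          rule_id = character()),
      summary = tot))
  }
  out <- lapply(seq_len(nrow(records)), function(i)
    gradeProtein(records[i, , drop = FALSE], evalue_max, coverage_min))
  grades <- data.frame(
    protein_id = records$protein_id,
    label = vapply(out, `[[`, "", "label"),
    rule_id = vapply(out, `[[`, "", "rule_id"))
  grp <- if ("seq_id" %in% names(records)) records$seq_id else
    rep("all", nrow(records))
  tab <- table(factor(grp), factor(grades$label, levels = labs))
  summ <- cbind(data.frame(seq_id = rownames(tab)),
                as.data.frame.matrix(tab))
  tot <- cbind(data.frame(seq_id = "Total"),
               as.data.frame(lapply(as.list(colSums(tab)), as.integer)))
  names(tot)[-1L] <- labs
  rownames(summ) <- NULL
  list(grades = grades, summary = rbind(summ, tot))
}

#' Build evidence records from BLAST tabular files
#'
#' Reads outfmt-6-style TSV with two extra columns (`qcovs`, `scovs`,
#' percent), keeps the best hit (lowest E-value, then highest bitscore) per
#' query per database, and joins with a completeness table.
#'
#' @param completeness data.frame with `protein_id`, `complete` (logical),
#'   optional `seq_id`.
#' @param blast Named list with elements `UniMag`, `UniPoa`, `PTREP`; each a
#'   file path or data.frame with columns `qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore qcovs scovs`.
#' @return A records data.frame for [gradeSet()].
#' @export
buildEvidenceRecords <- function(completeness, blast) {
  stopifnot(all(c("protein_id", "complete") %in% names(completeness)))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qcovs", "scovs")
  rec <- completeness
  for (db in .EV_DBS) {
    pre <- c(UniMag = "um", UniPoa = "up", PTREP = "pt")[[db]]
    rec[[paste0(pre, "_evalue")]] <- NA_real_
    rec[[paste0(pre, "_qcov")]] <- NA_real_
    rec[[paste0(pre, "_scov")]] <- NA_real_
    d <- blast[[db]]
    if (is.null(d)) next
    if (is.character(d))
      d <- read.delim(d, header = FALSE, col.names = cols)
    if (!nrow(d)) next
    d <- d[order(d$qseqid, d$evalue, -d$bitscore), , drop = FALSE]
    d <- d[!duplicated(d$qseqid), , drop = FALSE]
    m <- match(rec$protein_id, d$qseqid)
    rec[[paste0(pre, "_evalue")]] <- d$evalue[m]
    rec[[paste0(pre, "_qcov")]] <- d$qcovs[m]
    rec[[paste0(pre, "_scov")]] <- d$scovs[m]
  }
  rec
}

#' BUSCO-style completeness summary
#'
#' @param total Number of benchmark genes assessed.
#' @param complete_single,complete_dup,fragmented,missing Category counts;
#'   they must sum to `total`.
#' @return A list of percentages (one decimal): `coverage`
#'   (`100 * (total - missing) / total`), `complete_single`,
#'   `complete_dup`, `fragmented`, `missing`.
#' @examples
#' buscoSummary(1440, 1350, 24, 16, 50)$coverage  # 96.5
#' @export
buscoSummary <- function(total, complete_single, complete_dup, fragmented,
                         missing) {
  if (complete_single + complete_dup + fragmented + missing != total)
    .stopf("categories sum to %d, not total %d",
           complete_single + complete_dup + fragmented + missing, total)
  pct <- function(x) round(100 * x / total, 1)
  list(coverage = pct(total - missing),
       complete_single = pct(complete_single),
       complete_dup = pct(complete_dup),
       fragmented = pct(fragmented),
       missing = pct(missing))
}
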