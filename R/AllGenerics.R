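# Generics and accessors.

#' @describeIn Assembly-class the underlying DNAStringSet
#' @param x,object an object
#' @export
setGeneric("assemblySeqs", function(x) standardGeneric("assemblySeqs"))

#' @describeIn Assembly-class the gap registry as a GRanges
#' @export
setGeneric("gapRanges", function(x) standardGeneric("gapRanges"))

#' @describeIn LabelMap-class map name
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))

#' @describeIn LabelMap-class label positions (bp)
#' @export
setGeneric("mapLabels", function(x) standardGeneric("mapLabels"))

#' @describeIn LabelMap-class successive label spacings (bp)
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @describeIn EditLog-class the edit table
#' @export
setGeneric("editTable", function(x) standardGeneric("editTable"))

#' @describeIn EditLog-class the lift-over block table
#' @export
setGeneric("liftoverBlocks", function(x) standardGeneric("liftoverBlocks"))

#' @describeIn SyntheticTruth-class the truth genome
#' @export
setGeneric("truthGenome", function(x) standardGeneric("truthGenome"))

#' @export
#' @rdname Assembly-class
setMethod("assemblySeqs", "Assembly", function(x) x@seqs)

#' @export
#' @rdname Assembly-class
setMethod("gapRanges", "Assembly", function(x) x@gaps)

#' @export
#' @rdname Assembly-class
setMethod("length", "Assembly", function(x) length(x@seqs))

#' @export
#' @rdname Assembly-class
setMethod("names", "Assembly", function(x) names(x@seqs))

#' @export
#' @rdname LabelMap-class
setMethod("mapId", "LabelMap", function(x) x@map_id)

#' @export
#' @rdname LabelMap-class
setMethod("mapLabels", "LabelMap", function(x) x@labels)

#' @export
#' @rdname LabelMap-class
setMethod("length", "LabelMap", function(x) x@length)

#' @export
#' @rdname LabelMap-class
setMethod("fragments", "LabelMap", function(x) diff(x@labels))

#' @export
#' @rdname EditLog-class
setMethod("editTable", "EditLog", function(x) x@edits)

#' @export
#' @rdname EditLog-class
setMethod("liftoverBlocks", "EditLog", function(x) x@blocks)

#' @export
#' @rdname SyntheticTruth-class
setMethod("truthGenome", "SyntheticTruth", function(x) x@genome)

setMethod("show", "Assembly", function(object) {
  w <- Biostrings::width(object@seqs)
  cat("Assembly with", length(object@seqs), "sequence(s),",
      format(sum(as.numeric(w)), big.mark = ","), "bp total\n")
  tab <- table(factor(object@gaps$klass,
    levels = c("placeholder10", "placeholder100", "placeholder1000", "sized")))
  cat("  gaps:", length(object@gaps), "(",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap", object@map_id, ":", length(object@labels), "labels over",
      format(object@length, big.mark = ","), "bp\n")
})

setMethod("show", "MapAlignment", function(object) {
  cat("MapAlignment", object@query_id, "->", object@ref_id,
      paste0("(", object@orientation, ")"),
      nrow(object@pairs), "pairs, score", signif(object@score, 5),
      if (object@significant) "[significant]" else "[not significant]", "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@genome), "chromosome(s),",
      format(sum(as.numeric(Biostrings::width(object@genome))),
             big.mark = ","), "bp;",
      nrow(object@gap_truth), "gap(s),",
      nrow(object@planted_errors), "planted error(s)\n")
})

setMethod("show", "EditLog", function(object) {
  tab <- table(object@edits$kind)
  cat("EditLog with", nrow(object@edits), "edit(s)",
      if (nrow(object@edits))
        paste0("(", paste(names(tab), tab, sep = "=", collapse = ", "), ")"),
      "\n")
})
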