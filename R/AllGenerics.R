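#' @name spacerscope-accessors
#' @title Accessors for spacerscope classes
#' @description Small accessor generics: `typeLabels()` returns the CRISPR
#'   type labels known to an object; `observationTable()`,
#'   `clusterTable()`, `memberTable()`, `edgeTable()`, `fragmentTable()`
#'   and `fragmentPath()` return the underlying data.frames;
#'   `consensusString8()` returns the called PAM consensus of a
#'   [PamModel-class].
#' @param x an object of the documented class
#' @return see Description; data.frame accessors return copies, never
#'   references into the object.
NULL

#' @rdname spacerscope-accessors
#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("observationTable",
           function(x) standardGeneric("observationTable"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("memberTable", function(x) standardGeneric("memberTable"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @rdname spacerscope-accessors
#' @export
setGeneric("fragmentPath", function(x) standardGeneric("fragmentPath"))

setMethod("typeLabels", "RepeatSet", function(x) x@table$type_label)
setMethod("typeLabels", "SpacerObservations",
          function(x) unique(x@observations$type_label))
setMethod("typeLabels", "SpacerClusterSet",
          function(x) unique(x@clusters$type_label))

setMethod("observationTable", "SpacerObservations",
          function(x) x@observations)
setMethod("clusterTable", "SpacerClusterSet", function(x) x@clusters)
setMethod("memberTable", "SpacerClusterSet", function(x) x@members)
setMethod("edgeTable", "AdjacencyGraph", function(x) x@edges)
setMethod("fragmentTable", "ArrayFragmentSet", function(x) x@fragments)
setMethod("fragmentPath", "ArrayFragmentSet", function(x) x@path)

#' @rdname spacerscope-accessors
#' @export
repeatTable <- function(x) {
  stopifnot(is(x, "RepeatSet"))
  x@table
}

setMethod("show", "RepeatSet", function(object) {
  tb <- object@table
  cat("RepeatSet with", nrow(tb), "consensus repeat(s)\n")
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-6s %s (spacer %d +/- %d nt)\n", tb$type_label[i],
                tb$sequence[i], tb$expected_spacer_length[i],
                tb$length_tolerance[i]))
})

setMethod("show", "SpacerObservations", function(object) {
  ob <- object@observations
  cat("SpacerObservations:", nrow(ob), "spacer(s) from",
      length(unique(ob$source_id)), "source(s)\n")
  if (nrow(ob))
    cat("  types:", paste(sort(unique(ob$type_label)), collapse = ", "),
        "| samples:", paste(sort(unique(ob$sample_id)), collapse = ", "),
        "\n")
  if (nrow(object@flags))
    cat("  flagged sources:", nrow(object@flags), "\n")
})

setMethod("show", "GenomeArraySet", function(object) {
  cat("GenomeArraySet:", nrow(object@arrays), "array(s),",
      nrow(object@spacers), "spacer(s)\n")
})

setMethod("show", "SpacerClusterSet", function(object) {
  cl <- object@clusters
  cat("SpacerClusterSet:", nrow(cl), "cluster(s),",
      sum(cl$size), "reads total\n")
  if (nrow(cl))
    cat("  samples:", paste(sort(unique(cl$sample_id)), collapse = ", "),
        "| identity threshold:",
        object@params$identity %||% NA, "\n")
})

setMethod("show", "AdjacencyGraph", function(object) {
  cat("AdjacencyGraph:", nrow(object@edges), "edge(s),",
      nrow(object@triples), "triple(s), min support",
      object@params$min_support %||% NA, "\n")
})

setMethod("show", "ArrayFragmentSet", function(object) {
  fr <- object@fragments
  cat("ArrayFragmentSet:", nrow(fr), "fragment(s)")
  if (nrow(fr)) cat(", ", min(fr$n_spacers), "-", max(fr$n_spacers),
                    " spacers", sep = "")
  cat("\n")
})

setMethod("show", "PamModel", function(object) {
  cat("PamModel [", object@type_label, "]: ", object@n_flanks,
      " flank pair(s)\n", sep = "")
  cat("  5' (upstream, -8..-1):", object@consensus_up, "\n")
  cat("  3' (downstream, +1..+8):", object@consensus_down, "\n")
})

setMethod("show", "CommunityTruth", function(object) {
  cat("CommunityTruth:", length(object@sites), "site(s),",
      nrow(object@strains), "strain(s),",
      sum(vapply(object@arrays, length, integer(1))), "array(s)\n")
  if (length(object@phages))
    cat("  phages:", length(object@phages$genomes), "genome(s),",
        nrow(object@phages$plantings), "planted protospacer(s)\n")
  if (length(object@reads))
    cat("  reads simulated for", length(object@reads), "sample(s)\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
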