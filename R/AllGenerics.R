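#' Accessors for terminR data objects
#'
#' Small accessor generics: `refGenome()` returns the [GenomeRef-class] an
#' object refers to, `genomeLength()` its length, `libraryId()` /
#' `libraryIds()` library identifiers, `nLibraries()` the replicate count M,
#' `trackCounts()` the strand-specific count vector, and `rBar()` the averaged
#' readthrough statistic of a profile.
#'
#' @param x a terminR object.
#' @param strand `"+"` or `"-"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refGenome", function(x) standardGeneric("refGenome"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))
#' @rdname accessors
#' @export
setGeneric("nLibraries", function(x) standardGeneric("nLibraries"))
#' @rdname accessors
#' @export
setGeneric("trackCounts", function(x, strand) standardGeneric("trackCounts"))
#' @rdname accessors
#' @export
setGeneric("rBar", function(x, strand) standardGeneric("rBar"))

#' @rdname accessors
setMethod("refGenome", "GenomeRef", function(x) x)
#' @rdname accessors
setMethod("refGenome", "ReadStartTrack", function(x) x@genome)
#' @rdname accessors
setMethod("refGenome", "LibraryCollection", function(x) x@tracks[[1L]]@genome)
#' @rdname accessors
setMethod("refGenome", "ReadthroughProfile", function(x) x@genome)
#' @rdname accessors
setMethod("refGenome", "AnnotationDB", function(x) x@genome)

#' @rdname accessors
setMethod("genomeLength", "GenomeRef", function(x) x@length)
#' @rdname accessors
setMethod("genomeLength", "ANY", function(x) refGenome(x)@length)

#' @rdname accessors
setMethod("libraryId", "ReadStartTrack", function(x) x@libraryId)
#' @rdname accessors
setMethod("libraryIds", "LibraryCollection",
          function(x) vapply(x@tracks, libraryId, character(1)))
#' @rdname accessors
setMethod("libraryIds", "ReadthroughProfile", function(x) x@libraryIds)

#' @rdname accessors
setMethod("nLibraries", "LibraryCollection", function(x) length(x@tracks))
#' @rdname accessors
setMethod("nLibraries", "ReadthroughProfile", function(x) length(x@libraryIds))

#' @rdname accessors
setMethod("trackCounts", "ReadStartTrack", function(x, strand) {
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "+") x@countsPlus else x@countsMinus
})

#' @rdname accessors
setMethod("rBar", "ReadthroughProfile", function(x, strand) {
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "+") x@RBarPlus else x@RBarMinus
})
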