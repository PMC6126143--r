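#' @name dualTax-accessors
#' @title Accessors for dualTax S4 containers
#' @description Slot accessors for [ReferenceDB-class], [KmerIndex-class],
#'   [TaxAssignmentSet-class] and [SplitResult-class] objects.
#' @param x A dualTax S4 object.
NULL

#' @rdname dualTax-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname dualTax-accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname dualTax-accessors
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' @rdname dualTax-accessors
#' @export
setGeneric("sourceDb", function(x) standardGeneric("sourceDb"))

#' @rdname dualTax-accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname dualTax-accessors
#' @export
setGeneric("dbLabel", function(x) standardGeneric("dbLabel"))

#' @rdname dualTax-accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname dualTax-accessors
#' @export
setGeneric("leafPaths", function(x) standardGeneric("leafPaths"))

#' @rdname dualTax-accessors
#' @export
setGeneric("ecoIds", function(x) standardGeneric("ecoIds"))

#' @rdname dualTax-accessors
#' @export
setGeneric("compIds", function(x) standardGeneric("compIds"))

#' @rdname dualTax-accessors
#' @export
setGeneric("identityCutoff", function(x) standardGeneric("identityCutoff"))

#' @rdname dualTax-accessors
#' @export
setGeneric("bestIdentities", function(x) standardGeneric("bestIdentities"))
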