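# Accessors, show methods, subsetting and coercion for the S4 containers.

#' @rdname dualTax-accessors
setMethod("refSequences", "ReferenceDB", function(x) x@sequences)

#' @rdname dualTax-accessors
setMethod("taxonomy", "ReferenceDB", function(x) x@taxonomy)

#' @rdname dualTax-accessors
setMethod("dbLabel", "ReferenceDB", function(x) x@label)

#' @rdname dualTax-accessors
setMethod("dbLabel", "KmerIndex", function(x) x@label)

#' @rdname dualTax-accessors
setMethod("kmerSize", "KmerIndex", function(x) x@k)

#' @rdname dualTax-accessors
setMethod("leafPaths", "KmerIndex", function(x) x@leafPaths)

#' @rdname dualTax-accessors
setMethod("otuIds", "TaxAssignmentSet", function(x) x@ids)

#' @rdname dualTax-accessors
setMethod("taxonomy", "TaxAssignmentSet", function(x) x@ranks)

#' @rdname dualTax-accessors
setMethod("confidences", "TaxAssignmentSet", function(x) x@confidence)

#' @rdname dualTax-accessors
setMethod("sourceDb", "TaxAssignmentSet", function(x) x@source)

#' @rdname dualTax-accessors
setMethod("ecoIds", "SplitResult", function(x) x@ecoIds)

#' @rdname dualTax-accessors
setMethod("compIds", "SplitResult", function(x) x@compIds)

#' @rdname dualTax-accessors
setMethod("identityCutoff", "SplitResult", function(x) x@cutoff)

#' @rdname dualTax-accessors
setMethod("bestIdentities", "SplitResult", function(x) x@identities)

#' @describeIn TaxAssignmentSet Number of OTUs.
#' @param x A `TaxAssignmentSet`.
#' @export
setMethod("length", "TaxAssignmentSet", function(x) length(x@ids))

#' @describeIn TaxAssignmentSet Subset by index, logical or OTU id.
#' @param i Index vector (integer, logical or character OTU ids).
#' @param j,... Ignored.
#' @param drop Ignored.
#' @export
setMethod("[", "TaxAssignmentSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    i <- match(i, x@ids)
    if (anyNA(i)) stop("unknown OTU id(s) in subset")
  }
  new("TaxAssignmentSet", ids = x@ids[i],
      ranks = x@ranks[i, , drop = FALSE],
      confidence = x@confidence[i, , drop = FALSE],
      source = x@source[i])
})

#' @describeIn TaxAssignmentSet Coerce to a data.frame (`otu_id`, one column
#'   per rank, `conf_*` columns and `source`).
#' @export
setMethod("as.data.frame", "TaxAssignmentSet", function(x, ...) {
  rk <- x@ranks; cf <- x@confidence
  rownames(rk) <- rownames(cf) <- NULL
  df <- data.frame(otu_id = x@ids, rk, stringsAsFactors = FALSE)
  conf <- as.data.frame(cf)
  names(conf) <- paste0("conf_", .RANKS)
  cbind(df, conf, source = x@source)
})

setMethod("show", "ReferenceDB", function(object) {
  cat("ReferenceDB <", object@label, "> with ", length(object@sequences),
      " reference sequences\n", sep = "")
  named <- colSums(object@taxonomy != .UNCL)
  cat("  named per rank: ",
      paste(paste0(.RANKS, "=", named), collapse = " "), "\n", sep = "")
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex <", object@label, ">: k=", object@k, ", ",
      nrow(object@leafPaths), " leaves over ",
      sum(object@leafSizes), " references\n", sep = "")
})

setMethod("show", "TaxAssignmentSet", function(object) {
  cat("TaxAssignmentSet with", length(object@ids), "assignments\n")
  if (length(object@ids)) {
    src <- table(factor(object@source, c("ecosystem", "comprehensive")),
                 useNA = "ifany")
    cat("  source:", paste(names(src), unname(src), collapse = ", "), "\n")
    named <- colSums(object@ranks != .UNCL)
    cat("  named per rank:",
        paste(paste0(.RANKS, "=", named), collapse = " "), "\n")
  }
})

setMethod("show", "SplitResult", function(object) {
  cat("SplitResult at cutoff ", object@cutoff, ": ",
      length(object@ecoIds), " ecosystem / ",
      length(object@compIds), " comprehensive (",
      sum(!c(object@ecoIds, object@compIds) %in% names(object@identities)),
      " without hits)\n", sep = "")
})
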