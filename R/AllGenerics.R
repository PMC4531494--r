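#' @include utils.R
NULL

#' Accessor generics
#'
#' Small family of accessor generics used across the package's S4
#' classes. Each has methods documented on the relevant class page.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x, ...) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("functionality", function(x, ...) standardGeneric("functionality"))

#' @rdname accessors
#' @export
setGeneric("clonotypes", function(x, ...) standardGeneric("clonotypes"))

#' @rdname accessors
#' @export
setGeneric("definition", function(x, ...) standardGeneric("definition"))

#' @rdname accessors
#' @export
setGeneric("nRecordsUsed", function(x, ...) standardGeneric("nRecordsUsed"))

#' @rdname accessors
#' @export
setGeneric("divCalc", function(x, ...) standardGeneric("divCalc"))

#' @rdname accessors
#' @export
setGeneric("nGrid", function(x, ...) standardGeneric("nGrid"))

#' @rdname accessors
#' @export
setGeneric("fittedParams", function(x, ...) standardGeneric("fittedParams"))

#' @rdname accessors
#' @export
setGeneric("esTrace", function(x, ...) standardGeneric("esTrace"))

#' @rdname accessors
#' @export
setGeneric("primers", function(x, ...) standardGeneric("primers"))

#' @rdname accessors
#' @export
setGeneric("cells", function(x, ...) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("matrixTotal", function(x, ...) standardGeneric("matrixTotal"))

#' @rdname accessors
#' @export
setGeneric("referenceVersion", function(x, ...) standardGeneric("referenceVersion"))
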