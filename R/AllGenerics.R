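#' @rdname NumtSet-accessors
#' @export
setGeneric("numtIds", function(x) standardGeneric("numtIds"))

#' @rdname NumtSet-accessors
#' @export
setGeneric("numtIdentity", function(x) standardGeneric("numtIdentity"))

#' @rdname NumtSet-accessors
#' @export
setGeneric("mtFootprint", function(x) standardGeneric("mtFootprint"))

#' @rdname NumtSet-accessors
#' @export
setGeneric("speciesCode", function(x) standardGeneric("speciesCode"))

#' @rdname NumtSet-accessors
#' @export
setGeneric("mtLength", function(x) standardGeneric("mtLength"))

#' @rdname NumtBlockSet-accessors
#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @rdname NumtBlockSet-accessors
#' @export
setGeneric("blockMembers", function(x) standardGeneric("blockMembers"))

#' @rdname NumtBlockSet-accessors
#' @export
setGeneric("isComplex", function(x) standardGeneric("isComplex"))
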