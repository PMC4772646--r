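## Generics for the entity getter surface and release operations.
## Documentation lives with the ChebiEntity methods in entity.R.

#' @export
setGeneric("getId", function(x) standardGeneric("getId"))
#' @export
setGeneric("getParentId", function(x) standardGeneric("getParentId"))
#' @export
setGeneric("getName", function(x) standardGeneric("getName"))
#' @export
setGeneric("getDefinition", function(x) standardGeneric("getDefinition"))
#' @export
setGeneric("getStatus", function(x) standardGeneric("getStatus"))
#' @export
setGeneric("getSource", function(x) standardGeneric("getSource"))
#' @export
setGeneric("getCreatedBy", function(x) standardGeneric("getCreatedBy"))
#' @export
setGeneric("getModifiedOn", function(x) standardGeneric("getModifiedOn"))
#' @export
setGeneric("getStar", function(x) standardGeneric("getStar"))
#' @export
setGeneric("getNames", function(x) standardGeneric("getNames"))
#' @export
setGeneric("getFormula", function(x) standardGeneric("getFormula"))
#' @export
setGeneric("getFormulae", function(x) standardGeneric("getFormulae"))
#' @export
setGeneric("getMass", function(x) standardGeneric("getMass"))
#' @export
setGeneric("getCharge", function(x) standardGeneric("getCharge"))
#' @export
setGeneric("getMonoisotopicMass",
           function(x) standardGeneric("getMonoisotopicMass"))
#' @export
setGeneric("getDatabaseAccessions",
           function(x) standardGeneric("getDatabaseAccessions"))
#' @export
setGeneric("getComments", function(x) standardGeneric("getComments"))
#' @export
setGeneric("getCompoundOrigins",
           function(x) standardGeneric("getCompoundOrigins"))
#' @export
setGeneric("getInchi", function(x) standardGeneric("getInchi"))
#' @export
setGeneric("getInchiKey", function(x) standardGeneric("getInchiKey"))
#' @export
setGeneric("getSmiles", function(x) standardGeneric("getSmiles"))
#' @export
setGeneric("getMol", function(x) standardGeneric("getMol"))
#' @export
setGeneric("getMolFilename", function(x) standardGeneric("getMolFilename"))
#' @export
setGeneric("getOutgoings", function(x) standardGeneric("getOutgoings"))
#' @export
setGeneric("getIncomings", function(x) standardGeneric("getIncomings"))
#' @export
setGeneric("getReferences", function(x) standardGeneric("getReferences"))

#' @export
setGeneric("resolvePrimary",
           function(x, id) standardGeneric("resolvePrimary"))
#' @export
setGeneric("groupMembers", function(x, id) standardGeneric("groupMembers"))
#' @export
setGeneric("isStale",
           function(record, now, maxAge) standardGeneric("isStale"))
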