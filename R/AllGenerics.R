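#' @rdname dosages
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname trueEffects
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))

#' @rdname trueEffects
#' @export
setGeneric("trueEffectsTable", function(x) standardGeneric("trueEffectsTable"))

#' @rdname phenotypes
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname caseCohort
#' @export
setGeneric("caseCohort", function(x) standardGeneric("caseCohort"))

#' @rdname cohort-counts
#' @export
setGeneric("nCases", function(x) standardGeneric("nCases"))

#' @rdname cohort-counts
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname cohort-counts
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))

#' @rdname simConfig
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname fitSlopeMixture
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @rdname fitSlopeMixture
#' @export
setGeneric("mixingProportions", function(x) standardGeneric("mixingProportions"))

#' @rdname fitSlopeMixture
#' @export
setGeneric("posteriorMembership", function(x) standardGeneric("posteriorMembership"))

#' @rdname fitNullSurvival
#' @export
setGeneric("cumulativeHazard", function(x, ...) standardGeneric("cumulativeHazard"))
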