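#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors SimpleList DataFrame
#' @importFrom stats approx lowess median p.adjust phyper pnorm prcomp
#'   rmultinom rnorm runif setNames var dist hclust
#' @importFrom utils read.delim
NULL

#' @rdname bootstraps
#' @export
setGeneric("bootstraps", function(x, ...) standardGeneric("bootstraps"))

#' @rdname bootstraps
#' @export
setGeneric("bootstraps<-",
           function(x, value) standardGeneric("bootstraps<-"))

#' @rdname sampleSheet
#' @export
setGeneric("sampleSheet", function(x, ...) standardGeneric("sampleSheet"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("condMeans", function(x) standardGeneric("condMeans"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("condSE", function(x) standardGeneric("condSE"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("techVar", function(x) standardGeneric("techVar"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("bioVar", function(x) standardGeneric("bioVar"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("bioVarRaw", function(x) standardGeneric("bioVarRaw"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname ConditionModel-accessors
#' @export
setGeneric("conditionInfo", function(x) standardGeneric("conditionInfo"))
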