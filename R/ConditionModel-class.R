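#' ConditionModel: per-gene, per-condition normal expression models
#'
#' For every gene and condition the model holds the log2-scale mean `m`,
#' a technical variance `v_tech` (variance of a single observation, from
#' bootstrap resamples of the quantification), a raw and a shrunken
#' biological variance (`v_bio_raw`, `v_bio`), the replicate count `n`,
#' and the standard error of the condition mean,
#' `se = sqrt((v_tech + v_bio) / n)`. Gene expression under a condition
#' is modeled as Normal(m, v_tech + v_bio) on the log2 scale, so the
#' condition mean is Normal(m, se^2).
#'
#' @slot means,techVar,bioVarRaw,bioVar,se Numeric genes x conditions
#'   matrices. `bioVarRaw` is `NA` where a condition has a single
#'   replicate.
#' @slot nrep Integer vector of replicate counts per condition.
#' @slot conditions data.frame with `tissue`, `timepoint`, `label` per
#'   condition (column order of the matrices).
#' @slot sizeFactors Numeric per-sample size factors used upstream.
#' @slot offset The pseudo-count used in the log2 transform.
#'
#' @aliases ConditionModel-class
#' @export
.ConditionModel <- setClass(
    "ConditionModel",
    slots = c(means = "matrix", techVar = "matrix", bioVarRaw = "matrix",
              bioVar = "matrix", se = "matrix", nrep = "integer",
              conditions = "data.frame", sizeFactors = "numeric",
              offset = "numeric")
)

setValidity("ConditionModel", function(object) {
    dims <- dim(object@means)
    for (nm in c("techVar", "bioVarRaw", "bioVar", "se")) {
        if (!identical(dim(slot(object, nm)), dims))
            return(paste(nm, "dimensions differ from means"))
    }
    if (nrow(object@conditions) != dims[2L] ||
        length(object@nrep) != dims[2L])
        return("condition metadata length mismatch")
    if (any(!is.finite(object@means)))
        return("means must be finite")
    if (any(object@techVar < 0) || any(object@bioVar < 0))
        return("variances must be non-negative")
    if (any(!is.finite(object@se)) || any(object@se < 0))
        return("se must be finite and non-negative")
    if (any(object@nrep < 1L))
        return("each condition needs n >= 1 replicates")
    TRUE
})

#' Accessors for ConditionModel
#'
#' @param x A [ConditionModel-class] object.
#' @return `condMeans`, `condSE`, `techVar`, `bioVar` and `bioVarRaw`
#'   return genes x conditions matrices; `nReplicates` the per-condition
#'   replicate counts; `conditionInfo` the condition metadata data.frame.
#' @name ConditionModel-accessors
NULL

#' @rdname ConditionModel-accessors
#' @export
setMethod("condMeans", "ConditionModel", function(x) x@means)

#' @rdname ConditionModel-accessors
#' @export
setMethod("condSE", "ConditionModel", function(x) x@se)

#' @rdname ConditionModel-accessors
#' @export
setMethod("techVar", "ConditionModel", function(x) x@techVar)

#' @rdname ConditionModel-accessors
#' @export
setMethod("bioVar", "ConditionModel", function(x) x@bioVar)

#' @rdname ConditionModel-accessors
#' @export
setMethod("bioVarRaw", "ConditionModel", function(x) x@bioVarRaw)

#' @rdname ConditionModel-accessors
#' @export
setMethod("nReplicates", "ConditionModel", function(x)
    setNames(x@nrep, x@conditions$label))

#' @rdname ConditionModel-accessors
#' @export
setMethod("conditionInfo", "ConditionModel", function(x) x@conditions)

#' @describeIn ConditionModel-class Compact display.
#' @param object A `ConditionModel`.
#' @export
setMethod("show", "ConditionModel", function(object) {
    cat(sprintf("ConditionModel: %d genes x %d conditions\n",
                nrow(object@means), ncol(object@means)))
    cat("conditions:", paste(object@conditions$label, collapse = " "),
        "\n")
    cat(sprintf("log2 offset: %g; replicates: %s\n", object@offset,
                paste(object@nrep, collapse = "/")))
})

#' Per-condition summary of one gene for profile plots
#'
#' Returns, for each condition, the model mean and an interval reaching
#' two standard errors either side of it (approximately a 95% confidence
#' interval for the condition mean).
#'
#' @param model A [ConditionModel-class].
#' @param gene A gene id present in the model.
#' @return data.frame with columns `condition`, `tissue`, `timepoint`,
#'   `mean`, `lower`, `upper` (`lower = mean - 2 se`,
#'   `upper = mean + 2 se`).
#' @examples
#' mdl <- exampleModel()
#' conditionSummary(mdl, rownames(condMeans(mdl))[1])
#' @export
conditionSummary <- function(model, gene) {
    stopifnot(is(model, "ConditionModel"))
    i <- match(gene, rownames(model@means))
    if (is.na(i))
        stop("unknown gene id: ", gene)
    m <- model@means[i, ]
    s <- model@se[i, ]
    data.frame(condition = model@conditions$label,
               tissue = model@conditions$tissue,
               timepoint = model@conditions$timepoint,
               mean = unname(m), lower = unname(m - 2 * s),
               upper = unname(m + 2 * s), stringsAsFactors = FALSE)
}
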