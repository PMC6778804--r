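#' SkinExperiment: counts, sample metadata and bootstrap tensors
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' genes x samples expected-count matrix (assay `"counts"`), the sample
#' sheet as `colData` (columns `tissue`, `timepoint`, `replicate`), and
#' optionally one genes x B bootstrap count matrix per sample in the
#' `bootstraps` slot. Bootstrap matrices come from probabilistic
#' quantification (Gibbs resamples of the count estimates) and drive the
#' technical-variance component of the condition model.
#'
#' Validity enforces the sorted-cell design: (tissue, timepoint) must be
#' one of the 12 valid conditions (see [validConditions()]), the
#' (tissue, timepoint, replicate) triple is unique, every bootstrap matrix
#' matches the gene dimension and shares a common bootstrap count B, and
#' bootstrap names are a subset of the sample names.
#'
#' @slot bootstraps A [S4Vectors::SimpleList] of per-sample genes x B
#'   matrices (possibly empty).
#'
#' @aliases SkinExperiment-class
#' @export
.SkinExperiment <- setClass(
    "SkinExperiment",
    contains = "SummarizedExperiment",
    slots = c(bootstraps = "SimpleList")
)

setValidity("SkinExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("tissue", "timepoint", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):",
                     paste(miss, collapse = ", ")))
    sheet <- data.frame(sample_id = colnames(object),
                        tissue = cd$tissue, timepoint = cd$timepoint,
                        replicate = cd$replicate,
                        stringsAsFactors = FALSE)
    ok <- tryCatch({ .checkSampleSheet(sheet); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
        return("counts must be finite and non-negative")
    bt <- object@bootstraps
    if (length(bt)) {
        if (is.null(names(bt)) ||
            !all(names(bt) %in% colnames(object)))
            return("bootstrap names must be sample names")
        nr <- vapply(bt, nrow, 0L)
        if (any(nr != nrow(object)))
            return("bootstrap gene dimension does not match counts")
        nb <- vapply(bt, ncol, 0L)
        if (length(unique(nb)) != 1L)
            return("all samples must share the same bootstrap count B")
        if (nb[1L] < 2L)
            return("need at least B = 2 bootstraps")
    }
    TRUE
})

#' Construct a SkinExperiment
#'
#' @param counts Numeric genes x samples matrix of expected counts, with
#'   gene ids as rownames and sample ids as colnames.
#' @param sampleSheet data.frame with columns `sample_id`, `tissue`,
#'   `timepoint`, `replicate`; rows are matched to `colnames(counts)`.
#' @param bootstraps Optional named list of per-sample genes x B matrices.
#'
#' @return A `SkinExperiment`.
#' @examples
#' sim <- simulateCounts(generateTruth(simConfig(n_genes = 50)),
#'                       simConfig(n_genes = 50))
#' sim
#' @export
SkinExperiment <- function(counts, sampleSheet, bootstraps = list()) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts needs rownames (genes) and colnames (samples)")
    .checkSampleSheet(sampleSheet)
    missing <- setdiff(colnames(counts), sampleSheet$sample_id)
    if (length(missing))
        stop("sample present in counts but absent from sample sheet: ",
             missing[1L])
    sheet <- sampleSheet[match(colnames(counts), sampleSheet$sample_id), ,
                         drop = FALSE]
    cd <- S4Vectors::DataFrame(tissue = sheet$tissue,
                               timepoint = sheet$timepoint,
                               replicate = as.integer(sheet$replicate),
                               row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    .SkinExperiment(se, bootstraps = S4Vectors::SimpleList(bootstraps))
}

#' Bootstrap count tensors of a SkinExperiment
#'
#' @param x A `SkinExperiment`.
#' @param value A named list of per-sample genes x B matrices.
#' @param ... Ignored.
#' @return `bootstraps` returns the `SimpleList` of per-sample matrices.
#' @export
setMethod("bootstraps", "SkinExperiment", function(x, ...) x@bootstraps)

#' @rdname bootstraps
#' @export
setReplaceMethod("bootstraps", "SkinExperiment", function(x, value) {
    x@bootstraps <- S4Vectors::SimpleList(as.list(value))
    validObject(x)
    x
})

#' Sample sheet of a SkinExperiment
#'
#' @param x A `SkinExperiment`.
#' @param ... Ignored.
#' @return data.frame with columns `sample_id`, `tissue`, `timepoint`,
#'   `replicate` (one row per sample, in column order).
#' @export
setMethod("sampleSheet", "SkinExperiment", function(x, ...) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(sample_id = colnames(x), tissue = cd$tissue,
               timepoint = cd$timepoint,
               replicate = as.integer(cd$replicate),
               stringsAsFactors = FALSE)
})

#' @describeIn SkinExperiment-class Compact display.
#' @param object A `SkinExperiment`.
#' @export
setMethod("show", "SkinExperiment", function(object) {
    callNextMethod()
    nb <- length(object@bootstraps)
    if (nb) {
        cat(sprintf("bootstraps: %d samples x B = %d\n", nb,
                    ncol(object@bootstraps[[1L]])))
    } else {
        cat("bootstraps: none\n")
    }
})
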