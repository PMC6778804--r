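# Internal constants and validators for the 12-condition sorted-cell design.

.TISSUES <- c("all_skin", "nonskin1", "periderm", "basal", "nonskin2")
.TIMEPOINTS <- c("20SS", "52hpf", "72hpf")
.LATER_TISSUES <- c("periderm", "basal", "nonskin2")

#' Valid experimental conditions
#'
#' The sorted-cell design defines 12 (tissue, timepoint) conditions:
#' `all_skin` and `nonskin1` at all three timepoints (20-somite stage,
#' 52 hpf, 72 hpf), and `periderm`, `basal` and `nonskin2` at 52 and 72 hpf
#' only (the two skin layers are not separable by sorting at 20 SS).
#'
#' @return A data.frame with columns `tissue`, `timepoint` and `label`
#'   (tissue and timepoint joined by a dot), one row per valid condition.
#' @examples
#' validConditions()
#' @export
validConditions <- function() {
    tis <- c(rep(c("all_skin", "nonskin1"), each = 3L),
             rep(c("periderm", "basal", "nonskin2"), each = 2L))
    tp <- c(rep(.TIMEPOINTS, 2L), rep(c("52hpf", "72hpf"), 3L))
    data.frame(tissue = tis, timepoint = tp,
               label = paste(tis, tp, sep = "."),
               stringsAsFactors = FALSE)
}

.conditionLabel <- function(tissue, timepoint) {
    paste(tissue, timepoint, sep = ".")
}

.checkSampleSheet <- function(sheet) {
    need <- c("sample_id", "tissue", "timepoint", "replicate")
    miss <- setdiff(need, colnames(sheet))
    if (length(miss))
        stop("sample sheet is missing column(s): ",
             paste(miss, collapse = ", "))
    bad <- !sheet$tissue %in% .TISSUES
    if (any(bad))
        stop("unknown tissue: ", sheet$tissue[which(bad)[1L]])
    bad <- !sheet$timepoint %in% .TIMEPOINTS
    if (any(bad))
        stop("unknown timepoint: ", sheet$timepoint[which(bad)[1L]])
    lab <- .conditionLabel(sheet$tissue, sheet$timepoint)
    bad <- !lab %in% validConditions()$label
    if (any(bad))
        stop("invalid condition (layer-sorted tissues do not exist at ",
             "20SS): ", lab[which(bad)[1L]])
    rep <- sheet$replicate
    if (any(is.na(rep)) || any(rep < 1) || any(rep != round(rep)))
        stop("replicate indices must be positive integers")
    key <- paste(lab, rep, sep = "#")
    if (anyDuplicated(key))
        stop("duplicated (tissue, timepoint, replicate): ",
             key[which(duplicated(key))[1L]])
    invisible(sheet)
}

# Per-timepoint category alphabets: S/N at 20SS; N/G/B/P at 52 and 72 hpf.
.CATS_20SS <- c("S", "N")
.CATS_LATER <- c("N", "G", "B", "P")

#' All possible gene-expression flows
#'
#' A flow concatenates a gene's category at 20 SS (`S` or `N`) with its
#' categories at 52 and 72 hpf (`N`, `G`, `B` or `P`), giving
#' 2 x 4 x 4 = 32 possible three-character labels.
#'
#' @return Character vector of the 32 flow labels.
#' @examples
#' length(allFlows())
#' @export
allFlows <- function() {
    g <- expand.grid(t72 = .CATS_LATER, t52 = .CATS_LATER,
                     t20 = .CATS_20SS, stringsAsFactors = FALSE)
    sort(paste0(g$t20, g$t52, g$t72))
}

.checkFlowLabel <- function(flow) {
    ok <- is.character(flow) & nchar(flow) == 3L &
        substr(flow, 1L, 1L) %in% .CATS_20SS &
        substr(flow, 2L, 2L) %in% .CATS_LATER &
        substr(flow, 3L, 3L) %in% .CATS_LATER
    if (!all(ok))
        stop("invalid flow label: ", flow[which(!ok)[1L]])
    invisible(flow)
}
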