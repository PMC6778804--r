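# Readers and writers: counts (.tsv), sample sheets (.tsv), bootstrap
# tensors (.h5, one 2-D dataset per sample), gene-set tables (.tsv),
# category/flow tables (.tsv), generator configs (.yaml). Readers validate
# before constructing; no partially-valid object escapes.

.writeNumericTable <- function(mat, path, idcol) {
    # %.17g round-trips doubles exactly through decimal text
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c(idcol, colnames(mat)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(mat)), function(i)
        paste(c(rownames(mat)[i],
                formatC(mat[i, ], format = "g", digits = 17)),
              collapse = "\t"), "")
    writeLines(body, con)
}

#' Read and write expected-count matrices
#'
#' Tab-separated text: first column gene id, header row of sample ids.
#' `readCounts` validates uniqueness of gene ids, numeric cells and
#' non-negativity; `writeCounts` emits full double precision so
#' write-then-read reproduces values exactly. When `tx2gene` is given
#' the input rows are transcript-level and are summed to gene level
#' (genes handled as arithmetic sums of their transcript isoforms).
#'
#' @param path File path.
#' @param tx2gene Optional data.frame with columns `transcript`, `gene`
#'   mapping input row ids to gene ids.
#' @param mat Genes x samples numeric matrix with dimnames.
#' @return `readCounts`: the validated matrix. `writeCounts`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeCounts(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
#'                                            c("s1", "s2"))), f)
#' readCounts(f)
#' @export
readCounts <- function(path, tx2gene = NULL) {
    df <- read.delim(path, check.names = FALSE,
                     colClasses = "character")
    ids <- df[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated gene id: ", dup[1L])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat),
                                   dimnames = list(ids, colnames(mat))))
    bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at row %d (gene %s), column %s",
                     mat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                     ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
    if (anyNA(num) || any(num < 0))
        stop("counts must be present and non-negative")
    if (!is.null(tx2gene)) {
        stopifnot(all(c("transcript", "gene") %in% colnames(tx2gene)))
        g <- tx2gene$gene[match(ids, tx2gene$transcript)]
        if (anyNA(g))
            stop("transcript without gene mapping: ",
                 ids[which(is.na(g))[1L]])
        num <- rowsum(num, group = g)
    }
    num
}

#' @rdname readCounts
#' @export
writeCounts <- function(mat, path) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)),
              !is.null(colnames(mat)))
    .writeNumericTable(mat, path, "gene_id")
    invisible(path)
}

#' Read and write sample sheets
#'
#' Tab-separated with columns `sample_id`, `tissue`, `timepoint`,
#' `replicate`. Validation enforces the 12 valid (tissue, timepoint)
#' conditions (layer-sorted tissues never at 20 SS) and uniqueness of
#' (tissue, timepoint, replicate).
#'
#' @param path File path.
#' @param sheet A sample-sheet data.frame.
#' @return `readSampleSheet`: the validated data.frame.
#'   `writeSampleSheet`: `path`, invisibly.
#' @examples
#' cfg <- simConfig(n_genes = 5, n_bootstraps = 2, seed = 1)
#' sheet <- sampleSheet(simulateCounts(generateTruth(cfg), cfg))
#' f <- tempfile(fileext = ".tsv")
#' writeSampleSheet(sheet, f)
#' nrow(readSampleSheet(f))
#' @export
readSampleSheet <- function(path) {
    df <- read.delim(path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$replicate <- as.integer(df$replicate)
    .checkSampleSheet(df)
    df
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
    .checkSampleSheet(sheet)
    utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and write bootstrap tensors (HDF5)
#'
#' One 2-D dataset per sample id, each genes x B, with row order equal
#' to the gene order of the count matrix. Validation: every sample in
#' the container must appear in `sampleIds` (when given), all samples
#' share one B, and the gene dimension matches `geneIds` (when given).
#'
#' @param path HDF5 file path.
#' @param geneIds Optional gene ids to enforce/attach as rownames.
#' @param sampleIds Optional allowed sample ids.
#' @param boots Named list of per-sample genes x B matrices.
#' @return `readBootstraps`: named list of matrices.
#'   `writeBootstraps`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".h5")
#' writeBootstraps(list(s1 = matrix(1:6, 2)), f)
#' readBootstraps(f)
#' @export
readBootstraps <- function(path, geneIds = NULL, sampleIds = NULL) {
    info <- rhdf5::h5ls(path)
    dsets <- info$name[info$group == "/" & info$otype == "H5I_DATASET"]
    if (!length(dsets))
        stop("no datasets found in ", path)
    if (!is.null(sampleIds)) {
        extra <- setdiff(dsets, sampleIds)
        if (length(extra))
            stop("bootstrap sample not in sample sheet: ", extra[1L])
    }
    out <- lapply(dsets, function(s) {
        m <- rhdf5::h5read(path, s)
        storage.mode(m) <- "double"
        m
    })
    names(out) <- dsets
    nb <- vapply(out, ncol, 0L)
    if (length(unique(nb)) != 1L)
        stop("bootstrap count B differs across samples (",
             paste(unique(nb), collapse = " vs "), ")")
    if (!is.null(geneIds)) {
        ng <- vapply(out, nrow, 0L)
        if (any(ng != length(geneIds)))
            stop("bootstrap gene count (", ng[which(ng !=
                 length(geneIds))[1L]], ") does not match counts (",
                 length(geneIds), ")")
        out <- lapply(out, function(m) { rownames(m) <- geneIds; m })
    }
    out
}

#' @rdname readBootstraps
#' @export
writeBootstraps <- function(boots, path) {
    stopifnot(is.list(boots), !is.null(names(boots)))
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    for (s in names(boots))
        rhdf5::h5write(unname(as.matrix(boots[[s]])), path, s)
    rhdf5::h5closeAll()
    invisible(path)
}

#' Load a full dataset from disk
#'
#' Reads counts, sample sheet and (optionally) bootstraps, checks
#' referential integrity and assembles a [SkinExperiment-class].
#'
#' @param countsPath Counts .tsv.
#' @param sheetPath Sample-sheet .tsv.
#' @param bootstrapsPath Optional bootstrap .h5.
#' @return A [SkinExperiment-class].
#' @examples
#' cfg <- simConfig(n_genes = 5, n_bootstraps = 3, seed = 1)
#' sim <- simulateCounts(generateTruth(cfg), cfg)
#' d <- tempfile(); dir.create(d)
#' writeCounts(SummarizedExperiment::assay(sim, "counts"),
#'             file.path(d, "counts.tsv"))
#' writeSampleSheet(sampleSheet(sim), file.path(d, "samples.tsv"))
#' writeBootstraps(as.list(bootstraps(sim)), file.path(d, "boots.h5"))
#' readSkinExperiment(file.path(d, "counts.tsv"),
#'                    file.path(d, "samples.tsv"),
#'                    file.path(d, "boots.h5"))
#' @export
readSkinExperiment <- function(countsPath, sheetPath,
                               bootstrapsPath = NULL) {
    counts <- readCounts(countsPath)
    sheet <- readSampleSheet(sheetPath)
    boots <- list()
    if (!is.null(bootstrapsPath))
        boots <- readBootstraps(bootstrapsPath,
                                geneIds = rownames(counts),
                                sampleIds = sheet$sample_id)
    SkinExperiment(counts, sheet, bootstraps = boots)
}

#' Read gene-set membership tables
#'
#' Two tab-separated columns, `term` and `gene`, one row per membership;
#' an optional sidecar maps term ids to names/namespaces (columns
#' `term`, `name`, and optionally `namespace`). If a `universe` is
#' supplied, members outside it are an error. Whether annotations were
#' propagated to ancestor terms upstream is not inferable from the flat
#' table; record it via `propagated` (stored as an attribute).
#'
#' @param path Membership .tsv.
#' @param namesPath Optional sidecar .tsv.
#' @param universe Optional gene universe to validate against.
#' @param propagated Logical flag stored as attribute `propagated`.
#' @return Named list (term id -> character vector of member genes) with
#'   attributes `termInfo` (data.frame or NULL) and `propagated`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("term\tgene", "T1\tg1", "T1\tg2", "T2\tg2"), f)
#' readGeneSets(f)
#' @export
readGeneSets <- function(path, namesPath = NULL, universe = NULL,
                         propagated = NA) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("term", "gene") %in% colnames(df)))
    if (!is.null(universe)) {
        bad <- setdiff(df$gene, universe)
        if (length(bad))
            stop("gene-set member outside universe: ", bad[1L])
    }
    sets <- split(df$gene, df$term)
    sets <- lapply(sets, unique)
    info <- NULL
    if (!is.null(namesPath)) {
        info <- read.delim(namesPath, stringsAsFactors = FALSE)
        stopifnot(all(c("term", "name") %in% colnames(info)))
    }
    attr(sets, "termInfo") <- info
    attr(sets, "propagated") <- propagated
    sets
}

#' Read and write category/flow tables
#'
#' One row per gene with columns `gene`, `cat20SS`, `cat52hpf`,
#' `cat72hpf`, `flow`; the flow must equal the concatenated categories.
#'
#' @param calls data.frame from [classifyFlows()].
#' @param path File path.
#' @return `readCategoryTable`: the validated data.frame.
#'   `writeCategoryTable`: `path`, invisibly.
#' @examples
#' calls <- assignFlows(c(g = "S"), c(g = "P"), c(g = "P"))
#' f <- tempfile(fileext = ".tsv")
#' writeCategoryTable(calls, f)
#' readCategoryTable(f)
#' @export
writeCategoryTable <- function(calls, path) {
    need <- c("gene", "cat20SS", "cat52hpf", "cat72hpf", "flow")
    stopifnot(all(need %in% colnames(calls)))
    utils::write.table(calls[, need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCategoryTable
#' @export
readCategoryTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "cat20SS", "cat52hpf", "cat72hpf", "flow")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("category table lacks column(s): ",
             paste(miss, collapse = ", "))
    .checkFlowLabel(df$flow)
    if (!all(df$flow == paste0(df$cat20SS, df$cat52hpf, df$cat72hpf)))
        stop("flow column disagrees with category columns")
    if (anyDuplicated(df$gene))
        stop("duplicated gene in category table: ",
             df$gene[which(duplicated(df$gene))[1L]])
    df
}

#' Write the fitted model as a long table
#'
#' One row per gene x condition with `gene`, `condition`, `m`, `v_tech`,
#' `v_bio_raw`, `v_bio`, `n`, `se`.
#'
#' @param model A [ConditionModel-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeModelTable(exampleModel(n_genes = 5), f)
#' @export
writeModelTable <- function(model, path) {
    stopifnot(is(model, "ConditionModel"))
    g <- rownames(model@means)
    cl <- model@conditions$label
    long <- data.frame(
        gene = rep(g, times = length(cl)),
        condition = rep(cl, each = length(g)),
        m = as.vector(model@means),
        v_tech = as.vector(model@techVar),
        v_bio_raw = as.vector(model@bioVarRaw),
        v_bio = as.vector(model@bioVar),
        n = rep(model@nrep, each = length(g)),
        se = as.vector(model@se), stringsAsFactors = FALSE)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a generator configuration from YAML
#'
#' Accepts the [simConfig()] fields as top-level YAML keys; omitted
#' fields take the defaults. `truth_mix` and
#' `replicates_per_condition` are maps.
#'
#' @param path YAML file path.
#' @return A `simConfig` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("n_genes: 10", "seed: 3", "truth_mix:", "  NNN: 1.0"), f)
#' readSimConfig(f)$n_genes
#' @export
readSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    for (nm in c("n_genes", "n_bootstraps", "dispersion", "seed",
                 "effect_size", "assay_noise"))
        if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
    if (!is.null(y$library_size_range))
        args$library_size_range <- as.numeric(y$library_size_range)
    if (!is.null(y$truth_mix))
        args$truth_mix <- unlist(y$truth_mix)
    if (!is.null(y$replicates_per_condition)) {
        r <- unlist(y$replicates_per_condition)
        storage.mode(r) <- "integer"
        args$replicates_per_condition <- r
    }
    do.call(simConfig, args)
}
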