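## Canonicalising equivalence classes, matching them across samples into one
## count matrix, gene annotation and the multi-gene filter ("Match ECs").

#' Canonical key of a transcript set
#'
#' Deterministic, human-readable row key: unique transcript ids sorted in
#' C-locale (radix) order, joined with `"|"`. Equal sets map to equal keys
#' and differing sets to differing keys.
#'
#' @param transcriptIds character vector (a set; duplicates tolerated).
#' @return single character key.
#' @export
canonicalKey <- function(transcriptIds) {
    if (length(transcriptIds) == 0L) stop("empty transcript set has no key")
    paste(sort(unique(as.character(transcriptIds)), method = "radix"),
          collapse = "|")
}

#' Build the cross-sample equivalence-class count matrix
#'
#' Matches equivalence classes across samples by canonical key and compiles
#' them into one matrix: the row set is the union of classes over samples,
#' and a sample lacking a class gets count 0. Per-sample totals are
#' conserved. All tables must share one transcript name space (same
#' reference).
#'
#' @param tables list of [RawECTable-class].
#' @param sampleOrder column order; defaults to the tables' sample ids in
#'   input order.
#' @return an unannotated [ECCountMatrix-class].
#' @export
buildECMatrix <- function(tables, sampleOrder = vapply(tables, sampleId, "")) {
    stopifnot(length(tables) > 0L)
    ids <- vapply(tables, sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample id: ",
                                 ids[duplicated(ids)][1L])
    if (!setequal(sampleOrder, ids))
        stop("sampleOrder must cover exactly the input samples")
    ref <- tables[[1L]]@transcripts
    for (t in tables[-1L])
        if (!identical(t@transcripts, ref)) {
            if (setequal(t@transcripts, ref))
                stop("transcript name spaces agree as sets but differ in order; ",
                     "tables must come from one reference index")
            stop("transcript name spaces differ between samples ",
                 "(distinct references?)")
        }
    per_tab_keys <- lapply(tables, function(t)
        vapply(t@subsets, function(s) canonicalKey(ref[s]), ""))
    keys <- sort(unique(unlist(per_tab_keys)), method = "radix")
    m <- matrix(0L, nrow = length(keys), ncol = length(tables),
                dimnames = list(keys, ids))
    for (i in seq_along(tables))
        m[match(per_tab_keys[[i]], keys), i] <- tables[[i]]@counts
    m <- m[, sampleOrder, drop = FALSE]
    txl <- CharacterList(strsplit(keys, "|", fixed = TRUE))
    se <- SummarizedExperiment(
        assays = list(counts = m),
        rowData = DataFrame(ec_key = keys, transcripts = txl))
    new("ECCountMatrix", se)
}

#' Construct an ECCountMatrix from components
#'
#' Lower-level constructor used for comparator branches (transcript or
#' exon-bin count matrices flow through the same testing machinery).
#'
#' @param counts integer matrix (features x samples).
#' @param keys canonical feature keys (default rownames).
#' @param transcripts `CharacterList` of member transcripts per row
#'   (default: keys split on `"|"`).
#' @param geneIds optional per-row gene labels.
#' @return an [ECCountMatrix-class].
#' @export
ECCountMatrix <- function(counts, keys = rownames(counts),
                          transcripts = CharacterList(strsplit(keys, "|", fixed = TRUE)),
                          geneIds = NULL) {
    storage.mode(counts) <- "integer"
    rownames(counts) <- keys
    rd <- DataFrame(ec_key = keys, transcripts = transcripts)
    if (!is.null(geneIds)) rd$gene_id <- geneIds
    new("ECCountMatrix",
        SummarizedExperiment(assays = list(counts = counts), rowData = rd))
}

#' Annotate equivalence classes with genes
#'
#' Labels each row with the unique gene of its member transcripts,
#' `"AMBIGUOUS"` when the transcripts span more than one gene, or
#' `"UNKNOWN"` when any member transcript is missing from the map.
#'
#' @param matrix an [ECCountMatrix-class].
#' @param t2g named character vector mapping transcript id to gene id, or a
#'   [TranscriptAnnotation-class].
#' @param strict error on unknown transcripts instead of labelling.
#' @return the matrix with `gene_id` filled in.
#' @export
annotateGenes <- function(matrix, t2g, strict = FALSE) {
    stopifnot(is(matrix, "ECCountMatrix"))
    if (is(t2g, "TranscriptAnnotation")) t2g <- txGeneMap(t2g)
    txl <- ecTranscripts(matrix)
    lab <- vapply(as.list(txl), function(txs) {
        g <- t2g[txs]
        if (anyNA(g)) return("UNKNOWN")
        g <- unique(g)
        if (length(g) > 1L) "AMBIGUOUS" else g
    }, "")
    if (strict && any(lab == "UNKNOWN"))
        stop(sum(lab == "UNKNOWN"), " equivalence class(es) contain transcripts ",
             "absent from the transcript-to-gene map")
    rowData(matrix)$gene_id <- unname(lab)
    matrix
}

#' Remove multi-gene (and unannotated) equivalence classes
#'
#' Drops rows labelled `"AMBIGUOUS"` (classes mapping to more than a single
#' gene). `"UNKNOWN"` rows are dropped with a message, or are an error in
#' strict mode. Surviving rows and their counts are untouched; this is the
#' only filtering applied by the default pipeline.
#'
#' @param matrix an annotated [ECCountMatrix-class].
#' @param strict error on `"UNKNOWN"` rows.
#' @return the filtered matrix.
#' @export
filterMultiGene <- function(matrix, strict = FALSE) {
    gid <- ecGenes(matrix)
    if (is.null(gid)) stop("matrix is not gene-annotated; run annotateGenes() first")
    n_unk <- sum(gid == "UNKNOWN")
    if (n_unk > 0L) {
        if (strict) stop(n_unk, " UNKNOWN equivalence class(es) present")
        message("dropping ", n_unk, " equivalence class(es) with unannotated transcripts")
    }
    matrix[!(gid %in% c("AMBIGUOUS", "UNKNOWN")), ]
}

#' Convert an ECCountMatrix column back to a per-sample table
#'
#' @param matrix an [ECCountMatrix-class].
#' @param sample column to extract.
#' @param transcripts transcript name space for the table (default: all
#'   transcripts occurring in the matrix, sorted).
#' @return a [RawECTable-class] holding the sample's non-zero classes.
#' @export
asRawECTable <- function(matrix, sample,
                         transcripts = sort(unique(unlist(ecTranscripts(matrix))),
                                            method = "radix")) {
    cnt <- ecCounts(matrix)[, sample]
    keep <- cnt > 0L
    subsets <- lapply(as.list(ecTranscripts(matrix)[keep]),
                      function(txs) match(txs, transcripts))
    if (anyNA(unlist(subsets))) stop("matrix transcript absent from name space")
    RawECTable(sample, transcripts, subsets, cnt[keep])
}
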