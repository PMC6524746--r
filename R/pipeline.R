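## Convenience orchestration of the three counting branches feeding the
## same statistical test: equivalence classes, EM transcript counts, and
## flattened exon bins.

#' EM transcript count matrix across samples
#'
#' Runs [emAbundance()] per sample table, converts to scaledTPM counts via
#' [scaledTpmCounts()] with the sample's assigned-read total, rounds to
#' integers, and assembles a transcript x sample matrix annotated with
#' genes — the "transcripts" comparator branch.
#'
#' @param tables list of [RawECTable-class] (one per sample; ids become
#'   columns).
#' @param annotation a [TranscriptAnnotation-class].
#' @param fragmentMean mean fragment length for [effectiveLengths()].
#' @return a gene-annotated [ECCountMatrix-class] with one row per
#'   transcript.
#' @export
transcriptCountMatrix <- function(tables, annotation, fragmentMean) {
    el <- effectiveLengths(annotation, fragmentMean)
    txg <- txGeneMap(annotation)
    cols <- lapply(tables, function(t) {
        ab <- emAbundance(t, el)
        cnt <- scaledTpmCounts(ab, sum(t@counts))
        cnt[names(txg)]
    })
    m <- round(do.call(cbind, cols))
    storage.mode(m) <- "integer"
    colnames(m) <- vapply(tables, sampleId, "")
    rownames(m) <- names(txg)
    ECCountMatrix(m, keys = names(txg),
                  transcripts = CharacterList(as.list(names(txg))),
                  geneIds = unname(txg))
}

#' Gene q-values of a DTU run as a named vector
#'
#' @param res result of [runDTU()].
#' @return named numeric vector (gene id -> q-value).
#' @export
geneQValues <- function(res) {
    structure(res$genes$qvalue, names = res$genes$gene_id)
}

#' Read / write a transcript-to-gene map TSV
#'
#' Two tab-separated columns, `transcript_id` and `gene_id`, with a header.
#'
#' @param path TSV path.
#' @return `readT2G` returns a named character vector (transcript -> gene).
#' @export
readT2G <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
    if (!all(c("transcript_id", "gene_id") %in% colnames(df)))
        stop("t2g table needs columns transcript_id and gene_id")
    if (anyDuplicated(df$transcript_id))
        stop("transcript mapped to multiple genes in ", path)
    structure(df$gene_id, names = df$transcript_id)
}

#' @rdname readT2G
#' @param t2g named character vector (transcript -> gene).
#' @export
writeT2G <- function(t2g, path) {
    utils::write.table(data.frame(transcript_id = names(t2g),
                                  gene_id = unname(t2g)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
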