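#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges IntegerList CharacterList
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   rowData<- colData assayNames
#' @useDynLib ecdtu, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Transcript annotation: exon models grouped per transcript
#'
#' Holds the gene/transcript/exon structure used for gene assignment of
#' equivalence classes, exon-bin flattening and simulation. Exons are stored
#' as a named [GenomicRanges::GRangesList] (one element per transcript,
#' ranges sorted and non-overlapping within a transcript) and every
#' transcript belongs to exactly one gene.
#'
#' @slot exons named `GRangesList`, one element per transcript.
#' @slot txGene named character; `txGene[tx]` is the gene of transcript `tx`.
#' @aliases TranscriptAnnotation-class
#' @export
setClass("TranscriptAnnotation",
    representation(exons = "GRangesList", txGene = "character"))

setValidity("TranscriptAnnotation", function(object) {
    txs <- names(object@exons)
    if (is.null(txs) || anyDuplicated(txs))
        return("transcript names must be present and unique")
    if (!identical(sort(txs), sort(names(object@txGene))))
        return("txGene must be named by exactly the annotated transcripts")
    n_ex <- lengths(object@exons)
    if (any(n_ex == 0L)) return("transcript with no exons")
    # within a transcript, each exon must start after the previous one ends
    # (sorted by start and non-overlapping in one check)
    ex_all <- unlist(object@exons, use.names = FALSE)
    grp <- rep.int(seq_along(object@exons), n_ex)
    st <- GenomicRanges::start(ex_all)
    en <- GenomicRanges::end(ex_all)
    n <- length(st)
    if (n > 1L) {
        same <- grp[-1L] == grp[-n]
        if (any(same & st[-1L] <= en[-n]))
            return("unsorted or overlapping exons within a transcript")
    }
    TRUE
})

#' Per-sample raw equivalence-class table
#'
#' The direct in-memory image of one sample's equivalence-class output
#' (Salmon `eq_classes.txt` or one kallisto pseudo-batch column): a
#' transcript name space plus (transcript index set, count) entries.
#'
#' @slot sampleId single character sample identifier.
#' @slot transcripts ordered character vector of transcript names.
#' @slot subsets list of integer vectors; 1-based indices into `transcripts`,
#'   each sorted and duplicate-free, no duplicate set across entries.
#' @slot counts integer vector of non-negative read counts, parallel to
#'   `subsets`.
#' @aliases RawECTable-class
#' @export
setClass("RawECTable",
    representation(sampleId = "character", transcripts = "character",
                   subsets = "list", counts = "integer"))

setValidity("RawECTable", function(object) {
    if (length(object@sampleId) != 1L) return("sampleId must be length 1")
    if (length(object@subsets) != length(object@counts))
        return("subsets and counts differ in length")
    if (any(object@counts < 0L)) return("negative EC count")
    n <- length(object@transcripts)
    if (anyDuplicated(object@transcripts)) return("duplicate transcript names")
    for (s in object@subsets) {
        if (length(s) == 0L) return("empty transcript index set")
        if (any(s < 1L) || any(s > n)) return("transcript index out of bounds")
        if (is.unsorted(s, strictly = TRUE)) return("index set not strictly sorted")
    }
    keys <- vapply(object@subsets, paste, "", collapse = ",")
    if (anyDuplicated(keys)) return("duplicate equivalence class in table")
    TRUE
})

#' Cross-sample equivalence-class count matrix
#'
#' The central data object: one row per canonical equivalence class (or, for
#' the comparator branches, per transcript or exon bin), one column per
#' sample, integer counts. Extends
#' [SummarizedExperiment::SummarizedExperiment]; row metadata carries
#' `ec_key` (canonical row key), `transcripts` (a `CharacterList` of member
#' transcripts) and, once annotated, `gene_id` (a gene identifier, or the
#' sentinels `"AMBIGUOUS"` / `"UNKNOWN"`).
#'
#' @aliases ECCountMatrix-class
#' @export
setClass("ECCountMatrix", contains = "SummarizedExperiment")

setValidity("ECCountMatrix", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' missing")
    cn <- colnames(object)
    if (is.null(cn) || anyDuplicated(cn)) return("sample ids must be unique")
    rd <- rowData(object)
    if (!all(c("ec_key", "transcripts") %in% colnames(rd)))
        return("rowData must contain 'ec_key' and 'transcripts'")
    if (anyDuplicated(rd$ec_key)) return("duplicate row keys")
    m <- assay(object, "counts")
    if (any(m < 0)) return("negative counts")
    TRUE
})

#' k-mer index over a transcript sequence set
#'
#' Maps every k-mer of the reference to the set of transcripts containing
#' it; backs [assignEC()] and [pseudoalignSample()]. The table lives in
#' native memory (external pointer) and is not serialisable; rebuild with
#' [buildKmerIndex()] in a new session.
#'
#' @slot ptr external pointer to the native index.
#' @slot k k-mer length.
#' @slot transcripts ordered transcript names of the reference.
#' @aliases KmerIndex-class
#' @export
setClass("KmerIndex",
    representation(ptr = "externalptr", k = "integer", transcripts = "character"))

#' Simulation ground truth
#'
#' @slot dtuGenes character vector of genes simulated with an isoform switch.
#' @slot proportions data.frame with columns `gene_id`, `transcript_id`,
#'   `prop_cond1`, `prop_cond2`, `expected_count_cond1`,
#'   `expected_count_cond2` (expected reads per replicate).
#' @slot readSources data.frame of per-read source records (`read_id`,
#'   `sample`, `transcript_id`, `offset`); empty when reads were not
#'   materialised.
#' @aliases SimTruth-class
#' @export
setClass("SimTruth",
    representation(dtuGenes = "character", proportions = "data.frame",
                   readSources = "data.frame"))

setValidity("SimTruth", function(object) {
    pr <- object@proportions
    need <- c("gene_id", "transcript_id", "prop_cond1", "prop_cond2")
    if (!all(need %in% colnames(pr))) return("proportions table incomplete")
    s1 <- tapply(pr$prop_cond1, pr$gene_id, sum)
    s2 <- tapply(pr$prop_cond2, pr$gene_id, sum)
    if (any(abs(s1 - 1) > 1e-8) || any(abs(s2 - 1) > 1e-8))
        return("per-gene proportions must sum to 1 in each condition")
    if (!all(object@dtuGenes %in% pr$gene_id))
        return("dtuGenes not a subset of simulated genes")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "TranscriptAnnotation", function(object) {
    cat(sprintf("TranscriptAnnotation: %d transcripts, %d genes, %d exons\n",
                length(object@exons), length(unique(object@txGene)),
                sum(lengths(object@exons))))
})

setMethod("show", "RawECTable", function(object) {
    cat(sprintf("RawECTable '%s': %d equivalence classes over %d transcripts, %d reads\n",
                object@sampleId, length(object@subsets),
                length(object@transcripts), sum(object@counts)))
})

setMethod("show", "ECCountMatrix", function(object) {
    gid <- rowData(object)$gene_id
    ann <- if (is.null(gid)) "unannotated" else
        sprintf("%d genes (%d ambiguous, %d unknown rows)",
                length(unique(gid[!gid %in% c("AMBIGUOUS", "UNKNOWN")])),
                sum(gid == "AMBIGUOUS"), sum(gid == "UNKNOWN"))
    cat(sprintf("ECCountMatrix: %d classes x %d samples; %s\n",
                nrow(object), ncol(object), ann))
})

setMethod("show", "KmerIndex", function(object) {
    info <- .cpp_index_info(object@ptr)
    cat(sprintf("KmerIndex: k = %d, %d transcripts, %.0f k-mers, %d distinct sets\n",
                info$k, info$n_transcripts, info$n_kmers, info$n_sets))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d genes (%d with DTU), %d transcripts, %d read records\n",
                length(unique(object@proportions$gene_id)), length(object@dtuGenes),
                nrow(object@proportions), nrow(object@readSources)))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for package classes
#'
#' `transcriptNames()` returns transcript identifiers; `txGeneMap()` the
#' named transcript-to-gene character map; `exonsBy()` the per-transcript
#' exon `GRangesList`; `ecCounts()` the count matrix; `ecKeys()` canonical
#' row keys; `ecTranscripts()` the member transcripts per row;
#' `ecGenes()` the per-row gene labels (or `NULL` before annotation);
#' `dtuGenes()` and `truthProportions()` the simulator's ground truth.
#'
#' @param x an object of the corresponding class.
#' @return See description.
#' @name accessors
#' @aliases transcriptNames txGeneMap exonsBy ecCounts ecKeys ecTranscripts
#'   ecGenes dtuGenes truthProportions readSources sampleId
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptNames", function(x) standardGeneric("transcriptNames"))
#' @rdname accessors
#' @export
setGeneric("txGeneMap", function(x) standardGeneric("txGeneMap"))
#' @rdname accessors
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))
#' @rdname accessors
#' @export
setGeneric("ecCounts", function(x) standardGeneric("ecCounts"))
#' @rdname accessors
#' @export
setGeneric("ecKeys", function(x) standardGeneric("ecKeys"))
#' @rdname accessors
#' @export
setGeneric("ecTranscripts", function(x) standardGeneric("ecTranscripts"))
#' @rdname accessors
#' @export
setGeneric("ecGenes", function(x) standardGeneric("ecGenes"))
#' @rdname accessors
#' @export
setGeneric("dtuGenes", function(x) standardGeneric("dtuGenes"))
#' @rdname accessors
#' @export
setGeneric("truthProportions", function(x) standardGeneric("truthProportions"))
#' @rdname accessors
#' @export
setGeneric("readSources", function(x) standardGeneric("readSources"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
setMethod("transcriptNames", "TranscriptAnnotation", function(x) names(x@exons))
#' @rdname accessors
setMethod("transcriptNames", "RawECTable", function(x) x@transcripts)
#' @rdname accessors
setMethod("transcriptNames", "KmerIndex", function(x) x@transcripts)
#' @rdname accessors
setMethod("txGeneMap", "TranscriptAnnotation", function(x) x@txGene[names(x@exons)])
#' @rdname accessors
setMethod("exonsBy", "TranscriptAnnotation", function(x) x@exons)
#' @rdname accessors
setMethod("ecCounts", "ECCountMatrix", function(x) assay(x, "counts"))
#' @rdname accessors
setMethod("ecKeys", "ECCountMatrix", function(x) rowData(x)$ec_key)
#' @rdname accessors
setMethod("ecTranscripts", "ECCountMatrix", function(x) rowData(x)$transcripts)
#' @rdname accessors
setMethod("ecGenes", "ECCountMatrix", function(x) rowData(x)$gene_id)
#' @rdname accessors
setMethod("dtuGenes", "SimTruth", function(x) x@dtuGenes)
#' @rdname accessors
setMethod("truthProportions", "SimTruth", function(x) x@proportions)
#' @rdname accessors
setMethod("readSources", "SimTruth", function(x) x@readSources)
#' @rdname accessors
setMethod("sampleId", "RawECTable", function(x) x@sampleId)

#' Transcript lengths (spliced)
#'
#' @param annotation a [TranscriptAnnotation-class].
#' @return named integer vector of spliced transcript lengths in bases.
#' @export
transcriptLengths <- function(annotation) {
    stopifnot(is(annotation, "TranscriptAnnotation"))
    vapply(annotation@exons, function(g) sum(GenomicRanges::width(g)), 0L)
}

#' Construct a TranscriptAnnotation
#'
#' @param exons named `GRangesList` of exons per transcript (ranges need not
#'   be pre-sorted; they are sorted by start).
#' @param txGene named character mapping transcript id to gene id.
#' @return a [TranscriptAnnotation-class].
#' @export
TranscriptAnnotation <- function(exons, txGene) {
    exons <- GRangesList(lapply(exons, function(g) g[order(GenomicRanges::start(g))]))
    new("TranscriptAnnotation", exons = exons, txGene = txGene)
}

#' Construct a RawECTable
#'
#' @param sampleId sample identifier.
#' @param transcripts transcript name space.
#' @param subsets list of integer index vectors (1-based into `transcripts`);
#'   sorted/deduplicated here.
#' @param counts non-negative integer counts, one per subset.
#' @return a [RawECTable-class].
#' @export
RawECTable <- function(sampleId, transcripts, subsets, counts) {
    subsets <- unname(lapply(subsets, function(s) sort(unique(as.integer(s)))))
    new("RawECTable", sampleId = as.character(sampleId),
        transcripts = as.character(transcripts),
        subsets = subsets, counts = as.integer(counts))
}

#' Construct a SimTruth
#' @param dtuGenes,proportions,readSources see [SimTruth-class].
#' @return a [SimTruth-class].
#' @export
SimTruth <- function(dtuGenes, proportions,
                     readSources = data.frame(read_id = character(),
                                              sample = character(),
                                              transcript_id = character(),
                                              offset = integer())) {
    new("SimTruth", dtuGenes = dtuGenes, proportions = proportions,
        readSources = readSources)
}
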