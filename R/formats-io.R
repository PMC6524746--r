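## Readers and writers for the external formats the pipeline touches:
## Salmon eq_classes.txt, kallisto pseudo-batch directories, GTF, FASTA/FASTQ,
## TSV count matrices and sample tables. Gzip inputs are handled
## transparently by extension (base R connections).

.open_lines <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    readLines(path)
}

#' Read a Salmon equivalence-class file
#'
#' Parses the `eq_classes.txt` produced by `salmon quant --dumpEq`: two
#' header lines (number of transcripts N, number of classes M), N transcript
#' names, then M class lines `k idx1 ... idxk count`. The newer weighted
#' dialect (`k idx1 ... idxk w1 ... wk count`) is auto-detected and the
#' weights ignored: this method uses plain counts.
#'
#' @param path path to `eq_classes.txt` (may be gzipped).
#' @param sampleId sample identifier stored in the table; defaults to the
#'   name of the directory containing the file.
#' @return a [RawECTable-class].
#' @export
readSalmonEq <- function(path, sampleId = basename(dirname(normalizePath(path)))) {
    lines <- .open_lines(path)
    if (length(lines) < 2L) stop("malformed header: fewer than 2 lines in ", path)
    n_tx <- suppressWarnings(as.integer(lines[1L]))
    n_ec <- suppressWarnings(as.integer(lines[2L]))
    if (is.na(n_tx)) stop("malformed header at line 1: expected transcript count")
    if (is.na(n_ec)) stop("malformed header at line 2: expected class count")
    if (length(lines) < 2L + n_tx + n_ec)
        stop("file truncated: expected ", 2L + n_tx + n_ec, " lines, found ",
             length(lines))
    txs <- lines[2L + seq_len(n_tx)]
    subsets <- vector("list", n_ec)
    counts <- integer(n_ec)
    for (i in seq_len(n_ec)) {
        ln <- 2L + n_tx + i
        tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]))
        if (any(is.na(tok)) || length(tok) < 3L)
            stop("malformed class line ", ln, " in ", path)
        k <- as.integer(tok[1L])
        if (length(tok) == k + 2L) {            # plain: k, indices, count
            idx <- as.integer(tok[1L + seq_len(k)])
        } else if (length(tok) == 2L * k + 2L) { # weighted: k, indices, weights, count
            idx <- as.integer(tok[1L + seq_len(k)])
        } else {
            stop("malformed class line ", ln, ": ", length(tok),
                 " tokens for k = ", k)
        }
        if (any(idx < 0L) || any(idx >= n_tx))
            stop("transcript index out of bounds on line ", ln)
        cnt <- tok[length(tok)]
        if (cnt < 0 || cnt != round(cnt))
            stop("invalid count on line ", ln)
        subsets[[i]] <- idx + 1L  # file is 0-based
        counts[i] <- as.integer(cnt)
    }
    keys <- vapply(lapply(subsets, sort), paste, "", collapse = ",")
    if (anyDuplicated(keys))
        stop("duplicate equivalence class line(s) in ", path)
    RawECTable(sampleId, txs, subsets, counts)
}

#' Write a Salmon-dialect equivalence-class file
#'
#' Serialises a [RawECTable-class] in the plain `eq_classes.txt` dialect
#' (0-based transcript indices), so the package's pseudo-aligner output and
#' real Salmon output are interchangeable downstream.
#'
#' @param table a [RawECTable-class].
#' @param path output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
writeSalmonEq <- function(table, path) {
    stopifnot(is(table, "RawECTable"))
    ec_lines <- mapply(function(s, n) paste(c(length(s), s - 1L, n), collapse = "\t"),
                       table@subsets, table@counts)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(c(length(table@transcripts), length(table@subsets),
                 table@transcripts, ec_lines), con)
    invisible(path)
}

#' Read a kallisto pseudo-batch directory
#'
#' Parses the four files written by `kallisto pseudo --batch`:
#' `transcripts.txt`, `matrix.ec` (class id, comma-separated 0-based
#' transcript indices), `matrix.cells` (sample names) and `matrix.tsv`
#' (class id, sample index, count triplets). Classes with zero count in a
#' sample are omitted from that sample's table.
#'
#' @param dir the batch output directory.
#' @return list of [RawECTable-class], one per sample in `matrix.cells`
#'   order.
#' @export
readKallistoPseudo <- function(dir) {
    need <- c("transcripts.txt", "matrix.ec", "matrix.cells", "matrix.tsv")
    for (f in need)
        if (!file.exists(file.path(dir, f)))
            stop("missing kallisto pseudo file: ", f)
    txs <- readLines(file.path(dir, "transcripts.txt"))
    cells <- readLines(file.path(dir, "matrix.cells"))
    ec_lines <- readLines(file.path(dir, "matrix.ec"))
    ec_ids <- as.integer(vapply(strsplit(ec_lines, "\t"), `[`, "", 1L))
    ec_sets <- lapply(strsplit(vapply(strsplit(ec_lines, "\t"), `[`, "", 2L), ","),
                      function(x) as.integer(x) + 1L)
    if (any(vapply(ec_sets, function(s) any(s < 1L | s > length(txs)), TRUE)))
        stop("transcript index out of bounds in matrix.ec")
    names(ec_sets) <- ec_ids
    tsv <- file.path(dir, "matrix.tsv")
    trip <- if (file.size(tsv) > 0)
        utils::read.table(tsv, sep = "\t", col.names = c("ec", "cell", "count"))
    else data.frame(ec = integer(), cell = integer(), count = integer())
    if (nrow(trip) && !all(as.character(trip$ec) %in% names(ec_sets)))
        stop("matrix.tsv refers to class id absent from matrix.ec")
    lapply(seq_along(cells), function(ci) {
        sub <- trip[trip$cell == ci - 1L & trip$count > 0, , drop = FALSE]
        RawECTable(cells[ci], txs, ec_sets[as.character(sub$ec)], sub$count)
    })
}

#' Write a set of tables as a kallisto pseudo-batch directory
#'
#' Inverse of [readKallistoPseudo()]; mainly used to exercise the parser
#' round trip on simulated data.
#'
#' @param tables list of [RawECTable-class] sharing one transcript name
#'   space.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeKallistoPseudo <- function(tables, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    txs <- tables[[1L]]@transcripts
    keys <- unique(unlist(lapply(tables, function(t)
        vapply(t@subsets, paste, "", collapse = ","))))
    writeLines(txs, file.path(dir, "transcripts.txt"))
    writeLines(vapply(seq_along(keys), function(i) {
        idx <- as.integer(strsplit(keys[i], ",")[[1L]]) - 1L
        paste0(i - 1L, "\t", paste(idx, collapse = ","))
    }, ""), file.path(dir, "matrix.ec"))
    writeLines(vapply(tables, sampleId, ""), file.path(dir, "matrix.cells"))
    rows <- character(0)
    for (ci in seq_along(tables)) {
        t <- tables[[ci]]
        k <- vapply(t@subsets, paste, "", collapse = ",")
        rows <- c(rows, sprintf("%d\t%d\t%d", match(k, keys) - 1L, ci - 1L, t@counts))
    }
    writeLines(rows, file.path(dir, "matrix.tsv"))
    invisible(dir)
}

#' Read transcript annotation from GTF
#'
#' Imports exon features (via [rtracklayer::import]) and groups them into a
#' [TranscriptAnnotation-class]. Exon records lacking a `transcript_id` are
#' skipped with a warning; a transcript assigned to two genes is an error.
#'
#' @param path GTF file (may be gzipped).
#' @param stripVersions drop trailing `.N` version suffixes from transcript
#'   and gene ids. Off by default: silent munging causes mismatches with the
#'   transcript-to-gene map.
#' @return a [TranscriptAnnotation-class].
#' @export
readGtfAnnotation <- function(path, stripVersions = FALSE) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", path)
    tx <- as.character(gr$transcript_id)
    gene <- as.character(gr$gene_id)
    bad <- is.na(tx) | tx == ""
    if (any(bad)) {
        warning(sum(bad), " exon feature(s) without transcript_id skipped")
        gr <- gr[!bad]; tx <- tx[!bad]; gene <- gene[!bad]
    }
    if (isTRUE(stripVersions)) {
        tx <- sub("\\.\\d+$", "", tx)
        gene <- sub("\\.\\d+$", "", gene)
    }
    g_per_tx <- tapply(gene, tx, function(g) length(unique(g)))
    if (any(g_per_tx > 1L))
        stop("transcript assigned to multiple genes: ",
             paste(names(g_per_tx)[g_per_tx > 1L], collapse = ", "))
    mcols(gr) <- NULL
    exons <- GenomicRanges::split(gr, tx)
    txGene <- vapply(split(gene, tx), `[`, "", 1L)
    TranscriptAnnotation(exons, txGene)
}

#' Write transcript annotation as GTF
#'
#' Emits one `exon` feature line per exon with `gene_id` and
#' `transcript_id` attributes; the simulator uses this to serialise toy
#' genomes.
#'
#' @param annotation a [TranscriptAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtfAnnotation <- function(annotation, path) {
    stopifnot(is(annotation, "TranscriptAnnotation"))
    lines <- character(0)
    txg <- txGeneMap(annotation)
    for (tx in transcriptNames(annotation)) {
        ex <- annotation@exons[[tx]]
        lines <- c(lines, sprintf(
            "%s\tecdtu\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            as.character(seqnames(ex)), GenomicRanges::start(ex),
            GenomicRanges::end(ex), as.character(strand(ex)), txg[tx], tx))
    }
    writeLines(lines, path)
    invisible(path)
}

#' FASTA / FASTQ convenience wrappers
#'
#' Thin wrappers around [Biostrings] readers/writers with the validation
#' the pipeline needs (unique ids; FASTQ written with constant quality
#' since simulated reads are error-free).
#'
#' @param path file path.
#' @return `readFastaSeqs` returns a [Biostrings::DNAStringSet].
#' @export
readFastaSeqs <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
    x
}

#' @rdname readFastaSeqs
#' @param seqs named character vector or `DNAStringSet`.
#' @export
writeFastaSeqs <- function(seqs, path) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' @rdname readFastaSeqs
#' @export
writeFastqReads <- function(seqs, path) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    if (anyDuplicated(names(seqs))) stop("duplicate read ids")
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
        function(w) paste(rep("I", w), collapse = ""), ""))
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
    invisible(path)
}

#' @rdname readFastaSeqs
#' @export
readFastqReads <- function(path) {
    Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Count matrix TSV I/O
#'
#' The pipeline's matrix interchange format: tab-separated, header row, first
#' two columns `feature_key` and `gene_id`, remaining columns one per sample
#' with integer counts. Round trips losslessly.
#'
#' @param path TSV path (may be gzipped).
#' @return `readCountMatrix` returns a list with `counts` (integer matrix,
#'   rownames = feature keys), `gene_id` (character, parallel to rows) and
#'   `samples`.
#' @export
readCountMatrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            colClasses = "character", quote = "")
    if (ncol(df) < 2L || !identical(colnames(df)[1:2], c("feature_key", "gene_id")))
        stop("count matrix must start with feature_key and gene_id columns")
    samples <- colnames(df)[-(1:2)]
    cnt <- as.matrix(df[, -(1:2), drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(cnt), nrow = nrow(df),
                                   ncol = length(samples)))
    if (nrow(df) > 0 && (any(is.na(num)) || any(num != round(num))))
        stop("non-integer count cell in ", path)
    m <- matrix(as.integer(num), nrow = nrow(df), ncol = length(samples),
                dimnames = list(df$feature_key, samples))
    list(counts = m, gene_id = df$gene_id, samples = samples)
}

#' @rdname readCountMatrix
#' @param counts integer matrix with feature-key rownames.
#' @param geneIds character vector parallel to rows.
#' @export
writeCountMatrix <- function(counts, geneIds, path) {
    if (any(counts != round(counts))) stop("counts must be integers")
    keys <- rownames(counts)
    if (is.null(keys)) keys <- character(nrow(counts))
    df <- data.frame(feature_key = keys, gene_id = as.character(geneIds),
                     counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample table
#'
#' TSV with columns `sample`, `condition`, `path`; sample ids must be
#' unique and every condition must have at least one sample.
#'
#' @param path TSV path.
#' @return data.frame with character columns `sample`, `condition`, `path`.
#' @export
readSampleTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
    need <- c("sample", "condition", "path")
    if (!all(need %in% colnames(df)))
        stop("sample table must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    if (anyDuplicated(df$sample)) stop("duplicate sample ids in sample table")
    if (nrow(df) == 0L || length(unique(df$condition)) < 1L)
        stop("sample table needs at least one sample and condition")
    df
}

#' @rdname readSampleTable
#' @param samples data.frame with columns `sample`, `condition`, `path`.
#' @export
writeSampleTable <- function(samples, path) {
    utils::write.table(samples[, c("sample", "condition", "path")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
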