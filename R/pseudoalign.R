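## Minimal k-mer pseudo-alignment: error-free reads are assigned to the
## equivalence class given by intersecting, over all read k-mers present in
## the index, the sets of transcripts containing each k-mer. k-mers absent
## from the index are skipped (lightweight-aligner behaviour; robust at toy
## exon junction edges).

#' Build a k-mer index over transcript sequences
#'
#' @param sequences named `DNAStringSet` or character vector of transcript
#'   sequences (alphabet ACGT). Sequences shorter than `k` are skipped with
#'   a warning.
#' @param k k-mer length, 3..31. Default 31 as used for realistic
#'   references; tiny toy references in unit tests use smaller k.
#' @return a [KmerIndex-class].
#' @export
buildKmerIndex <- function(sequences, k = 31L) {
    seqs <- structure(as.character(sequences), names = names(sequences))
    if (is.null(names(seqs))) stop("sequences must be named")
    ptr <- .cpp_build_index(unname(seqs), names(seqs), as.integer(k))
    new("KmerIndex", ptr = ptr, k = as.integer(k), transcripts = names(seqs))
}

#' Full k-mer table of a (small) index
#'
#' @param index a [KmerIndex-class].
#' @return data.frame-free list with `kmer` (character) and `transcripts`
#'   (list of character vectors), one entry per distinct k-mer.
#' @export
kmerTable <- function(index) {
    d <- .cpp_dump_table(index@ptr)
    list(kmer = d$kmer,
         transcripts = lapply(d$transcripts, function(i) index@transcripts[i]))
}

.revcomp <- function(x) {
    vapply(x, function(s) {
        chartr("ACGTacgt", "TGCAtgca",
               paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
    }, "", USE.NAMES = FALSE)
}

#' Assign reads to equivalence classes
#'
#' For each read, intersects the index's transcript sets over all read
#' k-mers present in the index; a read with no indexed k-mer, or an empty
#' intersection, is unassigned (`NA`).
#'
#' @param reads character vector / `DNAStringSet` of read sequences.
#' @param index a [KmerIndex-class].
#' @param stranded `"forward"` (default; the simulator emits forward-strand
#'   reads) or `"both"`, which unions the forward and reverse-complement
#'   assignments of each read.
#' @return list with `id` (integer EC id per read, `NA` = unassigned) and
#'   `sets` (list of character transcript sets indexed by `id`).
#' @export
assignEC <- function(reads, index, stranded = c("forward", "both")) {
    stranded <- match.arg(stranded)
    reads <- as.character(reads)
    short <- nchar(reads) < index@k
    if (any(short))
        message(sum(short), " read(s) shorter than k = ", index@k, " left unassigned")
    res <- .cpp_assign_reads(index@ptr, reads)
    sets <- lapply(res$sets, function(i) index@transcripts[i])
    ids <- res$id
    if (stranded == "both") {
        rc <- .cpp_assign_reads(index@ptr, .revcomp(reads))
        rc_sets <- lapply(rc$sets, function(i) index@transcripts[i])
        merged <- mapply(function(a, b) {
            fa <- if (is.na(a)) character(0) else sets[[a]]
            fb <- if (is.na(b)) character(0) else rc_sets[[b]]
            u <- union(fa, fb)
            if (length(u)) sort(u, method = "radix") else NULL
        }, ids, rc$id, SIMPLIFY = FALSE)
        keys <- vapply(merged, function(s) if (is.null(s)) NA_character_ else
            paste(s, collapse = "|"), "")
        uk <- unique(keys[!is.na(keys)])
        ids <- match(keys, uk)
        sets <- lapply(strsplit(uk, "|", fixed = TRUE), identity)
    }
    list(id = ids, sets = sets)
}

#' Pseudo-align a sample of reads into an equivalence-class table
#'
#' Aggregates per-read assignments into (class, count) entries. In paired
#' mode both mates' compatibility sets are intersected before classifying
#' (a mate without any indexed k-mer contributes no constraint). Unassigned
#' reads are tallied, reported via message, and excluded from the table.
#' The result is independent of read order.
#'
#' @param reads read sequences (character / `DNAStringSet`); in paired mode
#'   the first mates.
#' @param index a [KmerIndex-class].
#' @param mates second mates (enables paired mode).
#' @param sampleId sample id stored in the table.
#' @param stranded see [assignEC()] (single-end only).
#' @return a [RawECTable-class] over the index's transcript name space.
#' @export
pseudoalignSample <- function(reads, index, mates = NULL, sampleId = "sample",
                              stranded = "forward") {
    if (is.null(mates)) {
        a <- assignEC(reads, index, stranded = stranded)
        ids <- a$id
        sets <- a$sets
    } else {
        res <- .cpp_assign_pairs(index@ptr, as.character(reads), as.character(mates))
        ids <- res$id
        sets <- lapply(res$sets, function(i) index@transcripts[i])
    }
    n_un <- sum(is.na(ids))
    if (n_un > 0L) message(n_un, " read(s) unassigned")
    tab <- tabulate(ids[!is.na(ids)], nbins = length(sets))
    keep <- tab > 0L
    subsets <- lapply(sets[keep], function(txs) match(txs, index@transcripts))
    RawECTable(sampleId, index@transcripts, subsets, tab[keep])
}
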