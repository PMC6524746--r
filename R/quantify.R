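## The two comparator quantification branches: EM transcript abundance from
## equivalence-class counts ("transcripts") and flattened exon-bin counting
## ("exons").

#' Effective transcript lengths
#'
#' `l_eff(t) = max(L(t) - fragment_mean + 1, 1)`: the number of distinct
#' fragment start positions, floored at 1.
#'
#' @param lengths named numeric vector of transcript lengths, or a
#'   [TranscriptAnnotation-class].
#' @param fragmentMean mean fragment length in bases (> 0). Single-end data
#'   uses the read length.
#' @return named numeric vector of effective lengths.
#' @export
effectiveLengths <- function(lengths, fragmentMean) {
    stopifnot(fragmentMean > 0)
    if (is(lengths, "TranscriptAnnotation")) lengths <- transcriptLengths(lengths)
    pmax(lengths - fragmentMean + 1, 1)
}

#' EM estimation of transcript abundances from equivalence-class counts
#'
#' Standard equivalence-class-level EM on read fractions `alpha`: with
#' per-class counts `n_e` and effective lengths `l_t`, iterate
#' `alpha_t <- (1/N) * sum_e n_e (alpha_t/l_t) / sum_{t' in e} (alpha_{t'}/l_{t'})`
#' from a uniform start until the maximum absolute change drops below `tol`
#' or `maxIter` is reached. This is EM for the observed-data log-likelihood
#' `sum_e n_e log( sum_{t in e} alpha_t / l_t )` (up to a constant), which
#' is therefore non-decreasing across iterations. Estimated counts are
#' `N * alpha`; TPM renormalises `alpha/l_eff` to one million.
#'
#' @param table a [RawECTable-class].
#' @param effLengths named effective lengths covering every transcript that
#'   occurs in a class.
#' @param tol convergence tolerance on abundances (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return data.frame with columns `transcript_id`, `est_count`, `tpm`,
#'   `eff_length`; attributes `loglik` (per-iteration trace), `iterations`,
#'   `converged`.
#' @export
emAbundance <- function(table, effLengths, tol = 1e-8, maxIter = 1000L) {
    stopifnot(is(table, "RawECTable"))
    txs <- table@transcripts
    if (!all(txs %in% names(effLengths)))
        stop("effective length missing for some transcripts")
    l <- as.numeric(effLengths[txs])
    n_ec <- length(table@subsets)
    N <- sum(table@counts)
    out <- data.frame(transcript_id = txs, est_count = 0, tpm = 0,
                      eff_length = l)
    if (N == 0L || n_ec == 0L) {
        warning("zero assigned reads; returning all-zero abundance estimate")
        attr(out, "loglik") <- numeric(0)
        attr(out, "iterations") <- 0L
        attr(out, "converged") <- TRUE
        return(out)
    }
    A <- Matrix::sparseMatrix(
        i = rep.int(seq_len(n_ec), lengths(table@subsets)),
        j = unlist(table@subsets), x = 1,
        dims = c(n_ec, length(txs)))
    cnt <- as.numeric(table@counts)
    # Transcripts appearing in no class keep mass 0 from the first E-step.
    alpha <- rep(1 / length(txs), length(txs))
    ll <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        w <- alpha / l
        denom <- as.numeric(A %*% w)          # sum_{t in e} alpha_t / l_t
        ll <- c(ll, sum(cnt[denom > 0] * log(denom[denom > 0])))
        resp <- as.numeric(Matrix::crossprod(A, ifelse(denom > 0, cnt / denom, 0)))
        alpha_new <- w * resp / N
        alpha_new <- alpha_new / sum(alpha_new)
        delta <- max(abs(alpha_new - alpha))
        alpha <- alpha_new
        if (delta < tol) { converged <- TRUE; break }
    }
    out$est_count <- N * alpha
    dens <- alpha / l
    out$tpm <- dens / sum(dens) * 1e6
    attr(out, "loglik") <- ll
    attr(out, "iterations") <- it
    attr(out, "converged") <- converged
    out
}

#' scaledTPM transcript counts
#'
#' Converts TPM abundances into count-scale estimates by scaling to the
#' library size: `count_t = tpm_t * librarySize / 1e6`, so totals are
#' conserved.
#'
#' @param abundance data.frame from [emAbundance()] (columns
#'   `transcript_id`, `tpm`).
#' @param librarySize total assigned reads of the sample.
#' @return named numeric vector of per-transcript counts.
#' @export
scaledTpmCounts <- function(abundance, librarySize) {
    structure(abundance$tpm * librarySize / 1e6,
              names = abundance$transcript_id)
}

#' Flatten transcript exons into disjoint counting bins
#'
#' Projects, per gene, all transcript exons onto the genome and cuts at
#' every distinct exon boundary within the gene, yielding disjoint exon
#' parts each labelled with the transcripts containing it. Parts that
#' overlap a different gene on the same strand are excluded (the
#' aggregate-free counting-bin preparation).
#'
#' @param annotation a [TranscriptAnnotation-class].
#' @return `GRanges` of bins with metadata columns `gene_id`, `bin_id`
#'   (`gene:NNN`, numbered 5' to 3' in genomic order) and `transcripts`
#'   (a `CharacterList`).
#' @export
flattenExonBins <- function(annotation) {
    stopifnot(is(annotation, "TranscriptAnnotation"))
    txg <- txGeneMap(annotation)
    ex <- unlist(annotation@exons, use.names = FALSE)
    ex$transcript_id <- rep(transcriptNames(annotation),
                            lengths(annotation@exons))
    ex$gene_id <- txg[ex$transcript_id]
    out <- list()
    for (g in unique(ex$gene_id)) {
        gx <- ex[ex$gene_id == g]
        bins <- GenomicRanges::disjoin(gx)
        hit <- GenomicRanges::findOverlaps(bins, gx)
        txl <- unname(S4Vectors::splitAsList(
            gx$transcript_id[S4Vectors::subjectHits(hit)],
            factor(S4Vectors::queryHits(hit), levels = seq_along(bins))))
        bins$gene_id <- g
        bins$transcripts <- unique(txl)
        out[[g]] <- bins
    }
    bins <- unlist(GRangesList(out), use.names = FALSE)
    # exclude parts overlapping a different gene on the same strand
    hit <- GenomicRanges::findOverlaps(bins, ex)
    clash <- unique(S4Vectors::queryHits(hit)[
        bins$gene_id[S4Vectors::queryHits(hit)] !=
            ex$gene_id[S4Vectors::subjectHits(hit)]])
    if (length(clash)) bins <- bins[-clash]
    ord <- order(bins$gene_id, GenomicRanges::start(bins))
    bins <- bins[ord]
    idx <- stats::ave(seq_along(bins), bins$gene_id, FUN = seq_along)
    bins$bin_id <- sprintf("%s:%03d", bins$gene_id, idx)
    bins
}

#' Count reads over flattened exon bins
#'
#' A read increments every bin of its gene that it overlaps by at least one
#' base (multi-bin reads are counted once per overlapped bin). Consumes the
#' simulator's true genomic read intervals, so the counting-unit comparison
#' is isolated from aligner noise. Reads overlapping no bin are tallied and
#' reported.
#'
#' @param alignments `GRanges` of read blocks (a spliced read contributes
#'   one range per exon piece) with metadata columns `read_id`, `sample`
#'   and `gene_id` (the source gene).
#' @param bins output of [flattenExonBins()].
#' @param samples column order of the result; defaults to sorted unique
#'   sample labels.
#' @return an [ECCountMatrix-class] keyed by `bin_id`, gene-annotated.
#' @export
countExonBins <- function(alignments, bins,
                          samples = sort(unique(alignments$sample))) {
    hit <- GenomicRanges::findOverlaps(alignments, bins, minoverlap = 1L)
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    same_gene <- alignments$gene_id[q] == bins$gene_id[s]
    q <- q[same_gene]; s <- s[same_gene]
    # one increment per (read, bin), however many blocks overlap
    pair_key <- paste(alignments$read_id[q], s)
    keep <- !duplicated(pair_key)
    q <- q[keep]; s <- s[keep]
    n_missed <- length(setdiff(unique(alignments$read_id),
                               unique(alignments$read_id[q])))
    if (n_missed > 0L)
        message(n_missed, " read(s) overlapped no counting bin")
    m <- matrix(0L, nrow = length(bins), ncol = length(samples),
                dimnames = list(bins$bin_id, samples))
    tab <- table(factor(s, levels = seq_along(bins)),
                 factor(alignments$sample[q], levels = samples))
    m[, ] <- as.integer(tab)
    ECCountMatrix(m, keys = bins$bin_id,
                  transcripts = bins$transcripts,
                  geneIds = bins$gene_id)
}
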