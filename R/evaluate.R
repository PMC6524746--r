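## Evaluation machinery: TPR/FDR at nominal cutoffs, consensus truth sets,
## subset-iteration experiments, counting-bin and variance/mean diagnostics,
## and rank-order false-positive curves.

#' TPR and FDR at nominal q-value cutoffs
#'
#' At each threshold `t`, the called set is `{g : q_g < t}`;
#' `TPR = |called n truth| / |truth|` and `FDR = |called \ truth| /
#' |called|`, with the 0/0 convention that no calls means FDR 0. The truth
#' set is intersected with the tested universe before scoring so methods
#' are compared on comparable gene sets.
#'
#' @param qvalues named numeric vector of gene q-values (one method).
#' @param truth character vector of true DTU genes.
#' @param universe genes over which to score (default: the tested genes).
#' @param thresholds nominal cutoffs (default 0.01, 0.05, 0.1).
#' @return data.frame with `threshold`, `n_called`, `tpr`, `fdr`.
#' @export
tprFdr <- function(qvalues, truth, universe = names(qvalues),
                   thresholds = c(0.01, 0.05, 0.1)) {
    q <- qvalues[intersect(names(qvalues), universe)]
    truth <- intersect(truth, universe)
    do.call(rbind, lapply(thresholds, function(t) {
        called <- names(q)[q < t]
        tpr <- if (length(truth) == 0L) NA_real_ else
            length(intersect(called, truth)) / length(truth)
        fdr <- if (length(called) == 0L) 0 else
            length(setdiff(called, truth)) / length(called)
        data.frame(threshold = t, n_called = length(called),
                   tpr = tpr, fdr = fdr)
    }))
}

#' Consensus truth set across methods
#'
#' Union mode: genes significant in any method at the threshold; intersect
#' mode: genes significant in all methods. Used to score methods against
#' each other when no simulated truth exists.
#'
#' @param results named list of gene q-value vectors (one per method).
#' @param mode `"union"` or `"intersect"`.
#' @param threshold significance cutoff (default 0.05).
#' @return character vector of gene ids.
#' @export
consensusTruth <- function(results, mode = c("union", "intersect"),
                           threshold = 0.05) {
    mode <- match.arg(mode)
    stopifnot(length(results) >= 1L)
    sets <- lapply(results, function(q) names(q)[q < threshold])
    out <- Reduce(if (mode == "union") union else intersect, sets)
    sort(unique(out))
}

#' Subset-iteration experiment
#'
#' Repeatedly draws `nPerGroup` samples per condition without replacement,
#' re-runs the supplied pipeline on the subset, and scores its calls
#' against a fixed full-data truth set. The iteration set is redrawn until
#' every sample appears in at least one iteration. Fully seeded.
#'
#' @param pipeline function taking a character vector of sample ids and
#'   returning a named gene q-value vector.
#' @param sampleTable data.frame with columns `sample` and `condition`.
#' @param nPerGroup samples drawn per condition (< group size).
#' @param nIterations number of iterations.
#' @param truth gene set to score against.
#' @param threshold q-value cutoff (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with one row per iteration: `iteration`, `samples`
#'   (comma-joined), `n_called`, `tpr`, `fdr`.
#' @export
subsetExperiment <- function(pipeline, sampleTable, nPerGroup, nIterations,
                             truth, threshold = 0.05, seed = 1L) {
    groups <- split(sampleTable$sample, sampleTable$condition)
    if (any(vapply(groups, length, 0L) <= nPerGroup))
        stop("nPerGroup must be smaller than every group")
    set.seed(seed)
    for (attempt in 1:100) {
        draws <- lapply(seq_len(nIterations), function(i)
            unlist(lapply(groups, sample, size = nPerGroup), use.names = FALSE))
        if (setequal(unlist(draws), sampleTable$sample)) break
        if (attempt == 100L)
            stop("could not cover every sample in ", nIterations, " iterations")
    }
    out <- lapply(seq_len(nIterations), function(i) {
        q <- pipeline(draws[[i]])
        pt <- tprFdr(q, truth, thresholds = threshold)
        data.frame(iteration = i, samples = paste(draws[[i]], collapse = ","),
                   n_called = pt$n_called, tpr = pt$tpr, fdr = pt$fdr)
    })
    do.call(rbind, out)
}

#' Expressed features per gene, per counting-bin type
#'
#' For each gene and each supplied matrix, the number of features with at
#' least one associated read (row sum >= 1).
#'
#' @param matrices named list of annotated [ECCountMatrix-class] objects
#'   (e.g. `list(transcript = ..., ec = ..., exon = ...)`).
#' @return data.frame with `gene_id`, `type`, `n_features`; attribute
#'   `totals` gives the per-type totals.
#' @export
featureCountSummary <- function(matrices) {
    out <- do.call(rbind, lapply(names(matrices), function(ty) {
        m <- matrices[[ty]]
        gid <- ecGenes(m)
        if (is.null(gid)) stop("matrix '", ty, "' is not gene-annotated")
        expressed <- rowSums(ecCounts(m)) >= 1L
        tab <- table(gid[expressed])
        data.frame(gene_id = names(tab), type = rep(ty, length(tab)),
                   n_features = as.integer(tab), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    totals <- tapply(out$n_features, out$type, sum)
    structure(out, totals = totals)
}

#' Per-feature variance-to-mean summary on CPM
#'
#' Counts are CPM-transformed (count x 1e6 / column sum); features are
#' lightly filtered (at least one sample with CPM >= 1); per condition,
#' `log2(variance/mean)` of the CPM values is computed for each feature.
#' Zero-variance features are excluded and counted.
#'
#' @param counts feature x sample matrix or [ECCountMatrix-class].
#' @param conditions condition label per sample (>= 2 replicates each).
#' @return data.frame with `feature_key`, `condition`, `log2_var_mean`;
#'   attributes `mean` (grand mean of the finite values) and `n_excluded`.
#' @export
varianceMeanSummary <- function(counts, conditions) {
    if (is(counts, "ECCountMatrix")) counts <- ecCounts(counts)
    if (min(table(conditions)) < 2L)
        stop("need >= 2 replicates per condition")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("zero library size column")
    cpm <- sweep(counts, 2L, lib, "/") * 1e6
    keep <- rowSums(cpm >= 1) >= 1L
    cpm <- cpm[keep, , drop = FALSE]
    rows <- list()
    n_excluded <- 0L
    for (cond in unique(conditions)) {
        sub <- cpm[, conditions == cond, drop = FALSE]
        v <- apply(sub, 1L, stats::var)
        m <- rowMeans(sub)
        val <- log2(v / m)
        ok <- is.finite(val)
        n_excluded <- n_excluded + sum(!ok)
        rows[[cond]] <- data.frame(feature_key = rownames(cpm)[ok],
                                   condition = cond,
                                   log2_var_mean = val[ok],
                                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, mean = mean(out$log2_var_mean), n_excluded = n_excluded)
}

#' Cumulative false positives by q-value rank
#'
#' Genes are sorted by q-value (ties broken by gene id) and the cumulative
#' count of non-truth genes is reported at each rank up to `topN`.
#'
#' @param qvalues named gene q-value vector.
#' @param truth true gene set.
#' @param topN number of ranks (default 500).
#' @return data.frame with `rank`, `gene_id`, `qvalue`, `cum_fp`.
#' @export
rankOrderFP <- function(qvalues, truth, topN = 500L) {
    stopifnot(length(qvalues) > 0L)
    ord <- order(qvalues, names(qvalues))
    top <- ord[seq_len(min(topN, length(qvalues)))]
    fp <- cumsum(!(names(qvalues)[top] %in% truth))
    data.frame(rank = seq_along(top), gene_id = names(qvalues)[top],
               qvalue = unname(qvalues[top]), cum_fp = fp)
}
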