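## Count-based differential-usage testing applied to any feature matrix
## (equivalence classes, exon bins or transcript counts): median-of-ratios
## normalisation, Cox-Reid dispersion estimation with a parametric trend and
## log-normal shrinkage, per-feature NB GLM likelihood-ratio tests on the
## this-versus-others representation, and gene-level q-values.

#' Median-of-ratios size factors
#'
#' Per sample, the median over features (restricted to features with
#' positive counts in every sample) of the ratio of the count to the
#' feature's geometric mean across samples. Falls back to library-size
#' ratios, with a warning, when no feature is positive everywhere.
#'
#' @param counts feature x sample count matrix, or an
#'   [ECCountMatrix-class].
#' @return named numeric vector of positive per-sample factors.
#' @export
computeSizeFactors <- function(counts) {
    if (is(counts, "ECCountMatrix")) counts <- ecCounts(counts)
    lg <- log(counts)
    geo <- rowMeans(lg)
    ok <- is.finite(geo)
    if (!any(ok)) {
        warning("no feature with positive counts in every sample; ",
                "using library-size ratios")
        lib <- colSums(counts)
        return(lib / exp(mean(log(lib))))
    }
    geo_r <- exp(geo[ok])
    apply(counts[ok, , drop = FALSE], 2L, function(cl)
        stats::median(cl / geo_r))
}

## Design matrices for the two-row-per-sample (this/others) NB GLM.
## Full model mean: sample effect + bin effect + condition x bin
## interaction; the null drops the interaction. The condition main effect
## is absorbed by the sample effects.
.designMatrices <- function(conditions) {
    n <- length(conditions)
    cond <- factor(conditions)
    sample_f <- factor(seq_len(n))
    sample2 <- rep(sample_f, 2L)
    exon_this <- rep(c(0, 1), each = n)              # rows 1..n = others
    cond2 <- rep(cond, 2L)
    Xs <- stats::model.matrix(~sample2)              # intercept + sample dummies
    X_null <- cbind(Xs, this = exon_this)
    Cd <- stats::model.matrix(~cond2)[, -1L, drop = FALSE]
    X_full <- cbind(X_null, Cd * exon_this)
    colnames(X_full)[seq(ncol(X_null) + 1L, ncol(X_full))] <-
        paste0("this:", levels(cond)[-1L])
    list(full = X_full, null = X_null, df = nlevels(cond) - 1L)
}

## Ridge-stabilised IRLS for a log-link NB GLM with fixed dispersion alpha
## (native backend). Returns mu, log-likelihood and convergence flag.
.nbFit <- function(y, X, offset, alpha, tol = 1e-8, maxIter = 100L,
                   ridge = 1e-6) {
    .cpp_nb_fit(as.numeric(y), X, as.numeric(offset), alpha, tol,
                as.integer(maxIter), ridge)
}

.DISP_FLOOR <- 1e-8
.DISP_CEIL <- 10

## Per-feature Cox-Reid dispersion MLE on the this/others data. Alternates
## (twice) between fitting means at the current alpha and profiling alpha at
## fixed means.
## Profile APL: means refit at every candidate dispersion (native backend).
.profileApl <- function(log_alpha, y, X, offset) {
    .cpp_nb_apl(as.numeric(y), X, as.numeric(offset), log_alpha)
}

.dispMLE <- function(y, X, offset) {
    opt <- stats::optimize(.profileApl, c(log(.DISP_FLOOR), log(.DISP_CEIL)),
                           y = y, X = X, offset = offset, maximum = TRUE,
                           tol = 1e-6)
    alpha <- exp(opt$maximum)
    list(alpha = alpha, mu = .nbFit(y, X, offset, alpha)$mu)
}

#' Dispersion estimation with trend and shrinkage
#'
#' For every testable feature, estimates the negative-binomial dispersion of
#' its this-versus-others counts by Cox-Reid adjusted profile-likelihood
#' maximum likelihood under the full model; fits the parametric mean trend
#' `alpha(mu) = a1/mu + a0` across features by iterative gamma regression
#' with outlier exclusion; and shrinks each MLE towards the trend as the
#' posterior mode under a log-normal prior. Features whose log MLE exceeds
#' the trend by more than two residual standard deviations keep their MLE
#' (dispersion outliers). Dispersions are bounded in `[1e-8, 10]`; all-zero
#' features are flagged and excluded from testing.
#'
#' @param counts feature x sample integer matrix.
#' @param geneIds gene per feature.
#' @param conditions condition label per sample (>= 2 replicates per
#'   condition).
#' @param sizeFactors per-sample size factors (default
#'   [computeSizeFactors()]).
#' @return data.frame with one row per feature: `feature_key`, `gene_id`,
#'   `base_mean`, `disp_mle`, `disp_trend`, `disp_final`, `outlier`,
#'   `status` (`"ok"`, `"all_zero"` or `"single_feature"`); attributes
#'   `trend_coef` (a0, a1) and `prior_var`.
#' @export
fitDispersions <- function(counts, geneIds, conditions,
                           sizeFactors = computeSizeFactors(counts)) {
    if (min(table(conditions)) < 2L)
        stop("need >= 2 samples per condition to estimate dispersions")
    prep <- .prepFeatures(counts, geneIds)
    des <- .designMatrices(conditions)
    off <- rep(log(sizeFactors), 2L)
    n_feat <- nrow(counts)
    res <- data.frame(feature_key = rownames(counts), gene_id = geneIds,
                      base_mean = NA_real_, disp_mle = NA_real_,
                      disp_trend = NA_real_, disp_final = NA_real_,
                      outlier = FALSE, status = prep$status,
                      stringsAsFactors = FALSE)
    idx <- which(prep$status == "ok")
    for (i in idx) {
        y <- prep$ys[[i]]
        res$base_mean[i] <- mean(y[seq_along(conditions) + length(conditions)] /
                                     sizeFactors)
        m <- .dispMLE(y, des$full, off)
        res$disp_mle[i] <- m$alpha
    }
    # parametric trend a1/mu + a0 by gamma regression, iterating away outliers
    use <- idx[res$disp_mle[idx] > 10 * .DISP_FLOOR & res$base_mean[idx] > 0]
    coefs <- if (length(use) >= 10L)
        .fitTrend(res$disp_mle[use], res$base_mean[use])
    else  # (almost) everything at the floor: flat trend at the MLE median
        c(max(stats::median(res$disp_mle[idx]), .DISP_FLOOR), 0)
    res$disp_trend[idx] <- pmin(pmax(coefs[1L] + coefs[2L] / res$base_mean[idx],
                                     .DISP_FLOOR), .DISP_CEIL)
    lr <- log(res$disp_mle[idx]) - log(res$disp_trend[idx])
    s_lr <- stats::mad(lr, na.rm = TRUE)
    # subtract the approximate sampling variance of a log dispersion estimate
    m_obs <- 2L * length(conditions)
    p <- ncol(des$full)
    prior_var <- max(s_lr^2 - trigamma((m_obs - p) / 2), 0.25)
    for (i in idx) {
        y <- prep$ys[[i]]
        lt <- log(res$disp_trend[i])
        if (log(res$disp_mle[i]) > lt + 2 * s_lr) {   # outlier: keep MLE
            res$disp_final[i] <- res$disp_mle[i]
            res$outlier[i] <- TRUE
            next
        }
        post <- function(la) .profileApl(la, y, des$full, off) -
            (la - lt)^2 / (2 * prior_var)
        opt <- stats::optimize(post, c(log(.DISP_FLOOR), log(.DISP_CEIL)),
                               maximum = TRUE)
        res$disp_final[i] <- exp(opt$maximum)
    }
    attr(res, "trend_coef") <- c(a0 = unname(coefs[1L]), a1 = unname(coefs[2L]))
    attr(res, "prior_var") <- prior_var
    res
}

.fitTrend <- function(disps, means) {
    if (length(disps) < 10L) {
        med <- if (length(disps)) stats::median(disps) else 0.1
        return(c(max(med, .DISP_FLOOR), 0))
    }
    keep <- rep(TRUE, length(disps))
    coefs <- c(stats::median(disps), 0)
    for (it in 1:10) {
        fit <- tryCatch(
            stats::glm(disps[keep] ~ I(1 / means[keep]),
                       family = stats::Gamma(link = "identity"),
                       start = pmax(coefs, c(1e-4, 1e-4))),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) break
        new_coefs <- pmax(stats::coef(fit), 0)
        pred <- new_coefs[1L] + new_coefs[2L] / means
        ratio <- disps / pmax(pred, .DISP_FLOOR)
        new_keep <- ratio > 1e-4 & ratio < 15
        done <- identical(new_keep, keep) ||
            max(abs(new_coefs - coefs)) < 1e-6 * (max(abs(coefs)) + 1e-6)
        coefs <- new_coefs
        keep <- new_keep
        if (done) break
    }
    if (all(coefs == 0)) coefs <- c(max(stats::median(disps), .DISP_FLOOR), 0)
    coefs
}

## Build this/others response vectors per feature and flag untestable ones.
.prepFeatures <- function(counts, geneIds) {
    n_feat <- nrow(counts)
    status <- rep("ok", n_feat)
    status[rowSums(counts) == 0] <- "all_zero"
    gene_tot <- rowsum(counts, geneIds)
    ys <- vector("list", n_feat)
    testable_per_gene <- table(geneIds[status == "ok"])
    for (i in seq_len(n_feat)) {
        if (status[i] != "ok") next
        if (testable_per_gene[[geneIds[i]]] < 2L) {
            status[i] <- "single_feature"
            next
        }
        others <- gene_tot[geneIds[i], ] - counts[i, ]
        ys[[i]] <- c(as.numeric(others), as.numeric(counts[i, ]))
    }
    list(ys = ys, status = status)
}

#' Likelihood-ratio test of one feature against its gene's remaining counts
#'
#' Fits the full NB log-link GLM (sample effect + bin effect + condition x
#' bin interaction) and the null model without the interaction to the
#' two-row-per-sample data `(others, this)`, both with the supplied
#' dispersion, and compares twice the log-likelihood difference to a
#' chi-squared distribution with `n_conditions - 1` degrees of freedom.
#'
#' @param thisCounts the feature's counts per sample.
#' @param otherCounts per-sample sum of the gene's remaining features.
#' @param conditions condition label per sample.
#' @param dispersion NB dispersion for this feature.
#' @param sizeFactors per-sample size factors (default 1).
#' @return list with `lrt_statistic`, `df`, `p_value`, `converged`.
#' @export
testFeature <- function(thisCounts, otherCounts, conditions, dispersion,
                        sizeFactors = rep(1, length(conditions))) {
    y <- c(as.numeric(otherCounts), as.numeric(thisCounts))
    if (all(y == 0))
        return(list(lrt_statistic = 0, df = length(unique(conditions)) - 1L,
                    p_value = 1, converged = TRUE))
    des <- .designMatrices(conditions)
    off <- rep(log(sizeFactors), 2L)
    f1 <- .nbFit(y, des$full, off, dispersion)
    f0 <- .nbFit(y, des$null, off, dispersion)
    if (!f1$converged || !f0$converged || !is.finite(f1$ll) || !is.finite(f0$ll))
        return(list(lrt_statistic = NA_real_, df = des$df, p_value = 1,
                    converged = FALSE))
    stat <- max(2 * (f1$ll - f0$ll), 0)
    list(lrt_statistic = stat, df = des$df,
         p_value = stats::pchisq(stat, des$df, lower.tail = FALSE),
         converged = TRUE)
}

#' Gene-level q-values from feature p-values
#'
#' Aggregates each gene's feature p-values with the Sidak formula
#' `gene_p = 1 - (1 - min_p)^F` (F = number of tested features), then
#' applies Benjamini-Hochberg across genes. With one feature per gene this
#' reduces exactly to BH of the feature p-values.
#'
#' @param pvalues per-feature p-values (NA = untested).
#' @param genes gene id per feature.
#' @return data.frame with `gene_id`, `n_features`, `min_p`, `gene_p`,
#'   `qvalue`, ordered by `qvalue`.
#' @export
perGeneQValue <- function(pvalues, genes) {
    ok <- !is.na(pvalues)
    if (!any(ok)) return(data.frame(gene_id = character(), n_features = integer(),
                                    min_p = numeric(), gene_p = numeric(),
                                    qvalue = numeric()))
    p <- pvalues[ok]
    g <- as.character(genes[ok])
    minp <- tapply(p, g, min)
    nfeat <- tapply(p, g, length)
    gene_p <- -expm1(nfeat * log1p(-minp))  # 1 - (1 - minp)^F, underflow-safe
    out <- data.frame(gene_id = names(minp),
                      n_features = as.integer(nfeat),
                      min_p = as.numeric(minp),
                      gene_p = as.numeric(gene_p),
                      row.names = NULL)
    out$qvalue <- stats::p.adjust(out$gene_p, method = "BH")
    out[order(out$qvalue, out$gene_id), ]
}

#' Expression filter (DRIMSeq-style)
#'
#' Keeps features with count `>= minFeatureExpr` in at least
#' `minSampsFeatureExpr` samples, within genes whose per-sample total count
#' is `>= minGeneExpr` in at least `minSampsGeneExpr` samples. Opt-in: the
#' default pipeline applies no abundance filtering.
#'
#' @param matrix an annotated [ECCountMatrix-class].
#' @param params list from [filterParams()].
#' @return the filtered matrix.
#' @export
drimseqFilter <- function(matrix, params = filterParams()) {
    cnt <- ecCounts(matrix)
    gid <- ecGenes(matrix)
    if (is.null(gid)) stop("matrix must be gene-annotated")
    gene_tot <- rowsum(cnt, gid)
    gene_ok <- rownames(gene_tot)[
        rowSums(gene_tot >= params$minGeneExpr) >= params$minSampsGeneExpr]
    feat_ok <- rowSums(cnt >= params$minFeatureExpr) >= params$minSampsFeatureExpr
    matrix[feat_ok & gid %in% gene_ok, ]
}

#' @rdname drimseqFilter
#' @param minSampsFeatureExpr,minFeatureExpr,minSampsGeneExpr,minGeneExpr
#'   filter thresholds; defaults follow common practice for 3 vs 3 designs
#'   (feature count >= 10 in >= 3 samples, gene count >= 10 in >= 6
#'   samples).
#' @export
filterParams <- function(minSampsFeatureExpr = 3L, minFeatureExpr = 10L,
                         minSampsGeneExpr = 6L, minGeneExpr = 10L) {
    stopifnot(minSampsFeatureExpr >= 0, minFeatureExpr >= 0,
              minSampsGeneExpr >= 0, minGeneExpr >= 0)
    list(minSampsFeatureExpr = minSampsFeatureExpr,
         minFeatureExpr = minFeatureExpr,
         minSampsGeneExpr = minSampsGeneExpr,
         minGeneExpr = minGeneExpr)
}

#' Run the differential-usage test on a feature count matrix
#'
#' Orchestrates the full count-based test: size factors, optional
#' expression filter, per-feature Cox-Reid dispersion estimation with trend
#' and shrinkage, per-feature likelihood-ratio tests of the
#' condition-by-feature interaction, Benjamini-Hochberg across features,
#' and Sidak/BH gene-level q-values. Deterministic given its inputs.
#'
#' @param object an annotated [ECCountMatrix-class] (or plain count matrix
#'   plus `geneIds`).
#' @param conditions condition label per sample (two or more conditions,
#'   each with >= 2 replicates).
#' @param geneIds per-feature gene ids (only when `object` is a bare
#'   matrix).
#' @param filter `"none"` (default) or `"drimseq"`.
#' @param filterParams thresholds for the drimseq filter.
#' @return list with `features` (per-feature data.frame: key, gene,
#'   dispersion, LRT statistic, df, p, BH-adjusted p, status) and `genes`
#'   (the [perGeneQValue()] table); attribute `size_factors`.
#' @export
runDTU <- function(object, conditions, geneIds = NULL,
                   filter = c("none", "drimseq"),
                   filterParams = ecdtu::filterParams()) {
    filter <- match.arg(filter)
    if (is(object, "ECCountMatrix")) {
        if (is.null(ecGenes(object))) stop("matrix must be gene-annotated")
        if (filter == "drimseq") object <- drimseqFilter(object, filterParams)
        counts <- ecCounts(object)
        geneIds <- ecGenes(object)
    } else {
        counts <- object
        if (is.null(geneIds)) stop("geneIds required for a bare matrix")
        if (filter == "drimseq") {
            m <- drimseqFilter(ECCountMatrix(counts, geneIds = geneIds),
                               filterParams)
            counts <- ecCounts(m)
            geneIds <- ecGenes(m)
        }
    }
    if (length(conditions) != ncol(counts))
        stop("one condition label per sample required")
    if (length(unique(conditions)) < 2L) stop("need >= 2 conditions")
    sf <- computeSizeFactors(counts)
    disp <- fitDispersions(counts, geneIds, conditions, sf)
    prep <- .prepFeatures(counts, geneIds)
    feat <- data.frame(feature_key = rownames(counts), gene_id = geneIds,
                       dispersion = disp$disp_final,
                       lrt_statistic = NA_real_, df = NA_integer_,
                       p_value = NA_real_, status = disp$status,
                       stringsAsFactors = FALSE)
    n <- length(conditions)
    for (i in which(disp$status == "ok")) {
        y <- prep$ys[[i]]
        r <- testFeature(y[n + seq_len(n)], y[seq_len(n)], conditions,
                         disp$disp_final[i], sf)
        feat$lrt_statistic[i] <- r$lrt_statistic
        feat$df[i] <- r$df
        feat$p_value[i] <- r$p_value
        if (!r$converged) feat$status[i] <- "not_converged"
    }
    feat$padj <- NA_real_
    tested <- feat$status == "ok"
    feat$padj[tested] <- stats::p.adjust(feat$p_value[tested], method = "BH")
    genes <- perGeneQValue(feat$p_value[tested], feat$gene_id[tested])
    structure(list(features = feat, genes = genes), size_factors = sf)
}
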