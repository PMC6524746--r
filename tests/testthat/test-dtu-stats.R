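test_that("size factors are median-of-ratios with sensible degenerate behaviour", {
    m <- matrix(c(5L, 9L, 20L, 5L, 9L, 20L), ncol = 2,
                dimnames = list(paste0("f", 1:3), c("a", "b")))
    expect_equal(unname(computeSizeFactors(m)), c(1, 1), tolerance = 1e-12)

    m2 <- cbind(a = c(5L, 9L, 20L), b = c(10L, 18L, 40L))
    sf <- computeSizeFactors(m2)
    expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)

    # hand computation on a 4 x 3 matrix
    m3 <- matrix(c(10, 20, 5, 100,
                   12, 18, 8, 90,
                   9, 25, 4, 110), ncol = 3,
                 dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
    geo <- exp(rowMeans(log(m3)))
    hand <- apply(m3, 2, function(cl) stats::median(cl / geo))
    expect_equal(computeSizeFactors(m3), hand, tolerance = 1e-12)

    # no feature positive everywhere: library-size fallback
    m4 <- cbind(a = c(10L, 0L), b = c(0L, 30L))
    expect_warning(sf4 <- computeSizeFactors(m4), "library-size")
    expect_equal(unname(sf4["b"] / sf4["a"]), 3, tolerance = 1e-12)
})

test_that("dispersion machinery recovers simulated truth and hits the Poisson floor", {
    set.seed(81)
    cond <- rep(c("S1", "S2"), each = 3)
    # NB features at alpha = 0.1: mean final dispersion in [0.05, 0.2]
    nf <- 200L
    gene <- rep(sprintf("g%03d", seq_len(nf / 2)), each = 2)
    mu <- stats::rlnorm(nf, log(100), 0.5)
    m <- matrix(stats::rnbinom(nf * 6L, mu = rep(mu, 6L), size = 10),
                ncol = 6L, dimnames = list(sprintf("f%03d", 1:nf), NULL))
    fit <- fitDispersions(m, gene, cond)
    expect_true(mean(fit$disp_final, na.rm = TRUE) > 0.05)
    expect_true(mean(fit$disp_final, na.rm = TRUE) < 0.2)

    # Poisson counts: final dispersions collapse towards the floor
    mp <- matrix(stats::rpois(nf * 6L, rep(mu, 6L)), ncol = 6L,
                 dimnames = list(sprintf("f%03d", 1:nf), NULL))
    fitp <- fitDispersions(mp, gene, cond)
    expect_lt(stats::median(fitp$disp_final, na.rm = TRUE), 0.01)

    # all-zero features are flagged, not estimated
    mz <- m; mz[1L, ] <- 0L
    fz <- fitDispersions(mz, gene, cond)
    expect_identical(fz$status[1L], "all_zero")
    expect_true(is.na(fz$disp_final[1L]))
})

test_that("Cox-Reid dispersion MLE agrees with a generic-optimizer oracle", {
    set.seed(82)
    cond <- rep(c("S1", "S2"), each = 3)
    des <- ecdtu:::.designMatrices(cond)
    off <- rep(0, 12)
    for (rep in 1:4) {
        y <- stats::rnbinom(12L, mu = rep(stats::rlnorm(1, log(80), 0.3), 12L),
                            size = 8)
        got <- ecdtu:::.dispMLE(y, des$full, off)$alpha
        # oracle: profile the CR-adjusted likelihood, refitting the mean
        # coefficients by generic optimisation at every candidate dispersion
        beta0 <- qr.solve(des$full, log(y + 0.5))
        apl <- function(la) {
            a <- exp(la)
            nll <- function(beta) {
                mu <- exp(pmin(des$full %*% beta, 30))
                -sum(stats::dnbinom(y, size = 1 / a, mu = mu, log = TRUE))
            }
            o <- stats::optim(beta0, nll, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-12))
            mu <- exp(pmin(des$full %*% o$par, 30))
            W <- as.numeric(mu / (1 + a * mu))
            -o$value - 0.5 * as.numeric(determinant(
                crossprod(des$full * sqrt(W)), logarithm = TRUE)$modulus)
        }
        oracle <- exp(stats::optimize(apl, c(log(1e-4), log(2)),
                                      maximum = TRUE, tol = 1e-8)$maximum)
        expect_equal(log(got), log(oracle), tolerance = 1e-3)
    }
})

test_that("the feature LRT is null-calibrated in shape and matches a generic optimiser", {
    cond <- rep(c("S1", "S2"), each = 3)
    # identical this/other profiles in both conditions: statistic ~ 0
    r0 <- testFeature(rep(10, 6), rep(30, 6), cond, dispersion = 0.05)
    expect_lt(r0$lrt_statistic, 1e-6)
    expect_gt(r0$p_value, 0.999)

    # label symmetry under a balanced design
    set.seed(83)
    this <- stats::rnbinom(6, mu = 40, size = 10)
    oth <- stats::rnbinom(6, mu = 120, size = 10)
    a <- testFeature(this, oth, cond, 0.08)
    b <- testFeature(this, oth, rev(cond), 0.08)
    expect_equal(a$lrt_statistic, b$lrt_statistic, tolerance = 1e-6)

    # all-zero feature: p = 1 by convention
    expect_identical(testFeature(rep(0, 6), rep(0, 6), cond, 0.1)$p_value, 1)

    # generic-optimizer oracle for the statistic
    des <- ecdtu:::.designMatrices(cond)
    nll <- function(beta, X, y, a) {
        mu <- exp(pmin(X %*% beta, 30))
        -sum(stats::dnbinom(y, size = 1 / a, mu = mu, log = TRUE))
    }
    for (rep in 1:4) {
        this <- stats::rnbinom(6, mu = 50 * c(1, 1, 1, 2, 2, 2), size = 10)
        oth <- stats::rnbinom(6, mu = 150, size = 10)
        y <- c(oth, this)
        a <- 0.07
        got <- testFeature(this, oth, cond, a)$lrt_statistic
        o1 <- stats::optim(qr.solve(des$full, log(y + 0.5)), nll,
                           X = des$full, y = y, a = a, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14))
        o0 <- stats::optim(qr.solve(des$null, log(y + 0.5)), nll,
                           X = des$null, y = y, a = a, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14))
        oracle <- 2 * (o0$value - o1$value)
        expect_equal(got, oracle, tolerance = 1e-3)
    }
})

test_that("full-model likelihood always dominates the null (LRT non-negative)", {
    set.seed(84)
    cond <- rep(c("S1", "S2"), each = 3)
    for (rep in 1:30) {
        this <- stats::rnbinom(6, mu = stats::runif(1, 2, 80), size = 5)
        oth <- stats::rnbinom(6, mu = stats::runif(1, 2, 300), size = 5)
        r <- testFeature(this, oth, cond, stats::runif(1, 0.01, 1))
        if (is.na(r$lrt_statistic)) next
        expect_gte(r$lrt_statistic, 0)
    }
})

test_that("gene-level aggregation uses the closed-form Sidak formula", {
    # single feature: reduces to the feature p before BH
    g1 <- perGeneQValue(0.01, "g1")
    expect_equal(g1$gene_p, 0.01, tolerance = 1e-12)
    expect_equal(g1$qvalue, 0.01, tolerance = 1e-12)

    # all feature p = 1
    gq <- perGeneQValue(c(1, 1, 1), c("g", "g", "g"))
    expect_identical(gq$qvalue, 1)

    # worked example: 3 features, min p 0.01
    gx <- perGeneQValue(c(0.01, 0.5, 0.9), rep("g", 3))
    expect_equal(gx$gene_p, 1 - 0.99^3, tolerance = 1e-12)
    expect_equal(gx$gene_p, 0.029701, tolerance = 1e-12)

    # one feature per gene: identical to BH across features
    set.seed(85)
    p <- stats::runif(40)
    gq2 <- perGeneQValue(p, paste0("g", seq_along(p)))
    bh <- stats::p.adjust(p, "BH")
    expect_equal(gq2$qvalue[match(paste0("g", seq_along(p)), gq2$gene_id)],
                 unname(bh), tolerance = 1e-12)
})

test_that("the expression filter applies both feature and gene rules", {
    cnt <- rbind(f1 = c(12L, 11L, 10L, 0L, 0L, 0L),
                 f2 = c(0L, 0L, 0L, 2L, 1L, 0L))
    colnames(cnt) <- paste0("s", 1:6)
    m <- ECCountMatrix(cnt, geneIds = c("g1", "g1"))
    kept <- drimseqFilter(m, filterParams(minSampsFeatureExpr = 3,
                                          minFeatureExpr = 10,
                                          minSampsGeneExpr = 3,
                                          minGeneExpr = 10))
    expect_identical(ecKeys(kept), "f1")

    z <- ECCountMatrix(matrix(0L, 3, 6, dimnames = list(paste0("f", 1:3),
                                                        paste0("s", 1:6))),
                       geneIds = rep("g", 3))
    expect_identical(nrow(drimseqFilter(z)), 0L)

    # brute-force double loop over the two rules
    set.seed(86)
    for (rep in 1:10) {
        cnt <- matrix(stats::rnbinom(60, mu = 8, size = 2), nrow = 10,
                      dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
        genes <- sample(c("gA", "gB", "gC"), 10, replace = TRUE)
        pars <- filterParams(sample(1:4, 1), sample(c(5L, 10L), 1),
                             sample(1:6, 1), sample(c(5L, 10L), 1))
        got <- ecKeys(drimseqFilter(ECCountMatrix(cnt, geneIds = genes), pars))
        keep <- logical(10)
        for (i in 1:10) {
            gene_cnt <- colSums(cnt[genes == genes[i], , drop = FALSE])
            gene_ok <- sum(gene_cnt >= pars$minGeneExpr) >= pars$minSampsGeneExpr
            feat_ok <- sum(cnt[i, ] >= pars$minFeatureExpr) >=
                pars$minSampsFeatureExpr
            keep[i] <- gene_ok && feat_ok
        }
        expect_setequal(got, rownames(cnt)[keep])
    }
})

test_that("runDTU is deterministic and ranks a hard switch first", {
    set.seed(87)
    nm <- nullFeatureMatrix(40L)
    cond <- rep(c("S1", "S2"), each = 3)
    r1 <- runDTU(nm$counts, cond, geneIds = nm$gene)
    r2 <- runDTU(nm$counts, cond, geneIds = nm$gene)
    expect_identical(r1, r2)

    # plant one gene with a hard isoform switch at 10x coverage
    hot <- rbind(h1 = c(400L, 380L, 410L, 40L, 38L, 45L),
                 h2 = c(42L, 39L, 41L, 395L, 405L, 390L))
    colnames(hot) <- colnames(nm$counts)
    m <- rbind(nm$counts, hot)
    g <- c(nm$gene, "gHOT", "gHOT")
    res <- runDTU(m, cond, geneIds = g)
    expect_identical(res$genes$gene_id[1L], "gHOT")
    expect_lt(res$genes$qvalue[1L], 1e-6)

    # single-feature genes are reported untested
    ms <- rbind(nm$counts[1:3, ], lonely = c(50L, 60L, 55L, 45L, 52L, 58L))
    gs <- c(nm$gene[1:3], "gLON")
    rs <- runDTU(ms, cond, geneIds = gs)
    expect_identical(rs$features$status[rs$features$gene_id == "gLON"],
                     "single_feature")
    expect_false("gLON" %in% rs$genes$gene_id)
})
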