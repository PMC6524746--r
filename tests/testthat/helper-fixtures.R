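# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# Two genes on one chromosome: gA with transcripts tA1/tA2 sharing exon 1,
# gB single-transcript. Coordinates chosen by hand so expected bins and
# sequences are easy to reason about.
tinyAnnotation <- function() {
    exons <- GenomicRanges::GRangesList(
        tA1 = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(101, 301), c(200, 400)), strand = "+"),
        tA2 = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(101, 501), c(200, 650)), strand = "+"),
        tB1 = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(2001, 2300), strand = "+"))
    TranscriptAnnotation(exons, c(tA1 = "gA", tA2 = "gA", tB1 = "gB"))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# A random RawECTable over nTx transcripts for merge/matrix property tests.
randomECTable <- function(sampleId, nTx = 8L, nEc = 12L, maxCount = 50L) {
    txs <- sprintf("t%02d", seq_len(nTx))
    keys <- character(0)
    subsets <- list()
    while (length(subsets) < nEc) {
        s <- sort(sample(nTx, sample(1:3, 1L)))
        k <- paste(s, collapse = ",")
        if (k %in% keys) next
        keys <- c(keys, k)
        subsets[[length(subsets) + 1L]] <- s
    }
    RawECTable(sampleId, txs, subsets, sample(0:maxCount, nEc, replace = TRUE))
}

# Toy transcriptome via the simulator at small scale; k small enough for
# short exons.
toySim <- function(seed, nGenes = 5L, k = 11L, depth = 5e3) {
    cfg <- simConfig(nGenes = nGenes, isoformsPerGene = c(1L, 3L),
                     exonsPerGene = c(2L, 5L), exonLength = c(60L, 200L),
                     readLength = 50L, depth = depth, nbDispersion = 0.02,
                     propDtu = 0.2, nReplicates = 3L, k = k, seed = seed)
    list(cfg = cfg, sim = simulateTranscriptome(cfg))
}

# Null NB feature matrix: genes with 2..6 features, identical means in all
# samples. Used for calibration checks.
nullFeatureMatrix <- function(nGenes, nSamp = 6L, disp = 0.05,
                              meanlog = log(50), sdlog = 1) {
    nf <- sample(2:6, nGenes, replace = TRUE)
    gene <- rep(sprintf("g%04d", seq_len(nGenes)), nf)
    mu <- stats::rlnorm(length(gene), meanlog, sdlog)
    m <- matrix(stats::rnbinom(length(gene) * nSamp, mu = rep(mu, nSamp),
                               size = 1 / disp), ncol = nSamp)
    rownames(m) <- sprintf("f%05d", seq_along(gene))
    colnames(m) <- paste0("s", seq_len(nSamp))
    list(counts = m, gene = gene)
}

# Memoised default-design ("switch-mini") dataset shared by the acceptance checks that all
# run on the same simulated study.
.acc_cache <- new.env(parent = emptyenv())
switchMiniDataset <- function() {
    if (is.null(.acc_cache$ds)) {
        cfg <- simConfig(seed = 20260928L)
        .acc_cache$cfg <- cfg
        .acc_cache$ds <- simulateDataset(cfg, what = c("ec", "reads"))
    }
    list(cfg = .acc_cache$cfg, ds = .acc_cache$ds)
}
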