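test_that("transcriptome simulation respects configuration and is deterministic", {
    # degenerate config: one gene, one isoform, one exon
    cfg1 <- simConfig(nGenes = 1L, isoformsPerGene = c(1L, 1L),
                      exonsPerGene = c(1L, 1L), exonLength = c(150L, 150L),
                      readLength = 50L, depth = 100, seed = 91L)
    s1 <- simulateTranscriptome(cfg1)
    expect_length(s1$sequences, 1L)
    expect_identical(nchar(s1$sequences[[1L]]), 150L)

    # infeasible: 5 isoforms cannot come from 2 exons
    expect_error(simConfig(isoformsPerGene = c(5L, 5L),
                           exonsPerGene = c(2L, 2L)), "infeasible")

    # same seed, same output
    cfg <- simConfig(nGenes = 15L, seed = 92L)
    a <- simulateTranscriptome(cfg)
    b <- simulateTranscriptome(cfg)
    expect_identical(a$sequences, b$sequences)
    expect_identical(exonsBy(a$annotation), exonsBy(b$annotation))

    # config conformance over a 50-gene draw
    cfg50 <- simConfig(nGenes = 50L, seed = 93L)
    s50 <- simulateTranscriptome(cfg50)
    iso <- table(txGeneMap(s50$annotation))
    expect_true(all(iso >= cfg50$isoformsPerGene[1L] &
                    iso <= cfg50$isoformsPerGene[2L]))
    n_ex <- lengths(exonsBy(s50$annotation))
    expect_true(all(n_ex <= cfg50$exonsPerGene[2L]))
    w <- unlist(lapply(exonsBy(s50$annotation), GenomicRanges::width))
    expect_true(all(w >= cfg50$exonLength[1L] & w <= cfg50$exonLength[2L]))
})

test_that("abundances normalise per gene and follow the configured distributions", {
    cfg <- simConfig(nGenes = 40L, seed = 94L)
    sim <- simulateTranscriptome(cfg)
    ab <- assignAbundances(cfg, sim$annotation)
    sums <- tapply(ab$prop, ab$gene_id, sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
    single <- names(which(table(ab$gene_id) == 1L))
    expect_true(all(abs(ab$prop[ab$gene_id %in% single] - 1) < 1e-12))

    # distributional check: gene-weight CV matches the log-normal CV
    cfgBig <- simConfig(nGenes = 4000L, isoformsPerGene = c(1L, 2L),
                        exonsPerGene = c(1L, 2L), exonLength = c(60L, 100L),
                        seed = 95L)
    simBig <- simulateTranscriptome(cfgBig)
    abBig <- assignAbundances(cfgBig, simBig$annotation)
    gw <- abBig$gene_weight[!duplicated(abBig$gene_id)]
    cv_expected <- sqrt(exp(cfgBig$geneSdlog^2) - 1)   # lognormal CV
    se <- cv_expected / sqrt(2 * (length(gw) - 1))     # rough SE of a CV
    expect_lt(abs(stats::sd(gw) / mean(gw) - cv_expected), 5 * se + 0.05)
})

test_that("the isoform switch exchanges the top two proportions and conserves totals", {
    ab <- data.frame(gene_id = rep("g", 3),
                     transcript_id = c("t1", "t2", "t3"),
                     gene_weight = 1, prop = c(0.6, 0.3, 0.1))
    sw <- applyDtuSwitch(ab, "g")
    expect_equal(sw$prop, c(0.3, 0.6, 0.1), tolerance = 1e-12)

    # switching equal proportions changes nothing
    ab2 <- data.frame(gene_id = "g", transcript_id = c("a", "b"),
                      gene_weight = 1, prop = c(0.5, 0.5))
    expect_equal(applyDtuSwitch(ab2, "g")$prop, c(0.5, 0.5))

    expect_error(applyDtuSwitch(
        data.frame(gene_id = "g", transcript_id = "t", gene_weight = 1,
                   prop = 1), "g"), "single isoform")

    # random gene set: per-gene sums preserved; other genes bit-identical
    cfg <- simConfig(nGenes = 30L, seed = 96L)
    sim <- simulateTranscriptome(cfg)
    abr <- assignAbundances(cfg, sim$annotation)
    dtu <- selectDtuGenes(cfg, abr)
    swr <- applyDtuSwitch(abr, dtu)
    expect_equal(tapply(swr$prop, swr$gene_id, sum),
                 tapply(abr$prop, abr$gene_id, sum), tolerance = 1e-12)
    untouched <- !(abr$gene_id %in% dtu)
    expect_identical(swr$prop[untouched], abr$prop[untouched])
    expect_true(all(dtu %in% names(which(table(abr$gene_id) >= 2L))))
})

test_that("replicate counts follow the NB model and reads are fully ledgered", {
    cfg <- simConfig(nGenes = 8L, isoformsPerGene = c(1L, 2L),
                     exonsPerGene = c(2L, 4L), exonLength = c(80L, 150L),
                     readLength = 60L, depth = 2e4, nbDispersion = 0,
                     propDtu = 0, nReplicates = 10L, k = 11L, seed = 97L)
    ds <- simulateDataset(cfg, what = character(0))
    # Poisson limit: variance/mean across replicates near 1
    vm <- apply(ds$txCounts, 1L, function(x) stats::var(x) / mean(x))
    vm <- vm[is.finite(vm)]
    expect_lt(abs(mean(vm) - 1), 0.15)

    # empirical means within 3 SE of depth x abundance (20 replicates)
    cfg2 <- simConfig(nGenes = 8L, isoformsPerGene = c(1L, 2L),
                      exonsPerGene = c(2L, 4L), exonLength = c(80L, 150L),
                      readLength = 60L, depth = 2e4, nbDispersion = 0.05,
                      propDtu = 0, nReplicates = 20L, k = 11L, seed = 98L)
    ds2 <- simulateDataset(cfg2, what = character(0))
    pr <- truthProportions(ds2$truth)
    mu <- pr$expected_count_cond1
    obs <- rowMeans(ds2$txCounts[pr$transcript_id, 1:20])
    se <- sqrt((mu + cfg2$nbDispersion * mu^2) / 20)
    ok <- mu > 5
    expect_true(all(abs(obs[ok] - mu[ok]) <= 3.5 * se[ok]))

    # determinism: same config, same reads
    cfg3 <- simConfig(nGenes = 4L, isoformsPerGene = c(1L, 2L),
                      exonsPerGene = c(2L, 3L), exonLength = c(80L, 120L),
                      readLength = 50L, depth = 2e3, nReplicates = 2L,
                      k = 11L, seed = 99L)
    r1 <- {
        sim <- simulateTranscriptome(cfg3)
        ab <- assignAbundances(cfg3, sim$annotation)
        tr <- ecdtu:::.makeTruth(cfg3, ab, ab, character(0))
        simulateReads(sim, tr, cfg3, emitSequences = TRUE)
    }
    r2 <- {
        sim <- simulateTranscriptome(cfg3)
        ab <- assignAbundances(cfg3, sim$annotation)
        tr <- ecdtu:::.makeTruth(cfg3, ab, ab, character(0))
        simulateReads(sim, tr, cfg3, emitSequences = TRUE)
    }
    expect_identical(r1$reads, r2$reads)
    expect_identical(r1$sources, r2$sources)

    # ledger completeness: every emitted read appears exactly once
    expect_false(anyDuplicated(r1$sources$read_id) > 0)
    expect_identical(nrow(r1$sources), sum(r1$txCounts))
    expect_identical(sort(unlist(lapply(r1$reads, names), use.names = FALSE)),
                     sort(r1$sources$read_id))
})

test_that("fast-path EC counts put mass where sequence sharing dictates", {
    # single-transcript gene: all mass in the singleton class
    set.seed(100)
    seqs <- c(t1 = randomSeq(300))
    exons <- GenomicRanges::GRangesList(
        t1 = GenomicRanges::GRanges("c", IRanges::IRanges(1, 300), strand = "+"))
    sim <- list(annotation = TranscriptAnnotation(exons, c(t1 = "g1")),
                sequences = seqs)
    cfg <- simConfig(nGenes = 1L, isoformsPerGene = c(1L, 1L),
                     exonsPerGene = c(1L, 1L), readLength = 50L,
                     depth = 1000, nReplicates = 1L, k = 11L, propDtu = 0,
                     seed = NULL)
    tr <- SimTruth(character(0),
                   data.frame(gene_id = "g1", transcript_id = "t1",
                              prop_cond1 = 1, prop_cond2 = 1,
                              expected_count_cond1 = 1000,
                              expected_count_cond2 = 1000))
    ec <- simulateECCounts(sim, tr, cfg)
    expect_identical(nrow(ec$matrix), 1L)
    expect_identical(ecKeys(ec$matrix), "t1")
    expect_identical(unname(colSums(ecCounts(ec$matrix))),
                     unname(colSums(ec$txCounts)))

    # two identical sequences: all mass in the pair class
    seqs2 <- c(t1 = seqs[["t1"]], t2 = seqs[["t1"]])
    exons2 <- GenomicRanges::GRangesList(
        t1 = GenomicRanges::GRanges("c", IRanges::IRanges(1, 300), strand = "+"),
        t2 = GenomicRanges::GRanges("c", IRanges::IRanges(1, 300), strand = "+"))
    sim2 <- list(annotation = TranscriptAnnotation(exons2,
                                                   c(t1 = "g1", t2 = "g1")),
                 sequences = seqs2)
    tr2 <- SimTruth(character(0),
                    data.frame(gene_id = "g1", transcript_id = c("t1", "t2"),
                               prop_cond1 = 0.5, prop_cond2 = 0.5,
                               expected_count_cond1 = 500,
                               expected_count_cond2 = 500))
    ec2 <- simulateECCounts(sim2, tr2, cfg)
    expect_identical(ecKeys(ec2$matrix), "t1|t2")
})

test_that("fast-path and read-path EC count distributions agree", {
    ts <- toySim(102, nGenes = 5L, depth = 2.5e4)
    cfg <- ts$cfg
    sim <- simulateTranscriptome(cfg)
    ab <- assignAbundances(cfg, sim$annotation)
    tr <- ecdtu:::.makeTruth(cfg, ab, ab, character(0))
    set.seed(1021)
    txc <- drawTranscriptCounts(tr, cfg)[, 1L, drop = FALSE]  # one sample
    idx <- buildKmerIndex(sim$sequences, k = cfg$k)
    set.seed(1022)
    fast <- simulateECCounts(sim, tr, cfg, txCounts = txc, index = idx)
    set.seed(1023)
    rd <- simulateReads(sim, tr, cfg, emitSequences = TRUE, txCounts = txc)
    tab <- pseudoalignSample(rd$reads[[1L]], idx, sampleId = "S1R1")
    slow_keys <- vapply(tab@subsets, function(s)
        canonicalKey(tab@transcripts[s]), "")
    slow <- structure(tab@counts, names = slow_keys)
    fastv <- structure(ecCounts(fast$matrix)[, 1L], names = ecKeys(fast$matrix))
    expect_identical(sum(fastv), sum(slow))
    N <- sum(fastv)
    keys <- union(names(fastv), names(slow))
    for (k in keys) {
        pf <- ifelse(is.na(fastv[k]), 0, fastv[k]) / N
        ps <- ifelse(is.na(slow[k]), 0, slow[k]) / N
        p <- (pf + ps) / 2
        se <- sqrt(2 * p * (1 - p) / N) + 1e-9
        expect_lt(abs(pf - ps), 4 * se + 2 / N)
    }
})

test_that("a simulated dataset round-trips through its on-disk layout", {
    cfg <- simConfig(nGenes = 6L, isoformsPerGene = c(1L, 3L),
                     exonsPerGene = c(2L, 4L), exonLength = c(80L, 150L),
                     readLength = 50L, depth = 3e3, nReplicates = 2L,
                     k = 11L, seed = 103L)
    ds <- simulateDataset(cfg, what = "ec")
    sim <- list(annotation = ds$annotation, sequences = ds$sequences)
    rd <- simulateReads(sim, ds$truth, cfg, emitSequences = TRUE,
                        txCounts = ds$txCounts)
    d <- withr::local_tempdir()
    writeSimulation(ds, d, reads = rd)
    expect_true(all(file.exists(file.path(d,
        c("transcripts.fasta", "genes.gtf", "t2g.tsv", "truth.tsv",
          "samples.tsv", "reads_truth.tsv", "S1R1.fastq")))))
    seqs <- readFastaSeqs(file.path(d, "transcripts.fasta"))
    expect_identical(as.character(seqs), ds$sequences)
    t2g <- readT2G(file.path(d, "t2g.tsv"))
    expect_identical(t2g, txGeneMap(ds$annotation))
    st <- readSampleTable(file.path(d, "samples.tsv"))
    expect_identical(st$sample, ds$samples)
})
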