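## Ground-truth simulator for the isoform-switch DTU design: a toy
## transcriptome on a synthetic chromosome, log-normal gene expression with
## Dirichlet isoform proportions, DTU induced in a chosen fraction of genes
## by exchanging the expression of the two most abundant transcripts,
## negative-binomial replicate noise, and error-free fixed-length reads with
## genomic truth coordinates.

#' Simulation configuration
#'
#' Defaults are the "switch-mini" design: a two-group comparison with
#' three replicates per condition, 10% of genes given DTU by switching the
#' two most abundant transcripts, negative-binomial count noise and
#' error-free 100 bp single-end reads, sized so the full pipeline runs in
#' minutes (200 genes, 400k reads per sample).
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene integer range (min, max) of isoforms per gene.
#' @param exonsPerGene integer range of exons per gene.
#' @param exonLength integer range of exon lengths (bases).
#' @param readLength read length in bases.
#' @param depth expected reads per sample.
#' @param nbDispersion negative-binomial dispersion of replicate counts
#'   (variance = mu + disp * mu^2).
#' @param propDtu fraction of genes selected for an isoform switch.
#' @param nReplicates replicates per condition.
#' @param k k-mer length of the built-in pseudo-aligner.
#' @param intronLength integer range of intron lengths.
#' @param geneGap gap between adjacent genes on the synthetic chromosome.
#' @param overlapFraction fraction of genes laid out overlapping their
#'   neighbour on the same strand (exercises the exon-bin exclusion rule).
#' @param geneMeanlog,geneSdlog log-normal parameters of relative gene
#'   expression.
#' @param seed seed used by [simulateDataset()].
#' @return a list of class `sim_config`.
#' @export
simConfig <- function(nGenes = 200L, isoformsPerGene = c(2L, 5L),
                      exonsPerGene = c(3L, 12L), exonLength = c(100L, 600L),
                      readLength = 100L, depth = 4e5, nbDispersion = 0.05,
                      propDtu = 0.1, nReplicates = 3L, k = 31L,
                      intronLength = c(100L, 500L), geneGap = 1000L,
                      overlapFraction = 0, geneMeanlog = 0, geneSdlog = 1,
                      seed = 1L) {
    stopifnot(nGenes >= 1, all(isoformsPerGene >= 1), all(exonsPerGene >= 1),
              all(exonLength >= 1), readLength >= 1, depth > 0,
              nbDispersion >= 0, propDtu >= 0, propDtu <= 1, nReplicates >= 1)
    if (2^(exonsPerGene[1L] - 1L) < isoformsPerGene[1L])
        stop("infeasible config: cannot build ", isoformsPerGene[1L],
             " distinct isoforms from ", exonsPerGene[1L], " exons")
    structure(list(nGenes = as.integer(nGenes),
                   isoformsPerGene = as.integer(isoformsPerGene),
                   exonsPerGene = as.integer(exonsPerGene),
                   exonLength = as.integer(exonLength),
                   readLength = as.integer(readLength), depth = depth,
                   nbDispersion = nbDispersion, propDtu = propDtu,
                   nReplicates = as.integer(nReplicates), k = as.integer(k),
                   intronLength = as.integer(intronLength),
                   geneGap = as.integer(geneGap),
                   overlapFraction = overlapFraction,
                   geneMeanlog = geneMeanlog, geneSdlog = geneSdlog,
                   seed = if (is.null(seed)) NULL else as.integer(seed)),
              class = "sim_config")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## sample() treats a length-1 vector as 1:x; draw from an inclusive integer
## range safely.
.sampleRange <- function(lo, hi, n = 1L) {
    if (lo == hi) rep(as.integer(lo), n)
    else sample(lo:hi, n, replace = TRUE)
}

#' Simulate a toy annotated transcriptome
#'
#' Lays genes on one synthetic chromosome (non-overlapping unless
#' `overlapFraction > 0`), draws exon counts/lengths from the configured
#' ranges, and builds isoforms as distinct exon subsets that all share one
#' anchor exon; when the gene has enough exons, every isoform additionally
#' receives a private exon so each has a unique region. Exon sequences are
#' uniform random ACGT.
#'
#' @param config a [simConfig()]; if `config$seed` is non-NULL the RNG is
#'   seeded with it.
#' @return list with `annotation` (a [TranscriptAnnotation-class]) and
#'   `sequences` (named character vector of spliced transcript sequences).
#' @export
simulateTranscriptome <- function(config) {
    if (length(config$seed)) set.seed(config$seed)
    exons_l <- list()
    txGene <- character(0)
    seqs <- character(0)
    cursor <- 1L
    prev_end <- NA_integer_
    for (g in seq_len(config$nGenes)) {
        gid <- sprintf("g%04d", g)
        n_ex <- .sampleRange(config$exonsPerGene[1L], config$exonsPerGene[2L])
        ex_len <- .sampleRange(config$exonLength[1L], config$exonLength[2L], n_ex)
        if (config$overlapFraction > 0 && g > 1L &&
            stats::runif(1) < config$overlapFraction)
            cursor <- max(prev_end - ex_len[1L], 1L)  # overlap previous gene
        starts <- integer(n_ex)
        pos <- cursor
        for (j in seq_len(n_ex)) {
            starts[j] <- pos
            pos <- pos + ex_len[j] +
                .sampleRange(config$intronLength[1L], config$intronLength[2L])
        }
        prev_end <- starts[n_ex] + ex_len[n_ex] - 1L
        cursor <- prev_end + config$geneGap
        ex_seq <- vapply(ex_len, .randSeq, "")
        n_iso <- .sampleRange(config$isoformsPerGene[1L], config$isoformsPerGene[2L])
        n_iso <- min(n_iso, 2^(n_ex - 1L))
        subsets <- .drawIsoforms(n_ex, n_iso)
        for (i in seq_len(n_iso)) {
            tid <- sprintf("%s.t%d", gid, i)
            sel <- subsets[[i]]
            exons_l[[tid]] <- GRanges("chrS",
                IRanges(starts[sel], width = ex_len[sel]), strand = "+")
            txGene[tid] <- gid
            seqs[tid] <- paste(ex_seq[sel], collapse = "")
        }
    }
    list(annotation = TranscriptAnnotation(GRangesList(exons_l), txGene),
         sequences = seqs)
}

## Distinct exon subsets, all containing exon 1 (the anchor). When there are
## enough non-anchor exons, isoform i gets private exon i+1 (absent from all
## others); remaining exons are included independently at random.
.drawIsoforms <- function(n_ex, n_iso) {
    anchor <- 1L
    private <- if (n_ex - 1L >= n_iso) 1L + seq_len(n_iso) else integer(0)
    free <- setdiff(seq_len(n_ex), c(anchor, private))
    for (attempt in 1:100) {
        subsets <- lapply(seq_len(n_iso), function(i) {
            s <- anchor
            if (length(private)) s <- c(s, private[i])
            if (length(free))
                s <- c(s, free[stats::runif(length(free)) < 0.5])
            sort(s)
        })
        keys <- vapply(subsets, paste, "", collapse = ",")
        if (!anyDuplicated(keys)) return(subsets)
    }
    # fall back to systematic enumeration of distinct subsets
    all_sub <- lapply(0:(2^(n_ex - 1L) - 1L), function(m)
        sort(c(anchor, (2:n_ex)[bitwAnd(m, 2^(0:(n_ex - 2L))) > 0])))
    all_sub[seq_len(n_iso)]
}

#' Baseline expression and isoform proportions
#'
#' Draws relative gene expression from a log-normal and isoform
#' proportions within each gene from a symmetric Dirichlet, so "two most
#' abundant transcripts" is well defined (ties broken by transcript id).
#'
#' @param config a [simConfig()].
#' @param annotation a [TranscriptAnnotation-class].
#' @return data.frame with `gene_id`, `transcript_id`, `gene_weight`
#'   (relative gene expression, summing to 1 over genes) and `prop`
#'   (isoform proportion, summing to 1 within each gene).
#' @export
assignAbundances <- function(config, annotation) {
    txg <- txGeneMap(annotation)
    genes <- unique(txg)
    gw <- stats::rlnorm(length(genes), config$geneMeanlog, config$geneSdlog)
    gw <- gw / sum(gw)
    names(gw) <- genes
    ab <- data.frame(gene_id = unname(txg), transcript_id = names(txg),
                     stringsAsFactors = FALSE)
    ab <- ab[order(ab$gene_id, ab$transcript_id), ]
    prop <- unlist(lapply(split(ab$transcript_id, ab$gene_id), function(txs) {
        x <- stats::rgamma(length(txs), shape = 2, rate = 1)
        x / sum(x)
    }), use.names = FALSE)
    ab$gene_weight <- gw[ab$gene_id]
    ab$prop <- prop
    rownames(ab) <- NULL
    ab
}

#' Select DTU genes
#'
#' Uniform draw among genes with at least two expressed isoforms.
#'
#' @param config a [simConfig()].
#' @param abundances from [assignAbundances()].
#' @return character vector of gene ids.
#' @export
selectDtuGenes <- function(config, abundances) {
    eligible <- names(which(table(abundances$gene_id[abundances$prop > 0]) >= 2L))
    n_dtu <- round(config$propDtu * length(unique(abundances$gene_id)))
    if (n_dtu > length(eligible))
        stop("not enough multi-isoform genes for the requested DTU fraction")
    sort(sample(eligible, n_dtu))
}

#' Apply the isoform switch to build condition-2 abundances
#'
#' For each DTU gene, the proportions of the two most abundant transcripts
#' are exchanged; every other transcript and every non-DTU gene is
#' unchanged, so per-gene totals are identical across conditions (DTU
#' without differential gene expression).
#'
#' @param abundances from [assignAbundances()].
#' @param dtuGenes genes to switch; each must have >= 2 isoforms.
#' @return abundances data.frame with switched `prop`.
#' @export
applyDtuSwitch <- function(abundances, dtuGenes) {
    out <- abundances
    for (g in dtuGenes) {
        idx <- which(out$gene_id == g)
        if (length(idx) < 2L)
            stop("gene ", g, " has a single isoform and cannot be switched")
        ord <- idx[order(-out$prop[idx], out$transcript_id[idx])]
        top2 <- ord[1:2]
        out$prop[top2] <- out$prop[rev(top2)]
    }
    out
}

.sampleNames <- function(config)
    paste0(rep(c("S1", "S2"), each = config$nReplicates), "R",
           rep(seq_len(config$nReplicates), 2L))

.sampleConditions <- function(config)
    rep(c("S1", "S2"), each = config$nReplicates)

## Expected reads per transcript and replicate for each condition.
.expectedCounts <- function(config, ab1, ab2) {
    cbind(cond1 = config$depth * ab1$gene_weight * ab1$prop,
          cond2 = config$depth * ab2$gene_weight * ab2$prop)
}

#' Draw per-replicate transcript read counts
#'
#' `count ~ NB(mean = depth x relative abundance, dispersion)` per
#' transcript and replicate; `dispersion = 0` gives the Poisson limit.
#'
#' @param truth a [SimTruth-class] (carries expected per-replicate counts).
#' @param config a [simConfig()].
#' @return integer matrix transcripts x samples (columns `S1R1..S2Rn`).
#' @export
drawTranscriptCounts <- function(truth, config) {
    pr <- truthProportions(truth)
    mu <- cbind(matrix(rep(pr$expected_count_cond1, config$nReplicates),
                       ncol = config$nReplicates),
                matrix(rep(pr$expected_count_cond2, config$nReplicates),
                       ncol = config$nReplicates))
    cnt <- if (config$nbDispersion > 0)
        matrix(stats::rnbinom(length(mu), mu = mu,
                              size = 1 / config$nbDispersion), nrow = nrow(mu))
    else matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    storage.mode(cnt) <- "integer"
    dimnames(cnt) <- list(pr$transcript_id, .sampleNames(config))
    cnt
}

.makeTruth <- function(config, ab1, ab2, dtu) {
    ec <- .expectedCounts(config, ab1, ab2)
    SimTruth(dtu, data.frame(gene_id = ab1$gene_id,
                             transcript_id = ab1$transcript_id,
                             prop_cond1 = ab1$prop, prop_cond2 = ab2$prop,
                             expected_count_cond1 = ec[, 1L],
                             expected_count_cond2 = ec[, 2L],
                             stringsAsFactors = FALSE))
}

#' Simulate error-free reads with genomic truth coordinates
#'
#' Per replicate and transcript, draws an NB count, then uniform read start
#' positions; every read carries its source transcript and offset, and its
#' spliced genomic interval for exon-bin counting. Transcripts shorter than
#' the read length are excluded from sampling with a warning.
#'
#' @param sim output of [simulateTranscriptome()].
#' @param truth a [SimTruth-class].
#' @param config a [simConfig()].
#' @param emitSequences materialise read sequences (needed for
#'   pseudo-alignment of the reads; the exon-bin branch only needs the
#'   genomic intervals).
#' @param txCounts optional precomputed transcript count matrix from
#'   [drawTranscriptCounts()] (lets the read-level and fast equivalence
#'   class paths share one count draw).
#' @return list with `sources` (data.frame `read_id`, `sample`,
#'   `transcript_id`, `offset` (1-based start)), `alignments` (`GRanges`
#'   blocks with `read_id`, `sample`, `gene_id`), `reads` (named list of
#'   per-sample named character vectors, or NULL), `txCounts` and `truth`
#'   (with read sources filled in).
#' @export
simulateReads <- function(sim, truth, config, emitSequences = FALSE,
                          txCounts = NULL) {
    ann <- sim$annotation
    L <- transcriptLengths(ann)
    if (is.null(txCounts)) txCounts <- drawTranscriptCounts(truth, config)
    short <- names(L)[L < config$readLength]
    if (length(short)) {
        warning(length(short), " transcript(s) shorter than the read length ",
                "excluded from sampling")
        txCounts[short, ] <- 0L
    }
    txg <- txGeneMap(ann)
    samples <- colnames(txCounts)
    src_l <- list()
    for (s in samples) {
        n_t <- txCounts[, s]
        tx <- rep(rownames(txCounts), n_t)
        off <- floor(stats::runif(length(tx)) *
                         (L[tx] - config$readLength + 1)) + 1L
        src_l[[s]] <- data.frame(
            read_id = sprintf("%s_r%06d", s, seq_along(tx)),
            sample = s, transcript_id = tx, offset = as.integer(off),
            stringsAsFactors = FALSE)
    }
    sources <- do.call(rbind, src_l)
    rownames(sources) <- NULL
    aln <- .readsToGenome(ann, sources, config$readLength)
    aln$gene_id <- unname(txg[aln$transcript_id])
    reads <- NULL
    if (emitSequences) {
        reads <- lapply(split(sources, sources$sample), function(df) {
            structure(substring(sim$sequences[df$transcript_id], df$offset,
                                df$offset + config$readLength - 1L),
                      names = df$read_id)
        })[samples]
    }
    truth@readSources <- sources
    list(sources = sources, alignments = aln, reads = reads,
         txCounts = txCounts, truth = truth)
}

## Map transcript-coordinate reads to spliced genomic blocks. Accumulates
## plain vectors per (transcript, exon) chunk and builds one GRanges at the
## end.
.readsToGenome <- function(annotation, sources, readLength) {
    idx_by_tx <- split(seq_len(nrow(sources)), sources$transcript_id)
    acc <- list()
    for (tx in names(idx_by_tx)) {
        ex <- annotation@exons[[tx]]
        w <- GenomicRanges::width(ex)
        cumend <- cumsum(w)
        cumstart <- c(0L, cumend[-length(cumend)])
        ii <- idx_by_tx[[tx]]
        s <- sources$offset[ii]
        e <- s + readLength - 1L
        ex_start <- GenomicRanges::start(ex)
        for (j in seq_along(ex)) {
            bs <- pmax(s, cumstart[j] + 1L)
            be <- pmin(e, cumend[j])
            keep <- which(bs <= be)
            if (!length(keep)) next
            acc[[length(acc) + 1L]] <- list(
                chrom = as.character(seqnames(ex))[1L],
                strand = as.character(strand(ex))[1L],
                start = ex_start[j] + bs[keep] - cumstart[j] - 1L,
                end = ex_start[j] + be[keep] - cumstart[j] - 1L,
                row = ii[keep], tx = tx)
        }
    }
    n_per <- vapply(acc, function(a) length(a$start), 0L)
    rows <- unlist(lapply(acc, `[[`, "row"), use.names = FALSE)
    GRanges(rep(vapply(acc, `[[`, "", "chrom"), n_per),
            IRanges(unlist(lapply(acc, `[[`, "start"), use.names = FALSE),
                    unlist(lapply(acc, `[[`, "end"), use.names = FALSE)),
            strand = rep(vapply(acc, `[[`, "", "strand"), n_per),
            read_id = sources$read_id[rows],
            sample = sources$sample[rows],
            transcript_id = rep(vapply(acc, `[[`, "", "tx"), n_per))
}

#' Fast-path simulation of equivalence-class counts
#'
#' Skips read generation: every read start position of every transcript is
#' pseudo-aligned once (via the k-mer index), giving per-transcript EC
#' probability vectors; per sample, the NB transcript counts are then
#' distributed over classes multinomially. The resulting count
#' distribution matches pseudo-aligning [simulateReads()] output in
#' expectation, at a fraction of the cost.
#'
#' @inheritParams simulateReads
#' @param index optional prebuilt [KmerIndex-class] over `sim$sequences`.
#' @return list with `matrix` (an unannotated [ECCountMatrix-class]),
#'   `txCounts` and `truth`.
#' @export
simulateECCounts <- function(sim, truth, config, txCounts = NULL,
                             index = NULL) {
    if (is.null(index)) index <- buildKmerIndex(sim$sequences, k = config$k)
    if (is.null(txCounts)) txCounts <- drawTranscriptCounts(truth, config)
    pos <- .cpp_position_sets(index@ptr, unname(as.character(sim$sequences)),
                              config$readLength)
    sets <- lapply(pos$sets, function(i) index@transcripts[i])
    keys <- vapply(sets, canonicalKey, "")
    n_ec <- length(sets)
    samples <- colnames(txCounts)
    m <- matrix(0L, nrow = n_ec, ncol = length(samples),
                dimnames = list(keys, samples))
    tx_names <- names(sim$sequences)
    for (t in seq_along(tx_names)) {
        p <- pos$positions[[t]]
        p <- p[!is.na(p)]
        if (!length(p)) next
        prob <- tabulate(p, nbins = n_ec)
        cnts <- txCounts[tx_names[t], ]
        for (s in seq_along(samples)) {
            if (cnts[s] == 0L) next
            m[, s] <- m[, s] + as.integer(stats::rmultinom(1L, cnts[s],
                                                           prob))
        }
    }
    keep <- rowSums(m) > 0L
    ecm <- ECCountMatrix(m[keep, , drop = FALSE], keys = keys[keep],
                         transcripts = CharacterList(sets[keep]))
    list(matrix = ecm, txCounts = txCounts, truth = truth)
}

#' One-call simulation of a full dataset
#'
#' Seeds the RNG from `config$seed` and runs transcriptome simulation,
#' abundance assignment, DTU gene selection, the isoform switch and one
#' transcript count draw; equivalence-class counts and/or reads are
#' generated on request from that shared draw.
#'
#' @param config a [simConfig()].
#' @param what any of `"ec"` (fast-path EC matrix) and `"reads"`.
#' @return list with `annotation`, `sequences`, `truth`, `txCounts`,
#'   `conditions`, `samples`, and (per `what`) `ec` and `reads` components.
#' @export
simulateDataset <- function(config = simConfig(), what = c("ec", "reads")) {
    sim <- simulateTranscriptome(config)   # seeds the RNG
    ab1 <- assignAbundances(config, sim$annotation)
    dtu <- selectDtuGenes(config, ab1)
    ab2 <- applyDtuSwitch(ab1, dtu)
    truth <- .makeTruth(config, ab1, ab2, dtu)
    txCounts <- drawTranscriptCounts(truth, config)
    out <- list(annotation = sim$annotation, sequences = sim$sequences,
                truth = truth, txCounts = txCounts,
                samples = .sampleNames(config),
                conditions = .sampleConditions(config))
    if ("ec" %in% what)
        out$ec <- simulateECCounts(sim, truth, config, txCounts = txCounts)
    if ("reads" %in% what)
        out$reads <- simulateReads(sim, truth, config, emitSequences = FALSE,
                                   txCounts = txCounts)
    out
}

#' Write a simulated dataset to disk
#'
#' Emits `transcripts.fasta`, `genes.gtf`, `t2g.tsv`, `truth.tsv`
#' (gene, DTU flag, per-condition proportions), `samples.tsv`, per-sample
#' FASTQ files (when reads with sequences are supplied) and
#' `reads_truth.tsv`.
#'
#' @param dataset output of [simulateDataset()].
#' @param dir output directory.
#' @param reads optional output of `simulateReads(..., emitSequences =
#'   TRUE)`.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(dataset, dir, reads = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFastaSeqs(dataset$sequences, file.path(dir, "transcripts.fasta"))
    writeGtfAnnotation(dataset$annotation, file.path(dir, "genes.gtf"))
    txg <- txGeneMap(dataset$annotation)
    utils::write.table(data.frame(transcript_id = names(txg),
                                  gene_id = unname(txg)),
                       file.path(dir, "t2g.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pr <- truthProportions(dataset$truth)
    pr$is_dtu <- pr$gene_id %in% dtuGenes(dataset$truth)
    utils::write.table(pr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeSampleTable(data.frame(sample = dataset$samples,
                                condition = dataset$conditions,
                                path = file.path(dir, paste0(dataset$samples,
                                                             ".fastq"))),
                     file.path(dir, "samples.tsv"))
    if (!is.null(reads)) {
        for (s in names(reads$reads))
            writeFastqReads(reads$reads[[s]], file.path(dir, paste0(s, ".fastq")))
        utils::write.table(reads$sources, file.path(dir, "reads_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(dir)
}
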