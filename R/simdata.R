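## Synthetic multi-species ddRAD / capture experiments with known truth.

BASES <- c("A", "C", "G", "T")

## Fixed restriction half-site motifs (EcoRI- and PstI-flavoured), cycled to
## the configured half-site length.  Every ancestral locus starts and ends
## with these; a substitution inside either half-site is what triggers ddRAD
## allele dropout.
.halfSites <- function(len) {
    cyc <- function(motif) substr(strrep(motif, ceiling(len / nchar(motif))),
                                  1L, len)
    c(left = cyc("GAATTC"), right = cyc("CTGCAG"))
}

## 16 dual-index 8-mers from a Reed-Solomon [4,2,3] code over GF(4),
## duplicated to 8 positions (pairwise Hamming distance >= 6).
.indexPool <- function() {
    gf <- expand.grid(a = 0:3, b = 0:3)
    words <- apply(gf, 1L, function(x) {
        w4 <- c(x[1], x[2], (x[1] + x[2]) %% 4, (x[1] + 2 * x[2]) %% 4)
        paste(BASES[c(w4, w4) + 1L], collapse = "")
    })
    list(i5 = words[1:8], i7 = words[9:16])
}

.randSeq <- function(len) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
}

## substitute each position independently with probability p (new base
## uniform over the other three) -- the equal-rates substitution scheme.
.mutateSeq <- function(seq, p) {
    if (p <= 0) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < p)
    if (length(hit)) {
        cur <- match(ch[hit], BASES)
        ch[hit] <- BASES[(cur - 1L + sample(1:3, length(hit),
                                            replace = TRUE)) %% 4L + 1L]
    }
    paste(ch, collapse = "")
}

#' Simulate the ground truth of a multi-species ddRAD/capture experiment
#'
#' Draws ancestral loci uniformly over A/C/G/T with a fixed restriction
#' half-site at each end, derives one haplotype per species by equal-rates
#' substitution at the configured divergence, assigns diploid individuals
#' per-site heterozygosity `theta_het`, and records ddRAD allele dropout
#' wherever an allele's restriction half-site carries a substitution (with
#' probability `dropout_per_substitution`).
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A [TruthSet-class].
#' @examples
#' truth <- simulateTruth(simConfig(seed = 1, n_loci = 10))
#' truth
#' @export
simulateTruth <- function(config) {
    validObject(config)
    set.seed(config@seed)
    nl <- config@n_loci
    rs <- config@restriction_site_len
    hs <- .halfSites(rs)
    lens <- sample(seq(config@locus_length_range[1],
                       config@locus_length_range[2]), nl, replace = TRUE)
    anc <- vapply(lens, function(L) {
        core <- .randSeq(L - 2L * rs)
        paste0(hs["left"], core, hs["right"])
    }, "")
    names(anc) <- sprintf("L%04d", seq_len(nl))

    spp <- names(config@species_divergences)
    haplotypes <- lapply(spp, function(sp) {
        d <- config@species_divergences[[sp]]
        setNames(vapply(anc, .mutateSeq, "", p = d), names(anc))
    })
    names(haplotypes) <- spp

    nind <- config@n_individuals_per_species
    samples <- unlist(lapply(spp, function(sp)
        sprintf("%s_%02d", sp, seq_len(nind))))
    spp_of <- rep(spp, each = nind)

    rows <- vector("list", length(samples) * nl)
    k <- 0L
    for (si in seq_along(samples)) {
        hap <- haplotypes[[spp_of[si]]]
        for (li in seq_len(nl)) {
            a1 <- hap[[li]]
            a2 <- a1
            L <- nchar(a1)
            het <- which(runif(L) < config@theta_het)
            if (length(het)) {
                ch1 <- strsplit(a1, "", fixed = TRUE)[[1]]
                ch2 <- ch1
                pick2 <- runif(length(het)) < 0.5
                cur <- match(ch1[het], BASES)
                newb <- BASES[(cur - 1L + sample(1:3, length(het),
                                                 replace = TRUE)) %% 4L + 1L]
                ch1[het[!pick2]] <- newb[!pick2]
                ch2[het[pick2]] <- newb[pick2]
                a1 <- paste(ch1, collapse = "")
                a2 <- paste(ch2, collapse = "")
            }
            k <- k + 1L
            rows[[k]] <- data.frame(
                sample = samples[si], species = spp_of[si],
                locus = names(anc)[li], allele = c(1L, 2L),
                seq = c(a1, a2), stringsAsFactors = FALSE)
        }
    }
    alleles <- do.call(rbind, rows)
    ancfull <- anc[alleles$locus]
    len <- nchar(ancfull)
    site_seq <- paste0(substr(alleles$seq, 1L, rs),
                       substr(alleles$seq, len - rs + 1L, len))
    site_anc <- paste0(substr(ancfull, 1L, rs),
                       substr(ancfull, len - rs + 1L, len))
    alleles$site_mutated <- site_seq != site_anc
    alleles$dropped <- alleles$site_mutated &
        (runif(nrow(alleles)) < config@dropout_per_substitution)

    pool <- .indexPool()
    i <- seq_along(samples)
    if (config@era == "modern") {
        sheet <- data.frame(
            sample = samples,
            i5 = pool$i5[(i - 1L) %% 8L + 1L],
            i7 = pool$i7[((i - 1L) %/% 8L) %% 8L + 1L],
            species = spp_of,
            year = sample(2013:2015, length(samples), replace = TRUE),
            a260_a280 = round(rnorm(length(samples), 1.85, 0.04), 2),
            conc_ng_ul = round(rnorm(length(samples), 70, 10), 1),
            stringsAsFactors = FALSE)
    } else {
        sheet <- data.frame(
            sample = samples,
            i5 = pool$i5[(i - 1L) %% 8L + 1L],
            i7 = pool$i7[((i - 1L) %/% 8L) %% 8L + 1L],
            species = spp_of,
            year = sample(c(1967L, 1991L, 1995L), length(samples),
                          replace = TRUE),
            a260_a280 = round(runif(length(samples), 0.9, 1.4), 2),
            conc_ng_ul = round(runif(length(samples), 5, 60), 1),
            stringsAsFactors = FALSE)
    }
    new("TruthSet", config = config, ancestral = anc,
        haplotypes = haplotypes, alleles = alleles, sheet = sheet)
}

## vectorised substitution of one position across many strings
.mutateAt <- function(seqs, pos, idx) {
    tmp <- seqs[idx]
    cur <- substr(tmp, pos, pos)
    code <- match(cur, BASES)
    newb <- BASES[(code - 1L + sample(1:3, length(idx),
                                      replace = TRUE)) %% 4L + 1L]
    substr(tmp, pos, pos) <- newb
    seqs[idx] <- tmp
    seqs
}

#' Emit paired sequencing reads from a simulated truth set
#'
#' In `ddrad` mode each retained (non-dropped) allele yields full-locus
#' restriction fragments; dropped alleles emit nothing.  In `capture` mode
#' both alleles of every individual are sampled regardless of dropout, with
#' per-locus expected coverage downweighted by
#' `2^(-divergence/capture_halflife)` (never to exactly zero), and fragments
#' are random sonication inserts of the locus.  Museum-era configs draw
#' shorter inserts from the fragmentation distribution and apply terminal
#' deamination (C->T from the 5' end, G->A from the 3' end, probability
#' `damage_delta * damage_lambda^(position-1)`) before sequencing error, so
#' both can coexist on one read.  A `duplicate_fraction` of the emitted
#' fragments are exact PCR copies (same locus, start, length, strand) of an
#' existing fragment.
#'
#' @param truth a [TruthSet-class] from [simulateTruth()].
#' @param config the same [SimConfig-class] used to build `truth`.
#' @param mode "ddrad" or "capture".
#' @return A [ReadPairSet-class].
#' @export
emitReads <- function(truth, config, mode = c("capture", "ddrad")) {
    mode <- match.arg(mode)
    validObject(config)
    set.seed(config@seed + 1000L)
    al <- truth@alleles
    div <- config@species_divergences[al$species]
    eff <- if (mode == "capture")
        2 ^ (-div / config@capture_halflife) else 1
    keep <- if (mode == "ddrad") !al$dropped else rep(TRUE, nrow(al))
    lambda <- (config@coverage_mean / 2) * eff * keep
    nfrag <- rpois(nrow(al), lambda)
    src <- rep.int(seq_len(nrow(al)), nfrag)
    n <- length(src)
    if (n == 0L)
        stop("no fragments emitted; raise coverage_mean")
    locus_len <- nchar(al$seq)[src]
    if (mode == "ddrad") {
        insert <- locus_len
        fstart <- rep(0L, n)
    } else {
        mu <- if (config@era == "museum") config@fragmentation_mean
              else config@insert_mean
        sdv <- if (config@era == "museum") 0.3 * mu else config@insert_sd
        ## truncated normal on [40, locus_len] via inverse-CDF sampling so
        ## no probability mass piles up at the bounds (which would fake
        ## PCR duplicates by coordinate collision)
        lo <- pnorm(40L, mu, sdv)
        hi <- pnorm(locus_len + 0.49, mu, sdv)
        insert <- as.integer(round(qnorm(lo + runif(n) * (hi - lo), mu,
                                         sdv)))
        insert <- pmin(pmax(insert, 40L), locus_len)
        fstart <- as.integer(floor(runif(n) * (locus_len - insert + 1L)))
    }
    frag <- substr(al$seq[src], fstart + 1L, fstart + insert)
    ## ddRAD libraries are directional (read 1 always starts at the same
    ## cut site); sonicated capture fragments ligate in either orientation
    strand <- if (mode == "ddrad") rep("+", n)
              else ifelse(runif(n) < 0.5, "+", "-")
    neg <- strand == "-"
    frag[neg] <- cpp_revcomp(frag[neg])

    n_damage <- integer(n)
    if (config@era == "museum" && config@damage_delta > 0) {
        pmax_d <- min(25L, max(insert))
        for (p in seq_len(pmax_d)) {
            pr <- config@damage_delta * config@damage_lambda ^ (p - 1)
            ## 5' C -> T
            hit <- which(runif(n) < pr & insert >= p &
                         substr(frag, p, p) == "C")
            if (length(hit)) {
                tmp <- frag[hit]
                substr(tmp, p, p) <- "T"
                frag[hit] <- tmp
                n_damage[hit] <- n_damage[hit] + 1L
            }
            ## 3' G -> A
            pos3 <- insert - p + 1L
            hit <- which(runif(n) < pr & insert >= p &
                         substr(frag, pos3, pos3) == "G")
            if (length(hit)) {
                tmp <- frag[hit]
                substr(tmp, pos3[hit], pos3[hit]) <- "A"
                frag[hit] <- tmp
                n_damage[hit] <- n_damage[hit] + 1L
            }
        }
    }

    is_dup <- rep(FALSE, n)
    source_id <- seq_len(n)
    if (config@duplicate_fraction > 0) {
        f <- config@duplicate_fraction
        ndup <- round(n * f / (1 - f))
        pick <- sample.int(n, ndup, replace = TRUE)
        frag <- c(frag, frag[pick])
        insert <- c(insert, insert[pick])
        fstart <- c(fstart, fstart[pick])
        strand <- c(strand, strand[pick])
        src <- c(src, src[pick])
        n_damage <- c(n_damage, n_damage[pick])
        is_dup <- c(is_dup, rep(TRUE, ndup))
        source_id <- c(source_id, pick)
        n <- length(frag)
    }

    rl <- pmin(config@read_length, insert)
    r1 <- substr(frag, 1L, rl)
    r2 <- substr(cpp_revcomp(frag), 1L, rl)
    if (config@error_rate > 0) {
        for (p in seq_len(max(rl))) {
            idx <- which(runif(n) < config@error_rate & rl >= p)
            if (length(idx)) r1 <- .mutateAt(r1, p, idx)
            idx <- which(runif(n) < config@error_rate & rl >= p)
            if (length(idx)) r2 <- .mutateAt(r2, p, idx)
        }
    }
    ## constant per-base quality, Phred-calibrated to the injected error
    ## rate (capped at the platform-flavoured Q37 modern / Q30 museum)
    qcap <- if (config@era == "museum") 30L else 37L
    qval <- if (config@error_rate > 0)
        min(qcap, as.integer(round(-10 * log10(config@error_rate))))
    else qcap
    qchar <- rawToChar(as.raw(qval + 33L))
    q1 <- vapply(rl, function(L) strrep(qchar, L), "")
    perm <- sample.int(n)
    sheet <- truth@sheet
    samp <- al$sample[src]
    idx5 <- sheet$i5[match(samp, sheet$sample)]
    idx7 <- sheet$i7[match(samp, sheet$sample)]
    tr <- data.frame(
        sample = samp, species = al$species[src], locus = al$locus[src],
        allele = al$allele[src], frag_start = fstart, insert = insert,
        strand = strand, is_duplicate = is_dup, source_id = source_id,
        n_damage = n_damage, stringsAsFactors = FALSE)
    ids <- sprintf("%s:%07d", mode, seq_len(n))
    rps <- new("ReadPairSet",
               id = ids[perm], seq1 = r1[perm], qual1 = q1[perm],
               seq2 = r2[perm], qual2 = q1[perm],
               i5 = idx5[perm], i7 = idx7[perm],
               truth = tr[perm, , drop = FALSE], sheet = sheet)
    validObject(rps)
    rps
}

#' Per-sample missing-locus fraction of an emitted read set
#'
#' A locus counts as missing for a sample when the sample emitted zero
#' fragments for it.  This is the quantity the ddRAD-vs-capture missing
#' data contrast is stated on.
#'
#' @param reads a [ReadPairSet-class].
#' @param truth the [TruthSet-class] the reads came from.
#' @return Named numeric vector, fraction of loci missing per sample.
#' @export
missingLociBySample <- function(reads, truth) {
    tr <- readTruth(reads)
    samples <- truth@sheet$sample
    nl <- length(truth@ancestral)
    have <- table(tr$sample, tr$locus)
    out <- setNames(rep(1, length(samples)), samples)
    present <- rownames(have)
    out[present] <- 1 - rowSums(have > 0) / nl
    out
}

#' True alt-allele dosage of each sample at given sites
#'
#' Looks up, for each requested (locus, 0-based position, alt base), how
#' many of a sample's two true allele sequences carry the alt base.  Used to
#' score genotype concordance against the simulator's truth.
#'
#' @param truth a [TruthSet-class].
#' @param sites data.frame with columns locus, pos (0-based), alt.
#' @return Integer matrix samples x sites of true alt dosages.
#' @export
truthGenotypes <- function(truth, sites) {
    al <- truth@alleles
    samples <- truth@sheet$sample
    out <- matrix(NA_integer_, length(samples), nrow(sites),
                  dimnames = list(samples, NULL))
    for (j in seq_len(nrow(sites))) {
        rows <- al$locus == sites$locus[j]
        b <- substr(al$seq[rows], sites$pos[j] + 1L, sites$pos[j] + 1L)
        d <- tapply((b == sites$alt[j]) * 1L, al$sample[rows], sum)
        out[names(d), j] <- as.integer(d)
    }
    out
}

#' Score a built reference against the simulated truth
#'
#' Each reference locus is matched to its best true locus (best shared-kmer
#' diagonal hit at >= 75\% identity, both strands).  The recovery rate is
#' the fraction of true loci represented by exactly one reference locus;
#' label accuracy is the fraction of matched reference loci whose
#' on/off-target origin agrees with whether the matched true locus was in
#' the targeted (probe-design) set.
#'
#' @param ref a [ReferenceSet-class].
#' @param truth the [TruthSet-class] the reads came from.
#' @param targeted character vector of true locus ids covered by probes.
#' @return list(recovery_rate, label_accuracy, n_reference, matched).
#' @export
referenceRecovery <- function(ref, truth, targeted) {
    rt <- refTable(ref)
    anc <- setNames(as.character(ancestralLoci(truth)),
                    names(truth@ancestral))
    hits <- cpp_pair_hits(rt$sequence, anc, k = 12L, both_strands = TRUE)
    best <- .bestHits(hits)
    ident <- (best$overlap - best$n_mismatch) / best$overlap
    best <- best[ident >= 0.75, , drop = FALSE]
    match_locus <- rep(NA_character_, nrow(rt))
    match_locus[best$qi] <- names(anc)[best$ri]
    tab <- table(match_locus)
    recovery_rate <- sum(tab == 1L) / length(anc)
    ok <- !is.na(match_locus)
    truth_lab <- ifelse(match_locus %in% targeted, "on_target",
                        "off_target")
    label_accuracy <- mean(rt$origin[ok] == truth_lab[ok])
    list(recovery_rate = recovery_rate, label_accuracy = label_accuracy,
         n_reference = nrow(rt), matched = match_locus)
}

#' Write a read pair set as FASTQ plus truth tables
#'
#' Writes `<prefix>_R1.fastq` / `<prefix>_R2.fastq` (Phred+33, index pair in
#' the description), `<prefix>_truth.tsv` and `<prefix>_sheet.tsv`, and the
#' true loci as `<prefix>_loci.fasta` when `truth` is supplied.
#'
#' @param reads a [ReadPairSet-class].
#' @param prefix output path prefix.
#' @param truth optional [TruthSet-class] for the locus FASTA.
#' @return Invisibly, the paths written.
#' @export
writeReads <- function(reads, prefix, truth = NULL) {
    desc <- sprintf("%s 1:N:0:%s+%s", reads@id, reads@i5, reads@i7)
    p1 <- paste0(prefix, "_R1.fastq")
    p2 <- paste0(prefix, "_R2.fastq")
    s1 <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(reads@seq1, desc)),
        Biostrings::PhredQuality(reads@qual1))
    s2 <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(reads@seq2, desc)),
        Biostrings::PhredQuality(reads@qual2))
    Biostrings::writeQualityScaledXStringSet(s1, p1)
    Biostrings::writeQualityScaledXStringSet(s2, p2)
    pt <- paste0(prefix, "_truth.tsv")
    write.table(cbind(id = reads@id, readTruth(reads)), pt, sep = "\t",
                quote = FALSE, row.names = FALSE)
    ps <- paste0(prefix, "_sheet.tsv")
    write.table(reads@sheet, ps, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(p1, p2, pt, ps)
    if (!is.null(truth)) {
        pl <- paste0(prefix, "_loci.fasta")
        Biostrings::writeXStringSet(ancestralLoci(truth), pl)
        paths <- c(paths, pl)
    }
    invisible(paths)
}

#' Read paired FASTQ written by [writeReads()] (or compatible)
#'
#' @param r1,r2 FASTQ paths.
#' @return A [ReadPairSet-class] with indexes parsed from the description
#'   (`... 1:N:0:I5+I7`) when present.
#' @export
readFastqPairs <- function(r1, r2) {
    ## readQualityScaledDNAStringSet warns that the mcols it attaches
    ## itself are dropped on rewrap; harmless here
    q1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
    q2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
    nm <- names(q1)
    id <- sub(" .*", "", nm)
    idx <- regmatches(nm, regexpr("[ACGTN]+\\+[ACGTN]+$", nm))
    if (length(idx) == length(nm)) {
        i5 <- sub("\\+.*", "", idx)
        i7 <- sub(".*\\+", "", idx)
    } else {
        i5 <- i7 <- rep(NA_character_, length(nm))
    }
    new("ReadPairSet", id = id,
        seq1 = unname(as.character(q1)),
        qual1 = unname(as.character(quality(q1))),
        seq2 = unname(as.character(q2)),
        qual2 = unname(as.character(quality(q2))),
        i5 = i5, i7 = i7,
        truth = data.frame(), sheet = data.frame())
}
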