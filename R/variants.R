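## Diploid genotype calling from non-duplicate alignments, site
## annotations (QUAL, QD, MQ, FS, ReadPosZ) and hard filtering.

#' Hard-filter thresholds for variant sites
#'
#' Defaults mirror stringent capture-data practice: quality-by-depth < 4,
#' RMS mapping quality < 18, site quality < 40, Fisher strand > 60, fewer
#' than 8 individuals at 5X, heterozygote read-position rank z < -12, and
#' biallelic sites only.
#'
#' @param qd_min,mq_rms_min,qual_min,fs_max numeric thresholds.
#' @param site_depth_min,min_samples_at_depth the per-sample depth floor
#'   and how many samples must reach it.
#' @param read_pos_z_min heterozygous sites with a read-position rank-sum
#'   z below this fail.
#' @param biallelic_only drop sites with more than one alt allele.
#' @return A named list of thresholds.
#' @export
filterThresholds <- function(qd_min = 4, mq_rms_min = 18, qual_min = 40,
                             fs_max = 60, site_depth_min = 5L,
                             min_samples_at_depth = 8L,
                             read_pos_z_min = -12,
                             biallelic_only = TRUE) {
    th <- list(qd_min = qd_min, mq_rms_min = mq_rms_min,
               qual_min = qual_min, fs_max = fs_max,
               site_depth_min = as.integer(site_depth_min),
               min_samples_at_depth = as.integer(min_samples_at_depth),
               read_pos_z_min = read_pos_z_min,
               biallelic_only = isTRUE(biallelic_only))
    stopifnot(all(is.finite(unlist(th[1:7]))))
    th
}

.logsumexp <- function(m) {
    ## rowwise over a list of matrices
    mx <- pmax(m[[1]], m[[2]], m[[3]])
    mx + log(exp(m[[1]] - mx) + exp(m[[2]] - mx) + exp(m[[3]] - mx))
}

## two-sided Fisher exact p of a 2x2 table by hypergeometric enumeration
.fisherP <- function(a, b, c, d) {
    m <- a + c
    n <- b + d
    k <- a + b
    if (m == 0 || n == 0 || k == 0 || (a + b + c + d) == k) return(1)
    lo <- max(0L, k - n)
    hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    p0 <- dhyper(a, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
}

## Mann-Whitney z (normal approximation, tie-corrected) of alt vs ref
## distances to the nearer read end; negative z = alt closer to read ends.
.rankSumZ <- function(alt_d, ref_d) {
    n1 <- length(alt_d)
    n2 <- length(ref_d)
    if (n1 == 0 || n2 == 0) return(NA_real_)
    x <- c(alt_d, ref_d)
    r <- rank(x)
    N <- n1 + n2
    R1 <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) return(0)
    (R1 - mu) / sqrt(v)
}

## per-locus pileup -> called sites; internal work-horse of callVariants
.callLocus <- function(u, refseq, locus, samples, min_alt_reads = 2L) {
    L <- nchar(refseq)
    ns <- length(samples)
    lens <- u$end - u$start
    base <- unlist(strsplit(u$seq, "", fixed = TRUE), use.names = FALSE)
    pos <- unlist(lapply(seq_len(nrow(u)), function(i)
        u$start[i] + seq_len(lens[i])), use.names = FALSE) # 1-based
    ri <- rep.int(seq_len(nrow(u)), lens)
    bcode <- match(base, BASES)
    valid <- !is.na(bcode)
    samp <- match(u$sample, samples)[ri]
    cell <- (pos - 1L) * ns * 4L + (samp - 1L) * 4L + bcode
    counts <- array(tabulate(cell[valid], 4L * ns * L), dim = c(4L, ns, L))
    q <- (u$mean_q)[ri]
    qsums <- rowsum(q[valid], cell[valid])
    qarr <- array(0, dim = c(4L, ns, L))
    qarr[as.integer(rownames(qsums))] <- qsums
    fwd <- u$strand[ri] == "+"
    cellf <- (pos - 1L) * 4L + bcode
    counts_f <- array(tabulate(cellf[valid & fwd], 4L * L), dim = c(4L, L))
    counts_all2 <- array(tabulate(cellf[valid], 4L * L), dim = c(4L, L))

    refb <- strsplit(refseq, "", fixed = TRUE)[[1]]
    refcode <- match(refb, BASES)
    tot <- apply(counts_all2, 2L, identity)
    nonref <- counts_all2
    nonref[cbind(refcode, seq_len(L))] <- 0L
    alt_count <- apply(nonref, 2L, max)
    altcode <- apply(nonref, 2L, which.max)
    dp_tot <- colSums(counts_all2)
    cand <- which(alt_count >= min_alt_reads & !is.na(refcode))
    if (!length(cand))
        return(NULL)

    ## genotype likelihoods at candidate sites
    nc <- length(cand)
    n_sub <- counts[, , cand, drop = FALSE]
    q_sub <- qarr[, , cand, drop = FALSE]
    qbar <- ifelse(n_sub > 0, q_sub / pmax(n_sub, 1L), 30)
    e <- pmin(0.75, 10^(-qbar / 10))
    isref <- aperm(array(outer(1:4, refcode[cand], "=="),
                         dim = c(4L, nc, ns)), c(1L, 3L, 2L))
    isalt <- aperm(array(outer(1:4, altcode[cand], "=="),
                         dim = c(4L, nc, ns)), c(1L, 3L, 2L))
    lpRR <- ifelse(isref, log(1 - e), log(e / 3))
    lpAA <- ifelse(isalt, log(1 - e), log(e / 3))
    lpRA <- ifelse(isref | isalt, log((1 - e) / 2 + e / 6), log(e / 3))
    llRR <- apply(n_sub * lpRR, c(2L, 3L), sum)
    llRA <- apply(n_sub * lpRA, c(2L, 3L), sum)
    llAA <- apply(n_sub * lpAA, c(2L, 3L), sum)
    dp <- apply(n_sub, c(2L, 3L), sum)
    lse <- .logsumexp(list(llRR, llRA, llAA))
    ll <- array(c(llRR, llRA, llAA), dim = c(ns, nc, 3L))
    gt <- apply(ll, c(1L, 2L), which.max) - 1L
    sorted2 <- apply(ll, c(1L, 2L), function(v) sort(v, decreasing = TRUE)[2])
    best <- apply(ll, c(1L, 2L), max)
    gq <- (best - sorted2) * 10 / log(10)
    gt[dp == 0L] <- NA_integer_
    gq[dp == 0L] <- NA_real_
    qual_site <- colSums(-10 * (llRR - lse) / log(10) * (dp > 0))

    keep <- which(colSums(gt >= 1L, na.rm = TRUE) > 0)
    if (!length(keep)) return(NULL)
    cand <- cand[keep]
    gt <- gt[, keep, drop = FALSE]
    gq <- gq[, keep, drop = FALSE]
    dp <- dp[, keep, drop = FALSE]
    qual_site <- qual_site[keep]
    nc <- length(cand)

    ## alt allele count per site (multi-allelic detection, noise-robust)
    n_alt_alleles <- vapply(cand, function(j) {
        thr <- max(min_alt_reads, ceiling(0.02 * dp_tot[j]))
        sum(nonref[, j] >= thr)
    }, 0L)
    n_alt_alleles <- pmax(n_alt_alleles, 1L)

    ## AD of the top alt
    adAlt <- t(vapply(seq_len(ns), function(s)
        counts[cbind(altcode[cand], s, cand)], integer(nc)))
    if (nc == 1L) adAlt <- matrix(adAlt, nrow = ns)

    ## annotations
    alt_samples <- colSums(dp * (gt >= 1L), na.rm = TRUE)
    qd <- ifelse(alt_samples > 0, qual_site / alt_samples, 0)
    ## RMS mapping quality per position from coverage-weighted sums
    cov1 <- as.numeric(IRanges::coverage(
        IRanges::IRanges(u$start + 1L, u$end), width = L))
    cov2 <- as.numeric(IRanges::coverage(
        IRanges::IRanges(u$start + 1L, u$end), weight = u$maq^2,
        width = L))
    mq <- sqrt(cov2[cand] / pmax(cov1[cand], 1))
    ## strand table and read positions at each kept site
    fs <- numeric(nc)
    rpz <- rep(NA_real_, nc)
    dist_near <- pmin(pos - u$start[ri], u$end[ri] - pos + 1L)
    for (j in seq_len(nc)) {
        p <- cand[j]
        rb <- refcode[p]; ab <- altcode[p]
        a <- counts_f[ab, p]                      # alt fwd
        b2 <- counts_all2[ab, p] - a              # alt rev
        cc <- counts_f[rb, p]                     # ref fwd
        d2 <- counts_all2[rb, p] - cc             # ref rev
        fs[j] <- max(0, -10 * log10(max(.fisherP(a, b2, cc, d2),
                                        1e-300)))
        at <- valid & pos == p & bcode == ab
        rt <- valid & pos == p & bcode == rb
        rpz[j] <- .rankSumZ(dist_near[at], dist_near[rt])
    }
    n5x <- colSums(dp >= 5L)
    sites <- data.frame(
        locus = locus, pos = cand - 1L, ref = refb[cand],
        alt = BASES[altcode[cand]], n_alt_alleles = n_alt_alleles,
        QUAL = qual_site, QD = qd, MQ = mq, FS = fs, ReadPosZ = rpz,
        n_samples_5x = n5x, filter = "", stringsAsFactors = FALSE)
    list(sites = sites, gt = gt, gq = gq, dp = dp, adAlt = adAlt)
}

#' Call diploid genotypes and annotate variant sites
#'
#' Non-duplicate alignments at maQ >= `maq_min` are piled up per locus.
#' Per sample and site, genotype likelihoods over \{hom-ref, het, hom-alt\}
#' use the product over reads of P(base | genotype) with
#' P(correct) = 1 - e (e from base quality) and a heterozygote emitting
#' either allele at one half; a flat prior gives the MAP genotype and GQ
#' (phred distance to the second-best).  Site QUAL is the phred-scaled
#' probability that all samples are homozygous reference.  Sites where at
#' least one sample carries an alt allele are emitted with QD, MQ (RMS
#' mapping quality), FS (phred-scaled two-sided Fisher strand p) and
#' ReadPosZ (tie-corrected rank-sum z of alt vs ref distances to the
#' nearer read end).
#'
#' @param aln an [AlignmentSet-class] with duplicates marked.
#' @param reference named character / DNAStringSet of locus sequences.
#' @param params a [captureParams()] list (maq_min is used).
#' @param species optional named character sample -> species.
#' @return A [VariantSet-class].
#' @export
callVariants <- function(aln, reference, params = captureParams(),
                         species = NULL) {
    refs <- .asSeqChar(reference)
    r <- aln@records
    u <- r[!r$is_duplicate & r$maq >= params$maq_min, , drop = FALSE]
    samples <- sort(unique(r$sample))
    per_locus <- split(u, u$locus)
    out <- vector("list", length(per_locus))
    for (i in seq_along(per_locus)) {
        loc <- names(per_locus)[i]
        if (!loc %in% names(refs)) next
        out[[i]] <- .callLocus(per_locus[[i]], refs[[loc]], loc, samples)
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) {
        empty <- matrix(NA_integer_, length(samples), 0,
                        dimnames = list(samples, NULL))
        return(new("VariantSet",
                   sites = data.frame(locus = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      n_alt_alleles = integer(),
                                      QUAL = numeric(), QD = numeric(),
                                      MQ = numeric(), FS = numeric(),
                                      ReadPosZ = numeric(),
                                      n_samples_5x = integer(),
                                      filter = character()),
                   geno = empty, gq = empty + NA_real_, dp = empty,
                   adAlt = empty, samples = samples,
                   species = .speciesOf(samples, species)))
    }
    sites <- do.call(rbind, lapply(out, `[[`, "sites"))
    rownames(sites) <- NULL
    bindm <- function(f) do.call(cbind, lapply(out, `[[`, f))
    gt <- bindm("gt"); mode(gt) <- "integer"
    dp <- bindm("dp"); mode(dp) <- "integer"
    ad <- bindm("adAlt"); mode(ad) <- "integer"
    rownames(gt) <- rownames(dp) <- rownames(ad) <- samples
    gq <- bindm("gq")
    rownames(gq) <- samples
    new("VariantSet", sites = sites, geno = gt, gq = gq, dp = dp,
        adAlt = ad, samples = samples,
        species = .speciesOf(samples, species))
}

.speciesOf <- function(samples, species) {
    if (is.null(species)) return(sub("_[0-9]+$", "", samples))
    unname(species[samples])
}

#' Apply hard site filters
#'
#' A site fails when QD < `qd_min`, MQ < `mq_rms_min`, QUAL < `qual_min`,
#' FS > `fs_max`, fewer than `min_samples_at_depth` samples reach
#' `site_depth_min`X, or (for sites carrying heterozygote calls) ReadPosZ
#' < `read_pos_z_min`.  With `biallelic_only` sites with more than one alt
#' allele are removed.  Every failure reason is recorded in the filter
#' column; the per-filter counts are attached as attribute
#' `filter_counts`.
#'
#' @param vs a [VariantSet-class].
#' @param thresholds a [filterThresholds()] list.
#' @return The [VariantSet-class] with filter status filled in.
#' @export
hardFilter <- function(vs, thresholds = filterThresholds()) {
    s <- vs@sites
    n5 <- colSums(vs@dp >= thresholds$site_depth_min, na.rm = TRUE)
    het_driven <- colSums(vs@geno == 1L, na.rm = TRUE) > 0
    fails <- list(
        LowQD = s$QD < thresholds$qd_min,
        LowMQ = s$MQ < thresholds$mq_rms_min,
        LowQual = s$QUAL < thresholds$qual_min,
        HighFS = s$FS > thresholds$fs_max,
        LowCov = n5 < thresholds$min_samples_at_depth,
        ReadPos = het_driven & !is.na(s$ReadPosZ) &
            s$ReadPosZ < thresholds$read_pos_z_min)
    if (thresholds$biallelic_only)
        fails$NotBiallelic <- s$n_alt_alleles > 1L
    fm <- do.call(cbind, fails)
    fm[is.na(fm)] <- FALSE
    s$filter <- apply(fm, 1L, function(x)
        if (any(x)) paste(names(fails)[x], collapse = ";") else "PASS")
    out <- new("VariantSet", sites = s, geno = vs@geno, gq = vs@gq,
               dp = vs@dp, adAlt = vs@adAlt, samples = vs@samples,
               species = vs@species)
    attr(out, "filter_counts") <- colSums(fm)
    out
}

#' Summaries of a filtered variant set
#'
#' Transition/transversion ratio (transitions = A<->G and C<->T),
#' deamination-candidate counts (sites whose major-to-minor direction is
#' C->T or G->A; major allele by overall frequency, ties to the reference
#' base), and per-species SNP and SNP-per-locus counts.
#'
#' @param vs a [VariantSet-class] (normally PASS sites).
#' @return list(tstv, n_transitions, n_transversions,
#'   n_deamination_candidates, per_species).
#' @export
variantSummaries <- function(vs) {
    s <- vs@sites
    pair <- paste0(s$ref, s$alt)
    is_ts <- pair %in% c("AG", "GA", "CT", "TC")
    n_ts <- sum(is_ts)
    n_tv <- sum(!is_ts)
    tstv <- if (n_tv == 0) Inf else n_ts / n_tv
    dir <- .majorMinorDirection(vs)
    deam <- dir %in% c("CT", "GA")
    per_species <- do.call(rbind, lapply(unique(vs@species), function(sp) {
        g <- vs@geno[vs@species == sp, , drop = FALSE]
        has <- colSums(g >= 1L, na.rm = TRUE) > 0
        loci <- unique(s$locus[colSums(!is.na(g)) > 0])
        data.frame(species = sp, n_snps = sum(has),
                   n_loci = length(loci),
                   snp_per_locus = sum(has) / max(1L, length(loci)),
                   stringsAsFactors = FALSE)
    }))
    list(tstv = tstv, n_transitions = n_ts, n_transversions = n_tv,
         n_deamination_candidates = sum(deam),
         per_species = per_species)
}

## "RT" strings giving major -> minor direction per site
.majorMinorDirection <- function(vs) {
    s <- vs@sites
    altf <- colMeans(vs@geno, na.rm = TRUE) / 2
    altf[is.nan(altf)] <- 0
    major_alt <- altf > 0.5          # ties break toward the reference
    ifelse(major_alt, paste0(s$alt, s$ref), paste0(s$ref, s$alt))
}
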