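# Shared fixtures and independent oracles.

rand_dna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), "")
}

mutate_positions <- function(seq, pos, to = NULL) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos) {
        others <- setdiff(c("A", "C", "G", "T"), ch[p])
        ch[p] <- if (is.null(to)) others[1] else to
    }
    paste(ch, collapse = "")
}

# build a ReadPairSet by hand
make_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       i5 = "AAAAAAAA", i7 = "CCCCCCCC") {
    n <- length(seq1)
    if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))  # Q40
    if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
    new("ReadPairSet", id = sprintf("r%03d", seq_len(n)),
        seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
        i5 = rep_len(i5, n), i7 = rep_len(i7, n),
        truth = data.frame(), sheet = data.frame())
}

revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# build an AlignmentSet by hand from reference-oriented placements
make_aln <- function(locus, start, seq, strand = "+", sample = "S1",
                     maq = 60L, qual = NULL, ref_lengths) {
    n <- length(seq)
    if (is.null(qual)) qual <- strrep("I", nchar(seq))
    rec <- data.frame(
        read_id = sprintf("r%04d", seq_len(n)),
        sample = rep_len(sample, n), locus = rep_len(locus, n),
        start = rep_len(as.integer(start), n),
        end = rep_len(as.integer(start), n) + nchar(seq),
        strand = rep_len(strand, n),
        n_mismatch = 0L, maq = rep_len(as.integer(maq), n),
        insert_len = nchar(seq), is_duplicate = FALSE,
        seq = seq, qual = qual,
        mean_q = vapply(qual, function(q) mean(utf8ToInt(q)) - 33, 0,
                        USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    new("AlignmentSet", records = rec, refLengths = ref_lengths)
}

# independent Weir-Cockerham oracle: scalar arithmetic straight from the
# component formulas, one site at a time
oracle_wc_site <- function(gt, pops) {
    ok <- !is.na(gt)
    use <- unique(pops[ok])
    ni <- vapply(use, function(pp) sum(ok & pops == pp), 0)
    if (length(ni) < 2) return(NULL)
    pi <- vapply(use, function(pp) mean(gt[ok & pops == pp]) / 2, 0)
    hi <- vapply(use, function(pp) mean(gt[ok & pops == pp] == 1), 0)
    r <- length(ni)
    nbar <- sum(ni) / r
    pbar <- sum(ni * pi) / sum(ni)
    if (pbar <= 0 || pbar >= 1) return(NULL)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
}

oracle_wc_global <- function(geno, pops) {
    comps <- apply(geno, 2, oracle_wc_site, pops = pops)
    if (is.list(comps)) comps <- do.call(cbind, comps[!vapply(comps, is.null, TRUE)])
    sum(comps["a", ]) / sum(comps)
}

# brute-force diploid genotype likelihood oracle (flat prior)
oracle_genotype <- function(bases, ref, alt, e) {
    like <- function(probs) prod(probs)
    pr <- function(b, g) {
        if (g == 0) { if (b == ref) 1 - e else e / 3 }
        else if (g == 2) { if (b == alt) 1 - e else e / 3 }
        else { if (b %in% c(ref, alt)) (1 - e) / 2 + e / 6 else e / 3 }
    }
    ll <- vapply(0:2, function(g)
        sum(log(vapply(bases, pr, 0, g = g))), 0)
    which.max(ll) - 1L
}
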