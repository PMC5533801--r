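# helper: a one-locus pileup from hand-written read sequences, all maQ 60
call_one <- function(reads, ref, qual_char = "?", strand = NULL,
                     samples = NULL) {
    if (is.null(strand)) strand <- rep("+", length(reads))
    if (is.null(samples)) samples <- rep("S1", length(reads))
    al <- make_aln("L1", 0, reads, strand = strand, sample = samples,
                   qual = strrep(qual_char, nchar(reads)),
                   ref_lengths = c(L1 = nchar(ref)))
    callVariants(al, c(L1 = ref))
}

test_that("genotype calls match the brute-force likelihood oracle", {
    set.seed(1)
    ref <- rand_dna(1, 60)
    refb <- substr(ref, 31, 31)
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
    mk <- function(n_ref, n_alt)
        c(rep(ref, n_ref),
          rep(mutate_positions(ref, 31, to = alt), n_alt))
    ## 20 reads all ref at Q30: hom-ref everywhere, so no site emitted
    expect_equal(length(call_one(mk(20, 0), ref, "?")), 0L)
    ## 10 ref / 10 alt at Q30 -> het, matching the oracle
    vs <- call_one(mk(10, 10), ref, "?")
    j <- which(siteTable(vs)$pos == 30L)
    expect_equal(unname(genotypes(vs)[1, j]), 1L)
    e30 <- 10^(-30 / 10)
    expect_equal(oracle_genotype(c(rep(refb, 10), rep(alt, 10)),
                                 refb, alt, e30), 1L)
    ## 1 alt among 19 ref at e = 0.001 (Q30): error explains it better
    expect_equal(oracle_genotype(c(rep(refb, 19), alt), refb, alt, e30),
                 0L)
    vs2 <- call_one(mk(19, 1), ref, "?")
    expect_false(30L %in% siteTable(vs2)$pos)
    ## randomized cases: package call equals the oracle
    for (rep_i in 1:20) {
        n_alt <- sample(0:20, 1)
        n_ref <- 20 - n_alt
        oracle <- oracle_genotype(c(rep(refb, n_ref), rep(alt, n_alt)),
                                  refb, alt, e30)
        vs3 <- call_one(mk(n_ref, n_alt), ref, "?")
        got <- if (length(vs3) == 0 ||
                   !30L %in% siteTable(vs3)$pos) 0L
               else unname(genotypes(vs3)[1, siteTable(vs3)$pos == 30L])
        expect_identical(got, oracle)
    }
})

test_that("high-confidence calls carry high GQ and QUAL", {
    set.seed(2)
    ref <- rand_dna(1, 60)
    alt_seq <- mutate_positions(ref, 20)
    vs <- call_one(c(rep(ref, 10), rep(alt_seq, 30)), ref, "I")
    j <- which(siteTable(vs)$pos == 19L)
    expect_gt(siteTable(vs)$QUAL[j], 100)
    expect_gt(vs@gq[1, j], 20)
    expect_equal(siteTable(vs)$MQ[j], 60)
})

test_that("FS equals the exact hypergeometric strand test", {
    ## balanced table -> p = 1 -> FS = 0
    expect_equal(radcapkit:::.fisherP(10, 10, 10, 10), 1)
    ## enumerated agreement with fisher.test across small tables
    set.seed(3)
    for (i in 1:150) {
        tb <- matrix(sample(0:12, 4, replace = TRUE), 2)
        if (sum(tb) == 0) next
        p_pkg <- radcapkit:::.fisherP(tb[1, 1], tb[1, 2], tb[2, 1],
                                      tb[2, 2])
        p_ora <- stats::fisher.test(tb)$p.value
        expect_equal(p_pkg, p_ora, tolerance = 1e-9)
    }
    ## strand-biased site annotated with the exact value
    set.seed(4)
    ref <- rand_dna(1, 60)
    refb <- substr(ref, 31, 31)
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
    alt_seq <- mutate_positions(ref, 31, to = alt)
    reads <- c(rep(alt_seq, 20), rep(ref, 10), rep(ref, 10))
    strands <- c(rep("+", 20), rep("+", 10), rep("-", 10))
    vs <- call_one(reads, ref, "I", strand = strands)
    j <- which(siteTable(vs)$pos == 30L)
    p_exp <- stats::fisher.test(matrix(c(20, 0, 10, 10), 2,
                                       byrow = TRUE))$p.value
    expect_equal(siteTable(vs)$FS[j], -10 * log10(p_exp),
                 tolerance = 1e-6)
})

test_that("identical alt and ref read-position distributions give z = 0", {
    expect_equal(radcapkit:::.rankSumZ(c(5, 10, 20), c(5, 10, 20)), 0)
    expect_equal(radcapkit:::.rankSumZ(numeric(), c(1, 2)), NA_real_)
    ## alt clustered at read starts is strongly negative
    expect_lt(radcapkit:::.rankSumZ(rep(1, 10), rep(50, 10)), -3)
})

test_that("hard filters classify threshold-straddling sites exactly", {
    ns <- 10L
    n_sites <- 12L
    base_dp <- matrix(20L, ns, n_sites)
    mk_vs <- function() {
        sites <- data.frame(
            locus = "L1", pos = seq_len(n_sites) - 1L, ref = "A",
            alt = "G", n_alt_alleles = 1L, QUAL = 100, QD = 10, MQ = 60,
            FS = 0, ReadPosZ = 0, n_samples_5x = ns, filter = "",
            stringsAsFactors = FALSE)
        geno <- matrix(1L, ns, n_sites)
        new("VariantSet", sites = sites, geno = geno,
            gq = matrix(99, ns, n_sites), dp = base_dp,
            adAlt = matrix(10L, ns, n_sites),
            samples = paste0("S", 1:ns), species = rep("A", ns))
    }
    vs <- mk_vs()
    vs@sites$QD[1] <- 3.99; vs@sites$QD[2] <- 4.00
    vs@sites$QUAL[3] <- 39; vs@sites$QUAL[4] <- 40
    vs@sites$MQ[5] <- 17.9; vs@sites$MQ[6] <- 18
    vs@sites$FS[7] <- 61;   vs@sites$FS[8] <- 59
    vs@dp[, 9] <- c(rep(20L, 7), rep(4L, 3))   # 7 samples at >= 5X
    vs@dp[, 10] <- c(rep(20L, 8), rep(4L, 2))  # 8 samples at >= 5X
    vs@sites$n_alt_alleles[11] <- 2L           # triallelic
    vs@sites$ReadPosZ[12] <- -12.5             # het-driven, below -12
    hf <- hardFilter(vs)
    st <- siteTable(hf)$filter
    expect_identical(st[1], "LowQD");   expect_identical(st[2], "PASS")
    expect_identical(st[3], "LowQual"); expect_identical(st[4], "PASS")
    expect_identical(st[5], "LowMQ");   expect_identical(st[6], "PASS")
    expect_identical(st[7], "HighFS");  expect_identical(st[8], "PASS")
    expect_identical(st[9], "LowCov");  expect_identical(st[10], "PASS")
    expect_identical(st[11], "NotBiallelic")
    expect_identical(st[12], "ReadPos")
})

test_that("tightening any threshold never increases the PASS count", {
    set.seed(5)
    ns <- 10L; m <- 80L
    sites <- data.frame(
        locus = "L1", pos = seq_len(m) - 1L, ref = "A", alt = "G",
        n_alt_alleles = sample(1:2, m, TRUE, prob = c(0.9, 0.1)),
        QUAL = runif(m, 20, 200), QD = runif(m, 0, 20),
        MQ = runif(m, 10, 60), FS = runif(m, 0, 80),
        ReadPosZ = rnorm(m, 0, 8), n_samples_5x = 0L, filter = "",
        stringsAsFactors = FALSE)
    vs <- new("VariantSet", sites = sites,
              geno = matrix(sample(c(0L, 1L, 2L), ns * m, TRUE), ns, m),
              gq = matrix(50, ns, m),
              dp = matrix(sample(2:12, ns * m, TRUE), ns, m),
              adAlt = matrix(3L, ns, m), samples = paste0("S", 1:ns),
              species = rep("A", ns))
    n_pass <- function(th) sum(siteTable(hardFilter(vs, th))$filter ==
                                   "PASS")
    base <- n_pass(filterThresholds())
    expect_lte(n_pass(filterThresholds(qd_min = 6)), base)
    expect_lte(n_pass(filterThresholds(qual_min = 60)), base)
    expect_lte(n_pass(filterThresholds(mq_rms_min = 30)), base)
    expect_lte(n_pass(filterThresholds(fs_max = 30)), base)
    expect_lte(n_pass(filterThresholds(min_samples_at_depth = 9)), base)
    expect_lte(n_pass(filterThresholds(read_pos_z_min = -2)), base)
})

test_that("summaries compute ts/tv and deamination direction", {
    mk_vs <- function(ref, alt, altfreq) {
        m <- length(ref); ns <- 4L
        geno <- vapply(altfreq, function(f)
            as.integer(round(rep(2 * f, ns))), integer(ns))
        new("VariantSet",
            sites = data.frame(locus = "L1", pos = seq_len(m) - 1L,
                               ref = ref, alt = alt, n_alt_alleles = 1L,
                               QUAL = 100, QD = 10, MQ = 60, FS = 0,
                               ReadPosZ = 0, n_samples_5x = ns,
                               filter = "PASS", stringsAsFactors = FALSE),
            geno = geno, gq = matrix(99, ns, m),
            dp = matrix(20L, ns, m), adAlt = matrix(10L, ns, m),
            samples = paste0("S", 1:ns), species = rep("A", ns))
    }
    ## {C->T, A->G, A->C, G->T} -> 2 transitions / 2 transversions = 1
    vs <- mk_vs(c("C", "A", "A", "G"), c("T", "G", "C", "T"),
                rep(0.25, 4))
    sm <- variantSummaries(vs)
    expect_equal(sm$tstv, 1.0)
    ## all A<->C -> ratio 0; all transitions -> infinite marker
    expect_equal(variantSummaries(mk_vs(c("A", "C"), c("C", "A"),
                                        c(0.25, 0.25)))$tstv, 0)
    expect_identical(variantSummaries(mk_vs("A", "G", 0.25))$tstv, Inf)
    ## major C -> minor T and major G -> minor A are deamination
    ## candidates; major T -> minor C is not
    vs2 <- mk_vs(c("C", "G", "C"), c("T", "A", "T"),
                 c(0.25, 0.25, 0.75))
    expect_equal(variantSummaries(vs2)$n_deamination_candidates, 2L)
})

test_that("simulated equal-rates mutations give ts/tv near one half", {
    cfg <- simConfig(seed = 41, n_loci = 40,
                     species_divergences = c(A = 0.03, B = 0.03),
                     n_individuals_per_species = 6, coverage_mean = 25,
                     error_rate = 0.002)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    al <- markDuplicates(mapReads(pr$fragments, ancestralLoci(tr)))
    vs <- passSites(hardFilter(callVariants(al, ancestralLoci(tr))))
    sm <- variantSummaries(vs)
    n <- sm$n_transitions + sm$n_transversions
    ## one transition class vs two transversion classes: E[ts frac] = 1/3
    se <- sqrt(1 / 3 * 2 / 3 / n)
    expect_lt(abs(sm$n_transitions / n - 1 / 3), 4 * se)
})
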