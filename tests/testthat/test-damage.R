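test_that("damage parameters are recovered from museum reads", {
    cfg <- simConfig(seed = 11, n_loci = 50,
                     species_divergences = c(M = 0.02),
                     n_individuals_per_species = 6, era = "museum",
                     damage_delta = 0.3, damage_lambda = 0.5,
                     coverage_mean = 35, error_rate = 0.005)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    al <- markDuplicates(mapReads(pr$fragments, ancestralLoci(tr)))
    dp <- profileDamage(al, ancestralLoci(tr))
    expect_lt(abs(dp@delta - 0.3) / 0.3, 0.15)
    expect_false(dp@no_damage)
    ## monotone decay: position 1 frequency >= position 5
    expect_gte(dp@ct5[1], dp@ct5[5])
    expect_gte(dp@ga3[1], dp@ga3[5])
})

test_that("undamaged reads are reported as no-damage", {
    cfg <- simConfig(seed = 12, n_loci = 30,
                     species_divergences = c(M = 0.02),
                     n_individuals_per_species = 4)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    al <- markDuplicates(mapReads(pr$fragments, ancestralLoci(tr)))
    dp <- profileDamage(al, ancestralLoci(tr))
    expect_true(dp@no_damage)
})

test_that("strand-flipping the input swaps the 5' and 3' profiles", {
    set.seed(13)
    ref <- c(L1 = rand_dna(1, 200))
    reads <- vapply(1:300, function(i) {
        s <- sample(1:60, 1)
        sub <- substr(ref[[1]], s, s + 99)
        if (substr(sub, 1, 1) == "C" && runif(1) < 0.5)
            sub <- mutate_positions(sub, 1, to = "T")
        sub
    }, "")
    starts <- rep(0L, 300)  # recompute: place each read at its true start
    al <- local({
        st <- integer(300)
        for (i in 1:300) st[i] <- as.integer(
            regexpr(substr(reads[i], 5, 40), ref[[1]], fixed = TRUE)) - 5L
        make_aln("L1", 0, reads, ref_lengths = c(L1 = 200L))
    })
    ## simpler: map them properly
    al <- mapReads(reads, ref)
    p_fwd <- profileDamage(al, ref)
    flip <- al
    r <- flip@records
    r$strand <- ifelse(r$strand == "+", "-", "+")
    flip@records <- r
    p_rev <- profileDamage(flip, ref)
    expect_equal(p_fwd@ct5, p_rev@ga3, tolerance = 1e-12)
    expect_equal(p_fwd@ga3, p_rev@ct5, tolerance = 1e-12)
})

test_that("profiles from few reads are marked unreliable", {
    set.seed(14)
    ref <- c(L1 = rand_dna(1, 200))
    al <- mapReads(substr(ref[[1]], 1, 120), ref)
    expect_warning(p <- profileDamage(al, ref), "unreliable")
    expect_false(p@reliable)
})

test_that("coverage exclusion applies the 2.0X floor exactly", {
    qc <- data.frame(sample = c("a", "b", "c", "d"),
                     mean_target_coverage = c(1.99, 2.00, 25, 0.5),
                     a260_a280 = c(1.8, 1.8, 0.95, 1.7),
                     conc_ng_ul = c(80, 80, 50, 10),
                     stringsAsFactors = FALSE)
    qx <- qcExclude(qc)
    expect_identical(qx$retained$sample, c("b", "c"))
    expect_identical(qx$excluded$sample, c("a", "d"))
    ## low purity retained but flagged
    expect_match(qx$retained$flags[qx$retained$sample == "c"],
                 "low_purity")
    ## all below the floor -> explicit empty retention
    all_low <- qc; all_low$mean_target_coverage <- 0.1
    expect_equal(nrow(qcExclude(all_low)$retained), 0L)
})

test_that("the deamination filter is directional", {
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
    ## major C, minor T -> removed; major T, minor C -> retained;
    ## major A, minor C (transversion) -> retained; major G, minor A
    ## -> removed; minor G, major A (i.e. A->G direction) -> retained
    vs <- mk_vs(ref = c("C", "C", "A", "G", "A"),
                alt = c("T", "T", "C", "A", "G"),
                altfreq = c(0.25, 0.75, 0.25, 0.25, 0.25))
    df <- deaminationFilter(vs)
    expect_equal(df$n_removed, 2L)
    expect_identical(df$removed$pos, c(0L, 3L))
    expect_identical(siteTable(df$kept)$pos, c(1L, 2L, 4L))
})

test_that("without directional sites the filter leaves Fst untouched", {
    set.seed(15)
    m <- 40L; ns <- 12L
    geno <- matrix(sample(c(0L, 1L, 2L), ns * m, TRUE), ns, m)
    ## allele pairs whose either orientation is never C->T or G->A
    pairs <- list(c("A", "C"), c("G", "T"), c("A", "T"), c("G", "C"))
    pick <- pairs[sample(4, m, TRUE)]
    vs <- new("VariantSet",
              sites = data.frame(locus = "L1", pos = seq_len(m) - 1L,
                                 ref = vapply(pick, `[`, "", 1),
                                 alt = vapply(pick, `[`, "", 2),
                                 n_alt_alleles = 1L, QUAL = 100, QD = 10,
                                 MQ = 60, FS = 0, ReadPosZ = 0,
                                 n_samples_5x = ns, filter = "PASS",
                                 stringsAsFactors = FALSE),
              geno = geno, gq = matrix(99, ns, m),
              dp = matrix(20L, ns, m), adAlt = matrix(5L, ns, m),
              samples = paste0("S", 1:ns),
              species = rep(c("A", "B"), each = ns / 2))
    df <- deaminationFilter(vs)
    expect_equal(df$n_removed, 0L)
    before <- globalTheta(wcFst(genotypeMatrix(vs)))
    after <- globalTheta(wcFst(genotypeMatrix(df$kept)))
    expect_identical(before, after)
})
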