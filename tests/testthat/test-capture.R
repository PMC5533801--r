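test_that("mapping assigns unique reads maQ 60 and ambiguous reads maQ 0", {
    set.seed(1)
    refs <- setNames(rand_dna(3, 180), c("L1", "L2", "L3"))
    al <- mapReads(substr(refs[["L2"]], 21, 140), refs)
    r <- alignments(al)
    expect_equal(r$locus, "L2")
    expect_equal(r$start, 20L)
    expect_equal(r$maq, 60L)
    ## identical duplicated loci: tie -> zero margin -> excluded at maQ 5
    refs2 <- setNames(c(refs[["L1"]], refs[["L1"]]), c("A", "B"))
    r2 <- alignments(mapReads(substr(refs[["L1"]], 1, 120), refs2))
    expect_equal(r2$maq, 0L)
    ## reverse-complement reads map on the minus strand, same interval
    r3 <- alignments(mapReads(revcomp(substr(refs[["L3"]], 31, 150)),
                              refs))
    expect_equal(r3$locus, "L3")
    expect_equal(r3$strand, "-")
    expect_equal(r3$start, 30L)
    expect_error(mapReads("ACGT", character()), "empty reference")
})

test_that("reads at 5% divergence map back to their true locus", {
    set.seed(2)
    refs <- setNames(rand_dna(30, 180), sprintf("L%02d", 1:30))
    true_locus <- sample(names(refs), 400, replace = TRUE)
    reads <- vapply(true_locus, function(l) {
        s <- sample(1:60, 1)
        sub <- substr(refs[[l]], s, s + 119)
        mutate_positions(sub, sample(120, 6))          # 5% divergence
    }, "", USE.NAMES = FALSE)
    r <- alignments(mapReads(reads, refs))
    acc <- sum(r$locus == true_locus[match(r$read_id,
        sprintf("read%07d", seq_along(reads)))]) / length(reads)
    expect_gte(acc, 0.95)
})

test_that("raising the maQ floor never increases the usable read count", {
    cfg <- simConfig(seed = 19, n_loci = 15, n_individuals_per_species = 2)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    r <- alignments(mapReads(pr$fragments, ancestralLoci(tr)))
    counts <- vapply(c(0, 5, 10, 30, 60), function(q) sum(r$maq >= q), 0)
    expect_true(all(diff(counts) <= 0))
})

test_that("duplicate marking groups by fragment identity", {
    set.seed(3)
    refs <- setNames(rand_dna(1, 200), "L1")
    frag <- substr(refs[[1]], 11, 170)
    ## 3 identical fragments -> 2 flagged
    a1 <- make_aln("L1", 10, rep(frag, 3),
                   ref_lengths = c(L1 = 200L))
    m1 <- markDuplicates(a1)
    expect_equal(sum(alignments(m1)$is_duplicate), 2L)
    ## idempotence
    expect_identical(alignments(markDuplicates(m1)),
                     alignments(m1))
    ## same start, inserts 160 vs 161 -> no duplicates
    a2 <- make_aln("L1", 10, c(frag, substr(refs[[1]], 11, 171)),
                   ref_lengths = c(L1 = 200L))
    expect_equal(sum(alignments(markDuplicates(a2))$is_duplicate), 0L)
    ## different strands are distinct fragments
    a3 <- make_aln("L1", 10, rep(frag, 2), strand = c("+", "-"),
                   ref_lengths = c(L1 = 200L))
    expect_equal(sum(alignments(markDuplicates(a3))$is_duplicate), 0L)
})

test_that("an injected 30% duplicate fraction is recovered within 0.02", {
    cfg <- simConfig(seed = 7, n_loci = 40, n_individuals_per_species = 4,
                     duplicate_fraction = 0.30)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    al <- markDuplicates(mapReads(pr$fragments, ancestralLoci(tr)))
    rate <- mean(alignments(al)$is_duplicate)
    expect_lt(abs(rate - 0.30), 0.02)
})

test_that("reference building applies the 40-read cluster floor", {
    set.seed(4)
    locusA <- rand_dna(1, 180)
    locusB <- rand_dna(1, 180)
    probes <- tileProbes(setNames(c(locusA, locusB), c("A", "B")))
    mk <- function(nA, nB) c(rep(locusA, nA), rep(locusB, nB))
    ref1 <- buildReference(mk(39, 45), probes)
    expect_equal(nrow(refTable(ref1)), 1L)
    ref2 <- buildReference(mk(40, 45), probes)
    expect_equal(nrow(refTable(ref2)), 2L)
    expect_true(all(refTable(ref2)$origin == "on_target"))
    expect_error(buildReference(mk(10, 10), probes), "empty reference")
})

test_that("simulated loci are recovered with correct on/off-target labels", {
    cfg <- simConfig(seed = 29, n_loci = 60, n_individuals_per_species = 6,
                     species_divergences = c(A = 0.02, B = 0.05))
    tr <- simulateTruth(cfg)
    anc <- ancestralLoci(tr)
    targeted <- names(anc)[1:40]
    probes <- tileProbes(anc[targeted])
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 20))
    ref <- buildReference(pr$fragments, probes)
    ev <- referenceRecovery(ref, tr, targeted)
    expect_gte(ev$recovery_rate, 0.95)
    expect_gte(ev$label_accuracy, 0.95)
})

test_that("reference building works from a probe FASTA round trip", {
    set.seed(6)
    locusA <- rand_dna(1, 200)
    probes <- tileProbes(setNames(locusA, "A"))
    path <- file.path(tempdir(), "probes.fasta")
    exportProbes(probes, path)
    back <- Biostrings::readDNAStringSet(path)
    ref <- buildReference(rep(locusA, 50), back)
    rt <- refTable(ref)
    ## two probes of one template must not read as a chimera
    expect_equal(nrow(rt), 1L)
    expect_identical(rt$origin, "on_target")
    expect_identical(rt$probe_hit, "A")
})

test_that("coverage metrics match hand-computed values", {
    refs <- c(L1 = 100L)
    one <- make_aln("L1", 0, strrep("A", 100), ref_lengths = refs)
    cm <- coverageMetrics(one)
    expect_equal(cm$mean_depth, 1.0)
    expect_equal(cm$gc_pct, 0)
    gg <- make_aln("L1", 0, strrep("GC", 50), ref_lengths = refs)
    expect_equal(coverageMetrics(gg)$gc_pct, 100)
})

test_that("heterozygous read rate reflects the injected error rate", {
    cfg <- simConfig(seed = 37, n_loci = 25,
                     species_divergences = c(A = 0), theta_het = 0,
                     n_individuals_per_species = 4, error_rate = 0.01)
    tr <- simulateTruth(cfg)
    pr <- processReads(emitReads(tr, cfg, "capture"),
                       params = readProcParams(min_mean_phred = 19))
    al <- markDuplicates(mapReads(pr$fragments, ancestralLoci(tr)))
    cm <- coverageMetrics(al)
    ## every injected error substitutes a different base, so the expected
    ## mismatch rate equals the error rate (merged overlaps halve it a
    ## touch where the two mates disagree; allow a generous band)
    expect_gt(mean(cm$het_read_rate), 0.005)
    expect_lt(mean(cm$het_read_rate), 0.015)
})
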