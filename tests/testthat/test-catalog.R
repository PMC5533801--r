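test_that("within-sample clustering calls consensus and ambiguity", {
    set.seed(1)
    base <- rand_dna(1, 140)
    ## 20 identical reads -> one clean cluster
    cl <- clusterWithinSample(rep(base, 20))
    expect_equal(nrow(cl), 1L)
    expect_identical(cl$consensus, base)
    expect_equal(cl$n_het, 0L)
    ## two alleles differing at 2 sites -> one cluster, 2 ambiguity columns
    alt <- mutate_positions(base, c(30, 90))
    cl2 <- clusterWithinSample(c(rep(base, 10), rep(alt, 10)))
    expect_equal(nrow(cl2), 1L)
    expect_equal(cl2$n_het, 2L)
    ## 10 differences over 140 bp (92.9% identity) -> two clusters
    far <- mutate_positions(base, seq(10, 100, by = 10))
    cl3 <- clusterWithinSample(c(rep(base, 10), rep(far, 10)))
    expect_equal(nrow(cl3), 2L)
    ## degenerate inputs
    expect_equal(nrow(clusterWithinSample(character())), 0L)
    expect_error(clusterWithinSample("ACGT"), "50 bp")
})

test_that("catalogue building counts individuals and flags shared het", {
    set.seed(2)
    base <- rand_dna(1, 150)
    mkclust <- function(consensus)
        data.frame(consensus = consensus, depth = 20L, n_het = 0L,
                   discarded = FALSE, stringsAsFactors = FALSE)
    ## same consensus in 5 samples -> one locus, n_individuals 5
    ps <- setNames(rep(list(mkclust(base)), 5), paste0("S", 1:5))
    cat1 <- buildCatalog(ps, sim = 0.85, source = "species1")
    expect_equal(nrow(lociTable(cat1)), 1L)
    expect_equal(lociTable(cat1)$n_individuals, 5L)
    expect_equal(lociFlags(cat1)[[1]], character())

    ## a column heterozygous (IUPAC) in 5 of 8 samples -> flagged (5 > 4);
    ## in exactly 4 -> not flagged
    hetseq <- mutate_positions(base, 60, to = "R")
    for (n_het_samples in c(4L, 5L)) {
        ps8 <- setNames(c(rep(list(mkclust(hetseq)), n_het_samples),
                          rep(list(mkclust(base)), 8 - n_het_samples)),
                        paste0("S", 1:8))
        cc <- buildCatalog(ps8, sim = 0.85, source = "species1")
        expect_equal(nrow(lociTable(cc)), 1L)
        flagged <- "paralog_shared_het" %in% lociFlags(cc)[[1]]
        expect_identical(flagged, n_het_samples > 4L)
    }

    ## a column with 4 distinct bases across samples -> paralog flag
    ps4 <- setNames(lapply(c("A", "C", "G", "T"), function(b)
        mkclust(mutate_positions(base, 10, to = b))), paste0("S", 1:4))
    c4 <- buildCatalog(ps4, sim = 0.85, source = "species1")
    expect_true("paralog_shared_het" %in% lociFlags(c4)[[1]])
})

test_that("redundant loci merge by transitive closure across assemblies", {
    set.seed(3)
    a <- rand_dna(1, 160)
    mk <- function(seqs, samples, source) {
        ps <- setNames(lapply(seqs, function(s)
            data.frame(consensus = s, depth = 10L, n_het = 0L,
                       discarded = FALSE, stringsAsFactors = FALSE)),
            samples)
        buildCatalog(ps, sim = 0.99, source = source)
    }
    ## identical locus in two catalogues -> merged once, flagged redundant
    c1 <- mk(list(a), "S1", "species1")
    c2 <- mk(list(a), "S2", "species2")
    m <- synonymizeRedundant(list(c1, c2))
    expect_equal(nrow(lociTable(m)), 1L)
    expect_true("redundant" %in% lociFlags(m)[[1]])
    expect_equal(attr(m, "n_merged"), 1L)

    ## 80% identity -> not merged
    far <- mutate_positions(a, seq(4, 128, by = 4))   # 32 subs -> 80%
    m2 <- synonymizeRedundant(list(c1, mk(list(far), "S2", "species2")))
    expect_equal(nrow(lociTable(m2)), 2L)

    ## chain A~B, B~C with A !~ C -> one merged group (union-find closure)
    b <- mutate_positions(a, seq(10, 100, by = 10))        # 10 subs, 93.8%
    cseq <- mutate_positions(b, seq(15, 105, by = 10))     # 10 more
    idAC <- 1 - radcapkit:::cpp_hamming(a, cseq) / 160
    expect_lt(idAC, 0.90)
    m3 <- synonymizeRedundant(list(mk(list(a), "S1", "species1"),
                                   mk(list(b), "S2", "species2"),
                                   mk(list(cseq), "S3", "combined")))
    expect_equal(nrow(lociTable(m3)), 1L)
    expect_equal(lociTable(m3)$n_individuals, 3L)
})

test_that("similarity purge flags pairs above 90% over 55% coverage", {
    set.seed(4)
    a <- rand_dna(1, 200)
    near <- mutate_positions(a, seq(20, 200, by = 20))     # 95% identity
    mkcat <- function(seqs) {
        loci <- data.frame(locus_id = sprintf("L%02d", seq_along(seqs)),
                           consensus = unlist(seqs),
                           length = nchar(unlist(seqs)),
                           n_individuals = 12L, source = "species1",
                           flags = "", stringsAsFactors = FALSE)
        al <- lapply(seqs, function(s) setNames(s, "S1"))
        names(al) <- loci$locus_id
        loci$n_individuals <- 1L
        new("LocusCatalog", loci = loci, alleles = al)
    }
    p1 <- purgeSimilarLoci(mkcat(list(a, near)))
    expect_true(all(vapply(lociFlags(p1), function(f)
        "paralog_similarity" %in% f, TRUE)))

    ## 95% identical over only half the length -> coverage below 55%
    tail_random <- rand_dna(1, 100)
    halfsim <- paste0(substr(near, 1, 100), tail_random)
    p2 <- purgeSimilarLoci(mkcat(list(a, halfsim)))
    expect_false(any(vapply(lociFlags(p2), function(f)
        "paralog_similarity" %in% f, TRUE)))

    ## mutually dissimilar random loci -> zero flags
    p3 <- purgeSimilarLoci(mkcat(as.list(rand_dna(6, 180))))
    expect_true(all(lengths(lociFlags(p3)) == 0L))
})

test_that("low-complexity masking catches runs and dimer repeats", {
    set.seed(5)
    mkcat <- function(seqs) {
        loci <- data.frame(locus_id = sprintf("L%02d", seq_along(seqs)),
                           consensus = unlist(seqs),
                           length = nchar(unlist(seqs)),
                           n_individuals = 1L, source = "species1",
                           flags = "", stringsAsFactors = FALSE)
        al <- lapply(seqs, function(s) setNames(s, "S1"))
        names(al) <- loci$locus_id
        new("LocusCatalog", loci = loci, alleles = al)
    }
    rnd <- rand_dna(1, 200)
    homo <- paste0(substr(rnd, 1, 90), strrep("A", 10),
                   substr(rnd, 101, 200))
    dimer <- strrep("AC", 70)
    mc <- maskLowComplexity(mkcat(list(rnd, homo, dimer)))
    fl <- lociFlags(mc)
    expect_false("low_complexity" %in% fl[[1]])
    expect_true("low_complexity" %in% fl[[2]])
    expect_true("low_complexity" %in% fl[[3]])
    ## brute-force triplet score agrees with the flag for the dimer repeat
    w <- substr(dimer, 1, 64)
    tri <- substring(w, 1:62, 3:64)
    score <- sum(table(tri) * (table(tri) - 1) / 2) / 61
    expect_gt(score, 2)
})

test_that("mitochondrial screen is strand-aware", {
    set.seed(6)
    mito <- rand_dna(1, 600)
    seg <- substr(mito, 101, 280)
    mkcat <- function(seqs) {
        loci <- data.frame(locus_id = sprintf("L%02d", seq_along(seqs)),
                           consensus = unlist(seqs),
                           length = nchar(unlist(seqs)),
                           n_individuals = 1L, source = "species1",
                           flags = "", stringsAsFactors = FALSE)
        al <- lapply(seqs, function(s) setNames(s, "S1"))
        names(al) <- loci$locus_id
        new("LocusCatalog", loci = loci, alleles = al)
    }
    cat3 <- mkcat(list(seg, revcomp(seg), rand_dna(1, 180)))
    sc <- screenMitochondrial(cat3, mito)
    fl <- lociFlags(sc)
    expect_true("mitochondrial" %in% fl[[1]])
    expect_true("mitochondrial" %in% fl[[2]])
    expect_false("mitochondrial" %in% fl[[3]])
    expect_warning(screenMitochondrial(cat3, NULL), "skipped")
})

test_that("candidate selection respects individual floors and flags", {
    set.seed(7)
    mkcat <- function(n_ind, source, flags = "") {
        loci <- data.frame(locus_id = "L01", consensus = rand_dna(1, 150),
                           length = 150L, n_individuals = n_ind,
                           source = source, flags = flags,
                           stringsAsFactors = FALSE)
        al <- list(L01 = setNames(rep(loci$consensus, n_ind),
                                  paste0("S", seq_len(n_ind))))
        new("LocusCatalog", loci = loci, alleles = al)
    }
    is_cand <- function(cat) "candidate" %in% lociFlags(selectCandidates(cat))[[1]]
    expect_true(is_cand(mkcat(10L, "species1")))
    expect_false(is_cand(mkcat(9L, "species1")))
    expect_true(is_cand(mkcat(20L, "combined")))
    expect_false(is_cand(mkcat(19L, "combined")))
    expect_false(is_cand(mkcat(40L, "species1", "paralog_similarity")))
})

test_that("probe tiling is end-anchored with deduplicated offsets", {
    set.seed(8)
    tpl <- setNames(rand_dna(3, 1), c("a", "b", "c"))
    tpl <- setNames(c(rand_dna(1, 140), rand_dna(1, 120),
                      rand_dna(1, 240)), c("a", "b", "c"))
    pb <- probeTable(tileProbes(tpl))
    offs <- split(pb$offset, pb$parent_locus_id)
    expect_identical(offs$a, c(0L, 20L))
    expect_identical(offs$b, 0L)
    expect_identical(offs$c, c(0L, 60L, 120L))
    expect_true(all(nchar(pb$sequence) == 120L))
    ## every length in (120, 180] yields exactly 2 probes
    lens <- 121:180
    tp2 <- tileProbes(setNames(vapply(lens, function(L)
        rand_dna(1, L), ""), paste0("t", lens)))
    counts <- table(probeTable(tp2)$parent_locus_id)
    expect_true(all(counts == 2L))
    expect_error(tileProbes(setNames(rand_dna(1, 100), "short")),
                 "short")
})

test_that("a clean simulated experiment is fully recovered as candidates", {
    cfg <- simConfig(seed = 31, n_loci = 15,
                     species_divergences = c(A = 0.01),
                     n_individuals_per_species = 12, theta_het = 0.003,
                     dropout_per_substitution = 0, error_rate = 0)
    tr <- simulateTruth(cfg)
    rp <- emitReads(tr, cfg, "ddrad")
    pr <- processReads(rp, params = readProcParams(min_mean_phred = 20),
                       mode = "ddrad")
    per_sample <- lapply(split(pr$fragments$seq, pr$fragments$sample),
                         clusterWithinSample)
    cat1 <- buildCatalog(per_sample, sim = 0.95, source = "species1")
    cat1 <- selectCandidates(cat1)
    expect_equal(nrow(lociTable(cat1)), 15L)
    expect_true(all(vapply(lociFlags(cat1), function(f)
        "candidate" %in% f, TRUE)))
})
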