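## Central S4 containers.  Tabular slots are plain data.frames (one row per
## record) wrapped behind accessors; sequence payloads are character vectors
## internally and DNAStringSet at the interfaces.

#' Simulation configuration for synthetic ddRAD / capture experiments
#'
#' Holds every tunable of the synthetic-experiment generator.  Defaults
#' describe a modern multi-species capture experiment: loci of 140-220 bp
#' flanked by 6 bp restriction half-sites, Jukes-Cantor style divergence from
#' a common ancestor, deterministic allele dropout when a restriction
#' half-site is mutated, divergence-dependent capture efficiency with
#' half-life 0.1 substitutions/site, 20 fragments per locus per individual,
#' 0.5\% base error and no PCR duplication or damage.
#'
#' @slot seed integer RNG seed; identical seeds give byte-identical output.
#' @slot n_loci number of ancestral loci.
#' @slot locus_length_range integer pair, locus length bounds in bp.
#' @slot species_divergences named numeric, substitutions/site from the
#'   ancestor per species.
#' @slot n_individuals_per_species integer.
#' @slot theta_het per-site probability that an individual is heterozygous.
#' @slot restriction_site_len length in bp of each terminal half-site.
#' @slot dropout_per_substitution probability an allele drops out of a ddRAD
#'   library given its restriction half-site carries at least one
#'   substitution.
#' @slot capture_halflife divergence at which capture efficiency halves.
#' @slot coverage_mean expected fragments (read pairs) per locus per
#'   individual before capture-efficiency downweighting.
#' @slot error_rate per-base sequencing error probability.
#' @slot duplicate_fraction fraction of emitted fragments that are PCR
#'   copies of another fragment.
#' @slot damage_delta terminal deamination probability at fragment
#'   position 1 (museum era only).
#' @slot damage_lambda per-position geometric decay of deamination.
#' @slot fragmentation_mean mean insert length (bp) for museum-era
#'   fragments.
#' @slot insert_mean,insert_sd sonication insert-length distribution for
#'   modern-era capture fragments.
#' @slot read_length sequenced read length per mate.
#' @slot era "modern" or "museum".
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    n_loci = "integer",
    locus_length_range = "integer",
    species_divergences = "numeric",
    n_individuals_per_species = "integer",
    theta_het = "numeric",
    restriction_site_len = "integer",
    dropout_per_substitution = "numeric",
    capture_halflife = "numeric",
    coverage_mean = "numeric",
    error_rate = "numeric",
    duplicate_fraction = "numeric",
    damage_delta = "numeric",
    damage_lambda = "numeric",
    fragmentation_mean = "numeric",
    insert_mean = "numeric",
    insert_sd = "numeric",
    read_length = "integer",
    era = "character"))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(theta_het = object@theta_het,
            dropout_per_substitution = object@dropout_per_substitution,
            error_rate = object@error_rate,
            duplicate_fraction = object@duplicate_fraction,
            damage_delta = object@damage_delta,
            damage_lambda = object@damage_lambda)
    bad <- names(pr)[pr < 0 | pr > 1]
    if (length(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(bad, collapse = ", ")))
    if (object@n_loci < 1L) msg <- c(msg, "n_loci must be >= 1")
    r <- object@locus_length_range
    if (length(r) != 2L || r[1] > r[2] || r[1] < 121L || r[2] > 1000L)
        msg <- c(msg, "locus_length_range must lie within [121, 1000]")
    if (any(object@species_divergences < 0) ||
        any(object@species_divergences > 0.75))
        msg <- c(msg, "species divergences must lie in [0, 0.75]")
    if (is.null(names(object@species_divergences)) ||
        anyDuplicated(names(object@species_divergences)))
        msg <- c(msg, "species_divergences must have unique names")
    if (!object@era %in% c("modern", "museum"))
        msg <- c(msg, "era must be 'modern' or 'museum'")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed integer RNG seed.
#' @param n_loci number of ancestral loci.
#' @param locus_length_range bp bounds of locus length (inclusive).
#' @param species_divergences named numeric vector of substitutions/site.
#' @param n_individuals_per_species individuals per species.
#' @param theta_het per-site heterozygosity probability within individuals.
#' @param restriction_site_len bp per terminal restriction half-site.
#' @param dropout_per_substitution dropout probability given a mutated
#'   half-site.
#' @param capture_halflife divergence at which capture efficiency halves.
#' @param coverage_mean expected fragments/locus/individual.
#' @param error_rate per-base sequencing error.
#' @param duplicate_fraction fraction of fragments that are PCR copies.
#' @param damage_delta 5' deamination probability at position 1.
#' @param damage_lambda geometric decay of deamination per position.
#' @param fragmentation_mean museum-mode mean insert (bp).
#' @param insert_mean,insert_sd modern sonication insert distribution (bp).
#' @param read_length mate length (bp).
#' @param era "modern" or "museum".
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_loci = 20)
#' cfg
#' @export
simConfig <- function(seed = 1L, n_loci = 100L,
                      locus_length_range = c(140L, 220L),
                      species_divergences = c(A = 0.02, B = 0.05, C = 0.08),
                      n_individuals_per_species = 8L,
                      theta_het = 0.005,
                      restriction_site_len = 6L,
                      dropout_per_substitution = 1.0,
                      capture_halflife = 0.1,
                      coverage_mean = 20,
                      error_rate = 0.005,
                      duplicate_fraction = 0,
                      damage_delta = 0,
                      damage_lambda = 0.5,
                      fragmentation_mean = 90,
                      insert_mean = 120,
                      insert_sd = 30,
                      read_length = 120L,
                      era = c("modern", "museum")) {
    era <- match.arg(era)
    new("SimConfig", seed = as.integer(seed), n_loci = as.integer(n_loci),
        locus_length_range = as.integer(locus_length_range),
        species_divergences = species_divergences,
        n_individuals_per_species = as.integer(n_individuals_per_species),
        theta_het = theta_het,
        restriction_site_len = as.integer(restriction_site_len),
        dropout_per_substitution = dropout_per_substitution,
        capture_halflife = capture_halflife,
        coverage_mean = coverage_mean, error_rate = error_rate,
        duplicate_fraction = duplicate_fraction,
        damage_delta = damage_delta, damage_lambda = damage_lambda,
        fragmentation_mean = fragmentation_mean,
        insert_mean = insert_mean, insert_sd = insert_sd,
        read_length = as.integer(read_length), era = era)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_loci, "loci,",
        length(object@species_divergences), "species x",
        object@n_individuals_per_species, "individuals,",
        object@era, "era, seed", object@seed, "\n")
    cat("  divergences:",
        paste0(names(object@species_divergences), "=",
               object@species_divergences, collapse = ", "), "\n")
})

#' Known truth of a synthetic experiment
#'
#' Produced by [simulateTruth()].  Slot `alleles` is the flat per-allele
#' table: one row per (individual, locus, allele copy) with its full
#' sequence and its ddRAD dropout status; `haplotypes` holds one derived
#' haplotype per (species, locus).
#'
#' @slot config the [SimConfig-class] used.
#' @slot ancestral named character, ancestral locus sequences.
#' @slot haplotypes list species -> named character of per-locus haplotypes.
#' @slot alleles data.frame: sample, species, locus, allele (1/2), seq,
#'   dropped (logical ddRAD dropout), site_mutated (logical: restriction
#'   half-site carries a substitution).
#' @slot sheet data.frame sample sheet: sample, i5, i7, species, year,
#'   a260_a280, conc_ng_ul.
#' @export
setClass("TruthSet", representation(
    config = "SimConfig",
    ancestral = "character",
    haplotypes = "list",
    alleles = "data.frame",
    sheet = "data.frame"))

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", length(object@ancestral), "loci,",
        length(object@haplotypes), "species,",
        nrow(object@sheet), "individuals;",
        sum(object@alleles$dropped), "ddRAD dropout alleles\n")
})

#' @describeIn TruthSet-class ancestral locus sequences as a DNAStringSet.
#' @param truth a TruthSet.
#' @export
ancestralLoci <- function(truth) {
    stopifnot(is(truth, "TruthSet"))
    Biostrings::DNAStringSet(truth@ancestral)
}

#' @describeIn TruthSet-class the per-allele truth table.
#' @export
alleleTable <- function(truth) {
    stopifnot(is(truth, "TruthSet"))
    truth@alleles
}

#' @describeIn TruthSet-class the simulated sample sheet.
#' @export
sampleSheet <- function(truth) {
    stopifnot(is(truth, "TruthSet"))
    truth@sheet
}

#' Paired sequencing reads with emission truth
#'
#' Returned by [emitReads()].  Parallel character slots hold mate sequences
#' and Phred+33 qualities; `truth` records, per pair, the emitting sample,
#' locus, fragment coordinates, duplicate status and damage counts.
#'
#' @slot id read id stems.
#' @slot seq1,qual1,seq2,qual2 mate sequences/qualities.
#' @slot i5,i7 dual index sequences attached to each pair.
#' @slot truth data.frame of emission truth (sample, species, locus, allele,
#'   frag_start, insert, strand, is_duplicate, source_id, n_damage).
#' @slot sheet sample sheet as in [TruthSet-class].
#' @export
setClass("ReadPairSet", representation(
    id = "character", seq1 = "character", qual1 = "character",
    seq2 = "character", qual2 = "character",
    i5 = "character", i7 = "character",
    truth = "data.frame", sheet = "data.frame"))

setValidity("ReadPairSet", function(object) {
    n <- length(object@id)
    lens <- c(length(object@seq1), length(object@qual1), length(object@seq2),
              length(object@qual2), length(object@i5), length(object@i7))
    if (any(lens != n)) return("parallel slots differ in length")
    if (nrow(object@truth) && nrow(object@truth) != n)
        return("truth table does not match read count")
    if (any(nchar(object@seq1) != nchar(object@qual1)) ||
        any(nchar(object@seq2) != nchar(object@qual2)))
        return("sequence and quality lengths differ")
    TRUE
})

setMethod("length", "ReadPairSet", function(x) length(x@id))

setMethod("show", "ReadPairSet", function(object) {
    cat("ReadPairSet:", length(object), "read pairs,",
        length(unique(object@truth$sample)), "samples;",
        sum(object@truth$is_duplicate), "PCR duplicates\n")
})

setMethod("[", "ReadPairSet", function(x, i, j, ..., drop = TRUE) {
    new("ReadPairSet", id = x@id[i], seq1 = x@seq1[i], qual1 = x@qual1[i],
        seq2 = x@seq2[i], qual2 = x@qual2[i], i5 = x@i5[i], i7 = x@i7[i],
        truth = x@truth[i, , drop = FALSE], sheet = x@sheet)
})

#' @describeIn ReadPairSet-class emission truth table.
#' @param x a ReadPairSet.
#' @export
readTruth <- function(x) {
    stopifnot(is(x, "ReadPairSet"))
    x@truth
}

#' RAD locus catalogue
#'
#' One row of `loci` per catalogue locus: IUPAC consensus, number of
#' individuals present, source assembly and accumulated filter flags
#' (semicolon-joined).  `alleles` holds, per locus, the per-sample consensus
#' sequences that clustered into it.
#'
#' @slot loci data.frame: locus_id, consensus, length, n_individuals,
#'   source, flags.
#' @slot alleles named list: locus_id -> named character of per-sample
#'   allele consensi (names = sample, possibly repeated for two alleles).
#' @export
setClass("LocusCatalog", representation(
    loci = "data.frame", alleles = "list"))

setValidity("LocusCatalog", function(object) {
    if (nrow(object@loci) != length(object@alleles))
        return("allele list does not match locus table")
    ni <- vapply(object@alleles, function(a) length(unique(names(a))), 0L)
    if (nrow(object@loci) && any(ni != object@loci$n_individuals))
        return("n_individuals inconsistent with per-sample alleles")
    TRUE
})

setMethod("show", "LocusCatalog", function(object) {
    fl <- lociFlags(object)
    cat("LocusCatalog:", nrow(object@loci), "loci (",
        sum(vapply(fl, function(f) "candidate" %in% f, TRUE)),
        "candidates );", sum(lengths(fl) > 0), "flagged\n")
})

#' @describeIn LocusCatalog-class the locus table.
#' @param x a LocusCatalog.
#' @export
lociTable <- function(x) {
    stopifnot(is(x, "LocusCatalog"))
    x@loci
}

#' @describeIn LocusCatalog-class flags as a list of character vectors.
#' @export
lociFlags <- function(x) {
    stopifnot(is(x, "LocusCatalog"))
    out <- strsplit(x@loci$flags, ";", fixed = TRUE)
    lapply(out, function(f) f[nzchar(f)])
}

#' @describeIn LocusCatalog-class consensus sequences (IUPAC) as a
#'   DNAStringSet.
#' @export
consensusSeqs <- function(x) {
    stopifnot(is(x, "LocusCatalog"))
    Biostrings::DNAStringSet(setNames(x@loci$consensus, x@loci$locus_id))
}

#' Tiled capture probe set
#'
#' @slot probes data.frame: probe_id, parent_locus_id, offset (0-based),
#'   sequence (probe-length bp).
#' @export
setClass("ProbeSet", representation(probes = "data.frame"))

setValidity("ProbeSet", function(object) {
    p <- object@probes
    if (nrow(p) && length(unique(nchar(p$sequence))) > 1)
        return("probes differ in length")
    if (nrow(p) && any(p$offset < 0)) return("negative probe offset")
    TRUE
})

setMethod("length", "ProbeSet", function(x) nrow(x@probes))

setMethod("show", "ProbeSet", function(object) {
    cat("ProbeSet:", nrow(object@probes), "probes on",
        length(unique(object@probes$parent_locus_id)), "template loci\n")
})

#' @describeIn ProbeSet-class the probe table.
#' @param x a ProbeSet.
#' @export
probeTable <- function(x) {
    stopifnot(is(x, "ProbeSet"))
    x@probes
}

#' @describeIn ProbeSet-class probe sequences as a DNAStringSet.
#' @export
probeSeqs <- function(x) {
    stopifnot(is(x, "ProbeSet"))
    Biostrings::DNAStringSet(setNames(x@probes$sequence, x@probes$probe_id))
}

#' Read-to-locus alignments
#'
#' A flat table of placements (0-based, half-open coordinates) plus the
#' reference locus lengths.  Sequences are stored reference-oriented;
#' `strand` records the sequenced orientation.
#'
#' @slot records data.frame: read_id, sample, locus, start, end, strand,
#'   n_mismatch, maq, insert_len, is_duplicate, seq, qual, mean_q.
#' @slot refLengths named integer of reference locus lengths.
#' @export
setClass("AlignmentSet", representation(
    records = "data.frame", refLengths = "integer"))

setValidity("AlignmentSet", function(object) {
    r <- object@records
    if (!nrow(r)) return(TRUE)
    if (any(r$start < 0) || any(r$end <= r$start))
        return("invalid coordinates (need 0 <= start < end)")
    if (any(r$maq < 0)) return("negative mapping quality")
    len <- object@refLengths[r$locus]
    if (any(is.na(len)) || any(r$end > len))
        return("alignment exceeds reference locus length")
    TRUE
})

setMethod("length", "AlignmentSet", function(x) nrow(x@records))

setMethod("show", "AlignmentSet", function(object) {
    r <- object@records
    cat("AlignmentSet:", nrow(r), "alignments on",
        length(object@refLengths), "loci;",
        sum(r$is_duplicate), "duplicates flagged;",
        sum(r$maq >= 5), "with maQ >= 5\n")
})

#' @describeIn AlignmentSet-class the alignment table.
#' @param x an AlignmentSet.
#' @export
alignments <- function(x) {
    stopifnot(is(x, "AlignmentSet"))
    x@records
}

#' Assembly-based reference loci
#'
#' @slot loci data.frame: ref_id, sequence, n_supporting_reads, origin
#'   ("on_target"/"off_target"), probe_hit (template locus id or NA), flags
#'   (semicolon-joined over paralog/chimera/mitochondrial/artefact).
#' @export
setClass("ReferenceSet", representation(loci = "data.frame"))

setMethod("length", "ReferenceSet", function(x) nrow(x@loci))

setMethod("show", "ReferenceSet", function(object) {
    l <- object@loci
    cat("ReferenceSet:", nrow(l), "loci (",
        sum(l$origin == "on_target"), "on-target,",
        sum(l$origin == "off_target"), "off-target );",
        sum(nzchar(l$flags)), "flagged\n")
})

#' @describeIn ReferenceSet-class the reference locus table.
#' @param x a ReferenceSet.
#' @export
refTable <- function(x) {
    stopifnot(is(x, "ReferenceSet"))
    x@loci
}

#' @describeIn ReferenceSet-class reference sequences as a DNAStringSet.
#' @export
refSeqs <- function(x) {
    stopifnot(is(x, "ReferenceSet"))
    Biostrings::DNAStringSet(setNames(x@loci$sequence, x@loci$ref_id))
}

#' Called and annotated variant sites
#'
#' Site annotations follow hard-filter conventions: QUAL is the
#' phred-scaled probability that every sample is homozygous reference, QD is
#' QUAL over the summed depth of alt-carrying samples, MQ the
#' root-mean-square mapping quality of covering reads, FS the phred-scaled
#' two-sided Fisher exact p of the strand x allele table, and ReadPosZ a
#' rank-sum z statistic of alt vs ref distances to the nearer read end.
#'
#' @slot sites data.frame: locus, pos (0-based), ref, alt, n_alt_alleles,
#'   QUAL, QD, MQ, FS, ReadPosZ, n_samples_5x, filter.
#' @slot geno integer matrix samples x sites of alt-allele dosage (0/1/2,
#'   NA = missing).
#' @slot gq,dp,adAlt numeric/integer matrices parallel to `geno`.
#' @slot samples,species character vectors describing the rows of `geno`.
#' @export
setClass("VariantSet", representation(
    sites = "data.frame", geno = "matrix", gq = "matrix", dp = "matrix",
    adAlt = "matrix", samples = "character", species = "character"))

setValidity("VariantSet", function(object) {
    n <- length(object@samples)
    m <- nrow(object@sites)
    for (sl in c("geno", "gq", "dp", "adAlt")) {
        mt <- slot(object, sl)
        if (!identical(dim(mt), c(n, m)))
            return(sprintf("%s matrix is not samples x sites", sl))
    }
    if (length(object@species) != n)
        return("species labels do not match samples")
    if (m && any(object@sites$FS < 0, na.rm = TRUE))
        return("FS must be non-negative")
    TRUE
})

setMethod("length", "VariantSet", function(x) nrow(x@sites))

setMethod("show", "VariantSet", function(object) {
    s <- object@sites
    cat("VariantSet:", nrow(s), "sites x", length(object@samples),
        "samples;", sum(s$filter == "PASS"), "PASS\n")
})

setMethod("[", "VariantSet", function(x, i, j, ..., drop = TRUE) {
    new("VariantSet", sites = x@sites[i, , drop = FALSE],
        geno = x@geno[, i, drop = FALSE], gq = x@gq[, i, drop = FALSE],
        dp = x@dp[, i, drop = FALSE], adAlt = x@adAlt[, i, drop = FALSE],
        samples = x@samples, species = x@species)
})

#' @describeIn VariantSet-class the per-site annotation table.
#' @param x a VariantSet.
#' @export
siteTable <- function(x) {
    stopifnot(is(x, "VariantSet"))
    x@sites
}

#' @describeIn VariantSet-class alt-dosage genotype matrix (samples x
#'   sites).
#' @export
genotypes <- function(x) {
    stopifnot(is(x, "VariantSet"))
    x@geno
}

#' @describeIn VariantSet-class subset to sites whose filter status is PASS.
#' @export
passSites <- function(x) {
    stopifnot(is(x, "VariantSet"))
    x[x@sites$filter == "PASS"]
}

#' Genotype matrix for population statistics
#'
#' @slot geno integer matrix samples x sites, alt dosage 0/1/2, NA missing.
#' @slot species character per sample.
#' @slot sites data.frame with at least locus and pos.
#' @export
setClass("GenotypeMatrix", representation(
    geno = "matrix", species = "character", sites = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
    if (length(object@species) != nrow(object@geno))
        return("species labels do not match samples")
    if (nrow(object@sites) != ncol(object@geno))
        return("site table does not match genotype columns")
    g <- object@geno
    if (length(g) && !all(g[!is.na(g)] %in% 0:2))
        return("genotype codes must be 0/1/2 or NA")
    TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@geno), "samples x",
        ncol(object@geno), "sites;",
        round(100 * mean(is.na(object@geno)), 2), "% missing\n")
})

#' Construct a GenotypeMatrix
#'
#' @param geno samples x sites matrix of alt dosages (0/1/2/NA).
#' @param species character vector of population labels per sample.
#' @param sites optional site table (locus, pos); a default is built.
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(geno, species, sites = NULL) {
    if (is(geno, "VariantSet")) {
        vs <- geno
        return(new("GenotypeMatrix", geno = vs@geno, species = vs@species,
                   sites = vs@sites[, c("locus", "pos")]))
    }
    geno <- as.matrix(geno)
    mode(geno) <- "integer"
    if (is.null(sites))
        sites <- data.frame(locus = paste0("S", seq_len(ncol(geno))),
                            pos = seq_len(ncol(geno)) - 1L)
    new("GenotypeMatrix", geno = geno, species = as.character(species),
        sites = sites)
}

#' Per-sample damage profile
#'
#' @slot sample sample id.
#' @slot ct5,ga3 numeric vectors: C->T frequency by 5' read position and
#'   G->A frequency by distance from the 3' end.
#' @slot delta,lambda least-squares fit of f(p) = delta * lambda^(p-1) to
#'   the 5' C->T profile.
#' @slot background interior (positions 11..P) per-base mismatch rate.
#' @slot n_informative number of scored terminal positions.
#' @slot no_damage TRUE when the fitted delta is below twice the background
#'   rate.
#' @slot reliable FALSE when fewer than 1000 informative positions were
#'   available.
#' @export
setClass("DamageProfile", representation(
    sample = "character", ct5 = "numeric", ga3 = "numeric",
    delta = "numeric", lambda = "numeric", background = "numeric",
    n_informative = "numeric", no_damage = "logical",
    reliable = "logical"))

setValidity("DamageProfile", function(object) {
    if (length(object@ct5) != length(object@ga3))
        return("ct5 and ga3 must have equal length")
    f <- c(object@ct5, object@ga3)
    if (any(f[!is.na(f)] < 0 | f[!is.na(f)] > 1))
        return("frequencies outside [0,1]")
    TRUE
})

setMethod("show", "DamageProfile", function(object) {
    cat(sprintf(
        "DamageProfile [%s]: delta=%.4f lambda=%.3f background=%.5f%s%s\n",
        object@sample, object@delta, object@lambda, object@background,
        if (object@no_damage) " (no damage detected)" else "",
        if (!object@reliable) " [unreliable: few informative positions]"
        else ""))
})

#' Weir-Cockerham Fst estimate
#'
#' @slot perSite data.frame of per-site components a, b, c and theta.
#' @slot theta global ratio-of-sums estimate sum(a)/sum(a+b+c).
#' @slot r number of populations.
#' @export
setClass("FstEstimate", representation(
    perSite = "data.frame", theta = "numeric", r = "integer"))

setMethod("show", "FstEstimate", function(object) {
    cat(sprintf("FstEstimate: global theta = %.4f over %d sites, %d pops\n",
                object@theta, nrow(object@perSite), object@r))
})

#' @describeIn FstEstimate-class the global ratio-of-sums theta.
#' @param x an FstEstimate.
#' @export
globalTheta <- function(x) {
    stopifnot(is(x, "FstEstimate"))
    x@theta
}
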