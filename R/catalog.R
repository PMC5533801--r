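## ddRAD locus catalogue: within/across-sample greedy clustering, paralog,
## low-complexity and mitochondrial screening, candidate selection, probe
## tiling.

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
AMBIG_EXPAND <- c(M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT")

#' Catalogue-building thresholds
#'
#' Defaults: 95\% within-species and 85\% across-species clustering
#' identity, at most 3 mismatches and 0.5 site heterozygosity per
#' within-sample cluster, a shared-heterozygosity paralog flag above 4
#' individuals, a 3-distinct-base column cap, candidate thresholds of 10
#' (single-species) / 20 (combined) individuals, a 90\%-identity /
#' 55\%-coverage similarity purge scoped by a 75\% grouping threshold, and
#' 120-mer probes at 60 bp step.
#'
#' @param within_sim,across_sim clustering identity thresholds.
#' @param max_mismatch,max_site_het within-sample cluster caps.
#' @param shared_het_max_individuals flag loci with a column heterozygous in
#'   more than this many individuals.
#' @param paralog_filter maximum distinct bases per catalogue column.
#' @param min_individuals_single,min_individuals_combined candidate floors.
#' @param purge_similarity,purge_coverage,assembly_sim similarity purge.
#' @param probe_len,probe_step probe tiling geometry.
#' @return A named list of thresholds.
#' @export
catalogThresholds <- function(within_sim = 0.95, across_sim = 0.85,
                              max_mismatch = 3L, max_site_het = 0.5,
                              shared_het_max_individuals = 4L,
                              paralog_filter = 3L,
                              min_individuals_single = 10L,
                              min_individuals_combined = 20L,
                              purge_similarity = 0.90, purge_coverage = 0.55,
                              assembly_sim = 0.75,
                              probe_len = 120L, probe_step = 60L) {
    th <- list(within_sim = within_sim, across_sim = across_sim,
               max_mismatch = as.integer(max_mismatch),
               max_site_het = max_site_het,
               shared_het_max_individuals =
                   as.integer(shared_het_max_individuals),
               paralog_filter = as.integer(paralog_filter),
               min_individuals_single = as.integer(min_individuals_single),
               min_individuals_combined =
                   as.integer(min_individuals_combined),
               purge_similarity = purge_similarity,
               purge_coverage = purge_coverage, assembly_sim = assembly_sim,
               probe_len = as.integer(probe_len),
               probe_step = as.integer(probe_step))
    sims <- c(th$within_sim, th$across_sim, th$purge_similarity,
              th$purge_coverage, th$assembly_sim)
    stopifnot(all(sims > 0 & sims <= 1),
              th$probe_len > 0, th$probe_step > 0)
    th
}

.asSeqChar <- function(x) {
    setNames(as.character(x), names(x))
}

## column-wise consensus from a 5 x W count matrix (rows A,C,G,T,other):
## majority base, two-base IUPAC code where two bases each exceed 25% of
## the column's A/C/G/T depth, N where the column is uncovered.
.consensusFromCounts <- function(counts) {
    acgt <- counts[1:4, , drop = FALSE]
    depth <- colSums(acgt)
    W <- ncol(acgt)
    out <- character(W)
    het <- logical(W)
    for (j in seq_len(W)) {
        if (depth[j] == 0L) { out[j] <- "N"; next }
        v <- acgt[, j]
        ord <- order(v, decreasing = TRUE)
        frac <- v / depth[j]
        if (frac[ord[2]] > 0.25 && frac[ord[1]] > 0.25) {
            pair <- sort(BASES[ord[1:2]])
            out[j] <- IUPAC2[paste(pair, collapse = "")]
            het[j] <- TRUE
        } else out[j] <- BASES[ord[1]]
    }
    list(seq = paste(out, collapse = ""), het = het)
}

## dereplicate and order by descending abundance, ties lexicographic
.derepOrder <- function(seqs) {
    tab <- table(seqs)
    ab <- as.integer(tab)
    us <- names(tab)
    o <- order(-ab, us)
    list(seq = us[o], count = ab[o])
}

#' Greedy within-sample clustering of RAD reads into allele clusters
#'
#' Reads are dereplicated and visited by descending abundance (ties broken
#' lexicographically); a read joins a seed when the diagonal identity is at
#' least `within_sim` and the mismatch count (terminal length difference
#' included) is at most `max_mismatch`.  The consensus is called per column
#' by majority with a two-base IUPAC code where two bases each exceed 25\%
#' of the column depth; clusters whose fraction of ambiguous columns
#' exceeds `max_site_het` are discarded.
#'
#' @param reads character vector or DNAStringSet of trimmed reads.
#' @param thresholds a [catalogThresholds()] list.
#' @return data.frame with columns consensus, depth, n_het, discarded.
#' @export
clusterWithinSample <- function(reads, thresholds = catalogThresholds()) {
    reads <- .asSeqChar(reads)
    if (length(reads) == 0L)
        return(data.frame(consensus = character(), depth = integer(),
                          n_het = integer(), discarded = logical()))
    if (any(nchar(reads) < 50L))
        stop("reads shorter than 50 bp are rejected")
    d <- .derepOrder(reads)
    cl <- cpp_greedy_cluster(d$seq, k = 8L,
                             min_ident = thresholds$within_sim,
                             max_mismatch = thresholds$max_mismatch,
                             min_overlap = 0L, allow_offsets = FALSE)
    out <- lapply(sort(unique(cl$cluster)), function(ci) {
        sel <- cl$cluster == ci
        width <- max(nchar(d$seq[sel]))
        counts <- cpp_base_counts(d$seq[sel], rep(0L, sum(sel)),
                                  d$count[sel], width)
        cons <- .consensusFromCounts(counts)
        data.frame(consensus = cons$seq, depth = sum(d$count[sel]),
                   n_het = sum(cons$het),
                   discarded = mean(cons$het) > thresholds$max_site_het,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

.addFlag <- function(flags, idx, flag) {
    cur <- strsplit(flags[idx], ";", fixed = TRUE)
    flags[idx] <- vapply(cur, function(f) {
        f <- f[nzchar(f)]
        paste(union(f, flag), collapse = ";")
    }, "")
    flags
}

#' Build a locus catalogue from per-sample allele clusters
#'
#' Per-sample consensus sequences are pooled and greedily clustered at
#' identity `sim` (descending depth, ties lexicographic).  Each catalogue
#' locus records its per-sample alleles and the number of individuals
#' present.  Loci with the same column ambiguous in more than
#' `shared_het_max_individuals` samples, or with more than `paralog_filter`
#' distinct bases in any column across samples, are flagged
#' `paralog_shared_het`.
#'
#' @param per_sample_clusters named list (sample -> data.frame from
#'   [clusterWithinSample()]).
#' @param sim across-sample clustering identity (default: the
#'   `across_sim` threshold).
#' @param thresholds a [catalogThresholds()] list.
#' @param source assembly label ("species1", "species2", "combined", ...).
#' @return A [LocusCatalog-class].
#' @export
buildCatalog <- function(per_sample_clusters,
                         sim = NULL,
                         thresholds = catalogThresholds(),
                         source = "combined") {
    if (is.null(sim)) sim <- thresholds$across_sim
    samples <- rep(names(per_sample_clusters),
                   vapply(per_sample_clusters, nrow, 0L))
    df <- do.call(rbind, per_sample_clusters)
    keep <- !df$discarded
    df <- df[keep, , drop = FALSE]
    samples <- samples[keep]
    o <- order(-df$depth, df$consensus)
    df <- df[o, , drop = FALSE]
    samples <- samples[o]
    cl <- cpp_greedy_cluster(df$consensus, k = 8L, min_ident = sim,
                             max_mismatch = -1L, min_overlap = 0L,
                             allow_offsets = FALSE)
    ids <- sort(unique(cl$cluster))
    loci <- vector("list", length(ids))
    alleles <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        sel <- which(cl$cluster == ids[i])
        mem <- df$consensus[sel]
        msam <- samples[sel]
        width <- max(nchar(mem))
        counts <- cpp_base_counts(mem, rep(0L, length(mem)),
                                  rep(1L, length(mem)), width)
        cons <- .consensusFromCounts(counts)
        ## per-column count of samples whose own consensus is ambiguous
        mm <- matrix("", length(mem), width)
        for (r in seq_along(mem)) {
            ch <- strsplit(mem[r], "", fixed = TRUE)[[1]]
            mm[r, seq_along(ch)] <- ch
        }
        is_amb <- matrix(mm %in% names(AMBIG_EXPAND), nrow(mm))
        shared_het <- apply(is_amb, 2L, function(col)
            length(unique(msam[col])))
        ## distinct plain bases per column, ambiguity codes expanded
        ndistinct <- apply(mm, 2L, function(col) {
            exp <- unlist(strsplit(
                ifelse(col %in% names(AMBIG_EXPAND),
                       AMBIG_EXPAND[col], col), "", fixed = TRUE))
            length(intersect(unique(exp), BASES))
        })
        flag <- character()
        if (any(shared_het > thresholds$shared_het_max_individuals) ||
            any(ndistinct > thresholds$paralog_filter))
            flag <- "paralog_shared_het"
        loci[[i]] <- data.frame(
            locus_id = "", consensus = cons$seq,
            length = nchar(cons$seq),
            n_individuals = length(unique(msam)), source = source,
            flags = paste(flag, collapse = ";"), stringsAsFactors = FALSE)
        alleles[[i]] <- setNames(mem, msam)
    }
    loci <- do.call(rbind, loci)
    loci$locus_id <- sprintf("%s_L%05d", source, seq_len(nrow(loci)))
    names(alleles) <- loci$locus_id
    new("LocusCatalog", loci = loci, alleles = alleles)
}

.unionFind <- function(n, pairs) {
    parent <- seq_len(n)
    find <- function(x) {
        while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
        }
        x
    }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    vapply(seq_len(n), find, 0L)
}

#' Merge redundant loci shared between assemblies
#'
#' Loci from different source assemblies whose consensus identity is at
#' least `purge_similarity` over at least `purge_coverage` of the shorter
#' length are synonymized into a single locus (transitive closure of the
#' pairwise relation).  The merged locus keeps the longer consensus, the
#' union of per-sample alleles, and gains a `redundant` flag; existing
#' flags are unioned.
#'
#' @param catalogs list of [LocusCatalog-class] objects (>= 2).
#' @param thresholds a [catalogThresholds()] list.
#' @return A merged [LocusCatalog-class]; attribute `n_merged` counts the
#'   merge groups collapsed.
#' @export
synonymizeRedundant <- function(catalogs, thresholds = catalogThresholds()) {
    stopifnot(length(catalogs) >= 2L)
    loci <- do.call(rbind, lapply(catalogs, lociTable))
    alleles <- do.call(c, lapply(catalogs, function(x) x@alleles))
    n <- nrow(loci)
    hits <- cpp_pair_hits(loci$consensus, loci$consensus, k = 12L,
                          both_strands = FALSE)
    minlen <- pmin(loci$length[hits$qi], loci$length[hits$ri])
    ident <- (hits$overlap - hits$n_mismatch) / hits$overlap
    keep <- hits$qi < hits$ri &
        loci$source[hits$qi] != loci$source[hits$ri] &
        ident >= thresholds$purge_similarity &
        hits$overlap >= thresholds$purge_coverage * minlen
    pairs <- cbind(hits$qi[keep], hits$ri[keep])
    comp <- .unionFind(n, pairs)
    groups <- split(seq_len(n), comp)
    out_loci <- vector("list", length(groups))
    out_alleles <- vector("list", length(groups))
    n_merged <- 0L
    for (g in seq_along(groups)) {
        idx <- groups[[g]]
        if (length(idx) == 1L) {
            out_loci[[g]] <- loci[idx, , drop = FALSE]
            out_alleles[[g]] <- alleles[[idx]]
            next
        }
        n_merged <- n_merged + 1L
        keep_i <- idx[which.max(loci$length[idx])]
        al <- do.call(c, alleles[idx])
        fl <- unique(unlist(strsplit(loci$flags[idx], ";", fixed = TRUE)))
        fl <- union(fl[nzchar(fl)], "redundant")
        row <- loci[keep_i, , drop = FALSE]
        row$source <- paste(sort(unique(loci$source[idx])), collapse = "+")
        row$n_individuals <- length(unique(names(al)))
        row$flags <- paste(fl, collapse = ";")
        out_loci[[g]] <- row
        out_alleles[[g]] <- al
    }
    loci <- do.call(rbind, out_loci)
    rownames(loci) <- NULL
    names(out_alleles) <- loci$locus_id
    res <- new("LocusCatalog", loci = loci, alleles = out_alleles)
    attr(res, "n_merged") <- n_merged
    res
}

#' Flag near-duplicate (putatively paralogous) catalogue loci
#'
#' All-vs-all comparison of consensus sequences; any pair with identity
#' above `purge_similarity` over at least `purge_coverage` of the shorter
#' locus flags both members `paralog_similarity`.  (Pairs below the
#' `assembly_sim` grouping threshold can never reach the purge identity, so
#' the 75\% grouping stage is subsumed by the direct rule.)
#'
#' @param catalog a [LocusCatalog-class].
#' @param thresholds a [catalogThresholds()] list.
#' @return The catalogue with `paralog_similarity` flags added.
#' @export
purgeSimilarLoci <- function(catalog, thresholds = catalogThresholds()) {
    loci <- catalog@loci
    if (nrow(loci) < 2L) return(catalog)
    hits <- cpp_pair_hits(loci$consensus, loci$consensus, k = 12L,
                          both_strands = FALSE)
    minlen <- pmin(loci$length[hits$qi], loci$length[hits$ri])
    ident <- (hits$overlap - hits$n_mismatch) / hits$overlap
    bad <- hits$qi != hits$ri &
        ident > thresholds$purge_similarity &
        hits$overlap >= thresholds$purge_coverage * minlen
    idx <- unique(c(hits$qi[bad], hits$ri[bad]))
    loci$flags <- .addFlag(loci$flags, idx, "paralog_similarity")
    new("LocusCatalog", loci = loci, alleles = catalog@alleles)
}

## DUST-style triplet complexity score of one window of triplet count n:
## sum c_t (c_t - 1) / 2 over triplet types, normalised by (n - 1).
.dustScore <- function(seq, window = 64L, step = 32L) {
    L <- nchar(seq)
    if (L < 3L) return(0)
    starts <- unique(c(seq(1L, max(1L, L - window + 1L), by = step),
                       max(1L, L - window + 1L)))
    best <- 0
    for (s in starts) {
        w <- substr(seq, s, min(L, s + window - 1L))
        n <- nchar(w) - 2L
        if (n < 2L) next
        tri <- substring(w, 1:n, 3:(n + 2L))
        ct <- table(tri)
        sc <- sum(ct * (ct - 1) / 2) / (n - 1)
        if (sc > best) best <- sc
    }
    best
}

#' Flag low-complexity loci (homopolymer runs and DUST-style score)
#'
#' A locus is flagged `low_complexity` when it contains a homopolymer run
#' of at least `max_homopolymer` bases or when any 64 bp window has a
#' DUST-style triplet score above `dust_threshold`.
#'
#' @param catalog a [LocusCatalog-class].
#' @param max_homopolymer run length (bp) that triggers the flag.
#' @param dust_threshold windowed triplet-score threshold.
#' @return The catalogue with `low_complexity` flags added.
#' @export
maskLowComplexity <- function(catalog, max_homopolymer = 10L,
                              dust_threshold = 2) {
    loci <- catalog@loci
    pat <- paste(sprintf("%s{%d,}", BASES, max_homopolymer),
                 collapse = "|")
    homo <- grepl(pat, loci$consensus)
    dust <- vapply(loci$consensus, .dustScore, 0) > dust_threshold
    idx <- which(homo | dust)
    loci$flags <- .addFlag(loci$flags, idx, "low_complexity")
    new("LocusCatalog", loci = loci, alleles = catalog@alleles)
}

#' Flag catalogue loci matching a mitochondrial reference
#'
#' Strand-aware screen: loci aligning to the mitochondrial reference at
#' >= `min_ident` identity over >= `min_cov` of the locus length are
#' flagged `mitochondrial` (kept in the catalogue; whether they enter the
#' probe templates is decided in [selectCandidates()]).
#'
#' @param catalog a [LocusCatalog-class].
#' @param mito_reference DNAStringSet / character of mitochondrial
#'   sequence(s); NULL or empty skips the screen with a warning.
#' @param min_ident,min_cov identity and locus-length coverage floors.
#' @return The catalogue with `mitochondrial` flags added.
#' @export
screenMitochondrial <- function(catalog, mito_reference,
                                min_ident = 0.80, min_cov = 0.50) {
    if (missing(mito_reference) || is.null(mito_reference) ||
        length(mito_reference) == 0L) {
        warning("no mitochondrial reference supplied; screening skipped")
        return(catalog)
    }
    mito <- .asSeqChar(mito_reference)
    loci <- catalog@loci
    hits <- cpp_pair_hits(loci$consensus, mito, k = 12L,
                          both_strands = TRUE)
    if (nrow(hits)) {
        ident <- (hits$overlap - hits$n_mismatch) / hits$overlap
        good <- ident >= min_ident &
            hits$overlap >= min_cov * loci$length[hits$qi]
        idx <- unique(hits$qi[good])
        loci$flags <- .addFlag(loci$flags, idx, "mitochondrial")
    }
    new("LocusCatalog", loci = loci, alleles = catalog@alleles)
}

#' Select probe-template candidate loci
#'
#' A locus becomes a `candidate` when it carries no discard flag
#' (`paralog_shared_het`, `paralog_similarity`, `low_complexity`, and
#' `mitochondrial` when `include_mito = FALSE`) and is shared across at
#' least `min_individuals_single` individuals (single-species assemblies)
#' or `min_individuals_combined` (combined assemblies).
#'
#' @param catalog a [LocusCatalog-class] with all flags computed.
#' @param thresholds a [catalogThresholds()] list.
#' @param include_mito keep mitochondrially flagged loci as candidates
#'   (default TRUE).
#' @return The catalogue with `candidate` flags added.
#' @export
selectCandidates <- function(catalog, thresholds = catalogThresholds(),
                             include_mito = TRUE) {
    loci <- catalog@loci
    fl <- lociFlags(catalog)
    discard <- c("paralog_shared_het", "paralog_similarity",
                 "low_complexity", if (!include_mito) "mitochondrial")
    clean <- !vapply(fl, function(f) any(f %in% discard), TRUE)
    minn <- ifelse(grepl("combined", loci$source),
                   thresholds$min_individuals_combined,
                   thresholds$min_individuals_single)
    idx <- which(clean & loci$n_individuals >= minn)
    loci$flags <- .addFlag(loci$flags, idx, "candidate")
    new("LocusCatalog", loci = loci, alleles = catalog@alleles)
}

#' Tile capture probes across template loci
#'
#' Probes of `probe_len` bp start at offsets 0, `probe_step`,
#' 2*`probe_step`, ...; when the final stepped probe would overrun the
#' template it is right-anchored at `length - probe_len`.  Duplicate
#' offsets collapse, so a template of exactly `probe_len` bp yields one
#' probe and templates in (`probe_len`, `probe_len + probe_step`] yield
#' two.
#'
#' @param templates a [LocusCatalog-class] (candidate loci are used when
#'   any are flagged, otherwise all loci) or a named character vector /
#'   DNAStringSet of template sequences.
#' @param thresholds a [catalogThresholds()] list (probe_len, probe_step).
#' @return A [ProbeSet-class].
#' @export
tileProbes <- function(templates, thresholds = catalogThresholds()) {
    if (is(templates, "LocusCatalog")) {
        fl <- lociFlags(templates)
        cand <- vapply(fl, function(f) "candidate" %in% f, TRUE)
        if (!any(cand)) cand <- rep(TRUE, length(fl))
        seqs <- setNames(templates@loci$consensus[cand],
                         templates@loci$locus_id[cand])
    } else seqs <- .asSeqChar(templates)
    pl <- thresholds$probe_len
    ps <- thresholds$probe_step
    lens <- nchar(seqs)
    if (any(lens < pl))
        stop("templates shorter than probe length: ",
             paste(head(names(seqs)[lens < pl], 5L), collapse = ", "))
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("T%05d", seq_along(seqs))
    rows <- lapply(seq_along(seqs), function(i) {
        L <- lens[i]
        off <- unique(c(seq(0L, L - pl, by = ps), L - pl))
        off <- sort(off)
        data.frame(parent_locus_id = names(seqs)[i], offset = off,
                   sequence = substring(seqs[i], off + 1L, off + pl),
                   stringsAsFactors = FALSE)
    })
    probes <- do.call(rbind, rows)
    probes <- cbind(probe_id = sprintf("P%06d", seq_len(nrow(probes))),
                    probes, stringsAsFactors = FALSE)
    new("ProbeSet", probes = probes)
}
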