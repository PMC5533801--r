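## Mapping, PCR-duplicate marking by fragment identity, assembly-based
## reference construction, per-sample coverage metrics.

#' Capture-stage parameters
#'
#' Defaults: mapping-quality floor 5, 90\% read-clustering identity with a
#' 40-read cluster floor, cluster merging at 120 bp minimum overlap and
#' 85\% identity, reciprocal-best-hit on-target labelling at 75\% identity.
#'
#' @param maq_min mapping-quality floor for downstream use.
#' @param cluster_sim greedy read-clustering identity.
#' @param min_cluster_reads clusters below this read count are dropped.
#' @param merge_min_overlap,merge_sim cluster-consensus merge rule.
#' @param rbh_identity_min reciprocal-best-hit identity floor.
#' @param cluster_min_overlap minimum read-vs-seed overlap during
#'   clustering.
#' @param kmer seed k-mer length for clustering/comparison.
#' @param map_kmer seed k-mer length for read mapping.
#' @return A named list of parameters.
#' @export
captureParams <- function(maq_min = 5L, cluster_sim = 0.90,
                          min_cluster_reads = 40L,
                          merge_min_overlap = 120L, merge_sim = 0.85,
                          rbh_identity_min = 0.75,
                          cluster_min_overlap = 60L, kmer = 12L,
                          map_kmer = 15L) {
    p <- list(maq_min = as.integer(maq_min), cluster_sim = cluster_sim,
              min_cluster_reads = as.integer(min_cluster_reads),
              merge_min_overlap = as.integer(merge_min_overlap),
              merge_sim = merge_sim, rbh_identity_min = rbh_identity_min,
              cluster_min_overlap = as.integer(cluster_min_overlap),
              kmer = as.integer(kmer), map_kmer = as.integer(map_kmer))
    stopifnot(p$maq_min >= 0, p$cluster_sim > 0, p$cluster_sim <= 1,
              p$min_cluster_reads > 0, p$merge_min_overlap > 0)
    p
}

#' Map processed reads to reference loci
#'
#' Seed (k-mer index) and extend on the best shared diagonal, both strands,
#' scored as matches minus mismatches over the overlap.  Mapping quality is
#' the margin between the best and second-best locus scores, capped at 60;
#' ties across loci give maQ 0.  Records below `maq_min` stay in the object
#' but are excluded by downstream consumers.
#'
#' @param reads data.frame(id, sample, seq, qual) as from [processReads()],
#'   or a character vector of sequences (then ids/samples are synthesised).
#' @param reference named character vector or DNAStringSet of locus
#'   sequences.
#' @param params a [captureParams()] list.
#' @return An [AlignmentSet-class]; attribute `n_unmapped` counts reads
#'   without any seed hit.
#' @export
mapReads <- function(reads, reference, params = captureParams()) {
    refs <- .asSeqChar(reference)
    if (length(refs) == 0L) stop("empty reference")
    if (is.null(names(refs))) names(refs) <- sprintf("R%05d",
                                                     seq_along(refs))
    if (is.character(reads))
        reads <- data.frame(id = sprintf("read%07d", seq_along(reads)),
                            sample = "S1", seq = reads,
                            qual = strrep("I", nchar(reads)),
                            stringsAsFactors = FALSE)
    useq <- unique(reads$seq)
    hit <- cpp_map_reads(useq, refs, params$map_kmer)
    m <- match(reads$seq, useq)
    ref <- hit$ref[m]
    mapped <- !is.na(ref)
    pos <- hit$pos[m]
    len <- nchar(reads$seq)
    reflen <- nchar(refs)
    ok <- mapped & pos >= 0L & pos + len <= reflen[ref]
    n_unmapped <- sum(!ok)
    idx <- which(ok)
    strand <- hit$strand[m][idx]
    seq_ref <- reads$seq[idx]
    qual_ref <- reads$qual[idx]
    neg <- strand == "-"
    if (any(neg)) {
        seq_ref[neg] <- cpp_revcomp(seq_ref[neg])
        qual_ref[neg] <- vapply(qual_ref[neg], function(q)
            paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
            "", USE.NAMES = FALSE)
    }
    mean_q <- vapply(qual_ref, function(q)
        mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
    rec <- data.frame(
        read_id = reads$id[idx], sample = reads$sample[idx],
        locus = names(refs)[ref[idx]], start = pos[idx],
        end = pos[idx] + len[idx], strand = strand,
        n_mismatch = hit$n_mismatch[m][idx], maq = hit$maq[m][idx],
        insert_len = len[idx], is_duplicate = FALSE,
        seq = seq_ref, qual = qual_ref, mean_q = mean_q,
        stringsAsFactors = FALSE)
    out <- new("AlignmentSet", records = rec,
               refLengths = setNames(as.integer(reflen), names(refs)))
    attr(out, "n_unmapped") <- n_unmapped
    out
}

#' Mark PCR duplicates by fragment identity
#'
#' Within a sample, fragments sharing (locus, start, insert length, strand)
#' form a duplicate group; the member with the highest summed base quality
#' is kept and the others are flagged.  Flagged records are excluded from
#' depth and variant calling.  Idempotent.
#'
#' @param aln an [AlignmentSet-class].
#' @return The alignment set with `is_duplicate` set.
#' @export
markDuplicates <- function(aln) {
    r <- aln@records
    if (!nrow(r)) return(aln)
    qsum <- vapply(r$qual, function(q) sum(utf8ToInt(q)) - 33 * nchar(q),
                   0, USE.NAMES = FALSE)
    key <- paste(r$sample, r$locus, r$start, r$insert_len, r$strand,
                 sep = "\r")
    o <- order(key, -qsum, seq_len(nrow(r)))
    dup <- duplicated(key[o])
    r$is_duplicate <- FALSE
    r$is_duplicate[o] <- dup
    new("AlignmentSet", records = r, refLengths = aln@refLengths)
}

.majorityConsensus <- function(counts) {
    acgt <- counts[1:4, , drop = FALSE]
    depth <- colSums(acgt)
    top <- apply(acgt, 2L, which.max)
    out <- BASES[top]
    out[depth == 0L] <- "N"
    paste(out, collapse = "")
}

.bestHits <- function(hits) {
    ## best ri per qi by (matches desc, overlap desc, ri asc)
    matches <- hits$overlap - hits$n_mismatch
    o <- order(hits$qi, -matches, -hits$overlap, hits$ri)
    h <- hits[o, , drop = FALSE]
    h[!duplicated(h$qi), , drop = FALSE]
}

#' Build an assembly-based reference from merged capture reads
#'
#' Greedy strand-aware clustering of merged fragments at `cluster_sim`;
#' clusters with fewer than `min_cluster_reads` reads are dropped; cluster
#' consensi overlapping by at least `merge_min_overlap` bp at
#' `merge_sim` identity are merged (transitive closure) into single
#' reference loci.  Reciprocal best hits against the probe set label loci
#' on-target (mutual best hit at identity >= `rbh_identity_min`), others
#' off-target.  Consensi matching the mitochondrial reference are flagged
#' `mitochondrial`; consensi whose 5' and 3' halves best-hit different
#' probe template loci are flagged `chimera` and excluded as artefacts.
#'
#' @param fragments data.frame(id, sample, seq, qual) of merged reads from
#'   modern samples (museum reads are excluded from reference building by
#'   contract), or a character vector of sequences.
#' @param probes a [ProbeSet-class] (or named character of probe
#'   sequences; names taken as template ids).
#' @param mito_ref optional mitochondrial reference sequence(s).
#' @param params a [captureParams()] list.
#' @return A [ReferenceSet-class].
#' @export
buildReference <- function(fragments, probes, mito_ref = NULL,
                           params = captureParams()) {
    seqs <- if (is.character(fragments)) fragments else fragments$seq
    d <- .derepOrder(seqs)
    cl <- cpp_greedy_cluster(d$seq, k = params$kmer,
                             min_ident = params$cluster_sim,
                             max_mismatch = -1L,
                             min_overlap = params$cluster_min_overlap,
                             allow_offsets = TRUE, both_strands = TRUE)
    sizes <- tapply(d$count, cl$cluster, sum)
    keep_cl <- as.integer(names(sizes)[sizes >= params$min_cluster_reads])
    if (!length(keep_cl))
        stop("no cluster reached ", params$min_cluster_reads,
             " reads: empty reference")
    cons <- character(length(keep_cl))
    nsup <- integer(length(keep_cl))
    for (i in seq_along(keep_cl)) {
        sel <- which(cl$cluster == keep_cl[i])
        sq <- d$seq[sel]
        neg <- cl$strand[sel] == "-"
        sq[neg] <- cpp_revcomp(sq[neg])
        off <- cl$offset[sel]
        off <- off - min(off)
        width <- max(off + nchar(sq))
        counts <- cpp_base_counts(sq, off, d$count[sel], width)
        cons[i] <- .majorityConsensus(counts)
        nsup[i] <- sum(d$count[sel])
    }
    ## merge overlapping cluster consensi
    hits <- cpp_pair_hits(cons, cons, k = params$kmer, both_strands = TRUE)
    ident <- (hits$overlap - hits$n_mismatch) / hits$overlap
    mrg <- hits$qi < hits$ri & ident >= params$merge_sim &
        hits$overlap >= params$merge_min_overlap
    comp <- .unionFind(length(cons), cbind(hits$qi[mrg], hits$ri[mrg]))
    groups <- split(seq_along(cons), comp)
    ref_seq <- vapply(groups, function(idx)
        cons[idx[which.max(nchar(cons[idx]))]], "")
    ref_nsup <- vapply(groups, function(idx) sum(nsup[idx]), 0L)
    nref <- length(ref_seq)
    flags <- rep("", nref)

    pseqs <- if (is(probes, "ProbeSet"))
        setNames(probes@probes$sequence, probes@probes$probe_id)
    else .asSeqChar(probes)
    if (is(probes, "ProbeSet")) {
        parent <- setNames(probes@probes$parent_locus_id,
                           probes@probes$probe_id)
    } else {
        ## plain sequences: take the parent template from a
        ## "parent=<id>" tag in the name (as written by exportProbes),
        ## falling back to the name itself
        pnames <- if (is.null(names(pseqs)))
            sprintf("P%06d", seq_along(pseqs)) else names(pseqs)
        par <- ifelse(grepl("parent=", pnames),
                      sub(".*parent=(\\S+).*", "\\1", pnames), pnames)
        names(pseqs) <- pnames
        parent <- setNames(par, pnames)
    }
    ## reciprocal best hit, at probe level
    h_cp <- cpp_pair_hits(ref_seq, pseqs, k = params$kmer,
                          both_strands = TRUE)
    best_cp <- .bestHits(h_cp)
    h_pc <- cpp_pair_hits(pseqs, ref_seq, k = params$kmer,
                          both_strands = TRUE)
    best_pc <- .bestHits(h_pc)
    origin <- rep("off_target", nref)
    probe_hit <- rep(NA_character_, nref)
    if (nrow(best_cp)) {
        bi <- (best_cp$overlap - best_cp$n_mismatch) / best_cp$overlap
        for (r in seq_len(nrow(best_cp))) {
            ci <- best_cp$qi[r]
            pi <- best_cp$ri[r]
            if (bi[r] < params$rbh_identity_min) next
            back <- best_pc[best_pc$qi == pi, , drop = FALSE]
            if (nrow(back) && back$ri[1] == ci) {
                origin[ci] <- "on_target"
                probe_hit[ci] <- unname(parent[names(pseqs)[pi]])
            }
        }
    }
    ## chimera: 5' and 3' halves best-hitting different template loci
    half1 <- substr(ref_seq, 1L, floor(nchar(ref_seq) / 2))
    half2 <- substr(ref_seq, floor(nchar(ref_seq) / 2) + 1L,
                    nchar(ref_seq))
    bh1 <- .bestHits(cpp_pair_hits(half1, pseqs, k = params$kmer,
                                   both_strands = TRUE))
    bh2 <- .bestHits(cpp_pair_hits(half2, pseqs, k = params$kmer,
                                   both_strands = TRUE))
    p1 <- rep(NA_character_, nref)
    p2 <- rep(NA_character_, nref)
    g1 <- (bh1$overlap - bh1$n_mismatch) / bh1$overlap >=
        params$rbh_identity_min
    g2 <- (bh2$overlap - bh2$n_mismatch) / bh2$overlap >=
        params$rbh_identity_min
    p1[bh1$qi[g1]] <- unname(parent[names(pseqs)[bh1$ri[g1]]])
    p2[bh2$qi[g2]] <- unname(parent[names(pseqs)[bh2$ri[g2]]])
    chim <- !is.na(p1) & !is.na(p2) & p1 != p2
    flags <- .addFlag(flags, which(chim), "chimera")
    if (!is.null(mito_ref) && length(mito_ref)) {
        hm <- cpp_pair_hits(ref_seq, .asSeqChar(mito_ref),
                            k = params$kmer, both_strands = TRUE)
        im <- (hm$overlap - hm$n_mismatch) / hm$overlap
        mi <- unique(hm$qi[im >= 0.80 &
                           hm$overlap >= 0.5 * nchar(ref_seq)[hm$qi]])
        flags <- .addFlag(flags, mi, "mitochondrial")
    }
    loci <- data.frame(
        ref_id = sprintf("ref%05d", seq_len(nref)), sequence = ref_seq,
        n_supporting_reads = as.integer(ref_nsup), origin = origin,
        probe_hit = probe_hit, flags = flags, stringsAsFactors = FALSE)
    ## chimeric artefacts are excluded from the reference proper
    loci <- loci[!grepl("chimera", loci$flags), , drop = FALSE]
    rownames(loci) <- NULL
    new("ReferenceSet", loci = loci)
}

#' Per-sample coverage, GC content and heterozygous read rate
#'
#' Computed from non-duplicate alignments at maQ >= `maq_min`.  Mean depth
#' of targets is aligned bases over the total reference length; the
#' heterozygous read rate is the fraction of aligned read bases
#' disagreeing with the reference over all aligned columns (the definition
#' is recorded in the `het_definition` attribute).
#'
#' @param aln an [AlignmentSet-class] with duplicates flagged.
#' @param params a [captureParams()] list.
#' @return data.frame(sample, n_reads, n_duplicates, mean_depth, gc_pct,
#'   het_read_rate).
#' @export
coverageMetrics <- function(aln, params = captureParams()) {
    r <- aln@records
    total_ref <- sum(aln@refLengths)
    use <- !r$is_duplicate & r$maq >= params$maq_min
    u <- r[use, , drop = FALSE]
    samples <- sort(unique(r$sample))
    out <- do.call(rbind, lapply(samples, function(s) {
        i <- u$sample == s
        alen <- sum(u$end[i] - u$start[i])
        gc <- sum(nchar(gsub("[^GCgc]", "", u$seq[i])))
        data.frame(sample = s,
                   n_reads = sum(r$sample == s),
                   n_duplicates = sum(r$is_duplicate[r$sample == s]),
                   mean_depth = alen / total_ref,
                   gc_pct = 100 * gc / max(1L, alen),
                   het_read_rate = sum(u$n_mismatch[i]) / max(1L, alen),
                   stringsAsFactors = FALSE)
    }))
    attr(out, "het_definition") <-
        "mismatching aligned bases / all aligned bases (all columns)"
    out
}
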