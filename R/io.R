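## Text exports: VCF 4.2, minimal SAM, FASTA/TSV tables.

#' Export a variant set as VCF 4.2
#'
#' INFO keys QD, MQ, FS, ReadPosZ and NS5X; FORMAT GT:DP:AD:GQ; FILTER
#' names as assigned by [hardFilter()].  Positions are 1-based in the
#' output as VCF requires.
#'
#' @param vs a [VariantSet-class].
#' @param path output file.
#' @param ref_lengths optional named integer vector for contig headers.
#' @return Invisibly, `path`.
#' @export
exportVcf <- function(vs, path, ref_lengths = NULL) {
    s <- vs@sites
    hdr <- c("##fileformat=VCFv4.2",
             "##source=radcapkit",
             if (!is.null(ref_lengths))
                 sprintf("##contig=<ID=%s,length=%d>",
                         names(ref_lengths), ref_lengths),
             "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
             "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
             "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand p\">",
             "##INFO=<ID=ReadPosZ,Number=1,Type=Float,Description=\"Alt vs ref read-position rank-sum z\">",
             "##INFO=<ID=NS5X,Number=1,Type=Integer,Description=\"Samples with depth >= 5\">",
             "##FILTER=<ID=LowQD,Description=\"QD below threshold\">",
             "##FILTER=<ID=LowMQ,Description=\"RMS mapping quality below threshold\">",
             "##FILTER=<ID=LowQual,Description=\"Site quality below threshold\">",
             "##FILTER=<ID=HighFS,Description=\"Fisher strand above threshold\">",
             "##FILTER=<ID=LowCov,Description=\"Too few samples at depth\">",
             "##FILTER=<ID=ReadPos,Description=\"Heterozygote read-position bias\">",
             "##FILTER=<ID=NotBiallelic,Description=\"More than one alt allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt allele depth\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", vs@samples),
                   collapse = "\t"))
    gtc <- c("0/0", "0/1", "1/1")
    lines <- vapply(seq_len(nrow(s)), function(j) {
        gt <- vs@geno[, j]
        cells <- sprintf("%s:%s:%s:%s",
                         ifelse(is.na(gt), "./.", gtc[gt + 1L]),
                         ifelse(is.na(vs@dp[, j]), ".", vs@dp[, j]),
                         ifelse(is.na(vs@adAlt[, j]), ".", vs@adAlt[, j]),
                         ifelse(is.na(vs@gq[, j]), ".",
                                round(vs@gq[, j])))
        info <- sprintf("QD=%.2f;MQ=%.2f;FS=%.2f;ReadPosZ=%s;NS5X=%d",
                        s$QD[j], s$MQ[j], s$FS[j],
                        ifelse(is.na(s$ReadPosZ[j]), ".",
                               sprintf("%.2f", s$ReadPosZ[j])),
                        s$n_samples_5x[j])
        paste(c(s$locus[j], s$pos[j] + 1L, ".", s$ref[j], s$alt[j],
                sprintf("%.1f", min(s$QUAL[j], 99999)),
                ifelse(nzchar(s$filter[j]), s$filter[j], "."),
                info, "GT:DP:AD:GQ", cells), collapse = "\t")
    }, "")
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Export alignments as minimal SAM
#'
#' QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ/QUAL with the reverse-strand (0x10)
#' and duplicate (0x400) flags; CIGAR is full-length match (substitution
#' -only alignments).
#'
#' @param aln an [AlignmentSet-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
exportSam <- function(aln, path) {
    r <- aln@records
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(aln@refLengths),
                     aln@refLengths))
    flag <- ifelse(r$strand == "-", 16L, 0L) +
        ifelse(r$is_duplicate, 1024L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tXS:Z:%s",
                     r$read_id, flag, r$locus, r$start + 1L, r$maq,
                     nchar(r$seq), r$seq, r$qual, r$sample)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Import a minimal SAM file as an AlignmentSet
#'
#' Reads the subset of SAM emitted by [exportSam()]: ungapped
#' (full-length-match CIGAR) records with the reverse (0x10) and duplicate
#' (0x400) flags and the per-record sample in the `XS:Z:` tag (defaulting
#' to "S1" when absent).
#'
#' @param path SAM file.
#' @return An [AlignmentSet-class].
#' @export
importSam <- function(path) {
    lines <- readLines(path)
    sq <- lines[startsWith(lines, "@SQ")]
    refn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    refl <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    body <- lines[!startsWith(lines, "@")]
    f <- strsplit(body, "\t", fixed = TRUE)
    gettag <- function(x) {
        hit <- grep("^XS:Z:", x[-(1:11)], value = TRUE)
        if (length(hit)) sub("^XS:Z:", "", hit[1]) else "S1"
    }
    flag <- as.integer(vapply(f, `[`, "", 2))
    seqs <- vapply(f, `[`, "", 10)
    quals <- vapply(f, `[`, "", 11)
    rec <- data.frame(
        read_id = vapply(f, `[`, "", 1),
        sample = vapply(f, gettag, ""),
        locus = vapply(f, `[`, "", 3),
        start = as.integer(vapply(f, `[`, "", 4)) - 1L,
        end = as.integer(vapply(f, `[`, "", 4)) - 1L + nchar(seqs),
        strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
        n_mismatch = 0L,
        maq = as.integer(vapply(f, `[`, "", 5)),
        insert_len = nchar(seqs),
        is_duplicate = bitwAnd(flag, 1024L) > 0,
        seq = seqs, qual = quals,
        mean_q = vapply(quals, function(q) mean(utf8ToInt(q)) - 33, 0,
                        USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    new("AlignmentSet", records = rec,
        refLengths = setNames(refl, refn))
}

#' Export a locus catalogue as FASTA plus a flag table
#'
#' @param catalog a [LocusCatalog-class].
#' @param prefix path prefix; writes `<prefix>.fasta` and
#'   `<prefix>_flags.tsv`.
#' @return Invisibly, the paths written.
#' @export
exportCatalog <- function(catalog, prefix) {
    fa <- paste0(prefix, ".fasta")
    Biostrings::writeXStringSet(consensusSeqs(catalog), fa)
    tsv <- paste0(prefix, "_flags.tsv")
    write.table(catalog@loci[, c("locus_id", "length", "n_individuals",
                                 "source", "flags")],
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fa, tsv))
}

#' Export probes as FASTA with parent-template tags
#'
#' Names carry `parent=<template id>` so a reference build fed with the
#' FASTA (rather than the [ProbeSet-class]) can still group probes by
#' template for reciprocal-best-hit labelling and chimera screening.
#'
#' @param probes a [ProbeSet-class].
#' @param path output FASTA.
#' @return Invisibly, `path`.
#' @export
exportProbes <- function(probes, path) {
    p <- probeTable(probes)
    x <- Biostrings::DNAStringSet(setNames(
        p$sequence,
        sprintf("%s parent=%s offset=%d", p$probe_id,
                p$parent_locus_id, p$offset)))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Per-locus depth track (BED-graph-style TSV)
#'
#' Columns locus, start, end, depth over non-duplicate maQ-passing
#' alignments.
#'
#' @param aln an [AlignmentSet-class] with duplicates marked.
#' @param path output file.
#' @param maq_min mapping-quality floor.
#' @return Invisibly, `path`.
#' @export
exportDepth <- function(aln, path, maq_min = 5L) {
    r <- aln@records
    u <- r[!r$is_duplicate & r$maq >= maq_min, , drop = FALSE]
    rows <- lapply(names(aln@refLengths), function(loc) {
        L <- aln@refLengths[[loc]]
        i <- u$locus == loc
        cov <- as.numeric(IRanges::coverage(
            IRanges::IRanges(u$start[i] + 1L, u$end[i]), width = L))
        rl <- rle(cov)
        ends <- cumsum(rl$lengths)
        data.frame(locus = loc, start = c(0L, head(ends, -1L)),
                   end = ends, depth = rl$values)
    })
    out <- do.call(rbind, rows)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a damage profile as TSV
#'
#' @param profile a [DamageProfile-class].
#' @param path output file (columns position, ct5_freq, ga3_freq).
#' @return Invisibly, `path`.
#' @export
exportDamageProfile <- function(profile, path) {
    write.table(data.frame(position = seq_along(profile@ct5),
                           ct5_freq = profile@ct5,
                           ga3_freq = profile@ga3),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
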