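## Capture/ddRAD read processing: quality trim, contaminant screen,
## paired-end merge, dual-index demultiplex.

#' Read-processing parameters
#'
#' Defaults: whole-pair discard below mean Phred 33, 140 bp minimum merged
#' fragment in ddRAD catalogue mode, 220 bp merged-fragment cap, 20 bp
#' minimum mate overlap at <= 10\% mismatch, canonical 31-mer contaminant
#' screen at fraction 0.5, one mismatch allowed per index, 3' bases below
#' Q20 trimmed, TruSeq-style read-through adapter.
#'
#' @param min_mean_phred whole-read mean-quality floor (pair discarded
#'   below it).
#' @param ddrad_min_len minimum merged fragment length kept in ddRAD mode.
#' @param capture_max_len merged fragments are truncated to this length.
#' @param min_overlap,max_overlap_mismatch mate-merge geometry.
#' @param kmer_k,contaminant_kmer_frac contaminant screen settings.
#' @param index_mismatch_allow per-index mismatch allowance.
#' @param tail_q 3' quality-trim threshold.
#' @param adapters adapter sequence(s) removed from read 3' ends.
#' @return A named list of parameters.
#' @export
readProcParams <- function(min_mean_phred = 33, ddrad_min_len = 140L,
                           capture_max_len = 220L, min_overlap = 20L,
                           max_overlap_mismatch = 0.10, kmer_k = 31L,
                           contaminant_kmer_frac = 0.5,
                           index_mismatch_allow = 1L, tail_q = 20L,
                           adapters = "AGATCGGAAGAGC") {
    p <- list(min_mean_phred = min_mean_phred,
              ddrad_min_len = as.integer(ddrad_min_len),
              capture_max_len = as.integer(capture_max_len),
              min_overlap = as.integer(min_overlap),
              max_overlap_mismatch = max_overlap_mismatch,
              kmer_k = as.integer(kmer_k),
              contaminant_kmer_frac = contaminant_kmer_frac,
              index_mismatch_allow = as.integer(index_mismatch_allow),
              tail_q = as.integer(tail_q), adapters = adapters)
    stopifnot(p$ddrad_min_len > 0, p$capture_max_len > 0,
              p$min_overlap > 0,
              p$max_overlap_mismatch >= 0, p$max_overlap_mismatch <= 1,
              p$contaminant_kmer_frac >= 0, p$contaminant_kmer_frac <= 1)
    p
}

.checkQuals <- function(x) {
    bad <- which(nchar(x@seq1) != nchar(x@qual1) |
                 nchar(x@seq2) != nchar(x@qual2) |
                 grepl("[^\x21-\x7e]", x@qual1) |
                 grepl("[^\x21-\x7e]", x@qual2))
    if (length(bad))
        stop("malformed quality string for read ", x@id[bad[1]])
}

#' Quality-trim read pairs
#'
#' Removes adapter read-through from the 3' end (semi-global prefix match),
#' trims 3' bases below `tail_q`, and discards the whole pair when either
#' mate's mean Phred score is below `min_mean_phred`.
#'
#' @param pairs a [ReadPairSet-class].
#' @param params a [readProcParams()] list.
#' @return list(pairs = trimmed [ReadPairSet-class], n_discarded).
#' @export
qualityTrim <- function(pairs, params = readProcParams()) {
    .checkQuals(pairs)
    t1 <- cpp_quality_trim(pairs@seq1, pairs@qual1, params$tail_q,
                           params$adapters)
    t2 <- cpp_quality_trim(pairs@seq2, pairs@qual2, params$tail_q,
                           params$adapters)
    keep <- t1$mean_q >= params$min_mean_phred &
        t2$mean_q >= params$min_mean_phred
    out <- new("ReadPairSet", id = pairs@id[keep],
               seq1 = t1$seq[keep], qual1 = t1$qual[keep],
               seq2 = t2$seq[keep], qual2 = t2$qual[keep],
               i5 = pairs@i5[keep], i7 = pairs@i7[keep],
               truth = if (nrow(pairs@truth))
                   pairs@truth[keep, , drop = FALSE] else pairs@truth,
               sheet = pairs@sheet)
    list(pairs = out, n_discarded = sum(!keep))
}

#' Screen read pairs against contaminant references
#'
#' A read is flagged when the fraction of its canonical `kmer_k`-mers
#' present in the contaminant k-mer set reaches
#' `contaminant_kmer_frac`; flagged pairs are removed.  (A keep/remove
#' screen; no taxonomic classification is attempted.)
#'
#' @param pairs a [ReadPairSet-class].
#' @param contaminant_refs DNAStringSet / character of contaminant
#'   sequences; NULL or empty skips the screen with a warning.
#' @param params a [readProcParams()] list.
#' @return list(pairs = kept pairs, n_removed).
#' @export
screenContaminants <- function(pairs, contaminant_refs,
                               params = readProcParams()) {
    if (missing(contaminant_refs) || is.null(contaminant_refs) ||
        length(contaminant_refs) == 0L) {
        warning("empty contaminant reference set; screening skipped")
        return(list(pairs = pairs, n_removed = 0L))
    }
    refs <- .asSeqChar(contaminant_refs)
    f1 <- cpp_kmer_fraction(pairs@seq1, refs, params$kmer_k)
    f2 <- cpp_kmer_fraction(pairs@seq2, refs, params$kmer_k)
    f1[is.na(f1)] <- 0
    f2[is.na(f2)] <- 0
    flagged <- f1 >= params$contaminant_kmer_frac |
        f2 >= params$contaminant_kmer_frac
    list(pairs = pairs[!flagged], n_removed = sum(flagged))
}

#' Merge mate pairs by 3' overlap
#'
#' The best overlap of at least `min_overlap` bp with mismatch fraction at
#' most `max_overlap_mismatch` merges the mates; conflicting overlap bases
#' take the higher-quality call.  Merged fragments are truncated to
#' `capture_max_len`; in `mode = "ddrad"` merged fragments shorter than
#' `ddrad_min_len` are discarded.
#'
#' @param pairs a [ReadPairSet-class].
#' @param params a [readProcParams()] list.
#' @param mode "capture" or "ddrad" (ddRAD applies the minimum-length
#'   rule used when building locus catalogues).
#' @return list(fragments = data.frame(id, seq, qual, i5, i7[, sample]),
#'   unmerged = [ReadPairSet-class], n_short_discarded).
#' @export
mergePairs <- function(pairs, params = readProcParams(),
                       mode = c("capture", "ddrad")) {
    mode <- match.arg(mode)
    m <- cpp_merge_pairs(pairs@seq1, pairs@qual1, pairs@seq2, pairs@qual2,
                         params$min_overlap, params$max_overlap_mismatch,
                         params$capture_max_len)
    ok <- m$merged
    frag <- data.frame(id = pairs@id[ok], seq = m$seq[ok],
                       qual = m$qual[ok], i5 = pairs@i5[ok],
                       i7 = pairs@i7[ok], stringsAsFactors = FALSE)
    if (nrow(pairs@truth))
        frag$sample <- pairs@truth$sample[ok]
    n_short <- 0L
    if (mode == "ddrad") {
        short <- nchar(frag$seq) < params$ddrad_min_len
        n_short <- sum(short)
        frag <- frag[!short, , drop = FALSE]
    }
    list(fragments = frag, unmerged = pairs[!ok],
         n_short_discarded = n_short)
}

#' Assign read pairs to samples by their dual indexes
#'
#' Validates that sample-sheet index pairs are mutually at least
#' `2 * index_mismatch_allow + 1` mismatches apart (else a configuration
#' error), then assigns a pair when both of its indexes match one sheet
#' entry within `index_mismatch_allow`; ambiguous or non-matching pairs
#' are unassigned (NA).
#'
#' @param x a [ReadPairSet-class] or data.frame with i5/i7 columns.
#' @param sample_sheet data.frame with columns sample, i5, i7.
#' @param params a [readProcParams()] list.
#' @return list(sample = character assignment per input (NA unassigned),
#'   n_assigned, n_unassigned).
#' @export
demultiplex <- function(x, sample_sheet, params = readProcParams()) {
    allow <- params$index_mismatch_allow
    ns <- nrow(sample_sheet)
    if (ns > 1L) {
        for (a in seq_len(ns - 1L)) {
            d <- cpp_hamming(sample_sheet$i5[a],
                             sample_sheet$i5[(a + 1L):ns]) +
                cpp_hamming(sample_sheet$i7[a],
                            sample_sheet$i7[(a + 1L):ns])
            if (any(d < 2L * allow + 1L))
                stop("sample sheet index pairs closer than ",
                     2L * allow + 1L, " mismatches: configuration error")
        }
    }
    i5 <- if (is(x, "ReadPairSet")) x@i5 else x$i5
    i7 <- if (is(x, "ReadPairSet")) x@i7 else x$i7
    key <- paste(i5, i7, sep = "+")
    uk <- unique(key)
    u5 <- sub("\\+.*", "", uk)
    u7 <- sub(".*\\+", "", uk)
    assign_u <- vapply(seq_along(uk), function(j) {
        d5 <- cpp_hamming(u5[j], sample_sheet$i5)
        d7 <- cpp_hamming(u7[j], sample_sheet$i7)
        hit <- which(d5 <= allow & d7 <= allow)
        if (length(hit) == 1L) sample_sheet$sample[hit] else NA_character_
    }, "")
    sample <- assign_u[match(key, uk)]
    list(sample = sample, n_assigned = sum(!is.na(sample)),
         n_unassigned = sum(is.na(sample)))
}

#' Run the first four processing steps on raw pairs
#'
#' Quality trim, optional contaminant screen, mate merging and
#' demultiplexing, in that order, with a read-conservation report
#' (assigned + unassigned + discarded = input).
#'
#' @param pairs a [ReadPairSet-class].
#' @param sample_sheet data.frame(sample, i5, i7); defaults to the sheet
#'   carried by the read set.
#' @param params a [readProcParams()] list.
#' @param contaminants optional contaminant reference sequences.
#' @param mode "capture" or "ddrad" (see [mergePairs()]).
#' @return list(fragments = data.frame(id, sample, seq, qual),
#'   report = named integer vector of per-stage counts).
#' @export
processReads <- function(pairs, sample_sheet = NULL,
                         params = readProcParams(), contaminants = NULL,
                         mode = c("capture", "ddrad")) {
    mode <- match.arg(mode)
    if (is.null(sample_sheet)) sample_sheet <- pairs@sheet
    n_in <- length(pairs)
    qt <- qualityTrim(pairs, params)
    n_low <- qt$n_discarded
    sc <- if (!is.null(contaminants) && length(contaminants))
        screenContaminants(qt$pairs, contaminants, params)
    else list(pairs = qt$pairs, n_removed = 0L)
    mg <- mergePairs(sc$pairs, params, mode)
    dm <- demultiplex(mg$fragments, sample_sheet, params)
    frag <- mg$fragments
    frag$sample <- dm$sample
    assigned <- frag[!is.na(frag$sample),
                     c("id", "sample", "seq", "qual")]
    report <- c(input = n_in, low_quality = n_low,
                contaminant = sc$n_removed,
                unmerged = length(mg$unmerged),
                short = mg$n_short_discarded,
                unassigned = dm$n_unassigned,
                assigned = dm$n_assigned)
    list(fragments = assigned, report = report)
}
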