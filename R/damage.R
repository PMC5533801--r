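## Museum-DNA handling: empirical deamination profiles, coverage-based
## sample exclusion, directional deamination variant filter.

#' Profile terminal deamination from mapped reads
#'
#' For each read (in sequencing orientation) the frequency of
#' reference-C/read-T mismatches by position from the 5' end and of
#' reference-G/read-A mismatches by distance from the 3' end is
#' accumulated over non-duplicate alignments, then an exponential decay
#' f(p) = delta * lambda^(p-1) is fitted to the 5' C->T profile by
#' weighted least squares.  Profiles whose fitted delta is below twice the
#' background mismatch rate (interior positions 11..P) are reported as "no
#' damage detected".  Profiles with fewer than 1000 informative terminal
#' positions are marked unreliable.
#'
#' @param aln an [AlignmentSet-class].
#' @param reference named character / DNAStringSet of locus sequences.
#' @param positions number of terminal positions profiled (default 25).
#' @param sample optional sample id to restrict to.
#' @param pool pool all (selected) reads into one profile (default TRUE);
#'   otherwise a named list of per-sample profiles is returned.
#' @return A [DamageProfile-class], or a named list of them.
#' @export
profileDamage <- function(aln, reference, positions = 25L, sample = NULL,
                          pool = TRUE) {
    refs <- .asSeqChar(reference)
    r <- aln@records
    r <- r[!r$is_duplicate, , drop = FALSE]
    if (!is.null(sample)) r <- r[r$sample %in% sample, , drop = FALSE]
    if (!pool && is.null(sample)) {
        out <- lapply(sort(unique(r$sample)), function(s)
            profileDamage(aln, reference, positions, sample = s,
                          pool = TRUE))
        names(out) <- sort(unique(r$sample))
        return(out)
    }
    P <- as.integer(positions)
    rd <- r$seq
    rf <- substr(refs[r$locus], r$start + 1L, r$end)
    neg <- r$strand == "-"
    if (any(neg)) {
        rd[neg] <- cpp_revcomp(rd[neg])
        rf[neg] <- cpp_revcomp(rf[neg])
    }
    len <- nchar(rd)
    ct_n <- ct_d <- ga_n <- ga_d <- numeric(P)
    mism_int <- opp_int <- 0
    for (p in seq_len(P)) {
        okp <- len >= p
        b5r <- substr(rf[okp], p, p)
        b5d <- substr(rd[okp], p, p)
        isC <- b5r == "C"
        ct_d[p] <- sum(isC)
        ct_n[p] <- sum(isC & b5d == "T")
        p3 <- len[okp] - p + 1L
        b3r <- substr(rf[okp], p3, p3)
        b3d <- substr(rd[okp], p3, p3)
        isG <- b3r == "G"
        ga_d[p] <- sum(isG)
        ga_n[p] <- sum(isG & b3d == "A")
        if (p >= 11L) {
            mism_int <- mism_int + sum(b5r != b5d) + sum(b3r != b3d)
            opp_int <- opp_int + sum(okp) * 2
        }
    }
    ct5 <- as.numeric(ifelse(ct_d > 0, ct_n / ct_d, NA_real_))
    ga3 <- as.numeric(ifelse(ga_d > 0, ga_n / ga_d, NA_real_))
    background <- if (opp_int > 0) mism_int / opp_int else 0
    n_inf <- sum(ct_d) + sum(ga_d)
    fit <- .fitDecay(ct5, ct_d)
    prof <- new("DamageProfile",
                sample = if (is.null(sample)) "pooled" else sample,
                ct5 = ct5, ga3 = ga3, delta = fit$delta,
                lambda = fit$lambda, background = background,
                n_informative = n_inf,
                no_damage = fit$delta < 2 * background,
                reliable = n_inf >= 1000)
    if (!prof@reliable)
        warning("damage profile unreliable: fewer than 1000 informative ",
                "positions")
    prof
}

## weighted least-squares fit of f(p) = delta * lambda^(p-1)
.fitDecay <- function(freq, weight) {
    ok <- !is.na(freq) & weight > 0
    p <- which(ok)
    f <- freq[ok]
    w <- weight[ok]
    if (length(p) < 2L || all(f == 0))
        return(list(delta = if (length(f)) sum(f * w) / sum(w) else 0,
                    lambda = 0.5))
    ## log-linear start (positive frequencies only)
    pos <- f > 0
    if (sum(pos) >= 2) {
        co <- coef(lm_wfit <- stats::lm(log(f[pos]) ~ I(p[pos] - 1),
                                        weights = w[pos]))
        start <- c(delta = min(1, max(1e-6, exp(co[1]))),
                   lambda = min(0.999, max(0.01, exp(co[2]))))
    } else start <- c(delta = max(f), lambda = 0.5)
    obj <- function(par)
        sum(w * (f - par[1] * par[2]^(p - 1))^2)
    op <- optim(start, obj, method = "L-BFGS-B",
                lower = c(0, 0.01), upper = c(1, 0.999))
    list(delta = unname(op$par[1]), lambda = unname(op$par[2]))
}

#' Build a per-sample QC table from coverage metrics and lab metadata
#'
#' @param cov data.frame from [coverageMetrics()].
#' @param sheet sample sheet with a260_a280 and conc_ng_ul columns.
#' @return data.frame(sample, mean_target_coverage, a260_a280,
#'   conc_ng_ul).
#' @export
sampleQC <- function(cov, sheet) {
    m <- match(cov$sample, sheet$sample)
    data.frame(sample = cov$sample,
               mean_target_coverage = cov$mean_depth,
               a260_a280 = sheet$a260_a280[m],
               conc_ng_ul = sheet$conc_ng_ul[m],
               stringsAsFactors = FALSE)
}

#' Exclude low-coverage samples; flag purity/yield rules of thumb
#'
#' Samples below `min_cov` mean target coverage are removed from
#' population-genetic analysis.  A260/A280 <= 1.0 (low purity) and
#' concentration <= 30 ng/uL (low yield) are attached as warnings only.
#'
#' @param qc data.frame from [sampleQC()] (columns sample,
#'   mean_target_coverage, a260_a280, conc_ng_ul).
#' @param min_cov coverage floor (X).
#' @return list(retained, excluded): data.frames with a `flags` column.
#' @export
qcExclude <- function(qc, min_cov = 2.0) {
    flags <- mapply(function(cov, ratio, conc) {
        f <- character()
        if (cov < min_cov) f <- c(f, "low_coverage")
        if (!is.na(ratio) && ratio <= 1.0) f <- c(f, "low_purity")
        if (!is.na(conc) && conc <= 30) f <- c(f, "low_yield")
        paste(f, collapse = ";")
    }, qc$mean_target_coverage, qc$a260_a280, qc$conc_ng_ul)
    qc$flags <- unname(flags)
    drop <- qc$mean_target_coverage < min_cov
    list(retained = qc[!drop, , drop = FALSE],
         excluded = qc[drop, , drop = FALSE])
}

#' Remove directionally deaminated variant sites
#'
#' Deamination is directional (C->T and G->A, never T->C or A->G), so
#' sites whose major-to-minor allele direction is C->T or G->A are removed
#' from every sample's genotype matrix -- modern and museum alike.  Major
#' and minor alleles are determined by overall allele frequency, ties
#' breaking toward the reference base as major.
#'
#' @param vs a [VariantSet-class].
#' @param per_species determine major/minor within each species and remove
#'   a site when any species shows a deamination direction (default FALSE:
#'   global major/minor).
#' @return list(kept = [VariantSet-class], removed = site table of removed
#'   sites, n_removed).
#' @export
deaminationFilter <- function(vs, per_species = FALSE) {
    if (!per_species) {
        dir <- .majorMinorDirection(vs)
        bad <- dir %in% c("CT", "GA")
    } else {
        bad <- rep(FALSE, ncol(vs@geno))
        for (sp in unique(vs@species)) {
            sub <- vs
            sel <- vs@species == sp
            sub@geno <- vs@geno[sel, , drop = FALSE]
            sub@species <- vs@species[sel]
            sub@samples <- vs@samples[sel]
            sub@gq <- vs@gq[sel, , drop = FALSE]
            sub@dp <- vs@dp[sel, , drop = FALSE]
            sub@adAlt <- vs@adAlt[sel, , drop = FALSE]
            dir <- .majorMinorDirection(sub)
            bad <- bad | dir %in% c("CT", "GA")
        }
    }
    list(kept = vs[!bad], removed = vs@sites[bad, , drop = FALSE],
         n_removed = sum(bad))
}
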