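## Population summaries: site filters, LD pruning, Weir-Cockerham Fst,
## diversity/sharing, PCA.

#' Missingness and minor-allele-frequency site filters
#'
#' Removes sites with missing fraction above `max_missing` or minor allele
#' frequency below `maf_min` (fixed sites, MAF 0, always go); a site at
#' exactly `maf_min` is retained.  Idempotent.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param max_missing maximum tolerated missing fraction per site.
#' @param maf_min minor-allele-frequency floor (strict "below removes").
#' @return The filtered [GenotypeMatrix-class].
#' @export
siteFilters <- function(gm, max_missing = 0.10, maf_min = 0.05) {
    g <- gm@geno
    miss <- colMeans(is.na(g))
    p <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0
    keep <- miss <= max_missing & maf >= maf_min & maf > 0
    new("GenotypeMatrix", geno = g[, keep, drop = FALSE],
        species = gm@species, sites = gm@sites[keep, , drop = FALSE])
}

## genotype r^2 between two dosage columns (pairwise complete)
.r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(0)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(0)
    cor(x[ok], y[ok])^2
}

#' Prune sites in linkage disequilibrium
#'
#' Sliding windows of `window` sites advancing by `step`; while any pair
#' in the window has genotype correlation r^2 above `r2_max`, the member
#' with more missing data is dropped (ties: lower MAF, then later
#' position).  Deterministic.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window,step window geometry in sites.
#' @param r2_max correlation threshold.
#' @return The pruned [GenotypeMatrix-class].
#' @export
ldPrune <- function(gm, window = 50L, step = 5L, r2_max = 0.5) {
    g <- gm@geno
    m <- ncol(g)
    if (m < 2L) return(gm)
    miss <- colSums(is.na(g))
    p <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    alive <- rep(TRUE, m)
    starts <- unique(c(seq(1L, max(1L, m - window + 1L), by = step),
                       max(1L, m - window + 1L)))
    for (s in starts) {
        idx <- s:min(m, s + window - 1L)
        repeat {
            cur <- idx[alive[idx]]
            if (length(cur) < 2L) break
            worst <- NULL
            for (a in seq_len(length(cur) - 1L)) {
                for (b in (a + 1L):length(cur)) {
                    if (.r2(g[, cur[a]], g[, cur[b]]) > r2_max) {
                        worst <- c(cur[a], cur[b])
                        break
                    }
                }
                if (!is.null(worst)) break
            }
            if (is.null(worst)) break
            a <- worst[1]; b <- worst[2]
            drop <- if (miss[a] != miss[b]) {
                if (miss[a] > miss[b]) a else b
            } else if (maf[a] != maf[b]) {
                if (maf[a] < maf[b]) a else b
            } else max(a, b)
            alive[drop] <- FALSE
        }
    }
    new("GenotypeMatrix", geno = g[, alive, drop = FALSE],
        species = gm@species, sites = gm@sites[alive, , drop = FALSE])
}

#' Weir-Cockerham Fst from a genotype matrix
#'
#' Per biallelic site, variance components a (among populations), b
#' (among individuals within populations) and c (within individuals) are
#' computed from sample sizes, allele frequencies and observed
#' heterozygote frequencies per population; theta per site is
#' a / (a + b + c) and the global estimate is the ratio of sums
#' sum(a) / sum(a + b + c).  Sites monomorphic overall, or genotyped in
#' fewer than two populations, are skipped.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param populations population label per sample (default: the species
#'   labels).
#' @return An [FstEstimate-class].
#' @export
wcFst <- function(gm, populations = NULL) {
    if (is.null(populations)) populations <- gm@species
    pops <- unique(populations)
    if (length(pops) < 2L) stop("need at least two populations")
    g <- gm@geno
    m <- ncol(g)
    a_v <- b_v <- c_v <- theta_v <- rep(NA_real_, m)
    for (j in seq_len(m)) {
        x <- g[, j]
        ok <- !is.na(x)
        ni <- tapply(ok, populations, sum)
        ni <- ni[!is.na(ni) & ni > 0]
        if (length(ni) < 2L) next
        use <- names(ni)
        pi <- vapply(use, function(pp)
            mean(x[populations == pp], na.rm = TRUE) / 2, 0)
        hi <- vapply(use, function(pp)
            mean(x[populations == pp] == 1L, na.rm = TRUE), 0)
        r <- length(ni)
        nbar <- mean(ni)
        pbar <- sum(ni * pi) / (r * nbar)
        if (pbar <= 0 || pbar >= 1) next
        nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
        s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(ni * hi) / (r * nbar)
        a <- (nbar / nc) *
            (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                 (nbar - 1))
        b <- (nbar / (nbar - 1)) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 -
                 (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        a_v[j] <- a; b_v[j] <- b; c_v[j] <- cc
        denom <- a + b + cc
        theta_v[j] <- if (denom != 0) a / denom else NA_real_
    }
    used <- !is.na(a_v)
    denom <- sum(a_v[used] + b_v[used] + c_v[used])
    theta <- if (denom != 0) sum(a_v[used]) / denom else NA_real_
    per_site <- cbind(gm@sites, a = a_v, b = b_v, c = c_v,
                      theta = theta_v)
    new("FstEstimate", perSite = per_site, theta = theta,
        r = length(pops))
}

#' Per-site diversity, cross-species locus sharing and missingness
#'
#' Emits per-site MAF, observed and expected heterozygosity (with means
#' and SDs), the locus-sharing histogram (how many loci are genotyped in
#' exactly k of the n species; presence = at least one genotyped
#' individual of the species at the locus), and per-sample / per-locus
#' missingness.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return list(per_site, mean_obs_het, sd_obs_het, mean_exp_het,
#'   sd_exp_het, sharing (named integer, k = 1..n species),
#'   per_sample_missing_pct, mean_missing_pct, sd_missing_pct,
#'   per_locus_missing).
#' @export
diversityAndSharing <- function(gm) {
    g <- gm@geno
    p <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    obs_het <- colMeans(g == 1L, na.rm = TRUE)
    exp_het <- 2 * p * (1 - p)
    per_site <- cbind(gm@sites, maf = maf, obs_het = obs_het,
                      exp_het = exp_het)
    spp <- unique(gm@species)
    loci <- unique(gm@sites$locus)
    pres <- vapply(spp, function(sp) {
        sub <- g[gm@species == sp, , drop = FALSE]
        has_site <- colSums(!is.na(sub)) > 0
        vapply(loci, function(l)
            any(has_site[gm@sites$locus == l]), TRUE)
    }, logical(length(loci)))
    if (length(loci) == 1L) pres <- matrix(pres, nrow = 1L)
    k <- rowSums(pres)
    sharing <- vapply(seq_along(spp), function(i) sum(k == i), 0L)
    names(sharing) <- seq_along(spp)
    samp_miss <- 100 * rowMeans(is.na(g))
    locus_miss <- vapply(loci, function(l)
        mean(is.na(g[, gm@sites$locus == l, drop = FALSE])), 0)
    list(per_site = per_site,
         mean_obs_het = mean(obs_het, na.rm = TRUE),
         sd_obs_het = sd(obs_het, na.rm = TRUE),
         mean_exp_het = mean(exp_het, na.rm = TRUE),
         sd_exp_het = sd(exp_het, na.rm = TRUE),
         sharing = sharing,
         per_sample_missing_pct = samp_miss,
         mean_missing_pct = mean(samp_miss),
         sd_missing_pct = sd(samp_miss),
         per_locus_missing = setNames(locus_miss, loci))
}

#' Principal component analysis of genotypes
#'
#' Genotype dosages are centred per site (missing values imputed at the
#' site mean) and scaled by sqrt(p(1-p)); the sample scores are taken from
#' the singular value decomposition with a deterministic sign convention
#' (the largest-magnitude loading of each component is positive).
#'
#' @param gm a [GenotypeMatrix-class] (filtered/pruned).
#' @param n_components number of components to return.
#' @return list(scores = samples x components matrix, explained =
#'   proportion of variance per component).
#' @export
pcaGenotypes <- function(gm, n_components = 10L) {
    g <- gm@geno
    if (nrow(g) < 3L) stop("PCA needs at least 3 samples")
    p <- colMeans(g, na.rm = TRUE) / 2
    keep <- !is.na(p) & p > 0 & p < 1
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
    X <- sweep(g, 2L, 2 * p)
    X[is.na(X)] <- 0
    X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
    sv <- svd(X)
    k <- min(n_components, length(sv$d))
    scores <- sv$u[, seq_len(k), drop = FALSE] %*%
        diag(sv$d[seq_len(k)], k, k)
    for (j in seq_len(k)) {
        ld <- sv$v[, j]
        if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
    }
    rownames(scores) <- rownames(g)
    colnames(scores) <- paste0("PC", seq_len(k))
    list(scores = scores, explained = sv$d^2 / sum(sv$d^2))
}
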