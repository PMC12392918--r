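## Group comparison layer: baseline normalization, one-way ANOVA with
## eta squared, a Monte Carlo Dunnett many-to-one test, and Cohen's d.

#' Normalize per-unit values to baseline
#'
#' `100 * value / baseline` per unit (organoid). Units with a zero
#' baseline yield NA with a warning.
#'
#' @param values numeric vector.
#' @param baseline numeric vector (recycled if length 1).
#' @return Percentages.
#' @export
normalizeToBaseline <- function(values, baseline) {
  if (length(baseline) == 1L) baseline <- rep(baseline, length(values))
  if (length(baseline) != length(values))
    stop("values and baseline lengths differ")
  out <- 100 * values / baseline
  if (any(baseline == 0)) {
    warning("zero baseline: normalized value undefined for that unit")
    out[baseline == 0] <- NA_real_
  }
  out
}

#' One-way ANOVA with eta squared
#'
#' Classical fixed-effects one-way ANOVA (`F = MSbetween / MSwithin`)
#' with `eta2 = SSbetween / SStotal`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total
#'   n >= 3).
#' @return List with `F`, `p`, `eta2`, `dfBetween`, `dfWithin`,
#'   `ssBetween`, `ssWithin`, `degenerate` (TRUE when all within-group
#'   variance is zero).
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- lengths(groups)
  if (sum(n) < 3L) stop("need total n >= 3")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  ssb <- a$`Sum Sq`[1]; ssw <- a$`Sum Sq`[2]
  degenerate <- ssw <= .Machine$double.eps * sum(y^2)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       eta2 = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
       dfBetween = a$Df[1], dfWithin = a$Df[2],
       ssBetween = ssb, ssWithin = ssw, degenerate = degenerate)
}

#' Monte Carlo null sample for the Dunnett max-|T| statistic
#'
#' Draws from the joint null of the k many-to-one comparisons: group
#' means `N(0, 1/n)`, shared pooled variance `chi^2_nu / nu`, and
#' returns the per-draw maximum |T|. Computing this once and passing it
#' to [dunnettTest()] makes repeated tests with the same design cheap.
#'
#' @param nControl control group size.
#' @param nTreat integer vector of treatment group sizes.
#' @param nu within-group degrees of freedom.
#' @param mcDraws number of Monte Carlo draws.
#' @param seed integer seed.
#' @return Numeric vector of `mcDraws` max-|T| values.
#' @export
dunnettNull <- function(nControl, nTreat, nu, mcDraws = 200000L, seed = 1L) {
  set.seed(seedOffset(seed, 77))
  k <- length(nTreat)
  z0 <- stats::rnorm(mcDraws, 0, sqrt(1 / nControl))
  s <- sqrt(stats::rchisq(mcDraws, nu) / nu)
  mx <- rep(-Inf, mcDraws)
  for (j in seq_len(k)) {
    zj <- stats::rnorm(mcDraws, 0, sqrt(1 / nTreat[j]))
    Tj <- abs(zj - z0) / (s * sqrt(1 / nTreat[j] + 1 / nControl))
    mx <- pmax(mx, Tj)
  }
  mx
}

#' Dunnett's many-to-one test (Monte Carlo)
#'
#' Compares each treatment group against the designated control using t
#' statistics with the pooled within-group variance, and adjusts
#' two-sidedly for multiplicity against the Monte Carlo distribution of
#' the maximum |T| under the equicorrelated multivariate t null
#' (correlation induced by the shared control and group sizes). The
#' adjusted p is clipped from below at the unadjusted two-sided t
#' p-value, so the multiplicity inequality holds despite Monte Carlo
#' noise. With the default 200,000 draws the Monte Carlo SE of an
#' adjusted p is at most about 0.0011.
#'
#' @param groups named list of numeric vectors.
#' @param control name of the control group.
#' @param mcDraws Monte Carlo draws for the null (ignored when `null`
#'   given).
#' @param seed integer seed.
#' @param null optional precomputed [dunnettNull()] sample.
#' @return data.frame with one row per comparison: `comparison`,
#'   `mean_diff`, `t`, `p_unadjusted`, `p_adjusted`, `cohens_d`.
#' @export
dunnettTest <- function(groups, control, mcDraws = 200000L, seed = 1L,
                        null = NULL) {
  if (!control %in% names(groups)) stop("control group not found")
  treat <- setdiff(names(groups), control)
  if (!length(treat)) stop("need at least one treatment group")
  n <- lengths(groups)
  N <- sum(n); kAll <- length(groups)
  nu <- N - kAll
  if (nu < 1L) stop("no within-group degrees of freedom")
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  msw <- ssw / nu
  if (msw <= 0) stop("zero pooled within-group variance")
  if (is.null(null))
    null <- dunnettNull(n[control], n[treat], nu, mcDraws, seed)
  rows <- lapply(treat, function(tr) {
    se <- sqrt(msw * (1 / n[tr] + 1 / n[control]))
    tval <- (means[tr] - means[control]) / se
    pun <- 2 * stats::pt(-abs(tval), nu)
    padj <- max(mean(null >= abs(tval)), pun)
    data.frame(comparison = paste(tr, "vs", control),
               mean_diff = means[tr] - means[control],
               t = tval, p_unadjusted = pun, p_adjusted = min(padj, 1),
               cohens_d = cohensD(groups[[tr]], groups[[control]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's d with pooled SD
#'
#' `d = (mean(a) - mean(b)) / sqrt(((nA-1) sA^2 + (nB-1) sB^2) /
#' (nA + nB - 2))`; returns signed Inf when the pooled SD is zero and
#' the means differ, 0 when both are zero.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return Numeric effect size.
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need n >= 2 per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' Full effect report for grouped values
#'
#' One-way ANOVA plus Dunnett comparisons against the control, the
#' layout used for concentration-response endpoints. Warns that
#' variance estimates are unstable for very small group sizes (the
#' typical design has n = 3 organoids per group) but computes as
#' specified.
#'
#' @inheritParams dunnettTest
#' @return List with `anova` (see [anovaOneway()]) and `comparisons`
#'   (see [dunnettTest()]).
#' @export
effectReport <- function(groups, control, mcDraws = 200000L, seed = 1L,
                         null = NULL) {
  if (min(lengths(groups)) <= 3L)
    warning("group sizes <= 3: variance estimates are unstable")
  list(anova = anovaOneway(groups),
       comparisons = dunnettTest(groups, control, mcDraws, seed, null))
}
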