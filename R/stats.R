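# Bespoke statistics: two-sample two-dimensional Kolmogorov-Smirnov test
# (Fasano-Franceschini variant), exact-matching weights on an integer
# covariate, and the weighted Welch's t-test.

# asymptotic Kolmogorov survival function Q_KS(lambda)
q_ks <- function(lambda) {
  if (lambda < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample two-dimensional Kolmogorov-Smirnov test
#'
#' Fasano-Franceschini variant of Peacock's test: the statistic is the
#' largest difference, over the four quadrant orientations anchored at each
#' data point, between the two samples' empirical quadrant fractions,
#' averaged over anchoring in either sample. The p-value uses the standard
#' asymptotic formula with the correlation-adjusted effective sample size;
#' it is approximate, and flagged so, below n = 20 per sample.
#'
#' @param sample1,sample2 two-column matrices or data.frames of (x, y)
#'   observations, at least 3 rows each.
#' @return an object of class `htest` with `statistic` (D), `p.value`, and
#'   the per-sample sizes; `approximate` is TRUE for small samples.
#' @export
ks2d <- function(sample1, sample2) {
  s1 <- as.matrix(sample1); s2 <- as.matrix(sample2)
  if (ncol(s1) != 2L || ncol(s2) != 2L) stop("samples must have two columns")
  if (anyNA(s1) || anyNA(s2) || !all(is.finite(s1)) || !all(is.finite(s2))) {
    stop("samples must be finite")
  }
  n1 <- nrow(s1); n2 <- nrow(s2)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 points per sample")
  D <- ks2d_stat_cpp(s1[, 1L], s1[, 2L], s2[, 1L], s2[, 2L])
  safe_cor <- function(s) {
    if (var(s[, 1L]) == 0 || var(s[, 2L]) == 0) return(0)
    cor(s[, 1L], s[, 2L])
  }
  rr <- sqrt(1 - 0.5 * (safe_cor(s1)^2 + safe_cor(s2)^2))
  sqen <- sqrt(n1 * n2 / (n1 + n2))
  p <- q_ks(D * sqen / (1 + rr * (0.25 - 0.75 / sqen)))
  structure(list(statistic = c(D = D), p.value = p,
                 method = "Two-sample 2D Kolmogorov-Smirnov test (Fasano-Franceschini)",
                 data.name = paste(deparse(substitute(sample1)), "and",
                                   deparse(substitute(sample2))),
                 n = c(n1 = n1, n2 = n2),
                 approximate = (n1 < 20L || n2 < 20L)),
            class = "htest")
}

#' Exact-matching weights on an integer covariate
#'
#' Matches observations exactly on an integer stratum (here: cells per
#' cross-section). Strata missing any group are dropped (weight 0). Within a
#' retained stratum the reference group keeps weight 1 and every other group
#' is weighted `n_ref / n_group`, so the weighted stratum frequencies of all
#' groups equal the reference group's, exactly. A coarsening width can merge
#' neighbouring strata first; it defaults to off (pure exact matching).
#'
#' @param data data.frame with columns `group` and `stratum` (integer-valued);
#'   other columns pass through.
#' @param reference reference group; defaults to the first level / first
#'   occurring group.
#' @param coarsen optional positive width; strata become
#'   `floor(stratum / coarsen)`.
#' @return `data` with added columns `weight` and (if coarsened) `stratum_c`.
#' @export
cem_weights <- function(data, reference = NULL, coarsen = NULL) {
  if (!all(c("group", "stratum") %in% names(data))) {
    stop("data needs columns 'group' and 'stratum'")
  }
  grp <- as.factor(data$group)
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  strat <- data$stratum
  if (!is.null(coarsen)) {
    strat <- floor(strat / coarsen)
    data$stratum_c <- strat
  }
  if (is.null(reference)) reference <- levels(grp)[1L]
  if (!reference %in% levels(grp)) stop("reference group not present")
  tab <- table(strat, grp)
  keep <- rownames(tab)[apply(tab > 0, 1L, all)]
  if (length(keep) == 0L) stop("no overlap: no stratum contains every group")
  w <- numeric(nrow(data))
  for (s in keep) {
    in_s <- strat == as.numeric(s)
    n_ref <- sum(in_s & grp == reference)
    for (g in levels(grp)) {
      sel <- in_s & grp == g
      w[sel] <- if (g == reference) 1 else n_ref / sum(sel)
    }
  }
  data$weight <- w
  data
}

#' Weighted Welch's t-test
#'
#' Welch's unequal-variance t-test on weighted samples: weighted means and
#' variances with the effective sample size `n_eff = (sum w)^2 / sum(w^2)`,
#' Welch-Satterthwaite degrees of freedom on the weighted quantities, and a
#' two-sided p-value. With unit weights this reproduces the textbook Welch
#' test exactly.
#'
#' @param x,y numeric outcome vectors.
#' @param wx,wy nonnegative weights (default all 1). Zero-weight observations
#'   are dropped.
#' @return an object of class `htest` with `statistic` (t), `parameter` (df),
#'   `p.value`, the group means, and the effective sample sizes.
#' @export
weighted_welch_ttest <- function(x, wx = NULL, y, wy = NULL) {
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  if (any(wx < 0) || any(wy < 0)) stop("weights must be nonnegative")
  kx <- wx > 0; ky <- wy > 0
  x <- x[kx]; wx <- wx[kx]; y <- y[ky]; wy <- wy[ky]
  wstats <- function(v, w) {
    n_eff <- sum(w)^2 / sum(w^2)
    m <- sum(w * v) / sum(w)
    s2 <- sum(w * (v - m)^2) / sum(w) * n_eff / (n_eff - 1)
    list(m = m, s2 = s2, n_eff = n_eff)
  }
  a <- wstats(x, wx); b <- wstats(y, wy)
  if (a$n_eff <= 1 || b$n_eff <= 1) stop("effective sample size must exceed 1")
  if (a$s2 == 0 && b$s2 == 0) stop("zero weighted variance in both groups")
  va <- a$s2 / a$n_eff; vb <- b$s2 / b$n_eff
  t <- (a$m - b$m) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n_eff - 1) + vb^2 / (b$n_eff - 1))
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = 2 * pt(-abs(t), df),
                 estimate = c(mean1 = a$m, mean2 = b$m),
                 n_eff = c(n_eff1 = a$n_eff, n_eff2 = b$n_eff),
                 method = "Weighted Welch's two-sample t-test",
                 data.name = "x and y"),
            class = "htest")
}
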