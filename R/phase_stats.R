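#' Kruskal-Wallis omnibus test across phases
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected
#' H statistic and the chi-square p-value with k - 1 degrees of freedom.
#' When every value is identical the statistic is 0 and p = 1.
#'
#' @param samples Named list of numeric vectors, one per phase (values
#'   across cultures).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2 || any(lengths(samples) < 2))
    stop("need >= 2 groups with >= 2 values each")
  vals <- unlist(samples, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    return(list(H = 0, p = 1, df = length(samples) - 1L))
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Conover-Iman all-pairs post-hoc comparisons
#'
#' Computes the Conover-Iman t statistics on the pooled ranks used by the
#' Kruskal-Wallis test, with tie correction and N - k degrees of freedom,
#' and returns two-sided p-values adjusted for the multiplicity of pairs
#' (Holm by default). For group means of ranks Ri, Rj the statistic is
#' `t = (Ri - Rj) / sqrt(S2 * (N - 1 - H) / (N - k) * (1/ni + 1/nj))` with
#' `S2 = (sum(R^2) - N (N+1)^2 / 4) / (N - 1)`.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param p_adjust_method Method for [stats::p.adjust()] over the pairs
#'   (default `"holm"`).
#' @return List with `p` (symmetric matrix of adjusted p-values, diagonal
#'   `NA`), `p_unadjusted`, `t` (statistics), `df`, and
#'   `p_adjust_method`. Groups with fewer than 2 values yield `NA` rows.
#' @export
conover_all_pairs <- function(samples, p_adjust_method = "holm") {
  k <- length(samples)
  if (k < 2) stop("need >= 2 groups")
  g <- names(samples) %||% paste0("g", seq_len(k))
  n <- lengths(samples)
  vals <- unlist(samples, use.names = FALSE)
  N <- length(vals)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(g, g))
  tmat <- mk(); praw <- mk()
  if (length(unique(vals)) == 1L) {
    praw[upper.tri(praw) | lower.tri(praw)] <- 1
    tmat[upper.tri(tmat) | lower.tri(tmat)] <- 0
    return(list(p = praw, p_unadjusted = praw, t = tmat, df = N - k,
                p_adjust_method = p_adjust_method))
  }
  r <- rank(vals)
  grp <- rep(seq_len(k), n)
  rbar <- tapply(r, grp, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- unname(stats::kruskal.test(samples)$statistic)
  scale2 <- S2 * (N - 1 - H) / (N - k)
  df <- N - k
  pair <- utils::combn(k, 2)
  pr <- numeric(ncol(pair))
  for (c in seq_len(ncol(pair))) {
    i <- pair[1, c]; j <- pair[2, c]
    if (n[i] < 2 || n[j] < 2) { pr[c] <- NA_real_; next }
    se <- sqrt(scale2 * (1 / n[i] + 1 / n[j]))
    tij <- (rbar[i] - rbar[j]) / se
    tmat[i, j] <- tmat[j, i] <- tij
    pr[c] <- 2 * stats::pt(-abs(tij), df)
  }
  padj <- stats::p.adjust(pr, method = p_adjust_method)
  for (c in seq_len(ncol(pair))) {
    i <- pair[1, c]; j <- pair[2, c]
    praw[i, j] <- praw[j, i] <- pr[c]
  }
  pmat <- mk()
  for (c in seq_len(ncol(pair))) {
    i <- pair[1, c]; j <- pair[2, c]
    pmat[i, j] <- pmat[j, i] <- padj[c]
  }
  list(p = pmat, p_unadjusted = praw, t = tmat, df = df,
       p_adjust_method = p_adjust_method)
}

#' Median percent change between two phases
#'
#' `100 * (median(a) - median(b)) / median(b)`; negative values mean a
#' decrease in `a` relative to `b`.
#'
#' @param a,b Numeric vectors (e.g. normalized metric values across
#'   cultures for two phases).
#' @return Percent change (scalar).
#' @export
median_percent_change <- function(a, b) {
  mb <- stats::median(b, na.rm = TRUE)
  if (is.na(mb) || mb == 0) stop("reference median is zero or undefined")
  100 * (stats::median(a, na.rm = TRUE) - mb) / mb
}

#' Nonparametric phase comparison for every metric
#'
#' For each of the four normalized metrics: Kruskal-Wallis omnibus across
#' the phases, Conover-Iman all-pairs post-hoc (Holm-adjusted), and the
#' matrix of median percent changes between phases.
#'
#' @param norm_table A normalized `metrics_table` over several cultures
#'   (see [normalize_metrics()]).
#' @param metrics Metric columns to analyse.
#' @param p_adjust_method Passed to [conover_all_pairs()].
#' @return An object of class `stats_report`: named list per metric with
#'   `H`, `p_omnibus`, `pairwise_p`, `median_change` (percent,
#'   `[a, b]` = change of phase a relative to phase b), `n_cultures`.
#' @export
phase_stats <- function(norm_table, metrics = c("MFR", "MBR", "MBD", "MOBFR"),
                        p_adjust_method = "holm") {
  stopifnot(inherits(norm_table, "metrics_table"))
  if (!isTRUE(attr(norm_table, "normalized")))
    warning("phase_stats is normally run on a normalized metrics table")
  phases <- unique(norm_table$phase)
  out <- list()
  for (m in metrics) {
    samples <- lapply(phases, function(ph)
      stats::na.omit(norm_table[[m]][norm_table$phase == ph]))
    names(samples) <- phases
    usable <- lengths(samples) >= 2
    rep_m <- list(H = NA_real_, p_omnibus = NA_real_,
                  pairwise_p = NULL, median_change = NULL,
                  n_cultures = length(unique(norm_table$culture)))
    if (sum(usable) >= 2) {
      kw <- kruskal_wallis(samples[usable])
      co <- conover_all_pairs(samples[usable], p_adjust_method)
      mc <- matrix(NA_real_, length(phases), length(phases),
                   dimnames = list(phases, phases))
      for (a in phases) for (b in phases)
        if (a != b && length(samples[[b]]) > 0 &&
            stats::median(samples[[b]]) != 0)
          mc[a, b] <- median_percent_change(samples[[a]], samples[[b]])
      rep_m <- list(H = kw$H, p_omnibus = kw$p, pairwise_p = co$p,
                    median_change = mc,
                    n_cultures = length(unique(norm_table$culture)))
    }
    out[[m]] <- rep_m
  }
  structure(out, class = "stats_report",
            p_adjust_method = p_adjust_method)
}

#' @export
print.stats_report <- function(x, ...) {
  for (m in names(x)) {
    cat(m, ": H = ", signif(x[[m]]$H, 4),
        ", omnibus p = ", signif(x[[m]]$p_omnibus, 3),
        " (n = ", x[[m]]$n_cultures, " cultures)\n", sep = "")
  }
  invisible(x)
}
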