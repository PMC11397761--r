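# Sampling-design utilities and nonparametric group comparisons.

#' Sample size under simple random sampling with finite-population correction
#'
#' Computes `n0 = z^2 p (1-p) / d^2` and corrects for a finite frame:
#' `net = ceil(n0 / (1 + (n0 - 1) / N))`. A loss allowance inflates the net
#' size multiplicatively, rounding half up. For the basket program's frame of
#' 1874 municipalities at p = 0.5 (maximum variance), 95% confidence and a
#' 0.05 margin this gives a net sample of 319 and, with 30% loss, a gross
#' sample of 415.
#'
#' @param N frame (population) size, >= 2.
#' @param p expected proportion in (0, 1); default 0.5.
#' @param conf_level confidence level; default 0.95.
#' @param d absolute margin of error in (0, 1); default 0.05.
#' @param loss_fraction anticipated loss in \[0, 1); default 0.
#' @return list with `net_n` and `gross_n`.
#' @export
sample_size_fpc <- function(N, p = 0.5, conf_level = 0.95, d = 0.05,
                            loss_fraction = 0) {
  if (!is.numeric(d) || d <= 0 || d >= 1) {
    canasta_error("canasta_domain_error", "margin d must lie in (0, 1)")
  }
  stopifnot(N >= 2, p > 0, p < 1, conf_level > 0, conf_level < 1,
            loss_fraction >= 0, loss_fraction < 1)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n0 <- z^2 * p * (1 - p) / d^2
  net <- ceiling(n0 / (1 + (n0 - 1) / N))
  gross <- round_half_up(net * (1 + loss_fraction))
  list(net_n = as.integer(net), gross_n = as.integer(gross))
}

#' Stratified random selection without replacement
#'
#' Draws a without-replacement sample within each stratum. By default the
#' total is allocated proportionally to stratum frame sizes
#' (largest-remainder rounding); an explicit per-stratum allocation may be
#' given instead. Selection is deterministic under a fixed seed.
#'
#' @param frame data frame of units.
#' @param stratum name of the stratum column.
#' @param n total sample size (proportional allocation), ignored when
#'   `allocation` is given.
#' @param allocation optional named vector of per-stratum sample sizes.
#' @param seed integer RNG seed.
#' @return the sampled rows of `frame`.
#' @export
stratified_select <- function(frame, stratum = "domain", n = NULL,
                              allocation = NULL, seed = 1L) {
  sizes <- table(frame[[stratum]])
  if (is.null(allocation)) {
    stopifnot(!is.null(n), n <= nrow(frame))
    share <- n * as.numeric(sizes) / nrow(frame)
    alloc <- floor(share)
    rem <- n - sum(alloc)
    if (rem > 0) {
      top <- order(share - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[top] <- alloc[top] + 1L
    }
    allocation <- stats::setNames(alloc, names(sizes))
  }
  over <- names(allocation)[allocation > as.numeric(sizes[names(allocation)])]
  if (length(over)) {
    canasta_error("canasta_domain_error",
                  sprintf("allocation exceeds frame size in stratum: %s",
                          paste(over, collapse = ", ")))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  idx <- unlist(lapply(names(allocation), function(s) {
    pool <- which(frame[[stratum]] == s)
    pool[sample.int(length(pool), allocation[[s]])]
  }))
  frame[sort(idx), , drop = FALSE]
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7), fixed so that published-style `Me (IQR)` tables are reproducible.
#'
#' @param x numeric sample, n >= 1, NAs removed.
#' @return list with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) canasta_error("canasta_domain_error", "empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom (via [stats::kruskal.test()]). The degenerate all-identical case,
#' where the tie correction is undefined, is reported as H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels, same length; >= 2 groups.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(droplevels(groups)) >= 2,
            length(values) >= 3)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's rank-based post-hoc comparisons
#'
#' All-pairs z tests on mean ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups, two-sided p-values and a
#' multiplicity adjustment (Holm by default).
#'
#' @inheritParams kruskal_wallis
#' @param adjust adjustment method passed to [stats::p.adjust()].
#' @return data frame: `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  stopifnot(k >= 2)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_T <- sum(ties^3 - ties)
  v0 <- N * (N + 1) / 12 - tie_T / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(v0 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
    p_adj = stats::p.adjust(p, method = adjust),
    stringsAsFactors = FALSE
  )
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: groups sharing no letter differ
#' significantly; groups sharing a letter do not.
#'
#' @param pairwise data frame from [dunn_posthoc()].
#' @param alpha significance level applied to `p_adj`; default 0.05.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairwise, alpha = 0.05) {
  lev <- sort(unique(c(pairwise$group1, pairwise$group2)))
  cols <- list(lev) # each column: a set of mutually non-different groups
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    for (j in seq_along(cols)) {
      if (all(c(a, b) %in% cols[[j]])) {
        cols[[j]] <- setdiff(cols[[j]], a)
        cols[[length(cols) + 1L]] <- setdiff(c(cols[[j]], a), b)
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (j in seq_along(cols)) {
      for (l in seq_along(cols)) {
        if (j != l && keep[l] && all(cols[[j]] %in% cols[[l]]) &&
            length(cols[[j]]) < length(cols[[l]])) {
          keep[j] <- FALSE
        }
      }
    }
    cols <- cols[keep]
    cols <- cols[!duplicated(lapply(cols, sort))]
  }
  cols <- cols[order(vapply(cols, function(cl) min(match(cl, lev)), numeric(1)))]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (j in seq_along(cols)) {
    out[cols[[j]]] <- paste0(out[cols[[j]]], letters[j])
  }
  out
}

#' Compare a variable across groups: medians, Kruskal-Wallis and letters
#'
#' The presentation used in the basket tables: per-group `Me (IQR)` with a
#' Kruskal-Wallis test and Dunn post-hoc compact letters at `alpha`.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level; default 0.05.
#' @param adjust multiplicity adjustment for the post-hoc tests.
#' @return list with `summary` (per-group median/q1/q3/letter), `H`, `df`,
#'   `p`, and the `pairwise` table.
#' @export
group_comparison <- function(values, groups, alpha = 0.05, adjust = "holm") {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) {
    # a single stratum: summarize only, no test to run
    mi <- median_iqr(values)
    return(list(
      summary = data.frame(group = levels(groups), n = length(values),
                           median = mi$median, q1 = mi$q1, q3 = mi$q3,
                           letter = "a", stringsAsFactors = FALSE),
      H = NA_real_, df = NA_integer_, p = NA_real_, pairwise = NULL
    ))
  }
  kw <- kruskal_wallis(values, groups)
  pw <- dunn_posthoc(values, groups, adjust = adjust)
  # letters only meaningful when the global test rejects; otherwise all share one
  lets <- if (kw$p < alpha) compact_letters(pw, alpha) else
    stats::setNames(rep("a", nlevels(groups)), levels(groups))
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    mi <- median_iqr(values[groups == g])
    data.frame(group = g, n = sum(groups == g), median = mi$median,
               q1 = mi$q1, q3 = mi$q3, letter = unname(lets[g]),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, H = kw$H, df = kw$df, p = kw$p, pairwise = pw)
}
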