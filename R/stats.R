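#' Mann-Whitney U test for two independent samples
#'
#' U is computed from rank sums with midrank ties. The p-value is exact
#' (distribution-free enumeration) when the combined sample size is at
#' most `exact_max` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' When every value in both groups is identical the comparison is
#' degenerate and p = 1 is returned with a flag.
#'
#' @param x,y numeric vectors (finite, length >= 1).
#' @param exact_max largest combined n for the exact path. Default 12.
#' @return list: `U` (U statistic of `x`), `p` (two-sided), `method`
#'   ("exact" or "normal_approx"), `degenerate`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) < 1L || length(y) < 1L) stop("both groups need data")
  if (!all(is.finite(c(x, y)))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p = 1, method = "degenerate", degenerate = TRUE))
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- (n1 + n2) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = U, p = unname(wt$p.value),
       method = if (use_exact) "exact" else "normal_approx",
       degenerate = FALSE)
}

#' Permutation test for a time-by-group interaction
#'
#' A distribution-free replacement for the two-way repeated-measures ANOVA
#' interaction test: after removing each fly's own mean (the
#' repeated-measures structure), the statistic is the interaction sum of
#' squares of the group-by-day cell means. The null distribution comes
#' from permuting group labels across whole flies, which preserves each
#' fly's within-subject correlation. p = (1 + #permuted >= observed) /
#' (1 + n_perm).
#'
#' @param tab data.frame with columns `fly`, `day`, `group`, `value`; each
#'   (fly, day) at most once, each fly in exactly one group.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list: `p`, `statistic` (observed interaction SS), `n_perm`.
#' @export
interaction_permutation_test <- function(tab, n_perm = 999, seed = 1) {
  req <- c("fly", "day", "group", "value")
  if (!all(req %in% names(tab))) stop("tab needs columns fly/day/group/value")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (anyDuplicated(tab[, c("fly", "day")]) > 0L)
    stop("each (fly, day) may appear at most once")
  grp_of_fly <- tapply(as.character(tab$group), tab$fly,
                       function(g) unique(g))
  if (any(lengths(grp_of_fly) != 1L))
    stop("each fly must belong to exactly one group")
  flies <- names(grp_of_fly)
  groups <- unname(vapply(grp_of_fly, identity, character(1)))
  days <- sort(unique(tab$day))
  if (length(unique(groups)) < 2L || length(days) < 2L)
    stop("need at least 2 groups and 2 days")
  if (any(table(groups) < 2L)) stop("need at least 2 flies per group")
  # flies x days value matrix, fly-mean-centered
  M <- matrix(NA_real_, nrow = length(flies), ncol = length(days),
              dimnames = list(flies, as.character(days)))
  M[cbind(match(as.character(tab$fly), flies),
          match(tab$day, days))] <- tab$value
  M <- M - rowMeans(M, na.rm = TRUE)
  inter_ss <- function(assign) {
    # rowsum and table both order cells by sorted group label
    C <- rowsum(M, assign, na.rm = TRUE) / as.vector(table(assign))
    resid <- C - outer(rowMeans(C), rep(1, ncol(C))) -
      outer(rep(1, nrow(C)), colMeans(C)) + mean(C)
    sum(resid^2)
  }
  obs <- inter_ss(groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (inter_ss(sample(groups)) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + n_perm), statistic = obs, n_perm = n_perm)
}

#' One-sided sign test for paired increases
#'
#' Tests whether paired differences are positive more often than chance
#' (ties dropped), via the exact binomial test.
#'
#' @param after,before paired numeric vectors.
#' @return list: `p` (one-sided, H1: after > before), `n_increase`,
#'   `n_informative`.
#' @export
sign_test_increase <- function(after, before) {
  stopifnot(length(after) == length(before))
  d <- after - before
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0L)
    return(list(p = 1, n_increase = 0L, n_informative = 0L))
  bt <- stats::binom.test(sum(d > 0), length(d), p = 0.5,
                          alternative = "greater")
  list(p = unname(bt$p.value), n_increase = sum(d > 0),
       n_informative = length(d))
}
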