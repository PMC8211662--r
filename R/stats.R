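#' Kruskal-Wallis test on a list of groups
#'
#' Tie-corrected rank-based H statistic with a chi-square p-value on k-1
#' degrees of freedom, for comparing cell counts (or any measurements)
#' across treatment groups.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return List with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)   # all observations tied: no evidence, H = 0
    return(list(H = 0, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z-statistics on pooled ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))`, two-sided p-values, and a family-wise
#' multiplicity adjustment across the compared pairs (Holm by default; the
#' exact family-wise method behind published "Dunn's correction" labels
#' varies by software, so it is configurable).
#'
#' @param groups named list of numeric vectors (unnamed lists get
#'   `group1..k`).
#' @param adjust multiplicity method passed to [stats::p.adjust]
#'   (default `"holm"`; e.g. `"bonferroni"`, `"BH"`, `"none"`).
#' @param control optional group name: compare only control vs each other
#'   group instead of all pairs.
#' @return data.frame with columns `group_a`, `group_b`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "holm", control = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 observations")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  gid <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, gid, mean)
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  if (!is.null(control)) {
    if (!control %in% names(groups)) stop("unknown control group: ", control)
    pairs <- Filter(function(p) control %in% p, pairs)
  }
  z <- vapply(pairs, function(p) {
    se <- sqrt(max(0, N * (N + 1) / 12 - tie_term) *
                 (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    num <- rbar[[p[1]]] - rbar[[p[2]]]
    if (se == 0) 0 else num / se   # fully tied data: no separation
  }, 0)
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = vapply(pairs, `[`, "", 1),
             group_b = vapply(pairs, `[`, "", 2),
             z = z,
             p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = adjust),
             stringsAsFactors = FALSE)
}

#' Descriptive summary with interquartile range
#'
#' Median, quartiles (type-7 linear interpolation), mean, minimum and
#' maximum - the quantities behind the package's box-plot style cohort
#' summaries.
#'
#' @param values numeric vector, length >= 1.
#' @return Named list: `median`, `q25`, `q75`, `mean`, `min`, `max`.
#' @export
iqr_summary <- function(values) {
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       mean = mean(values), min = min(values), max = max(values))
}
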