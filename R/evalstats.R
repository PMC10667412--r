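dice_from_arrays <- function(pred, truth, class_id) {
  a <- pred == class_id
  b <- truth == class_id
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Dice overlap coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` between the voxel sets of `class_id` in two
#' aligned label maps; defined as 1 when the class is absent from both.
#'
#' @param pred,truth [cta_labelmap()] objects (or plain integer arrays of
#'   equal shape).
#' @param class_id 1 (brain/cavity) or 2 (extracranial arteries).
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, class_id) {
  if (!class_id %in% 1:2) stop("class_id must be 1 or 2")
  pa <- if (inherits(pred, "cta_labelmap")) pred$labels else pred
  ta <- if (inherits(truth, "cta_labelmap")) truth$labels else truth
  if (inherits(pred, "cta_labelmap") && inherits(truth, "cta_labelmap")) {
    if (!identical(dim(pa), dim(ta)) ||
        max(abs(pred$spacing - truth$spacing)) > 1e-6)
      stop("label maps are not aligned")
  } else if (!identical(dim(pa), dim(ta))) {
    stop("label maps are not aligned")
  }
  dice_from_arrays(pa, ta, class_id)
}

# exact null distribution of the signed-rank sum via subset convolution
# over doubled (integer) midranks; returns P(W <= w) and P(W >= w)
signrank_exact_tail <- function(ranks2, w2) {
  maxs <- sum(ranks2)
  f <- numeric(maxs + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(maxs + 1L)] <- g[(r + 1L):(maxs + 1L)] + f[1:(maxs + 1L - r)]
    f <- g / 2
  }
  list(lower = sum(f[seq_len(w2 + 1L)]),
       upper = sum(f[(w2 + 1L):(maxs + 1L)]))
}

#' Wilcoxon signed-rank test for paired ordinal scores
#'
#' Two-sided paired test. Zero differences are dropped by default (the
#' Pratt variant, which ranks them before discarding, is available).
#' Absolute differences are ranked with midranks for ties; for up to 25
#' remaining pairs the p-value comes from the exact permutation
#' distribution of the signed-rank sum (computed by convolution over sign
#' assignments, valid under ties), otherwise from the normal approximation
#' with the tie-corrected variance.
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact for n <= 25 (drop method only).
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `n` (pairs used), and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("drop", "pratt"),
                                 exact = NULL) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be non-empty and of equal length")
  d <- as.numeric(x) - as.numeric(y)
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  use_exact <- if (is.null(exact)) n <= 25L && zero_method == "drop"
  else isTRUE(exact)
  if (use_exact && zero_method == "drop") {
    r2 <- as.integer(round(2 * r))
    tails <- signrank_exact_tail(r2, as.integer(round(2 * W)))
    p <- min(1, 2 * min(tails$lower, tails$upper))
    method <- "exact"
  } else {
    if (zero_method == "drop") {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    } else {
      n0 <- sum(x == y)
      m <- n + n0
      mu <- (m * (m + 1) - n0 * (n0 + 1)) / 4
      ties <- table(r)
      v <- (m * (m + 1) * (2 * m + 1) -
              n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
        sum(ties^3 - ties) / 48
    }
    z <- (W - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = min(1, p), n = n, method = method)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for two independent samples. U is computed from
#' midranks; p comes from the exact U distribution when both samples are
#' small (<= 25) and tie-free, otherwise from the normal approximation
#' with the tie-corrected variance.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact force/suppress the exact distribution; default `NULL`
#'   chooses exact for tie-free samples with both sizes <= 25.
#' @return List with `statistic` (U for sample `a`), `p_value`, and
#'   `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  no_ties <- !anyDuplicated(c(a, b))
  use_exact <- if (is.null(exact)) no_ties && max(n1, n2) <= 25L
  else isTRUE(exact)
  if (use_exact && no_ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p <- if (v <= 0) 1 else min(1, 2 * stats::pnorm(-abs((U - mu) / sqrt(v))))
    method <- "normal approximation"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Computes `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' continuity term floored at zero, and the two-sided p-value from the
#' chi-square distribution with one degree of freedom (p = 1 when the
#' statistic is zero).
#'
#' @param table 2x2 non-negative integer matrix (rows = groups, columns =
#'   outcome), or a length-4 vector `c(a, b, c, d)` filled by row.
#' @return List with `statistic` and `p_value`.
#' @examples
#' chi_square_yates(c(61, 39, 29, 12))$p_value  # 0.369
#' @export
chi_square_yates <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2L, 2L, byrow = TRUE)
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != round(table)))
    stop("table must be a 2x2 matrix of non-negative counts")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  N <- a + b + cc + d
  if (N == 0) stop("table is empty")
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0)) stop("chi-square undefined: a marginal total is zero")
  chi <- N * max(abs(a * d - b * cc) - N / 2, 0)^2 / prod(marg)
  list(statistic = chi,
       p_value = if (chi == 0) 1 else stats::pchisq(chi, 1,
                                                    lower.tail = FALSE))
}

#' Cohen's weighted kappa for ordinal ratings
#'
#' Chance-corrected inter-rater agreement with distance-based disagreement
#' weights: `kappa = 1 - sum(w O) / sum(w E)` with observed cell
#' proportions `O`, expected-under-independence `E` from the marginal
#' products, and weights `w_ij = |i-j|/(k-1)` (linear, default) or
#' `((i-j)/(k-1))^2` (quadratic). With two categories both weightings
#' reduce to unweighted kappa.
#'
#' @param ratings_a,ratings_b equal-length vectors of ratings.
#' @param categories ordered category set, default `1:5`.
#' @param weighting `"linear"` or `"quadratic"`.
#' @return Scalar kappa. Errors if both raters use a single identical
#'   category (kappa undefined).
#' @export
weighted_kappa <- function(ratings_a, ratings_b, categories = 1:5,
                           weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 1L)
    stop("ratings must be non-empty and of equal length")
  if (!all(ratings_a %in% categories) || !all(ratings_b %in% categories))
    stop("ratings outside the category set")
  k <- length(categories)
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  O <- table(fa, fb) / length(ratings_a)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weighting == "linear") d else d^2
  denom <- sum(w * E)
  if (denom == 0)
    stop("kappa undefined: both raters use a single category")
  1 - sum(w * O) / denom
}

#' Reader-study score table
#'
#' Validates a table of per-case, per-structure ordinal visibility scores
#' (1 = not visible ... 5 = completely visible, diagnostically sufficient)
#' under one or two reading conditions.
#'
#' @param df data frame with columns `case`, `structure`, `condition`
#'   (`"focused"` or `"unmodified"`), `reader`, `score`.
#' @return The validated data frame, classed `score_table`.
#' @export
score_table <- function(df) {
  need <- c("case", "structure", "condition", "reader", "score")
  if (!all(need %in% names(df)))
    stop("score table needs columns ", paste(need, collapse = ", "))
  if (!all(df$score %in% 1:5))
    stop("scores must be integers in 1..5")
  if (!all(df$condition %in% c("focused", "unmodified")))
    stop("condition must be 'focused' or 'unmodified'")
  key <- do.call(paste, c(df[c("case", "structure", "condition", "reader")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (case, structure, condition, reader) rows")
  class(df) <- c("score_table", "data.frame")
  df
}

#' Summarize visibility scores per group
#'
#' Median, interquartile range, and range of the scores within each group
#' (default: per structure and condition), with quartiles by inclusive
#' linear interpolation — the rule that yields half-integer medians such
#' as 2.5 on small even samples. Empty groups are omitted with a warning.
#'
#' @param table a [score_table()] (or compatible data frame).
#' @param by grouping columns, default `c("structure", "condition")`.
#' @return Data frame with one row per group: `n`, `median`, `q1`, `q3`,
#'   `min`, `max`, and `summary` formatted as
#'   `"m (IQR: a-b, range: c-d)"`.
#' @export
summarize_scores <- function(table, by = c("structure", "condition")) {
  if (nrow(table) == 0L) stop("empty score table")
  if (!all(by %in% names(table))) stop("unknown grouping columns")
  groups <- split(seq_len(nrow(table)),
                  lapply(by, function(b) table[[b]]), drop = FALSE)
  empty <- vapply(groups, length, 0L) == 0L
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  fmt <- function(v) formatC(v, format = "g")
  rows <- lapply(names(groups), function(g) {
    s <- table$score[groups[[g]]]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      group = g, n = length(s), median = q[2], q1 = q[1], q3 = q[3],
      min = min(s), max = max(s),
      summary = sprintf("%s (IQR: %s-%s, range: %s-%s)", fmt(q[2]),
                        fmt(q[1]), fmt(q[3]), fmt(min(s)), fmt(max(s))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keys <- do.call(rbind, strsplit(out$group, ".", fixed = TRUE))
  for (i in seq_along(by)) out[[by[i]]] <- keys[, i]
  out$group <- NULL
  out[c(by, setdiff(names(out), by))]
}
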