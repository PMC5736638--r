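## Two-group differential module activity: Student's t-test and fold
## change on the per-sample activity scores (metasamples). "Fold change"
## is the difference of group means: activity scores are centered PC
## projections, so a ratio would be ill-defined.

#' Differential activity of one signature between two groups
#'
#' Pooled-variance (Student) two-sample t-test on the activity scores,
#' two-sided; the Welch variant is available via `var_equal = FALSE`.
#' Group A is the alphabetically first group label, and `fold_change =
#' mean_b - mean_a`. Degenerate inputs: zero pooled variance with equal
#' means gives `t = 0`, `p = 1`; zero pooled variance with unequal means
#' gives `t = +/-Inf` and the 1e-300 p floor.
#'
#' @param metasample Named numeric vector of per-sample activity scores.
#' @param groups A [sample_groups()] object (each group needs >= 2
#'   scored samples).
#' @param alpha Significance threshold on the raw p-value (default 0.05;
#'   no multiple-testing correction at this step).
#' @param var_equal Pooled-variance Student test when `TRUE` (default).
#' @return List: `mean_a`, `mean_b`, `fold_change`, `t_stat`, `df`,
#'   `p_value`, `significant`.
#' @export
differential_activity <- function(metasample, groups, alpha = 0.05,
                                  var_equal = TRUE) {
  stopifnot(inherits(groups, "sample_groups"))
  lev <- attr(groups, "levels")
  labs <- unclass(groups)[intersect(names(groups), names(metasample))]
  xa <- metasample[names(labs)[labs == lev[1]]]
  xb <- metasample[names(labs)[labs == lev[2]]]
  if (length(xa) < 2L || length(xb) < 2L)
    stop_("each group needs at least 2 scored samples")
  na <- length(xa); nb <- length(xb)
  ma <- mean(xa); mb <- mean(xb)
  if (var_equal) {
    sp2 <- (sum((xa - ma)^2) + sum((xb - mb)^2)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(xa) / na; vb <- stats::var(xb) / nb
    se <- sqrt(va + vb)
    df <- if (se > 0) (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)) else
      na + nb - 2
  }
  if (se == 0) {
    t_stat <- if (mb == ma) 0 else sign(mb - ma) * Inf
    p <- if (mb == ma) 1 else 1e-300
  } else {
    t_stat <- (mb - ma) / se
    p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
    p <- min(max(p, 1e-300), 1)
  }
  list(mean_a = ma, mean_b = mb, fold_change = mb - ma, t_stat = t_stat,
       df = df, p_value = p, significant = p < alpha)
}

#' Differential activity of every scored signature
#'
#' Applies [differential_activity()] to each signature's metasample from
#' one dataset's activity scores. The PCA defining the scores is fit on
#' all samples pooled; the groups are compared on that shared component.
#'
#' @param scores An `activity_scores` object from [score_collection()].
#' @param groups A [sample_groups()] object over the dataset's samples.
#' @inheritParams differential_activity
#' @return Data frame: `signature`, `mean_a`, `mean_b`, `fold_change`,
#'   `t_stat`, `p_value`, `significant`.
#' @export
differential_table <- function(scores, groups, alpha = 0.05,
                               var_equal = TRUE) {
  stopifnot(inherits(scores, "activity_scores"))
  rows <- lapply(names(scores$metasamples), function(nm) {
    d <- differential_activity(scores$metasamples[[nm]], groups,
                               alpha = alpha, var_equal = var_equal)
    data.frame(signature = nm, mean_a = d$mean_a, mean_b = d$mean_b,
               fold_change = d$fold_change, t_stat = d$t_stat,
               p_value = d$p_value, significant = d$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
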