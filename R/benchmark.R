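#' Build a gold standard
#'
#' @param positives,negatives data frames of pairs (columns `a`, `b`);
#'   canonicalized and de-duplicated. The two sets must be disjoint and
#'   non-empty.
#' @return object of class `gold_standard`: list of canonical pair-key
#'   character vectors `positives` and `negatives`.
#' @export
gold_standard <- function(positives, negatives) {
  pos <- unique(pair_key(positives$a, positives$b))
  neg <- unique(pair_key(negatives$a, negatives$b))
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("gold standard needs non-empty positive and negative sets")
  }
  if (length(intersect(pos, neg)) > 0L) {
    stop("gold standard positive and negative sets overlap")
  }
  out <- list(positives = pos, negatives = neg)
  class(out) <- "gold_standard"
  out
}

#' F-beta measure
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`, with the convention that the
#' value is 0 when precision and recall are both 0. The default
#' `beta = 0.5` weights precision more than recall, the criterion used to
#' pick the score threshold.
#'
#' @param precision,recall fractions in \[0, 1\] (vectorized).
#' @param beta trade-off parameter.
#' @return F-beta in \[0, 1\].
#' @examples
#' f_beta(0.5, 0.2)        # 0.3846...
#' f_beta(0.3, 0.3)        # = 0.3 for any beta
#' @export
f_beta <- function(precision, recall, beta = 0.5) {
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

#' Threshold sweep over a scored, labeled pair set
#'
#' Restricts the scored pairs to those present in the gold standard
#' (unlabeled pairs carry no evaluation signal and are excluded), sorts by
#' the chosen score descending, and emits one curve point per distinct
#' score value (tied scores form a single step). Each point reports the
#' confusion counts and derived rates at threshold `score >= threshold`.
#'
#' @param pairs scored pair table (from [aggregate_pair_scores()]), with
#'   columns `a`, `b` and the score column.
#' @param gold a `gold_standard`.
#' @param score_key column to sweep: one of `"s_sim"`, `"s_rank"`,
#'   `"s_con"`, `"s_total"`, or any other numeric column; composite keys
#'   `"s_sim+s_rank"` and `"s_sim+s_con"` are recognized and summed.
#' @param beta F-beta parameter carried on each point.
#' @return object of class `score_curve`: data frame with columns
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, `precision`,
#'   `recall`, `f_beta`; the trapezoidal ROC AUC is attached as attribute
#'   `auc`, and the evaluated set sizes as `n_pos` / `n_neg`.
#' @export
score_curves <- function(pairs, gold, score_key = "s_total", beta = 0.5) {
  stopifnot(inherits(gold, "gold_standard"))
  score <- curve_score_vector(pairs, score_key)
  keys <- pair_key(pairs$a, pairs$b)
  lab <- ifelse(keys %in% gold$positives, 1L,
                ifelse(keys %in% gold$negatives, 0L, NA_integer_))
  keep <- !is.na(lab)
  if (!any(keep)) stop("no scored pair is present in the gold standard")
  score <- score[keep]; lab <- lab[keep]
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("gold-standard overlap must contain both positives and negatives")
  }
  ord <- order(-score)
  score <- score[ord]; lab <- lab[ord]
  cum_tp <- cumsum(lab)
  cum_fp <- cumsum(1L - lab)
  last <- which(!duplicated(score, fromLast = TRUE))  # end of each tie group
  thr <- score[last]
  tp <- cum_tp[last]; fp <- cum_fp[last]
  fn <- n_pos - tp; tn <- n_neg - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- tp / n_pos
  out <- data.frame(threshold = thr, tp = tp, fp = fp, tn = tn, fn = fn,
                    tpr = tp / n_pos, fpr = fp / n_neg,
                    precision = precision, recall = recall,
                    f_beta = f_beta(ifelse(is.na(precision), 0, precision),
                                    recall, beta))
  rownames(out) <- NULL
  # trapezoid over (0,0) -> curve points -> (1,1)
  x <- c(0, out$fpr, 1); y <- c(0, out$tpr, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  attr(out, "auc") <- auc
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "score_key") <- score_key
  class(out) <- c("score_curve", "data.frame")
  out
}

# resolve a score key, allowing "s_sim+s_rank"-style composites
curve_score_vector <- function(pairs, score_key) {
  parts <- trimws(strsplit(score_key, "+", fixed = TRUE)[[1L]])
  missing <- setdiff(parts, colnames(pairs))
  if (length(missing) > 0L) {
    stop("score column(s) not found: ", paste(missing, collapse = ", "))
  }
  Reduce(`+`, lapply(parts, function(p) pairs[[p]]))
}

#' @rdname score_curves
#' @param curve a `score_curve`.
#' @export
curve_auc <- function(curve) {
  attr(curve, "auc")
}

#' Pick the score threshold maximizing F-beta
#'
#' Sweeps the curve and returns the threshold with the highest F-beta;
#' ties are resolved toward the smallest threshold (the most inclusive
#' prediction set at equal F).
#'
#' @param curve a `score_curve` from [score_curves()].
#' @return list with `threshold` and `f_value`.
#' @export
select_threshold <- function(curve) {
  if (nrow(curve) == 0L) stop("empty curve")
  best <- max(curve$f_beta)
  cand <- curve$threshold[curve$f_beta == best]
  list(threshold = min(cand), f_value = best)
}

#' Distribution of orthologous interactions over Srank bins
#'
#' Among candidates that are known ortholog-pair interactions, computes
#' the fraction falling in each normalized-rank bin, plus the cumulative
#' fractions at Srank >= 0.9 and >= 0.5 (the summary statistics used to
#' show that top-ranked candidates are enriched for orthologous
#' interactions).
#'
#' @param ranked ranked candidate table (needs `a_prime`, `b_prime`,
#'   `s_rank`) or a per-pair table (`a`, `b`, `s_rank`).
#' @param orthologs data frame of ortholog pairs (`a`, `b`).
#' @param breaks bin boundaries on \[0, 1\] (default width 0.1).
#' @return list with `bins` (data frame: `lower`, `upper`, `n`,
#'   `fraction`), `frac_ge_0.9`, `frac_ge_0.5`, `n_ortholog`.
#' @export
ortholog_enrichment <- function(ranked, orthologs,
                                breaks = seq(0, 1, by = 0.1)) {
  if (nrow(orthologs) == 0L) stop("empty ortholog set")
  okeys <- unique(pair_key(orthologs$a, orthologs$b))
  if ("a_prime" %in% colnames(ranked)) {
    keys <- pair_key(ranked$a_prime, ranked$b_prime)
  } else {
    keys <- pair_key(ranked$a, ranked$b)
  }
  is_orth <- keys %in% okeys
  sr <- ranked$s_rank[is_orth]
  n <- length(sr)
  if (n == 0L) {
    warning("no orthologous interaction among the candidates")
  }
  lower <- utils::head(breaks, -1); upper <- utils::tail(breaks, -1)
  cnt <- vapply(seq_along(lower), function(i) {
    hi_ok <- if (i == length(lower)) sr <= upper[i] else sr < upper[i]
    sum(sr >= lower[i] & hi_ok)
  }, 1L)
  bins <- data.frame(lower = lower, upper = upper, n = cnt,
                     fraction = if (n > 0) cnt / n else rep(0, length(cnt)))
  list(bins = bins,
       frac_ge_0.9 = if (n > 0) sum(sr >= 0.9) / n else 0,
       frac_ge_0.5 = if (n > 0) sum(sr >= 0.5) / n else 0,
       n_ortholog = n)
}
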