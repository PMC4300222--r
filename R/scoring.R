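#' Normalized joint sequence similarity (Ssim)
#'
#' Because the best attainable BLAST E-value depends on protein length, the
#' joint similarity of a candidate is normalized by the self-alignment
#' E-values of the template proteins:
#'
#' \deqn{S_{sim} = \frac{(-\log_{10} E_{A'}) (-\log_{10} E_{B'})}
#'                      {(-\log_{10} E_{A}) (-\log_{10} E_{B})}}
#'
#' where \eqn{E_{A'}} is the E-value of template protein A aligned to the
#' candidate member A', and \eqn{E_A} is the E-value of A aligned to
#' itself. The result is clamped to \[0, 1\]: floating-point artifacts in
#' upstream searches can make a cross-alignment marginally stronger than
#' the self-alignment.
#'
#' @param e_a_prime,e_b_prime E-values of the template-to-candidate
#'   alignments (vectorized).
#' @param e_a_self,e_b_self self-alignment E-values of the two template
#'   proteins; must be < 1.
#' @param floor E-value floor applied before logs.
#' @return Ssim in \[0, 1\].
#' @examples
#' compute_ssim(4e-49, 4e-49, 3e-68, 3e-68)  # ~0.514
#' @export
compute_ssim <- function(e_a_prime, e_b_prime, e_a_self, e_b_self,
                         floor = 1e-200) {
  if (any(e_a_self >= 1) || any(e_b_self >= 1)) {
    stop("self-alignment E-value >= 1: Ssim normalization undefined")
  }
  num <- neglog10_evalue(e_a_prime, floor) * neglog10_evalue(e_b_prime, floor)
  den <- neglog10_evalue(e_a_self, floor) * neglog10_evalue(e_b_self, floor)
  pmin(pmax(num / den, 0), 1)
}

#' Joint sequence identity of a candidate pair
#'
#' Combines the two members' sequence identities into one value, by
#' default as a geometric mean (consistent with the joint E-value, which
#' is the geometric mean of the member E-values); `method = "product"`
#' uses the plain product instead. Both are monotone in each argument, so
#' the choice never changes a ranking.
#'
#' @param si1,si2 sequence identities as fractions in \[0, 1\].
#' @param method `"geometric"` (default) or `"product"`.
#' @return joint identity in \[0, 1\].
#' @export
joint_si <- function(si1, si2, method = c("geometric", "product")) {
  method <- match.arg(method)
  stopifnot(all(si1 >= 0 & si1 <= 1), all(si2 >= 0 & si2 <= 1))
  if (method == "geometric") sqrt(si1 * si2) else si1 * si2
}

#' Rank candidates within each template and compute Srank
#'
#' Candidates of one template are sorted by similarity (`s_sim`)
#' descending; ties are broken by joint sequence identity descending, then
#' by canonical pair id ascending so the ordering is total and the
#' resulting ordinal ranks are strict. The normalized rank score is
#'
#' \deqn{S_{rank} = 1 - \frac{\log r}{\log r_{max}}}
#'
#' where r is the candidate's rank and r_max the number of candidates of
#' its template; the top-ranked candidate scores 1, the last scores 0, and
#' a template with a single candidate scores 1. The score is independent
#' of the logarithm base.
#'
#' @param candidates data frame from [enumerate_candidates()].
#' @param floor E-value floor for the similarity computation.
#' @return the input with columns `s_sim`, `rank`, `r_max`, `s_rank`
#'   added, ordered by template then rank.
#' @export
rank_candidates <- function(candidates, floor = 1e-200) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$s_sim <- numeric(0); out$rank <- integer(0)
    out$r_max <- integer(0); out$s_rank <- numeric(0)
    return(out)
  }
  candidates$s_sim <- compute_ssim(candidates$e_a_prime,
                                   candidates$e_b_prime,
                                   candidates$e_a_self,
                                   candidates$e_b_self, floor = floor)
  tmpl <- paste(candidates$source_org, candidates$template_a,
                candidates$template_b, sep = "|")
  pair <- paste(candidates$a_prime, candidates$b_prime, sep = "|")
  ord <- order(tmpl, -candidates$s_sim, -candidates$joint_si, pair)
  candidates <- candidates[ord, , drop = FALSE]
  tmpl <- tmpl[ord]
  r <- stats::ave(seq_along(tmpl), tmpl, FUN = seq_along)
  rmax <- stats::ave(seq_along(tmpl), tmpl, FUN = length)
  candidates$rank <- as.integer(r)
  candidates$r_max <- as.integer(rmax)
  candidates$s_rank <- ifelse(candidates$r_max == 1L, 1,
                              1 - log(candidates$rank) /
                                log(candidates$r_max))
  rownames(candidates) <- NULL
  candidates
}

#' Conservation score (Scon) of a candidate pair
#'
#' The conservation score of a candidate pair is the sum of the normalized
#' evolutionary distances of the source organisms from which it can be
#' derived; an organism that does not support the pair contributes 0.
#' With two sources at normalized distances 0.765 and 0.235, a pair
#' supported by both scores 1, by the first only 0.765, by the second only
#' 0.235.
#'
#' @param supporting_sources character vector of source organism codes
#'   supporting the pair (possibly empty).
#' @param config a `distance_config`.
#' @return Scon in \[0, 1\].
#' @export
compute_scon <- function(supporting_sources, config) {
  stopifnot(inherits(config, "distance_config"))
  supporting_sources <- unique(supporting_sources)
  unknown <- setdiff(supporting_sources, names(config$distances))
  if (length(unknown) > 0L) {
    stop("organism(s) not in distance config: ",
         paste(unknown, collapse = ", "))
  }
  if (length(supporting_sources) == 0L) return(0)
  sum(config$distances[supporting_sources])
}

#' Aggregate candidate scores per target pair
#'
#' Candidates are scored per template, but the network is built per target
#' pair. For each canonical target pair: the supporting source organisms
#' are the union over all its templates (feeding Scon); Ssim and Srank are
#' taken from the best-supporting template (the one maximizing
#' `w1*Ssim + w2*Srank`); and the total score is
#' `S = w1*Ssim + w2*Srank + w3*Scon`. With the default unit weights each
#' component lies in \[0, 1\] and S in \[0, 3\].
#'
#' @param ranked ranked candidates from [rank_candidates()].
#' @param config a `distance_config` for Scon.
#' @param weights numeric length-3 vector `(w1, w2, w3)`; default
#'   `c(1, 1, 1)`.
#' @return data frame with one row per target pair: `a`, `b`, `s_sim`,
#'   `s_rank`, `s_con`, `s_total`, `n_templates`, `sources`
#'   (comma-separated), and provenance of the chosen template
#'   (`template_a`, `template_b`, `template_org`).
#' @export
aggregate_pair_scores <- function(ranked, config, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, inherits(config, "distance_config"))
  if (nrow(ranked) == 0L) {
    return(data.frame(a = character(), b = character(), s_sim = numeric(),
                      s_rank = numeric(), s_con = numeric(),
                      s_total = numeric(), n_templates = integer(),
                      sources = character(), template_a = character(),
                      template_b = character(), template_org = character(),
                      stringsAsFactors = FALSE))
  }
  pair <- paste(ranked$a_prime, ranked$b_prime, sep = "|")
  partial <- weights[1] * ranked$s_sim + weights[2] * ranked$s_rank
  # best template first within each pair, deterministic tie-break on
  # template id so provenance is reproducible
  tkey <- paste(ranked$source_org, ranked$template_a, ranked$template_b,
                sep = "|")
  ord <- order(pair, -partial, tkey)
  ranked <- ranked[ord, , drop = FALSE]
  pair <- pair[ord]; partial <- partial[ord]
  first <- !duplicated(pair)
  sources <- vapply(split(ranked$source_org, pair), function(s) {
    paste(sort(unique(s)), collapse = ",")
  }, "")
  ntmpl <- vapply(split(tkey, pair), function(t) length(unique(t)), 1L)
  best <- ranked[first, , drop = FALSE]
  key <- pair[first]
  s_con <- vapply(strsplit(sources[key], ","), compute_scon, 0,
                  config = config)
  out <- data.frame(
    a = best$a_prime, b = best$b_prime,
    s_sim = best$s_sim, s_rank = best$s_rank, s_con = s_con,
    s_total = weights[1] * best$s_sim + weights[2] * best$s_rank +
      weights[3] * s_con,
    n_templates = unname(ntmpl[key]),
    sources = unname(sources[key]),
    template_a = best$template_a, template_b = best$template_b,
    template_org = best$source_org,
    stringsAsFactors = FALSE)
  out <- out[order(-out$s_total, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select predicted PPIs by score threshold
#'
#' Keeps pairs whose total score meets the threshold (inclusive:
#' `s_total >= s_min`), sorted by score descending. The default 2.3 is the
#' threshold at which the F0.5 measure peaks on the yeast benchmark.
#'
#' @param pairs scored pair table from [aggregate_pair_scores()].
#' @param s_min minimum total score (default 2.3).
#' @return the surviving rows, score-descending.
#' @export
filter_predicted <- function(pairs, s_min = 2.3) {
  out <- pairs[pairs$s_total >= s_min, , drop = FALSE]
  out <- out[order(-out$s_total, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidates end to end
#'
#' Convenience wrapper: rank candidates per template, aggregate per target
#' pair, and (optionally) filter by the score threshold.
#'
#' @inheritParams aggregate_pair_scores
#' @param candidates raw candidates from [enumerate_candidates()] (possibly
#'   concatenated over several source organisms).
#' @param s_min score threshold passed to [filter_predicted()], or `NULL`
#'   to return all scored pairs.
#' @param mode `"generalized"` (default) keeps all candidates;
#'   `"interolog"` keeps only the rank-1 candidate per template before
#'   aggregation.
#' @return list with `ranked` (per-candidate table), `pairs` (per-pair
#'   scores) and `predicted` (thresholded pairs, `NULL` if `s_min` is).
#' @export
score_candidates <- function(candidates, config, weights = c(1, 1, 1),
                             s_min = 2.3,
                             mode = c("generalized", "interolog")) {
  mode <- match.arg(mode)
  ranked <- rank_candidates(candidates)
  if (mode == "interolog") ranked <- interolog_mode_filter(ranked)
  pairs <- aggregate_pair_scores(ranked, config, weights)
  predicted <- if (is.null(s_min)) NULL else filter_predicted(pairs, s_min)
  list(ranked = ranked, pairs = pairs, predicted = predicted)
}
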