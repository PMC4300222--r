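#' Joint E-value of a candidate pair
#'
#' The joint E-value (JE) of a candidate pair is the geometric mean of the
#' two member proteins' homology E-values, computed in log space:
#' `10^((log10 e1 + log10 e2) / 2)`. Zero E-values (BLAST reports 0 for
#' alignments beyond its printable range) are clamped to `floor` before
#' taking logs so the result stays finite.
#'
#' @param e1,e2 non-negative E-values (vectorized).
#' @param floor E-value floor applied before the logarithm.
#' @return the joint E-value(s).
#' @examples
#' joint_evalue(1e-40, 1e-60)   # 1e-50
#' joint_evalue(0, 1e-10)       # 1e-105 under the default floor
#' @export
joint_evalue <- function(e1, e2, floor = 1e-200) {
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE)) {
    stop("E-values must be non-negative")
  }
  10^((log10(pmax(e1, floor)) + log10(pmax(e2, floor))) / 2)
}

#' Enumerate interolog candidates by generalized mapping
#'
#' For each template PPI A-B in a source organism, candidate pairs A'-B' in
#' the target organism are the cross product of the homologs of A and the
#' homologs of B, where each member hit passes the per-protein homolog
#' E-value threshold and the pair passes the joint E-value threshold.
#' Both orientations (A' from A, B' from B) and (A' from B, B' from A) are
#' generated; the candidate pair is canonicalized and, per (template,
#' pair), the orientation with the smaller joint E-value is kept.
#'
#' Templates whose proteins are absent from the homology index, or lack a
#' self-alignment E-value (required later to normalize similarity), are
#' skipped with a warning: the similarity score is undefined without the
#' self E-value, and no fallback is attempted.
#'
#' @param templates data frame of template PPIs as returned by
#'   [read_ppi_table()] (columns `a`, `b`, `organism`).
#' @param hom a `homology_index` for the same source organism.
#' @param homolog_evalue_max per-protein homolog threshold (default 1e-10).
#' @param joint_evalue_max joint E-value threshold (default 1e-40).
#' @param floor E-value floor (see [joint_evalue()]).
#' @return data frame of candidate assignments, one row per
#'   (template, canonical target pair): columns `a_prime`, `b_prime`
#'   (canonical order), `template_a`, `template_b`, `source_org`,
#'   `e_a_prime`, `e_b_prime`, `si_a`, `si_b`, `e_a_self`, `e_b_self`,
#'   `joint_evalue`, `joint_si`.
#' @export
enumerate_candidates <- function(templates, hom,
                                 homolog_evalue_max = 1e-10,
                                 joint_evalue_max = 1e-40,
                                 floor = 1e-200) {
  stopifnot(inherits(hom, "homology_index"),
            homolog_evalue_max > 0, joint_evalue_max > 0)
  hits <- hom$hits[hom$hits$evalue <= homolog_evalue_max, , drop = FALSE]
  by_query <- split(seq_len(nrow(hits)), hits$query)
  selfs <- hom$self_evalues

  n_skipped <- 0L
  out <- vector("list", nrow(templates))
  for (i in seq_len(nrow(templates))) {
    ta <- templates$a[i]; tb <- templates$b[i]
    if (is.null(by_query[[ta]]) || is.null(by_query[[tb]]) ||
        is.na(selfs[ta]) || is.na(selfs[tb]) ||
        !(ta %in% names(selfs)) || !(tb %in% names(selfs))) {
      n_skipped <- n_skipped + 1L
      next
    }
    ha <- hits[by_query[[ta]], , drop = FALSE]
    hb <- hits[by_query[[tb]], , drop = FALSE]
    # cross product of homolog sets, in the A->A', B->B' orientation;
    # the swapped orientation is covered because for A != B the roles of
    # ha and hb are exchanged below, and for A == B ha == hb already.
    grid <- expand.grid(ia = seq_len(nrow(ha)), ib = seq_len(nrow(hb)))
    cand <- data.frame(
      ap = ha$subject[grid$ia], bp = hb$subject[grid$ib],
      e_from_a = ha$evalue[grid$ia], e_from_b = hb$evalue[grid$ib],
      si_from_a = ha$identity[grid$ia], si_from_b = hb$identity[grid$ib],
      stringsAsFactors = FALSE)
    if (ta != tb) {
      swapped <- data.frame(
        ap = hb$subject[grid$ib], bp = ha$subject[grid$ia],
        e_from_a = hb$evalue[grid$ib], e_from_b = ha$evalue[grid$ia],
        si_from_a = hb$identity[grid$ib], si_from_b = ha$identity[grid$ia],
        stringsAsFactors = FALSE)
      cand <- rbind(cand, swapped)
    }
    cand$je <- joint_evalue(cand$e_from_a, cand$e_from_b, floor = floor)
    cand <- cand[cand$je <= joint_evalue_max, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cp <- canonical_pair(cand$ap, cand$bp)
    cand$pair <- paste(cp$a, cp$b, sep = "|")
    # orientation dedup: keep the smaller joint E-value per canonical pair
    cand <- cand[order(cand$je), , drop = FALSE]
    cand <- cand[!duplicated(cand$pair), , drop = FALSE]
    cp <- canonical_pair(cand$ap, cand$bp)
    out[[i]] <- data.frame(
      a_prime = cp$a, b_prime = cp$b,
      template_a = ta, template_b = tb,
      source_org = templates$organism[i],
      e_a_prime = cand$e_from_a, e_b_prime = cand$e_from_b,
      si_a = cand$si_from_a, si_b = cand$si_from_b,
      e_a_self = unname(selfs[ta]), e_b_self = unname(selfs[tb]),
      joint_evalue = cand$je,
      joint_si = joint_si(cand$si_from_a, cand$si_from_b),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " template(s) skipped: protein missing from ",
            "homology index or without self E-value")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(a_prime = character(), b_prime = character(),
                      template_a = character(), template_b = character(),
                      source_org = character(), e_a_prime = numeric(),
                      e_b_prime = numeric(), si_a = numeric(),
                      si_b = numeric(), e_a_self = numeric(),
                      e_b_self = numeric(), joint_evalue = numeric(),
                      joint_si = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Keep only the top-ranked candidate per template (interolog mode)
#'
#' The classical interolog method keeps only the best candidate of each
#' template, where "best" is rank 1 under the similarity ranking used for
#' the rank score (similarity descending, then joint sequence identity,
#' then canonical pair id). Input candidates must already carry ranks from
#' [rank_candidates()].
#'
#' @param ranked data frame of ranked candidates (column `rank` present).
#' @return the rank-1 rows.
#' @export
interolog_mode_filter <- function(ranked) {
  stopifnot("rank" %in% colnames(ranked))
  out <- ranked[ranked$rank == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
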