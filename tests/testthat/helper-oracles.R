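# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (plain loops, no package internals) so
# that agreement with the implementation is informative.

# --- candidate enumeration: explicit double loop with sqrt(e1*e2) filter
oracle_enumerate <- function(templates, hits, selfs,
                             max_e = 1e-10, max_je = 1e-40,
                             floor = 1e-200) {
  out <- list()
  for (i in seq_len(nrow(templates))) {
    ta <- templates$a[i]; tb <- templates$b[i]
    if (!(ta %in% names(selfs)) || !(tb %in% names(selfs))) next
    ha <- hits[hits$query == ta & hits$evalue <= max_e, , drop = FALSE]
    hb <- hits[hits$query == tb & hits$evalue <= max_e, , drop = FALSE]
    if (nrow(ha) == 0 || nrow(hb) == 0) next
    best <- list()
    for (x in seq_len(nrow(ha))) for (y in seq_len(nrow(hb))) {
      for (orient in if (ta == tb) 1 else 1:2) {
        if (orient == 1) {
          e1 <- ha$evalue[x]; e2 <- hb$evalue[y]
          p1 <- ha$subject[x]; p2 <- hb$subject[y]
        } else {
          e1 <- hb$evalue[y]; e2 <- ha$evalue[x]
          p1 <- hb$subject[y]; p2 <- ha$subject[x]
        }
        je <- sqrt(max(e1, floor) * max(e2, floor))
        if (je > max_je) next
        key <- paste(sort(c(p1, p2)), collapse = "|")
        if (is.null(best[[key]]) || je < best[[key]]) best[[key]] <- je
      }
    }
    for (key in names(best)) {
      out[[paste(ta, tb, key, sep = "::")]] <- best[[key]]
    }
  }
  out
}

# --- ROC AUC by exhaustive threshold sweep and trapezoid
oracle_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  tpr <- c(0, vapply(thr, function(t) sum(labels == 1 & scores >= t), 1) /
             npos, 1)
  fpr <- c(0, vapply(thr, function(t) sum(labels == 0 & scores >= t), 1) /
             nneg, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# --- best F-beta threshold by exhaustive sweep
oracle_best_fbeta <- function(scores, labels, beta = 0.5) {
  thr <- sort(unique(scores), decreasing = TRUE)
  f <- vapply(thr, function(t) {
    tp <- sum(labels == 1 & scores >= t)
    fp <- sum(labels == 0 & scores >= t)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / sum(labels == 1)
    if (p == 0 && r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
  }, 1)
  best <- max(f)
  list(threshold = min(thr[f == best]), f_value = best)
}

# --- RSS from first principles by exhaustive path enumeration on a
#     child->parent edge table (recursive, no graph library)
oracle_rss <- function(terms, edges, ti, tj) {
  parents_of <- function(t) edges$parent[edges$child == t]
  children_of <- function(t) edges$child[edges$parent == t]
  longest_from_root <- function(t) {
    p <- parents_of(t)
    if (length(p) == 0) 0 else 1 + max(vapply(p, longest_from_root, 1))
  }
  min_to_leaf <- function(t) {
    ch <- children_of(t)
    if (length(ch) == 0) 0 else 1 + min(vapply(ch, min_to_leaf, 1))
  }
  shortest_up <- function(from, to) {
    if (from == to) return(0)
    p <- parents_of(from)
    if (length(p) == 0) return(Inf)
    1 + min(vapply(p, shortest_up, 1, to = to))
  }
  ancestors <- function(t) {
    res <- t
    for (p in parents_of(t)) res <- union(res, ancestors(p))
    res
  }
  maxD <- max(vapply(terms, longest_from_root, 1))
  common <- intersect(ancestors(ti), ancestors(tj))
  dep <- vapply(common, longest_from_root, 1)
  gam <- vapply(common, function(a) {
    shortest_up(ti, a) + shortest_up(tj, a)
  }, 1)
  ord <- order(-dep, gam, common)
  alpha <- dep[ord[1]]
  gamma <- gam[ord[1]]
  beta <- max(min_to_leaf(ti), min_to_leaf(tj))
  spec <- if (alpha == 0 && beta == 0) 0 else alpha / (alpha + beta)
  unname(maxD / (maxD + gamma) * spec)
}

# --- one-layer extension by scanning an edge data frame
oracle_extension <- function(members, edge_df) {
  nb <- unique(c(edge_df$b[edge_df$a %in% members],
                 edge_df$a[edge_df$b %in% members]))
  ext <- union(members, nb)
  n_edges <- sum(edge_df$a %in% ext & edge_df$b %in% ext &
                   edge_df$a != edge_df$b)
  list(members = sort(ext), n_edges = n_edges)
}

# --- shared small fixture: a study plus its enumerated candidates
make_scored_study <- function(seed, ...) {
  st <- simulate_interolog_study(seed = seed, ...)
  cand <- do.call(rbind, lapply(names(st$templates), function(o) {
    suppressWarnings(enumerate_candidates(st$templates[[o]],
                                          st$homology[[o]]))
  }))
  res <- score_candidates(cand, st$distances)
  list(study = st, candidates = cand, result = res)
}

# scored, labeled pair set with partly separated class scores
labeled_fixture <- function(seed, n = 200) {
  set.seed(seed)
  lab <- rbinom(n, 1, 0.4)
  score <- lab * rnorm(n, 1.8, 0.8) + (1 - lab) * rnorm(n, 1, 0.8)
  pairs <- data.frame(a = sprintf("u%03d", 1:n),
                      b = sprintf("v%03d", 1:n),
                      s_total = score, stringsAsFactors = FALSE)
  gs <- gold_standard(pairs[lab == 1, c("a", "b")],
                      pairs[lab == 0, c("a", "b")])
  list(pairs = pairs, gold = gs, score = score, lab = lab)
}

# random small homology fixture for enumeration oracles
random_mapping_instance <- function(seed, n_src = 4, n_tgt = 12,
                                    hits_per_src = 6) {
  set.seed(seed)
  src <- paste0("S", seq_len(n_src))
  tgt <- paste0("X", seq_len(n_tgt))
  hits <- do.call(rbind, lapply(src, function(q) {
    data.frame(query = q,
               subject = sample(tgt, hits_per_src),
               identity = runif(hits_per_src, 0.2, 1),
               evalue = 10^-runif(hits_per_src, 5, 80),
               stringsAsFactors = FALSE)
  }))
  selfs <- stats::setNames(10^-runif(n_src, 80, 120), src)
  pairs <- t(combn(src, 2))
  take <- sample(nrow(pairs), min(4, nrow(pairs)))
  templates <- data.frame(a = pairs[take, 1], b = pairs[take, 2],
                          organism = "org1", stringsAsFactors = FALSE)
  list(templates = templates, hits = hits, selfs = selfs)
}
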