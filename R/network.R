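#' Reconstruct a PPI network from predicted pairs
#'
#' Builds a simple undirected graph over all proteins incident to a
#' surviving edge. Duplicate pairs collapse to a single edge (keeping the
#' maximum score); self-pairs become loops, which are stored but excluded
#' from degree-distribution fitting.
#'
#' @param pairs data frame with columns `a`, `b` and optionally `s_total`.
#' @return an igraph object with edge attribute `score` (if scores were
#'   supplied).
#' @export
reconstruct_network <- function(pairs) {
  cp <- canonical_pair(pairs$a, pairs$b)
  df <- data.frame(a = cp$a, b = cp$b, stringsAsFactors = FALSE)
  if ("s_total" %in% colnames(pairs)) df$score <- pairs$s_total
  ord <- if ("score" %in% colnames(df)) order(-df$score) else
    seq_len(nrow(df))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$a, df$b, sep = "|")), , drop = FALSE]
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Power-law degree exponent by log-binned least squares
#'
#' Estimates the exponent gamma of a scale-free degree distribution
#' `P(k) ~ k^-gamma` the way it is read off a log-log plot: node degrees
#' (self-loops excluded, zero-degree nodes dropped) are binned into
#' logarithmic bins `[2^j, 2^(j+1))`; per bin the empirical probability
#' mass is divided by the number of integer degrees in the bin (a bin
#' density) and placed at the geometric midpoint; `log10 P` is regressed
#' on `log10 k` over non-empty bins. Gamma is minus the slope.
#'
#' @param network an igraph object.
#' @param min_distinct minimum number of distinct degrees required
#'   (default 10); fewer is an error, the fit would be meaningless.
#' @return list with `gamma`, `intercept`, `r_squared`, and `fit_data`
#'   (the binned points used).
#' @export
degree_exponent <- function(network, min_distinct = 10) {
  g <- igraph::simplify(network, remove.multiple = FALSE,
                        remove.loops = TRUE)
  k <- igraph::degree(g)
  k <- k[k > 0]
  if (length(unique(k)) < min_distinct) {
    stop("need at least ", min_distinct,
         " distinct degrees for a power-law fit (have ",
         length(unique(k)), ")")
  }
  n <- length(k)
  jmax <- ceiling(log2(max(k) + 1))
  lo <- 2^(0:(jmax - 1)); hi <- 2^(1:jmax)
  pts <- lapply(seq_along(lo), function(j) {
    in_bin <- k >= lo[j] & k < hi[j]
    if (!any(in_bin)) return(NULL)
    # cap the bin at the observed maximum so a mostly-empty last bin
    # does not dilute its density
    hi_eff <- min(hi[j], max(k) + 1)
    width <- hi_eff - lo[j]            # number of integer degrees in bin
    data.frame(log_k = log10(sqrt(lo[j] * (hi_eff - 1))),
               log_p = log10(sum(in_bin) / n / width))
  })
  pts <- do.call(rbind, pts)
  fit <- stats::lm(log_p ~ log_k, data = pts)
  list(gamma = -unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       fit_data = pts)
}

# edges of `network` with both endpoints in `members` (loops excluded)
.induced_edge_count <- function(members, network) {
  present <- intersect(members, igraph::V(network)$name)
  if (length(present) < 2L) return(0L)
  sub <- igraph::induced_subgraph(network, present)
  sub <- igraph::simplify(sub, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::ecount(sub)
}

#' Module connectivity Ct = m / C(n, 2)
#'
#' For a module with `n` member proteins and `m` network edges among
#' them, connectivity is the fraction of possible member-member
#' interactions realized. `n` counts ALL module members, whether or not
#' they appear in the network: members the method failed to recover
#' depress connectivity, which keeps networks of different coverage
#' comparable. A 4-member module with 4 internal edges has
#' `Ct = 4/6 = 0.67`; with 3 edges, `0.5`.
#'
#' @param members character vector of module member proteins (or a one-row
#'   slice of a module table with a `members` list-column).
#' @param network an igraph object.
#' @return Ct in \[0, 1\], or `NA` (with a warning) when `n < 2`.
#' @export
module_connectivity <- function(members, network) {
  members <- unique(unlist(members))
  n <- length(members)
  if (n < 2L) {
    warning("module with fewer than 2 members: connectivity undefined")
    return(NA_real_)
  }
  m <- .induced_edge_count(members, network)
  m / choose(n, 2)
}

#' One-layer-extended module
#'
#' Extends a module by the direct network neighbors of its members: the
#' extended member set is `P  U  P'` where `P'` are the interacting
#' partners of the proteins in `P`, and the extended edge set is every
#' network edge within the enlarged set.
#'
#' @inheritParams module_connectivity
#' @return list with `members` (extended set) and `n_edges` (edges of the
#'   network within it).
#' @export
one_layer_extension <- function(members, network) {
  members <- unique(unlist(members))
  present <- intersect(members, igraph::V(network)$name)
  nb <- if (length(present) > 0L) {
    unique(unlist(lapply(igraph::adjacent_vertices(network, present),
                         names)))
  } else character()
  ext <- union(members, nb)
  list(members = ext, n_edges = .induced_edge_count(ext, network))
}

#' Module connectivity ratio
#'
#' The ratio `C_M / C_M-extended` between the connectivity of a module
#' and that of its one-layer extension. Values above 1 indicate high
#' cohesion and low coupling: the module is denser than its network
#' neighborhood.
#'
#' @inheritParams module_connectivity
#' @return the ratio, or `NA` (with a warning) when either connectivity
#'   is undefined or the extended connectivity is 0.
#' @export
connectivity_ratio <- function(members, network) {
  members <- unique(unlist(members))
  cm <- suppressWarnings(module_connectivity(members, network))
  ext <- one_layer_extension(members, network)
  cext <- suppressWarnings(module_connectivity(ext$members, network))
  if (is.na(cm) || is.na(cext) || cext == 0) {
    warning("connectivity ratio undefined for this module")
    return(NA_real_)
  }
  cm / cext
}

#' Connectivity ratios for a batch of modules
#'
#' @param modules module table from [read_modules()] (columns `module_id`,
#'   `kind`, list-column `members`).
#' @param network an igraph object.
#' @return list with `table` (per-module: `module_id`, `kind`, `n`, `m`,
#'   `ct`, `ct_extended`, `ratio`) and `mean_ratio`, the unweighted
#'   arithmetic mean over modules with a defined ratio.
#' @export
average_connectivity_ratio <- function(modules, network) {
  rows <- lapply(seq_len(nrow(modules)), function(i) {
    mem <- unique(unlist(modules$members[[i]]))
    n <- length(mem)
    ct <- suppressWarnings(module_connectivity(mem, network))
    ext <- one_layer_extension(mem, network)
    cext <- suppressWarnings(module_connectivity(ext$members, network))
    ratio <- if (is.na(ct) || is.na(cext) || cext == 0) NA_real_ else
      ct / cext
    data.frame(module_id = modules$module_id[i], kind = modules$kind[i],
               n = n, m = .induced_edge_count(mem, network),
               ct = ct, ct_extended = cext, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$ratio)
  if (!any(ok)) warning("no module has a defined connectivity ratio")
  list(table = tab,
       mean_ratio = if (any(ok)) mean(tab$ratio[ok]) else NA_real_)
}
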