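#' Read a Gene Ontology OBO file (format 1.2 subset)
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' lines; obsolete terms are dropped. Only `is_a` edges are used: they
#' form the minimal defensible DAG for specificity measures (`part_of`
#' and other relations are ignored).
#'
#' @param path path to the OBO file.
#' @param namespace optional namespace filter (e.g.
#'   `"biological_process"`); edges to terms outside the namespace are
#'   dropped with the terms.
#' @return an `ontology` object (see [build_ontology()]).
#' @export
read_obo <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanzas in '", path, "'")
  bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(); names_ <- character(); ns <- character()
  parents <- list()
  for (k in seq_along(term_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ": "), chunk, value = TRUE)
      if (length(m) == 0L) NA_character_ else
        sub(paste0("^", key, ": "), "", m[1L])
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    isa <- grep("^is_a: ", chunk, value = TRUE)
    isa <- sub("^is_a: ", "", isa)
    isa <- sub("\\s*!.*$", "", isa)          # strip trailing "! name"
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- trimws(isa)
  }
  if (!is.null(namespace)) {
    keep <- !is.na(ns) & ns == namespace
    ids <- ids[keep]; names_ <- names_[keep]; ns <- ns[keep]
    parents <- parents[ids]
    parents <- lapply(parents, function(p) intersect(p, ids))
  }
  edges <- do.call(rbind, lapply(ids, function(id) {
    p <- intersect(parents[[id]], ids)
    if (length(p) == 0L) return(NULL)
    data.frame(child = id, parent = p, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  build_ontology(ids, edges,
                 namespace = if (is.null(namespace)) NA_character_
                             else namespace,
                 term_names = stats::setNames(names_, ids))
}

#' Build an ontology DAG from terms and is_a edges
#'
#' The ontology must be a rooted DAG (exactly one term with no parent).
#' On construction the following are precomputed for every term:
#' `depth` -- the LONGEST path length (in edges) from the root, the
#' standard specificity convention for GO; and `dl` -- the MINIMUM path
#' length to any descendant leaf (0 for leaves). `max_depth` is the
#' maximum term depth, i.e. the depth of the deepest leaf.
#'
#' @param terms character vector of term ids.
#' @param edges data frame with columns `child`, `parent` (is_a links).
#' @param namespace optional namespace tag.
#' @param term_names optional named character vector of term names.
#' @return object of class `ontology`: list with `terms`, `graph`
#'   (igraph, edges child -> parent), `depth`, `dl`, `max_depth`,
#'   `namespace`, `root`.
#' @export
build_ontology <- function(terms, edges, namespace = NA_character_,
                           term_names = NULL) {
  terms <- unique(as.character(terms))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop("ontology is_a graph is not acyclic")
  outdeg <- igraph::degree(g, mode = "out")   # edges point child -> parent
  roots <- names(outdeg)[outdeg == 0]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root; found ",
         length(roots), " (", paste(utils::head(roots, 5), collapse = ", "),
         ")")
  }
  # longest path from root: DP over a topological order of parent->child
  topo <- names(igraph::topo_sort(g, mode = "in"))  # parents first
  depth <- stats::setNames(rep(-Inf, length(terms)), terms)
  depth[roots] <- 0
  adj_parents <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
  names(adj_parents) <- igraph::V(g)$name
  for (t in topo) {
    p <- names(adj_parents[[t]])
    if (length(p) > 0L) depth[t] <- max(depth[p]) + 1
  }
  if (any(!is.finite(depth))) stop("term(s) unreachable from the root")
  # min path to a descendant leaf: DP over reverse order (children first)
  adj_children <- igraph::adjacent_vertices(g, igraph::V(g), mode = "in")
  names(adj_children) <- igraph::V(g)$name
  dl <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (t in rev(topo)) {
    ch <- names(adj_children[[t]])
    dl[t] <- if (length(ch) == 0L) 0 else min(dl[ch]) + 1
  }
  out <- list(terms = terms, graph = g, depth = depth, dl = dl,
              max_depth = max(depth), namespace = namespace,
              root = roots,
              term_names = term_names)
  class(out) <- "ontology"
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", length(x$terms), "terms, root", x$root,
      ", max depth", x$max_depth,
      if (!is.na(x$namespace)) paste0(" [", x$namespace, "]"), "\n")
  invisible(x)
}

# ancestors of a term including itself (following child -> parent edges)
.ancestors <- function(onto, term) {
  names(igraph::subcomponent(onto$graph, term, mode = "out"))
}

#' Relative specificity similarity (RSS) of two GO terms
#'
#' \deqn{RSS(t_i, t_j) = \frac{maxD}{maxD + \gamma} \times
#'   \frac{\alpha}{\alpha + \beta}}
#'
#' where `maxD` is the maximum root-to-leaf depth of the ontology,
#' `alpha` the depth of the most recent common ancestor (MRCA) of the two
#' terms, `beta` the larger of the two terms' minimum distances to a
#' descendant leaf, and `gamma` the sum of the shortest-path distances
#' from the MRCA to each term. The MRCA is the common ancestor of maximal
#' depth; among equally deep candidates the one minimizing `gamma` is
#' taken (then term id), so the value is deterministic. When both terms
#' are the root (`alpha = beta = 0`) the similarity is defined as 0: the
#' root carries no specificity.
#'
#' @param onto an `ontology`.
#' @param t_i,t_j term ids present in the ontology.
#' @param components if `TRUE`, return a list with `rss`, `alpha`, `beta`,
#'   `gamma`, `mrca`, `max_depth` instead of the bare score.
#' @return RSS in \[0, 1\] (or the component list).
#' @examples
#' # maxD = 20, gamma = 3, alpha = 4, beta = 1  =>  (20/23) * (4/5) = 0.696
#' @export
rss <- function(onto, t_i, t_j, components = FALSE) {
  stopifnot(inherits(onto, "ontology"))
  missing <- setdiff(c(t_i, t_j), onto$terms)
  if (length(missing) > 0L) {
    stop("term(s) not in ontology: ", paste(missing, collapse = ", "))
  }
  anc_i <- .ancestors(onto, t_i)
  anc_j <- .ancestors(onto, t_j)
  common <- intersect(anc_i, anc_j)
  # shortest path (in edges, child -> parent direction) to each ancestor
  d_i <- igraph::distances(onto$graph, v = t_i, to = common, mode = "out")
  d_j <- igraph::distances(onto$graph, v = t_j, to = common, mode = "out")
  gam <- as.numeric(d_i[1, ]) + as.numeric(d_j[1, ])
  dep <- onto$depth[common]
  ord <- order(-dep, gam, common)
  mrca <- common[ord[1L]]
  alpha <- unname(dep[mrca])
  gamma <- gam[ord[1L]]
  beta <- max(onto$dl[t_i], onto$dl[t_j])
  spec <- if (alpha == 0 && beta == 0) 0 else alpha / (alpha + beta)
  val <- onto$max_depth / (onto$max_depth + gamma) * spec
  if (components) {
    list(rss = val, alpha = alpha, beta = unname(beta), gamma = gamma,
         mrca = mrca, max_depth = onto$max_depth)
  } else {
    val
  }
}

#' Read a GAF 2.x annotation file
#'
#' Keeps the DB object id (column 2), GO id (column 5) and aspect
#' (column 9: P, F, or C). Comment lines (`!`) are skipped.
#'
#' @param path path to the GAF file.
#' @return data frame with columns `protein`, `go_id`, `aspect`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  if (any(vapply(fields, length, 1L) < 9L)) {
    stop("GAF rows need >= 9 columns: '", path, "'")
  }
  out <- data.frame(protein = vapply(fields, `[[`, "", 2L),
                    go_id = vapply(fields, `[[`, "", 5L),
                    aspect = vapply(fields, `[[`, "", 9L),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Annotation list for one GO aspect
#'
#' @param gaf data frame from [read_gaf()].
#' @param aspect `"P"` (biological process) or `"C"` (cellular component)
#'   or `"F"`.
#' @param onto optional `ontology`; annotations to unknown terms dropped.
#' @return named list: protein -> character vector of term ids.
#' @export
gaf_annotations <- function(gaf, aspect, onto = NULL) {
  sub <- gaf[gaf$aspect == aspect, , drop = FALSE]
  if (!is.null(onto)) sub <- sub[sub$go_id %in% onto$terms, , drop = FALSE]
  split(sub$go_id, sub$protein)
}

#' Protein-level RSS
#'
#' The RSS of two proteins in one namespace is the maximum term-level RSS
#' over all pairs of their annotated terms (best-match aggregation).
#' Returns `NA` with a warning if either protein is unannotated.
#'
#' @param onto an `ontology` for one namespace.
#' @param annotations named list protein -> term ids (see
#'   [gaf_annotations()]).
#' @param p1,p2 protein ids.
#' @return RSS in \[0, 1\], or `NA_real_`.
#' @export
protein_rss <- function(onto, annotations, p1, p2) {
  t1 <- annotations[[p1]]; t2 <- annotations[[p2]]
  if (is.null(t1) || is.null(t2) || length(t1) == 0L || length(t2) == 0L) {
    warning("unannotated protein: ",
            paste(c(p1, p2)[c(is.null(t1) || length(t1) == 0L,
                              is.null(t2) || length(t2) == 0L)],
                  collapse = ", "))
    return(NA_real_)
  }
  best <- 0
  for (a in t1) for (b in t2) {
    v <- rss(onto, a, b)
    if (v > best) best <- v
  }
  best
}

#' Joint RSS of a protein pair
#'
#' Combines the biological-process and cellular-component RSS of a pair
#' into one functional-similarity value, by default as a geometric mean
#' (consistent with the joint E-value convention); `method = "product"`
#' uses the plain product.
#'
#' @param rss_bp,rss_cc RSS values in \[0, 1\].
#' @param method `"geometric"` (default) or `"product"`.
#' @return joint RSS in \[0, 1\].
#' @export
joint_rss <- function(rss_bp, rss_cc, method = c("geometric", "product")) {
  method <- match.arg(method)
  stopifnot(all(rss_bp >= 0 & rss_bp <= 1, na.rm = TRUE),
            all(rss_cc >= 0 & rss_cc <= 1, na.rm = TRUE))
  if (method == "geometric") sqrt(rss_bp * rss_cc) else rss_bp * rss_cc
}

#' Construct an RSS-based negative set
#'
#' Non-interacting pairs for benchmarking are defined as pairs that are
#' functionally dissimilar in BOTH namespaces: `RSS_BP < rss_max` and
#' `RSS_CC < rss_max` (strict), excluding known positives. Pairs with an
#' unannotated member are excluded (their RSS is undefined).
#'
#' @param universe character vector of proteins, or a data frame of
#'   candidate pairs with columns `a`, `b`. When a protein vector is
#'   given, all unordered pairs are considered.
#' @param ann_bp,ann_cc annotation lists for BP and CC.
#' @param onto_bp,onto_cc ontologies for the two namespaces.
#' @param positives data frame of known positive pairs (`a`, `b`).
#' @param rss_max exclusive upper bound on both RSS values (default 0.4).
#' @return data frame of negative pairs with columns `a`, `b`, `rss_bp`,
#'   `rss_cc`.
#' @export
build_negative_set <- function(universe, ann_bp, ann_cc, onto_bp, onto_cc,
                               positives = NULL, rss_max = 0.4) {
  if (is.data.frame(universe)) {
    cp <- canonical_pair(universe$a, universe$b)
    pairs <- unique(cp)
  } else {
    prot <- sort(unique(as.character(universe)))
    if (length(prot) < 2L) stop("need >= 2 proteins for a negative set")
    idx <- utils::combn(length(prot), 2L)
    pairs <- data.frame(a = prot[idx[1L, ]], b = prot[idx[2L, ]],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(positives) && nrow(positives) > 0L) {
    pos_keys <- pair_key(positives$a, positives$b)
    pairs <- pairs[!(pair_key(pairs$a, pairs$b) %in% pos_keys), ,
                   drop = FALSE]
  }
  annotated <- function(p, ann) {
    !vapply(ann[p], function(x) is.null(x) || length(x) == 0L, TRUE)
  }
  ok <- annotated(pairs$a, ann_bp) & annotated(pairs$b, ann_bp) &
    annotated(pairs$a, ann_cc) & annotated(pairs$b, ann_cc)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(a = character(), b = character(),
                      rss_bp = numeric(), rss_cc = numeric(),
                      stringsAsFactors = FALSE))
  }
  bp <- mapply(function(a, b) protein_rss(onto_bp, ann_bp, a, b),
               pairs$a, pairs$b)
  cc <- mapply(function(a, b) protein_rss(onto_cc, ann_cc, a, b),
               pairs$a, pairs$b)
  keep <- !is.na(bp) & !is.na(cc) & bp < rss_max & cc < rss_max
  out <- data.frame(a = pairs$a, b = pairs$b, rss_bp = unname(bp),
                    rss_cc = unname(cc), stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
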