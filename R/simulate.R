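#' Simulate a complete cross-species interolog study
#'
#' Generates every input the pipeline consumes, with planted structure so
#' that recovery can be checked: a target proteome with lognormal protein
#' lengths; for each of two source organisms, one source protein per
#' target protein (its ortholog) with a homolog family in the target
#' proteome; a true target interaction backbone whose templates exist in
#' one or both source organisms; and a gold standard whose negatives are
#' family cross-product pairs (the pairs generalized mapping actually
#' proposes) that are not true interactions.
#'
#' The homology model follows the empirical behavior of sequence search:
#' the alignment strength grows with query length and identity,
#' `-log10 E = scale * L * identity + noise`, truncated at the E-value
#' floor, so longer proteins and closer homologs get smaller E-values.
#' Self-alignments use identity 1 without noise. Exactly one designated
#' ortholog per source protein receives the family's smallest E-value.
#'
#' @param n_target_proteins size of the target proteome (default 200).
#' @param n_true_ppis number of true target interactions (default 120).
#' @param family_mean overall mean homolog family size under a geometric
#'   distribution (default 3); ignored when `family_size` is given.
#' @param p_ancient fraction of target proteins flagged as anciently
#'   conserved (default 0.5). Ancient proteins carry expanded paralog
#'   families (`ancient_family_factor` times the modern mean, default 3),
#'   and true interactions between ancient proteins are the ones
#'   preferentially templated in both source organisms -- mirroring the
#'   empirical pattern that interactions conserved across large
#'   evolutionary distances involve old, family-expanded proteins
#'   (kinases, zinc fingers), which is also where pure similarity ranking
#'   degrades.
#' @param ancient_family_factor family-size inflation for ancient
#'   proteins (default 3).
#' @param family_size optional fixed family size (every source protein
#'   gets exactly this many target homologs).
#' @param both_source_fraction fraction of true interactions templated in
#'   both source organisms (default 0.5); the rest are templated in one,
#'   chosen at random.
#' @param ortholog_fraction base probability that a source protein's
#'   target counterpart is a clean, designated ortholog receiving the
#'   family's smallest E-value (default 0.8, the order of one-to-one
#'   ortholog coverage between mammalian proteomes); the realized
#'   probability decays with family size as
#'   `ortholog_fraction^sqrt(family size)` because one-to-one orthology
#'   is rarer inside expanded families. Setting 1 guarantees designation
#'   everywhere. Non-designated counterparts are still in the homolog
#'   family but at paralog-grade identity, so their candidates are not
#'   guaranteed the top rank -- these are the hard positives that only
#'   conservation across source organisms can recover.
#' @param n_negatives gold-standard negatives to sample (default 400).
#' @param length_meanlog,length_sdlog lognormal parameters of protein
#'   length (defaults log(350) and 0.5, lengths clamped to \[60, 2000\]).
#' @param evalue_scale scale `s` in the E-value model (default 0.25).
#' @param evalue_noise_sd standard deviation of the noise on `-log10 E`
#'   (default 3).
#' @param ortholog_identity,paralog_identity identity ranges (uniform) for
#'   designated orthologs and other family members.
#' @param source_orgs named numeric vector: source organism codes mapped
#'   to raw evolutionary distances to the target (default
#'   `c(human = 0.765, fly = 0.235)`, already normalized).
#' @param source_coverage relative interaction-database coverage of the
#'   source organisms, used to pick which organism carries a
#'   single-source template (default `c(0.64, 0.36)`, the proportion of
#'   known human vs fly interactions in the public databases the method
#'   draws templates from).
#' @param target_org target organism code (default `"mouse"`).
#' @param seed integer seed; fixed seed gives identical output.
#' @return object of class `interolog_study`: list with `proteins`
#'   (target proteome data frame), `homology` (named list of
#'   `homology_index` per source organism), `templates` (named list of
#'   template PPI data frames), `distances` (a `distance_config`),
#'   `positives`, `negatives`, `orthologs` (pair data frames), and
#'   `params`.
#' @export
simulate_interolog_study <- function(n_target_proteins = 200,
                                     n_true_ppis = 120,
                                     family_mean = 3,
                                     family_size = NULL,
                                     p_ancient = 0.5,
                                     ancient_family_factor = 3,
                                     both_source_fraction = 0.5,
                                     ortholog_fraction = 0.8,
                                     n_negatives = 400,
                                     length_meanlog = log(350),
                                     length_sdlog = 0.5,
                                     evalue_scale = 0.25,
                                     evalue_noise_sd = 3,
                                     ortholog_identity = c(0.80, 0.98),
                                     paralog_identity = c(0.35, 0.90),
                                     source_orgs = c(human = 0.765,
                                                     fly = 0.235),
                                     source_coverage = c(0.64, 0.36),
                                     target_org = "mouse",
                                     seed = 1L) {
  stopifnot(n_target_proteins >= 4, n_true_ppis >= 1,
            length(source_orgs) >= 1, !is.null(names(source_orgs)),
            length(source_coverage) == length(source_orgs))
  set.seed(seed)
  tnames <- sprintf("T%04d", seq_len(n_target_proteins))
  lengths <- round(pmin(pmax(
    stats::rlnorm(n_target_proteins, length_meanlog, length_sdlog),
    60), 2000))
  names(lengths) <- tnames
  ancient <- stats::runif(n_target_proteins) < p_ancient
  names(ancient) <- tnames
  # per-protein geometric family-size means; overall mean = family_mean
  modern_mean <- family_mean /
    (1 + mean(ancient) * (ancient_family_factor - 1))
  fam_mean_of <- ifelse(ancient, ancient_family_factor * modern_mean,
                        modern_mean)
  fam_mean_of <- pmax(fam_mean_of, 1)
  proteins <- data.frame(protein = tnames, length = as.numeric(lengths),
                         ancient = unname(ancient),
                         stringsAsFactors = FALSE)

  org_prefix <- stats::setNames(toupper(substr(names(source_orgs), 1, 1)),
                                names(source_orgs))
  if (anyDuplicated(org_prefix)) {
    org_prefix <- stats::setNames(
      paste0("S", seq_along(source_orgs)), names(source_orgs))
  }
  src_name <- function(org, t) paste(org_prefix[[org]], t, sep = "_")

  nl_cap <- 199
  homology <- list()
  ortholog_of <- list()   # per org: source protein -> designated ortholog
  for (org in names(source_orgs)) {
    rows <- vector("list", n_target_proteins)
    self_nl <- numeric(n_target_proteins)
    orth <- character(n_target_proteins)
    for (i in seq_len(n_target_proteins)) {
      t <- tnames[i]
      L <- lengths[[t]]
      fam_n <- if (is.null(family_size)) {
        1L + stats::rgeom(1L, prob = 1 / fam_mean_of[[t]])
      } else as.integer(family_size)
      fam_n <- max(1L, min(fam_n, n_target_proteins))
      paralogs <- sample(setdiff(tnames, t), fam_n - 1L)
      fam <- c(t, paralogs)
      # one-to-one orthology is harder to resolve inside expanded
      # families (one-to-many relationships): the designation
      # probability decays with family size, and ortholog_fraction = 1
      # remains a hard guarantee
      designated <- stats::runif(1) < ortholog_fraction^sqrt(fam_n)
      own_id <- if (designated) {
        stats::runif(1L, ortholog_identity[1], ortholog_identity[2])
      } else {
        # diverged counterpart: detectable, but at paralog-grade identity
        stats::runif(1L, paralog_identity[1], paralog_identity[2])
      }
      id <- c(own_id,
              stats::runif(fam_n - 1L, paralog_identity[1],
                           paralog_identity[2]))
      nl <- evalue_scale * L * id +
        stats::rnorm(fam_n, 0, evalue_noise_sd)
      nl <- pmin(pmax(nl, 1), nl_cap)
      # a designated ortholog gets the family's smallest E-value
      if (designated && fam_n > 1L && nl[1L] <= max(nl[-1L])) {
        nl[1L] <- min(max(nl) + stats::runif(1L, 0.5, 3), nl_cap + 1)
      }
      rows[[i]] <- data.frame(query = src_name(org, t), subject = fam,
                              identity = id, evalue = 10^(-nl),
                              source_org = org, target_org = target_org,
                              stringsAsFactors = FALSE)
      self_nl[i] <- min(evalue_scale * L, nl_cap + 1)
      orth[i] <- t
    }
    hits <- do.call(rbind, rows)
    selfs <- stats::setNames(10^(-self_nl), src_name(org, tnames))
    homology[[org]] <- homology_index(hits, self_evalues = selfs)
    ortholog_of[[org]] <- stats::setNames(orth, src_name(org, tnames))
  }

  # true target interaction backbone; the both-source (conserved) slots
  # go preferentially to interactions between ancient proteins, and a
  # single-source template sits in one organism chosen with probability
  # proportional to its database coverage (the larger, closer source
  # contributes most templates)
  true_pairs <- unique_random_pairs(tnames, n_true_ppis)
  n_both <- round(both_source_fraction * nrow(true_pairs))
  ancientness <- ancient[true_pairs$a] + ancient[true_pairs$b] +
    stats::runif(nrow(true_pairs))            # noise breaks ties
  both_idx <- order(-ancientness)[seq_len(n_both)]
  support <- lapply(seq_len(nrow(true_pairs)), function(i) {
    if (i %in% both_idx) names(source_orgs)
    else sample(names(source_orgs), 1L, prob = source_coverage)
  })
  templates <- list()
  for (org in names(source_orgs)) {
    sel <- vapply(support, function(s) org %in% s, TRUE)
    tp <- true_pairs[sel, , drop = FALSE]
    cp <- canonical_pair(src_name(org, tp$a), src_name(org, tp$b))
    templates[[org]] <- data.frame(a = cp$a, b = cp$b, organism = org,
                                   self_pair = cp$a == cp$b,
                                   stringsAsFactors = FALSE)
  }

  # negatives: pairs generalized mapping is prone to propose (family
  # cross products of the templates) that are not true interactions and
  # share no interaction neighborhood with one (one-hop exclusion)
  true_keys <- pair_key(true_pairs$a, true_pairs$b)
  true_g <- igraph::graph_from_data_frame(true_pairs, directed = FALSE,
                                          vertices = tnames)
  neg_pool <- character(0)
  for (org in names(source_orgs)) {
    hits <- homology[[org]]$hits
    fam <- split(hits$subject, hits$query)
    tp <- templates[[org]]
    for (i in seq_len(nrow(tp))) {
      fa <- fam[[tp$a[i]]]; fb <- fam[[tp$b[i]]]
      if (is.null(fa) || is.null(fb)) next
      grid <- expand.grid(x = fa, y = fb, stringsAsFactors = FALSE)
      grid <- grid[grid$x != grid$y, , drop = FALSE]
      neg_pool <- c(neg_pool, pair_key(grid$x, grid$y))
    }
  }
  neg_pool <- setdiff(unique(neg_pool), true_keys)
  if (length(neg_pool) > 0L) {
    parts <- strsplit(neg_pool, "|", fixed = TRUE)
    xa <- vapply(parts, `[[`, "", 1L); xb <- vapply(parts, `[[`, "", 2L)
    # drop pairs with a common neighbor in the true graph
    nb <- igraph::adjacent_vertices(true_g, tnames)
    names(nb) <- tnames
    has_common <- mapply(function(u, v) {
      length(intersect(names(nb[[u]]), names(nb[[v]]))) > 0L
    }, xa, xb)
    neg_pool <- neg_pool[!has_common]
  }
  n_neg <- min(n_negatives, length(neg_pool))
  neg_keys <- if (n_neg > 0L) sample(neg_pool, n_neg) else character(0)
  parts <- strsplit(neg_keys, "|", fixed = TRUE)
  negatives <- data.frame(
    a = vapply(parts, `[[`, "", 1L),
    b = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE)

  out <- list(
    proteins = proteins,
    homology = homology,
    templates = templates,
    distances = distance_config(target_org, source_orgs),
    positives = true_pairs,
    negatives = negatives,
    orthologs = true_pairs,   # ortholog images of the true templates
    params = list(n_target_proteins = n_target_proteins,
                  n_true_ppis = n_true_ppis, family_mean = family_mean,
                  family_size = family_size,
                  both_source_fraction = both_source_fraction,
                  evalue_scale = evalue_scale,
                  evalue_noise_sd = evalue_noise_sd, seed = seed))
  class(out) <- "interolog_study"
  out
}

#' @export
print.interolog_study <- function(x, ...) {
  cat("interolog_study:", nrow(x$proteins), "target proteins,",
      nrow(x$positives), "true PPIs,",
      nrow(x$negatives), "negatives; sources:",
      paste(names(x$homology), collapse = ", "), "\n")
  invisible(x)
}

# n distinct unordered non-self pairs over `items`
unique_random_pairs <- function(items, n) {
  seen <- character(0)
  a <- character(0); b <- character(0)
  guard <- 0L
  while (length(seen) < n && guard < 50L * n) {
    guard <- guard + 1L
    p <- sample(items, 2L)
    k <- pair_key(p[1L], p[2L])
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      cp <- canonical_pair(p[1L], p[2L])
      a <- c(a, cp$a); b <- c(b, cp$b)
    }
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Write a simulated study as a file bundle
#'
#' Serializes every input of an `interolog_study` in the formats the
#' readers consume: per-organism PPI tables and BLAST tabular files
#' (including self-alignment rows), a distance config, gold-standard
#' positive/negative pair tables, and the ortholog pair set.
#'
#' @param study an `interolog_study`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "interolog_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (org in names(study$templates)) {
    tp <- study$templates[[org]]
    writeLines(paste(tp$a, tp$b, sep = "\t"),
               file.path(dir, paste0("ppi_", org, ".tsv")))
    hom <- study$homology[[org]]
    self_rows <- data.frame(query = names(hom$self_evalues),
                            subject = names(hom$self_evalues),
                            identity = 1,
                            evalue = unname(hom$self_evalues),
                            stringsAsFactors = FALSE)
    all_rows <- rbind(hom$hits[, c("query", "subject", "identity",
                                   "evalue")], self_rows)
    blast12 <- paste(all_rows$query, all_rows$subject,
                     formatC(all_rows$identity * 100, digits = 3,
                             format = "f"),
                     100L, 0L, 0L, 1L, 100L, 1L, 100L,
                     formatC(all_rows$evalue, digits = 6, format = "e"),
                     200L, sep = "\t")
    writeLines(blast12, file.path(dir, paste0("blast_", org, ".tsv")))
  }
  dcfg <- study$distances
  writeLines(c(paste("target", dcfg$target, sep = "\t"),
               paste(names(dcfg$distances),
                     formatC(dcfg$distances, digits = 12, format = "g"),
                     sep = "\t")),
             file.path(dir, "distances.tsv"))
  writeLines(paste(study$positives$a, study$positives$b, sep = "\t"),
             file.path(dir, "gold_positives.tsv"))
  writeLines(paste(study$negatives$a, study$negatives$b, sep = "\t"),
             file.path(dir, "gold_negatives.tsv"))
  writeLines(paste(study$orthologs$a, study$orthologs$b, sep = "\t"),
             file.path(dir, "orthologs.tsv"))
  invisible(dir)
}

#' Simulate a random rooted GO-like DAG with annotations
#'
#' Terms are organized in a tree of the requested depth and branching,
#' then extra `is_a` parents are added with probability `p_extra_parent`
#' (always to a shallower term, so the graph stays acyclic). Each
#' protein is annotated with 1-3 terms.
#'
#' @param n_terms number of terms including the root (default 60).
#' @param depth target tree depth (default 6); the longest-path depth of
#'   the result is at least the realized tree depth.
#' @param branching mean number of children per internal term, used to
#'   spread terms over levels (default 2).
#' @param p_extra_parent probability of a second parent (default 0.2).
#' @param proteins character vector of proteins to annotate (may be
#'   empty).
#' @param namespace ontology namespace tag (default
#'   `"biological_process"`).
#' @param seed integer seed.
#' @return list with `ontology` (an [build_ontology()] object) and
#'   `annotations` (data frame `protein`, `go_id`, `aspect`).
#' @export
simulate_ontology <- function(n_terms = 60, depth = 6, branching = 2,
                              p_extra_parent = 0.2,
                              proteins = character(0),
                              namespace = "biological_process",
                              seed = 1L) {
  stopifnot(n_terms >= 2, depth >= 1)
  set.seed(seed)
  ids <- sprintf("GO:SYN%04d", seq_len(n_terms))
  lvl <- integer(n_terms)
  lvl[1L] <- 0L
  # guarantee one root-to-leaf chain of the full depth
  chain_len <- min(depth, n_terms - 1L)
  lvl[1L + seq_len(chain_len)] <- seq_len(chain_len)
  if (n_terms > chain_len + 1L) {
    lvl[(chain_len + 2L):n_terms] <-
      sample(seq_len(depth), n_terms - chain_len - 1L, replace = TRUE,
             prob = branching^seq_len(depth))
  }
  parent1 <- integer(n_terms)
  for (i in 2L:n_terms) {
    if (i <= chain_len + 1L) {
      parent1[i] <- i - 1L
    } else {
      cand <- which(lvl == lvl[i] - 1L & seq_len(n_terms) < i)
      if (length(cand) == 0L) cand <- which(lvl < lvl[i] &
                                              seq_len(n_terms) < i)
      parent1[i] <- cand[sample.int(length(cand), 1L)]
    }
  }
  edges <- data.frame(child = ids[2L:n_terms],
                      parent = ids[parent1[2L:n_terms]],
                      stringsAsFactors = FALSE)
  for (i in 3L:n_terms) {
    if (stats::runif(1) < p_extra_parent) {
      cand <- which(lvl < lvl[i] & seq_len(n_terms) != parent1[i])
      cand <- cand[cand < i]
      if (length(cand) > 0L) {
        p2 <- cand[sample.int(length(cand), 1L)]
        edges <- rbind(edges, data.frame(child = ids[i],
                                         parent = ids[p2],
                                         stringsAsFactors = FALSE))
      }
    }
  }
  onto <- build_ontology(ids, edges, namespace = namespace)
  aspect <- switch(namespace, biological_process = "P",
                   cellular_component = "C", "F")
  ann <- NULL
  if (length(proteins) > 0L) {
    ann <- do.call(rbind, lapply(proteins, function(p) {
      k <- sample(1:3, 1L)
      data.frame(protein = p,
                 go_id = sample(ids[-1L], k),
                 aspect = aspect, stringsAsFactors = FALSE)
    }))
  }
  list(ontology = onto, annotations = ann)
}

#' Hand-built ontology realizing the worked RSS example
#'
#' A deterministic DAG whose deepest leaf sits 20 levels below the root
#' (`maxD = 20`) and which contains two terms, GO:0000002 and GO:0043653,
#' whose most recent common ancestor lies at depth 4 (`alpha = 4`), whose
#' distances below that ancestor sum to 3 (`gamma = 1 + 2`), and whose
#' minimum distances to a descendant leaf are 1 and 0 (`beta = 1`), so
#' that `RSS = (20 / 23) * (4 / 5) = 0.696`.
#'
#' @return an `ontology` object.
#' @export
rss_demo_ontology <- function() {
  root <- "GO:SYNROOT"
  chain <- sprintf("GO:CHAIN%02d", 1:20)       # depth 1..20, leaf at 20
  ti <- "GO:0000002"                            # depth 5, one leaf child
  ti_leaf <- "GO:TI_LEAF"
  tj_mid <- "GO:TJ_MID"                         # depth 5
  tj <- "GO:0043653"                            # depth 6, leaf
  terms <- c(root, chain, ti, ti_leaf, tj_mid, tj)
  edges <- rbind(
    data.frame(child = chain, parent = c(root, chain[-20]),
               stringsAsFactors = FALSE),
    data.frame(child = c(ti, ti_leaf, tj_mid, tj),
               parent = c(chain[4], ti, chain[4], tj_mid),
               stringsAsFactors = FALSE))
  build_ontology(terms, edges, namespace = "biological_process",
                 term_names = stats::setNames(
                   c("synthetic root",
                     "mitochondrial genome maintenance",
                     "mitochondrial fragmentation involved in apoptotic process"),
                   c(root, ti, tj)))
}

#' Serialize an ontology as OBO 1.2 and annotations as GAF 2.2
#'
#' @param onto an `ontology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  stopifnot(inherits(onto, "ontology"))
  el <- igraph::as_edgelist(onto$graph)   # child -> parent
  parents <- split(el[, 2L], el[, 1L])
  ns <- if (is.na(onto$namespace)) "biological_process" else onto$namespace
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    nm <- if (!is.null(onto$term_names) && t %in% names(onto$term_names) &&
              !is.na(onto$term_names[[t]])) onto$term_names[[t]] else t
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", nm),
             paste0("namespace: ", ns),
             if (!is.null(parents[[t]]))
               paste0("is_a: ", parents[[t]], " ! ", parents[[t]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_obo
#' @param annotations data frame with `protein`, `go_id`, `aspect`.
#' @export
write_gaf <- function(annotations, path) {
  header <- "!gaf-version: 2.2"
  rows <- paste("SYN", annotations$protein, annotations$protein, "",
                annotations$go_id, "SYN:0000001", "IEA", "",
                annotations$aspect, "", "", "protein", "taxon:0",
                "20140529", "SYN", "", "", sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Simulate a modular (planted-partition) network with module definitions
#'
#' Nodes are split into modules; edges appear with probability `p_in`
#' inside a module and `p_out` between modules (a stochastic block
#' model). With `p_in >> p_out`, modules are cohesive and weakly coupled,
#' so their connectivity ratio exceeds 1.
#'
#' @param n_modules number of modules (default 5).
#' @param module_size proteins per module (default 8).
#' @param p_in,p_out within/between edge probabilities.
#' @param seed integer seed.
#' @return list with `network` (igraph) and `modules` (data frame as from
#'   [read_modules()], kind `"complex"`).
#' @export
simulate_modular_network <- function(n_modules = 5, module_size = 8,
                                     p_in = 0.8, p_out = 0.02,
                                     seed = 1L) {
  set.seed(seed)
  n <- n_modules * module_size
  pref <- matrix(p_out, n_modules, n_modules)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(module_size, n_modules))
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n))
  modules <- data.frame(
    module_id = sprintf("M%03d", seq_len(n_modules)),
    kind = "complex",
    members = I(lapply(seq_len(n_modules), function(i) {
      sprintf("N%04d", ((i - 1L) * module_size + 1L):(i * module_size))
    })),
    stringsAsFactors = FALSE)
  list(network = g, modules = modules)
}
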