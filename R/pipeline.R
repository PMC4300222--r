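#' Run the full prediction pipeline
#'
#' Chains mapping, scoring, optional benchmark evaluation, network
#' reconstruction and topology/module analysis, writing one TSV per stage
#' plus a run log. Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config a named list (or path to a YAML file with the same
#'   structure) with entries:
#'   \describe{
#'     \item{ppi}{named list: source organism code -> PPI table path}
#'     \item{blast}{named list: source organism code -> BLAST tabular
#'       path (self-alignment rows included or supplied separately)}
#'     \item{self_evalues}{optional named list: organism -> two-column
#'       TSV of self-alignment E-values}
#'     \item{distances}{path to the distance config}
#'     \item{positives, negatives}{optional gold-standard pair tables;
#'       when both are given, evaluation curves are computed}
#'     \item{orthologs}{optional ortholog pair table for enrichment}
#'     \item{modules}{optional module definition table}
#'     \item{homolog_evalue_max, joint_evalue_max, s_min, weights, mode}{
#'       method parameters; defaults 1e-10, 1e-40, 2.3, c(1,1,1),
#'       "generalized"}
#'     \item{out_dir}{output directory}
#'     \item{seed}{integer seed (recorded; the pipeline itself is
#'       deterministic)}
#'   }
#' @return invisibly, a list with the in-memory results of each stage
#'   (`candidates`, `ranked`, `pairs`, `predicted`, `curves`, `network`,
#'   `topology`, `modules`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(homolog_evalue_max = 1e-10, joint_evalue_max = 1e-40,
                   s_min = 2.3, weights = c(1, 1, 1),
                   mode = "generalized", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_lines <- c(
    paste0("interologr ",
           as.character(utils::packageVersion("interologr"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("mode: ", config$mode),
    paste0("homolog_evalue_max: ", config$homolog_evalue_max),
    paste0("joint_evalue_max: ", config$joint_evalue_max),
    paste0("s_min: ", config$s_min),
    paste0("weights: ", paste(config$weights, collapse = ",")))

  inputs <- stage("read_inputs", {
    if (is.null(config$ppi) || is.null(config$blast)) {
      stop("config must name 'ppi' and 'blast' files per source organism")
    }
    if (is.null(config$distances)) stop("missing distance config file")
    orgs <- names(config$ppi)
    homology <- lapply(orgs, function(org) {
      hom <- read_blast_tabular(config$blast[[org]], org,
                                target_org = "target")
      if (!is.null(config$self_evalues[[org]])) {
        hom <- homology_index(
          hom$hits, self_evalues = c(
            hom$self_evalues,
            read_self_evalues(config$self_evalues[[org]])))
      }
      hom
    })
    names(homology) <- orgs
    list(templates = lapply(orgs, function(org) {
      read_ppi_table(config$ppi[[org]], org)
    }) |> stats::setNames(orgs),
    homology = homology,
    distances = read_distance_config(config$distances))
  })

  candidates <- stage("map", {
    do.call(rbind, lapply(names(inputs$templates), function(org) {
      enumerate_candidates(inputs$templates[[org]],
                           inputs$homology[[org]],
                           homolog_evalue_max = config$homolog_evalue_max,
                           joint_evalue_max = config$joint_evalue_max)
    }))
  })
  write_candidates(candidates, file.path(config$out_dir, "candidates.tsv"))
  log_lines <- c(log_lines, paste0("candidates: ", nrow(candidates)))

  scored <- stage("score", {
    score_candidates(candidates, inputs$distances,
                     weights = config$weights, s_min = config$s_min,
                     mode = config$mode)
  })
  write_candidates(scored$pairs, file.path(config$out_dir, "scored.tsv"))
  write_candidates(scored$predicted,
                   file.path(config$out_dir, "predicted.tsv"))
  log_lines <- c(log_lines,
                 paste0("scored pairs: ", nrow(scored$pairs)),
                 paste0("predicted (S >= ", config$s_min, "): ",
                        nrow(scored$predicted)))

  curves <- NULL
  if (!is.null(config$positives) && !is.null(config$negatives)) {
    curves <- stage("evaluate", {
      gold <- gold_standard(read_ppi_table(config$positives, "target"),
                            read_ppi_table(config$negatives, "target"))
      keys <- c("s_sim", "s_rank", "s_con", "s_sim+s_rank",
                "s_sim+s_con", "s_total")
      cv <- lapply(keys, function(k) score_curves(scored$pairs, gold, k))
      names(cv) <- keys
      cv
    })
    curve_tab <- do.call(rbind, lapply(names(curves), function(k) {
      cbind(score_key = k, as.data.frame(curves[[k]]))
    }))
    write_candidates(curve_tab, file.path(config$out_dir, "curves.tsv"))
    log_lines <- c(log_lines, vapply(names(curves), function(k) {
      paste0("AUC[", k, "]: ",
             formatC(curve_auc(curves[[k]]), digits = 4, format = "f"))
    }, ""))
  }

  network <- stage("reconstruct", reconstruct_network(scored$predicted))
  el <- igraph::as_data_frame(network, what = "edges")
  write_candidates(el, file.path(config$out_dir, "network.tsv"))
  log_lines <- c(log_lines,
                 paste0("network: ", igraph::vcount(network), " nodes, ",
                        igraph::ecount(network), " edges"))

  topology <- stage("topology", {
    tryCatch(degree_exponent(network), error = function(e) NULL)
  })
  if (!is.null(topology)) {
    log_lines <- c(log_lines,
                   paste0("degree exponent gamma: ",
                          formatC(topology$gamma, digits = 3,
                                  format = "f"),
                          " (r2 = ",
                          formatC(topology$r_squared, digits = 3,
                                  format = "f"), ")"))
  } else {
    log_lines <- c(log_lines,
                   "degree exponent: not fitted (too few distinct degrees)")
  }

  modtab <- NULL
  if (!is.null(config$modules)) {
    modtab <- stage("modules", {
      average_connectivity_ratio(read_modules(config$modules), network)
    })
    write_candidates(modtab$table, file.path(config$out_dir,
                                             "modules.tsv"))
    log_lines <- c(log_lines,
                   paste0("mean module connectivity ratio: ",
                          formatC(modtab$mean_ratio, digits = 3,
                                  format = "f")))
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(candidates = candidates, ranked = scored$ranked,
                 pairs = scored$pairs, predicted = scored$predicted,
                 curves = curves, network = network, topology = topology,
                 modules = modtab))
}
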