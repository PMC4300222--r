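#' Read a source-organism PPI table
#'
#' Reads a tab-delimited edge list of known protein-protein interactions
#' (the "templates" used for interolog mapping). Only the first two columns
#' are used; extra columns (e.g. PSI-MITAB provenance) are ignored, so a
#' MITAB subset with bare accessions in columns 1-2 parses as-is. Lines
#' starting with `#` are comments. Pairs are canonicalized (smaller
#' accession first) and de-duplicated; self-pairs are retained and flagged.
#'
#' @param path path to a tab- (or whitespace-) delimited file with at least
#'   two columns.
#' @param organism organism code attached to every pair (e.g. `"human"`).
#' @return data frame with columns `a`, `b` (canonical order), `organism`,
#'   `self_pair` (logical).
#' @examples
#' f <- tempfile()
#' writeLines(c("P1\tP2", "P2\tP1", "P1\tP2"), f)
#' read_ppi_table(f, "human")   # one canonical pair
#' @export
read_ppi_table <- function(path, organism) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty PPI table: '", path, "'")
    return(data.frame(a = character(), b = character(),
                      organism = character(), self_pair = logical(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t|\\s+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed PPI row (need >= 2 columns) at line ", idx[bad[1L]],
         " of '", path, "'")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("empty accession in PPI table '", path, "'")
  }
  cp <- canonical_pair(a, b)
  out <- data.frame(a = cp$a, b = cp$b, organism = organism,
                    self_pair = cp$a == cp$b, stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$a, out$b, sep = "|")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read homology hits in NCBI BLAST tabular format (outfmt 6)
#'
#' Parses the standard 12-column tabular output (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, E-value, bit score). Percent identity is rescaled to a fraction in
#' \[0, 1\]. Rows where query accession equals subject accession are
#' self-alignments: they are routed into a self-E-value lookup (needed to
#' normalize joint sequence similarity) and removed from the hit list.
#' E-values equal to 0 are preserved as 0 here; clamping to the E-value
#' floor happens in scoring, not at I/O.
#'
#' @param path path to the BLAST tabular file.
#' @param source_org,target_org organism codes for query (source) and
#'   subject (target) proteins.
#' @return an object of class `homology_index`: a list with
#'   `hits` (data frame: `query`, `subject`, `identity`, `evalue`,
#'   `source_org`, `target_org`) and `self_evalues` (named numeric vector,
#'   query accession to self-alignment E-value).
#' @seealso [homology_index()] to build the same structure in memory.
#' @export
read_blast_tabular <- function(path, source_org, target_org) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf != 12L)) {
    stop("BLAST tabular row with ", nf[nf != 12L][1L],
         " columns (expected 12) at line ", idx[nf != 12L][1L],
         " of '", path, "'")
  }
  query <- vapply(fields, `[[`, "", 1L)
  subject <- vapply(fields, `[[`, "", 2L)
  pident <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (any(is.na(evalue))) {
    stop("non-numeric E-value at line ", idx[which(is.na(evalue))[1L]],
         " of '", path, "'")
  }
  if (any(is.na(pident)) || any(pident < 0) || any(pident > 100)) {
    stop("percent identity outside [0, 100] in '", path, "'")
  }
  if (any(evalue < 0)) stop("negative E-value in '", path, "'")
  hits <- data.frame(query = query, subject = subject,
                     identity = pident / 100, evalue = evalue,
                     source_org = source_org, target_org = target_org,
                     stringsAsFactors = FALSE)
  homology_index(hits)
}

#' Build a homology index from a hit table
#'
#' Splits a homology hit table into cross-organism hits and a
#' self-E-value lookup, the two inputs candidate enumeration needs.
#' Self-alignments are rows whose query and subject accessions are equal.
#'
#' @param hits data frame with columns `query`, `subject`, `identity`
#'   (fraction), `evalue`, and optionally `source_org`, `target_org`.
#' @param self_evalues optional named numeric vector of self-alignment
#'   E-values, merged with (and overriding) any self rows found in `hits`.
#' @return a `homology_index` (see [read_blast_tabular()]).
#' @export
homology_index <- function(hits, self_evalues = NULL) {
  stopifnot(all(c("query", "subject", "identity", "evalue") %in%
                  colnames(hits)))
  is_self <- hits$query == hits$subject
  selfs <- stats::setNames(hits$evalue[is_self], hits$query[is_self])
  selfs <- selfs[!duplicated(names(selfs))]
  if (!is.null(self_evalues)) {
    selfs[names(self_evalues)] <- self_evalues
  }
  bad <- selfs >= 1
  if (any(bad)) {
    stop("self-alignment E-value >= 1 for ",
         paste(names(selfs)[bad], collapse = ", "),
         " (cannot normalize similarity)")
  }
  out <- list(hits = hits[!is_self, , drop = FALSE], self_evalues = selfs)
  rownames(out$hits) <- NULL
  class(out) <- "homology_index"
  out
}

#' @export
print.homology_index <- function(x, ...) {
  cat("homology_index:", nrow(x$hits), "hits,",
      length(x$self_evalues), "self E-values\n")
  invisible(x)
}

#' Read self-alignment E-values from a two-column TSV
#'
#' @param path TSV with columns: protein accession, E-value.
#' @return named numeric vector.
#' @export
read_self_evalues <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("self-E-value table needs 2 columns: '", path, "'")
  ev <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(ev))) stop("non-numeric self E-value in '", path, "'")
  stats::setNames(ev, as.character(tab[[1L]]))
}

#' Read an evolutionary-distance configuration
#'
#' A flat key-value TSV with one `organism<TAB>distance` row per source
#' organism plus a `target<TAB><code>` row. Raw (unnormalized) distances
#' are allowed; they are divided by their sum so the configured sources
#' total 1. With the distances used for mapping human and fly templates
#' onto mouse, the normalized values are 0.765 and 0.235.
#'
#' @param path path to the TSV.
#' @return object of class `distance_config`: list with `target` (organism
#'   code) and `distances` (named numeric, summing to 1).
#' @seealso [distance_config()] for in-memory construction.
#' @export
read_distance_config <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("distance config needs 2 columns: '", path, "'")
  keys <- as.character(tab[[1L]])
  target <- tab[[2L]][keys == "target"]
  if (length(target) != 1L) {
    stop("distance config must contain exactly one 'target' row: '",
         path, "'")
  }
  src <- tab[keys != "target", , drop = FALSE]
  d <- suppressWarnings(as.numeric(src[[2L]]))
  if (any(is.na(d))) stop("non-numeric distance in '", path, "'")
  distance_config(as.character(target),
                  stats::setNames(d, as.character(src[[1L]])))
}

#' @rdname read_distance_config
#' @param target target organism code.
#' @param distances named numeric vector of raw distances (one per source
#'   organism); normalized to sum to 1 on construction.
#' @export
distance_config <- function(target, distances) {
  if (any(distances < 0)) stop("negative evolutionary distance")
  total <- sum(distances)
  if (total <= 0) stop("distances sum to zero; cannot normalize")
  out <- list(target = target, distances = distances / total)
  class(out) <- "distance_config"
  out
}

#' @export
print.distance_config <- function(x, ...) {
  cat("distance_config: target =", x$target, "\n")
  print(round(x$distances, 4))
  invisible(x)
}

#' Write / read candidate tables
#'
#' Candidate and scored-pair tables round-trip through TSV with a header
#' at 12 significant digits.
#'
#' @param candidates data frame of candidates (any column set; numeric
#'   columns are formatted at 12 significant digits).
#' @param path output path.
#' @return `write_candidates()` returns `path` invisibly;
#'   `read_candidates()` returns the data frame.
#' @export
write_candidates <- function(candidates, path) {
  write_tsv_table(candidates, path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  read_tsv_table(path)
}

#' Read module definitions
#'
#' KEGG-style module table: `module_id<TAB>kind<TAB>member1,member2,...`
#' where `kind` is `pathway` or `complex`.
#'
#' @param path path to the TSV (no header).
#' @return data frame with columns `module_id`, `kind` and a list-column
#'   `members` (character vectors).
#' @export
read_modules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  if (any(vapply(fields, length, 1L) < 3L)) {
    stop("module rows need 3 tab-separated fields: '", path, "'")
  }
  data.frame(
    module_id = vapply(fields, `[[`, "", 1L),
    kind = vapply(fields, `[[`, "", 2L),
    members = I(lapply(fields, function(f) {
      unique(trimws(strsplit(f[[3L]], ",")[[1L]]))
    })),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_modules
#' @param modules module data frame as returned by `read_modules()`.
#' @export
write_modules <- function(modules, path) {
  lines <- paste(modules$module_id, modules$kind,
                 vapply(modules$members, paste, "", collapse = ","),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
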