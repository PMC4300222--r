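#' @keywords internal
"_PACKAGE"

# Global E-value floor: smallest magnitude BLAST prints before reporting 0.
# Applied before any logarithm so E = 0 hits stay finite.
.EVALUE_FLOOR <- 1e-200

#' Canonicalize protein pairs
#'
#' Interactions are undirected: a pair and its reverse denote the same PPI.
#' Pairs are stored with the lexicographically smaller accession first so
#' that de-duplication and cross-referencing are deterministic.
#'
#' @param a,b character vectors of protein accessions (recycled to common
#'   length).
#' @return `canonical_pair()`: a data frame with columns `a` and `b` in
#'   canonical order. `pair_key()`: a character vector, one key per pair,
#'   identical for `(a, b)` and `(b, a)`.
#' @examples
#' canonical_pair(c("SOS2", "GRB2"), c("GRB2", "SOS2"))
#' pair_key("P1", "P2") == pair_key("P2", "P1")
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- b < a
  data.frame(a = ifelse(swap, b, a), b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' @rdname canonical_pair
#' @export
pair_key <- function(a, b) {
  cp <- canonical_pair(a, b)
  paste(cp$a, cp$b, sep = "|")
}

# -log10 with the global floor; keeps E = 0 finite.
neglog10_evalue <- function(e, floor = .EVALUE_FLOOR) {
  if (any(e < 0, na.rm = TRUE)) stop("E-values must be non-negative")
  -log10(pmax(e, floor))
}

# Write a data frame as TSV with header, numbers at 12 significant digits
# so that read-back reproduces them exactly at that precision.
write_tsv_table <- function(x, path, digits = 12) {
  xx <- x
  for (j in seq_along(xx)) {
    if (is.numeric(xx[[j]]) && !is.integer(xx[[j]])) {
      xx[[j]] <- formatC(xx[[j]], digits = digits, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.table(xx, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}
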