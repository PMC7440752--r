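#' @keywords internal
.iupac <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
            R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
            B = 14L, D = 13L, H = 11L, V = 7L,
            N = 15L, "-" = 15L, "?" = 15L, "." = 15L, X = 15L)

.state_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Compress an alignment into weighted site patterns
#'
#' Builds the pattern matrix shared by parsimony and likelihood: every cell
#' is the subset of \{A,C,G,T\} compatible with the observed IUPAC symbol
#' (gaps, `?` and `N` map to the full set, i.e. missing), identical columns
#' are merged, and each pattern carries an integer weight. `nsites` is the
#' total alignment length including constant sites.
#'
#' @param x character matrix (taxa x sites) of IUPAC DNA symbols, with
#'   rownames giving the taxa, or an object from [read_alignment].
#' @return An object of class `pattern_matrix` with elements `taxa`,
#'   `states` (bitmask matrix, taxa x patterns), `weights` and `nsites`.
#' @examples
#' aln <- matrix(c("A","A","A","A", "A","A","G","G"), nrow = 4,
#'               dimnames = list(c("a","b","c","d"), NULL))
#' pattern_matrix(aln)
#' @export
pattern_matrix <- function(x) {
  if (inherits(x, "pattern_matrix")) return(x)
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("alignment must carry taxon names as rownames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon name: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  up <- toupper(x)
  bad <- which(!(up %in% names(.iupac)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop("unknown symbol '", x[bad[1]], "' for taxon ", rownames(x)[i[1]],
         " at site ", i[2])
  }
  bits <- matrix(.iupac[up], nrow = nrow(x))
  key <- apply(bits, 2, paste, collapse = ",")
  first <- !duplicated(key)
  states <- bits[, first, drop = FALSE]
  weights <- as.vector(table(key)[key[first]])
  structure(list(taxa = rownames(x), states = states,
                 weights = as.numeric(weights), nsites = ncol(x)),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat("pattern matrix:", length(x$taxa), "taxa,", x$nsites, "sites,",
      ncol(x$states), "distinct patterns\n")
  invisible(x)
}

#' Expand compressed patterns back to per-site state sets
#'
#' Inverse of the compression step (site order is the pattern order repeated
#' by weight, not the original file order). Used by the oracle tests that
#' compare compressed and uncompressed computations.
#'
#' @param pm a [pattern_matrix].
#' @return Integer bitmask matrix, taxa x nsites.
#' @export
expand_patterns <- function(pm) {
  idx <- rep(seq_along(pm$weights), pm$weights)
  out <- pm$states[, idx, drop = FALSE]
  rownames(out) <- pm$taxa
  out
}

#' Read a DNA alignment (FASTA or a simple NEXUS data block)
#'
#' @param file path to the alignment.
#' @param format `"auto"` (sniff the first character), `"fasta"` or
#'   `"nexus"`.
#' @return A [pattern_matrix]; the raw character matrix is attached as
#'   attribute `"alignment"` for workflows that re-compress a subset of
#'   sites (parsimony guidance from the first *m* sites).
#' @export
read_alignment <- function(file, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 1)
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "fasta"
  }
  if (format == "fasta") {
    dn <- ape::read.FASTA(file)
    if (length(dn) == 0) stop("no sequences found in ", file)
    lens <- lengths(dn)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    chars <- toupper(do.call(rbind, as.character(dn)))
  } else {
    nx <- ape::read.nexus.data(file)
    lens <- lengths(nx)
    if (length(unique(lens)) != 1)
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    chars <- toupper(do.call(rbind, lapply(nx, as.character)))
  }
  pm <- pattern_matrix(chars)
  attr(pm, "alignment") <- chars
  pm
}

# reorder pattern data to the tip order of a tree; error on missing taxa
.pm_for_tree <- function(pm, tree) {
  missing <- setdiff(tree$labels, pm$taxa)
  if (length(missing))
    stop("taxa in tree but not in data: ", paste(missing, collapse = ", "))
  i <- match(tree$labels, pm$taxa)
  list(states = pm$states[i, , drop = FALSE], weights = pm$weights,
       nsites = pm$nsites)
}

#' Observed (empirical) base frequencies
#'
#' Proportions of A, C, G, T over all unambiguous cells of the alignment,
#' used to fix stationary frequencies during a run.
#'
#' @param pm a [pattern_matrix].
#' @return Numeric vector of length 4 summing to 1 (order A, C, G, T).
#' @export
empirical_frequencies <- function(pm) {
  counts <- numeric(4)
  for (k in 1:4) {
    is_k <- pm$states == .state_bits[k]
    counts[k] <- sum(pm$weights[col(pm$states)[is_k]])
  }
  if (sum(counts) == 0) return(rep(0.25, 4))
  stats::setNames(counts / sum(counts), c("A", "C", "G", "T"))
}
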