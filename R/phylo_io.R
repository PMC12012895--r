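#' Read a rooted phylogeny from a Newick string or file
#'
#' Parses a Newick tree with branch lengths into an \code{ape} \code{"phylo"}
#' object, validating the invariants the downstream comparative machinery
#' relies on: a single root, unique tip labels, a branch length on every
#' non-root edge, and no negative branch lengths.  Polytomies are resolved
#' deterministically (left-to-right) into zero-length internal branches, to
#' which every downstream Brownian covariance is invariant.
#'
#' @param text a Newick string (must end in \code{";"}).
#' @param file path to a Newick file; exactly one of \code{text}/\code{file}.
#' @param resolve_polytomies resolve multifurcations into zero-length
#'   branches (default \code{TRUE}).
#' @return an object of class \code{"phylo"}.
#' @export
read_newick <- function(text = NULL, file = NULL, resolve_polytomies = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  .check_parens(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string: could not be parsed")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch length on at least one edge; ",
         "branch lengths are required (no silent default)")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) found")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (resolve_polytomies && !ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (a basal multifurcation counts as rooted ",
         "only after polytomy resolution)")
  tree
}

## balanced-parenthesis precheck so parse errors can name an offset
.check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars))
  invisible(TRUE)
}

#' Write a phylogeny in Newick format
#'
#' @param tree a \code{"phylo"} object.
#' @param file optional path; if \code{NULL} the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree on \code{keep}: dropped tips are removed and
#' degree-2 internal nodes are collapsed with their branch lengths summed, so
#' all pairwise tip-to-tip path lengths are preserved.
#'
#' @param tree a \code{"phylo"} object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned \code{"phylo"} object.
#' @export
prune_to <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("labels not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2)
    stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion the covariance between two tips is the (rate-weighted)
#' length of their shared root path; the diagonal holds rate-weighted
#' root-to-tip depths.  This matrix is the error covariance used by all the
#' phylogenetic regressions in the package.
#'
#' @param tree a \code{"phylo"} object.
#' @param rates optional positive per-branch rate multipliers, aligned with
#'   the rows of \code{tree$edge}; default all 1.
#' @return a symmetric positive semidefinite matrix with dimnames
#'   \code{tree$tip.label}.
#' @export
bm_covariance <- function(tree, rates = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(rates)) {
    if (length(rates) != nrow(tree$edge))
      stop("'rates' must have one entry per branch (", nrow(tree$edge), ")")
    if (any(rates <= 0)) stop("branch rates must be positive")
    tree$edge.length <- tree$edge.length * rates
  }
  ape::vcv.phylo(tree)
}

#' Canonical species order of a phylogeny
#'
#' All trait matrices in the package conform to this order (the tree's tip
#' label order).
#'
#' @param tree a \code{"phylo"} object.
#' @return character vector of tip labels.
#' @export
canonical_order <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label
}

.measurement_cols <- c("sl", "il", "ol", "pm", "mx", "na", "oc", "snl")

#' Read a specimen measurement table
#'
#' Reads a delimited text file of per-specimen linear measurements (mm).
#' The header must name a \code{species} column and the eight measurement
#' columns \code{sl, il, ol, pm, mx, na, oc, snl} (standard length, in-lever,
#' out-lever, premaxilla, maxilla, nasal, oral cavity, snout length).
#' Multiple rows (specimens) per species are expected.
#'
#' @param path path to a CSV or TSV file (separator inferred from the
#'   extension, comma by default).
#' @param sep optional field separator overriding the inference.
#' @return a \code{data.frame} with a character \code{species} column and the
#'   eight numeric measurement columns.
#' @export
read_measurements <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_measurements(tab)
}

#' Validate a measurement table
#'
#' @param tab a data.frame with columns \code{species} and
#'   \code{sl, il, ol, pm, mx, na, oc, snl}.
#' @return the validated data.frame (column-ordered), invisibly usable.
#' @export
validate_measurements <- function(tab) {
  missing_cols <- setdiff(c("species", .measurement_cols), names(tab))
  if (length(missing_cols))
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$species <- as.character(tab$species)
  for (cn in .measurement_cols) {
    x <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(x))
      stop("non-numeric value in column '", cn, "' at row ",
           which(is.na(x))[1])
    bad <- which(x <= 0)
    if (length(bad))
      stop("non-positive measurement in column '", cn, "' at row ", bad[1])
    tab[[cn]] <- x
  }
  tab[, c("species", .measurement_cols)]
}

#' Collapse specimens to species means
#'
#' Averages the raw (mm-scale) measurements within species arithmetically
#' before any log transform (the default), or averages on the log scale
#' (geometric means) when \code{scale = "log"}.
#'
#' @param tab a validated measurement table.
#' @param scale \code{"raw"} (arithmetic means, the default) or \code{"log"}
#'   (means of ln-measurements, back-transformed).
#' @return a data.frame with one row per species.
#' @export
species_means <- function(tab, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  tab <- validate_measurements(tab)
  sp <- unique(tab$species)
  agg <- function(x) if (scale == "raw") mean(x) else exp(mean(log(x)))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (cn in .measurement_cols)
    out[[cn]] <- vapply(sp, function(s) agg(tab[[cn]][tab$species == s]),
                        numeric(1))
  rownames(out) <- NULL
  out
}
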