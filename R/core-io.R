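#' @keywords internal
"_PACKAGE"

#' Canonicalize species labels
#'
#' Trims surrounding whitespace and maps runs of internal whitespace or
#' underscores to a single underscore, so that tip labels and table rows
#' written with either convention match exactly.  No fuzzy matching is ever
#' attempted: a silent mismatch is worse than a reported drop.
#'
#' @param x character vector of species names.
#' @return character vector of canonical names.
#' @export
canonical_species <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", as.character(x))
  gsub("[\\s_]+", "_", x, perl = TRUE)
}

#' Read and validate a phylogeny in Newick format
#'
#' Wraps [ape::read.tree()] with the validation this package's comparative
#' methods require: at least two uniquely labelled tips, a branch length on
#' every edge, and no negative branch lengths.  Zero-length terminal edges
#' are allowed but flagged with a warning, since two coincident tips make
#' the Brownian-motion covariance singular.
#'
#' @param file path to a Newick file, or `NULL` if `text` is given.
#' @param text a Newick string (alternative to `file`).
#' @return an object of class `"phylo"` with canonical tip labels.
#' @seealso [write_newick()], [align_tree_and_table()]
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'")
  if (is.null(text)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  # cheap structural check before handing to the parser, so malformed input
  # fails loudly with a position instead of producing a nonsense tree
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (length(bal) && (any(bal < 0L) || bal[length(bal)] != 0L)) {
    pos <- if (any(bal < 0L)) which(bal < 0L)[1L] else length(bal)
    stop("malformed Newick: unbalanced parenthesis at character ", pos)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: input is not a valid tree")
  validate_phylo(tree)
}

#' Validate a phylo object for comparative analysis
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly unchanged apart from canonical tip labels.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  tree$tip.label <- canonical_species(tree$tip.label)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; edge lengths are required")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths on some edges")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal edges present; coincident tips will make ",
            "the phylogenetic covariance singular")
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree a `"phylo"` object.
#' @param file output path; if `NULL` the Newick string is returned.
#' @return the file path (invisibly), or the Newick string if `file = NULL`.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- validate_phylo(tree)
  # 15 significant digits so edge lengths survive a round-trip
  if (is.null(file)) return(ape::write.tree(tree, digits = 15))
  ape::write.tree(tree, file = file, digits = 15)
  invisible(file)
}

# canonical trait columns and their validators
.trait_columns <- c("p50", "pn", "latitude", "longitude", "altitude",
                    "mat", "map", "mtcm", "wd", "d_h")

#' Read a species trait table
#'
#' Reads a delimited text file with one row per species: a species column,
#' an optional threat-status column with levels `non_threatened` /
#' `threatened`, and numeric trait and environment columns (`p50` in MPa,
#' `pn` in umol CO2 m-2 s-1, `latitude`, `longitude`, `altitude`, `mat`,
#' `map`, `mtcm`, `wd`, `d_h`).  Units are taken as given; no conversion is
#' performed.
#'
#' @param path path to the delimited file (header row required).
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param na_token missing-value token, default `"NA"`.
#' @param schema optional named character vector mapping canonical column
#'   names (names of the vector) to the column names used in the file.
#' @return a `data.frame` with canonical column names, species names
#'   canonicalized, `status` as a factor with the two recognised levels.
#' @export
read_species_table <- function(path, sep = ",", na_token = "NA",
                               schema = NULL) {
  if (!file.exists(path)) stop("species table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema column '", schema[[canon]], "' not found in ", path)
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  names(raw) <- tolower(names(raw))
  if (!"species" %in% names(raw)) stop("no 'species' column in ", path)
  out <- data.frame(species = canonical_species(raw$species),
                    stringsAsFactors = FALSE)
  if (any(out$species == "")) stop("empty species name in row ",
                                   which(out$species == "")[1L])
  dup <- unique(out$species[duplicated(out$species)])
  if (length(dup))
    stop("duplicated species in table: ", paste(dup, collapse = ", "))
  if ("status" %in% names(raw)) {
    st <- raw$status
    st[st %in% na_token] <- NA
    bad <- stats::na.omit(setdiff(unique(st),
                                  c("non_threatened", "threatened")))
    if (length(bad))
      stop("unknown status level(s): ", paste(bad, collapse = ", "),
           " (expected 'non_threatened' or 'threatened')")
    out$status <- factor(st, levels = c("non_threatened", "threatened"))
  } else {
    out$status <- factor(rep("non_threatened", nrow(out)),
                         levels = c("non_threatened", "threatened"))
  }
  for (col in intersect(.trait_columns, names(raw))) {
    v <- raw[[col]]
    v[v %in% na_token] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", v[bad[1L]], "' in column '", col,
           "', row ", bad[1L])
    out[[col]] <- num
  }
  if ("p50" %in% names(out) && any(out$p50 > 0, na.rm = TRUE))
    warning("positive p50 values found; p50 is a (negative) water potential")
  if ("pn" %in% names(out) && any(out$pn <= 0, na.rm = TRUE))
    warning("non-positive pn values found")
  out
}

#' Write a species trait table
#'
#' Inverse of [read_species_table()]: writes the canonical columns as
#' delimited text so a table round-trips value-identically.
#'
#' @param records data.frame as returned by [read_species_table()].
#' @param path output path.
#' @param sep field separator.
#' @param na_token token used for missing values.
#' @return the path, invisibly.
#' @export
write_species_table <- function(records, path, sep = ",", na_token = "NA") {
  utils::write.table(records, path, sep = sep, na = na_token,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a phylogeny with a species trait table
#'
#' Prunes the tree to species that are present in the table and have
#' non-missing values for every column in `required`, drops table rows with
#' no matching tip, and reorders the surviving rows to tip order.  Matching
#' is exact on canonical names (see [canonical_species()]).  The operation
#' is idempotent.
#'
#' @param tree a `"phylo"` object.
#' @param records a species `data.frame` (see [read_species_table()]).
#' @param required character vector of column names that must be
#'   non-missing for a species to be retained.
#' @return an object of class `"ecophylo_data"`: a list with elements
#'   `tree` (pruned phylo), `data` (records in tip order, row names =
#'   species) and `dropped` (list of names dropped from each side).
#' @export
align_tree_and_table <- function(tree, records, required = character()) {
  tree <- validate_phylo(tree)
  if (inherits(records, "ecophylo_data")) records <- records$data
  records$species <- canonical_species(records$species)
  bad <- setdiff(required, names(records))
  if (length(bad))
    stop("required column(s) absent from table: ", paste(bad, collapse = ", "))
  complete <- rep(TRUE, nrow(records))
  for (col in required) complete <- complete & !is.na(records[[col]])
  keep <- intersect(tree$tip.label, records$species[complete])
  if (length(keep) < 3L)
    stop("fewer than 3 species shared between tree and (complete) table; ",
         "comparative methods are undefined")
  dropped_tree <- setdiff(tree$tip.label, keep)
  dropped_table <- setdiff(records$species, keep)
  pruned <- if (length(dropped_tree))
    ape::drop.tip(tree, dropped_tree) else tree
  data <- records[match(pruned$tip.label, records$species), , drop = FALSE]
  rownames(data) <- data$species
  structure(list(tree = pruned, data = data,
                 dropped = list(tree = dropped_tree, table = dropped_table)),
            class = "ecophylo_data")
}

#' @export
print.ecophylo_data <- function(x, ...) {
  cat("Aligned comparative dataset:", length(x$tree$tip.label),
      "species\n")
  cat("  traits:", paste(setdiff(names(x$data), c("species", "status")),
                         collapse = ", "), "\n")
  if ("status" %in% names(x$data))
    cat("  threatened:", sum(x$data$status == "threatened", na.rm = TRUE),
        "\n")
  nd <- lengths(x$dropped)
  if (any(nd > 0))
    cat("  dropped:", nd[["tree"]], "tips,", nd[["table"]], "table rows\n")
  invisible(x)
}

# subset an aligned dataset to rows satisfying a status filter and having
# complete values for 'needed'; reprunes the tree.
subset_aligned <- function(x, subset = c("all", "non_threatened",
                                         "threatened"),
                           needed = character()) {
  stopifnot(inherits(x, "ecophylo_data"))
  subset <- match.arg(subset)
  keep <- rep(TRUE, nrow(x$data))
  if (subset != "all") keep <- keep & (as.character(x$data$status) == subset)
  for (col in needed) keep <- keep & !is.na(x$data[[col]])
  sp <- x$data$species[keep]
  if (length(sp) < 3L)
    stop("subset '", subset, "' leaves fewer than 3 complete species")
  align_tree_and_table(x$tree, x$data[keep, , drop = FALSE])
}
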