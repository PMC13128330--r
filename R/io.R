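# Readers/writers for the package's plain-text exchange formats.
# Matrix dialect: TSV (CSV via `sep`), header row = ids, first column =
# ids, "." decimal point.

#' Read / write a similarity matrix
#'
#' @param path file path.
#' @param sep field separator (`"\t"` default; `","` for CSV).
#' @return `read_similarity` returns a validated similarity matrix.
#' @export
read_similarity <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("similarity matrix in ", path, " is not numeric")
  as_similarity(M, ids = rownames(df))
}

#' @rdname read_similarity
#' @param W similarity matrix to write.
#' @export
write_similarity <- function(W, path, sep = "\t") {
  df <- data.frame(id = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix (rows = items, header = feature names)
#'
#' @param path file path.
#' @param sep field separator.
#' @return numeric matrix with item ids as rownames.
#' @export
read_features <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read item labels (two-column TSV: item, label)
#'
#' @param path file path.
#' @param sep field separator.
#' @return named character vector item -> label.
#' @export
read_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  out <- as.character(df[[2]])
  names(out) <- as.character(df[[1]])
  out
}

#' Read a child-parent ontology edge list
#'
#' Two-column TSV (`child`, `parent`); the DAG must be acyclic.
#'
#' @param path file path.
#' @param sep field separator.
#' @return ontology list with `parents`, `terms`, `root`.
#' @export
read_ontology_edges <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  parents <- split(as.character(df[[2]]), as.character(df[[1]]))
  terms <- unique(c(df[[1]], df[[2]]))
  roots <- setdiff(terms, names(parents))
  for (t in names(parents)) {  # cycle check via ancestor closure
    if (t %in% ontology_ancestors(list(parents = parents), t)) {
      stop("ontology edge list contains a cycle through '", t, "'")
    }
  }
  list(parents = parents, terms = terms, root = roots)
}

#' Write an ontology as a child-parent edge TSV
#' @param ontology ontology list.
#' @param path file path.
#' @export
write_ontology_edges <- function(ontology, path) {
  df <- do.call(rbind, lapply(names(ontology$parents), function(ch) {
    data.frame(child = ch, parent = ontology$parents[[ch]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write merge tables as TSV
#'
#' @param tree a [mergetree()].
#' @param path file path.
#' @return `read_merge_table` returns a [mergetree()].
#' @export
write_merge_table <- function(tree, path) {
  utils::write.table(to_merge_table(tree), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_merge_table
#' @export
read_merge_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  from_merge_table(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
}

#' Read a rooted binary Newick tree as a mergetree
#'
#' @param path path to a Newick file.
#' @return a [mergetree()].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ph <- ape::read.tree(path)
  if (is.null(ph)) stop("could not parse Newick in ", path)
  n <- length(ph$tip.label)
  kids <- split(ph$edge[, 2], ph$edge[, 1])
  nest <- function(v) {
    if (v <= n) return(v)
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2) {
      stop("tree is not binary (node with ", length(ch), " children)")
    }
    list(nest(ch[1]), nest(ch[2]))
  }
  tree_from_nested(nest(n + 1L), ph$tip.label)
}

#' Write a run manifest
#'
#' Every command writes a JSON manifest with the seed, the parameters
#' and the md5 of each input, sufficient to re-run it bit-identically.
#'
#' @param path output path.
#' @param command command name.
#' @param seed master seed.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths.
#' @export
write_manifest <- function(path, command, seed, params = list(),
                           inputs = character(0)) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("dendroblend")),
    seed = seed,
    params = params,
    inputs = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
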