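#' Read an expression matrix with sample metadata
#'
#' The values file is tab-separated with a header row of sample ids
#' and gene symbols in the first column (duplicates allowed; collapse
#' them with [collapse_probes()]). The metadata file has columns
#' `sample_id`, `day`, `replicate`, `batch`. Lines starting with `#`
#' are ignored in both files.
#'
#' @param path_values path to the expression TSV.
#' @param path_meta path to the sample-metadata TSV.
#' @return a [tn_expr()] object.
#' @export
read_expression <- function(path_values, path_meta) {
  stopifnot(file.exists(path_values), file.exists(path_meta))
  raw <- utils::read.delim(path_values, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  genes <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(body)[bad[1, 2]]))
  dimnames(num) <- list(genes, colnames(body))
  meta <- utils::read.delim(path_meta, comment.char = "#",
                            stringsAsFactors = FALSE)
  tn_expr(num, meta)
}

#' Write an expression matrix and its metadata
#'
#' @param expr a [tn_expr()] object.
#' @param path_values,path_meta output TSV paths.
#' @param header_lines optional character vector written as
#'   `#`-prefixed metadata lines at the top of each file.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(expr, path_values, path_meta,
                             header_lines = NULL) {
  stopifnot(inherits(expr, "tn_expr"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write_tsv_with_header(df, path_values, header_lines)
  write_tsv_with_header(expr$meta, path_meta, header_lines)
  invisible(c(path_values, path_meta))
}

write_tsv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name TAB description TAB member genes. Sets with
#' fewer than three members are retained here; size filtering happens
#' in [run_gsea()].
#'
#' @param path GMT file path.
#' @return a `tn_genesets` named list with a `description` attribute.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!length(f) || !nzchar(trimws(f[1])))
      stop("blank set name on GMT line ", i)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicated member(s) in set '", f[1], "', deduplicated")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- if (length(f) >= 2) f[2] else ""
  }
  structure(sets, description = desc, class = "tn_genesets")
}

#' Write a GMT gene-set file
#'
#' @param sets a `tn_genesets` (or plain named list of character
#'   vectors, optionally with a `description` attribute).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interactome edge list
#'
#' Expects a TSV with header `gene1`, `gene2`, `combined_score`.
#' Scores on STRING's 0-1000 scale are auto-detected (all scores > 1)
#' and divided by 1000; a file mixing both scales is rejected. Edges
#' are kept only when the confidence strictly exceeds
#' `confidence_threshold`; self-loops are dropped and parallel edges
#' keep the maximum confidence. An optional curated extra-edges TSV
#' (`gene1`, `gene2`, optional `direction`) is merged with confidence
#' 1.0, standing in for manually curated interactions.
#'
#' @param path edge-list TSV.
#' @param confidence_threshold strict lower bound on confidence
#'   (default 0.4).
#' @param extra_edges_path optional curated edge TSV.
#' @return igraph object with vertex `name` and edge `confidence`.
#' @export
read_interactome <- function(path, confidence_threshold = 0.4,
                             extra_edges_path = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("edge list needs columns gene1, gene2, combined_score")
  names(df)[1:3] <- c("gene1", "gene2", "combined_score")
  sc <- as.numeric(df$combined_score)
  if (anyNA(sc)) stop("non-numeric combined_score in ", path)
  if (length(sc)) {
    if (max(sc) > 1) {
      if (min(sc) < 1)
        stop("mixed confidence scales: scores both <= 1 and > 1 in ", path)
      sc <- sc / 1000
    }
  }
  df$confidence <- sc
  df <- df[df$gene1 != df$gene2, , drop = FALSE]          # self-loops
  df <- df[df$confidence > confidence_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    df[, c("gene1", "gene2", "confidence")], directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
  if (!is.null(extra_edges_path)) {
    ex <- utils::read.delim(extra_edges_path, comment.char = "#",
                            stringsAsFactors = FALSE)
    names(ex)[1:2] <- c("gene1", "gene2")
    ex <- ex[ex$gene1 != ex$gene2, , drop = FALSE]
    newv <- setdiff(unique(c(ex$gene1, ex$gene2)), igraph::V(g)$name)
    if (length(newv)) g <- igraph::add_vertices(g, length(newv), name = newv)
    g <- igraph::add_edges(g, rbind(ex$gene1, ex$gene2), confidence = 1.0)
    g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
  }
  g
}

#' Write an interactome (or subgraph) as an edge-list TSV
#'
#' @param graph igraph with edge attribute `confidence`.
#' @param path output path.
#' @param header_lines optional `#` metadata lines.
#' @return invisibly, the path.
#' @export
write_edges <- function(graph, path, header_lines = NULL) {
  el <- igraph::as_edgelist(graph)
  conf <- igraph::E(graph)$confidence
  if (is.null(conf)) conf <- rep(1, nrow(el))
  df <- data.frame(gene1 = el[, 1], gene2 = el[, 2], combined_score = conf)
  write_tsv_with_header(df, path, header_lines)
}

#' Export an annotated network as GraphML
#'
#' Vertex and edge attributes already on the graph (scores, module
#' ids, centralities, confidences) are carried into the file.
#'
#' @param graph igraph object.
#' @param path output `.graphml` path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
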