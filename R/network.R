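# Per-day bipartite miRNA-gene evidence networks: construction, connected
# components, Freeman degree centralization, SIF/GraphML export.

#' Build a bipartite miRNA-gene network
#'
#' One node per distinct miRNA and gene, one undirected edge per couple
#' (parallel evidence collapsed to a simple edge; the sign of the retained
#' record is kept as an edge attribute). miRNA and gene name spaces must
#' be disjoint.
#'
#' @param records couple records with columns `mir`, `gene` and optionally
#'   `sign` and `day` (e.g. output of [collapse_probes()]).
#' @param day if given, restrict to records of this day.
#' @return object of class `mir_network`: list with `mirs`, `genes` and an
#'   `edges` data.frame (`mir`, `gene`, `sign`).
#' @export
build_network <- function(records, day = NULL) {
  if (!is.null(day) && "day" %in% names(records))
    records <- records[records$day == day, , drop = FALSE]
  sign <- if ("sign" %in% names(records)) records$sign
          else rep(NA_character_, nrow(records))
  edges <- data.frame(mir = as.character(records$mir),
                      gene = as.character(records$gene),
                      sign = as.character(sign), stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("mir", "gene")]), , drop = FALSE]
  rownames(edges) <- NULL
  mirs <- unique(edges$mir)
  genes <- unique(edges$gene)
  clash <- intersect(mirs, genes)
  if (length(clash))
    stop("node sets must be disjoint; IDs on both sides: ",
         paste(clash, collapse = ", "))
  structure(list(mirs = mirs, genes = genes, edges = edges),
            class = "mir_network")
}

#' @export
print.mir_network <- function(x, ...) {
  cat(sprintf("<mir_network> %d miRNAs, %d genes, %d edges\n",
              length(x$mirs), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Convert to an igraph object
#' @param net a `mir_network`.
#' @return undirected [igraph::graph] with vertex attribute `type`
#'   (`"mir"`/`"gene"`) and edge attribute `sign`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mir_network"))
  verts <- data.frame(name = c(net$mirs, net$genes),
                      type = c(rep("mir", length(net$mirs)),
                               rep("gene", length(net$genes))),
                      stringsAsFactors = FALSE)
  edges <- net$edges
  edges$sign[is.na(edges$sign)] <- "unknown"
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

# internal: igraph (with type/sign attributes) back to mir_network
from_igraph <- function(g) {
  type <- igraph::vertex_attr(g, "type")
  name <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  sign <- igraph::edge_attr(g, "sign")
  if (is.null(sign)) sign <- rep(NA_character_, nrow(el))
  sign[sign == "unknown"] <- NA_character_
  # orient every edge miR -> gene
  flip <- type[match(el[, 1], name)] != "mir"
  mir <- ifelse(flip, el[, 2], el[, 1])
  gene <- ifelse(flip, el[, 1], el[, 2])
  net <- build_network(data.frame(mir = mir, gene = gene, sign = sign,
                                  stringsAsFactors = FALSE))
  # keep isolated vertices
  net$mirs <- unique(c(net$mirs, name[type == "mir"]))
  net$genes <- unique(c(net$genes, name[type == "gene"]))
  net
}

#' Connected subnetworks
#'
#' Partitions the network into connected components, largest (by node
#' count) first.
#'
#' @param net a `mir_network`.
#' @return list of `mir_network` components.
#' @export
connected_subnetworks <- function(net) {
  stopifnot(inherits(net, "mir_network"))
  if (length(net$mirs) + length(net$genes) == 0) return(list())
  g <- as_igraph(net)
  comp <- igraph::components(g)
  nets <- lapply(seq_len(comp$no), function(i) {
    from_igraph(igraph::induced_subgraph(g, which(comp$membership == i)))
  })
  sizes <- vapply(nets, function(n) length(n$mirs) + length(n$genes),
                  integer(1))
  nets[order(-sizes)]
}

#' Freeman degree centralization
#'
#' \deqn{C = \frac{\sum_i (d_{max} - d_i)}{(n-1)(n-2)}}
#'
#' computed on the undirected simple graph. Equals 1 exactly for a star
#' (one hub connected to all leaves) and 0 for any regular graph;
#' algebraically identical to the NetworkAnalyzer form
#' `(n/(n-2)) * (d_max/(n-1) - density)`.
#'
#' @param net a `mir_network` with at least 3 nodes.
#' @return centralization in \[0, 1\].
#' @export
degree_centralization <- function(net) {
  stopifnot(inherits(net, "mir_network"))
  nodes <- c(net$mirs, net$genes)
  n <- length(nodes)
  if (n < 3) stop("degree centralization is undefined for fewer than 3 nodes")
  deg <- table(factor(c(net$edges$mir, net$edges$gene), levels = nodes))
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Export a network to SIF or GraphML
#'
#' SIF writes one `miR  regulates  gene` line per edge (tab-separated) for
#' import into interactive viewers; GraphML (via igraph) carries the
#' node-type and edge-sign attributes and round-trips losslessly through
#' [import_network()].
#'
#' @param net a `mir_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "mir_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges))
      sprintf("%s\tregulates\t%s", net$edges$mir, net$edges$gene)
    else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' SIF files carry no node-type annotation, so the source column of each
#' interaction is taken as the miRNA side; GraphML restores types and
#' signs exactly.
#'
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @return a `mir_network`.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(build_network(data.frame(mir = character(0),
                                      gene = character(0))))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3))
      stop("malformed SIF line(s) in ", path)
    mat <- do.call(rbind, parts)
    build_network(data.frame(mir = mat[, 1], gene = mat[, 3],
                             stringsAsFactors = FALSE))
  } else {
    from_igraph(igraph::read_graph(path, format = "graphml"))
  }
}
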