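## Interaction networks: graph construction from typed edge lists, degree
## and hub scores, and QTL co-localization of genomic features.

#' Build an interaction graph from a typed edge list
#'
#' `ppi` and `interacts` edges give an undirected graph; `targets` edges a
#' directed one (a single call must use one or the other family).
#' Self-loops and edges touching nodes outside `node_ids` are rejected and
#' reported; duplicate edges are collapsed.
#'
#' @param edges Data frame with `source`, `target`, `kind` (one of `ppi`,
#'   `interacts`, `targets`) and optionally `weight` (>= 0).
#' @param node_ids Character vector of known node ids.
#' @return An igraph graph with a `rejected` attribute (data frame of
#'   dropped edges).
#' @export
build_network <- function(edges, node_ids) {
  stopifnot(all(c("source", "target", "kind") %in% names(edges)))
  bad_kind <- setdiff(unique(edges$kind), c("ppi", "interacts", "targets"))
  if (length(bad_kind) > 0) {
    stop("build_network: unknown edge kind(s): ", paste(bad_kind, collapse = ", "))
  }
  directed_kinds <- unique(edges$kind) %in% "targets"
  if (nrow(edges) > 0 && length(unique(directed_kinds)) > 1) {
    stop("build_network: cannot mix directed (targets) and undirected edges")
  }
  directed <- nrow(edges) > 0 && all(edges$kind == "targets")
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  if (any(edges$weight < 0)) stop("build_network: negative edge weight")

  unknown <- !(edges$source %in% node_ids) | !(edges$target %in% node_ids)
  self <- edges$source == edges$target
  rejected <- edges[unknown | self, , drop = FALSE]
  edges <- edges[!(unknown | self), , drop = FALSE]
  key <- if (directed) {
    paste(edges$source, edges$target, edges$kind)
  } else {
    paste(pmin(edges$source, edges$target),
          pmax(edges$source, edges$target), edges$kind)
  }
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "kind", "weight"), drop = FALSE],
    directed = directed,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "rejected", rejected)
  g
}

#' Degree and hub score of every node
#'
#' Degree is the incident edge count. The hub score is the
#' principal-eigenvector centrality of the adjacency matrix (for directed
#' target graphs, of `A %*% t(A)`, the Kleinberg hub formulation), computed
#' by power iteration to tolerance 1e-10 and normalized so the maximum
#' score is 1. On a disconnected graph the score concentrates on the
#' spectrally dominant component. Graphs without edges get all-zero hub
#' scores.
#'
#' @param graph An igraph graph (e.g. from [build_network()]).
#' @param tol Power iteration convergence tolerance.
#' @return Data frame with `node`, `degree`, `hub_score`.
#' @export
hub_scores <- function(graph, tol = 1e-10) {
  if (igraph::vcount(graph) == 0) stop("hub_scores: empty graph")
  deg <- igraph::degree(graph)
  nodes <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0) {
    hub <- rep(0, length(nodes))
  } else {
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    ## The identity shift keeps the dominant eigenvalue strictly largest in
    ## magnitude (bipartite graphs otherwise make the iteration oscillate)
    ## without changing the eigenvectors.
    step <- if (igraph::is_directed(graph)) {
      function(v) as.numeric(A %*% (Matrix::crossprod(A, v))) + v
    } else {
      function(v) as.numeric(A %*% v) + v
    }
    v <- rep(1, length(nodes))
    for (iter in 1:10000) {
      w <- step(v)
      w <- w / max(w)
      if (max(abs(w - v)) < tol) {
        v <- w
        break
      }
      v <- w
    }
    hub <- v / max(v)
  }
  data.frame(node = nodes, degree = as.integer(deg),
             hub_score = as.numeric(hub), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Co-localize features with QTL regions
#'
#' Flags each feature-QTL pair with >= 1 bp overlap under half-open
#' interval semantics (a feature ending exactly at a QTL start does not
#' overlap). Chromosome mismatches never overlap.
#'
#' @param features Data frame with `id`, `chrom`, `start`, `end`.
#' @param qtl_regions Data frame with `name`, `chrom`, `start`, `end`.
#' @return Logical matrix, features x QTL regions.
#' @export
qtl_colocalize <- function(features, qtl_regions) {
  validate_intervals(features, "features")
  validate_intervals(qtl_regions, "QTL regions")
  out <- matrix(FALSE, nrow(features), nrow(qtl_regions),
                dimnames = list(features$id, qtl_regions$name))
  if (nrow(features) == 0 || nrow(qtl_regions) == 0) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(features),
                                as_granges0(qtl_regions),
                                ignore.strand = TRUE))
  out[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- TRUE
  out
}
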