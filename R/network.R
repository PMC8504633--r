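## Fragment-similarity networks: build from a hit table, components, hubs,
## summary, GraphML/DOT export. Graph machinery is igraph; the semantics
## (node identity, edge collapsing) live here.

.nodeId <- function(domain, cluster, collapsed) {
  if (collapsed) domain else paste(domain, cluster, sep = "_")
}

#' Build a fragment-similarity network from hits
#'
#' One node per distinct (domain, cluster) occurring on either side of a hit;
#' one edge per connected node pair. A domain appearing with two different
#' cluster tags yields two distinct nodes, because the two tags mark
#' different fragment occurrences. Parallel hits between the same node pair
#' (including reciprocal duplicates) collapse into a single edge whose
#' \code{multiplicity} attribute counts them; self-hits are dropped. The
#' build is deterministic given the input order: nodes appear in first-use
#' order.
#'
#' @param hits a \linkS4class{HitSet}.
#' @param collapseClusters if \code{TRUE}, cluster tags are ignored and nodes
#'   are bare domains (non-default).
#' @return a \linkS4class{SimilarityNetwork}.
#' @export
buildNetwork <- function(hits, collapseClusters = FALSE) {
  stopifnot(methods::is(hits, "HitSet"))
  h <- hits@hits
  qn <- .nodeId(h$query_id, h$q_cluster, collapseClusters)
  sn <- .nodeId(h$subject_id, h$s_cluster, collapseClusters)
  nodes <- unique(c(rbind(qn, sn)))        # first-appearance order
  scop <- c(h$q_scop, h$s_scop)[match(nodes, c(qn, sn))]
  domain <- c(h$query_id, h$subject_id)[match(nodes, c(qn, sn))]
  cluster <- c(h$q_cluster, h$s_cluster)[match(nodes, c(qn, sn))]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes, scop = scop,
                            domain = domain, cluster = cluster,
                            fold = sub("^([^.]+\\.[^.]+).*$", "\\1", scop))
  keep <- qn != sn                          # no self-loops
  if (any(keep)) {
    a <- pmin(qn[keep], sn[keep]); b <- pmax(qn[keep], sn[keep])
    key <- paste(a, b, sep = "\r")
    mult <- table(key)[unique(key)]
    first <- !duplicated(key)
    g <- igraph::add_edges(g, rbind(a[first], b[first]),
                           multiplicity = as.integer(mult))
  }
  methods::new("SimilarityNetwork", graph = g, collapsed = collapseClusters)
}

#' Connected components of a similarity network
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @return list of character vectors of node ids (each sorted), ordered by
#'   component size descending, ties broken by the smallest node id.
#' @export
networkComponents <- function(net) {
  stopifnot(methods::is(net, "SimilarityNetwork"))
  g <- net@graph
  if (igraph::gorder(g) == 0L) return(list())
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- lapply(groups, sort)
  sizes <- lengths(groups)
  mins <- vapply(groups, `[`, "", 1L)
  unname(groups[order(-sizes, mins)])
}

#' Most-connected nodes of a similarity network
#'
#' Degrees are computed on collapsed edges (multiplicity ignored).
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @param k how many nodes to return (>= 1); if larger than the node count,
#'   all nodes are returned with a warning.
#' @return data.frame with columns \code{node}, \code{degree}, ordered by
#'   degree descending then node id.
#' @export
networkHubs <- function(net, k) {
  stopifnot(methods::is(net, "SimilarityNetwork"), k >= 1)
  g <- net@graph
  n <- igraph::gorder(g)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d nodes; returning all", k, n),
            call. = FALSE)
    k <- n
  }
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  data.frame(node = names(deg)[ord][seq_len(k)],
             degree = unname(deg[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Summarize a similarity network
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @return list with \code{nNodes}, \code{nEdges}, \code{nComponents},
#'   \code{componentSizes} (descending) and \code{foldCounts} (named integer
#'   vector of node counts per fold).
#' @export
summarizeNetwork <- function(net) {
  stopifnot(methods::is(net, "SimilarityNetwork"))
  comps <- networkComponents(net)
  folds <- igraph::V(net@graph)$fold
  fc <- if (length(folds)) table(folds) else table(character())
  list(nNodes = igraph::gorder(net@graph),
       nEdges = igraph::gsize(net@graph),
       nComponents = length(comps),
       componentSizes = lengths(comps),
       foldCounts = stats::setNames(as.integer(fc), names(fc)))
}

#' Export a similarity network
#'
#' @param net a \linkS4class{SimilarityNetwork}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return invisibly, the path.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "dot")) {
  stopifnot(methods::is(net, "SimilarityNetwork"))
  format <- match.arg(format)
  igraph::write_graph(net@graph, path, format = format)
  invisible(path)
}
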