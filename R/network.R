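#' Construct an undirected simple PPI network
#'
#' The basic data container of the package: an undirected simple graph
#' over labelled nodes (proteins), stored as a deterministic node order
#' plus an integer edge matrix.  Self-loops and duplicate edges are
#' removed on construction.
#'
#' @param edges a two-column matrix or data.frame of edge endpoints
#'   (node labels, or integer indices into `nodes`), possibly empty.
#' @param nodes optional character vector fixing the node set and order;
#'   defaults to the labels in `edges` in order of first occurrence.
#' @return an object of class `ppi_net`: a list with elements `nodes`
#'   (character) and `edges` (m x 2 integer matrix, each row `i < j`,
#'   rows sorted lexicographically).
#' @examples
#' net <- ppi_network(cbind(c("a", "b"), c("b", "c")))
#' net
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    ed <- matrix(integer(0), 0, 2)
    nodes <- as.character(nodes %||% character(0))
    return(new_ppi_net(nodes, ed))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two columns")
  edges <- edges[, 1:2, drop = FALSE]
  if (is.numeric(edges) && !is.null(nodes)) {
    idx <- matrix(as.integer(edges), ncol = 2)
    if (any(idx < 1 | idx > length(nodes))) stop("edge index out of range")
    nodes <- as.character(nodes)
  } else {
    lab <- matrix(as.character(edges), ncol = 2)
    if (is.null(nodes)) {
      nodes <- unique(as.vector(t(lab)))  # first-occurrence order, row-wise
    } else {
      nodes <- as.character(nodes)
      if (!all(lab %in% nodes)) stop("edge endpoint not in `nodes`")
    }
    idx <- matrix(match(lab, nodes), ncol = 2)
  }
  keep <- idx[, 1] != idx[, 2]
  n_loops <- sum(!keep)
  idx <- idx[keep, , drop = FALSE]
  ed <- cbind(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2]))
  o <- order(ed[, 1], ed[, 2])
  ed <- ed[o, , drop = FALSE]
  dup <- duplicated(ed)
  n_dup <- sum(dup)
  ed <- ed[!dup, , drop = FALSE]
  if (n_loops + n_dup > 0) {
    message(sprintf("ppi_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  }
  new_ppi_net(nodes, ed)
}

new_ppi_net <- function(nodes, edges) {
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("i", "j")
  structure(list(nodes = nodes, edges = edges), class = "ppi_net")
}

#' @export
print.ppi_net <- function(x, ...) {
  cat(sprintf("ppi_net: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  if (n_edges(x) > 0) {
    k <- min(5L, n_edges(x))
    shown <- apply(x$edges[seq_len(k), , drop = FALSE], 1,
                   function(e) paste(x$nodes[e], collapse = " -- "))
    cat(paste0("  ", shown, collapse = "\n"), "\n")
    if (n_edges(x) > k) cat(sprintf("  ... and %d more\n", n_edges(x) - k))
  }
  invisible(x)
}

#' Number of nodes / edges of a `ppi_net`
#' @param net a [ppi_network()] object.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node degrees of a `ppi_net`
#' @inheritParams n_nodes
#' @return named integer vector of degrees in node order.
#' @export
degrees <- function(net) {
  d <- tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = n_nodes(net))
  names(d) <- net$nodes
  d
}

#' Convert a `ppi_net` to an igraph object
#' @inheritParams n_nodes
#' @return an undirected [igraph::graph] preserving node order and
#'   isolated nodes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$nodes[net$edges[, 1]],
               to   = net$nodes[net$edges[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Read an undirected edge list from a text file
#'
#' Lines starting with `#` are comments; the first two whitespace- or
#' tab-separated tokens of each remaining line are the edge endpoints
#' (opaque string labels); extra columns are ignored.  Self-loops and
#' duplicate edges are dropped with a message.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_network()] object.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(ppi_network())
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(toks, length, integer(1)) < 2
  if (any(bad)) {
    stop(sprintf("malformed edge list line %d in %s: need two tokens",
                 lineno[which(bad)[1]], path))
  }
  ends <- t(vapply(toks, function(x) x[1:2], character(2)))
  ppi_network(ends)
}

#' Write a `ppi_net` as a tab-separated edge list
#'
#' @inheritParams n_nodes
#' @param path output file path.
#' @return `path`, invisibly.  Note isolated nodes are not representable
#'   in an edge list and are lost on write.
#' @export
write_edgelist <- function(net, path) {
  lab <- cbind(net$nodes[net$edges[, 1]], net$nodes[net$edges[, 2]])
  writeLines(paste(lab[, 1], lab[, 2], sep = "\t"), path)
  invisible(path)
}

#' Connected components of a network
#'
#' @inheritParams n_nodes
#' @return list of `ppi_net` objects, one per connected component,
#'   ordered largest first (ties broken by smallest member index).
#' @export
graph_components <- function(net) {
  if (n_nodes(net) == 0) return(list())
  comp <- igraph::components(as_igraph(net))$membership
  sizes <- table(comp)
  first <- tapply(seq_along(comp), comp, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  lapply(names(sizes)[ord], function(cid) {
    members <- which(comp == as.integer(cid))
    sub_network(net, members)
  })
}

# induced subgraph on a set of node indices (keeps node order)
sub_network <- function(net, members) {
  members <- sort(members)
  keep <- net$edges[, 1] %in% members & net$edges[, 2] %in% members
  remap <- match(seq_len(n_nodes(net)), members)
  ed <- net$edges[keep, , drop = FALSE]
  ed <- cbind(remap[ed[, 1]], remap[ed[, 2]])
  new_ppi_net(net$nodes[members], matrix(as.integer(ed), ncol = 2,
                                         dimnames = list(NULL, c("i", "j"))))
}

#' Sample distinct non-adjacent node pairs uniformly
#'
#' Used both for negative sampling in the embedding objective and for
#' evaluation against non-interacting pairs.
#'
#' @inheritParams n_nodes
#' @param count number of non-edges to draw.
#' @param seed integer seed; the draw is reproducible and leaves the
#'   caller's RNG stream untouched.
#' @return `count` x 2 integer matrix of node-index pairs (`i < j`).
#' @export
sample_non_edges <- function(net, count, seed = 1) {
  n <- n_nodes(net)
  total <- n * (n - 1) / 2
  n_non <- total - n_edges(net)
  if (count > n_non) {
    stop(sprintf("requested %d non-edges but only %d exist", count, n_non))
  }
  if (count == 0) return(matrix(integer(0), 0, 2))
  edge_keys <- pair_index(net$edges[, 1], net$edges[, 2], n)
  with_seed(seed, {
    if (total <= 5e6) {
      pool <- setdiff(seq_len(total), edge_keys)
      ks <- if (length(pool) == 1) pool else sample(pool, count)
    } else {
      ks <- integer(0)
      while (length(ks) < count) {
        cand <- ceiling(runif(2 * (count - length(ks))) * total)
        cand <- setdiff(unique(cand), c(edge_keys, ks))
        ks <- c(ks, cand)
      }
      ks <- ks[seq_len(count)]
    }
    pu <- pair_unindex(ks, n)
    colnames(pu) <- c("i", "j")
    pu
  })
}

#' All non-adjacent pairs of a network
#'
#' Exhaustive complement of the edge set; only sensible for networks
#' small enough that the quadratic pair count fits in memory.
#'
#' @inheritParams n_nodes
#' @return m x 2 integer matrix of all non-edges (`i < j`).
#' @export
all_non_edges <- function(net) {
  n <- n_nodes(net)
  total <- n * (n - 1) / 2
  if (total > 5e7) stop("network too large to enumerate all non-edges")
  keys <- setdiff(seq_len(total), pair_index(net$edges[, 1], net$edges[, 2], n))
  pu <- pair_unindex(keys, n)
  colnames(pu) <- c("i", "j")
  pu
}

# dense logical adjacency matrix (desk-scale only)
adjacency_logical <- function(net) {
  n <- n_nodes(net)
  A <- matrix(FALSE, n, n)
  if (n_edges(net) > 0) {
    A[net$edges] <- TRUE
    A[net$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  A
}
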