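#' Hydrogen-suppressed molecular graphs
#'
#' A molecular graph is the simple undirected graph of heavy atoms: hydrogens
#' are omitted, bond order is ignored (a double bond contributes one edge),
#' and every vertex is a heavy atom identified by an opaque label.  All
#' degree-based topological indices in this package are computed on this
#' representation.
#'
#' @param edges a two-column character matrix or data frame, one row per
#'   bond; a length-two character vector is taken as a single edge.
#' @param allow_disconnected keep a disconnected graph instead of raising an
#'   error.  Disconnected input almost always indicates a transcription
#'   mistake (the study molecules are single covalent structures), so the
#'   default is to refuse it.
#'
#' @return An object of class \code{"molgraph"}: a list with elements
#'   \code{vertices} (character), \code{edges} (two-column character matrix)
#'   and \code{degrees} (named integer vector).
#'
#' @examples
#' k2 <- molecular_graph(c("a", "b"))
#' degree_spectrum(k2)
#'
#' @seealso [read_edgelist()], [edge_partition()], [degree_spectrum()]
#' @export
molecular_graph <- function(edges, allow_disconnected = FALSE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.character(edges) && is.null(dim(edges))) {
    if (length(edges) != 2L)
      stop_molgraph("an edge vector must have exactly two vertex labels")
    edges <- matrix(edges, ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop_molgraph("'edges' must be a two-column matrix of vertex labels")
  edges <- matrix(trimws(as.character(edges)), ncol = 2L)
  if (nrow(edges) == 0L)
    stop_molgraph("a molecular graph needs at least one edge")
  if (any(!nzchar(edges)) || anyNA(edges))
    stop_molgraph("empty or missing vertex labels")

  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops))
    stop_molgraph(sprintf(
      "self-loop on vertex '%s' (edge %d)",
      edges[which(loops)[1L], 1L], which(loops)[1L]))

  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key))
    stop_molgraph(sprintf(
      "duplicate edge {%s} (edge %d); bond order must not be encoded as parallel edges",
      key[which(duplicated(key))[1L]], which(duplicated(key))[1L]))

  vertices <- unique(c(t(edges)))  # first-appearance order, reproducible
  degrees <- integer(length(vertices))
  names(degrees) <- vertices
  tab <- table(factor(c(edges), levels = vertices))
  degrees[names(tab)] <- as.integer(tab)

  comp <- graph_components(vertices, edges)
  if (max(comp) > 1L && !allow_disconnected) {
    small <- names(comp)[comp == comp[which.min(tabulate(comp)[comp])]]
    stop_molgraph(sprintf(
      "graph is disconnected (%d components; one component is {%s})",
      max(comp), paste(utils::head(small, 8L), collapse = ", ")))
  }

  structure(
    list(vertices = vertices, edges = edges, degrees = degrees),
    class = "molgraph")
}

stop_molgraph <- function(msg) {
  stop(errorCondition(msg, class = c("molgraph_error", "error", "condition")))
}

# connected-component labels via breadth-first search (base R on purpose:
# the validator must not depend on the structures it validates)
graph_components <- function(vertices, edges) {
  idx <- seq_along(vertices)
  names(idx) <- vertices
  adj <- vector("list", length(vertices))
  for (i in seq_len(nrow(edges))) {
    a <- idx[[edges[i, 1L]]]; b <- idx[[edges[i, 2L]]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(length(vertices))
  cur <- 0L
  for (s in idx) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  names(comp) <- vertices
  comp
}

#' Read a molecular graph from an edge-list file
#'
#' The format is one bond per line, two whitespace-separated vertex labels;
#' \code{#} starts a comment.  This is the on-disk form of the packaged drug
#' fixtures and of the synthetic-data writer.
#'
#' @param path path to an edge-list file.
#' @param allow_disconnected passed on to [molecular_graph()].
#' @return A \code{"molgraph"} object.
#' @export
read_edgelist <- function(path, allow_disconnected = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  tokens <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nbad <- lengths(tokens) != 2L
  if (any(nbad)) {
    lineno <- which(keep)[which(nbad)[1L]]
    stop_molgraph(sprintf(
      "%s:%d: expected two vertex labels, found %d",
      path, lineno, lengths(tokens)[which(nbad)[1L]]))
  }
  edges <- do.call(rbind, tokens)
  withCallingHandlers(
    molecular_graph(edges, allow_disconnected = allow_disconnected),
    molgraph_error = function(e) {
      stop_molgraph(sprintf("%s: %s", path, conditionMessage(e)))
    })
}

#' Degree spectrum of a molecular graph
#'
#' Counts the vertices at each degree.  The counts always satisfy the
#' handshake lemma: \eqn{\sum_d d \cdot n_d = 2|E|}.
#'
#' @param g a \code{"molgraph"}.
#' @return A named integer vector; names are the degree values.
#' @export
degree_spectrum <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  tab <- table(g$degrees)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Edge partition by endpoint degrees
#'
#' Groups the edges of a molecular graph into classes by the unordered pair
#' of endpoint degrees \eqn{(d_s, d_t)}, the computational intermediate from
#' which every index in this package can be evaluated class-wise.
#'
#' @param g a \code{"molgraph"}.
#' @return An object of class \code{"edge_partition"}: a data frame with
#'   columns \code{d1} (\eqn{\min}), \code{d2} (\eqn{\max}) and \code{freq},
#'   ordered by \code{(d1, d2)}.  Frequencies sum to \eqn{|E|}.
#' @examples
#' g <- molecular_graph(rbind(c("a", "b"), c("b", "c")))
#' edge_partition(g)
#' @export
edge_partition <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  d <- g$degrees
  ds <- d[g$edges[, 1L]]
  dt <- d[g$edges[, 2L]]
  d1 <- pmin(ds, dt)
  d2 <- pmax(ds, dt)
  agg <- stats::aggregate(
    list(freq = rep(1L, length(d1))),
    by = list(d1 = d1, d2 = d2), FUN = sum)
  agg <- agg[order(agg$d1, agg$d2), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("edge_partition", "data.frame"),
            n_edges = nrow(g$edges))
}

#' Relabel the vertices of a molecular graph
#'
#' Applies a bijection on vertex labels and returns the isomorphic graph.
#' All degree-based summaries and indices are invariant under relabelling;
#' this operation exists to make that property testable.
#'
#' @param g a \code{"molgraph"}.
#' @param permutation a named character vector mapping every old label to a
#'   new label; must be a bijection on the vertex set.
#' @return A \code{"molgraph"} with the same topology and new labels.
#' @export
relabel <- function(g, permutation) {
  stopifnot(inherits(g, "molgraph"))
  if (is.null(names(permutation)) ||
      !setequal(names(permutation), g$vertices) ||
      length(permutation) != length(g$vertices))
    stop_molgraph("'permutation' must be named by all current vertex labels")
  if (anyDuplicated(permutation) || anyNA(permutation))
    stop_molgraph("'permutation' must be a bijection (unique new labels)")
  new_edges <- matrix(permutation[c(g$edges)], ncol = 2L)
  molecular_graph(new_edges)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("Molecular graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  spec <- degree_spectrum(x)
  cat("Degree spectrum:",
      paste(sprintf("%s:%d", names(spec), spec), collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.edge_partition <- function(x, ...) {
  cat(sprintf("Edge partition (%d edges):\n", attr(x, "n_edges")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
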