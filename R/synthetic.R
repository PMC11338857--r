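#' Random chemical-like molecular graphs
#'
#' Generates a connected simple graph with all degrees in
#' \code{[1, max_degree]}, emulating a hydrogen-suppressed organic skeleton
#' (the default degree cap of 4 is the heavy-atom valence proxy).  The
#' construction draws a random spanning tree first -- each new vertex
#' attaches to a uniformly chosen existing vertex with spare valence, which
#' guarantees connectivity -- and then adds random extra edges subject to
#' the cap, creating rings.
#'
#' @param n_vertices number of heavy atoms (\eqn{\ge 2}).
#' @param max_degree maximum vertex degree (default 4).
#' @param extra_edges number of ring-forming edges to attempt beyond the
#'   spanning tree; \code{NULL} draws it uniformly from
#'   \code{0:floor(n_vertices / 5)}.
#' @param seed optional integer; when given, generation is a pure function
#'   of the seed (the caller's RNG state is saved and restored).
#' @return A \code{"molgraph"} with vertices \code{v1 ... vn}.
#' @examples
#' g <- random_molecular_graph(12, seed = 1)
#' max(g$degrees) <= 4
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4L,
                                   extra_edges = NULL, seed = NULL) {
  if (n_vertices < 2L) stop("'n_vertices' must be at least 2")
  if (max_degree < 1L) stop("'max_degree' must be at least 1")
  if (max_degree == 1L && n_vertices > 2L)
    stop("infeasible constraints: a connected graph on more than two ",
         "vertices needs max_degree >= 2")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }

  labels <- paste0("v", seq_len(n_vertices))
  deg <- integer(n_vertices)
  edges <- matrix(character(), ncol = 2L)
  # spanning tree
  for (i in seq_len(n_vertices)[-1L]) {
    open <- which(deg[seq_len(i - 1L)] < max_degree)
    if (!length(open))
      stop("infeasible constraints: no vertex with spare valence")
    j <- open[sample.int(length(open), 1L)]
    edges <- rbind(edges, c(labels[j], labels[i]))
    deg[j] <- deg[j] + 1L
    deg[i] <- deg[i] + 1L
  }
  # ring-forming extras
  if (is.null(extra_edges))
    extra_edges <- sample.int(floor(n_vertices / 5) + 1L, 1L) - 1L
  present <- paste(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
  added <- 0L
  while (added < extra_edges) {
    open <- which(deg < max_degree)
    if (length(open) < 2L) break
    cand <- t(utils::combn(open, 2L))
    key <- paste(pmin(labels[cand[, 1L]], labels[cand[, 2L]]),
                 pmax(labels[cand[, 1L]], labels[cand[, 2L]]))
    cand <- cand[!key %in% present, , drop = FALSE]
    if (!nrow(cand)) break
    pick <- cand[sample.int(nrow(cand), 1L), ]
    a <- labels[pick[1L]]; b <- labels[pick[2L]]
    edges <- rbind(edges, c(a, b))
    present <- c(present, paste(min(a, b), max(a, b)))
    deg[pick] <- deg[pick] + 1L
    added <- added + 1L
  }
  molecular_graph(edges)
}

#' Specification for a synthetic QSPR study
#'
#' Bundles the ground truth of a simulated structure-property experiment:
#' random graphs provide the topological index, and the property is the
#' chosen family's curve evaluated at the index plus Gaussian noise.
#'
#' Defaults mirror the reproduced study's strongest model (molecular weight
#' on a degree-based index over 15 molecules): \code{A = 50.608},
#' \code{b = 38.815}, \code{noise_sd = 30} (about the residual standard
#' deviation of that fit), \code{n_molecules = 15}, graphs of 5--40 heavy
#' atoms with degree cap 4.
#'
#' @param n_molecules number of simulated molecules.
#' @param vertex_range two integers: inclusive range of graph sizes.
#' @param max_degree degree cap for the graph generator.
#' @param family \code{"linear"}, \code{"quadratic"} or
#'   \code{"logarithmic"} generating curve.
#' @param A,b,c true generating coefficients (\code{c} is used only by the
#'   quadratic family).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (\eqn{\ge 0}), in property units.
#' @param index which index supplies the predictor (one of \code{"ABC_R"},
#'   \code{"GA"}, \code{"SDD"}, \code{"GAPi"}, \code{"lnEPi1"},
#'   \code{"lnEPi2"}).
#' @param seed integer seed; the simulation is a pure function of it.
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_molecules = 15L, vertex_range = c(5L, 40L),
                           max_degree = 4L, family = c("linear", "quadratic",
                                                       "logarithmic"),
                           A = 50.608, b = 38.815, c = 0,
                           noise_sd = 30, index = "ABC_R", seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_molecules >= 1L, length(vertex_range) == 2L,
            vertex_range[1L] >= 2L, vertex_range[2L] >= vertex_range[1L],
            max_degree >= 1L, noise_sd >= 0, is.numeric(seed))
  index <- match.arg(index, c("ABC_R", "GA", "SDD", "GAPi",
                              "lnEPi1", "lnEPi2"))
  structure(list(n_molecules = as.integer(n_molecules),
                 vertex_range = as.integer(vertex_range),
                 max_degree = as.integer(max_degree), family = family,
                 A = A, b = b, c = c, noise_sd = noise_sd,
                 index = index, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a paired index/property table with known ground truth
#'
#' Draws \code{spec$n_molecules} random molecular graphs, computes the
#' chosen index on each, and generates the property as
#' \code{family(A, b, c)(TI)} plus \code{N(0, noise_sd^2)} noise.  This is
#' the inverse of the fitting problem, so [qspr_fit()] applied to the output
#' should recover \code{(A, b, c)} as the noise vanishes.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with \code{data} (data frame: \code{molecule}, \code{TI},
#'   \code{property}), \code{truth} (the spec), and \code{graphs} (list of
#'   \code{"molgraph"}).
#' @export
simulate_property_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  pool <- seq(spec$vertex_range[1L], spec$vertex_range[2L])
  sizes <- pool[sample.int(length(pool), spec$n_molecules, replace = TRUE)]
  graphs <- lapply(sizes, function(nv)
    random_molecular_graph(nv, max_degree = spec$max_degree))
  ti <- vapply(graphs, function(g) {
    ix <- compute_indices(g, contribution_digits = NULL)
    switch(spec$index,
           ABC_R = ix$ABC_R$value, GA = ix$GA$value, SDD = ix$SDD$value,
           GAPi = ix$GAPi$value, lnEPi1 = ix$EPi1$ln, lnEPi2 = ix$EPi2$ln)
  }, numeric(1L))

  mean_curve <- switch(spec$family,
    linear = spec$A + spec$b * ti,
    quadratic = spec$A + spec$b * ti + spec$c * ti^2,
    logarithmic = {
      if (any(ti <= 0))
        stop(errorCondition(
          "logarithmic generating family requires positive index values",
          class = c("qspr_domain_error", "qspr_error", "error", "condition")))
      spec$A + spec$b * log(ti)
    })
  prop <- mean_curve + stats::rnorm(spec$n_molecules, 0, spec$noise_sd)
  list(data = data.frame(molecule = paste0("m", seq_along(ti)),
                         TI = ti, property = prop),
       truth = spec, graphs = graphs)
}
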