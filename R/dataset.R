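#' The 15-drug study dataset
#'
#' The package ships a curated reproduction dataset of fifteen repurposed
#' non-cancer drugs: a hydrogen-suppressed edge-list graph per drug, the six
#' physicochemical properties used as regression responses (melting point MP
#' in deg C, boiling point BP in deg C, water solubility WS in mg/mL, density
#' D in g/cm^3, vapour pressure VP in mmHg, molecular weight MW in g/mol),
#' and the descriptor table as published by the source study, annotated with
#' an errata layer (see [published_index_table()]).
#'
#' Graph fixtures were transcribed from the drugs' standard 2D structures
#' and validated against the two descriptor columns that withstand
#' independent hand-verification (ABC-R and SDD).  Three fixtures follow the
#' study's drawings where those demonstrably differ from the canonical
#' structures; each such file carries a \code{depiction_note} in its
#' metadata.
#'
#' @return \code{drug_records()}: a named list of class \code{"drug_set"};
#'   each element is a list with \code{name}, \code{graph} (a
#'   \code{"molgraph"}), \code{properties} (named numeric vector of the six
#'   properties) and optional \code{smiles} / \code{depiction_note}
#'   documentation fields.  Order follows the study's table order and is
#'   stable.
#' @examples
#' drugs <- drug_records()
#' drugs[["Thalidomide"]]$graph      # 19 vertices, 21 edges
#' @export
drug_records <- function() {
  meta <- jsonlite::fromJSON(pkg_extdata("drugs.json"),
                             simplifyDataFrame = FALSE)
  props <- drug_properties()
  out <- lapply(meta, function(m) {
    graph <- tryCatch(
      read_edgelist(pkg_extdata(m$file)),
      error = function(e) stop("corrupted fixture for record '", m$name,
                               "': ", conditionMessage(e), call. = FALSE))
    if (length(graph$vertices) != m$n_vertices ||
        nrow(graph$edges) != m$n_edges)
      stop("corrupted fixture for record '", m$name,
           "': vertex/edge counts disagree with metadata", call. = FALSE)
    row <- props[props$Name == m$name, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("corrupted fixture: no property row for record '", m$name, "'",
           call. = FALSE)
    pr <- unlist(row[, c("MP", "BP", "WS", "D", "VP", "MW")])
    if (anyNA(pr) || pr[["MW"]] <= 0 || pr[["D"]] <= 0)
      stop("corrupted fixture: invalid properties for record '", m$name, "'",
           call. = FALSE)
    rec <- list(name = m$name, graph = graph, properties = pr)
    rec$smiles <- m$smiles
    rec$depiction_note <- m$depiction_note
    class(rec) <- "drug_record"
    rec
  })
  names(out) <- vapply(meta, `[[`, "", "name")
  structure(out, class = c("drug_set", "list"))
}

pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "topoqspr", mustWork = TRUE)
}

#' @rdname drug_records
#' @return \code{drug_properties()}: a 15-row data frame with columns
#'   \code{Name}, \code{MP}, \code{BP}, \code{WS}, \code{D}, \code{VP},
#'   \code{MW}, bit-equal to the study's property table.
#' @export
drug_properties <- function() {
  utils::read.csv(pkg_extdata("properties.csv"), stringsAsFactors = FALSE)
}

#' Published descriptor table with errata annotations
#'
#' The descriptor table as printed by the source study, cell by cell, plus
#' an annotation layer.  \code{Status} classifies each printed cell against
#' the structure-derived value: \code{"verbatim"} (agrees within 5e-4
#' relative), \code{"rounding"} (within 2e-3) or \code{"erratum"}.
#' \code{Corrected} is non-missing only where the study's own material
#' pins down the intended value (its worked example, or an exponential-index
#' cell whose printed mantissa matches the structure-derived one while the
#' power of ten was dropped or mistyped); all other cells -- including
#' defective ones -- stay verbatim so that reproduction runs see exactly the
#' inputs the study's regressions used.
#'
#' @return A data frame with columns \code{Name}, \code{Index} (one of
#'   \code{ABC_R}, \code{GA}, \code{EPi1}, \code{EPi2}, \code{GAPi},
#'   \code{SDD}), \code{Published} (string as printed), \code{Value}
#'   (numeric parse of \code{Published}), \code{Status}, \code{Corrected}
#'   (numeric or \code{NA}) and \code{Note}.
#' @export
published_index_table <- function() {
  tbl <- utils::read.csv(pkg_extdata("published_indices.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  tbl$Value <- as.numeric(tbl$Published)
  tbl$Corrected <- suppressWarnings(as.numeric(tbl$Corrected))
  tbl[c("Name", "Index", "Published", "Value", "Status", "Corrected", "Note")]
}

#' Descriptor matrix computed from the fixture graphs
#'
#' Evaluates all six indices on every drug graph.  Exponential indices are
#' reported as exact integer log-values, as linear values (all fixture
#' magnitudes are representable in double precision) and as
#' mantissa/exponent strings.
#'
#' @param drugs a \code{"drug_set"}, by default [drug_records()].
#' @return A 15-row data frame: \code{Name}, \code{ABC_R}, \code{GA},
#'   \code{SDD}, \code{GAPi}, \code{lnEPi1}, \code{lnEPi2}, \code{EPi1},
#'   \code{EPi2}, \code{EPi1_sci}, \code{EPi2_sci}.
#' @export
computed_index_table <- function(drugs = drug_records()) {
  rows <- lapply(drugs, function(rec) {
    cbind(Name = rec$name, as.data.frame(compute_indices(rec$graph)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconcile computed and published descriptor values
#'
#' Compares the structure-derived descriptor matrix with the published one,
#' cell by cell, and classifies every cell as \code{"match"} (within 5e-4
#' relative), \code{"rounding"} (within 2e-3) or \code{"erratum"}.
#'
#' @param computed data frame from [computed_index_table()].
#' @param published data frame from [published_index_table()].
#' @return A data frame of class \code{"discrepancy_report"} with columns
#'   \code{Name}, \code{Index}, \code{published}, \code{computed},
#'   \code{rel_diff} and \code{classification}.
#' @export
discrepancy_report <- function(computed = computed_index_table(),
                               published = published_index_table()) {
  idx_names <- c("ABC_R", "GA", "EPi1", "EPi2", "GAPi", "SDD")
  need <- expand.grid(Name = unique(published$Name), Index = idx_names,
                      stringsAsFactors = FALSE)
  have <- paste(published$Name, published$Index)
  if (!all(paste(need$Name, need$Index) %in% have))
    stop("published table does not cover all drug/index cells")
  if (!all(unique(published$Name) %in% computed$Name))
    stop("computed table does not cover all drugs")

  rows <- lapply(seq_len(nrow(published)), function(i) {
    nm <- published$Name[i]; ix <- published$Index[i]
    comp <- computed[computed$Name == nm, ix]
    pub <- published$Value[i]
    rel <- abs(comp - pub) / max(abs(comp), .Machine$double.xmin)
    cls <- if (rel <= 5e-4) "match" else if (rel <= 2e-3) "rounding" else "erratum"
    data.frame(Name = nm, Index = ix, published = pub, computed = comp,
               rel_diff = rel, classification = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("discrepancy_report", "data.frame"))
}

#' @export
print.discrepancy_report <- function(x, ...) {
  tab <- table(x$classification)
  cat(sprintf("Discrepancy report: %d cells (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  bad <- x[x$classification != "match", , drop = FALSE]
  if (nrow(bad)) print.data.frame(bad, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Assemble aligned regression inputs
#'
#' Builds the 15 x 6 index matrix and 15 x 6 property matrix that feed the
#' QSPR regressions, in fixed drug order.
#'
#' @param source which descriptor values to use: \code{"published"} (the
#'   study's table verbatim, defective cells included), \code{"computed"}
#'   (structure-derived values), or \code{"published_with_corrections"}
#'   (published values with only the documented corrected cells replaced;
#'   see [published_index_table()]).
#' @return A list with elements \code{indices} (data frame: \code{Name},
#'   the six index columns, plus \code{lnEPi1}/\code{lnEPi2} log-scale
#'   columns) and \code{properties} (data frame: \code{Name} plus the six
#'   property columns).
#' @export
regression_input_table <- function(source = c("published", "computed",
                                              "published_with_corrections")) {
  source <- match.arg(source)
  props <- drug_properties()
  idx_names <- c("ABC_R", "GA", "EPi1", "EPi2", "GAPi", "SDD")

  if (source == "computed") {
    comp <- computed_index_table()
    ind <- comp[c("Name", idx_names)]
    ind$lnEPi1 <- comp$lnEPi1
    ind$lnEPi2 <- comp$lnEPi2
  } else {
    pub <- published_index_table()
    val <- pub$Value
    if (source == "published_with_corrections") {
      repl <- !is.na(pub$Corrected)
      val[repl] <- pub$Corrected[repl]
    }
    ind <- data.frame(Name = props$Name, stringsAsFactors = FALSE)
    for (ix in idx_names) {
      sel <- pub$Index == ix
      ind[[ix]] <- val[sel][match(props$Name, pub$Name[sel])]
    }
    ind$lnEPi1 <- log(ind$EPi1)
    ind$lnEPi2 <- log(ind$EPi2)
  }
  list(indices = ind,
       properties = props[c("Name", "MP", "BP", "WS", "D", "VP", "MW")])
}
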