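#' Construct a bipartite network
#'
#' A `bipartite_net` stores an unweighted, undirected two-mode network: an
#' ordered vector of drug labels, an ordered vector of disease labels, and a
#' set of edges given as (drug index, disease index) pairs.  Edges connect
#' unlike types only.  Isolated nodes are allowed: a label may be declared
#' without taking part in any edge, which matters because edge holdout can
#' strip a node of all its edges.
#'
#' @param drugs character vector of unique drug labels (first-appearance
#'   order is preserved and fixes the row order of the incidence matrix).
#' @param diseases character vector of unique disease labels.
#' @param edges two-column integer matrix; column 1 indexes into `drugs`,
#'   column 2 into `diseases`.  Duplicate rows are an error (use
#'   [read_edge_list()] to collapse duplicates with a warning).
#' @return an object of class `bipartite_net`.
#' @seealso [read_edge_list()], [incidence_matrix()], [unconnected_pair_count()]
#' @export
bipartite_net <- function(drugs, diseases, edges) {
  drugs <- as.character(drugs)
  diseases <- as.character(diseases)
  if (anyDuplicated(drugs)) stop("duplicate drug labels", call. = FALSE)
  if (anyDuplicated(diseases)) stop("duplicate disease labels", call. = FALSE)
  both <- intersect(drugs, diseases)
  if (length(both) > 0) {
    stop("label(s) appear on both sides (not bipartite): ",
         paste(utils::head(both, 3), collapse = ", "), call. = FALSE)
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] < 1L | edges[, 1] > length(drugs)))
      stop("edge references an invalid drug index", call. = FALSE)
    if (any(edges[, 2] < 1L | edges[, 2] > length(diseases)))
      stop("edge references an invalid disease index", call. = FALSE)
    key <- (edges[, 1] - 1) * length(diseases) + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    edges <- edges[order(key), , drop = FALSE]
  }
  colnames(edges) <- c("drug", "disease")
  structure(list(drugs = drugs, diseases = diseases, edges = edges),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("bipartite network: %d drugs x %d diseases, %d edges (density %.3g)\n",
              n_drugs(x), n_diseases(x), n_edges(x),
              n_edges(x) / (n_drugs(x) * n_diseases(x))))
  invisible(x)
}

#' Node and edge counts
#'
#' @param net a [bipartite_net()].
#' @return a single integer.
#' @export
n_drugs <- function(net) length(net$drugs)

#' @rdname n_drugs
#' @export
n_diseases <- function(net) length(net$diseases)

#' @rdname n_drugs
#' @export
n_edges <- function(net) nrow(net$edges)

# Dense linear index of a (drug, disease) pair; the deterministic secondary
# sort key used to break score ties reproducibly.
pair_index <- function(net, u, v) (u - 1) * n_diseases(net) + v

#' Node degrees
#'
#' @param net a [bipartite_net()].
#' @return integer vector of degrees, one per drug (or disease), including
#'   zeros for isolated nodes.
#' @export
drug_degrees <- function(net) {
  tabulate(net$edges[, 1], nbins = n_drugs(net))
}

#' @rdname drug_degrees
#' @export
disease_degrees <- function(net) {
  tabulate(net$edges[, 2], nbins = n_diseases(net))
}

#' Read a bipartite edge list
#'
#' Reads a delimited text file with one edge per line: drug label, disease
#' label.  Lines starting with `#` are comments, except directive lines
#' `#!drug <label>` / `#!disease <label>` which declare nodes (possibly
#' isolated) ahead of the edges.  Node order is first-appearance order
#' (directives first, then edge lines).  Duplicate edge lines collapse to a
#' single edge with a warning.
#'
#' @param path file to read.
#' @param sep field delimiter (default tab).
#' @return a [bipartite_net()].
#' @export
read_edge_list <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  drug_seen <- character(0)
  dis_seen <- character(0)
  eu <- character(0)
  ev <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#!drug")) {
        lab <- trimws(sub("^#!drug[ \t]+", "", ln))
        drug_seen <- c(drug_seen, lab)
      } else if (startsWith(ln, "#!disease")) {
        lab <- trimws(sub("^#!disease[ \t]+", "", ln))
        dis_seen <- c(dis_seen, lab)
      }
      next
    }
    fields <- strsplit(ln, sep, fixed = TRUE)[[1]]
    if (length(fields) < 2 || !nzchar(fields[1]) || !nzchar(fields[2])) {
      stop(sprintf("malformed line %d in %s: need at least 2 fields", i, path),
           call. = FALSE)
    }
    eu <- c(eu, fields[1])
    ev <- c(ev, fields[2])
  }
  drugs <- unique(c(drug_seen, eu))
  diseases <- unique(c(dis_seen, ev))
  clash <- intersect(drugs, diseases)
  if (length(clash) > 0) {
    stop("label(s) appear as both drug and disease: ",
         paste(utils::head(clash, 3), collapse = ", "), call. = FALSE)
  }
  u <- match(eu, drugs)
  v <- match(ev, diseases)
  key <- paste(u, v)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicated edge line(s) collapsed", sum(duplicated(key))),
            call. = FALSE)
    keep <- !duplicated(key)
    u <- u[keep]; v <- v[keep]
  }
  bipartite_net(drugs, diseases, cbind(u, v))
}

#' Write a bipartite edge list
#'
#' Writes the TSV dialect read by [read_edge_list()], declaring isolated
#' nodes with `#!drug` / `#!disease` directives so that the round trip
#' preserves the node sets exactly.
#'
#' @param net a [bipartite_net()].
#' @param path file to write.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, sep = "\t") {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  iso_u <- which(drug_degrees(net) == 0)
  iso_v <- which(disease_degrees(net) == 0)
  for (i in iso_u) writeLines(paste0("#!drug\t", net$drugs[i]), con)
  for (i in iso_v) writeLines(paste0("#!disease\t", net$diseases[i]), con)
  if (n_edges(net) > 0) {
    writeLines(paste(net$drugs[net$edges[, 1]], net$diseases[net$edges[, 2]],
                     sep = sep), con)
  }
  invisible(path)
}

#' Incidence matrix of a bipartite network
#'
#' The `n_drugs x n_diseases` binary matrix B with `B[u, v] = 1` iff drug u
#' is connected to disease v.  Row sums are drug degrees, column sums are
#' disease degrees.
#'
#' @param net a [bipartite_net()].
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense base
#'   matrix.
#' @return the incidence matrix, with node labels as dimnames.
#' @export
incidence_matrix <- function(net, sparse = TRUE) {
  if (sparse) {
    B <- Matrix::sparseMatrix(i = net$edges[, 1], j = net$edges[, 2], x = 1,
                              dims = c(n_drugs(net), n_diseases(net)))
  } else {
    B <- matrix(0, n_drugs(net), n_diseases(net))
    B[net$edges] <- 1
  }
  dimnames(B) <- list(net$drugs, net$diseases)
  B
}

#' Number of unconnected drug-disease pairs
#'
#' The pool of link-prediction candidates: `n_drugs * n_diseases - m`.
#'
#' @param net a [bipartite_net()].
#' @return a non-negative number (double, to avoid integer overflow on large
#'   networks).
#' @export
unconnected_pair_count <- function(net) {
  as.numeric(n_drugs(net)) * n_diseases(net) - n_edges(net)
}

#' One-line structural summary
#'
#' @param net a [bipartite_net()].
#' @return a named list (n_drugs, n_diseases, m, density) suitable for JSON
#'   serialization.
#' @export
network_summary <- function(net) {
  list(n_drugs = n_drugs(net), n_diseases = n_diseases(net),
       m = n_edges(net),
       density = n_edges(net) / (as.numeric(n_drugs(net)) * n_diseases(net)))
}

# Remove a set of edges (row indices into net$edges), keeping all labels.
drop_edges <- function(net, idx) {
  bipartite_net(net$drugs, net$diseases, net$edges[-idx, , drop = FALSE])
}
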