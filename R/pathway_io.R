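#' Construct a pathway graph
#'
#' A pathway is represented as an undirected, unweighted gene--gene graph:
#' a set of gene symbols plus a set of unordered gene pairs. Self-loops are
#' rejected and duplicate / reversed edges are collapsed to a single edge.
#'
#' @param pathway_id Single pathway identifier string.
#' @param genes Character vector of gene symbols (unique, non-empty).
#' @param edges Two-column character matrix of gene pairs; may be empty.
#' @return An object of class `pathway_graph` with fields `pathway_id`,
#'   `genes`, `edges` (canonicalised, each pair stored once) and an internal
#'   integer adjacency list `adj`.
#' @export
pathway_graph <- function(pathway_id, genes, edges = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  genes <- as.character(genes)
  if (any(!nzchar(genes)) || anyNA(genes)) {
    stop("gene symbols must be non-empty strings")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in pathway ", pathway_id)
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- rbind(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge in pathway ", pathway_id)
  unknown <- setdiff(c(edges), genes)
  if (length(unknown)) {
    stop("edges reference genes absent from the gene set: ",
         paste(unknown, collapse = ", "))
  }
  # canonical order within a pair, then deduplicate
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(gene_a = a[keep], gene_b = b[keep])
  ia <- match(edges[, 1L], genes)
  ib <- match(edges[, 2L], genes)
  adj <- vector("list", length(genes))
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  adj <- lapply(adj, function(v) sort(unique(v %||% integer(0))))
  structure(
    list(pathway_id = pathway_id, genes = genes, edges = edges, adj = adj),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph> ", x$pathway_id, ": ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Read pathway graphs from an edge-list TSV
#'
#' The file holds one edge per row, `pathway_id<TAB>gene_a<TAB>gene_b`.
#' Lines starting with `#` are comments. Reversed duplicates collapse to a
#' single undirected edge; self-loop rows are dropped with a warning but
#' the gene is kept as an isolated node.
#'
#' @param path Path to the TSV file.
#' @return Named list of [pathway_graph] objects, one per distinct
#'   `pathway_id`, in order of first appearance.
#' @export
load_pathway_edgelists <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed pathway edge row at line ", lineno[which(nf != 3L)[1L]],
         ": expected 3 tab-separated columns, got ", nf[nf != 3L][1L])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  # drop a header row if present
  if (identical(tolower(m[1L, ]), c("pathway_id", "gene_a", "gene_b"))) {
    m <- m[-1L, , drop = FALSE]
  }
  if (!nrow(m)) return(list())
  out <- list()
  for (pid in unique(m[, 1L])) {
    rows <- m[m[, 1L] == pid, , drop = FALSE]
    self <- rows[, 2L] == rows[, 3L]
    if (any(self)) {
      warning("pathway ", pid, ": dropped ", sum(self),
              " self-loop edge(s); gene(s) kept as isolated nodes")
    }
    genes <- unique(c(rows[, 2L], rows[, 3L]))
    out[[pid]] <- pathway_graph(pid, genes, rows[!self, 2:3, drop = FALSE])
  }
  out
}

#' Write pathway graphs to an edge-list TSV
#'
#' Isolated genes are written as self-referencing rows only if they have no
#' edges at all; such rows round-trip back to isolated nodes via the
#' self-loop rule of [load_pathway_edgelists()].
#'
#' @param graphs List of [pathway_graph] objects.
#' @param path Output path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @export
write_pathway_edgelists <- function(graphs, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("pathway_id\tgene_a\tgene_b", con)
  for (g in graphs) {
    if (nrow(g$edges)) {
      writeLines(paste(g$pathway_id, g$edges[, 1L], g$edges[, 2L], sep = "\t"), con)
    }
    iso <- setdiff(g$genes, c(g$edges))
    if (length(iso)) {
      writeLines(paste(g$pathway_id, iso, iso, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Parse a minimal KGML pathway file
#'
#' Reads the KEGG XML dialect restricted to `<entry type="gene">` and
#' `<relation>` elements: every relation between two gene entries yields an
#' undirected edge between all gene symbols of the two entries (entries can
#' carry several space-separated names). Non-gene entries (maps, compounds,
#' groups) and relation subtypes are ignored.
#'
#' @param path Path to a KGML file.
#' @return A [pathway_graph]; empty (with a warning) if the file has no
#'   gene entries.
#' @export
parse_kgml_minimal <- function(path) {
  doc <- xml2::read_xml(path)
  pid <- xml2::xml_attr(doc, "name")
  if (is.na(pid)) pid <- basename(path)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  if (!length(entries)) {
    warning("KGML file has no gene entries: ", path)
    return(pathway_graph(pid, character(0)))
  }
  ids <- xml2::xml_attr(entries, "id")
  names_by_id <- lapply(xml2::xml_attr(entries, "name"),
                        function(s) strsplit(trimws(s), "\\s+")[[1L]])
  names(names_by_id) <- ids
  genes <- unique(unlist(names_by_id))
  rel <- xml2::xml_find_all(doc, ".//relation")
  e1 <- xml2::xml_attr(rel, "entry1")
  e2 <- xml2::xml_attr(rel, "entry2")
  edges <- matrix(character(0), ncol = 2L)
  for (k in seq_along(rel)) {
    g1 <- names_by_id[[e1[k]]]
    g2 <- names_by_id[[e2[k]]]
    if (is.null(g1) || is.null(g2)) next  # relation touches a non-gene entry
    pairs <- expand.grid(g1, g2, stringsAsFactors = FALSE)
    pairs <- pairs[pairs[[1L]] != pairs[[2L]], , drop = FALSE]
    if (nrow(pairs)) edges <- rbind(edges, as.matrix(pairs))
  }
  pathway_graph(pid, genes, edges)
}

# Indices of graph nodes adjacent to any member of `idx` (excluding members).
graph_frontier <- function(graph, idx, allowed = NULL) {
  nb <- unique(unlist(graph$adj[idx], use.names = FALSE))
  nb <- setdiff(nb, idx)
  if (!is.null(allowed)) nb <- intersect(nb, allowed)
  nb
}

# Is the induced subgraph on node indices `idx` connected?
induced_connected <- function(graph, idx) {
  if (length(idx) <= 1L) return(TRUE)
  seen <- idx[1L]
  frontier <- idx[1L]
  while (length(frontier)) {
    nb <- intersect(unique(unlist(graph$adj[frontier], use.names = FALSE)), idx)
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(idx)
}
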