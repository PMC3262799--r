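#' Collapse regulators of a gene whose seed sites coincide
#'
#' Two miRNAs hitting one gene through overlapping seed sites may be
#' counted twice for what is a single binding signal (seed-family
#' similarity). Two regulators of a gene are declared seed-similar when the
#' overlap is mutual and complete: every seed site of each overlaps a site
#' of the other (non-empty intersection of 0-based half-open intervals on
#' the same chromosome/transcript). Seed-similar groups (connected
#' components of that relation) are collapsed to a single representative,
#' the lexically smallest miRNA identifier. A regulator with any
#' independent (non-overlapping) site is never collapsed away.
#'
#' @param gene The gene identifier (used for reporting only).
#' @param regulators Data.frame with columns `mirna`, `chrom`, `start`,
#'   `end`: one row per seed site of each regulator of this gene.
#' @return A list with `kept` (character vector of retained miRNAs) and
#'   `collapsed_groups` (list of character vectors; each group was reduced
#'   to its first element).
#' @export
collapse_seed_overlaps <- function(gene, regulators) {
  mirnas <- sort(unique(regulators$mirna))
  n <- length(mirnas)
  if (n <= 1L)
    return(list(kept = mirnas, collapsed_groups = list()))
  sites <- split(regulators[, c("chrom", "start", "end")], regulators$mirna)

  every_site_overlaps <- function(a, b) {
    all(vapply(seq_len(nrow(a)), function(i)
      any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end),
      logical(1L)))
  }
  similar <- diag(n) == 1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- sites[[mirnas[i]]]
    b <- sites[[mirnas[j]]]
    if (every_site_overlaps(a, b) && every_site_overlaps(b, a))
      similar[i, j] <- similar[j, i] <- TRUE
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(similar, mode = "undirected"))
  groups <- split(mirnas, comp$membership)
  kept <- sort(unname(vapply(groups, function(g) min(g), character(1L))))
  collapsed <- unname(groups[vapply(groups, length, integer(1L)) > 1L])
  list(kept = kept, collapsed_groups = collapsed)
}

#' Assemble the bipartite miRNA-gene regulatory network
#'
#' Builds the multi-miRNA repression network from replicated pairs: keeps
#' only pairs whose miRNA carries a cell-type specificity call, collapses
#' seed-similar regulators per gene ([collapse_seed_overlaps()]), then
#' retains genes regulated by at least `min_degree` distinct miRNAs (the
#' "shared target" filter, applied after collapse). miRNA nodes are
#' annotated with their specific cell types and lineage.
#'
#' @param replicated Data.frame with columns `mirna`, `gene` and optionally
#'   `r` (per-pair correlation carried onto the edges).
#' @param specificity_calls A `specificity_calls` data.frame; only miRNAs
#'   present here enter the network.
#' @param predictions A `prediction_table` supplying the seed-site
#'   intervals of each (miRNA, gene) pair.
#' @param min_degree Minimum number of distinct regulators per gene node
#'   (default 2).
#' @param scheme A [cell_scheme()] used to annotate miRNA lineage.
#' @return A list of class `regulatory_network` with `nodes` (id, kind,
#'   specific_cell_types, lineage), `edges` (mirna, gene, r) and
#'   `collapse_report`.
#' @export
build_network <- function(replicated, specificity_calls, predictions,
                          min_degree = 2, scheme = default_cell_scheme()) {
  spec_mirnas <- unique(specificity_calls$transcript)
  edges <- replicated[replicated$mirna %in% spec_mirnas, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$mirna, edges$gene, sep = "\r")), ,
                 drop = FALSE]
  if (!"r" %in% names(edges)) edges$r <- NA_real_

  report <- list()
  keep_edge <- rep(TRUE, nrow(edges))
  for (g in unique(edges$gene)) {
    idx <- which(edges$gene == g)
    if (length(idx) < 2L) next
    regs <- predictions[predictions$gene == g &
                          predictions$mirna_family %in% edges$mirna[idx], ,
                        drop = FALSE]
    regs <- data.frame(mirna = regs$mirna_family, chrom = regs$chrom,
                       start = regs$start, end = regs$end,
                       stringsAsFactors = FALSE)
    # regulators without recorded sites cannot be seed-similar; keep them
    with_sites <- intersect(edges$mirna[idx], regs$mirna)
    if (length(with_sites) >= 2L) {
      col <- collapse_seed_overlaps(g, regs[regs$mirna %in% with_sites, ,
                                            drop = FALSE])
      drop <- setdiff(with_sites, col$kept)
      keep_edge[idx[edges$mirna[idx] %in% drop]] <- FALSE
      if (length(col$collapsed_groups))
        report[[g]] <- col$collapsed_groups
    }
  }
  edges <- edges[keep_edge, , drop = FALSE]

  deg <- table(edges$gene)
  keep_genes <- names(deg)[deg >= min_degree]
  edges <- edges[edges$gene %in% keep_genes, , drop = FALSE]
  rownames(edges) <- NULL

  mirna_nodes <- sort(unique(edges$mirna))
  ann <- specificity_calls[match(mirna_nodes, specificity_calls$transcript), ,
                           drop = FALSE]
  lineage_of <- function(cts) {
    if (is.na(cts)) return(NA_character_)
    lin <- unique(scheme$lineage_map[strsplit(cts, ";")[[1L]]])
    if (length(lin) == 1L) lin else "mixed"
  }
  gene_nodes <- sort(unique(edges$gene))
  nodes <- rbind(
    data.frame(id = mirna_nodes, kind = rep("mirna", length(mirna_nodes)),
               specific_cell_types = ann$specific_cell_types,
               lineage = vapply(ann$specific_cell_types, lineage_of,
                                character(1L), USE.NAMES = FALSE),
               stringsAsFactors = FALSE),
    data.frame(id = gene_nodes, kind = rep("gene", length(gene_nodes)),
               specific_cell_types = rep(NA_character_, length(gene_nodes)),
               lineage = rep(NA_character_, length(gene_nodes)),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 edges = edges[, c("mirna", "gene", "r"), drop = FALSE],
                 collapse_report = report, min_degree = min_degree),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d miRNAs -> %d genes, %d edges (min degree %d)\n",
              sum(x$nodes$kind == "mirna"), sum(x$nodes$kind == "gene"),
              nrow(x$edges), x$min_degree))
  invisible(x)
}

#' Rank gene hubs by number of distinct regulators
#'
#' @param network A `regulatory_network`.
#' @return Data.frame `gene`, `degree`, sorted by decreasing degree with
#'   ties broken by gene identifier.
#' @export
rank_hubs <- function(network) {
  if (!nrow(network$edges))
    return(data.frame(gene = character(), degree = integer()))
  deg <- table(network$edges$gene)
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a regulatory network to an igraph object
#'
#' @param network A `regulatory_network`.
#' @return A directed bipartite igraph with `kind`, `specific_cell_types`
#'   and `lineage` node attributes and `r` edge attribute.
#' @export
as_igraph <- function(network) {
  nodes <- network$nodes
  nodes$specific_cell_types[is.na(nodes$specific_cell_types)] <- ""
  nodes$lineage[is.na(nodes$lineage)] <- ""
  edges <- network$edges
  edges$r[is.na(edges$r)] <- NaN
  igraph::graph_from_data_frame(
    data.frame(from = edges$mirna, to = edges$gene, r = edges$r),
    directed = TRUE, vertices = nodes)
}

#' Export a regulatory network as SIF or GraphML
#'
#' SIF writes one line per edge, `mirna represses gene`; GraphML (via
#' igraph) carries the node and edge attributes and round-trips the full
#' topology.
#'
#' @param network A `regulatory_network`.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\trepresses\t%s", network$edges$mirna,
                     network$edges$gene)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported network's topology
#'
#' @param path File written by [export_network()].
#' @param format `"sif"` or `"graphml"`.
#' @return Data.frame with columns `mirna`, `gene`.
#' @export
import_network_edges <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(data.frame(mirna = character(), gene = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                      gene = vapply(parts, `[`, "", 3L),
                      stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g)
    out <- data.frame(mirna = el[, 1L], gene = el[, 2L],
                      stringsAsFactors = FALSE)
  }
  out[order(out$mirna, out$gene), , drop = FALSE]
}
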