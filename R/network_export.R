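# Network export in Cytoscape-importable formats: SIF, GraphML, and a
# node-attribute table.

hgrn_node_roles <- function(net) {
  roles <- c(
    stats::setNames(rep("pathway_gene", length(net$pathway_genes)),
                    net$pathway_genes),
    unlist(lapply(seq_along(net$layers), function(l) {
      stats::setNames(rep(sprintf("tf_layer%d", l), length(net$layers[[l]])),
                      net$layers[[l]])
    })),
    stats::setNames(rep("metabolite",
                        length(unique(net$gene_metabolite_edges$metabolite))),
                    unique(net$gene_metabolite_edges$metabolite))
  )
  roles[!duplicated(names(roles))]
}

#' Node attribute table for Cytoscape import
#'
#' @param net An `hgrn` network.
#' @param status Optional named regulation-status vector over node ids.
#' @return Data frame `id`, `role`, `status`.
#' @export
node_attributes <- function(net, status = NULL) {
  stopifnot(inherits(net, "hgrn"))
  roles <- hgrn_node_roles(net)
  st <- rep("ns", length(roles))
  if (!is.null(status)) {
    hit <- names(roles) %in% names(status)
    st[hit] <- status[names(roles)[hit]]
  }
  data.frame(id = names(roles), role = unname(roles), status = st,
             row.names = NULL, stringsAsFactors = FALSE)
}

hgrn_edge_frame <- function(net) {
  rbind(
    if (nrow(net$tf_edges)) {
      data.frame(source = net$tf_edges$regulator,
                 interaction = "regulates",
                 target = net$tf_edges$target,
                 weight = net$tf_edges$weight,
                 stringsAsFactors = FALSE)
    },
    if (nrow(net$gene_metabolite_edges)) {
      data.frame(source = net$gene_metabolite_edges$gene,
                 interaction = "correlates",
                 target = net$gene_metabolite_edges$metabolite,
                 weight = net$gene_metabolite_edges$r,
                 stringsAsFactors = FALSE)
    }
  )
}

#' Write a network in simple interaction format (SIF)
#'
#' One line per edge: `source TAB interaction TAB target`, with
#' interaction `regulates` for TF edges and `correlates` for
#' gene-metabolite edges.
#'
#' @param net An `hgrn` network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "hgrn"))
  e <- hgrn_edge_frame(net)
  lines <- if (is.null(e)) character() else {
    paste(e$source, e$interaction, e$target, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Nodes carry `role` and `status` attributes, edges carry `interaction`
#' and `weight`, matching the node-attribute CSV.
#'
#' @inheritParams node_attributes
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, status = NULL) {
  stopifnot(inherits(net, "hgrn"))
  nodes <- node_attributes(net, status)
  e <- hgrn_edge_frame(net)
  if (is.null(e)) {
    e <- data.frame(source = character(), interaction = character(),
                    target = character(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(
    e[, c("source", "target", "interaction", "weight")],
    directed = TRUE, vertices = nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
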