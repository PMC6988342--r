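#' Mixed gene-taxon correlation network
#'
#' Nodes are genes or taxa; edges are either gene-taxon Spearman links or
#' taxon-taxon SparCC links. Edge weight is the correlation value (so
#' |weight| <= 1), `sign` its sign, and `significance` the q-value
#' (gene-taxon) or pseudo p-value (taxon-taxon).
#'
#' @param nodes data.frame with columns id, node_type ("gene"/"taxon")
#' @param edges data.frame with columns source, target, edge_type
#'   ("gene_taxon"/"taxon_taxon"), weight, significance
#' @return an object of class `gutnet_network`
#' @export
gutnet_network <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      node_type = as.character(nodes$node_type),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        edge_type = character(), weight = numeric(),
                        sign = integer(), significance = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        edge_type = as.character(edges$edge_type),
                        weight = as.numeric(edges$weight),
                        sign = as.integer(sign(as.numeric(edges$weight))),
                        significance = as.numeric(edges$significance),
                        stringsAsFactors = FALSE)
  }
  net <- structure(list(nodes = nodes, edges = edges), class = "gutnet_network")
  validate_network(net)
  net
}

#' Validate network invariants
#' @param net a `gutnet_network`
#' @return `net` invisibly
#' @export
validate_network <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    stop("node ID(s) typed inconsistently or duplicated: ",
         paste(dup, collapse = ", "))
  }
  if (!all(nodes$node_type %in% c("gene", "taxon"))) stop("unknown node_type")
  if (nrow(edges)) {
    type_of <- setNames(nodes$node_type, nodes$id)
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing)) stop("edge endpoint(s) missing from nodes: ",
                              paste(missing, collapse = ", "))
    if (any(abs(edges$weight) > 1 + 1e-12)) stop("|edge weight| must be <= 1")
    st <- type_of[edges$source]; tt <- type_of[edges$target]
    gt <- edges$edge_type == "gene_taxon"
    if (any(gt & !((st == "gene" & tt == "taxon") | (st == "taxon" & tt == "gene")))) {
      stop("gene_taxon edges must connect one gene and one taxon")
    }
    tt_edges <- edges$edge_type == "taxon_taxon"
    if (any(tt_edges & !(st == "taxon" & tt == "taxon" & edges$source != edges$target))) {
      stop("taxon_taxon edges must connect two distinct taxa")
    }
  }
  invisible(net)
}

#' @export
print.gutnet_network <- function(x, ...) {
  cat(sprintf("<gutnet_network> %d nodes (%d genes, %d taxa), %d edges (%d gene-taxon, %d taxon-taxon)\n",
              nrow(x$nodes), sum(x$nodes$node_type == "gene"),
              sum(x$nodes$node_type == "taxon"), nrow(x$edges),
              sum(x$edges$edge_type == "gene_taxon"),
              sum(x$edges$edge_type == "taxon_taxon")))
  invisible(x)
}

#' Export a network to disk
#'
#' `edge_list` writes a TSV with columns source, target, edge_type, weight,
#' significance (node types recoverable from edge types); `graphml` writes a
#' GraphML document carrying node_type and all edge attributes, round-trippable
#' with [read_network_graphml()].
#'
#' @param net a `gutnet_network`
#' @param path output path
#' @param format "edge_list" or "graphml"
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("edge_list", "graphml")) {
  if (length(format) == 1L && !format %in% c("edge_list", "graphml")) {
    stop("unknown network format: ", format)
  }
  format <- match.arg(format)
  validate_network(net)
  if (format == "edge_list") {
    e <- net$edges[c("source", "target", "edge_type", "weight", "significance")]
    header <- paste(names(e), collapse = "\t")
    rows <- if (nrow(e)) {
      vapply(seq_len(nrow(e)), function(i) {
        paste(c(e$source[i], e$target[i], e$edge_type[i],
                format(e$weight[i], digits = 15L, trim = TRUE),
                format(e$significance[i], digits = 15L, trim = TRUE)),
              collapse = "\t")
      }, character(1L))
    } else character()
    writeLines(c(header, rows), path)
  } else {
    write_network_graphml(net, path)
  }
  invisible(path)
}

write_network_graphml <- function(net, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydef <- function(id, dom, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = name, `attr.type` = type)
  }
  keydef("ntype", "node", "node_type", "string")
  keydef("etype", "edge", "edge_type", "string")
  keydef("w", "edge", "weight", "double")
  keydef("sgn", "edge", "sign", "int")
  keydef("sig", "edge", "significance", "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$id[i])
    d <- xml2::xml_add_child(nd, "data", key = "ntype")
    xml2::xml_text(d) <- net$nodes$node_type[i]
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge", source = e$source[i], target = e$target[i])
    add <- function(key, val) {
      d <- xml2::xml_add_child(ed, "data", key = key)
      xml2::xml_text(d) <- val
    }
    add("etype", e$edge_type[i])
    add("w", format(e$weight[i], digits = 15L, trim = TRUE))
    add("sgn", as.character(e$sign[i]))
    add("sig", format(e$significance[i], digits = 15L, trim = TRUE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file path
#' @return a `gutnet_network`
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes_xml <- xml2::xml_find_all(doc, ".//graph/node")
  nodes <- data.frame(
    id = xml2::xml_attr(nodes_xml, "id"),
    node_type = vapply(nodes_xml, function(n)
      xml2::xml_text(xml2::xml_find_first(n, "./data[@key='ntype']")), character(1L)),
    stringsAsFactors = FALSE
  )
  edges_xml <- xml2::xml_find_all(doc, ".//graph/edge")
  get_edge_data <- function(key) vapply(edges_xml, function(e)
    xml2::xml_text(xml2::xml_find_first(e, sprintf("./data[@key='%s']", key))),
    character(1L))
  edges <- if (length(edges_xml)) {
    data.frame(
      source = xml2::xml_attr(edges_xml, "source"),
      target = xml2::xml_attr(edges_xml, "target"),
      edge_type = get_edge_data("etype"),
      weight = as.numeric(get_edge_data("w")),
      significance = as.numeric(get_edge_data("sig")),
      stringsAsFactors = FALSE
    )
  } else NULL
  gutnet_network(nodes, edges)
}
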