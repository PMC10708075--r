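#' Build a bipartite flavor network for one group
#'
#' Key flavor compounds (ROAV >= 1) are linked to their odor descriptors;
#' every edge carries the compound's ROAV as weight and every descriptor
#' node accumulates the summed ROAV of its incident edges, so descriptors
#' shared by several key compounds become heavy flavor hubs.  Descriptor
#' tags are matched exactly after canonicalization (trim, case-fold); a key
#' compound with no descriptors stays in the network as an isolated node
#' (with a warning).
#'
#' @param result a `roav_result` for one group.
#' @param thresholds the `threshold_table` carrying odor descriptors.
#' @return an object of class `flavor_network`: list with `compound_nodes`
#'   (`compound`, `roav`), `descriptor_nodes` (`descriptor`, `summed_roav`,
#'   `degree`), `edges` (`compound`, `descriptor`, `weight`) and attribute
#'   `group`.
#' @export
build_flavor_network <- function(result, thresholds) {
  stopifnot(inherits(result, "roav_result"),
            inherits(thresholds, "threshold_table"))
  key <- classify_roav(result)$key
  desc <- thresholds$descriptors[match(key$compound, thresholds$compound)]
  empty <- lengths(desc) == 0
  if (any(empty))
    warning("key compound(s) without odor descriptors kept as isolated ",
            "nodes: ", paste(key$compound[empty], collapse = ", "))
  edges <- do.call(rbind, lapply(which(!empty), function(i) {
    data.frame(compound = key$compound[i],
               descriptor = unique(desc[[i]]),   # duplicate tags collapse
               weight = key$roav[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(compound = character(), descriptor = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  dn <- if (nrow(edges)) {
    agg <- stats::aggregate(weight ~ descriptor, edges, sum)
    deg <- stats::aggregate(weight ~ descriptor, edges, length)
    data.frame(descriptor = agg$descriptor, summed_roav = agg$weight,
               degree = deg$weight, stringsAsFactors = FALSE)
  } else {
    data.frame(descriptor = character(), summed_roav = numeric(),
               degree = integer(), stringsAsFactors = FALSE)
  }
  dn <- dn[order(-dn$summed_roav, dn$descriptor), , drop = FALSE]
  rownames(dn) <- NULL
  structure(list(compound_nodes = key[c("compound", "roav")],
                 descriptor_nodes = dn,
                 edges = edges),
            group = attr(result, "group"), class = "flavor_network")
}

#' @export
print.flavor_network <- function(x, ...) {
  cat("flavor_network '", attr(x, "group"), "': ",
      nrow(x$compound_nodes), " key compounds, ",
      nrow(x$descriptor_nodes), " descriptors, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$descriptor_nodes)) {
    top <- utils::head(x$descriptor_nodes, 5)
    cat("top descriptors by summed ROAV:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Convert a flavor network to an igraph object
#'
#' @param network a `flavor_network`.
#' @return a bipartite [igraph::graph_from_data_frame()] graph with vertex
#'   attributes `type` ("compound"/"descriptor") and `weight` (ROAV or
#'   summed ROAV) and edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "flavor_network"))
  verts <- rbind(
    data.frame(name = network$compound_nodes$compound, type = "compound",
               weight = network$compound_nodes$roav,
               stringsAsFactors = FALSE),
    data.frame(name = network$descriptor_nodes$descriptor,
               type = "descriptor",
               weight = network$descriptor_nodes$summed_roav,
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = verts)
}

#' Export a flavor network
#'
#' Writes the edge list as CSV and, optionally, the full bipartite graph as
#' GraphML (node attributes `type` and `weight`).
#'
#' @param network a `flavor_network`.
#' @param csv_path edge-list CSV path (NULL to skip).
#' @param graphml_path GraphML path (NULL to skip).
#' @return invisibly, the edge data.frame.
#' @export
write_flavor_network <- function(network, csv_path = NULL,
                                 graphml_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(network$edges, csv_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(network), graphml_path,
                        format = "graphml")
  invisible(network$edges)
}
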