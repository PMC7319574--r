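# serialize the node-link view to GraphML / node-link JSON / DOT
.exportNodeLink <- function(nl, format, file) {
  doc <- switch(format,
                graphml = .toGraphML(nl),
                json = .toNodeLinkJSON(nl),
                dot = .toDOT(nl))
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

.toGraphML <- function(nl) {
  n <- nl$nodes; e <- nl$edges
  esc <- xmlEscape
  optStr <- function(x) ifelse(is.na(x), "", as.character(x))
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"d_kind\" for=\"node\" attr.name=\"kind\" attr.type=\"string\"/>",
    "  <key id=\"d_label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
    "  <key id=\"d_compartment\" for=\"node\" attr.name=\"compartment\" attr.type=\"string\"/>",
    "  <key id=\"d_flux\" for=\"node\" attr.name=\"flux\" attr.type=\"double\"/>",
    "  <key id=\"d_weight\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
    "  <key id=\"d_role\" for=\"edge\" attr.name=\"role\" attr.type=\"string\"/>",
    "  <key id=\"d_stoich\" for=\"edge\" attr.name=\"stoich\" attr.type=\"double\"/>",
    "  <key id=\"d_metabolite\" for=\"edge\" attr.name=\"metabolite\" attr.type=\"string\"/>",
    "  <key id=\"d_reaction\" for=\"edge\" attr.name=\"reaction\" attr.type=\"string\"/>",
    "  <graph id=\"G\" edgedefault=\"directed\">")
  for (i in seq_len(nrow(n))) {
    L <- c(L, sprintf("    <node id=\"%s\">", esc(n$instance[i])),
           sprintf("      <data key=\"d_kind\">%s</data>", esc(n$kind[i])),
           sprintf("      <data key=\"d_label\">%s</data>",
                   esc(optStr(n$label[i]))),
           sprintf("      <data key=\"d_compartment\">%s</data>",
                   esc(optStr(n$compartment[i]))))
    if (!is.na(n$flux[i]))
      L <- c(L, sprintf("      <data key=\"d_flux\">%s</data>",
                        fmtNum(n$flux[i])))
    L <- c(L, "    </node>")
  }
  for (i in seq_len(nrow(e)))
    L <- c(L,
      sprintf("    <edge source=\"%s\" target=\"%s\">",
              esc(e$from[i]), esc(e$to[i])),
      sprintf("      <data key=\"d_weight\">%s</data>", fmtNum(e$weight[i])),
      sprintf("      <data key=\"d_role\">%s</data>", esc(e$role[i])),
      sprintf("      <data key=\"d_stoich\">%s</data>", fmtNum(e$stoich[i])),
      sprintf("      <data key=\"d_metabolite\">%s</data>",
              esc(e$metabolite[i])),
      sprintf("      <data key=\"d_reaction\">%s</data>", esc(e$reaction[i])),
      "    </edge>")
  paste(c(L, "  </graph>", "</graphml>"), collapse = "\n")
}

.toNodeLinkJSON <- function(nl) {
  nodes <- nl$nodes[, c("instance", "node", "kind", "label", "compartment",
                        "flux")]
  names(nodes)[1] <- "id"
  links <- nl$edges[, c("from", "to", "metabolite", "reaction", "role",
                        "stoich", "weight")]
  names(links)[1:2] <- c("source", "target")
  as.character(jsonlite::toJSON(list(nodes = nodes, links = links),
                                dataframe = "rows", na = "null", digits = NA,
                                auto_unbox = TRUE, pretty = TRUE))
}

.toDOT <- function(nl) {
  n <- nl$nodes; e <- nl$edges
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  L <- c("digraph fluxgraph {", "  rankdir=LR;")
  shape <- ifelse(n$kind == "metabolite", "ellipse", "box")
  L <- c(L, sprintf("  %s [shape=%s, label=%s];",
                    q(n$instance), shape, q(n$node)))
  if (nrow(e))
    L <- c(L, sprintf("  %s -> %s [weight=%s, label=%s];",
                      q(e$from), q(e$to), fmtNum(e$weight), q(e$role)))
  paste(c(L, "}"), collapse = "\n")
}

#' @rdname exportGraph
#' @export
setMethod("exportGraph", "FluxGraph", function(x, format, file) {
  format <- match.arg(format, c("graphml", "json", "dot"))
  .exportNodeLink(.asNodeLink(x), format, file)
})

#' @rdname exportGraph
#' @export
setMethod("exportGraph", "SpanningTree", function(x, format, file) {
  format <- match.arg(format, c("graphml", "json", "dot"))
  .exportNodeLink(.asNodeLink(x), format, file)
})

#' @rdname exportGraph
#' @export
setMethod("exportGraph", "DuplicatedTree", function(x, format, file) {
  format <- match.arg(format, c("graphml", "json", "dot"))
  .exportNodeLink(.asNodeLink(x), format, file)
})

#' Read a GraphML file written by [exportGraph()]
#'
#' Reconstructs a [FluxGraph-class] with the node kinds, labels, compartments
#' and fluxes, and the edge roles, stoichiometric coefficients and weights,
#' exactly as exported (numbers are written at full precision).
#'
#' @param path GraphML file path.
#' @return a [FluxGraph-class].
#' @export
importGraphML <- function(path) {
  doc <- xml2::read_xml(path)
  g <- .xfirst(doc, "graph")
  dataOf <- function(node) {
    d <- .xfind(node, "data")
    stats::setNames(vapply(d, xml2::xml_text, character(1)),
                    vapply(d, .xattr, character(1), "key"))
  }
  nn <- .xfind(g, "node")
  nodes <- do.call(rbind, lapply(nn, function(nd) {
    d <- dataOf(nd)
    data.frame(id = .xattr(nd, "id"),
               kind = unname(d["d_kind"]),
               label = unname(d["d_label"]),
               compartment = if (nzchar(d["d_compartment"] %na% ""))
                 unname(d["d_compartment"]) else NA_character_,
               flux = if ("d_flux" %in% names(d)) as.numeric(d["d_flux"])
                      else NA_real_,
               stringsAsFactors = FALSE)
  }))
  en <- .xfind(g, "edge")
  edges <- do.call(rbind, lapply(en, function(ed) {
    d <- dataOf(ed)
    data.frame(metabolite = unname(d["d_metabolite"]),
               reaction = unname(d["d_reaction"]),
               role = unname(d["d_role"]),
               stoich = as.numeric(d["d_stoich"]),
               weight = as.numeric(d["d_weight"]),
               from = .xattr(ed, "source"), to = .xattr(ed, "target"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(metabolite = character(), reaction = character(),
                        role = character(), stoich = numeric(),
                        weight = numeric(), from = character(),
                        to = character(), stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- data.frame(id = character(), kind = character(),
                                          label = character(),
                                          compartment = character(),
                                          flux = numeric())
  new("FluxGraph", nodes = nodes, edges = edges, options = list())
}

`%na%` <- function(a, b) if (is.na(a)) b else a
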