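# fit layout coordinates into a drawing area, returning pixel positions
.fitCoords <- function(co, width = 800, height = 600, margin = 40) {
  if (!nrow(co))
    return(data.frame(instance = character(), px = numeric(), py = numeric(),
                      stringsAsFactors = FALSE))
  spanX <- max(co$x) - min(co$x)
  spanY <- max(co$y) - min(co$y)
  sx <- if (spanX > 0) (width - 2 * margin) / spanX else 0
  sy <- if (spanY > 0) (height - 2 * margin) / spanY else 0
  data.frame(instance = co$instance,
             px = margin + (co$x - min(co$x)) * sx +
               (if (spanX > 0) 0 else (width - 2 * margin) / 2),
             py = margin + (co$y - min(co$y)) * sy +
               (if (spanY > 0) 0 else (height - 2 * margin) / 2),
             stringsAsFactors = FALSE)
}

.svgHeader <- function(width = 800, height = 600)
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
                   "height=\"%d\" viewBox=\"0 0 %d %d\">"),
            width, height, width, height))

.svgEdges <- function(edges, p, style, colorFor) {
  if (!nrow(edges)) return(character())
  maxW <- max(edges$weight, 0)
  rel <- if (maxW > 0) edges$weight / maxW else rep(1, nrow(edges))
  sw <- if (style@edgeEmphasis == "width") 0.6 + 2.8 * rel else rep(1.2, nrow(edges))
  op <- if (style@edgeEmphasis == "opacity") 0.25 + 0.75 * rel else rep(1, nrow(edges))
  x1 <- p$px[match(edges$from, p$instance)]
  y1 <- p$py[match(edges$from, p$instance)]
  x2 <- p$px[match(edges$to, p$instance)]
  y2 <- p$py[match(edges$to, p$instance)]
  sprintf(paste0("  <line x1=\"%.2f\" y1=\"%.2f\" x2=\"%.2f\" y2=\"%.2f\" ",
                 "stroke=\"%s\" stroke-width=\"%.2f\" stroke-opacity=\"%.3f\"/>"),
          x1, y1, x2, y2, colorFor(edges), sw, op)
}

.svgNodes <- function(nodes, p, style) {
  if (!nrow(nodes)) return(character())
  fill <- ifelse(nodes$kind == "metabolite", style@metaboliteColor,
                 style@reactionColor)
  px <- p$px[match(nodes$instance, p$instance)]
  py <- p$py[match(nodes$instance, p$instance)]
  out <- sprintf(paste0("  <circle cx=\"%.2f\" cy=\"%.2f\" r=\"7\" ",
                        "fill=\"%s\" stroke=\"black\" stroke-width=\"0.8\"/>"),
                 px, py, xmlEscape(fill))
  lab <- switch(style@labelMode,
                id = nodes$node,
                name = nodes$label,
                flux = nodes$node,
                localization = nodes$compartment,
                none = NULL)
  if (!is.null(lab)) {
    lab <- ifelse(is.na(lab), "", lab)
    out <- c(out, sprintf(
      "  <text x=\"%.2f\" y=\"%.2f\" font-size=\"9\" text-anchor=\"middle\">%s</text>",
      px, py - 10, xmlEscape(lab)))
  }
  if (style@labelMode == "flux" && "flux" %in% names(nodes)) {
    ir <- which(nodes$kind == "reaction" & !is.na(nodes$flux))
    if (length(ir))
      out <- c(out, sprintf(
        "  <text x=\"%.2f\" y=\"%.2f\" font-size=\"8\" text-anchor=\"middle\" fill=\"#444444\">%.4g</text>",
        px[ir], py[ir] + 18, nodes$flux[ir]))
  }
  out
}

.writeSvg <- function(lines, file) {
  doc <- paste(c(lines, "</svg>"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

.renderNodeLink <- function(x, layout, style, file, treeColors) {
  nl <- .asNodeLink(x)
  co <- layout@coords
  missing <- setdiff(nl$nodes$instance, co$instance)
  if (length(missing))
    stopf("layout does not cover instance(s): %s",
          paste(utils::head(missing, 3), collapse = ", "))
  p <- .fitCoords(co)
  colorFor <- function(edges) {
    if (treeColors)
      ifelse(edges$towardRoot, style@towardRootEdgeColor,
             style@fromRootEdgeColor)
    else rep("#888888", nrow(edges))
  }
  lines <- c(.svgHeader(),
             .svgEdges(nl$edges, p, style, colorFor),
             .svgNodes(nl$nodes, p, style))
  .writeSvg(lines, file)
}

#' @rdname renderSVG
#' @export
setMethod("renderSVG", "FluxGraph", function(x, layout, style, file)
  .renderNodeLink(x, layout, style, file, treeColors = FALSE))

#' @rdname renderSVG
#' @export
setMethod("renderSVG", "SpanningTree", function(x, layout, style, file)
  .renderNodeLink(x, layout, style, file, treeColors = TRUE))

#' @rdname renderSVG
#' @export
setMethod("renderSVG", "DuplicatedTree", function(x, layout, style, file)
  .renderNodeLink(x, layout, style, file, treeColors = TRUE))

# fixed qualitative palette for path ranks (recycled past 8 paths)
.pathPalette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
                  "#e6ab02", "#a6761d", "#666666")

#' @rdname renderSVG
#' @export
setMethod("renderSVG", "PathSet", function(x, layout, style, file) {
  co <- layout@coords
  p <- .fitCoords(co)
  lines <- .svgHeader()
  # draw worst rank first so that where paths overlap the shorter
  # (lower-rank) path's color ends up on top
  for (pa in rev(x@paths)) {
    col <- .pathPalette[(pa@rank - 1) %% length(.pathPalette) + 1]
    if (nrow(pa@edges))
      lines <- c(lines, .svgEdges(
        pa@edges, p, style, colorFor = function(edges)
          rep(col, nrow(edges))))
  }
  nodes <- data.frame(instance = x@nodes$id, node = x@nodes$id,
                      kind = x@nodes$kind, label = x@nodes$label,
                      flux = NA_real_, compartment = NA_character_,
                      stringsAsFactors = FALSE)
  lines <- c(lines, .svgNodes(nodes, p, style))
  .writeSvg(lines, file)
})
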