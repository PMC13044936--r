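#' Workflow topology graphs
#'
#' A workflow's structure is rendered as a directed acyclic graph: nodes
#' are steps, edges are execution dependencies, and each node is annotated
#' with its rolled-up state (colour-coded), the fraction of successful
#' sample units (`k/n`) and the mean unit duration. All text outputs are
#' deterministic for a fixed state: node order is the lexicographic
#' topological order, edge order follows it, and no timestamps are
#' embedded.
#'
#' @name topology-graphs
NULL

SF_STATE_COLORS <- c(pending = "#cccccc", running = "#74a9cf",
                     success = "#a1d99b", warning = "#fdae6b",
                     error = "#fb6a4a")

#' Build the topology graph specification
#'
#' @param wf an `sf_workflow`.
#' @param layout `"top-down"` or `"left-right"` rendering hint.
#' @return An object of class `sf_graph`: `nodes` (data.frame: id, label,
#'   state, frac, mean_duration, tooltip), `edges` (data.frame: from, to)
#'   and `layout`.
#' @export
build_graph <- function(wf, layout = c("top-down", "left-right")) {
  layout <- match.arg(layout)
  order <- topological_order(wf)
  st <- wf$status
  nodes <- do.call(rbind, lapply(order, function(id) {
    rows <- st[st$step == id, , drop = FALSE]
    n <- nrow(rows)
    k <- sum(rows$state == "success")
    durs <- rows$duration_s[!is.na(rows$duration_s)]
    mean_dur <- if (length(durs)) mean(durs) else NA_real_
    state <- step_state(wf, id)
    bad <- rows$sample[rows$state %in% c("warning", "error")]
    tooltip <- paste0(
      "state: ", state, "; success ", k, "/", n,
      if (!is.na(mean_dur)) sprintf("; mean %.3fs", mean_dur),
      if (length(bad)) paste0("; attention: ", paste(bad, collapse = ", ")))
    data.frame(id = id, label = paste0(id, "\\n", k, "/", n),
               state = state, frac = paste0(k, "/", n),
               mean_duration = mean_dur, tooltip = tooltip,
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) nodes <- data.frame(
    id = character(), label = character(), state = character(),
    frac = character(), mean_duration = numeric(), tooltip = character(),
    stringsAsFactors = FALSE)
  edges <- wf_edges(wf)
  if (nrow(edges)) {
    ord <- order(match(edges$to, order), edges$from)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, layout = layout),
            class = "sf_graph")
}

#' Render a graph as Graphviz DOT
#'
#' @param g an `sf_graph`.
#' @return DOT text (single string). Deterministic: identical graphs give
#'   byte-identical output.
#' @export
to_dot <- function(g) {
  stopifnot(inherits(g, "sf_graph"))
  rankdir <- if (g$layout == "left-right") "LR" else "TB"
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  lines <- c("digraph workflow {",
             paste0("  rankdir=", rankdir, ";"),
             '  node [shape=box, style="rounded,filled", fontname="Helvetica"];')
  for (i in seq_len(nrow(g$nodes))) {
    nd <- g$nodes[i, ]
    lines <- c(lines, paste0(
      "  ", q(nd$id), " [label=", q(nd$label),
      ", fillcolor=", q(unname(SF_STATE_COLORS[nd$state])),
      ", tooltip=", q(nd$tooltip), "];"))
  }
  for (i in seq_len(nrow(g$edges)))
    lines <- c(lines, paste0("  ", q(g$edges$from[i]), " -> ",
                             q(g$edges$to[i]), ";"))
  paste0(paste(lines, collapse = "\n"), "\n}\n")
}

#' Render a graph as a mermaid flowchart
#'
#' @param g an `sf_graph`.
#' @return Mermaid flowchart text.
#' @export
to_mermaid <- function(g) {
  stopifnot(inherits(g, "sf_graph"))
  dir <- if (g$layout == "left-right") "LR" else "TD"
  lines <- paste0("flowchart ", dir)
  for (i in seq_len(nrow(g$nodes))) {
    nd <- g$nodes[i, ]
    lines <- c(lines, paste0("  ", nd$id, "[\"", nd$id, " ", nd$frac,
                             "\"]"))
  }
  for (i in seq_len(nrow(g$edges)))
    lines <- c(lines, paste0("  ", g$edges$from[i], " --> ",
                             g$edges$to[i]))
  for (s in names(SF_STATE_COLORS))
    lines <- c(lines, paste0("  classDef ", s, " fill:",
                             SF_STATE_COLORS[s], ";"))
  for (i in seq_len(nrow(g$nodes)))
    lines <- c(lines, paste0("  class ", g$nodes$id[i], " ",
                             g$nodes$state[i]))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# simple layered (longest-path) layout for the built-in SVG renderer
graph_layers <- function(g) {
  depth <- stats::setNames(integer(length(g$nodes$id)), g$nodes$id)
  for (id in g$nodes$id) {   # nodes already topologically ordered
    preds <- g$edges$from[g$edges$to == id]
    depth[id] <- if (length(preds)) max(depth[preds]) + 1L else 0L
  }
  depth
}

#' Render a graph as standalone SVG
#'
#' A dependency-layered box diagram with native hover tooltips (SVG
#' `<title>` elements carrying sample-level counts and mean durations).
#'
#' @param g an `sf_graph`.
#' @return SVG text.
#' @export
to_svg <- function(g) {
  stopifnot(inherits(g, "sf_graph"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  if (!nrow(g$nodes))
    return(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="200" ',
                  'height="40"><text x="10" y="25">empty workflow</text>',
                  "</svg>\n"))
  depth <- graph_layers(g)
  horiz <- g$layout == "left-right"
  bw <- 170; bh <- 46; gx <- 40; gy <- 34
  lay_index <- integer(0)
  pos <- lapply(g$nodes$id, function(id) {
    d <- depth[[id]]
    k <- sum(names(lay_index) %in% names(depth)[depth == d])
    lay_index[[id]] <<- k
    if (horiz) c(x = d * (bw + gx) + 10, y = k * (bh + gy) + 10)
    else c(x = k * (bw + gx) + 10, y = d * (bh + gy) + 10)
  })
  names(pos) <- g$nodes$id
  xs <- vapply(pos, `[[`, numeric(1), "x")
  ys <- vapply(pos, `[[`, numeric(1), "y")
  w <- as.integer(max(xs) + bw + 20); h <- as.integer(max(ys) + bh + 20)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   w, h, w, h),
           "<defs><marker id=\"arr\" markerWidth=\"8\" markerHeight=\"8\"",
           " refX=\"7\" refY=\"3\" orient=\"auto\">",
           "<path d=\"M0,0 L7,3 L0,6 z\" fill=\"#555\"/></marker></defs>")
  for (i in seq_len(nrow(g$edges))) {
    p1 <- pos[[g$edges$from[i]]]; p2 <- pos[[g$edges$to[i]]]
    out <- c(out, sprintf(
      paste0('<line x1="%.0f" y1="%.0f" x2="%.0f" y2="%.0f" ',
             'stroke="#555" marker-end="url(#arr)"/>'),
      p1["x"] + bw / 2, p1["y"] + bh, p2["x"] + bw / 2, p2["y"]))
  }
  for (i in seq_len(nrow(g$nodes))) {
    nd <- g$nodes[i, ]
    p <- pos[[nd$id]]
    out <- c(out,
             "<g>",
             sprintf(paste0('<rect x="%.0f" y="%.0f" width="%d" height="%d"',
                            ' rx="8" fill="%s" stroke="#333"/>'),
                     p["x"], p["y"], bw, bh,
                     unname(SF_STATE_COLORS[nd$state])),
             sprintf('<title>%s</title>', esc(nd$tooltip)),
             sprintf(paste0('<text x="%.0f" y="%.0f" text-anchor="middle" ',
                            'font-family="Helvetica" font-size="12">%s',
                            '</text>'),
                     p["x"] + bw / 2, p["y"] + 19, esc(nd$id)),
             sprintf(paste0('<text x="%.0f" y="%.0f" text-anchor="middle" ',
                            'font-family="Helvetica" font-size="11">%s',
                            '</text>'),
                     p["x"] + bw / 2, p["y"] + 35, esc(nd$frac)),
             "</g>")
  }
  paste0(paste(out, collapse = "\n"), "\n</svg>\n")
}

#' Render a graph as a standalone HTML page
#'
#' Embeds the SVG topology (tooltips work natively on hover) in a minimal
#' HTML wrapper; no external assets, works fully offline.
#'
#' @param g an `sf_graph`.
#' @return HTML text.
#' @export
to_html_graph <- function(g) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
         "<title>workflow topology</title></head>\n",
         "<body style=\"font-family:Helvetica,sans-serif\">",
         "<h1>Workflow topology</h1>\n",
         "<p>Hover over a node for sample-level status and timing.</p>\n",
         "<div style=\"overflow:auto\">\n", to_svg(g), "</div>\n",
         "</body></html>\n")
}

#' @export
print.sf_graph <- function(x, ...) {
  cat("<sf_graph> ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s), layout ", x$layout, "\n", sep = "")
  invisible(x)
}

#' @export
plot.sf_workflow <- function(x, ...) {
  g <- build_graph(x)
  cat(to_mermaid(g))
  invisible(g)
}
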