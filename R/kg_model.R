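#' Build the knowledge graph from a complete triplet table
#'
#' Nodes are normalised entity labels (first-seen original casing kept as a
#' `display` vertex attribute); one directed edge per table row, so repeated
#' rows yield parallel edges — build the graph after [deduplicate()] if you
#' want each fact once. Edge attributes: `relation`, `doc_id`, `sent_index`.
#'
#' @param table an `mlr_triplets` table whose rows are all complete.
#' @return a directed `igraph` multigraph.
#' @export
build_graph <- function(table) {
  if (!all(table$complete)) {
    stop("contract error: incomplete row(s) at index ",
         paste(which(!table$complete), collapse = ", "),
         "; run filter_complete() first", call. = FALSE)
  }
  src <- normalize_label(table$source)
  dst <- normalize_label(table$target)
  labels <- c(rbind(src, dst))
  display <- c(rbind(trimws(table$source), trimws(table$target)))
  first <- !duplicated(labels)
  g <- igraph::make_empty_graph(directed = TRUE)
  if (nrow(table) == 0L) return(g)
  g <- igraph::add_vertices(g, sum(first), name = labels[first],
                            display = display[first])
  g <- igraph::add_edges(g, rbind(match(src, labels[first]),
                                  match(dst, labels[first])),
                         relation = table$edge,
                         doc_id = table$doc_id,
                         sent_index = table$sent_index)
  g
}

#' Convert a knowledge graph back to a triplet table
#'
#' Inverse of [build_graph()] up to label normalisation: one row per edge,
#' entity labels taken from the vertices' display surfaces.
#'
#' @param graph an `igraph` built by [build_graph()].
#' @return an `mlr_triplets` table.
#' @export
as_triplet_table <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(triplet_table(stage_label = "graph"))
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  disp <- igraph::vertex_attr(graph, "display") %||%
    igraph::V(graph)$name
  triplet_table(data.frame(
    source = disp[ends[, 1]],
    edge = igraph::edge_attr(graph, "relation"),
    target = disp[ends[, 2]],
    doc_id = igraph::edge_attr(graph, "doc_id") %||% NA_character_,
    sent_index = igraph::edge_attr(graph, "sent_index") %||% NA_integer_,
    stringsAsFactors = FALSE), stage_label = "graph")
}

#' Most frequent relations in a triplet table
#'
#' Tallies relation labels as they appear (surface forms: "include" and
#' "included" count separately) and returns the `k` most frequent,
#' descending by count with ties broken lexicographically ascending. Useful
#' for carving a large graph into per-relation sub-graphs.
#'
#' @param table an `mlr_triplets` table.
#' @param k number of relations to return (default 10; fewer are returned
#'   if fewer distinct relations exist).
#' @return a tibble with columns `relation`, `count`.
#' @export
top_relations <- function(table, k = 10) {
  if (k < 1) stop("argument error: k must be >= 1", call. = FALSE)
  if (nrow(table) == 0L) {
    return(tibble::tibble(relation = character(0), count = integer(0)))
  }
  tab <- table(table$edge)
  ord <- order(-as.integer(tab), names(tab))
  top <- utils::head(ord, k)
  tibble::tibble(relation = names(tab)[top], count = as.integer(tab)[top])
}

#' Sub-knowledge-graph for one relation
#'
#' The subgraph induced by the edges carrying exactly the given relation
#' label, with their endpoint nodes; the empty graph if the relation is
#' absent. The union of all relation sub-KGs reconstitutes the full edge
#' multiset.
#'
#' @param graph an `igraph` knowledge graph.
#' @param relation relation label (matched exactly).
#' @return a directed `igraph` subgraph.
#' @export
sub_kg_by_relation <- function(graph, relation) {
  if (igraph::ecount(graph) == 0L) return(graph)
  eids <- which(igraph::edge_attr(graph, "relation") == relation)
  igraph::subgraph_from_edges(graph, eids, delete.vertices = TRUE)
}

#' Write a triplet table as CSV
#'
#' UTF-8, comma-separated, RFC-4180 quoting, header starting exactly
#' `Source,Edge,Target`; provenance columns `DocId,SentIndex` are appended
#' when requested. [read_table()] inverts this losslessly on the three
#' mandatory columns, including phrases containing commas or quotes.
#'
#' @param table an `mlr_triplets` table.
#' @param path output path.
#' @param provenance include `DocId,SentIndex` columns?
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, provenance = FALSE) {
  df <- data.frame(Source = table$source, Edge = table$edge,
                   Target = table$target, stringsAsFactors = FALSE)
  if (provenance) {
    df$DocId <- table$doc_id
    df$SentIndex <- table$sent_index
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = which(vapply(df, is.character, logical(1))))
  invisible(path)
}

#' Read a triplet table from CSV
#'
#' @param path a CSV file with header `Source,Edge,Target` (extra columns,
#'   including `DocId,SentIndex`, are carried through when present).
#' @return an `mlr_triplets` table.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE, colClasses = "character")
  need <- c("Source", "Edge", "Target")
  if (!all(need %in% names(df))) {
    stop("format error: expected header Source,Edge,Target; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  rows <- data.frame(source = df$Source, edge = df$Edge, target = df$Target,
                     stringsAsFactors = FALSE)
  if ("DocId" %in% names(df)) rows$doc_id <- df$DocId
  if ("SentIndex" %in% names(df)) {
    rows$sent_index <- suppressWarnings(as.integer(df$SentIndex))
  }
  triplet_table(rows, stage_label = "loaded")
}

#' Default node colour classes
#'
#' Colour constants for graph exports: `default` blue for ordinary
#' entities, `joint2` orange for entities overlapping two triplets,
#' `joint3` purple for three or more (see [overlap_classes()]).
#'
#' @return named character vector of hex colours.
#' @export
kg_palette <- function() {
  c(default = "#1f78b4", joint2 = "#ff7f0e", joint3 = "#6a3d9a")
}

#' Export an interactive HTML knowledge graph
#'
#' Writes a single self-contained HTML document: the node and edge lists
#' are embedded once as a JSON block, and a small inline script renders
#' them on a canvas with mouse-wheel zoom, drag-to-pan and a force-directed
#' layout seeded deterministically. Node colours follow the supplied class
#' map (classes `default`, `joint2`, `joint3`).
#'
#' @param graph an `igraph` knowledge graph.
#' @param colors named character vector mapping node name to colour class;
#'   unmapped nodes get `"default"`.
#' @param path output `.html` path.
#' @param palette class-to-hex map, default [kg_palette()].
#' @param title document title.
#' @return `path`, invisibly.
#' @export
export_interactive <- function(graph, colors = character(0), path,
                               palette = kg_palette(), title = "Knowledge graph") {
  stopifnot(all(colors %in% names(palette)))
  nm <- igraph::V(graph)$name %||% character(0)
  disp <- igraph::vertex_attr(graph, "display") %||% nm
  cls <- unname(ifelse(nm %in% names(colors), colors[nm], "default"))
  nodes <- data.frame(id = nm, label = disp, class = cls,
                      color = unname(palette[cls]), stringsAsFactors = FALSE)
  if (igraph::ecount(graph) > 0L) {
    ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
    edges <- data.frame(from = ends[, 1], to = ends[, 2],
                        label = igraph::edge_attr(graph, "relation"),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        label = character(0), stringsAsFactors = FALSE)
  }
  payload <- jsonlite::toJSON(list(nodes = nodes, edges = edges),
                              dataframe = "rows", auto_unbox = TRUE)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", title, "</title>"),
    "<style>body{margin:0;font-family:sans-serif}canvas{display:block}</style>",
    "</head><body>",
    "<script type=\"application/json\" id=\"kg-data\">",
    as.character(payload),
    "</script>",
    "<canvas id=\"kg\"></canvas>",
    "<script>", interactive_js(), "</script>",
    "</body></html>")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(html, con)
  invisible(path)
}

# minimal canvas renderer: deterministic force layout, wheel zoom, drag pan
interactive_js <- function() {
  paste(
    "var data=JSON.parse(document.getElementById('kg-data').textContent);",
    "var cv=document.getElementById('kg'),cx=cv.getContext('2d');",
    "cv.width=window.innerWidth;cv.height=window.innerHeight;",
    "var seed=42;function rnd(){seed=(seed*1103515245+12345)%2147483648;return seed/2147483648;}",
    "var N=data.nodes,E=data.edges,ix={};",
    "N.forEach(function(n,i){ix[n.id]=i;n.x=rnd()*cv.width;n.y=rnd()*cv.height;});",
    "for(var it=0;it<200;it++){",
    " N.forEach(function(a){a.fx=0;a.fy=0;});",
    " for(var i=0;i<N.length;i++)for(var j=i+1;j<N.length;j++){",
    "  var dx=N[i].x-N[j].x,dy=N[i].y-N[j].y,d2=dx*dx+dy*dy+0.01,f=2000/d2;",
    "  N[i].fx+=dx*f;N[i].fy+=dy*f;N[j].fx-=dx*f;N[j].fy-=dy*f;}",
    " E.forEach(function(e){var a=N[ix[e.from]],b=N[ix[e.to]];",
    "  var dx=b.x-a.x,dy=b.y-a.y;a.fx+=dx*0.01;a.fy+=dy*0.01;b.fx-=dx*0.01;b.fy-=dy*0.01;});",
    " N.forEach(function(a){a.x+=Math.max(-5,Math.min(5,a.fx));a.y+=Math.max(-5,Math.min(5,a.fy));});}",
    "var scale=1,ox=0,oy=0,drag=null;",
    "function draw(){cx.setTransform(1,0,0,1,0,0);cx.clearRect(0,0,cv.width,cv.height);",
    " cx.setTransform(scale,0,0,scale,ox,oy);",
    " cx.strokeStyle='#999';cx.fillStyle='#333';cx.font='10px sans-serif';",
    " E.forEach(function(e){var a=N[ix[e.from]],b=N[ix[e.to]];",
    "  cx.beginPath();cx.moveTo(a.x,a.y);cx.lineTo(b.x,b.y);cx.stroke();",
    "  cx.fillText(e.label,(a.x+b.x)/2,(a.y+b.y)/2);});",
    " N.forEach(function(n){cx.beginPath();cx.arc(n.x,n.y,6,0,6.29);",
    "  cx.fillStyle=n.color;cx.fill();cx.fillStyle='#000';cx.fillText(n.label,n.x+8,n.y+3);});}",
    "cv.addEventListener('wheel',function(ev){ev.preventDefault();",
    " var k=ev.deltaY<0?1.1:0.9;scale*=k;ox=ev.offsetX-(ev.offsetX-ox)*k;",
    " oy=ev.offsetY-(ev.offsetY-oy)*k;draw();});",
    "cv.addEventListener('mousedown',function(ev){drag=[ev.clientX-ox,ev.clientY-oy];});",
    "window.addEventListener('mousemove',function(ev){if(drag){ox=ev.clientX-drag[0];oy=ev.clientY-drag[1];draw();}});",
    "window.addEventListener('mouseup',function(){drag=null;});",
    "draw();",
    sep = "\n")
}
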