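# Ontology-to-graph conversion.
#
# Ontologies are treated purely as class graphs: one node per named class, one
# directed child -> parent edge per asserted subclass axiom, and no reasoning
# over any other logical axiom. Class annotations (label, synonyms including
# brand names, definition) ride along on the nodes and later feed both the
# node-feature encoder and the rule-based entity tagger.

#' Construct an ontology graph from class records
#'
#' @param classes A list of class records, each a list with elements `id`,
#'   `label`, `synonyms` (character vector), `definition` and `parents`
#'   (character vector of class identifiers).
#' @param virtual_root Optional identifier for a virtual root node. When the
#'   class records contain more than one parentless class, a virtual root with
#'   this identifier adopts all of them; when `NULL` (the default) multiple
#'   parentless classes raise an error.
#'
#' @return An object of class `ontology_graph` with elements `classes` (named
#'   list of class records), `nodes` (sorted identifier vector), `edges`
#'   (two-column character matrix, child then parent) and `root`.
#' @export
ontology_graph <- function(classes, virtual_root = NULL) {
  ids <- unname(vapply(classes, function(x) x$id, character(1)))
  if (any(!nzchar(ids))) stop("class identifiers must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate class identifier: ", ids[duplicated(ids)][1])
  }
  names(classes) <- ids
  known <- ids
  # Parent references to classes outside the graph (e.g. dropped obsolete
  # classes or foreign ontologies) are discarded rather than invented.
  for (i in seq_along(classes)) {
    p <- classes[[i]]$parents
    classes[[i]]$parents <- sort(unique(p[p %in% known & p != classes[[i]]$id]))
    if (is.null(classes[[i]]$synonyms)) classes[[i]]$synonyms <- character(0)
    if (is.null(classes[[i]]$definition)) classes[[i]]$definition <- ""
    if (is.null(classes[[i]]$label)) classes[[i]]$label <- ""
  }
  parentless <- ids[vapply(classes, function(x) length(x$parents) == 0L,
                           logical(1))]
  if (length(parentless) == 0L) stop("ontology has no root (cyclic input?)")
  if (length(parentless) > 1L) {
    if (is.null(virtual_root)) {
      stop("ambiguous root: ", length(parentless),
           " parentless classes; supply virtual_root= to adopt them")
    }
    if (virtual_root %in% ids) stop("virtual root id collides with a class")
    for (p in parentless) classes[[p]]$parents <- virtual_root
    classes[[virtual_root]] <- list(id = virtual_root, label = virtual_root,
                                    synonyms = character(0), definition = "",
                                    parents = character(0))
    ids <- c(ids, virtual_root)
    parentless <- virtual_root
  }
  edges <- do.call(rbind, lapply(classes, function(x) {
    if (length(x$parents)) cbind(x$id, x$parents) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  dimnames(edges) <- list(NULL, c("child", "parent"))
  g <- structure(list(classes = classes[sort(ids)], nodes = sort(ids),
                      edges = edges[order(edges[, 1L], edges[, 2L]), ,
                                    drop = FALSE],
                      root = parentless),
                 class = "ontology_graph")
  validate_ontology_graph(g)
  g
}

validate_ontology_graph <- function(g) {
  ig <- as_igraph(g)
  if (!igraph::is_dag(ig)) stop("ontology graph contains a cycle")
  if (length(g$nodes) > 1L &&
      !igraph::is_connected(ig, mode = "weak")) {
    stop("ontology graph is not weakly connected")
  }
  invisible(g)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = TRUE)
  ig <- igraph::add_vertices(ig, length(g$nodes), name = g$nodes)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d nodes, %d edges, root '%s'\n",
              length(x$nodes), nrow(x$edges), x$root))
  invisible(x)
}

#' Number of nodes / edges of an ontology graph
#' @param g An `ontology_graph`.
#' @return An integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

obo_unquote <- function(x) {
  m <- regmatches(x, regexpr('"(\\\\.|[^"\\\\])*"', x))
  if (!length(m)) return("")
  gsub('\\\\(.)', "\\1", substr(m, 2L, nchar(m) - 1L))
}

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  # Stanza boundaries; only [Term] stanzas describe classes.
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("not a parsable OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  classes <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    body <- lines[seq(starts[s] + 1L, bounds[s + 1L] - 1L)]
    body <- body[nzchar(body)]
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    if (any(key == "is_obsolete" & tolower(val) == "true")) next
    id <- val[key == "id"][1]
    if (is.na(id)) next
    cls <- list(
      id = id,
      label = if (any(key == "name")) val[key == "name"][1] else "",
      synonyms = vapply(val[key == "synonym"], obo_unquote, character(1),
                        USE.NAMES = FALSE),
      definition = if (any(key == "def")) obo_unquote(val[key == "def"][1])
                   else "",
      parents = sub("\\s*[!{].*$", "", val[key == "is_a"]))
    classes[[length(classes) + 1L]] <- cls
  }
  classes
}

parse_owl <- function(path, synonym_props) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not a parsable OWL/RDF-XML file: ",
                                           path, " (", conditionMessage(e), ")"))
  ns <- xml2::xml_ns(doc)
  cls_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='Class' and @*[local-name()='about']]")
  syn_names <- sub("^.*[:#]", "", synonym_props)
  classes <- list()
  for (cn in cls_nodes) {
    id <- xml2::xml_attr(cn, "about")
    if (is.na(id) || !nzchar(id)) next
    depr <- xml2::xml_text(xml2::xml_find_first(
      cn, "./*[local-name()='deprecated']"))
    if (!is.na(depr) && tolower(depr) == "true") next
    label <- xml2::xml_text(xml2::xml_find_first(
      cn, "./*[local-name()='label']"))
    # Only subclass axioms pointing at a named class become edges; anonymous
    # restriction superclasses are logical axioms and are ignored.
    parents <- xml2::xml_attr(xml2::xml_find_all(
      cn, "./*[local-name()='subClassOf' and @*[local-name()='resource']]"),
      "resource")
    syns <- character(0)
    for (sp in syn_names) {
      syns <- c(syns, xml2::xml_text(xml2::xml_find_all(
        cn, sprintf("./*[local-name()='%s']", sp))))
    }
    defn <- xml2::xml_text(xml2::xml_find_first(
      cn, "./*[local-name()='IAO_0000115' or local-name()='definition']"))
    classes[[length(classes) + 1L]] <- list(
      id = id, label = if (is.na(label)) "" else label,
      synonyms = syns[nzchar(syns)],
      definition = if (is.na(defn)) "" else defn,
      parents = parents[!is.na(parents)])
  }
  classes
}

#' Load an ontology file as a directed class graph
#'
#' Reads an ontology in OWL (RDF/XML serialization) or OBO 1.4 flat-file
#' format and converts it to a directed graph with one node per named,
#' non-obsolete class and one child-to-parent edge per asserted subclass
#' axiom. All other logical axioms are ignored.
#'
#' @param path Path to the ontology file.
#' @param format Either `"owl"` or `"obo"`.
#' @param virtual_root See [ontology_graph()].
#' @param synonym_props For OWL input, the annotation-property local names (or
#'   CURIEs) read as synonyms.
#'
#' @return An [ontology_graph()].
#' @export
load_ontology <- function(path, format = c("owl", "obo"), virtual_root = NULL,
                          synonym_props = c("oboInOwl:hasExactSynonym",
                                            "oboInOwl:hasRelatedSynonym")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  classes <- switch(format,
                    obo = parse_obo(path),
                    owl = parse_owl(path, synonym_props))
  if (!length(classes)) stop("no classes found in ", path)
  ontology_graph(classes, virtual_root = virtual_root)
}

#' Combine two ontology graphs into one knowledge graph
#'
#' Takes the union of nodes and edges and adds exactly one bridging edge that
#' makes the root of `g2` a child of the root of `g1`, so two trees combine
#' into one tree: node and edge counts add up as |V1|+|V2| and |E1|+|E2|+1.
#'
#' @param g1,g2 Objects of class `ontology_graph` with disjoint identifiers.
#' @return The combined `ontology_graph`, rooted at `g1`'s root.
#' @export
combine_graphs <- function(g1, g2) {
  clash <- intersect(g1$nodes, g2$nodes)
  if (length(clash)) {
    stop("node identifier collision between graphs: ", clash[1])
  }
  classes <- c(g1$classes, g2$classes)
  classes[[g2$root]]$parents <- g1$root
  g <- ontology_graph(classes)
  # The adopted root stays a structural node: top-level labeling treats the
  # bridge as identifying the two roots, so each ontology keeps its own
  # branches (14 + 14 = 28 for two 14-branch ontologies).
  g$secondary_roots <- sort(c(g1$secondary_roots, g2$secondary_roots,
                              g2$root))
  g
}

#' Label every node by its top-level branch
#'
#' Assigns each node the child-of-root ancestor found by walking parent
#' links toward the root; for nodes with several parents the walk
#' deterministically follows the lexicographically smallest parent, except
#' that a node having a root itself as a parent is labeled as its own
#' branch. On a combined graph the bridging edge identifies the two roots:
#' branches are the children of either root (so two 14-branch ontologies
#' yield 28 classes) and the structural former root is excluded from the
#' labeled set, like the root.
#'
#' @param g An `ontology_graph`.
#' @return An object of class `top_level_labeling`: list with `labels` (named
#'   integer vector, indices `0:(n_classes-1)`), `n_classes` and `branches`
#'   (branch node id per label index).
#' @export
assign_top_level_labels <- function(g) {
  structural <- c(g$root, g$secondary_roots)
  top <- sort(setdiff(
    g$edges[g$edges[, "parent"] %in% structural, "child"], structural))
  if (!length(top)) stop("root has no children; nothing to label")
  branch_of <- new.env(parent = emptyenv())
  for (b in top) assign(b, b, envir = branch_of)
  walk <- function(n) {
    if (exists(n, envir = branch_of, inherits = FALSE)) {
      return(get(n, envir = branch_of))
    }
    p <- g$classes[[n]]$parents
    if (!length(p)) stop("node unreachable from root: ", n)
    b <- if (any(p %in% structural)) n else walk(sort(p)[1])
    assign(n, b, envir = branch_of)
    b
  }
  non_root <- setdiff(g$nodes, structural)
  branches <- vapply(non_root, walk, character(1))
  idx <- structure(seq_along(top) - 1L, names = top)
  structure(list(labels = structure(idx[branches], names = non_root),
                 n_classes = length(top), branches = top),
            class = "top_level_labeling")
}

#' @export
print.top_level_labeling <- function(x, ...) {
  cat(sprintf("top_level_labeling: %d nodes in %d classes\n",
              length(x$labels), x$n_classes))
  invisible(x)
}

# Depth of every node below the root (root = 0), following child edges.
node_depths <- function(g) {
  ig <- as_igraph(g)
  d <- igraph::distances(ig, v = g$nodes, to = g$root, mode = "out")
  structure(as.integer(d[, 1L]), names = g$nodes)
}

#' Write / read an ontology graph as plain text
#'
#' The on-disk form is a `edges.tsv` file (child TAB parent, one edge per
#' line) plus a `nodes.json` sidecar with the per-class annotations and the
#' root identifier.
#'
#' @param g An `ontology_graph`.
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_graph` returns `dir` invisibly; `read_graph` returns the
#'   reloaded `ontology_graph`.
#' @export
write_graph <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(g$edges[, "child"], g$edges[, "parent"], sep = "\t"),
             file.path(dir, "edges.tsv"))
  jsonlite::write_json(
    list(root = g$root,
         secondary_roots = as.list(g$secondary_roots),
         classes = lapply(unname(g$classes), function(x) {
           x[c("id", "label", "synonyms", "definition", "parents")]
         })),
    file.path(dir, "nodes.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "nodes.json"))
  classes <- lapply(meta$classes, function(x) {
    list(id = x$id, label = x$label,
         synonyms = as.character(unlist(x$synonyms)),
         definition = if (is.null(x$definition)) "" else x$definition,
         parents = as.character(unlist(x$parents)))
  })
  g <- ontology_graph(classes)
  sr <- as.character(unlist(meta$secondary_roots))
  if (length(sr)) g$secondary_roots <- sr
  g
}
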