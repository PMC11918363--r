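test_that("OBO files load into class graphs with subclass edges only", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.4", "",
    "[Term]", "id: A", "name: root class", "",
    "[Term]", "id: B", "name: b class",
    "synonym: \"b-ish\" EXACT []",
    "def: \"the b class\" [src]", "is_a: A ! root class", "",
    "[Term]", "id: C", "name: c class", "is_a: A", "",
    "[Term]", "id: D", "name: dead class", "is_obsolete: true",
    "is_a: A", "",
    "[Typedef]", "id: part_of"), path)
  g <- load_ontology(path, "obo")
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)
  expect_equal(g$root, "A")
  expect_equal(g$classes$B$synonyms, "b-ish")
  expect_equal(g$classes$B$definition, "the b class")
  # obsolete classes are dropped on load
  expect_false("D" %in% g$nodes)
})

test_that("single-class OBO gives the degenerate one-node graph", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: ONLY", "name: only"), path)
  g <- load_ontology(path, "obo")
  expect_equal(n_nodes(g), 1L)
  expect_equal(n_edges(g), 0L)
})

test_that("OWL RDF/XML loads with labels, synonyms and named superclasses", {
  path <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '  xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">',
    '<owl:Class rdf:about="http://x/A"><rdfs:label>root</rdfs:label></owl:Class>',
    '<owl:Class rdf:about="http://x/B"><rdfs:label>child</rdfs:label>',
    '  <oboInOwl:hasExactSynonym>kid</oboInOwl:hasExactSynonym>',
    '  <rdfs:subClassOf rdf:resource="http://x/A"/>',
    '  <rdfs:subClassOf><owl:Restriction/></rdfs:subClassOf>',
    '</owl:Class>',
    '<owl:Class rdf:about="http://x/C"><owl:deprecated>true</owl:deprecated>',
    '  <rdfs:subClassOf rdf:resource="http://x/A"/></owl:Class>',
    '</rdf:RDF>'), path)
  g <- load_ontology(path, "owl")
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_edges(g), 1L)
  expect_equal(g$classes[["http://x/B"]]$synonyms, "kid")
  expect_error(load_ontology(withr::local_tempfile(lines = "not xml",
                                                   fileext = ".owl"), "owl"),
               "parsable")
})

test_that("multiple parentless classes need a virtual root", {
  classes <- list(list(id = "A", label = "a", parents = character(0)),
                  list(id = "B", label = "b", parents = character(0)))
  expect_error(ontology_graph(classes), "ambiguous root")
  g <- ontology_graph(classes, virtual_root = "VROOT")
  expect_equal(g$root, "VROOT")
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)
})

test_that("generated tree ontologies have n nodes and n-1 edges", {
  for (n in c(10L, 137L, 860L)) {
    g <- generate_ontology(ontology_spec(n_classes = n,
                                         n_top = min(14L, n - 1L),
                                         seed = n))
    expect_equal(n_nodes(g), n)
    expect_equal(n_edges(g), n - 1L)
  }
})

test_that("combining graphs adds node sets and one bridging edge", {
  g1 <- generate_ontology(ontology_spec(n_classes = 3L, n_top = 2L,
                                        prefix = "A", seed = 1L))
  g2 <- generate_ontology(ontology_spec(n_classes = 4L, n_top = 2L,
                                        prefix = "B", seed = 2L))
  g <- combine_graphs(g1, g2)
  expect_equal(n_nodes(g), 7L)
  expect_equal(n_edges(g), 6L)
  expect_equal(g$root, g1$root)
  # two single-node graphs: bridge forced
  s1 <- ontology_graph(list(list(id = "X", label = "x",
                                 parents = character(0))))
  s2 <- ontology_graph(list(list(id = "Y", label = "y",
                                 parents = character(0))))
  s <- combine_graphs(s1, s2)
  expect_equal(n_nodes(s), 2L)
  expect_equal(n_edges(s), 1L)
  expect_error(combine_graphs(g1, g1), "collision")
})

test_that("top-level labels follow the child-of-root branch", {
  g <- ontology_graph(list(
    list(id = "R", label = "r", parents = character(0)),
    list(id = "X", label = "x", parents = "R"),
    list(id = "Y", label = "y", parents = "R"),
    list(id = "x1", label = "x1", parents = "X")))
  lab <- assign_top_level_labels(g)
  expect_equal(lab$n_classes, 2L)
  expect_equal(lab$labels[["X"]], 0L)
  expect_equal(lab$labels[["x1"]], 0L)
  expect_equal(lab$labels[["Y"]], 1L)
  # chain: everything under the single branch
  ch <- ontology_graph(list(
    list(id = "R", label = "r", parents = character(0)),
    list(id = "a", label = "a", parents = "R"),
    list(id = "b", label = "b", parents = "a"),
    list(id = "c", label = "c", parents = "b")))
  lc <- assign_top_level_labels(ch)
  expect_equal(lc$n_classes, 1L)
  expect_true(all(lc$labels == 0L))
})

test_that("labeling is invariant to node-insertion order and covers |V|-1 nodes", {
  g <- generate_ontology(ontology_spec(n_classes = 40L, n_top = 5L,
                                       seed = 77L))
  lab1 <- assign_top_level_labels(g)
  g2 <- ontology_graph(rev(unname(g$classes)))
  lab2 <- assign_top_level_labels(g2)
  expect_equal(lab1$labels[sort(names(lab1$labels))],
               lab2$labels[sort(names(lab2$labels))])
  expect_equal(length(lab1$labels), n_nodes(g) - 1L)
  expect_equal(sum(table(lab1$labels)), n_nodes(g) - 1L)
})

test_that("a combined graph keeps both ontologies' top-level branches", {
  g1 <- generate_ontology(ontology_spec(n_classes = 60L, n_top = 14L,
                                        prefix = "P", seed = 5L))
  g2 <- generate_ontology(ontology_spec(n_classes = 60L, n_top = 14L,
                                        prefix = "Q", seed = 6L))
  lab <- assign_top_level_labels(combine_graphs(g1, g2))
  expect_equal(lab$n_classes, 28L)
})

test_that("graphs round-trip through the edge-list + sidecar format", {
  g <- generate_ontology(ontology_spec(n_classes = 25L, n_top = 4L,
                                       synonyms_per_class = 2L, seed = 9L))
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  g2 <- read_graph(dir)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$classes, g$classes)
  expect_equal(g2$root, g$root)
})
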