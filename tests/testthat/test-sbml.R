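test_that("SBML write/read round-trips the toy network exactly", {
  net <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, path)
  back <- read_sbml(path)
  expect_equal(length(back$reactions), length(net$reactions))
  expect_equal(nrow(back$metabolites), nrow(net$metabolites))
  expect_setequal(back$genes, net$genes)
  for (rid in names(net$reactions)) {
    a <- net$reactions[[rid]]; b <- back$reactions[[rid]]
    expect_equal(sort(names(b$stoichiometry)), sort(names(a$stoichiometry)),
                 info = rid)
    expect_equal(b$stoichiometry[names(a$stoichiometry)], a$stoichiometry,
                 info = rid)
    expect_equal(b$lb, a$lb, info = rid)
    expect_equal(b$ub, a$ub, info = rid)
    expect_equal(parse_gene_rule(b$gene_rule), parse_gene_rule(a$gene_rule),
                 info = rid)
    expect_equal(b$subsystem, a$subsystem, info = rid)
  }
})

test_that("default bounds follow the reversible flag when absent", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="a_c" compartment="c"/><species id="b_c" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R1" reversible="true">',
    '<listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b_c"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R2" reversible="false">',
    '<listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b_c"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  net <- read_sbml(path)
  expect_equal(net$reactions$R1$lb, -1000)
  expect_equal(net$reactions$R1$ub, 1000)
  expect_equal(net$reactions$R2$lb, 0)
  expect_equal(net$reactions$R2$ub, 1000)
  # default stoichiometry of an omitted attribute is 1
  expect_equal(net$reactions$R1$stoichiometry, c(a_c = -1, b_c = 1))
})

test_that("fbc-style bounds and gene associations are read", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    '<model id="m">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="a_c" compartment="c"/><species id="b_c" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfParameters>',
    '<parameter id="lb_m5" value="-5" constant="true"/>',
    '<parameter id="ub_7" value="7" constant="true"/>',
    '</listOfParameters>',
    '<fbc:listOfGeneProducts>',
    '<fbc:geneProduct fbc:id="G_x" fbc:label="GENEX"/>',
    '<fbc:geneProduct fbc:id="G_y" fbc:label="GENEY"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfReactions>',
    '<reaction id="R1" reversible="true" fbc:lowerFluxBound="lb_m5" fbc:upperFluxBound="ub_7">',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="G_x"/>',
    '<fbc:and><fbc:geneProductRef fbc:geneProduct="G_y"/>',
    '<fbc:geneProductRef fbc:geneProduct="G_x"/></fbc:and>',
    '</fbc:or></fbc:geneProductAssociation>',
    '<listOfReactants><speciesReference species="a_c" stoichiometry="2"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b_c" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  net <- read_sbml(path)
  expect_equal(net$reactions$R1$lb, -5)
  expect_equal(net$reactions$R1$ub, 7)
  expect_equal(net$reactions$R1$stoichiometry, c(a_c = -2, b_c = 1))
  tree <- parse_gene_rule(net$reactions$R1$gene_rule)
  expect_setequal(gene_rule_genes(tree), c("GENEX", "GENEY"))
  expect_equal(tree$op, "or")
})

test_that("malformed XML and missing stoichiometry raise clear errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed>", bad)
  expect_error(read_sbml(bad), "parse error")

  empty_rxn <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies><species id="a_c" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="RX"/></listOfReactions></model></sbml>'),
    empty_rxn)
  expect_error(read_sbml(empty_rxn), "RX")

  expect_error(read_sbml("no/such/file.xml"), "not found")
})

test_that("boundary species are dropped from stoichiometries", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="a_c" compartment="c"/>',
    '<species id="a_b" compartment="b" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="EX" reversible="true">',
    '<listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="a_b"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  net <- read_sbml(path)
  expect_equal(net$reactions$EX$stoichiometry, c(a_c = -1))
  expect_true(is_exchange(net)[["EX"]])
})
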