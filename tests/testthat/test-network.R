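test_that("TSV networks parse, validate, and round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# metabolites",
    "id\tname\trole\tcompartment\tcarbon",
    "Ax\tA external\texternal\tmedium\t6",
    "Bx\tB external\texternal\tmedium\t6",
    "A\tA\tinternal\tcytosol\t6",
    "B\tB\tinternal\tcytosol\t6",
    "# reactions",
    "id\tequation\tnotes",
    "v1\tAx -> A\tuptake",
    "v2\tA <-> B\tisomerase",
    "v3\tB -> Bx\texport"
  ), tsv)
  net <- suppressMessages(read_network(tsv))
  expect_s3_class(net, "rxn_network")
  expect_equal(nrow(net$reactions), 3L)
  expect_equal(sum(net$metabolites$role == "internal"), 2L)
  expect_true(net$reactions$reversible[2])
  expect_equal(net$reactions$stoich[[2]], c(A = -1, B = 1))

  # write -> read round-trips identically
  out <- tempfile(fileext = ".tsv")
  write_network(net, out)
  net2 <- suppressMessages(read_network(out))
  expect_equal(net2$reactions$stoich, net$reactions$stoich)
  expect_equal(net2$metabolites$carbon, net$metabolites$carbon)
  expect_equal(net2$reactions$reversible, net$reactions$reversible)
})

test_that("validation rejects duplicates and unknown metabolites by name", {
  mets <- dplyr::bind_rows(tiny_met("A", "internal"), tiny_met("B", "internal"))
  expect_error(
    rxn_network(mets, dplyr::bind_rows(tiny_rxn("v1", "A -> Q"))),
    "unknown metabolite Q"
  )
  expect_error(
    rxn_network(dplyr::bind_rows(mets, tiny_met("A", "internal")),
                dplyr::bind_rows(tiny_rxn("v1", "A -> B"))),
    "duplicate metabolite id: A"
  )
  expect_error(
    rxn_network(mets, dplyr::bind_rows(tiny_rxn("v1", "A -> B"),
                                       tiny_rxn("v1", "B -> A"))),
    "duplicate reaction id: v1"
  )
})

test_that("stoichiometric matrix follows declaration order and drops externals", {
  net <- toy_network("linear_chain", n = 3)
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(unname(S), rbind(c(1, -1, 0), c(0, 1, -1)))
  expect_equal(rownames(S), c("M1", "M2"))
  expect_equal(colnames(S), c("v1", "v2", "v3"))

  # no internal metabolites: 0 x N, accepted
  fan <- fan_fixture()
  S0 <- stoichiometric_matrix(fan$net)
  expect_equal(dim(S0), c(0L, 3L))
})

test_that("split_reversible counts, idempotence, and signed recombination", {
  net <- rxn_network(
    dplyr::bind_rows(tiny_met("Ax", "external"), tiny_met("A", "internal"),
                     tiny_met("B", "internal"), tiny_met("Bx", "external")),
    dplyr::bind_rows(tiny_rxn("v1", "Ax -> A"), tiny_rxn("v2", "A <-> B"),
                     tiny_rxn("v3", "B -> Bx"))
  )
  sp <- split_reversible(net)
  expect_equal(nrow(sp$reactions), 4L)
  expect_false(any(sp$reactions$reversible))

  # idempotent on a fully irreversible network
  sp2 <- split_reversible(sp)
  expect_equal(sp2$reactions$id, sp$reactions$id)

  # split preserves the signed nullspace: a signed steady flux maps to a
  # nonnegative split flux and back; equal fwd/rev flux cancels to zero
  smap <- attr(sp, "split_map")
  v_signed <- c(v1 = 1, v2 = -1, v3 = 1) # v2 running backwards
  v_split <- setNames(numeric(nrow(smap)), smap$split_id)
  for (i in seq_len(nrow(smap))) {
    x <- v_signed[[smap$orig_id[i]]] * smap$sign[i]
    v_split[i] <- max(x, 0)
  }
  back <- polarflux:::recombine_flux(v_split, smap, net$reactions$id)
  expect_equal(unname(back), unname(v_signed))
  cancel <- setNames(c(0, 2, 2, 0), smap$split_id)
  expect_equal(polarflux:::recombine_flux(cancel, smap, net$reactions$id)[["v2"]], 0)
})

test_that("carbon balance flags only non-boundary imbalances", {
  net <- toy_network("two_substrate_mini")
  bal <- suppressWarnings(carbon_balance(net))
  off <- dplyr::filter(bal, !boundary, abs(imbalance) > 1e-9)
  # only the biomass-precursor syntheses break carbon (X carries no carbon
  # count in the fixture); every catabolic conversion balances
  expect_setequal(off$reaction, c("v8", "v10"))

  bad <- rxn_network(
    dplyr::bind_rows(tiny_met("A", "internal", 6), tiny_met("B", "internal", 2),
                     tiny_met("Ax", "external", 6)),
    dplyr::bind_rows(tiny_rxn("v0", "Ax -> A"), tiny_rxn("v1", "A -> B"))
  )
  expect_warning(carbon_balance(bad), "carbon imbalance.*v1")
})

test_that("SBML level 3 documents read with boundary species as external", {
  sbml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="toy">',
    '<listOfSpecies>',
    '<species id="Ax" compartment="e" boundaryCondition="true"/>',
    '<species id="A" compartment="c" boundaryCondition="false"/>',
    '<species id="B" compartment="c" boundaryCondition="false"/>',
    '<species id="Bx" compartment="e" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="v1" reversible="false">',
    '<listOfReactants><speciesReference species="Ax" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="v2" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '<reaction id="v3" reversible="false">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="Bx" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>'
  ), sbml)
  net <- suppressWarnings(read_network(sbml, format = "sbml"))
  expect_equal(nrow(net$reactions), 3L)
  expect_equal(sort(net$metabolites$id[net$metabolites$role == "external"]),
               c("Ax", "Bx"))
  expect_true(net$reactions$reversible[net$reactions$id == "v2"])
  expect_equal(net$reactions$stoich[[2]], c(A = -1, B = 2))
})
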