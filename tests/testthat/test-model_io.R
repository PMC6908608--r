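test_that("tabular and JSON round-trips reproduce the model field by field", {
  m <- makeChainModel(0.5, 10)
  d <- withr::local_tempdir()
  writeModel(m, d, "tabular")
  m2 <- readModel(d)
  expect_equal(reactions(m2), reactions(m))
  expect_equal(metabolites(m2), metabolites(m))
  expect_equal(m2@stoichiometry, m@stoichiometry)
  expect_equal(biomassId(m2), biomassId(m))
  jp <- withr::local_tempfile(fileext = ".json")
  writeModel(m, jp)
  m3 <- readModel(jp)
  expect_equal(m3@stoichiometry, m@stoichiometry)
  expect_equal(reactions(m3), reactions(m))
})

test_that("model validation names the offending record", {
  met <- data.frame(id = "a_c", compartment = "c")
  rxn <- data.frame(id = c("R1", "BIO"), lb = 0, ub = 10,
                    is_exchange = FALSE, is_biomass = c(FALSE, TRUE))
  expect_error(
    MetabolicModel("bad", met, rxn,
                   list(R1 = c(ghost_c = -1), BIO = c(a_c = -1))),
    "ghost_c")
  # unknown compartment
  expect_error(validObject(
    new("MetabolicModel", id = "bad2",
        metabolites = data.frame(id = "a_x", name = "a", compartment = "x",
                                 carbon = NA_real_),
        reactions = data.frame(id = "BIO", lb = 0, ub = 1, is_exchange = FALSE,
                               is_biomass = TRUE),
        stoichiometry = list(BIO = c(a_x = -1)), biomassId = "BIO")),
    "compartment")
  # missing biomass
  expect_error(
    MetabolicModel("bad3", met,
                   data.frame(id = "R1", lb = 0, ub = 1, is_exchange = FALSE,
                              is_biomass = FALSE),
                   list(R1 = c(a_c = -1))),
    "biomass")
  # lb > ub
  expect_error(validObject(
    new("MetabolicModel", id = "bad4",
        metabolites = data.frame(id = "a_c", name = "a", compartment = "c",
                                 carbon = NA_real_),
        reactions = data.frame(id = "BIO", lb = 5, ub = 1, is_exchange = FALSE,
                               is_biomass = TRUE),
        stoichiometry = list(BIO = c(a_c = -1)), biomassId = "BIO")),
    "lb > ub")
})

test_that("applyMedium sets uptake bounds, is idempotent, and warns on absent exchanges", {
  m <- makeChainModel(0.5, 10)
  med <- glcMedium(7)
  m2 <- applyMedium(m, med)
  expect_equal(reactions(m2)$lb[reactions(m2)$id == "EX_glc"], -7)
  m3 <- applyMedium(m2, med)
  expect_identical(reactions(m3), reactions(m2))
  # empty medium closes all uptake
  m4 <- applyMedium(m, Medium("none"))
  expect_true(all(reactions(m4)$lb[reactions(m4)$is_exchange] == 0))
  # absent metabolite: warning, bounds otherwise unchanged
  expect_warning(m5 <- applyMedium(m, Medium("odd", c(xyz_e = 5))), "xyz_e")
  expect_true(all(reactions(m5)$lb[reactions(m5)$is_exchange] == 0))
})

test_that("tabular readers validate headers, types and controls", {
  d <- withr::local_tempdir()
  mp <- file.path(d, "med.csv")
  writeLines(c("metabolite_id,max_uptake", "glc_e,10", "suc_e,2"), mp)
  med <- readMedium(mp)
  expect_s4_class(med, "Medium")
  expect_equal(uptakeLimits(med), c(glc_e = 10, suc_e = 2))
  bad <- file.path(d, "bad.csv")
  writeLines(c("metabolite,max_uptake", "glc_e,10"), bad)
  expect_error(readMedium(bad), "metabolite_id")

  hp <- file.path(d, "hits.tsv")
  writeLines(c("genome_id\tquery_id\tbitscore\tqcovs", "g1\tr1\t55\t0.8"), hp)
  expect_equal(readHitTable(hp)$qcovs, 0.8)
  hp2 <- file.path(d, "hits2.tsv")
  writeLines(c("genome_id\tquery_id\tbitscore\tqcovs", "g1\tr1\t55\t80"), hp2)
  expect_message(h2 <- readHitTable(hp2), "percent")
  expect_equal(h2$qcovs, 0.8)

  pp <- file.path(d, "plate.csv")
  df <- expand.grid(strain = "s1", substrate = c("subA", "water"),
                    replicate = 1, time_min = c(0, 2760))
  df$od <- 0.1
  utils::write.csv(df, pp, row.names = FALSE)
  expect_s3_class(readPlate(pp), "data.frame")
  df2 <- df[df$substrate != "water", ]
  utils::write.csv(df2, pp, row.names = FALSE)
  expect_error(readPlate(pp), "water")
})

test_that("the SBML subset reader recovers species, stoichiometry and bounds", {
  skip_if_not_installed("xml2")
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="glc_e" compartment="e"/>
   <species id="glc_c" compartment="c"/>
   <species id="prec_c" compartment="c"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb_ex" value="-10"/><parameter id="ub_def" value="1000"/>
  </listOfParameters>
  <listOfReactions>
   <reaction id="EX_glc" reversible="true" lowerFluxBound="lb_ex" upperFluxBound="ub_def">
    <listOfReactants><speciesReference species="glc_e" stoichiometry="1"/></listOfReactants>
   </reaction>
   <reaction id="T_glc" reversible="false">
    <listOfReactants><speciesReference species="glc_e"/></listOfReactants>
    <listOfProducts><speciesReference species="glc_c"/></listOfProducts>
   </reaction>
   <reaction id="CAT" reversible="false">
    <listOfReactants><speciesReference species="glc_c"/></listOfReactants>
    <listOfProducts><speciesReference species="prec_c" stoichiometry="0.5"/></listOfProducts>
   </reaction>
   <reaction id="biomass" reversible="false">
    <listOfReactants><speciesReference species="prec_c"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- readModel(f)
  expect_equal(modelId(m), "toy")
  expect_equal(biomassId(m), "biomass")
  expect_equal(reactions(m)$lb[reactions(m)$id == "EX_glc"], -10)
  expect_equal(solveFBA(m)$objective, 5, tolerance = 1e-7)
})
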