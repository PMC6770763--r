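## inline SBML fixtures (Level 2 Version 4, the dialect COPASI exports)

sbmlDoc <- function(body, level = 2L) {
  ns <- if (level == 2L) "http://www.sbml.org/sbml/level2/version4"
        else "http://www.sbml.org/sbml/level3/version1/core"
  tmp <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="%d" version="%d">', ns, level,
            if (level == 2L) 4L else 1L),
    body,
    '</sbml>'), tmp)
  tmp
}

massActionFixture <- function() sbmlDoc(c(
  '<model id="mini">',
  ' <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
  ' <listOfSpecies>',
  '  <species id="A" compartment="cell" initialConcentration="2"/>',
  '  <species id="B" compartment="cell" initialConcentration="0"/>',
  ' </listOfSpecies>',
  ' <listOfReactions>',
  '  <reaction id="conv" reversible="false">',
  '   <listOfReactants><speciesReference species="A"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="B"/></listOfProducts>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><times/><ci>cell</ci><ci>k1</ci><ci>A</ci></apply>',
  '    </math>',
  '    <listOfParameters><parameter id="k1" value="0.25"/></listOfParameters>',
  '   </kineticLaw>',
  '  </reaction>',
  ' </listOfReactions>',
  '</model>'))

hmmVmaxFixture <- function() sbmlDoc(c(
  '<model id="mm">',
  ' <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
  ' <listOfSpecies>',
  '  <species id="S" compartment="cell" initialConcentration="4"/>',
  '  <species id="P" compartment="cell" initialConcentration="0"/>',
  '  <species id="E" compartment="cell" initialConcentration="0.5"/>',
  ' </listOfSpecies>',
  ' <listOfParameters><parameter id="Vmax" value="3"/>',
  '  <parameter id="Km" value="2"/><parameter id="kcat" value="6"/>',
  ' </listOfParameters>',
  ' <listOfReactions>',
  '  <reaction id="vmax_form" reversible="false">',
  '   <listOfReactants><speciesReference species="S"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="P"/></listOfProducts>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><divide/>',
  '      <apply><times/><ci>Vmax</ci><ci>S</ci></apply>',
  '      <apply><plus/><ci>Km</ci><ci>S</ci></apply>',
  '     </apply>',
  '    </math>',
  '   </kineticLaw>',
  '  </reaction>',
  '  <reaction id="enzyme_form" reversible="false">',
  '   <listOfReactants><speciesReference species="S"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="P"/></listOfProducts>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><divide/>',
  '      <apply><times/><ci>kcat</ci><ci>E</ci><ci>S</ci></apply>',
  '      <apply><plus/><ci>Km</ci><ci>S</ci></apply>',
  '     </apply>',
  '    </math>',
  '   </kineticLaw>',
  '  </reaction>',
  '  <reaction id="modifier_form" reversible="false">',
  '   <listOfReactants><speciesReference species="S"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="P"/></listOfProducts>',
  '   <listOfModifiers><modifierSpeciesReference species="E"/></listOfModifiers>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><divide/>',
  '      <apply><times/><ci>kcat</ci><ci>E</ci><ci>S</ci></apply>',
  '      <apply><plus/><ci>Km</ci><ci>S</ci></apply>',
  '     </apply>',
  '    </math>',
  '   </kineticLaw>',
  '  </reaction>',
  ' </listOfReactions>',
  '</model>'))

reversibleFixture <- function() sbmlDoc(c(
  '<model id="rev">',
  ' <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
  ' <listOfSpecies>',
  '  <species id="A" compartment="cell" initialConcentration="2"/>',
  '  <species id="B" compartment="cell" initialConcentration="0"/>',
  ' </listOfSpecies>',
  ' <listOfReactions>',
  '  <reaction id="ab" reversible="true">',
  '   <listOfReactants><speciesReference species="A"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="B"/></listOfProducts>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><minus/>',
  '      <apply><times/><ci>kf</ci><ci>A</ci></apply>',
  '      <apply><times/><ci>kr</ci><ci>B</ci></apply>',
  '     </apply>',
  '    </math>',
  '    <listOfParameters><parameter id="kf" value="1"/>',
  '     <parameter id="kr" value="0.5"/></listOfParameters>',
  '   </kineticLaw>',
  '  </reaction>',
  ' </listOfReactions>',
  '</model>'))

## Hill coefficient 2: matches none of the three variants -> opaque
hillFixture <- function() sbmlDoc(c(
  '<model id="hill">',
  ' <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
  ' <listOfSpecies>',
  '  <species id="S" compartment="cell" initialConcentration="1.5"/>',
  '  <species id="P" compartment="cell" initialConcentration="0"/>',
  ' </listOfSpecies>',
  ' <listOfParameters><parameter id="V" value="2"/>',
  '  <parameter id="K" value="1"/></listOfParameters>',
  ' <listOfReactions>',
  '  <reaction id="hill2" reversible="false">',
  '   <listOfReactants><speciesReference species="S"/></listOfReactants>',
  '   <listOfProducts><speciesReference species="P"/></listOfProducts>',
  '   <kineticLaw>',
  '    <math xmlns="http://www.w3.org/1998/Math/MathML">',
  '     <apply><divide/>',
  '      <apply><times/><ci>V</ci><apply><power/><ci>S</ci><cn>2</cn></apply></apply>',
  '      <apply><plus/><apply><power/><ci>K</ci><cn>2</cn></apply>',
  '       <apply><power/><ci>S</ci><cn>2</cn></apply></apply>',
  '     </apply>',
  '    </math>',
  '   </kineticLaw>',
  '  </reaction>',
  ' </listOfReactions>',
  '</model>'))

test_that("a minimal mass-action document imports with exact counts", {
  res <- readSBML(massActionFixture())
  expect_equal(res$report@nSpecies, 2L)
  expect_equal(res$report@nReactions, 1L)
  expect_equal(unname(res$report@lawCounts["MassAction"]), 1L)
  law <- getReaction(res$model, "conv")@law
  expect_s4_class(law, "MassActionLaw")
  expect_equal(law@k1, 0.25)
  expect_true(is.na(law@k2))
  expect_equal(getSpecies(res$model, "A")@initialConcentration, 2)
})

test_that("Michaelis-Menten forms map to HMM with and without enzyme", {
  res <- readSBML(hmmVmaxFixture())
  expect_equal(unname(res$report@lawCounts["HMM"]), 2L)
  vmax <- getReaction(res$model, "vmax_form")@law
  expect_s4_class(vmax, "HMMLaw")
  expect_equal(vmax@Kcat, 3)
  expect_equal(vmax@Km, 2)
  expect_true(is.na(vmax@enzyme))
  enz <- getReaction(res$model, "enzyme_form")@law
  expect_s4_class(enz, "HMMLaw")
  expect_identical(enz@enzyme, "E")
  expect_equal(enz@Kcat, 6)
})

test_that("a modifier-declared cofactor maps to the modified HMM variant", {
  res <- readSBML(hmmVmaxFixture())
  expect_equal(unname(res$report@lawCounts["ModifiedHMM"]), 1L)
  mod <- getReaction(res$model, "modifier_form")
  expect_true("E" %in% mod@modifiers)
  expect_s4_class(mod@law, "ModifiedHMMLaw")
  expect_identical(mod@law@modifier, "E")
})

test_that("reversible mass action captures both rate constants", {
  res <- readSBML(reversibleFixture())
  law <- getReaction(res$model, "ab")@law
  expect_s4_class(law, "MassActionLaw")
  expect_equal(law@k1, 1)
  expect_equal(law@k2, 0.5)
})

test_that("unrecognized laws fall back to opaque expressions that simulate", {
  res <- readSBML(hillFixture())
  expect_equal(unname(res$report@lawCounts["Opaque"]), 1L)
  expect_identical(res$report@unmapped, "hill2")
  m <- res$model
  s <- fastSettings(2, nIntervals = 20)
  tr <- simulateNetwork(m, s)
  # independent oracle: integrate the Hill law with hand-written dynamics
  hillRhs <- function(t, y) {
    v <- 2 * y[1]^2 / (1 + y[1]^2)
    c(-v, v)
  }
  y <- c(1.5, 0)
  h <- 2 / 20000
  for (i in 1:20000) {
    k1 <- hillRhs(0, y); k2 <- hillRhs(0, y + h / 2 * k1)
    k3 <- hillRhs(0, y + h / 2 * k2); k4 <- hillRhs(0, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(unname(tr@values[, 21]), y, tolerance = 1e-5)
})

test_that("unsupported SBML features raise explicit errors", {
  evented <- sbmlDoc(c(
    '<model id="ev">',
    ' <listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    ' <listOfSpecies><species id="A" compartment="c" initialConcentration="1"/></listOfSpecies>',
    ' <listOfEvents><event id="e1"/></listOfEvents>',
    '</model>'))
  expect_error(readSBML(evented), "events")
  notSbml <- tempfile(fileext = ".xml")
  writeLines("<foo/>", notSbml)
  expect_error(readSBML(notSbml), "not an SBML document")
})

test_that("import is deterministic and order-stable", {
  f <- hmmVmaxFixture()
  m1 <- readSBML(f)$model
  m2 <- readSBML(f)$model
  expect_identical(speciesIds(m1), speciesIds(m2))
  expect_identical(modelFingerprint(m1), modelFingerprint(m2))
})

test_that("the native format round-trips models losslessly", {
  for (m in list(referenceCascade(),
                 networkModel(list(compartment("cell")),
                              list(speciesNode("A", compartment = "cell")),
                              list()))) {
    tmp <- tempfile(fileext = ".yaml")
    writeNetwork(m, tmp)
    back <- readNetwork(tmp)
    expect_identical(modelFingerprint(back), modelFingerprint(m))
    expect_identical(validateNetwork(back), validateNetwork(m))
  }
})

test_that("opaque imported laws survive the native round-trip", {
  m <- readSBML(hillFixture())$model
  tmp <- tempfile(fileext = ".yaml")
  writeNetwork(m, tmp)
  back <- readNetwork(tmp)
  r1 <- getReaction(m, "hill2")
  r2 <- getReaction(back, "hill2")
  expect_identical(r2@law@expression, r1@law@expression)
  # re-evaluated rates agree at random states
  set.seed(42)
  for (i in 1:10) {
    st <- c(S = runif(1, 0, 5), P = runif(1, 0, 5))
    expect_equal(pdl1net:::evalReactionRate(r2, st),
                 pdl1net:::evalReactionRate(r1, st))
  }
})

test_that("schema version mismatches are refused", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines("schema: something-else/9", tmp)
  expect_error(readNetwork(tmp), "schema version mismatch")
})
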