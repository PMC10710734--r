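#' Export the reaction network as Antimony model text
#'
#' Emits the six reactions with their rate laws: R1 `S1 -> S2` at `k1*S1`,
#' R2 `S2 -> S1` at `k2*S2`, R3 autocatalysis `S1 -> 2 S1` at `k3*S1`,
#' R4 zeroth-order degradation `S1 -> ` at constant rate `k4`,
#' R5 S1-controlled degradation `S2 -> ` at `k5*S1`,
#' R6 zeroth-order synthesis ` -> S2` at constant rate `k6`.
#' Parameter values are written at 17 significant digits so the text
#' round-trips exactly.
#'
#' @param p a [kineticParameters()] object.
#' @param x0 an [initialState()] (or length-2 numeric).
#' @return A single character string of Antimony model text.
#' @export
exportAntimony <- function(p, x0) {
  stopifnot(inherits(p, "KineticParameters"))
  x0 <- as.numeric(x0)
  num <- .shortestNumber
  paste0(
    "model two_species_harmonic_oscillator\n",
    "  // species and initial concentrations\n",
    sprintf("  S1 = %s;\n", num(x0[1])),
    sprintf("  S2 = %s;\n", num(x0[2])),
    "  // kinetic constants (k3 = k1 + k2 and k5 = k3 + kd are dependent)\n",
    paste(sprintf("  k%d = %s;", 1:6,
                  vapply(p[c("k1", "k2", "k3", "k4", "k5", "k6")],
                         num, character(1))),
          collapse = "\n"),
    "\n  // reactions\n",
    "  R1: S1 -> S2; k1*S1;\n",
    "  R2: S2 -> S1; k2*S2;\n",
    "  R3: S1 -> 2 S1; k3*S1;\n",
    "  R4: S1 -> ; k4;\n",
    "  R5: S2 -> ; k5*S1;\n",
    "  R6: -> S2; k6;\n",
    "end\n"
  )
}

# shortest decimal representation that round-trips to the exact double
.shortestNumber <- function(v) {
  for (d in 1:17) {
    s <- trimws(formatC(v, digits = d, format = "g"))
    if (as.numeric(s) == v) return(s)
  }
  s
}

#' Parse kinetic parameters back out of exported Antimony text
#'
#' Inverse of [exportAntimony()] for round-trip checks; only understands the
#' text emitted by this package.
#'
#' @param text Antimony model text from [exportAntimony()].
#' @return A list with `parameters` and `state`, as [readParameters()].
#' @export
parseAntimony <- function(text) {
  grab <- function(name) {
    m <- regmatches(text, regexec(paste0(name, " = ([-0-9.eE+]+);"), text))[[1]]
    if (length(m) < 2) stop("cannot parse ", name, " from Antimony text",
                            call. = FALSE)
    as.numeric(m[2])
  }
  k <- unname(vapply(paste0("k", 1:6), grab, numeric(1)))
  list(
    parameters = kineticParameters(k1 = k[1], k2 = k[2], k4 = k[4], k6 = k[6],
                                   k3 = k[3], k5 = k[5], kd = k[5] - k[3]),
    state = initialState(grab("S1"), grab("S2"))
  )
}

#' Export the reaction network as an SBML Level 3 Version 2 document
#'
#' Builds the document with `xml2`: one compartment, two species, six
#' parameters, and the six reactions of [exportAntimony()] with MathML
#' kinetic laws (S1 is declared a modifier of R5, whose rate it controls).
#'
#' @inheritParams exportAntimony
#' @return An `xml2::xml_document`. Use `xml2::write_xml()` to serialize.
#' @export
exportSBML <- function(p, x0) {
  stopifnot(inherits(p, "KineticParameters"))
  x0 <- as.numeric(x0)
  num <- .shortestNumber
  mathml_times <- function(ids) {
    paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
           if (length(ids) == 1) paste0("<ci>", ids, "</ci>")
           else paste0("<apply><times/>",
                       paste0("<ci>", ids, "</ci>", collapse = ""),
                       "</apply>"),
           "</math>")
  }
  species_ref <- function(id, stoich = 1) {
    sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
            id, num(stoich))
  }
  reaction <- function(id, reactants, products, rate_ids, modifiers = NULL) {
    paste0(
      sprintf("<reaction id=\"%s\" reversible=\"false\">", id),
      if (length(reactants)) paste0("<listOfReactants>",
                                    paste0(reactants, collapse = ""),
                                    "</listOfReactants>"),
      if (length(products)) paste0("<listOfProducts>",
                                   paste0(products, collapse = ""),
                                   "</listOfProducts>"),
      if (length(modifiers)) paste0("<listOfModifiers>",
                                    sprintf("<modifierSpeciesReference species=\"%s\"/>",
                                            modifiers),
                                    "</listOfModifiers>"),
      "<kineticLaw>", mathml_times(rate_ids), "</kineticLaw>",
      "</reaction>"
    )
  }
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
    "level=\"3\" version=\"2\">",
    "<model id=\"two_species_harmonic_oscillator\">",
    "<listOfCompartments>",
    "<compartment id=\"cell\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf(paste0("<species id=\"S%d\" compartment=\"cell\" ",
                   "initialConcentration=\"%s\" hasOnlySubstanceUnits=\"false\" ",
                   "boundaryCondition=\"false\" constant=\"false\"/>"),
            1:2, c(num(x0[1]), num(x0[2]))) |> paste0(collapse = ""),
    "</listOfSpecies>",
    "<listOfParameters>",
    paste0(sprintf("<parameter id=\"k%d\" value=\"%s\" constant=\"true\"/>",
                   1:6,
                   vapply(p[c("k1", "k2", "k3", "k4", "k5", "k6")],
                          num, character(1))),
           collapse = ""),
    "</listOfParameters>",
    "<listOfReactions>",
    reaction("R1", species_ref("S1"), species_ref("S2"), c("k1", "S1")),
    reaction("R2", species_ref("S2"), species_ref("S1"), c("k2", "S2")),
    reaction("R3", species_ref("S1"), species_ref("S1", 2), c("k3", "S1")),
    reaction("R4", species_ref("S1"), character(0), "k4"),
    reaction("R5", species_ref("S2"), character(0), c("k5", "S1"),
             modifiers = "S1"),
    reaction("R6", character(0), species_ref("S2"), "k6"),
    "</listOfReactions>",
    "</model>",
    "</sbml>"
  )
  xml2::read_xml(doc)
}

#' Parse kinetic parameters back out of an exported SBML document
#'
#' Inverse of [exportSBML()] for round-trip checks.
#'
#' @param doc an `xml2::xml_document` (or path readable by `xml2::read_xml`).
#' @return A list with `parameters` and `state`, as [readParameters()].
#' @export
parseSBML <- function(doc) {
  if (!inherits(doc, "xml_document")) doc <- xml2::read_xml(doc)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  pars <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  k <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                       xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  conc <- stats::setNames(
    as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    xml2::xml_attr(sp, "id"))
  list(
    parameters = kineticParameters(k1 = k[["k1"]], k2 = k[["k2"]],
                                   k4 = k[["k4"]], k6 = k[["k6"]],
                                   k3 = k[["k3"]], k5 = k[["k5"]],
                                   kd = k[["k5"]] - k[["k3"]]),
    state = initialState(conc[["S1"]], conc[["S2"]])
  )
}
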