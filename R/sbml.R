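# SBML reading (Level 3 + fbc v2, with legacy COBRA Level 2 fallbacks) and a
# Level 3 + fbc v2 writer. Parsing is namespace-agnostic: elements are located
# by local name and attributes by local attribute name, so files from
# different exporters (with or without prefixes) read identically.

.xfind <- function(node, localName)
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", localName))

.xfirst <- function(node, localName)
  xml2::xml_find_first(node, sprintf("./*[local-name()='%s']", localName))

# attribute by local name, ignoring any namespace prefix
.xattr <- function(node, localName) {
  a <- xml2::xml_attrs(node)
  if (!length(a)) return(NA_character_)
  hit <- names(a) == localName | endsWith(names(a), paste0(":", localName))
  if (any(hit)) unname(a[which(hit)[1]]) else NA_character_
}

.noteField <- function(text, field) {
  m <- regmatches(text,
                  regexec(paste0(field, ":[ \t]*([^<\n]+)"), text))[[1]]
  if (length(m) == 2) trimws(m[2]) else NA_character_
}

# notes text with one line per text node, so adjacent <p> fields stay apart
.notesText <- function(node) {
  if (inherits(node, "xml_missing")) return("")
  paste(xml2::xml_text(xml2::xml_find_all(node, ".//text()")), collapse = "\n")
}

#' Read an SBML genome-scale model
#'
#' Supports SBML Level 3 with the fbc extension (flux bound parameters,
#' objectives, chemical formulas and charges as fbc attributes) and legacy
#' COBRA-dialect Level 2 files (bounds and objective coefficients as
#' kinetic-law parameters `LOWER_BOUND` / `UPPER_BOUND` /
#' `OBJECTIVE_COEFFICIENT`; `FORMULA:` / `CHARGE:` / `GENE_ASSOCIATION:` in
#' notes). Files ending in `.gz` are decompressed transparently. Species and
#' reactions keep document order.
#'
#' @param path path to an SBML file (optionally gzip-compressed).
#' @return a [GEM-class]. If the model declares no objective a warning is
#'   emitted and `objectiveReaction()` is empty; [optimizeFlux()] then
#'   requires an explicit `objective` argument.
#' @seealso [writeSBML()]
#' @export
readSBML <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  doc <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con), add = TRUE)
    xml2::read_xml(con)
  } else xml2::read_xml(path)
  model <- .xfirst(doc, "model")
  if (inherits(model, "xml_missing")) stopf("no <model> element in '%s'", path)

  comps <- .xfind(.xfirst(model, "listOfCompartments"), "compartment")
  compIds <- vapply(comps, .xattr, character(1), "id")
  compNames <- vapply(comps, function(n) {
    nm <- .xattr(n, "name"); if (is.na(nm)) .xattr(n, "id") else nm
  }, character(1))
  compartments <- stats::setNames(compNames, compIds)

  # model-level parameters (fbc bound references)
  pars <- .xfind(.xfirst(model, "listOfParameters"), "parameter")
  parVal <- stats::setNames(
    vapply(pars, function(p) as.numeric(.xattr(p, "value")), numeric(1)),
    vapply(pars, .xattr, character(1), "id"))

  spNodes <- .xfind(.xfirst(model, "listOfSpecies"), "species")
  mets <- do.call(rbind, lapply(spNodes, function(sp) {
    noteTxt <- .notesText(.xfirst(sp, "notes"))
    formula <- .xattr(sp, "chemicalFormula")
    if (is.na(formula)) formula <- .noteField(noteTxt, "FORMULA")
    charge <- .xattr(sp, "charge")
    if (is.na(charge)) charge <- .noteField(noteTxt, "CHARGE")
    nm <- .xattr(sp, "name")
    data.frame(
      id = .xattr(sp, "id"),
      name = if (is.na(nm)) .xattr(sp, "id") else nm,
      compartment = .xattr(sp, "compartment"),
      formula = formula,
      charge = suppressWarnings(as.integer(charge)),
      isBoundary = identical(.xattr(sp, "boundaryCondition"), "true"),
      stringsAsFactors = FALSE)
  }))
  if (is.null(mets)) mets <- data.frame(id = character())

  rxNodes <- .xfind(.xfirst(model, "listOfReactions"), "reaction")
  if (length(rxNodes) == 0) stopf("model in '%s' contains no reactions", path)

  stoich <- list()
  rxns <- do.call(rbind, lapply(rxNodes, function(rx) {
    id <- .xattr(rx, "id")
    refs <- function(listName, sign) {
      lst <- .xfirst(rx, listName)
      if (inherits(lst, "xml_missing")) return(numeric())
      sr <- .xfind(lst, "speciesReference")
      co <- vapply(sr, function(s) {
        v <- .xattr(s, "stoichiometry")
        if (is.na(v)) 1 else as.numeric(v)
      }, numeric(1))
      stats::setNames(sign * co, vapply(sr, .xattr, character(1), "species"))
    }
    s <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    # a species on both sides keeps its net signed pair collapsed
    if (anyDuplicated(names(s)))
      s <- tapply(s, names(s), sum)[unique(names(s))]
    stoich[[id]] <<- s[s != 0]

    reversible <- identical(.xattr(rx, "reversible"), "true")
    lbRef <- .xattr(rx, "lowerFluxBound")
    ubRef <- .xattr(rx, "upperFluxBound")
    lb <- if (!is.na(lbRef)) parVal[[lbRef]] else NA_real_
    ub <- if (!is.na(ubRef)) parVal[[ubRef]] else NA_real_
    objCoef <- 0
    klaw <- .xfirst(rx, "kineticLaw")
    if (!inherits(klaw, "xml_missing")) {
      kp <- c(.xfind(.xfirst(klaw, "listOfParameters"), "parameter"),
              .xfind(.xfirst(klaw, "listOfLocalParameters"), "localParameter"))
      for (p in kp) {
        pid <- .xattr(p, "id")
        val <- as.numeric(.xattr(p, "value"))
        if (pid %in% c("LOWER_BOUND") && is.na(lb)) lb <- val
        if (pid %in% c("UPPER_BOUND") && is.na(ub)) ub <- val
        if (pid == "OBJECTIVE_COEFFICIENT") objCoef <- val
      }
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    gpr <- .gprString(.xfirst(rx, "geneProductAssociation"))
    if (is.na(gpr))
      gpr <- .noteField(.notesText(.xfirst(rx, "notes")), "GENE_ASSOCIATION")
    nm <- .xattr(rx, "name")
    data.frame(id = id, name = if (is.na(nm)) id else nm,
               lowerBound = lb, upperBound = ub,
               objectiveCoefficient = objCoef, geneAssociation = gpr,
               stringsAsFactors = FALSE)
  }))

  # fbc objective (overrides any COBRA-notes coefficients when present)
  objList <- .xfirst(model, "listOfObjectives")
  if (!inherits(objList, "xml_missing")) {
    active <- .xattr(objList, "activeObjective")
    objs <- .xfind(objList, "objective")
    ids <- vapply(objs, .xattr, character(1), "id")
    pick <- if (!is.na(active) && active %in% ids) which(ids == active)[1] else 1L
    if (length(objs)) {
      rxns$objectiveCoefficient <- 0
      fo <- .xfind(.xfirst(objs[[pick]], "listOfFluxObjectives"), "fluxObjective")
      for (f in fo) {
        rid <- .xattr(f, "reaction")
        co <- as.numeric(.xattr(f, "coefficient"))
        rxns$objectiveCoefficient[rxns$id == rid] <- co
      }
    }
  }
  if (all(rxns$objectiveCoefficient == 0))
    warning("model declares no objective reaction; optimizeFlux() will need ",
            "an explicit 'objective' argument", call. = FALSE)

  mid <- .xattr(model, "id")
  GEM(modelId = if (is.na(mid)) "model" else mid, compartments = compartments,
      metabolites = mets, reactions = rxns, stoichiometry = stoich)
}

# flatten an fbc geneProductAssociation subtree to "(a and b) or c"
.gprString <- function(node) {
  if (inherits(node, "xml_missing") || length(node) == 0) return(NA_character_)
  walk <- function(n) {
    nm <- xml2::xml_name(n)
    if (nm == "geneProductRef") return(.xattr(n, "geneProduct"))
    kids <- vapply(xml2::xml_children(n), walk, character(1))
    if (nm %in% c("and", "or"))
      paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
    else paste(kids, collapse = " ")
  }
  kids <- xml2::xml_children(node)
  if (length(kids) == 0) return(NA_character_)
  walk(kids[[1]])
}

#' Write a GEM as SBML Level 3 with the fbc v2 extension
#'
#' Flux bounds become shared model-level parameters; formulas and charges are
#' written as fbc species attributes; the objective becomes the active fbc
#' objective (type maximize); gene associations are preserved in reaction
#' notes. Reading the file back with [readSBML()] reproduces the model.
#'
#' @param gem a [GEM-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSBML <- function(gem, path) {
  m <- gem@metabolites; r <- gem@reactions
  bounds <- unique(c(r$lowerBound, r$upperBound))
  parId <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)), fmtNum(bounds))
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", xmlEscape(gem@modelId)),
    "    <listOfCompartments>")
  for (i in seq_along(gem@compartments))
    L <- c(L, sprintf(
      "      <compartment id=\"%s\" name=\"%s\" constant=\"true\"/>",
      xmlEscape(names(gem@compartments)[i]), xmlEscape(gem@compartments[i])))
  L <- c(L, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(m))) {
    extra <- ""
    if (!is.na(m$formula[i]))
      extra <- paste0(extra, sprintf(" fbc:chemicalFormula=\"%s\"",
                                     xmlEscape(m$formula[i])))
    if (!is.na(m$charge[i]))
      extra <- paste0(extra, sprintf(" fbc:charge=\"%d\"", m$charge[i]))
    L <- c(L, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"%s\" ",
             "constant=\"false\"%s/>"),
      xmlEscape(m$id[i]), xmlEscape(m$name[i]), xmlEscape(m$compartment[i]),
      if (m$isBoundary[i]) "true" else "false", extra))
  }
  L <- c(L, "    </listOfSpecies>", "    <listOfParameters>")
  for (i in seq_along(bounds))
    L <- c(L, sprintf(
      "      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
      parId[i], fmtNum(bounds[i])))
  L <- c(L, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(r))) {
    s <- gem@stoichiometry[[r$id[i]]]
    L <- c(L, sprintf(
      paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" ",
             "fast=\"false\" fbc:lowerFluxBound=\"%s\" ",
             "fbc:upperFluxBound=\"%s\">"),
      xmlEscape(r$id[i]), xmlEscape(r$name[i]),
      if (r$lowerBound[i] < 0) "true" else "false",
      parId[fmtNum(r$lowerBound[i])], parId[fmtNum(r$upperBound[i])]))
    if (!is.na(r$geneAssociation[i]))
      L <- c(L, "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
             sprintf("          <p>GENE_ASSOCIATION: %s</p>",
                     xmlEscape(r$geneAssociation[i])),
             "        </body></notes>")
    ref <- function(side, coefs) {
      if (!length(coefs)) return(character())
      c(sprintf("        <listOf%s>", side),
        sprintf(paste0("          <speciesReference species=\"%s\" ",
                       "stoichiometry=\"%s\" constant=\"true\"/>"),
                xmlEscape(names(coefs)), fmtNum(abs(unname(coefs)))),
        sprintf("        </listOf%s>", side))
    }
    L <- c(L, ref("Reactants", s[s < 0]), ref("Products", s[s > 0]),
           "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  hasObj <- any(r$objectiveCoefficient != 0)
  if (hasObj) {
    L <- c(L,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>")
    for (i in which(r$objectiveCoefficient != 0))
      L <- c(L, sprintf(
        paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
               "fbc:coefficient=\"%s\"/>"),
        xmlEscape(r$id[i]), fmtNum(r$objectiveCoefficient[i])))
    L <- c(L,
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  L <- c(L, "  </model>", "</sbml>")
  writeLines(L, path)
  invisible(path)
}
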