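## ---- MathML -> small AST -------------------------------------------------
## AST nodes: list(type = "num", value =), list(type = "sym", name =),
## list(type = "call", op =, args = list(...))

mathmlToAst <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed <math>: expected one child")
    return(mathmlToAst(kids[[1]]))
  }
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    txt <- xml2::xml_text(node)
    if (!is.na(type) && type == "e-notation") {
      parts <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
      parts <- parts[nzchar(parts)]
      return(list(type = "num",
                  value = as.numeric(parts[1]) * 10^as.numeric(parts[2])))
    }
    if (!is.na(type) && type == "rational") {
      parts <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
      parts <- parts[nzchar(parts)]
      return(list(type = "num",
                  value = as.numeric(parts[1]) / as.numeric(parts[2])))
    }
    return(list(type = "num", value = as.numeric(trimws(txt))))
  }
  if (nm == "ci")
    return(list(type = "sym", name = trimws(xml2::xml_text(node))))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url))
      return(list(type = "sym", name = ".time"))
    stop("unsupported MathML csymbol: ", xml2::xml_text(node))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathmlToAst)
    if (op %in% c("plus", "minus", "times", "divide", "power", "root",
                  "exp", "ln", "log", "abs", "floor", "ceiling"))
      return(list(type = "call", op = op, args = args))
    if (op == "ci") {  # user-defined function application
      return(list(type = "call", op = "userfun",
                  fname = trimws(xml2::xml_text(kids[[1]])), args = args))
    }
    stop("unsupported MathML operator: ", op)
  }
  if (nm == "pi") return(list(type = "num", value = pi))
  if (nm == "exponentiale") return(list(type = "num", value = exp(1)))
  stop("unsupported MathML element: ", nm)
}

## substitute symbols (named list name -> AST) into an AST
astSubstitute <- function(ast, bindings) {
  if (ast$type == "sym" && ast$name %in% names(bindings))
    return(bindings[[ast$name]])
  if (ast$type == "call")
    ast$args <- lapply(ast$args, astSubstitute, bindings = bindings)
  ast
}

## inline user-defined function applications given lambda definitions
astInlineFunctions <- function(ast, fundefs) {
  if (ast$type != "call") return(ast)
  ast$args <- lapply(ast$args, astInlineFunctions, fundefs = fundefs)
  if (ast$op == "userfun") {
    fd <- fundefs[[ast$fname]]
    if (is.null(fd)) stop("call to undefined function '", ast$fname, "'")
    if (length(fd$bvars) != length(ast$args))
      stop("function '", ast$fname, "' called with wrong arity")
    body <- astSubstitute(fd$body, setNames(ast$args, fd$bvars))
    return(astInlineFunctions(body, fundefs))
  }
  ast
}

## render an AST as an R expression string
astToR <- function(ast) {
  if (ast$type == "num") return(format(ast$value, digits = 17))
  if (ast$type == "sym") return(ast$name)
  a <- vapply(ast$args, astToR, "")
  switch(ast$op,
         plus = paste0("(", paste(a, collapse = " + "), ")"),
         minus = if (length(a) == 1L) paste0("(-", a, ")")
                 else paste0("(", a[1], " - ", a[2], ")"),
         times = paste0("(", paste(a, collapse = " * "), ")"),
         divide = paste0("(", a[1], " / ", a[2], ")"),
         power = paste0("(", a[1], " ^ ", a[2], ")"),
         root = paste0("sqrt(", a[1], ")"),
         exp = paste0("exp(", a[1], ")"),
         ln = paste0("log(", a[1], ")"),
         log = paste0("log10(", a[length(a)], ")"),
         abs = paste0("abs(", a[1], ")"),
         floor = paste0("floor(", a[1], ")"),
         ceiling = paste0("ceiling(", a[1], ")"),
         stop("cannot render operator ", ast$op))
}

## flatten nested products into a factor list; NULL when not a pure product
astProductFactors <- function(ast) {
  if (ast$type %in% c("num", "sym")) return(list(ast))
  if (ast$type == "call" && ast$op == "times") {
    out <- list()
    for (a in ast$args) {
      f <- astProductFactors(a)
      if (is.null(f)) return(NULL)
      out <- c(out, f)
    }
    return(out)
  }
  NULL
}

## collect all symbol names in an AST
astSymbols <- function(ast) {
  if (ast$type == "sym") return(ast$name)
  if (ast$type == "call") return(unique(unlist(lapply(ast$args, astSymbols))))
  character()
}

## ---- rate-law classification --------------------------------------------
## ctx: list(speciesIds, compartmentIds, paramValues (named), substrates,
##          products, modifiers)
## Splits a factor list into param product value, species symbols; NULL on
## a factor that is neither a known parameter/number nor a species.
splitFactors <- function(factors, ctx) {
  k <- 1
  sp <- character()
  for (f in factors) {
    if (f$type == "num") { k <- k * f$value; next }
    if (f$name %in% ctx$speciesIds) { sp <- c(sp, f$name); next }
    if (f$name %in% names(ctx$paramValues)) {
      k <- k * ctx$paramValues[[f$name]]; next
    }
    return(NULL)
  }
  list(k = k, species = sp)
}

## drop one leading compartment-volume factor (SBML kinetic laws are in
## amount/time; dividing by V gives the concentration dynamics)
stripCompartment <- function(ast, ctx) {
  f <- astProductFactors(ast)
  if (is.null(f)) return(ast)
  isComp <- vapply(f, function(x) x$type == "sym" &&
                     x$name %in% ctx$compartmentIds, TRUE)
  if (!any(isComp)) return(ast)
  keep <- f[!(isComp & cumsum(isComp) == 1)]   # remove first comp factor only
  if (length(keep) == 0L) return(list(type = "num", value = 1))
  if (length(keep) == 1L) return(keep[[1]])
  list(type = "call", op = "times", args = keep)
}

## try to classify an AST as one of the three law variants; NULL on failure
classifyRateLaw <- function(ast, ctx) {
  ast <- stripCompartment(ast, ctx)

  ## reversible mass action: fwd product - rev product
  if (ast$type == "call" && ast$op == "minus" && length(ast$args) == 2L) {
    fw <- astProductFactors(stripCompartment(ast$args[[1]], ctx))
    rv <- astProductFactors(stripCompartment(ast$args[[2]], ctx))
    if (!is.null(fw) && !is.null(rv)) {
      f1 <- splitFactors(fw, ctx); f2 <- splitFactors(rv, ctx)
      if (!is.null(f1) && !is.null(f2) &&
          setequal(f1$species, ctx$substrates) &&
          setequal(f2$species, ctx$products))
        return(massActionLaw(k1 = f1$k, k2 = f2$k))
    }
  }

  ## irreversible mass action: pure product of constants and substrates
  f <- astProductFactors(ast)
  if (!is.null(f)) {
    sf <- splitFactors(f, ctx)
    if (!is.null(sf) && setequal(sf$species, ctx$substrates))
      return(massActionLaw(k1 = sf$k))
  }

  ## (modified) Henri-Michaelis-Menten: num / (Km + S)
  if (ast$type == "call" && ast$op == "divide") {
    den <- ast$args[[2]]
    if (den$type == "call" && den$op == "plus" && length(den$args) == 2L) {
      terms <- den$args
      isS <- vapply(terms, function(t) t$type == "sym" &&
                      t$name %in% ctx$speciesIds, TRUE)
      if (sum(isS) == 1L) {
        S <- terms[isS][[1]]$name
        kmAst <- terms[!isS][[1]]
        Km <- if (kmAst$type == "num") kmAst$value
              else if (kmAst$type == "sym" &&
                       kmAst$name %in% names(ctx$paramValues))
                ctx$paramValues[[kmAst$name]]
              else NA_real_
        num <- astProductFactors(stripCompartment(ast$args[[1]], ctx))
        if (!is.na(Km) && Km > 0 && !is.null(num)) {
          sf <- splitFactors(num, ctx)
          if (!is.null(sf) && S %in% sf$species &&
              S %in% ctx$substrates &&
              sum(sf$species == S) == 1L) {
            others <- sf$species[sf$species != S]
            if (length(others) == 0L)
              return(hmmLaw(Kcat = sf$k, Km = Km))
            if (length(others) == 1L) {
              if (others %in% ctx$modifiers)
                return(modifiedHmmLaw(Kcat = sf$k, Km = Km,
                                      modifier = others))
              return(hmmLaw(Kcat = sf$k, Km = Km, enzyme = others))
            }
          }
        }
      }
    }
  }
  NULL
}

## ---- SBML document import ------------------------------------------------

#' Read an SBML model
#'
#' Imports an SBML Level 2 or Level 3 document into a
#' \linkS4class{NetworkModel}. Kinetic laws are recognized by structural
#' pattern matching on the MathML tree: a product of constants and the
#' reactant species maps to mass action (a difference of two such products
#' to reversible mass action), a rational form
#' Kcat * E * S / (Km + S) maps to Henri-Michaelis-Menten (modified
#' Henri-Michaelis-Menten when E is declared a modifier of the reaction);
#' user-defined function applications are inlined before matching, and one
#' leading compartment-volume factor is stripped (SBML laws are expressed
#' in amounts; the engine integrates concentrations). Laws that match no
#' variant are retained as opaque rate expressions evaluated symbolically
#' and listed in the report. Species declared in amounts are converted to
#' concentrations via their compartment size; boundary/constant species
#' are held fixed during simulation. Rate rules become opaque
#' pseudo-reactions; events and other rule types raise an explicit
#' unsupported-feature error rather than being dropped silently.
#'
#' @param path path to an SBML file
#' @return list with \code{model} (a \linkS4class{NetworkModel}) and
#'   \code{report} (an \linkS4class{ImportReport})
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml")
    stop("not an SBML document: root element is <",
         xml2::xml_name(doc), ">")
  level <- as.integer(xml2::xml_attr(doc, "level"))
  if (!level %in% c(2L, 3L))
    stop("unsupported SBML level ", level, " (levels 2 and 3 are supported)")
  modelNode <- xml2::xml_find_first(doc, "./model")
  if (inherits(modelNode, "xml_missing")) stop("SBML document has no <model>")

  if (length(xml2::xml_find_all(modelNode, ".//listOfEvents/event")))
    stop("unsupported SBML feature: events")
  for (ruleKind in c("assignmentRule", "algebraicRule"))
    if (length(xml2::xml_find_all(modelNode,
                                  paste0(".//listOfRules/", ruleKind))))
      stop("unsupported SBML feature: ", ruleKind)

  warnings <- character()

  comps <- lapply(xml2::xml_find_all(modelNode,
                                     "./listOfCompartments/compartment"),
                  function(nd) {
    size <- xml2::xml_attr(nd, "size")
    if (is.na(size)) size <- xml2::xml_attr(nd, "volume")  # L1 leftover
    compartment(xml2::xml_attr(nd, "id"),
                name = xml2::xml_attr(nd, "name") %na% xml2::xml_attr(nd, "id"),
                volume = if (is.na(size)) 1 else as.numeric(size))
  })
  compIds <- vapply(comps, function(x) x@id, "")
  compVol <- setNames(vapply(comps, function(x) x@volume, 0), compIds)

  spNodes <- xml2::xml_find_all(modelNode, "./listOfSpecies/species")
  constantSpecies <- character()
  sps <- lapply(spNodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    comp <- xml2::xml_attr(nd, "compartment")
    conc <- xml2::xml_attr(nd, "initialConcentration")
    if (is.na(conc)) {
      amt <- xml2::xml_attr(nd, "initialAmount")
      conc <- if (is.na(amt)) 0
              else as.numeric(amt) /
                (if (comp %in% names(compVol)) compVol[[comp]] else 1)
    } else conc <- as.numeric(conc)
    speciesNode(id, name = xml2::xml_attr(nd, "name") %na% id,
                compartment = comp, role = "simple molecule",
                initialConcentration = max(conc, 0))
  })
  for (i in seq_along(spNodes)) {
    bc <- xml2::xml_attr(spNodes[[i]], "boundaryCondition")
    cst <- xml2::xml_attr(spNodes[[i]], "constant")
    if (isTRUE(bc == "true") || isTRUE(cst == "true"))
      constantSpecies <- c(constantSpecies, sps[[i]]@id)
  }
  spIds <- vapply(sps, function(x) x@id, "")

  globalParams <- local({
    nds <- xml2::xml_find_all(modelNode, "./listOfParameters/parameter")
    setNames(vapply(nds, function(nd) as.numeric(xml2::xml_attr(nd, "value")),
                    0),
             vapply(nds, function(nd) xml2::xml_attr(nd, "id"), ""))
  })

  fundefs <- local({
    nds <- xml2::xml_find_all(modelNode,
                              "./listOfFunctionDefinitions/functionDefinition")
    defs <- lapply(nds, function(nd) {
      lam <- xml2::xml_find_first(nd, "./math/lambda")
      if (inherits(lam, "xml_missing"))
        stop("functionDefinition without lambda")
      kids <- xml2::xml_children(lam)
      isBvar <- xml2::xml_name(kids) == "bvar"
      bvars <- vapply(kids[isBvar],
                      function(b) trimws(xml2::xml_text(b)), "")
      body <- mathmlToAst(kids[!isBvar][[1]])
      list(bvars = bvars, body = body)
    })
    setNames(defs, vapply(nds, function(nd) xml2::xml_attr(nd, "id"), ""))
  })

  lawCounts <- c(MassAction = 0L, HMM = 0L, ModifiedHMM = 0L, Opaque = 0L)
  unmapped <- character()

  parseRefs <- function(nd, what) {
    refs <- xml2::xml_find_all(nd, paste0("./", what, "/speciesReference"))
    if (!length(refs)) return(numeric())
    st <- vapply(refs, function(r) {
      s <- xml2::xml_attr(r, "stoichiometry")
      if (is.na(s)) 1 else as.numeric(s)
    }, 0)
    setNames(st, vapply(refs, function(r) xml2::xml_attr(r, "species"), ""))
  }

  rxNodes <- xml2::xml_find_all(modelNode, "./listOfReactions/reaction")
  rxs <- lapply(rxNodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    subs <- parseRefs(nd, "listOfReactants")
    prods <- parseRefs(nd, "listOfProducts")
    mods <- vapply(xml2::xml_find_all(
      nd, "./listOfModifiers/modifierSpeciesReference"),
      function(r) xml2::xml_attr(r, "species"), "")
    klNode <- xml2::xml_find_first(nd, "./kineticLaw")
    if (inherits(klNode, "xml_missing"))
      stop("reaction '", id, "' has no kinetic law")
    localNds <- xml2::xml_find_all(
      klNode, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    localParams <- setNames(
      vapply(localNds, function(p) as.numeric(xml2::xml_attr(p, "value")), 0),
      vapply(localNds, function(p) xml2::xml_attr(p, "id"), ""))
    mathNode <- xml2::xml_find_first(klNode, "./math")
    if (inherits(mathNode, "xml_missing"))
      stop("reaction '", id, "' kinetic law has no <math>")
    ast <- astInlineFunctions(mathmlToAst(mathNode), fundefs)
    ctx <- list(speciesIds = spIds, compartmentIds = compIds,
                paramValues = c(localParams,
                                globalParams[setdiff(names(globalParams),
                                                     names(localParams))]),
                substrates = names(subs), products = names(prods),
                modifiers = mods)
    law <- classifyRateLaw(ast, ctx)
    if (is.null(law)) {
      lawCounts["Opaque"] <<- lawCounts[["Opaque"]] + 1L
      unmapped <<- c(unmapped, id)
      syms <- astSymbols(ast)
      pv <- ctx$paramValues[intersect(syms, names(ctx$paramValues))]
      pv <- c(pv, compVol[intersect(syms, compIds)])
      law <- new("OpaqueLaw", expression = astToR(ast),
                 parameters = as.numeric(pv) |> setNames(names(pv)))
    } else {
      cls <- sub("Law$", "", class(law))
      lawCounts[cls] <<- lawCounts[[cls]] + 1L
    }
    reaction(id, substrates = subs, products = prods, modifiers = mods,
             law = law)
  })

  ## rate rules: direct d[X]/dt contributions, kept as opaque pseudo-reactions
  rrNodes <- xml2::xml_find_all(modelNode, "./listOfRules/rateRule")
  for (nd in rrNodes) {
    var <- xml2::xml_attr(nd, "variable")
    if (!var %in% spIds)
      stop("rate rule for non-species variable '", var, "' is unsupported")
    ast <- astInlineFunctions(
      mathmlToAst(xml2::xml_find_first(nd, "./math")), fundefs)
    syms <- astSymbols(ast)
    pv <- globalParams[intersect(syms, names(globalParams))]
    pv <- c(pv, compVol[intersect(syms, compIds)])
    rxs[[length(rxs) + 1L]] <- reaction(
      paste0("raterule_", var), products = setNames(1, var),
      law = new("OpaqueLaw", expression = astToR(ast),
                parameters = setNames(as.numeric(pv), names(pv))))
    warnings <- c(warnings,
                  paste0("rate rule for '", var,
                         "' imported as an opaque pseudo-reaction"))
  }

  model <- networkModel(comps, sps, rxs,
                        metadata = list(source = path, sbmlLevel = level,
                                        constantSpecies = constantSpecies))
  report <- new("ImportReport", nSpecies = length(sps),
                nReactions = length(rxNodes), lawCounts = lawCounts,
                unmapped = unmapped, warnings = warnings)
  list(model = model, report = report)
}

`%na%` <- function(a, b) if (is.na(a)) b else a
`%||%` <- function(a, b) if (is.null(a)) b else a
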