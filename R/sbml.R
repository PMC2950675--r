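#' SBML input/output
#'
#' Reads and writes constraint-based models in the SBML Level 2 dialect used
#' by legacy COBRA exports: GPR rules and subsystems are carried in reaction
#' `<notes>` as `GENE_ASSOCIATION:` / `SUBSYSTEM:` lines, and flux bounds in
#' kinetic-law parameters named `LOWER_BOUND` / `UPPER_BOUND`. The writer is
#' deterministic, so write -> read -> write is byte-identical.
#'
#' @name sbml
NULL

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.12g", x)

#' Write a model to SBML
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
           sprintf('  <model id="%s">', xml_escape(model$id)),
           '    <listOfCompartments>',
           sprintf('      <compartment id="%s"/>', xml_escape(model$compartments)),
           '    </listOfCompartments>',
           '    <listOfSpecies>')
  m <- model$metabolites
  out <- c(out,
           sprintf('      <species id="%s" name="%s" compartment="%s"/>',
                   xml_escape(m$id), xml_escape(m$name), xml_escape(m$compartment)),
           '    </listOfSpecies>',
           '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[i]]
    lhs <- st[st < 0]; rhs <- st[st > 0]
    sref <- function(v) sprintf('          <speciesReference species="%s" stoichiometry="%s"/>',
                                xml_escape(names(v)), num_attr(abs(unname(v))))
    out <- c(out,
      sprintf('      <reaction id="%s" reversible="%s">',
              xml_escape(r$id), tolower(as.character(r$lb < 0))),
      '        <notes>',
      '          <body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('            <p>GENE_ASSOCIATION: %s</p>', xml_escape(r$gpr)),
      sprintf('            <p>SUBSYSTEM: %s</p>', xml_escape(r$subsystem)),
      sprintf('            <p>KIND: %s</p>', xml_escape(r$kind)),
      '          </body>',
      '        </notes>',
      if (length(lhs) > 0) c('        <listOfReactants>', sref(lhs),
                             '        </listOfReactants>'),
      if (length(rhs) > 0) c('        <listOfProducts>', sref(rhs),
                             '        </listOfProducts>'),
      '        <kineticLaw>',
      '          <listOfParameters>',
      sprintf('            <parameter id="LOWER_BOUND" value="%s"/>', num_attr(r$lb)),
      sprintf('            <parameter id="UPPER_BOUND" value="%s"/>', num_attr(r$ub)),
      '          </listOfParameters>',
      '        </kineticLaw>',
      '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' @param path SBML file path (Level 2 with notes-encoded GPR/subsystem).
#' @param vmax Flux bound cap for the resulting model.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path, vmax = VMAX_DEFAULT) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop("SBML parse error: no <model> element", call. = FALSE)
  comps <- xml2::xml_attr(xml2::xml_find_all(mod, ".//listOfCompartments/compartment"), "id")
  sp <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  rx <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  n <- length(rx)
  rxns <- data.frame(id = character(n), lb = numeric(n), ub = numeric(n),
                     subsystem = character(n), kind = character(n),
                     gpr = character(n), stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rx[[i]]
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("SBML parse error: reaction without id", call. = FALSE)
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    pick <- function(prefix) {
      hit <- grep(paste0("^\\s*", prefix, ":"), notes, value = TRUE)
      if (length(hit) == 0) return("")
      trimws(sub(paste0("^\\s*", prefix, ":"), "", hit[1]))
    }
    gpr_text <- pick("GENE_ASSOCIATION")
    gpr_tree <- tryCatch(parse_gpr(gpr_text), error = function(e) {
      stop(sprintf("SBML parse error in reaction %s: malformed GENE_ASSOCIATION note (%s)",
                   rid, conditionMessage(e)), call. = FALSE)
    })
    kind <- pick("KIND")
    if (!kind %in% REACTION_KINDS) {
      kind <- if (grepl("^EX_", rid)) "exchange" else if (grepl("^DM_", rid)) "demand"
              else "enzymatic"
    }
    coef <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
      ids <- xml2::xml_attr(refs, "species")
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      missing <- setdiff(ids, mets$id)
      if (length(missing) > 0) {
        stop(sprintf("SBML parse error in reaction %s: species reference to undeclared metabolite(s) %s",
                     rid, paste(missing, collapse = ", ")), call. = FALSE)
      }
      stats::setNames(sign * sto, ids)
    }
    st <- c(coef(".//listOfReactants/speciesReference", -1),
            coef(".//listOfProducts/speciesReference", 1))
    pars <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
    pids <- xml2::xml_attr(pars, "id")
    pval <- as.numeric(xml2::xml_attr(pars, "value"))
    lb <- pval[match("LOWER_BOUND", pids)]
    ub <- pval[match("UPPER_BOUND", pids)]
    if (is.na(lb)) lb <- if (rev) -vmax else 0
    if (is.na(ub)) ub <- vmax
    rxns$id[i] <- rid; rxns$lb[i] <- lb; rxns$ub[i] <- ub
    rxns$subsystem[i] <- pick("SUBSYSTEM")
    rxns$kind[i] <- kind
    rxns$gpr[i] <- deparse_gpr(gpr_tree)
    stoich[[i]] <- st
  }
  mid <- xml2::xml_attr(mod, "id")
  metabolic_model(mets, rxns, stoich,
                  compartments = if (length(comps) > 0) comps else unique(mets$compartment),
                  vmax = vmax, id = if (is.na(mid)) "model" else mid)
}
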