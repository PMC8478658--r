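# SBML Level 3 (+ fbc version 2) reading and writing for metabolic models.
# Bounds are stored as fbc flux-bound parameters and GPRs as nested
# fbc:geneProductAssociation elements, so models round-trip through other
# constraint-based toolchains.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a metabolic model to SBML L3 + fbc
#'
#' @param model `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment)) {
    lines <- c(lines, sprintf(
      '      <compartment id="%s" constant="true"/>', esc(cmp)))
  }
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    formula_attr <- if (!is.null(m$formula) && nzchar(m$formula)) {
      sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))
    } else ""
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      esc(m$id), esc(m$compartment), formula_attr))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines,
      sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
              esc(r$id), num(r$lb)),
      sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
              esc(r$id), num(r$ub)))
  }
  lines <- c(lines, '    </listOfParameters>')
  all_genes <- unique(unlist(lapply(model$reactions$gpr,
                                    function(g) gpr_genes(parse_gpr(g)))))
  if (length(all_genes)) {
    lines <- c(lines, '    <fbc:listOfGeneProducts>')
    for (g in all_genes) {
      lines <- c(lines, sprintf(
        '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
        esc(g), esc(g)))
    }
    lines <- c(lines, '    </fbc:listOfGeneProducts>')
  }
  gpa_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (!is.null(tree$gene)) {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     pad, esc(tree$gene)))
    }
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(tree$args, gpa_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  lines <- c(lines, '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">'),
      esc(r$id), tolower(as.character(r$lb < 0)), esc(r$id), esc(r$id)))
    if (nzchar(r$subsystem)) {
      lines <- c(lines, sprintf(
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p></body></notes>',
        esc(r$subsystem)))
    }
    col <- model$S[, r$id]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>')
      for (j in subs) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(rownames(model$S)[j]), num(-col[j])))
      }
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>')
      for (j in prods) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(rownames(model$S)[j]), num(col[j])))
      }
      lines <- c(lines, '        </listOfProducts>')
    }
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      lines <- c(lines,
        '        <fbc:geneProductAssociation>',
        gpa_xml(tree, 10),
        '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic model from SBML L3 + fbc
#'
#' Reactions missing flux-bound parameters get the documented defaults
#' (-1000, 1000) when marked reversible, (0, 1000) otherwise.
#'
#' @param path SBML file path.
#' @return `metabolic_model`.
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop2("malformed SBML: %s",
                                            conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop2("no <model> element found")
  model_id <- xml2::xml_attr(model_node, "id")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  metabolites <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                              xml2::xml_attr(pars, "id"))

  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_labels <- stats::setNames(xml2::xml_attr(gp, "label"),
                                 xml2::xml_attr(gp, "id"))

  gpa_tree <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lbl <- gene_labels[gid]
      if (is.na(lbl)) lbl <- sub("^G_", "", gid)
      return(list(gene = unname(lbl)))
    }
    if (!nm %in% c("and", "or"))
      stop2("unparseable GPR element <%s> in %s", nm, path)
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, gpa_tree))
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0) stop2("model has no reactions")
  n_rx <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  lb <- numeric(n_rx); ub <- numeric(n_rx)
  gpr <- character(n_rx); subsystem <- character(n_rx)
  S <- matrix(0, nrow(metabolites), n_rx,
              dimnames = list(metabolites$id, ids))
  for (i in seq_len(n_rx)) {
    node <- rx_nodes[[i]]
    rev_flag <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb[i] <- if (!is.na(lb_ref) && lb_ref %in% names(par_vals)) {
      par_vals[lb_ref]
    } else if (rev_flag) -1000 else 0
    ub[i] <- if (!is.na(ub_ref) && ub_ref %in% names(par_vals)) {
      par_vals[ub_ref]
    } else 1000
    for (ref in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      S[xml2::xml_attr(ref, "species"), i] <-
        S[xml2::xml_attr(ref, "species"), i] -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      S[xml2::xml_attr(ref, "species"), i] <-
        S[xml2::xml_attr(ref, "species"), i] +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr[i] <- if (!inherits(gpa, "xml_missing")) {
      deparse_gpr(gpa_tree(xml2::xml_child(gpa)))
    } else ""
    note <- xml2::xml_find_first(node, ".//*[local-name()='p']")
    subsystem[i] <- if (!inherits(note, "xml_missing")) {
      sub("^SUBSYSTEM: ", "", xml2::xml_text(note))
    } else ""
  }
  reactions <- data.frame(id = ids, lb = lb, ub = ub, gpr = gpr,
                          subsystem = subsystem, stringsAsFactors = FALSE)
  metabolic_model(model_id, metabolites, reactions, S)
}

#' Check element conservation of internal reactions
#'
#' Parses metabolite `formula` tags (e.g. `"C6N2"`) and verifies that every
#' non-exchange reaction conserves each element.
#'
#' @param model `metabolic_model` whose metabolites carry formulas.
#' @return data.frame reaction x element of imbalances (all zero when
#'   mass-balanced).
#' @export
check_mass_balance <- function(model) {
  parse_formula <- function(f) {
    if (!nzchar(f)) return(stats::setNames(numeric(0), character(0)))
    m <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    el <- sub("[0-9]*$", "", m)
    cnt <- as.numeric(sub("^[A-Za-z]+", "", m))
    cnt[is.na(cnt)] <- 1
    stats::setNames(cnt, el)
  }
  forms <- lapply(model$metabolites$formula, parse_formula)
  elements <- unique(unlist(lapply(forms, names)))
  E <- matrix(0, nrow(model$metabolites), length(elements),
              dimnames = list(model$metabolites$id, elements))
  for (i in seq_along(forms)) E[i, names(forms[[i]])] <- forms[[i]]
  internal <- setdiff(model$reactions$id, model$exchanges)
  imbalance <- t(E) %*% model$S[, internal, drop = FALSE]
  as.data.frame(t(imbalance))
}
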