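## SBML ingestion for constraint-based models. Two dialects circulate for
## Recon-family models: SBML L2 with COBRA-style notes (GENE_ASSOCIATION,
## SUBSYSTEM) and kineticLaw LOWER_BOUND/UPPER_BOUND parameters, and SBML L3
## with the fbc extension (flux-bound parameters, geneProductAssociation).
## Both are read; writing uses the L2/COBRA dialect, which round-trips all
## fields this package uses.

#' Read a constraint-based model from SBML
#'
#' Accepts SBML Level 2 (COBRA note conventions) and Level 3 (fbc
#' extension). When a reaction carries no explicit bounds, defaults of
#' `[-1000, 1000]` (reversible) or `[0, 1000]` (irreversible) are applied.
#' Species flagged `boundaryCondition="true"` are dropped from reaction
#' stoichiometries, the usual convention for boundary metabolites.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  model <- .x1(doc, ".//*[local-name()='model']")
  if (is.null(model)) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- tolower(xml2::xml_attr(sp_nodes, "compartment"))
  sp_bnd <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  metabolites <- data.frame(id = sp_id[!sp_bnd], name = sp_name[!sp_bnd],
                            compartment = sp_comp[!sp_bnd],
                            stringsAsFactors = FALSE)
  boundary_ids <- sp_id[sp_bnd]

  ## global flux-bound parameters (L3/fbc) and fbc gene products
  pars <- xml2::xml_find_all(model,
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                      xml2::xml_attr(pars, "id"))
  gp_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- setNames(.attr_local(gp_nodes, "label"), .attr_local(gp_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- vector("list", length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    reactions[[k]] <- .read_sbml_reaction(rx_nodes[[k]], par_val, gp_label,
                                          boundary_ids)
  }
  metabolic_network(metabolites, reactions, id = model_id)
}

.x1 <- function(node, xp) {
  res <- xml2::xml_find_all(node, xp)
  if (length(res) == 0L) NULL else res[[1L]]
}

## attribute lookup ignoring namespace prefixes (e.g. fbc:label)
.attr_local <- function(nodes, local) {
  vapply(nodes, function(n) {
    at <- xml2::xml_attrs(n)
    hit <- grep(paste0("(^|:)", local, "$"), names(at))
    if (length(hit)) at[[hit[1L]]] else NA_character_
  }, character(1))
}

.read_sbml_reaction <- function(node, par_val, gp_label, boundary_ids) {
  id <- xml2::xml_attr(node, "id")
  name <- xml2::xml_attr(node, "name")
  if (is.na(name)) name <- id
  rev_attr <- tolower(xml2::xml_attr(node, "reversible"))
  reversible <- !identical(rev_attr, "false")  # SBML L2 default is true

  get_side <- function(tag, sign) {
    refs <- xml2::xml_find_all(node, paste0(
      "./*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
    if (length(refs) == 0L) return(numeric(0))
    sp <- xml2::xml_attr(refs, "species")
    co <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    co[is.na(co)] <- 1
    setNames(sign * co, sp)
  }
  st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
  st <- st[!names(st) %in% boundary_ids]
  ## duplicated species on a side (or both sides) are summed
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
    st <- st[st != 0]
  }
  if (length(st) == 0L)
    stop("reaction ", id, " has no stoichiometry", call. = FALSE)

  lb <- NA_real_; ub <- NA_real_
  ## L2/COBRA: kineticLaw parameters
  kl_pars <- xml2::xml_find_all(node, paste0(
    ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))
  if (length(kl_pars)) {
    pid <- xml2::xml_attr(kl_pars, "id")
    pv <- as.numeric(xml2::xml_attr(kl_pars, "value"))
    if ("LOWER_BOUND" %in% pid) lb <- pv[match("LOWER_BOUND", pid)]
    if ("UPPER_BOUND" %in% pid) ub <- pv[match("UPPER_BOUND", pid)]
  }
  ## L3/fbc: attributes referencing global parameters
  at <- xml2::xml_attrs(node)
  lb_ref <- at[grep("(^|:)lowerFluxBound$", names(at))]
  ub_ref <- at[grep("(^|:)upperFluxBound$", names(at))]
  if (is.na(lb) && length(lb_ref)) lb <- unname(par_val[lb_ref[[1L]]])
  if (is.na(ub) && length(ub_ref)) ub <- unname(par_val[ub_ref[[1L]]])
  if (is.na(lb)) lb <- if (reversible) -1000 else 0
  if (is.na(ub)) ub <- 1000

  note_parts <- xml2::xml_find_all(node,
    ".//*[local-name()='notes']//*[local-name()='p' or local-name()='html:p']")
  if (length(note_parts) == 0L)
    note_parts <- xml2::xml_find_all(node, ".//*[local-name()='notes']")
  notes_txt <- paste(xml2::xml_text(note_parts), collapse = "\n")
  rule <- .notes_field(notes_txt, "GENE_ASSOCIATION")
  if (!nzchar(rule)) {
    gpa <- .x1(node, "./*[local-name()='geneProductAssociation']")
    if (!is.null(gpa)) {
      kids <- xml2::xml_children(gpa)
      rule <- if (length(kids)) .fbc_rule(kids[[1L]], gp_label) else ""
    }
  }
  subsystem <- .notes_field(notes_txt, "SUBSYSTEM")
  if (!nzchar(subsystem)) subsystem <- "unassigned"

  reaction(id = id, stoichiometry = st, lb = lb, ub = ub,
           gene_rule = rule, name = name, subsystem = subsystem)
}

.notes_field <- function(txt, key) {
  m <- regmatches(txt, regexec(paste0(key, ":[ \t]*([^\n]*)"), txt))[[1]]
  if (length(m) == 2L) trimws(m[2]) else ""
}

.fbc_rule <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- .attr_local(list(node), "geneProduct")
    lbl <- gp_label[ref]
    return(if (is.na(lbl)) ref else unname(lbl))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .fbc_rule, character(1), gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a network to SBML (Level 2, COBRA note conventions)
#'
#' Bounds are emitted as `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters
#' and GPR rules and subsystems as `GENE_ASSOCIATION:`/`SUBSYSTEM:` notes,
#' so [read_sbml()] round-trips the network exactly.
#'
#' @param net A [metabolic_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 15)
  comps <- unique(net$metabolites$compartment)
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    sprintf('<model id="%s">', esc(net$id)),
    '<listOfCompartments>',
    sprintf('<compartment id="%s"/>', esc(comps)),
    '</listOfCompartments>',
    '<listOfSpecies>',
    sprintf('<species id="%s" name="%s" compartment="%s"/>',
            esc(net$metabolites$id), esc(net$metabolites$name),
            esc(net$metabolites$compartment)),
    '</listOfSpecies>',
    '<listOfReactions>')
  for (r in net$reactions) {
    st <- r$stoichiometry
    side <- function(v, tag) {
      if (length(v) == 0L) return(character(0))
      c(sprintf('<%s>', tag),
        sprintf('<speciesReference species="%s" stoichiometry="%s"/>',
                esc(names(v)), num(abs(v))),
        sprintf('</%s>', tag))
    }
    out <- c(out,
      sprintf('<reaction id="%s" name="%s" reversible="%s">',
              esc(r$id), esc(r$name), if (r$lb < 0) "true" else "false"),
      '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('<p>GENE_ASSOCIATION: %s</p>', esc(r$gene_rule)),
      sprintf('<p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
      '</body></notes>',
      side(st[st < 0], "listOfReactants"),
      side(st[st > 0], "listOfProducts"),
      '<kineticLaw>',
      '<math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
      '<listOfParameters>',
      sprintf('<parameter id="LOWER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              num(r$lb)),
      sprintf('<parameter id="UPPER_BOUND" value="%s" units="mmol_per_gDW_per_hr"/>',
              num(r$ub)),
      '</listOfParameters>',
      '</kineticLaw>',
      '</reaction>')
  }
  out <- c(out, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}
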