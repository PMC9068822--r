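#' Construct a reaction
#'
#' @param id Unique reaction id.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lb,ub Flux bounds in mmol/gDW/h; `lb <= ub`.
#' @param gene_rule GPR rule string (see [parse_gene_rule()]); "" for none.
#' @param name Human-readable name (defaults to `id`).
#' @param subsystem Pathway label; "unassigned" when unknown.
#' @return A `reaction` object (list).
#' @export
reaction <- function(id, stoichiometry, lb = -1000, ub = 1000,
                     gene_rule = "", name = id, subsystem = "unassigned") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.numeric(stoichiometry), length(stoichiometry) > 0L,
            !is.null(names(stoichiometry)), all(nzchar(names(stoichiometry))))
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gene_rule = gene_rule, subsystem = subsystem),
            class = "reaction")
}

#' Construct a constraint-based metabolic network
#'
#' The network is the substrate of all flux computations: an ordered set of
#' metabolites with compartments, an ordered set of reactions with
#' stoichiometry, bounds and GPR rules, and the gene universe.
#'
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions List of [reaction()] objects.
#' @param genes Character vector of gene ids; defaults to the union of all
#'   GPR genes.
#' @param id Network id string.
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(metabolites, reactions, genes = NULL, id = "network") {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  metabolites <- metabolites[, c("id", "name", "compartment")]
  metabolites$id <- as.character(metabolites$id)
  stopifnot(is.list(reactions))
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions, function(r)
      gene_rule_genes(parse_gene_rule(r$gene_rule)))))
    if (is.null(genes)) genes <- character(0)
  }
  net <- structure(list(id = id, metabolites = metabolites,
                        reactions = reactions, genes = genes),
                   class = "metabolic_network")
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network '", x$id, "': ",
      length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Validate a metabolic network
#'
#' Checks id uniqueness, reference resolution (metabolites and genes cited
#' by reactions must exist) and bound ordering. Findings are returned, not
#' raised, so callers can report all problems at once.
#'
#' @param net A [metabolic_network()].
#' @return Data frame with columns `kind` and `entity`; zero rows when the
#'   network is valid.
#' @export
validate_network <- function(net) {
  kind <- character(0); entity <- character(0)
  add <- function(k, e) { kind <<- c(kind, k); entity <<- c(entity, e) }
  mids <- net$metabolites$id
  dup <- unique(mids[duplicated(mids)])
  for (d in dup) add("duplicate-id", d)
  rids <- vapply(net$reactions, `[[`, character(1), "id")
  dup <- unique(rids[duplicated(rids)])
  for (d in dup) add("duplicate-id", d)
  bad <- net$metabolites$id[!nzchar(net$metabolites$compartment)]
  for (b in bad) add("empty-compartment", b)
  for (r in net$reactions) {
    miss <- setdiff(names(r$stoichiometry), mids)
    for (m in miss) add("unresolved-metabolite", paste0(r$id, ":", m))
    if (r$lb > r$ub) add("bad-bounds", r$id)
    gr <- tryCatch(parse_gene_rule(r$gene_rule), error = function(e) NA)
    if (identical(gr, NA)) {
      add("unparseable-gene-rule", r$id)
    } else {
      gmiss <- setdiff(gene_rule_genes(gr), net$genes)
      for (g in gmiss) add("unresolved-gene", paste0(r$id, ":", g))
    }
  }
  data.frame(kind = kind, entity = entity, stringsAsFactors = FALSE)
}

#' Identify exchange (boundary) reactions
#'
#' An exchange reaction has a single metabolite in its stoichiometry: it
#' imports or exports one species across the system boundary. Demand and
#' supply reactions fall in the same class.
#'
#' @param net A metabolic network.
#' @return Logical vector named by reaction id.
#' @export
is_exchange <- function(net) {
  vapply(net$reactions, function(r) length(r$stoichiometry) == 1L, logical(1))
}

#' Build the stoichiometric matrix S
#'
#' @param net A metabolic network.
#' @param sparse Return a `Matrix::sparseMatrix` (default) or dense matrix.
#' @return Matrix with one row per metabolite and one column per reaction;
#'   `dimnames` carry metabolite and reaction ids.
#' @export
build_stoichiometric_matrix <- function(net, sparse = TRUE) {
  v <- validate_network(net)
  if (nrow(v) > 0L)
    stop("invalid network: ", paste(v$kind, v$entity, collapse = "; "))
  mids <- net$metabolites$id
  rids <- names(net$reactions)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(net$reactions)) {
    st <- net$reactions[[k]]$stoichiometry
    i <- c(i, match(names(st), mids))
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(mids), length(rids)),
                            dimnames = list(mids, rids))
  if (!sparse) S <- as.matrix(S)
  S
}

#' Split reversible reactions into forward/backward pairs
#'
#' Every reaction with a negative lower bound is replaced by an
#' irreversible forward child (`id_f`, bounds `[0, ub]`) and a backward
#' child (`id_b`, bounds `[0, -lb]`, negated stoichiometry), so flux
#' magnitudes become linear in the decision variables. Irreversible
#' reactions pass through unchanged. The mapping back to parent space is
#' stored in `attr(, "parent_map")` (columns `child`, `parent`, `sign`).
#'
#' @param net A metabolic network.
#' @return The split network (all lower bounds `>= 0`).
#' @export
split_reversible <- function(net) {
  out <- list(); child <- character(0); parent <- character(0); sgn <- numeric(0)
  for (r in net$reactions) {
    if (r$lb < 0) {
      f <- r; f$id <- paste0(r$id, "_f"); f$lb <- 0
      b <- r; b$id <- paste0(r$id, "_b"); b$lb <- 0; b$ub <- -r$lb
      b$stoichiometry <- -r$stoichiometry
      out <- c(out, list(f), list(b))
      child <- c(child, f$id, b$id); parent <- c(parent, r$id, r$id)
      sgn <- c(sgn, 1, -1)
    } else {
      out <- c(out, list(r))
      child <- c(child, r$id); parent <- c(parent, r$id); sgn <- c(sgn, 1)
    }
  }
  snet <- metabolic_network(net$metabolites, out, genes = net$genes,
                            id = paste0(net$id, "_split"))
  attr(snet, "parent_map") <- data.frame(child = child, parent = parent,
                                         sign = sgn, stringsAsFactors = FALSE)
  snet
}

#' Write a human-readable network dump
#'
#' One row per reaction: id, equation string, bounds, GPR rule, subsystem.
#'
#' @param net A metabolic network.
#' @param path Output TSV path; when `NULL` the data frame is returned.
#' @return The dump data frame, invisibly when written.
#' @export
network_table <- function(net, path = NULL) {
  eqn <- vapply(net$reactions, reaction_equation, character(1))
  df <- data.frame(
    reaction_id = names(net$reactions),
    equation = unname(eqn),
    lb = vapply(net$reactions, `[[`, numeric(1), "lb"),
    ub = vapply(net$reactions, `[[`, numeric(1), "ub"),
    gene_rule = vapply(net$reactions, `[[`, character(1), "gene_rule"),
    subsystem = vapply(net$reactions, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Format a reaction equation string
#' @param r A [reaction()].
#' @return e.g. `"glc_c --> 2 pyr_c"` (`<=>` when reversible).
#' @export
reaction_equation <- function(r) {
  st <- r$stoichiometry
  side <- function(v) {
    if (length(v) == 0L) return("")
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  }
  arrow <- if (r$lb < 0) "<=>" else "-->"
  paste(side(st[st < 0]), arrow, side(st[st > 0]))
}
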