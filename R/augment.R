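#' Default nuclear histone-modification augmentation
#'
#' Eight reactions wire bulk histone acetylation and methylation into a
#' network: an acetyl-CoA/CoA nuclear antiporter, nuclear import of
#' S-adenosyl-L-methionine (SAM), the acetylation and methylation reactions
#' themselves, nuclear export of S-adenosyl-L-homocysteine (SAH), demand
#' sinks for acetylated and methylated histone, and an unconstrained
#' histone supply. Histone species are non-conserved pseudo-metabolites, so
#' the modification fluxes are limited only by donor (acetyl-CoA / SAM)
#' availability; the demand fluxes `DM_histone_ac` and `DM_histone_me` are
#' the model's readout for bulk acetylation and methylation.
#'
#' @param accoa,coa,amet,ahcys Cytosolic ids of acetyl-CoA, coenzyme A, SAM
#'   and SAH in the host network.
#' @param nucleus Compartment code used for the added nuclear species.
#' @param acetyl_gene,methyl_gene GPR rules for the writer reactions
#'   (histone acetyltransferase / methyltransferase).
#' @return An `augmentation_spec`: list with `reactions` (list of
#'   [reaction()]), `required` (precursor ids that must pre-exist) and
#'   `nucleus`.
#' @export
default_histone_augmentation <- function(accoa = "accoa_c", coa = "coa_c",
                                         amet = "amet_c", ahcys = "ahcys_c",
                                         nucleus = "n",
                                         acetyl_gene = "KAT2A",
                                         methyl_gene = "EHMT2") {
  nn <- function(base) paste0(base, "_", nucleus)
  sub <- "Histone modification"
  rx <- list(
    reaction("ACCOAtn", c(setNames(c(-1, -1, 1, 1),
                                   c(accoa, nn("coa"), nn("accoa"), coa))),
             lb = 0, ub = 1000, name = "acetyl-CoA/CoA nuclear antiport",
             subsystem = sub),
    reaction("AMETtn", setNames(c(-1, 1), c(amet, nn("amet"))),
             lb = 0, ub = 1000, name = "SAM nuclear import", subsystem = sub),
    reaction("AHCYStn", setNames(c(-1, 1), c(nn("ahcys"), ahcys)),
             lb = 0, ub = 1000, name = "SAH nuclear export", subsystem = sub),
    reaction("HISTS", setNames(1, nn("hist")),
             lb = 0, ub = 1000, name = "histone supply", subsystem = sub),
    reaction("HIST_AC", setNames(c(-1, -1, 1, 1),
                                 c(nn("accoa"), nn("hist"), nn("histac"), nn("coa"))),
             lb = 0, ub = 1000, gene_rule = acetyl_gene,
             name = "histone acetylation", subsystem = sub),
    reaction("HIST_ME", setNames(c(-1, -1, 1, 1),
                                 c(nn("amet"), nn("hist"), nn("histme"), nn("ahcys"))),
             lb = 0, ub = 1000, gene_rule = methyl_gene,
             name = "histone methylation", subsystem = sub),
    reaction("DM_histone_ac", setNames(-1, nn("histac")),
             lb = 0, ub = 1000, name = "acetyl-histone demand", subsystem = sub),
    reaction("DM_histone_me", setNames(-1, nn("histme")),
             lb = 0, ub = 1000, name = "methyl-histone demand", subsystem = sub))
  structure(list(reactions = rx,
                 required = c(accoa, coa, amet, ahcys),
                 nucleus = nucleus),
            class = "augmentation_spec")
}

#' Augment a network with nuclear histone-modification reactions
#'
#' Adds the spec's reactions and any nuclear species they introduce. The
#' host network must already contain the cytosolic precursor species
#' (acetyl-CoA, CoA, SAM, SAH); augmenting twice fails on id collision.
#'
#' @param net A [metabolic_network()].
#' @param spec An augmentation spec, by default
#'   [default_histone_augmentation()].
#' @return The augmented network; the reaction count grows by exactly
#'   `length(spec$reactions)`.
#' @export
augment_with_histone_reactions <- function(net, spec = default_histone_augmentation()) {
  missing_pre <- setdiff(spec$required, net$metabolites$id)
  if (length(missing_pre))
    stop("precursor species not found in network: ",
         paste(missing_pre, collapse = ", "))
  new_ids <- vapply(spec$reactions, `[[`, character(1), "id")
  clash <- intersect(new_ids, names(net$reactions))
  if (length(clash))
    stop("duplicate-id: reaction(s) already present: ",
         paste(clash, collapse = ", "))
  used <- unique(unlist(lapply(spec$reactions, function(r) names(r$stoichiometry))))
  new_mets <- setdiff(used, net$metabolites$id)
  if (length(new_mets)) {
    comp <- sub("^.*_", "", new_mets)
    mets <- rbind(net$metabolites,
                  data.frame(id = new_mets, name = new_mets, compartment = comp,
                             stringsAsFactors = FALSE))
  } else mets <- net$metabolites
  new_genes <- unique(unlist(lapply(spec$reactions, function(r)
    gene_rule_genes(parse_gene_rule(r$gene_rule)))))
  metabolic_network(mets, c(net$reactions, spec$reactions),
                    genes = union(net$genes, new_genes), id = net$id)
}

#' Dump an augmentation spec as a table
#'
#' Same columns as [network_table()].
#' @param spec An augmentation spec.
#' @param path Optional TSV output path.
#' @return Data frame of the added reactions.
#' @export
augmentation_table <- function(spec, path = NULL) {
  fake <- metabolic_network(
    data.frame(id = unique(unlist(lapply(spec$reactions,
                                         function(r) names(r$stoichiometry)))),
               compartment = "x", stringsAsFactors = FALSE),
    spec$reactions)
  network_table(fake, path)
}

#' Construct a media configuration
#'
#' A media configuration names a condition and lists available nutrients
#' with their concentrations. Applying it caps each nutrient's exchange
#' uptake at `min(max_uptake, scale * mM)` (the default scale maps
#' 1 mM to an uptake cap of 1 mmol/gDW/h) and closes uptake for
#' fatty-acid exchanges listed in `closed_fatty_acids` but absent from the
#' nutrient list.
#'
#' @param condition Condition name.
#' @param nutrients Data frame with columns `metabolite_id`, `mM`.
#' @param scale Concentration-to-flux scale (mmol/gDW/h per mM).
#' @param closed_fatty_acids Extracellular metabolite ids whose uptake is
#'   closed when not supplied.
#' @param max_uptake Hard cap on any uptake bound.
#' @return A `media_config` object.
#' @export
media_config <- function(condition, nutrients, scale = 1,
                         closed_fatty_acids = character(0), max_uptake = 1000) {
  stopifnot(is.data.frame(nutrients),
            all(c("metabolite_id", "mM") %in% names(nutrients)))
  if (any(nutrients$mM < 0)) stop("nutrient concentrations must be >= 0")
  structure(list(condition = condition, nutrients = nutrients, scale = scale,
                 closed_fatty_acids = closed_fatty_acids,
                 max_uptake = max_uptake),
            class = "media_config")
}

#' Read a media configuration from YAML
#'
#' Expected keys: `condition`, `nutrients` (list of `{id, mM}`), optional
#' `scale`, `closed_fatty_acids`, `max_uptake`.
#'
#' @param path YAML file path.
#' @return A [media_config()].
#' @export
read_media_config <- function(path) {
  if (!file.exists(path)) stop("media config not found: ", path)
  y <- yaml::read_yaml(path)
  nut <- data.frame(
    metabolite_id = vapply(y$nutrients, `[[`, character(1), "id"),
    mM = vapply(y$nutrients, function(n) as.numeric(n$mM), numeric(1)),
    stringsAsFactors = FALSE)
  media_config(condition = y$condition, nutrients = nut,
               scale = if (is.null(y$scale)) 1 else y$scale,
               closed_fatty_acids = as.character(unlist(y$closed_fatty_acids)),
               max_uptake = if (is.null(y$max_uptake)) 1000 else y$max_uptake)
}

#' Write a media configuration to YAML
#' @param media A [media_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_media_config <- function(media, path) {
  yaml::write_yaml(list(
    condition = media$condition,
    nutrients = lapply(seq_len(nrow(media$nutrients)), function(i)
      list(id = media$nutrients$metabolite_id[i], mM = media$nutrients$mM[i])),
    scale = media$scale,
    closed_fatty_acids = as.list(media$closed_fatty_acids),
    max_uptake = media$max_uptake), path)
  invisible(path)
}

#' Apply a media configuration to a network
#'
#' Each listed nutrient's exchange uptake bound becomes
#' `min(max_uptake, scale * mM)`; closed fatty acids absent from the
#' nutrient list get uptake bound 0. Secretion bounds are untouched.
#' Exchanges are identified as single-metabolite reactions; for the usual
#' `met_e <=> (boundary)` orientation (coefficient -1) uptake is the
#' negative flux direction, so the lower bound is set to `-cap`.
#'
#' @param net A metabolic network.
#' @param media A [media_config()].
#' @return The bounded network.
#' @export
apply_media_config <- function(net, media) {
  exch <- which(is_exchange(net))
  exch_met <- vapply(net$reactions[exch],
                     function(r) names(r$stoichiometry), character(1))
  set_uptake <- function(net, met, cap) {
    hit <- exch[exch_met == met]
    if (length(hit) == 0L)
      stop("no exchange reaction found for nutrient: ", met)
    for (k in hit) {
      r <- net$reactions[[k]]
      if (unname(r$stoichiometry[met]) < 0) {
        net$reactions[[k]]$lb <- -cap
      } else {
        net$reactions[[k]]$ub <- cap
      }
    }
    net
  }
  comp <- setNames(net$metabolites$compartment, net$metabolites$id)
  for (i in seq_len(nrow(media$nutrients))) {
    met <- media$nutrients$metabolite_id[i]
    if (!met %in% names(comp))
      stop("nutrient metabolite not in network: ", met)
    if (!identical(comp[[met]], "e"))
      stop("nutrient is not extracellular: ", met)
    cap <- min(media$max_uptake, media$scale * media$nutrients$mM[i])
    net <- set_uptake(net, met, cap)
  }
  for (met in setdiff(media$closed_fatty_acids, media$nutrients$metabolite_id)) {
    net <- set_uptake(net, met, 0)
  }
  net
}
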