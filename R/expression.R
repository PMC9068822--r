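#' Read a differential-expression table
#'
#' Expects a TSV with columns `gene_id`, `log2fc`, `fdr` (case-insensitive;
#' `log2FC`/`logFC` and `padj`/`FDR` are accepted).
#'
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `log2fc`, `fdr`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- match(cands, tolower(names(df)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L)
      stop("DE table ", path, " lacks a column named one of: ",
           paste(cands, collapse = ", "))
    names(df)[hit[1L]]
  }
  out <- data.frame(gene_id = as.character(df[[pick(c("gene_id", "gene"))]]),
                    log2fc = as.numeric(df[[pick(c("log2fc", "logfc", "lfc"))]]),
                    fdr = as.numeric(df[[pick(c("fdr", "padj", "qvalue"))]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in DE table ", path)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE))
    stop("FDR values outside [0,1] in ", path)
  out
}

#' Categorize genes as up/down/neutral from a DE table
#'
#' Up: `fdr < fdr_cut` and `log2fc >= lfc_cut`; down: `fdr < fdr_cut` and
#' `log2fc <= -lfc_cut`; everything else neutral. The defaults (FDR 0.01,
#' |log2FC| >= 2) follow the RNA-seq workflow that produces the tables this
#' function consumes; a laxer |log2FC| > 1 variant is supported by passing
#' `lfc_cut = 1`.
#'
#' @param de Data frame with `gene_id`, `log2fc`, `fdr`.
#' @param fdr_cut,lfc_cut Positive thresholds.
#' @return An `expression_state`: list with `up`, `down` (disjoint gene-id
#'   sets) and `thresholds`.
#' @export
categorize_genes <- function(de, fdr_cut = 0.01, lfc_cut = 2) {
  stopifnot(fdr_cut > 0, lfc_cut > 0)
  if (nrow(de) == 0L) {
    return(structure(list(up = character(0), down = character(0),
                          thresholds = c(fdr_cut = fdr_cut, lfc_cut = lfc_cut)),
                     class = "expression_state"))
  }
  sig <- !is.na(de$fdr) & de$fdr < fdr_cut & !is.na(de$log2fc)
  up <- de$gene_id[sig & de$log2fc >= lfc_cut]
  down <- de$gene_id[sig & de$log2fc <= -lfc_cut]
  structure(list(up = up, down = down,
                 thresholds = c(fdr_cut = fdr_cut, lfc_cut = lfc_cut)),
            class = "expression_state")
}

#' Map gene categories onto reactions through GPR rules
#'
#' A reaction is UP when at least one gene of its rule is upregulated and
#' none is downregulated; DOWN symmetrically; NEUTRAL otherwise (empty
#' rules, mixed signals, or no categorized gene). An optional two-column
#' id-mapping table translates DE gene ids into the model's namespace
#' first; DE genes with no model counterpart stay neutral and their count
#' is attached as `attr(, "n_unmapped")`.
#'
#' @param net A metabolic network.
#' @param state An [categorize_genes()] `expression_state`.
#' @param mapping Optional data frame with columns `model_gene`, `de_gene`.
#' @return Named character vector (reaction id -> "UP"/"DOWN"/"NEUTRAL")
#'   of class `reaction_categories`.
#' @export
map_genes_to_reactions <- function(net, state, mapping = NULL) {
  up <- state$up; down <- state$down
  if (!is.null(mapping)) {
    stopifnot(all(c("model_gene", "de_gene") %in% names(mapping)))
    up <- mapping$model_gene[mapping$de_gene %in% up]
    down <- mapping$model_gene[mapping$de_gene %in% down]
  }
  n_unmapped <- sum(!c(state$up, state$down) %in%
                      if (is.null(mapping)) net$genes else mapping$de_gene)
  cats <- vapply(net$reactions, function(r) {
    g <- gene_rule_genes(parse_gene_rule(r$gene_rule))
    if (length(g) == 0L) return("NEUTRAL")
    has_up <- any(g %in% up); has_down <- any(g %in% down)
    if (has_up && !has_down) "UP"
    else if (has_down && !has_up) "DOWN"
    else "NEUTRAL"
  }, character(1))
  structure(cats, class = "reaction_categories", n_unmapped = n_unmapped)
}
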