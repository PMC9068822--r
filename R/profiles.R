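#' Expression response versus baseline expression
#'
#' For each gene, the baseline is `ln(E_ctrl / E_ctrl_avg)` — the log of
#' the gene's mean control expression relative to the grand mean over all
#' genes and control replicates — and the response is
#' `ln(E_trt / E_ctrl)`, the log fold response to treatment. A pseudocount
#' is added to all expression values before ratios so zero-TPM genes stay
#' finite. Plotting response against baseline exposes mean-reverting
#' regulation: a negative trend means lowly expressed genes come up and
#' highly expressed genes come down under treatment.
#'
#' @param m Genes x samples matrix of non-negative abundances (TPM), with
#'   unique rownames.
#' @param labels Condition label per column of `m`.
#' @param ctrl_label,trt_label Labels selecting control and treatment
#'   columns.
#' @param pseudocount Added to every expression value (default 0.5 TPM).
#' @param min_tpm Optional filter: genes whose mean control expression
#'   (before pseudocount) is below this are dropped (default 0 = keep all).
#' @return Data frame with columns `gene`, `baseline`, `response`;
#'   `attr(, "pseudocount")` records the offset used.
#' @export
response_vs_baseline <- function(m, labels, ctrl_label, trt_label,
                                 pseudocount = 0.5, min_tpm = 0) {
  stopifnot(is.matrix(m), ncol(m) == length(labels), pseudocount > 0)
  if (any(m < 0)) stop("expression matrix has negative entries")
  if (!ctrl_label %in% labels) stop("unknown condition label: ", ctrl_label)
  if (!trt_label %in% labels) stop("unknown condition label: ", trt_label)
  ctrl <- m[, labels == ctrl_label, drop = FALSE]
  trt <- m[, labels == trt_label, drop = FALSE]
  keep <- rowMeans(ctrl) >= min_tpm
  ctrl <- ctrl[keep, , drop = FALSE]; trt <- trt[keep, , drop = FALSE]
  e_ctrl <- rowMeans(ctrl + pseudocount)
  e_trt <- rowMeans(trt + pseudocount)
  e_ctrl_avg <- mean(ctrl + pseudocount)
  out <- data.frame(gene = rownames(m)[keep],
                    baseline = log(e_ctrl / e_ctrl_avg),
                    response = log(e_trt / e_ctrl),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Trend statistic for a response profile
#'
#' Spearman rank correlation (tie-aware) between baseline and response.
#'
#' @param p Data frame from [response_vs_baseline()].
#' @return List with `rho` (NA when either vector is constant) and `n`.
#' @export
trend_statistic <- function(p) {
  stopifnot(all(c("baseline", "response") %in% names(p)))
  if (nrow(p) < 3L) stop("need at least 3 genes for a trend statistic")
  if (length(unique(p$baseline)) < 2L || length(unique(p$response)) < 2L)
    return(list(rho = NA_real_, n = nrow(p)))
  list(rho = unname(cor(p$baseline, p$response, method = "spearman")),
       n = nrow(p))
}

#' qPCR log2 relative expression
#'
#' `log2RE = -(Ct_gene - Ct_reference)` per sample, i.e. expression
#' normalized to the reference gene on the log2 scale (the
#' `log2 2^-(dCt)` identity).
#'
#' @param ct Data frame with columns `sample`, `gene`, `ct` (threshold
#'   cycles, > 0).
#' @param reference Reference gene id (default "GAPDH").
#' @return Data frame `sample`, `gene`, `log2re` for all non-reference
#'   genes.
#' @export
log2_relative_expression <- function(ct, reference = "GAPDH") {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  refs <- ct[ct$gene == reference, , drop = FALSE]
  samples <- unique(ct$sample)
  missing_ref <- setdiff(samples, refs$sample)
  if (length(missing_ref))
    stop("reference gene '", reference, "' missing for sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- setNames(refs$ct, refs$sample)
  out <- ct[ct$gene != reference, , drop = FALSE]
  data.frame(sample = out$sample, gene = out$gene,
             log2re = -(out$ct - unname(ref_ct[out$sample])),
             stringsAsFactors = FALSE, row.names = NULL)
}
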