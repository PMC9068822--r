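## Seeded generators for every input of the pipeline, plus the fixed toy
## metabolic network. The toy network is a deliberate constant (not random)
## so direction-recovery results are reproducible: it spans glucose uptake
## -> glycolysis -> acetyl-CoA, octanoate/linoleate beta-oxidation, the
## folate and methionine cycles of one-carbon metabolism, and the nuclear
## histone acetylation/methylation chemistry. Carbon skeletons balance for
## every internal reaction (cofactors such as CoA, THF and the adenosyl
## moiety are modeled as carbon-free carriers; see the packaged carbon
## table).

.toy_metabolite_table <- function() {
  de <- function(id, name, comp, carbons)
    data.frame(id = id, name = name, compartment = comp, carbons = carbons,
               stringsAsFactors = FALSE)
  rbind(
    de("glc_e", "D-glucose", "e", 6), de("glc_c", "D-glucose", "c", 6),
    de("octa_e", "octanoate", "e", 8), de("octa_c", "octanoate", "c", 8),
    de("lnlc_e", "linoleate", "e", 18), de("lnlc_c", "linoleate", "c", 18),
    de("gln_e", "L-glutamine", "e", 5), de("gln_c", "L-glutamine", "c", 5),
    de("ser_e", "L-serine", "e", 3), de("ser_c", "L-serine", "c", 3),
    de("gly_e", "glycine", "e", 2), de("gly_c", "glycine", "c", 2),
    de("met_e", "L-methionine", "e", 5), de("met_c", "L-methionine", "c", 5),
    de("co2_e", "CO2", "e", 1), de("co2_c", "CO2", "c", 1),
    de("pyr_c", "pyruvate", "c", 3),
    de("accoa_c", "acetyl-CoA (acetyl moiety)", "c", 2),
    de("coa_c", "coenzyme A (carrier)", "c", 0),
    de("thf_c", "tetrahydrofolate (carrier)", "c", 0),
    de("mlthf_c", "5,10-methylene-THF (C1 unit)", "c", 1),
    de("mthf_c", "5-methyl-THF (C1 unit)", "c", 1),
    de("f10thf_c", "10-formyl-THF (C1 unit)", "c", 1),
    de("amet_c", "S-adenosyl-L-methionine (Met moiety)", "c", 5),
    de("ahcys_c", "S-adenosyl-L-homocysteine (Hcy moiety)", "c", 4),
    de("hcys_c", "L-homocysteine", "c", 4),
    de("aden_c", "adenosyl moiety (carrier)", "c", 0),
    de("sarcs_c", "sarcosine", "c", 3),
    de("accoa_n", "nuclear acetyl-CoA (acetyl moiety)", "n", 2),
    de("coa_n", "nuclear coenzyme A (carrier)", "n", 0),
    de("amet_n", "nuclear SAM (Met moiety)", "n", 5),
    de("ahcys_n", "nuclear SAH (Hcy moiety)", "n", 4),
    de("hist_n", "histone lysine pool (carrier)", "n", 0),
    de("histac_n", "acetylated histone (acetyl mark)", "n", 2),
    de("histme_n", "methylated histone (methyl mark)", "n", 1))
}

#' Carbon bookkeeping table for the toy network
#'
#' Carbon-skeleton counts per metabolite (carriers such as CoA, THF, the
#' adenosyl moiety and the histone lysine pool count 0). Internal toy
#' reactions are carbon-balanced against this table; the same table is
#' shipped as `extdata/toy_metabolite_carbons.tsv`.
#'
#' @return Data frame with columns `id`, `name`, `compartment`, `carbons`.
#' @export
toy_carbon_table <- function() {
  .toy_metabolite_table()
}

#' Build the fixed toy metabolic network
#'
#' A ~30-reaction carbon-balanced network: glucose uptake and lumped
#' glycolysis to pyruvate and acetyl-CoA; octanoate (medium-chain) and
#' linoleate (long-chain) exchanges with lumped beta-oxidation; lumped
#' glutaminolysis; serine/glycine-fed folate cycle (serine
#' hydroxymethyltransferase, glycine cleavage, MTHFD, MTHFR,
#' formyltetrahydrofolate dehydrogenase); the methionine cycle (methionine
#' adenosyltransferase, glycine N-methyltransferase, adenosyl
#' homocysteinase, methionine synthase); and, when `augmented = TRUE`
#' (default), the eight nuclear histone-modification reactions of
#' [default_histone_augmentation()]. Every named enzyme carries a gene id
#' and a subsystem label.
#'
#' @param augmented Include the histone augmentation (default `TRUE`).
#' @return A [metabolic_network()].
#' @export
make_toy_network <- function(augmented = TRUE) {
  mets <- .toy_metabolite_table()
  base_mets <- mets[mets$compartment != "n", c("id", "name", "compartment")]
  rx <- function(id, st, lb, ub, gr = "", sub, name = id)
    reaction(id, st, lb = lb, ub = ub, gene_rule = gr, subsystem = sub,
             name = name)
  ex <- function(met, lb = -1000, ub = 1000)
    rx(paste0("EX_", sub("_e$", "", met)), setNames(-1, met), lb, ub,
       sub = "Exchange", name = paste0("exchange of ", met))
  tp <- function(id, from, to, gr = "", rev = FALSE)
    rx(id, setNames(c(-1, 1), c(from, to)), if (rev) -1000 else 0, 1000,
       gr, sub = "Transport")
  reactions <- list(
    ex("glc_e"), ex("octa_e"), ex("lnlc_e"), ex("gln_e"),
    ex("ser_e"), ex("gly_e"), ex("met_e"),
    ex("co2_e", lb = 0),                       # secretion only
    tp("GLCt", "glc_e", "glc_c", "SLC2A1"),
    tp("OCTt", "octa_e", "octa_c", ""),        # passive diffusion
    tp("LNLCt", "lnlc_e", "lnlc_c", "SLC27A1"),
    tp("GLNt", "gln_e", "gln_c", "SLC1A5"),
    tp("SERt", "ser_e", "ser_c", "SLC1A4"),
    tp("GLYt", "gly_e", "gly_c", "SLC6A9"),
    tp("METt", "met_e", "met_c", "SLC7A5", rev = TRUE),
    tp("CO2t", "co2_c", "co2_e", "", rev = TRUE),
    rx("GLYC", c(glc_c = -1, pyr_c = 2), 0, 1000,
       "HK1 and GAPD and PKM", "Glycolysis", "glycolysis (lumped)"),
    rx("PDH", c(pyr_c = -1, coa_c = -1, accoa_c = 1, co2_c = 1), 0, 1000,
       "PDHA1", "Glycolysis", "pyruvate dehydrogenase"),
    rx("TCA", c(accoa_c = -1, coa_c = 1, co2_c = 2), 0, 1000,
       "CS", "TCA cycle", "acetyl-CoA oxidation (lumped)"),
    rx("FAOX8", c(octa_c = -1, coa_c = -4, accoa_c = 4), 0, 1000,
       "ACADM or ACADS", "Fatty acid oxidation",
       "octanoate beta-oxidation (lumped)"),
    rx("FAOX18", c(lnlc_c = -1, coa_c = -9, accoa_c = 9), 0, 1000,
       "ACADVL and HADHA", "Fatty acid oxidation",
       "linoleate beta-oxidation (lumped)"),
    rx("GLNOX", c(gln_c = -1, co2_c = 5), 0, 1000,
       "GLS", "Glutamine metabolism", "glutaminolysis (lumped)"),
    rx("SHMT", c(ser_c = -1, thf_c = -1, gly_c = 1, mlthf_c = 1), 0, 1000,
       "SHMT1 or SHMT2", "One-carbon/Methionine",
       "serine hydroxymethyltransferase"),
    rx("GCS", c(gly_c = -1, thf_c = -1, mlthf_c = 1, co2_c = 1), 0, 1000,
       "GLDC", "One-carbon/Methionine", "glycine cleavage system"),
    rx("MTHFD", c(mlthf_c = -1, f10thf_c = 1), 0, 1000,
       "MTHFD1", "One-carbon/Methionine",
       "methylene-THF dehydrogenase/cyclohydrolase (lumped)"),
    rx("MTHFR", c(mlthf_c = -1, mthf_c = 1), 0, 1000,
       "MTHFR", "One-carbon/Methionine",
       "5,10-methylene-THF reductase"),
    rx("FTHFD", c(f10thf_c = -1, thf_c = 1, co2_c = 1), 0, 1000,
       "ALDH1L1", "One-carbon/Methionine",
       "formyltetrahydrofolate dehydrogenase"),
    rx("MAT", c(met_c = -1, aden_c = -1, amet_c = 1), 0, 1000,
       "MAT2A or MAT1A", "One-carbon/Methionine",
       "methionine adenosyltransferase"),
    rx("MS", c(hcys_c = -1, mthf_c = -1, met_c = 1, thf_c = 1), 0, 1000,
       "MTR", "One-carbon/Methionine", "methionine synthase"),
    rx("AHCY", c(ahcys_c = -1, hcys_c = 1, aden_c = 1), 0, 1000,
       "AHCY", "One-carbon/Methionine", "adenosyl homocysteinase"),
    rx("GNMT", c(amet_c = -1, gly_c = -1, ahcys_c = 1, sarcs_c = 1), 0, 1000,
       "GNMT", "One-carbon/Methionine", "glycine N-methyltransferase"),
    rx("DM_sarcs", c(sarcs_c = -1), 0, 1000, sub = "Demand",
       name = "sarcosine demand"))
  net <- metabolic_network(base_mets, reactions, id = "toy")
  if (augmented) net <- augment_with_histone_reactions(net)
  net
}

#' Packaged media configurations for the toy network
#'
#' Control medium supplies glucose (8.0 mM, the molar equivalent of
#' 1.441 g/L), glutamine (2.0 mM, of 0.292 g/L), and low levels of serine,
#' glycine and methionine, with both fatty-acid exchanges closed. The
#' octanoate condition adds 5 mM octanoate; the linoleate condition adds
#' 0.5 mM linoleate.
#'
#' @param condition "control", "octanoate" or "linoleate".
#' @return A [media_config()].
#' @export
toy_media <- function(condition = c("control", "octanoate", "linoleate")) {
  condition <- match.arg(condition)
  base <- data.frame(
    metabolite_id = c("glc_e", "gln_e", "ser_e", "gly_e", "met_e"),
    mM = c(8.0, 2.0, 0.4, 0.4, 0.2), stringsAsFactors = FALSE)
  extra <- switch(condition,
    control = NULL,
    octanoate = data.frame(metabolite_id = "octa_e", mM = 5.0,
                           stringsAsFactors = FALSE),
    linoleate = data.frame(metabolite_id = "lnlc_e", mM = 0.5,
                           stringsAsFactors = FALSE))
  media_config(condition, rbind(base, extra), scale = 1,
               closed_fatty_acids = c("octa_e", "lnlc_e"))
}

#' Planted gene sets for the packaged presets
#'
#' "octanoate": beta-oxidation, one-carbon/methionine-cycle and
#' histone-writer genes up, glycolysis genes down — the treatment
#' signature. "control": glycolysis and the acetyltransferase up — the
#' glucose-fed baseline signature.
#'
#' @param preset "octanoate" or "control".
#' @return List with `up` and `down` gene-id vectors.
#' @export
preset_gene_sets <- function(preset = c("octanoate", "control")) {
  preset <- match.arg(preset)
  switch(preset,
    octanoate = list(
      up = c("ACADM", "ACADS", "SHMT1", "SHMT2", "GLDC", "MTHFD1", "MTHFR",
             "ALDH1L1", "MAT2A", "MTR", "AHCY", "GNMT", "EHMT2", "KAT2A"),
      down = c("HK1", "GAPD", "PKM")),
    control = list(
      up = c("HK1", "GAPD", "PKM", "PDHA1", "KAT2A"),
      down = character(0)))
}

#' Synthetic-data configuration
#'
#' One configuration object drives all generators. Planted effect sizes
#' default far beyond the calling thresholds (log2FC 4 versus a threshold
#' of 2) so recovery is exact by construction.
#'
#' @param seed Integer seed (all generators are deterministic given it).
#' @param n_genes Total genes in DE tables / expression matrices.
#' @param preset Named preset resolving `up_set`/`down_set`
#'   (see [preset_gene_sets()]), or `NULL`.
#' @param up_set,down_set Explicit planted gene sets (override the preset).
#' @param effect_lfc Planted |log2FC| for up/down genes.
#' @param noise_sd log2FC noise SD.
#' @param kappa Mean-reversion strength of the expression generator.
#' @param n_reps Replicates per condition in the expression matrix.
#' @param genome Named toy chromosome lengths.
#' @param n_peaks,peak_len,n_features,feature_len Interval-set geometry.
#' @param p_in,p_out Relative peak placement densities inside versus
#'   outside feature-proximal regions (`p_in == p_out` is uniform).
#' @param ct_effects Named vector of planted delta-Ct (treatment minus
#'   control) for the Ct-table generator.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_genes = 1000,
                             preset = NULL, up_set = NULL, down_set = NULL,
                             effect_lfc = 4, noise_sd = 0.25,
                             kappa = 0.5, n_reps = 3,
                             genome = c(chr1 = 1e6, chr2 = 1e6),
                             n_peaks = 200, peak_len = 500,
                             n_features = 20, feature_len = 1500,
                             p_in = 1, p_out = 1,
                             ct_effects = c(ACSS2 = -2, CPT1A = -1, FASN = 0)) {
  if (!is.null(preset)) {
    ps <- preset_gene_sets(preset)
    if (is.null(up_set)) up_set <- ps$up
    if (is.null(down_set)) down_set <- ps$down
  }
  if (is.null(up_set)) up_set <- character(0)
  if (is.null(down_set)) down_set <- character(0)
  if (length(intersect(up_set, down_set)))
    stop("up and down gene sets overlap: ",
         paste(intersect(up_set, down_set), collapse = ", "))
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 up_set = up_set, down_set = down_set,
                 effect_lfc = effect_lfc, noise_sd = noise_sd,
                 kappa = kappa, n_reps = n_reps, genome = genome,
                 n_peaks = n_peaks, peak_len = peak_len,
                 n_features = n_features, feature_len = feature_len,
                 p_in = p_in, p_out = p_out, ct_effects = ct_effects),
            class = "synthetic_config")
}

.synthetic_gene_universe <- function(cfg) {
  planted <- c(cfg$up_set, cfg$down_set)
  n_fill <- max(0L, cfg$n_genes - length(planted))
  c(planted, sprintf("g%05d", seq_len(n_fill)))
}

#' Simulate a differential-expression table
#'
#' Planted up genes draw `log2fc ~ N(+effect_lfc, noise_sd)` and
#' `fdr ~ U(0, 1e-4)`; down genes are mirrored; null genes draw
#' `log2fc ~ N(0, noise_sd)` and `fdr ~ U(0.2, 1)`. The planted truth is
#' attached as `attr(, "truth")`.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame `gene_id`, `log2fc`, `fdr`.
#' @export
simulate_de_table <- function(cfg) {
  genes <- .synthetic_gene_universe(cfg)
  .with_seed(cfg$seed, {
    n <- length(genes)
    lfc <- rnorm(n, 0, cfg$noise_sd)
    fdr <- runif(n, 0.2, 1)
    iu <- genes %in% cfg$up_set; idn <- genes %in% cfg$down_set
    lfc[iu] <- rnorm(sum(iu), cfg$effect_lfc, cfg$noise_sd)
    lfc[idn] <- rnorm(sum(idn), -cfg$effect_lfc, cfg$noise_sd)
    fdr[iu | idn] <- runif(sum(iu | idn), 0, 1e-4)
    out <- data.frame(gene_id = genes, log2fc = lfc, fdr = fdr,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(up = cfg$up_set, down = cfg$down_set)
    out
  })
}

#' Simulate a mean-reverting expression matrix
#'
#' Control TPMs are log-normal per gene with replicate noise; treatment
#' TPMs are `control * exp(-kappa * baseline + noise)` where the baseline
#' is the gene's log expression relative to the grand mean — so `kappa > 0`
#' plants the anticorrelation between baseline expression and treatment
#' response, and `kappa = 0` plants none.
#'
#' @param cfg A [synthetic_config()] (`kappa`, `n_genes`, `n_reps`,
#'   `noise_sd`, `seed`).
#' @return TPM matrix with genes as rows; `attr(, "labels")` gives the
#'   condition per column, `attr(, "truth")` the planted kappa.
#' @export
simulate_expression_matrix <- function(cfg) {
  .with_seed(cfg$seed + 1L, {
    n <- cfg$n_genes
    mu <- rlnorm(n, meanlog = 3, sdlog = 1.2)
    baseline <- log(mu / mean(mu))
    trt_mu <- mu * exp(-cfg$kappa * baseline + rnorm(n, 0, cfg$noise_sd))
    rep_noise <- function(m, k)
      m * matrix(exp(rnorm(length(m) * k, 0, 0.05)), nrow = length(m))
    ctrl <- rep_noise(mu, cfg$n_reps)
    trt <- rep_noise(trt_mu, cfg$n_reps)
    out <- cbind(ctrl, trt)
    rownames(out) <- sprintf("g%05d", seq_len(n))
    labels <- rep(c("control", "treatment"), each = cfg$n_reps)
    colnames(out) <- paste0(labels, "_", rep(seq_len(cfg$n_reps), 2))
    attr(out, "labels") <- labels
    attr(out, "truth") <- list(kappa = cfg$kappa)
    out
  })
}

#' Simulate peak and feature interval sets with cut profiles
#'
#' Features are placed uniformly on the toy genome; each peak lands in the
#' feature-proximal region (where it would overlap a feature) with
#' probability proportional to `p_in`, and uniformly elsewhere with
#' density `p_out`, so `p_in == p_out` is uniform placement (calibration:
#' expected enrichment 1) and `p_in >> p_out` concentrates peaks on
#' features. Per-peak Poisson cut intensities per sample emulate Tn5
#' cut-site profiles; emitted positions are read 5' ends (the +4/-5 shift
#' of [count_cut_sites()] recovers the planted cut sites).
#'
#' @param cfg A [synthetic_config()].
#' @param n_samples Number of cut-profile samples.
#' @return List with `peaks`, `features` (`interval_set`s), `cuts` (named
#'   list of per-sample data frames) and `truth` (placement parameters and
#'   per-peak lambda).
#' @export
simulate_peaks_and_features <- function(cfg, n_samples = 2) {
  .with_seed(cfg$seed + 2L, {
    G <- sum(cfg$genome)
    chrom_of <- function(pos) {
      br <- cumsum(cfg$genome)
      i <- findInterval(pos, c(0, br), rightmost.closed = TRUE)
      list(chrom = names(cfg$genome)[i], off = pos - c(0, br)[i])
    }
    place <- function(n, len) {
      pos <- floor(runif(n, 0, G - len))
      co <- chrom_of(pos)
      ## keep intervals within one chromosome
      over <- co$off + len > cfg$genome[co$chrom]
      co$off[over] <- cfg$genome[co$chrom[over]] - len
      data.frame(chrom = co$chrom, start = co$off, end = co$off + len,
                 stringsAsFactors = FALSE)
    }
    feats <- place(cfg$n_features, cfg$feature_len)
    features <- interval_set(feats, cfg$genome, "features")
    overlaps_feature <- function(chrom, st) {
      en <- st + cfg$peak_len
      vapply(seq_along(st), function(i) {
        any(feats$chrom == chrom[i] & feats$start < en[i] &
              feats$end > st[i])
      }, logical(1))
    }
    ## each peak lands in the feature-proximal region with probability
    ## p_in * L_in / (p_in * L_in + p_out * (G - L_in)); placement within
    ## each region is uniform (rejection keeps the two regions disjoint)
    L_in <- sum(feats$end - feats$start + cfg$peak_len)
    w_in <- cfg$p_in * L_in / (cfg$p_in * L_in + cfg$p_out * (G - L_in))
    targeted <- runif(cfg$n_peaks) < w_in
    pk <- place(cfg$n_peaks, cfg$peak_len)
    for (tries in 1:50) {      # move untargeted peaks off the features
      bad <- !targeted & overlaps_feature(pk$chrom, pk$start)
      if (!any(bad)) break
      pk[bad, ] <- place(sum(bad), cfg$peak_len)
    }
    if (any(targeted)) {
      fi <- sample.int(nrow(feats), sum(targeted), replace = TRUE)
      off <- floor(runif(sum(targeted), -cfg$peak_len + 1,
                         cfg$feature_len))
      st <- pmax(0, feats$start[fi] + off)
      st <- pmin(st, cfg$genome[feats$chrom[fi]] - cfg$peak_len)
      pk[targeted, ] <- data.frame(chrom = feats$chrom[fi], start = st,
                                   end = st + cfg$peak_len,
                                   stringsAsFactors = FALSE)
    }
    peaks <- interval_set(pk, cfg$genome, "peaks")
    pk <- peaks$intervals
    lambda <- runif(nrow(pk), 20, 120)
    cuts <- lapply(seq_len(n_samples), function(s) {
      per_peak <- rpois(nrow(pk), lambda)
      idx <- rep.int(seq_len(nrow(pk)), per_peak)
      cut_pos <- floor(runif(length(idx), pk$start[idx], pk$end[idx]))
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      data.frame(chrom = pk$chrom[idx],
                 pos = cut_pos + ifelse(strand == "-", 5, -4),
                 strand = strand, stringsAsFactors = FALSE)
    })
    names(cuts) <- paste0("sample_", seq_len(n_samples))
    list(peaks = peaks, features = features, cuts = cuts,
         truth = list(p_in = cfg$p_in, p_out = cfg$p_out, lambda = lambda))
  })
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct draws from N(20, 0.2) per sample; each target gene
#' gets a baseline delta-Ct of 2 plus, under treatment, the planted effect
#' from `cfg$ct_effects` (so a planted delta-Ct of -2 is recovered as a
#' +2 difference in log2 relative expression).
#'
#' @param cfg A [synthetic_config()].
#' @param n_reps Replicates per condition.
#' @return Data frame `sample`, `condition`, `gene`, `ct`;
#'   `attr(, "truth")` carries the planted effects.
#' @export
simulate_ct_table <- function(cfg, n_reps = 3) {
  .with_seed(cfg$seed + 3L, {
    genes <- names(cfg$ct_effects)
    rows <- list()
    for (cond in c("control", "treatment")) {
      for (r in seq_len(n_reps)) {
        smp <- paste0(cond, "_", r)
        ref_ct <- rnorm(1, 20, 0.2)
        rows[[length(rows) + 1L]] <-
          data.frame(sample = smp, condition = cond, gene = "GAPDH",
                     ct = ref_ct, stringsAsFactors = FALSE)
        eff <- if (cond == "treatment") cfg$ct_effects else
          setNames(rep(0, length(genes)), genes)
        rows[[length(rows) + 1L]] <-
          data.frame(sample = smp, condition = cond, gene = genes,
                     ct = ref_ct + 2 + unname(eff[genes]) +
                       rnorm(length(genes), 0, 0.1),
                     stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(delta_ct = cfg$ct_effects)
    out
  })
}
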