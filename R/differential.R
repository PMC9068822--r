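## Differential reaction activity between conditions. The fitted flux
## state is one point from a (possibly degenerate) optimal set; to attach
## uncertainty to each reaction's activity we re-solve the LP under small
## multiplicative jitter of the objective's category weights, giving a
## seeded ensemble of optima per condition. Reactions are then compared
## across conditions with a two-sample rank-sum test and BH correction.

#' Sample a flux ensemble under objective jitter
#'
#' Solves `n` linear programs whose +/-1 category weights are multiplied by
#' independent U(1-jitter, 1+jitter) draws per parent reaction; bound- and
#' stoichiometry-constraints are untouched, so bound-saturated reactions
#' have zero spread. Deterministic given `(seed, n, jitter)`.
#'
#' @param net A metabolic network.
#' @param cats Reaction categories (parent ids).
#' @param n Ensemble size (>= 2).
#' @param jitter Relative jitter amplitude in `[0, 1)`.
#' @param seed Integer seed.
#' @param epsilon,vmax Passed to the LP (see [solve_flux_state()]).
#' @param condition Condition label.
#' @return A `flux_ensemble`: list with `condition`, `activities`
#'   (`n` x reactions matrix), `subsystems`, `seed`, `jitter`.
#' @export
sample_flux_ensemble <- function(net, cats, n = 50, jitter = 0.05, seed = 1,
                                 epsilon = 1e-4, vmax = 1000,
                                 condition = "condition") {
  stopifnot(n >= 2, jitter >= 0, jitter < 1)
  snet <- .ensure_split(net)
  parents <- unique(attr(snet, "parent_map")$parent)
  acts <- matrix(NA_real_, nrow = n, ncol = length(parents),
                 dimnames = list(NULL, parents))
  mults <- .with_seed(seed, {
    matrix(runif(n * length(parents), 1 - jitter, 1 + jitter),
           nrow = n, dimnames = list(NULL, parents))
  })
  for (i in seq_len(n)) {
    sol <- .solve_split(snet, cats, epsilon, vmax, dir_mult = mults[i, ])
    if (!identical(sol$status, "optimal"))
      stop("ensemble member ", i, " not solved: status ", sol$status)
    acts[i, ] <- sol$activity[parents]
  }
  subsys <- vapply(net$reactions, `[[`, character(1), "subsystem")
  structure(list(condition = condition, activities = acts,
                 subsystems = subsys[parents], seed = seed, jitter = jitter),
            class = "flux_ensemble")
}

#' Test reactions for differential activity between two ensembles
#'
#' Per reaction, a two-sample Wilcoxon rank-sum test compares activities of
#' the reference ensemble `a` against the treatment ensemble `b`; p-values
#' are Benjamini-Hochberg adjusted across all tested reactions, and a
#' direction ("increased"/"decreased" in `b` relative to `a`) is assigned
#' from the sign of the mean difference when `p_adj < alpha`. Reactions
#' constant within both ensembles are handled without rank degeneracy:
#' equal constants give p = 1, different constants an exact difference
#' (p = 0).
#'
#' @param a,b `flux_ensemble` objects sharing the reaction index
#'   (`a` = reference/control, `b` = treatment).
#' @param alpha Significance level on adjusted p-values.
#' @return Data frame with columns `reaction_id`, `subsystem`, `mean_a`,
#'   `mean_b`, `difference`, `p_raw`, `p_adj`, `direction`.
#' @export
test_differential_reactions <- function(a, b, alpha = 0.01) {
  ra <- colnames(a$activities); rb <- colnames(b$activities)
  if (!setequal(ra, rb)) {
    stop("ensembles have mismatched reaction sets: ",
         paste(c(setdiff(ra, rb), setdiff(rb, ra)), collapse = ", "))
  }
  rb <- ra
  p_raw <- numeric(length(ra)); diff <- numeric(length(ra))
  mean_a <- numeric(length(ra)); mean_b <- numeric(length(ra))
  for (k in seq_along(ra)) {
    x <- a$activities[, ra[k]]; y <- b$activities[, ra[k]]
    mean_a[k] <- mean(x); mean_b[k] <- mean(y)
    diff[k] <- mean_b[k] - mean_a[k]
    if (max(x) - min(x) < 1e-9 && max(y) - min(y) < 1e-9) {
      p_raw[k] <- if (abs(mean_b[k] - mean_a[k]) < 1e-9) 1 else 0
    } else {
      p_raw[k] <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      if (is.na(p_raw[k])) p_raw[k] <- 1
    }
  }
  p_adj <- p.adjust(p_raw, method = "BH")
  direction <- rep("unchanged", length(ra))
  sig <- p_adj < alpha
  direction[sig & diff > 0] <- "increased"
  direction[sig & diff < 0] <- "decreased"
  data.frame(reaction_id = ra, subsystem = unname(a$subsystems[ra]),
             mean_a = mean_a, mean_b = mean_b, difference = diff,
             p_raw = p_raw, p_adj = p_adj, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize significant reactions by subsystem
#'
#' Counts reactions called "increased" or "decreased" per subsystem; the
#' counts partition the significant set.
#'
#' @param results Data frame from [test_differential_reactions()].
#' @return Data frame with columns `subsystem`, `increased`, `decreased`;
#'   zero rows when nothing is significant.
#' @export
summarize_subsystems <- function(results) {
  sig <- results[results$direction != "unchanged", , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(subsystem = character(0), increased = integer(0),
                      decreased = integer(0), stringsAsFactors = FALSE))
  tab <- table(sig$subsystem, factor(sig$direction,
                                     levels = c("increased", "decreased")))
  data.frame(subsystem = rownames(tab),
             increased = as.integer(tab[, "increased"]),
             decreased = as.integer(tab[, "decreased"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean-activity matrix across conditions
#'
#' Heatmap-ready export: one row per reaction, one column per condition,
#' entries are ensemble mean activities.
#'
#' @param ... `flux_ensemble` objects.
#' @return Numeric matrix (reactions x conditions).
#' @export
activity_matrix <- function(...) {
  ens <- list(...)
  stopifnot(length(ens) >= 1L)
  rid <- colnames(ens[[1L]]$activities)
  out <- vapply(ens, function(e) colMeans(e$activities[, rid, drop = FALSE]),
                numeric(length(rid)))
  colnames(out) <- vapply(ens, `[[`, character(1), "condition")
  rownames(out) <- rid
  out
}
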