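## Expression-constrained flux fitting. The condition-specific flux state
## is the solution of one linear program on the reversibility-split
## network: maximize total activity of reactions tied to upregulated genes,
## minus activity of reactions tied to downregulated genes, minus a small
## parsimony term over all reactions, subject to steady state S v = 0 and
## bounds 0 <= v <= u. Activity of a parent reaction is w = v_f + v_b (the
## flux magnitude); its signed flux is v = v_f - v_b.

## run expr with a local, restorable RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

## maximize obj'x  s.t.  S x = 0, 0 <= x <= ub.
## Bounded-variable simplex specialized to flux LPs: the zero flux vector
## is always feasible (the right-hand side is zero), so no phase-1 is
## needed; upper bounds are handled natively (no slack variables); Bland's
## smallest-index rule for both the entering and leaving choice prevents
## cycling on the heavily degenerate vertices these problems have.
## Variables pinned at zero are eliminated and linearly dependent rows of S
## (conserved-pool combinations) are dropped first; both transformations
## leave the feasible set unchanged.
.solve_lp <- function(obj, S, ub, max_iter = 100000L) {
  n <- length(obj)
  S <- as.matrix(S)
  x <- rep(0, n)
  keep <- ub > 0
  if (!any(keep))
    return(list(x = x, value = 0, status = "optimal"))
  A <- S[, keep, drop = FALSE]
  qr_rows <- qr(t(A))
  rows <- sort(qr_rows$pivot[seq_len(qr_rows$rank)])
  A <- A[rows, , drop = FALSE]
  sol <- .simplex_bounded(obj[keep], A, ub[keep], max_iter = max_iter)
  if (!identical(sol$status, "optimal"))
    return(list(x = NULL, value = NA_real_, status = sol$status))
  x[keep] <- sol$x
  list(x = x, value = sum(obj * x), status = "optimal")
}

.simplex_bounded <- function(cvec, A, u, tol = 1e-9, max_iter = 100000L) {
  n <- length(cvec)
  m <- nrow(A)
  x <- rep(0, n)
  if (m == 0L) {
    x[cvec > 0] <- u[cvec > 0]
    return(list(x = x, status = "optimal"))
  }
  qa <- qr(A)
  basis <- qa$pivot[seq_len(qa$rank)]       # rank == m after row reduction
  in_basis <- rep(FALSE, n); in_basis[basis] <- TRUE
  at_upper <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    Bmat <- A[, basis, drop = FALSE]
    y <- solve(t(Bmat), cvec[basis])
    nb <- which(!in_basis)
    d <- cvec[nb] - as.vector(crossprod(A[, nb, drop = FALSE], y))
    improving <- (!at_upper[nb] & d > tol) | (at_upper[nb] & d < -tol)
    if (!any(improving))
      return(list(x = x, status = "optimal"))
    j <- nb[improving][1L]                  # Bland: smallest index
    w <- solve(Bmat, A[, j])
    sgn <- if (at_upper[j]) -1 else 1
    g <- sgn * w                            # x[basis] moves by -g * t
    t_max <- u[j]; leave <- 0L              # 0 = bound-to-bound flip
    for (i in seq_len(m)) {
      if (g[i] > tol) {
        ti <- x[basis[i]] / g[i]
      } else if (g[i] < -tol) {
        ti <- (u[basis[i]] - x[basis[i]]) / (-g[i])
      } else next
      if (ti < t_max - tol ||
          (ti < t_max + tol && (leave == 0L || basis[i] < basis[leave]))) {
        t_max <- ti; leave <- i
      }
    }
    x[j] <- x[j] + sgn * t_max
    x[basis] <- pmax(0, pmin(u[basis], x[basis] - g * t_max))
    if (leave == 0L) {
      at_upper[j] <- !at_upper[j]
      x[j] <- if (at_upper[j]) u[j] else 0
    } else {
      out <- basis[leave]
      at_upper[out] <- g[leave] < 0
      x[out] <- if (at_upper[out]) u[out] else 0
      in_basis[out] <- FALSE
      in_basis[j] <- TRUE
      basis[leave] <- j
    }
  }
  list(x = x, status = "maxiter")
}

.category_direction <- function(cats) {
  d <- rep(0, length(cats))
  d[cats == "UP"] <- 1
  d[cats == "DOWN"] <- -1
  setNames(d, names(cats))
}

.ensure_split <- function(net) {
  if (!is.null(attr(net, "parent_map"))) return(net)
  split_reversible(net)
}

## core solve on a pre-split network; dir_mult is a named per-parent
## multiplier on the +/-1 category direction (objective jitter)
.solve_split <- function(snet, cats, epsilon, vmax, dir_mult = NULL) {
  pm <- attr(snet, "parent_map")
  dir <- .category_direction(cats)
  dpar <- dir[pm$parent]
  dpar[is.na(dpar)] <- 0
  if (!is.null(dir_mult)) {
    m <- dir_mult[pm$parent]
    m[is.na(m)] <- 1
    dpar <- dpar * m
  }
  obj <- dpar - epsilon
  ub <- pmin(vapply(snet$reactions, `[[`, numeric(1), "ub"), vmax)
  S <- build_stoichiometric_matrix(snet, sparse = FALSE)
  sol <- .solve_lp(obj, S, ub)
  if (!identical(sol$status, "optimal")) {
    return(list(status = sol$status, flux = NULL, activity = NULL,
                objective = sol$value))
  }
  x <- setNames(sol$x, names(snet$reactions))
  resid <- max(abs(S %*% x))
  if (resid > 1e-6)
    stop("LP solution violates mass balance (residual ", signif(resid, 3), ")")
  parents <- unique(pm$parent)
  flux <- setNames(numeric(length(parents)), parents)
  act <- setNames(numeric(length(parents)), parents)
  for (i in seq_len(nrow(pm))) {
    flux[pm$parent[i]] <- flux[pm$parent[i]] + pm$sign[i] * x[pm$child[i]]
    act[pm$parent[i]] <- act[pm$parent[i]] + x[pm$child[i]]
  }
  list(status = "optimal", flux = flux, activity = act,
       objective = sol$value, split_flux = x)
}

#' Solve the expression-constrained flux state
#'
#' Fits one steady-state flux vector per condition by maximizing
#' `sum(w[UP]) - sum(w[DOWN]) - epsilon * sum(w)` over the split network,
#' where `w` is reaction activity (flux magnitude). The parsimony weight
#' `epsilon` makes the reported optimum unique in magnitude among alternate
#' optima; it is small enough never to outweigh a category unit.
#'
#' @param net A metabolic network (split internally when needed).
#' @param cats [map_genes_to_reactions()] categories on parent reaction ids.
#' @param epsilon Parsimony weight (default 1e-4).
#' @param vmax Cap applied to all upper bounds (default 1000).
#' @param condition Condition label carried on the result.
#' @return A `flux_state`: list with `condition`, `flux` (signed parent
#'   fluxes), `activity` (parent flux magnitudes), `objective`, `status`,
#'   `subsystems`.
#' @export
solve_flux_state <- function(net, cats, epsilon = 1e-4, vmax = 1000,
                             condition = "condition") {
  snet <- .ensure_split(net)
  unknown <- setdiff(names(cats), unique(attr(snet, "parent_map")$parent))
  if (length(unknown))
    stop("categories reference unknown reactions: ",
         paste(head(unknown, 5), collapse = ", "))
  sol <- .solve_split(snet, cats, epsilon, vmax)
  if (!identical(sol$status, "optimal"))
    stop("flux LP not solved: status ", sol$status)
  subsys <- vapply(net$reactions, `[[`, character(1), "subsystem")
  structure(list(condition = condition, flux = sol$flux,
                 activity = sol$activity, objective = sol$objective,
                 status = sol$status, epsilon = epsilon, vmax = vmax,
                 subsystems = subsys[names(sol$flux)]),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state '", x$condition, "': ", length(x$flux),
      " reactions, objective ", signif(x$objective, 6),
      ", status ", x$status, "\n", sep = "")
  invisible(x)
}

#' Predicted bulk histone-modification fluxes
#'
#' Reads the two histone demand fluxes out of a flux state: acetylation is
#' the nuclear acetyl-CoA flux consumed by `DM_histone_ac`, methylation the
#' nuclear SAM-derived flux consumed by `DM_histone_me`.
#'
#' @param fs A [solve_flux_state()] result on an augmented model.
#' @return Named numeric vector `c(acetylation = ..., methylation = ...)`.
#' @export
predicted_histone_flux <- function(fs) {
  need <- c("DM_histone_ac", "DM_histone_me")
  if (!all(need %in% names(fs$flux)))
    stop("model not augmented: missing ",
         paste(setdiff(need, names(fs$flux)), collapse = ", "))
  c(acetylation = unname(fs$flux[["DM_histone_ac"]]),
    methylation = unname(fs$flux[["DM_histone_me"]]))
}

#' Export a flux state as a report table
#'
#' @param fs A `flux_state`.
#' @param cats Optional categories to include.
#' @param path Optional TSV path.
#' @return Data frame (reaction_id, subsystem, category, flux, activity).
#' @export
flux_report <- function(fs, cats = NULL, path = NULL) {
  df <- data.frame(reaction_id = names(fs$flux),
                   subsystem = unname(fs$subsystems),
                   category = if (is.null(cats)) "NEUTRAL"
                              else unname(cats[names(fs$flux)]),
                   flux = unname(fs$flux),
                   activity = unname(fs$activity),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
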