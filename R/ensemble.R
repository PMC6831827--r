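#' Generate a conformer pool over the flexible linker
#'
#' Draws `n` clash-free conformers with the linker-only mask (large hinge
#' bends, everything else rigid) and records their radii of gyration
#' (hydrated-bead convention, matching the reported model Rg values). The
#' default pool size of 1000 is the desk-scale stand-in for the
#' 10,000-conformer pools of the published protocol; pass `n = 10000` for
#' full published scale.
#'
#' @param start A `protein_model` template.
#' @param mask A [flexibility_mask()]; default [linker_only_mask()].
#' @param n Pool size (>= 10).
#' @param seed Integer seed.
#' @param clash_cutoff Clash rejection distance (Angstrom).
#' @return An `ensemble_pool`: list with `xyz` (list of coordinate
#'   matrices), `rg`, `template`, `mask`, `seed`.
#' @export
generate_pool <- function(start, mask = linker_only_mask(), n = 1000,
                          seed = 1, clash_cutoff = 2.5) {
  stopifnot(inherits(start, "protein_model"))
  if (n < 10) abort("pool size must be at least 10")
  mask_check_cover(mask, start)
  set.seed(seed)
  b0 <- beads_per_residue(start)
  radius <- b0$radius
  wts <- b0$weight
  xyz <- vector("list", n)
  rg <- numeric(n)
  for (i in seq_len(n)) {
    mi <- perturb_flexible(start, mask, clash_cutoff = clash_cutoff)
    X <- model_xyz(mi)
    xyz[[i]] <- X
    cen <- colSums(X * wts) / sum(wts)
    rg[i] <- sqrt(sum(wts * (rowSums(sweep(X, 2, cen)^2) + 0.6 * radius^2)) /
                    sum(wts))
  }
  structure(list(xyz = xyz, rg = rg, template = start, mask = mask,
                 n = n, seed = seed),
            class = "ensemble_pool")
}

#' @export
print.ensemble_pool <- function(x, ...) {
  cat(sprintf("<ensemble_pool> %d conformers, Rg %.1f-%.1f A (mean %.1f)\n",
              x$n, min(x$rg), max(x$rg), mean(x$rg)))
  invisible(x)
}

#' Settings for genetic sub-ensemble selection
#'
#' @param n_select Ensemble size (members drawn with replacement, equal
#'   weights).
#' @param population Number of candidate ensembles per cycle.
#' @param n_cycles Generations per run (desk-scale default 20; the
#'   published protocol uses 100).
#' @param n_runs Independent runs (default 5).
#' @param seed Base seed.
#' @return An `ensemble_settings` list.
#' @export
ensemble_settings <- function(n_select = 20, population = 40, n_cycles = 20,
                              n_runs = 5, seed = 1) {
  stopifnot(n_select >= 1, population >= 4, n_cycles >= 1, n_runs >= 1)
  structure(list(n_select = as.integer(n_select),
                 population = as.integer(population),
                 n_cycles = as.integer(n_cycles),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "ensemble_settings")
}

#' Select a weighted sub-ensemble that fits the data
#'
#' Genetic selection of an equal-weight multiset of pool conformers whose
#' average curve minimizes the reduced chi-square against the data
#' (multiplicative scale refit per evaluation). The final selection is
#' compared against the best single conformer and can only match or improve
#' on it. Reports the selected Rg distribution against the pool's.
#'
#' @param pool An [generate_pool()] result.
#' @param data A [saxs_curve()] with uncertainties.
#' @param settings An [ensemble_settings()].
#' @param form_factor,weights Forward-model options.
#' @return An `ensemble_selection` with members, weights, chi-square,
#'   selected and pool Rg summaries, and a per-run table.
#' @export
select_ensemble <- function(pool, data, settings = ensemble_settings(),
                            form_factor = "sphere", weights = NULL) {
  stopifnot(inherits(pool, "ensemble_pool"), inherits(data, "saxs_curve"))
  if (!has_sigma(data)) abort("ensemble selection needs data uncertainties")
  if (pool$n < 1) abort("empty pool")
  ev <- make_debye_evaluator(pool$template, data$q, weights = weights,
                             form_factor = form_factor)
  C <- t(vapply(pool$xyz, ev, numeric(nrow(data))))
  w2 <- 1 / data$sigma^2
  score_idx <- function(idx) chi2_of(colMeans(C[idx, , drop = FALSE]), data$I, w2)
  single <- vapply(seq_len(pool$n), function(i) chi2_of(C[i, ], data$I, w2),
                   numeric(1))
  best_single <- which.min(single)
  ns <- settings$n_select
  runs <- list()
  best <- NULL
  for (r in seq_len(settings$n_runs)) {
    set.seed(settings$seed + r - 1L)
    popn <- settings$population
    pop <- c(
      list(rep(best_single, ns)),
      replicate(popn - 1, sample.int(pool$n, ns, replace = TRUE),
                simplify = FALSE)
    )
    fit <- vapply(pop, score_idx, numeric(1))
    for (g in seq_len(settings$n_cycles)) {
      ord <- order(fit)
      keep <- max(2L, floor(popn / 4))
      parents <- pop[ord[seq_len(keep)]]
      children <- lapply(seq_len(popn - keep), function(i) {
        p1 <- parents[[sample.int(keep, 1)]]
        p2 <- parents[[sample.int(keep, 1)]]
        cut <- sample.int(ns - 1, 1)
        child <- c(p1[seq_len(cut)], p2[(cut + 1):ns])
        nmut <- sample(0:2, 1)
        if (nmut > 0) {
          pos <- sample.int(ns, nmut)
          child[pos] <- sample.int(pool$n, nmut, replace = TRUE)
        }
        child
      })
      cfit <- vapply(children, score_idx, numeric(1))
      pop <- c(parents, children)
      fit <- c(fit[ord[seq_len(keep)]], cfit)
    }
    ibest <- which.min(fit)
    sel <- sort(pop[[ibest]])
    runs[[r]] <- tibble(run = r, chi2 = fit[ibest],
                        mean_rg = mean(pool$rg[sel]))
    if (is.null(best) || fit[ibest] < best$chi2) {
      best <- list(idx = sel, chi2 = fit[ibest], run = r)
    }
  }
  # a weighted ensemble can only match or improve on the best single member
  if (single[best_single] < best$chi2) {
    best <- list(idx = rep(best_single, ns), chi2 = single[best_single],
                 run = NA_integer_)
  }
  tabw <- table(best$idx)
  structure(list(
    members = as.integer(names(tabw)),
    weights = as.numeric(tabw) / ns,
    chi2 = best$chi2,
    chi2_best_single = single[best_single],
    rg_selected = pool$rg[best$idx],
    mean_rg_selected = mean(pool$rg[best$idx]),
    mean_rg_pool = mean(pool$rg),
    rg_pool = pool$rg,
    runs = dplyr::bind_rows(runs),
    settings = settings
  ), class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_selection> chi2 %.3f; mean Rg selected %.1f A",
                     " vs pool %.1f A (%d distinct members)\n"),
              x$chi2, x$mean_rg_selected, x$mean_rg_pool, length(x$members)))
  invisible(x)
}
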