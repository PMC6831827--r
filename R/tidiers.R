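#' @exportS3Method generics::tidy
tidy.guinier_fit <- function(x, ...) {
  tibble(term = c("rg_a", "i0"), estimate = c(x$rg, x$i0))
}

#' @exportS3Method generics::glance
glance.guinier_fit <- function(x, ...) {
  tibble(rg_a = x$rg, i0 = x$i0, qmin = x$qmin, qmax = x$qmax,
         qrg_max = x$qrg_max, r_squared = x$r2, n = x$n, policy = x$policy)
}

#' @exportS3Method generics::tidy
tidy.mass_estimate <- function(x, ...) {
  tibble(term = c("mass_kda", "apparent_volume_a3", "corrected_volume_a3",
                  "porod_invariant"),
         estimate = c(x$mass_kda, x$apparent_volume, x$corrected_volume,
                      x$porod_invariant))
}

#' @exportS3Method generics::glance
glance.mass_estimate <- function(x, ...) {
  tibble(mass_kda = x$mass_kda, apparent_volume_a3 = x$apparent_volume,
         q_m = x$q_m)
}

#' @exportS3Method generics::tidy
tidy.hydro_result <- function(x, ...) {
  tibble(term = c("rg_a", "rh_nm", "s_sved", "f_ratio", "mass_kda"),
         estimate = c(x$rg_a, x$rh_nm, x$s_sved, x$f_ratio, x$mass_kda))
}

#' @exportS3Method generics::glance
glance.hydro_result <- function(x, ...) {
  tibble(rg_a = x$rg_a, rh_nm = x$rh_nm, s_sved = x$s_sved,
         f_ratio = x$f_ratio, mass_kda = x$mass_kda, n_beads = x$n_beads)
}

#' @exportS3Method generics::tidy
tidy.refinement_result <- function(x, ...) x$runs

#' @exportS3Method generics::glance
glance.refinement_result <- function(x, ...) {
  tibble(chi2_initial = x$chi2_initial, chi2_final = x$chi2_final,
         rg_best_a = x$rg_best, n_runs = nrow(x$runs),
         winner_run = x$winner_run)
}

#' @exportS3Method generics::tidy
tidy.ensemble_selection <- function(x, ...) {
  tibble(member = x$members, weight = x$weights, rg_a = x$rg_pool[x$members])
}

#' @exportS3Method generics::glance
glance.ensemble_selection <- function(x, ...) {
  tibble(chi2 = x$chi2, chi2_best_single = x$chi2_best_single,
         mean_rg_selected_a = x$mean_rg_selected,
         mean_rg_pool_a = x$mean_rg_pool,
         n_distinct_members = length(x$members))
}

#' @exportS3Method generics::tidy
tidy.chi2_fit <- function(x, ...) {
  tibble(term = c("chi2", "scale"), estimate = c(x$chi2, x$scale))
}
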