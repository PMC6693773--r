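#' Specification for a synthetic BG/WG cohort
#'
#' @param n_per_group participants per outcome group (>= 2).
#' @param group_effect additive WG-minus-BG mean stress offset (kPa), applied
#'   at the end-filling time point and propagated to the other time points in
#'   proportion to their baseline means.
#' @param noise_sd within-group stress standard deviation (kPa).
#' @param seed RNG seed.
#' @param rank_corr target magnitude of the (negative) rank correlation
#'   between delta-EF and end-filling stress.
#' @export
synthetic_cohort_spec <- function(n_per_group = 6, group_effect = 12.9,
                                  noise_sd = 9, seed = 1, rank_corr = 0.65) {
  stopifnot(n_per_group >= 2, noise_sd > 0, rank_corr >= 0, rank_corr < 1)
  structure(list(n_per_group = n_per_group, group_effect = group_effect,
                 noise_sd = noise_sd, seed = seed, rank_corr = rank_corr),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic TOF cohort with the analysis's group structure
#'
#' Stand-in for the undeposited per-patient data: BG stress values are drawn
#' around the bundled cohort's BG group means, WG values carry the additive
#' `group_effect` (scaled per time point by the ratio of baseline means to
#' the end-filling mean), strains are drawn with no group effect, and
#' delta-EF is generated with a negative monotone (Gaussian-copula)
#' association to end-filling stress of the target rank-correlation
#' magnitude. Deterministic given the seed.
#'
#' @param spec a `synthetic_cohort_spec`.
#' @return a `cohort`-classed data.frame (2 x n_per_group rows, groups BG/WG).
#' @export
generate_synthetic_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  base <- load_cohort()
  bg <- base[base$group == "BG", , drop = FALSE]
  tps <- c("bf", "ef", "be", "ee")
  mu_stress <- vapply(tps, function(tp) mean(bg[[paste0("stress_2g_", tp)]]),
                      numeric(1))
  mu_strain <- vapply(tps, function(tp) mean(bg[[paste0("strain_2g_", tp)]]),
                      numeric(1))
  strain_sd <- 0.03

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_per_group
  grp <- rep(c("BG", "WG"), each = n)
  ntot <- 2L * n
  # latent standard-normal deviates; z_ef also drives delta-EF via the copula
  z <- matrix(stats::rnorm(ntot * 4), ntot, 4, dimnames = list(NULL, tps))
  stress <- matrix(0, ntot, 4, dimnames = list(NULL, tps))
  for (j in seq_along(tps)) {
    offset <- spec$group_effect * mu_stress[j] / mu_stress["ef"]
    mu <- mu_stress[j] + ifelse(grp == "WG", offset, 0)
    stress[, j] <- pmax(mu + spec$noise_sd *
                          (mu_stress[j] / mu_stress["ef"]) * z[, j], 0.05)
  }
  strain <- matrix(0, ntot, 4, dimnames = list(NULL, tps))
  for (j in seq_along(tps)) {
    strain[, j] <- pmax(mu_strain[j] + strain_sd * stats::rnorm(ntot), 0)
  }

  tofd <- base[base$group %in% c("BG", "WG"), , drop = FALSE]
  mu_def <- vapply(c("BG", "WG"), function(g)
    mean(tofd$delta_ef_pct[tofd$group == g]), numeric(1))
  sd_def <- stats::sd(tofd$delta_ef_pct)
  rho <- spec$rank_corr
  z_ind <- stats::rnorm(ntot)
  delta_ef <- mu_def[grp] + sd_def * (-rho * z[, "ef"] +
                                        sqrt(1 - rho^2) * z_ind)

  edv <- pmax(stats::rnorm(ntot, mean = mean(tofd$edv_cm3),
                           sd = stats::sd(tofd$edv_cm3)), 80)
  ef_pct <- pmin(pmax(stats::rnorm(ntot, mean(tofd$ef_pct),
                                   stats::sd(tofd$ef_pct)), 15), 65)
  esv <- edv * (1 - ef_pct / 100)
  out <- data.frame(
    id = sprintf("S%02d", seq_len(ntot)),
    group = grp,
    sex = sample(c("M", "F"), ntot, replace = TRUE),
    age = round(stats::runif(ntot, 10, 60), 1),
    p_max_mmHg = round(stats::rnorm(ntot, mean(tofd$p_max_mmHg),
                                    stats::sd(tofd$p_max_mmHg)), 1),
    edv_cm3 = round(edv, 1),
    edvi_ml_m2 = NA_real_,
    esv_cm3 = round(esv, 1),
    esvi_ml_m2 = NA_real_,
    ef_pct = round(ef_pct, 1),
    delta_ef_pct = round(delta_ef, 2),
    stress_1g_bf = stress[, "bf"],
    stress_1g_be = stress[, "be"],
    stress_2g_bf = stress[, "bf"],
    stress_2g_ef = stress[, "ef"],
    stress_2g_be = stress[, "be"],
    stress_2g_ee = stress[, "ee"],
    strain_1g_bf = strain[, "bf"],
    strain_1g_be = strain[, "be"],
    strain_2g_bf = strain[, "bf"],
    strain_2g_ef = strain[, "ef"],
    strain_2g_be = strain[, "be"],
    strain_2g_ee = strain[, "ee"],
    stringsAsFactors = FALSE)
  structure(out, class = c("cohort", "data.frame"),
            provenance = sprintf("synthetic (seed %d)", spec$seed))
}
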