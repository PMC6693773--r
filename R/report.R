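#' Group comparison report reproducing the published summary statistics
#'
#' From a full cohort, computes (i) group mean +/- SD for every stress/strain
#' column per model generation and time point, (ii) the percent differences
#' quoted in the results narrative, (iii) Wilcoxon rank-sum p-values for
#' HG-vs-TG and BG-vs-WG comparisons, (iv) Wilcoxon signed-rank p-values for
#' the between-time-point comparisons, (v) the Spearman correlation table of
#' stress/strain vs delta-EF / EDV / EDVi on the TOF participants, and
#' optionally (vi) the repeated-CV prediction tables for the 13 predictors
#' plus the 1G-only counterpart.
#'
#' Percent differences are reported in two conventions: `pct_full` from the
#' full-precision group means and `pct_printed` from means first rounded to
#' the tabulated precision (2 decimals for stress, 3 for strain) -- the
#' narrative figures follow the rounded-mean arithmetic.
#'
#' @param cohort a `cohort` (bundled fixture by default).
#' @param cv also run the repeated-CV prediction tables (slower).
#' @param repeats,seed CV protocol controls.
#' @return a `group_report` list; see Details.
#' @export
group_report <- function(cohort = load_cohort(), cv = FALSE, repeats = 200,
                         seed = 1) {
  df <- as.data.frame(cohort)
  groups <- list(HG = df$group == "HG",
                 BG = df$group == "BG",
                 WG = df$group == "WG",
                 TG = df$group %in% c("BG", "WG"),
                 ALL = rep(TRUE, nrow(df)))
  cols <- expand.grid(generation = c("1g", "2g"),
                      timepoint = c("bf", "ef", "be", "ee"),
                      quantity = c("stress", "strain"),
                      stringsAsFactors = FALSE)
  cols <- cols[!(cols$generation == "1g" & cols$timepoint %in% c("ef", "ee")), ]

  means <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    do.call(rbind, lapply(seq_len(nrow(cols)), function(i) {
      cn <- paste0(cols$quantity[i], "_", cols$generation[i], "_",
                   cols$timepoint[i])
      v <- df[[cn]][sel]
      data.frame(group = g, generation = toupper(cols$generation[i]),
                 timepoint = toupper(cols$timepoint[i]),
                 quantity = cols$quantity[i],
                 mean = mean(v), sd = stats::sd(v), n = length(v))
    }))
  }))

  # group mean of a stress/strain column; 1G columns exist only for BF and BE,
  # the 1G EF/EE states alias BE/BF respectively
  gm <- function(g, qty, tp, gen = "2g") {
    if (gen == "1g" && tp %in% c("ef", "ee")) {
      tp <- if (tp == "ef") "be" else "bf"
    }
    mean(df[[paste0(qty, "_", gen, "_", tp)]][groups[[g]]])
  }
  dp_of <- function(qty) if (qty == "stress") 2L else 3L
  # tabulated precision uses round-half-up, the convention of the printed tables
  rhu <- function(x, dp) floor(x * 10^dp + 0.5) / 10^dp
  pct_row <- function(label, qty, g_hi, tp_hi, g_lo, tp_lo, printed_dp,
                      gen_hi = "2g", gen_lo = "2g") {
    a <- gm(g_hi, qty, tp_hi, gen_hi); b <- gm(g_lo, qty, tp_lo, gen_lo)
    dp <- dp_of(qty)
    data.frame(label = label, quantity = qty,
               higher = paste(g_hi, toupper(gen_hi), toupper(tp_hi)),
               lower = paste(g_lo, toupper(gen_lo), toupper(tp_lo)),
               mean_higher = a, mean_lower = b,
               pct_full = 100 * (a / b - 1),
               pct_printed = 100 * (rhu(a, dp) / rhu(b, dp) - 1),
               printed_dp = printed_dp)
  }
  pct <- rbind(
    pct_row("2G vs 1G stress at EE, all 18", "stress", "ALL", "ee", "ALL", "ee", 1L, gen_lo = "1g"),
    pct_row("2G vs 1G strain at EE, all 18", "strain", "ALL", "ee", "ALL", "ee", 0L, gen_lo = "1g"),
    pct_row("2G vs 1G stress at BE, all 18", "stress", "ALL", "be", "ALL", "be", 1L, gen_lo = "1g"),
    pct_row("2G vs 1G strain at BE, all 18", "strain", "ALL", "be", "ALL", "be", 1L, gen_lo = "1g"),
    pct_row("BE vs EF stress (2G), all 18", "stress", "ALL", "be", "ALL", "ef", 0L),
    pct_row("BE vs EF strain (2G), all 18", "strain", "ALL", "be", "ALL", "ef", 2L),
    pct_row("TG vs HG stress at BF", "stress", "TG", "bf", "HG", "bf", 2L),
    pct_row("TG vs HG stress at EE", "stress", "TG", "ee", "HG", "ee", 1L),
    pct_row("HG vs TG strain at EF", "strain", "HG", "ef", "TG", "ef", 1L),
    pct_row("HG vs TG strain at BE", "strain", "HG", "be", "TG", "be", 0L),
    pct_row("WG vs BG stress at BF", "stress", "WG", "bf", "BG", "bf", 1L),
    pct_row("WG vs BG stress at EF", "stress", "WG", "ef", "BG", "ef", 1L),
    pct_row("WG vs BG stress at BE", "stress", "WG", "be", "BG", "be", 1L),
    pct_row("WG vs BG stress at EE", "stress", "WG", "ee", "BG", "ee", 1L))

  rank_sum <- do.call(rbind, lapply(c("stress", "strain"), function(qty) {
    do.call(rbind, lapply(c("bf", "ef", "be", "ee"), function(tp) {
      cn <- paste0(qty, "_2g_", tp)
      p_hg_tg <- wilcoxon_rank_sum(df[[cn]][groups$HG],
                                   df[[cn]][groups$TG])$p_value
      p_bg_wg <- wilcoxon_rank_sum(df[[cn]][groups$BG],
                                   df[[cn]][groups$WG])$p_value
      data.frame(quantity = qty, timepoint = toupper(tp),
                 p_HG_vs_TG = p_hg_tg, p_BG_vs_WG = p_bg_wg)
    }))
  }))

  signed_rank <- do.call(rbind, lapply(c("stress", "strain"), function(qty) {
    do.call(rbind, lapply(list(c("be", "ef"), c("ee", "bf")), function(pair) {
      d <- df[[paste0(qty, "_2g_", pair[1])]] -
        df[[paste0(qty, "_2g_", pair[2])]]
      data.frame(quantity = qty,
                 comparison = paste(toupper(pair[1]), "vs", toupper(pair[2])),
                 p_value = wilcoxon_signed_rank(d)$p_value)
    }))
  }))

  tof <- df[groups$TG, , drop = FALSE]
  spearman <- do.call(rbind, lapply(
    c("stress_2g_ef", "stress_2g_be", "strain_2g_ef", "strain_2g_be"),
    function(cn) {
      do.call(rbind, lapply(
        c(delta_EF = "delta_ef_pct", EDV = "edv_cm3", EDVi = "edvi_ml_m2"),
        function(target) {
          s <- spearman_rank(tof[[cn]], tof[[target]])
          data.frame(variable = cn, against = target, rho = s$rho,
                     p_value = s$p_value)
        }))
    }))

  out <- list(means = means, pct_differences = pct, rank_sum = rank_sum,
              signed_rank = signed_rank, spearman = spearman)

  if (cv) {
    predictors_2g <- c("stress_2g_ef", "stress_2g_bf", "stress_2g_ee",
                       "stress_2g_be", "age", "edvi_ml_m2", "esvi_ml_m2",
                       "strain_2g_be", "ef_pct", "sex", "strain_2g_bf",
                       "strain_2g_ef", "strain_2g_ee")
    cv_table <- function(preds) {
      do.call(rbind, lapply(preds, function(p) {
        r <- cross_validate(p, df, repeats = repeats, seed = seed)
        data.frame(predictor = p, sensitivity = r$sensitivity,
                   specificity = r$specificity, auc = r$auc,
                   accuracy = r$accuracy)
      }))
    }
    out$prediction_2g <- cv_table(predictors_2g)
    out$prediction_1g <- cv_table(c("stress_1g_be", "strain_1g_be"))
  }
  structure(out, class = "group_report")
}

#' @export
print.group_report <- function(x, digits = 4, ...) {
  fmt_ms <- function(m, s, dp) sprintf(paste0("%.", dp, "f+/-%.", dp, "f"), m, s)
  cat("Group means +/- SD (stress kPa / strain, per generation and time point)\n")
  mm <- x$means
  mm$value <- ifelse(mm$quantity == "stress",
                     fmt_ms(mm$mean, mm$sd, 2), fmt_ms(mm$mean, mm$sd, 3))
  print(mm[, c("group", "generation", "timepoint", "quantity", "value")],
        row.names = FALSE)
  cat("\nPercent differences (printed-mean convention):\n")
  pd <- x$pct_differences
  cat(paste(sprintf("  %-32s %s%%", pd$label,
                    formatC(round(pd$pct_printed, pd$printed_dp),
                            format = "fg")), collapse = "\n"), "\n")
  cat("\nRank-sum p-values (2G):\n")
  print(x$rank_sum, row.names = FALSE, digits = digits)
  cat("\nSigned-rank p-values (2G, between time points):\n")
  print(x$signed_rank, row.names = FALSE, digits = digits)
  cat("\nSpearman correlations (12 TOF participants):\n")
  print(x$spearman, row.names = FALSE, digits = digits)
  if (!is.null(x$prediction_2g)) {
    cat("\nRepeated-CV prediction, 2G predictors:\n")
    print(x$prediction_2g, row.names = FALSE, digits = digits)
    cat("\nRepeated-CV prediction, 1G predictors:\n")
    print(x$prediction_1g, row.names = FALSE, digits = digits)
  }
  invisible(x)
}
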