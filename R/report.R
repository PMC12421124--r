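# End-to-end pipeline driver and table rendering.

#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one cohort source
#' is used, in priority order: `cohort` (an in-memory cohort tibble),
#' `cohort_path` (delimited file), `generator` (a [generator_params()]),
#' else `fixture_spec` (a [marginal_spec()], defaulting to the packaged
#' [baseline_marginals()]).
#'
#' @param cohort Optional cohort tibble.
#' @param cohort_path Optional cohort file path.
#' @param generator Optional [generator_params()].
#' @param fixture_spec A [marginal_spec()] (default
#'   [baseline_marginals()]).
#' @param protocol A [protocol_config()] (default [bts_protocol()]).
#' @param analyses Non-empty subset of `"rule_out"`, `"rule_in"`,
#'   `"roc"`, `"net_benefit"`.
#' @param rule_out_thresholds,rule_in_thresholds Tibbles with columns
#'   `scale`, `threshold` listing the cut-offs to tabulate.
#' @param net_benefit_weight_rule_out,net_benefit_weight_rule_in
#'   Weighting factors `W` for the two net-benefit comparisons.
#' @param prevalence_source Passed to [bootstrap_net_benefit()].
#' @param n_bootstrap Bootstrap resamples.
#' @param ci_level Confidence level throughout.
#' @param seed Integer seed driving every random stage.
#' @param out_dir Optional directory; when given, [run_pipeline()] writes
#'   the machine-readable summary and rendered tables there.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = NULL, cohort_path = NULL,
                            generator = NULL,
                            fixture_spec = baseline_marginals(),
                            protocol = bts_protocol(),
                            analyses = c("rule_out", "rule_in", "roc",
                                         "net_benefit"),
                            rule_out_thresholds = tibble(
                              scale = c("diameter", "diameter", "volume",
                                        "volume"),
                              threshold = c(5, 6, 80, 100)),
                            rule_in_thresholds = tibble(
                              scale = c("diameter", "volume"),
                              threshold = c(8, 300)),
                            net_benefit_weight_rule_out = 50,
                            net_benefit_weight_rule_in = 5,
                            prevalence_source = "nodule_participants",
                            n_bootstrap = 1000,
                            ci_level = 0.95,
                            seed = 1L,
                            out_dir = NULL) {
  analyses <- unique(analyses)
  if (length(analyses) == 0) {
    stop_domain("config invalid: 'analyses' must be non-empty")
  }
  bad <- setdiff(analyses, c("rule_out", "rule_in", "roc", "net_benefit"))
  if (length(bad)) stop_domain("unknown analysis: %s", bad[1])
  if (!is.null(cohort_path) && !file.exists(cohort_path)) {
    stop_domain("config invalid: cohort_path '%s' does not exist", cohort_path)
  }
  structure(list(
    cohort = cohort, cohort_path = cohort_path, generator = generator,
    fixture_spec = fixture_spec, protocol = protocol, analyses = analyses,
    rule_out_thresholds = as_tibble(rule_out_thresholds),
    rule_in_thresholds = as_tibble(rule_in_thresholds),
    net_benefit_weight_rule_out = net_benefit_weight_rule_out,
    net_benefit_weight_rule_in = net_benefit_weight_rule_in,
    prevalence_source = prevalence_source,
    n_bootstrap = n_bootstrap, ci_level = ci_level,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

resolve_cohort <- function(cfg) {
  if (!is.null(cfg$cohort)) return(cfg$cohort)
  if (!is.null(cfg$cohort_path)) return(read_cohort(cfg$cohort_path))
  if (!is.null(cfg$generator)) {
    params <- cfg$generator
    params$seed <- substream_seed(cfg$seed, "generator")
    return(generate_cohort(params))
  }
  reconstruct_fixture(cfg$fixture_spec)
}

rule_out_table <- function(indexed, thresholds, ci_level) {
  nod <- indexed |> filter(.data$has_nodule)
  none <- indexed |> filter(!.data$has_nodule)
  base_rows <- bind_rows(
    crude_risk(sum(none$cancer_outcome), max(nrow(none), 1), ci_level) |>
      mutate(label = "No nodules", .before = 1),
    crude_risk(sum(nod$cancer_outcome), nrow(nod), ci_level) |>
      mutate(label = "Any solid nodule", .before = 1)
  ) |>
    mutate(scale = NA_character_, threshold = NA_real_,
           pct_of_nodule_participants = c(NA, 100))
  thr_rows <- purrr::pmap(thresholds, function(scale, threshold) {
    below <- rule_positive(nod, threshold_rule(threshold, scale,
                                               direction = "lt"))
    risk <- crude_risk(sum(nod$cancer_outcome[below]), sum(below), ci_level)
    chi <- if (nrow(none) > 0) {
      pearson_chi2(matrix(c(sum(nod$cancer_outcome[below]),
                            sum(below) - sum(nod$cancer_outcome[below]),
                            sum(none$cancer_outcome),
                            sum(!none$cancer_outcome)), 2))$p_value
    } else NA_real_
    ds <- diagnostic_summary(
      stratify(nod, threshold_rule(threshold, scale)), ci_level)
    g <- glance(ds)
    risk |>
      mutate(label = sprintf("<%g %s", threshold,
                             ifelse(scale == "volume", "mm^3", "mm")),
             .before = 1) |>
      mutate(scale = scale, threshold = threshold,
             p_vs_no_nodules = chi,
             pct_of_nodule_participants = 100 * sum(below) / nrow(nod),
             sensitivity = g$sensitivity, specificity = g$specificity,
             npv = g$npv,
             sens_low = ds$metrics$conf.low[1], sens_high = ds$metrics$conf.high[1],
             spec_low = ds$metrics$conf.low[2], spec_high = ds$metrics$conf.high[2],
             npv_low = ds$metrics$conf.low[4], npv_high = ds$metrics$conf.high[4])
  })
  bind_rows(base_rows, bind_rows(thr_rows))
}

rule_in_table <- function(indexed, thresholds, brock_threshold, ci_level) {
  nod <- indexed |> filter(.data$has_nodule)
  has_brock <- "brock_probability" %in% names(nod) &&
    any(!is.na(nod$brock_probability))
  gates <- if (has_brock && !is.na(brock_threshold)) {
    c(NA_real_, brock_threshold)
  } else {
    NA_real_
  }
  rows <- purrr::pmap(thresholds, function(scale, threshold) {
    purrr::map(gates, function(g) {
      rule <- threshold_rule(threshold, scale,
                             brock_threshold = if (is.na(g)) NULL else g)
      cnt <- stratify(nod, rule)
      ds <- diagnostic_summary(cnt, ci_level)
      m <- ds$metrics
      tibble(label = sprintf(">=%g %s%s", threshold,
                             ifelse(scale == "volume", "mm^3", "mm"),
                             ifelse(is.na(g), "",
                                    sprintf(" + Brock >=%g", g))),
             scale = scale, threshold = threshold, brock_gate = g,
             positives = cnt$tp + cnt$fp, tp = cnt$tp, fp = cnt$fp,
             sensitivity = m$estimate[1], sens_low = m$conf.low[1],
             sens_high = m$conf.high[1],
             specificity = m$estimate[2], spec_low = m$conf.low[2],
             spec_high = m$conf.high[2],
             ppv = m$estimate[3], ppv_low = m$conf.low[3],
             ppv_high = m$conf.high[3])
    }) |> bind_rows()
  })
  bind_rows(rows)
}

#' Run the full stratification pipeline
#'
#' Resolves the cohort, reduces it to index nodules and runs the
#' configured analyses: a rule-out table (crude risk below each
#' threshold, chi-squared comparison against the no-nodule group,
#' proportion of nodule participants encompassed, and
#' sensitivity/specificity/NPV of each cut-off), a rule-in table (with
#' and without the Brock gate where probabilities are available), ROC
#' analyses (diameter on all nodule participants, volume on the
#' segmentable subset, DeLong comparison on the common subset, and the
#' Brock score among rule-in-sized nodules with its Youden-optimal
#' threshold), and bootstrap net-benefit comparisons (rule-out threshold
#' change, and adding the Brock gate to each rule-in threshold).
#' Deterministic for a fixed config and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A `nodule_report`: list with the requested result tibbles, the
#'   machine-readable `summary` (full precision), and run metadata (seed,
#'   config hash, package version). When `cfg$out_dir` is set the summary
#'   (YAML) and rendered tables (text) are also written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- resolve_cohort(cfg)
  indexed <- reduce_to_index(cohort)
  res <- list()

  if ("rule_out" %in% cfg$analyses) {
    res$rule_out <- rule_out_table(indexed, cfg$rule_out_thresholds,
                                   cfg$ci_level)
  }
  if ("rule_in" %in% cfg$analyses) {
    res$rule_in <- rule_in_table(indexed, cfg$rule_in_thresholds,
                                 cfg$protocol$brock_threshold, cfg$ci_level)
  }
  if ("roc" %in% cfg$analyses) {
    nod <- indexed |> filter(.data$has_nodule)
    roc_d <- delong_auc_variance(nod, diameter_mm, cancer_outcome)
    seg <- nod |> filter(isTRUE_v(.data$segmentation_reliable))
    roc_v <- delong_auc_variance(seg, volume_mm3, cancer_outcome)
    cmp <- delong_compare(seg, diameter_mm, volume_mm3, cancer_outcome)
    res$roc <- bind_rows(
      roc_d |> mutate(score = "diameter_mm", .before = 1),
      roc_v |> mutate(score = "volume_mm3", .before = 1)
    )
    res$roc_compare <- tidy(cmp)
    if (any(!is.na(nod$brock_probability))) {
      big <- nod |>
        filter(.data$diameter_mm >= cfg$protocol$rule_in_diameter_mm,
               !is.na(.data$brock_probability))
      if (any(big$cancer_outcome) && !all(big$cancer_outcome)) {
        res$brock_roc <- bind_cols(
          delong_auc_variance(big, brock_probability, cancer_outcome),
          youden_optimal(big, brock_probability, cancer_outcome))
      }
    }
  }
  if ("net_benefit" %in% cfg$analyses) {
    nbs <- list()
    ro <- cfg$rule_out_thresholds |> filter(.data$scale == "volume")
    if (nrow(ro) >= 2) {
      t1 <- min(ro$threshold); t2 <- max(ro$threshold)
      nbs$rule_out_volume <- bootstrap_net_benefit(
        indexed,
        rule_ref = threshold_rule(t1, "volume"),
        rule_new = threshold_rule(t2, "volume"),
        weight = cfg$net_benefit_weight_rule_out,
        prevalence_source = cfg$prevalence_source,
        B = cfg$n_bootstrap,
        seed = substream_seed(cfg$seed, "nb_rule_out")) |>
        tidy() |>
        mutate(comparison = sprintf("rule-out <%g vs <%g mm^3", t1, t2),
               .before = 1)
    }
    if (any(!is.na(indexed$brock_probability)) &&
        !is.na(cfg$protocol$brock_threshold)) {
      for (i in seq_len(nrow(cfg$rule_in_thresholds))) {
        sc <- cfg$rule_in_thresholds$scale[i]
        th <- cfg$rule_in_thresholds$threshold[i]
        nbs[[paste0("rule_in_", sc)]] <- bootstrap_net_benefit(
          indexed,
          rule_ref = threshold_rule(th, sc),
          rule_new = threshold_rule(th, sc,
                                    brock_threshold = cfg$protocol$brock_threshold),
          weight = cfg$net_benefit_weight_rule_in,
          prevalence_source = cfg$prevalence_source,
          B = cfg$n_bootstrap,
          seed = substream_seed(cfg$seed, paste0("nb_rule_in_", sc))) |>
          tidy() |>
          mutate(comparison = sprintf(">=%g %s + Brock vs size alone", th,
                                      ifelse(sc == "volume", "mm^3", "mm")),
                 .before = 1)
      }
    }
    if (length(nbs)) res$net_benefit <- bind_rows(nbs)
  }

  meta <- list(seed = cfg$seed,
               config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
               package_version = as.character(utils::packageVersion("nodulestrat")),
               n_participants = nrow(indexed),
               n_nodule_participants = sum(indexed$has_nodule),
               n_cancers = sum(indexed$cancer_outcome))
  report <- structure(c(res, list(meta = meta)), class = "nodule_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_summary(report, file.path(cfg$out_dir, "summary.yaml"))
    writeLines(render_table(report, style = "text"),
               file.path(cfg$out_dir, "report.txt"))
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        readr::write_csv(res[[nm]], file.path(cfg$out_dir,
                                              paste0(nm, ".csv")))
      }
    }
  }
  report
}

#' Write the machine-readable pipeline summary
#'
#' Full-precision YAML; rendered tables are a pure formatting function of
#' this file.
#'
#' @param report A `nodule_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_summary <- function(report, path) {
  ser <- lapply(unclass(report), function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) {
      r <- as.list(x[i, ])
      lapply(r, function(v) if (is.numeric(v)) unname(v) else v)
    }) else x
  })
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Render report tables in the published style
#'
#' Percentages at one decimal place (half-up), confidence intervals in
#' parentheses, p-values at four decimals with a `<0.0001` floor. Empty
#' sections are omitted with a notice.
#'
#' @param report A `nodule_report` from [run_pipeline()].
#' @param style `"text"` (aligned, default) or `"delimited"`
#'   (tab-separated).
#' @return Character vector of lines.
#' @export
render_table <- function(report, style = c("text", "delimited")) {
  style <- match.arg(style)
  sep <- if (style == "text") "  " else "\t"
  lines <- character()
  say <- function(...) lines <<- c(lines, paste(..., sep = sep))

  if (!is.null(report$rule_out) && nrow(report$rule_out) > 0) {
    t1 <- report$rule_out
    say("== Rule-out thresholds ==")
    say("Threshold", "Cancers/participants", "Risk (CI)", "P value",
        "% included", "Sensitivity (CI)", "Specificity (CI)", "NPV (CI)")
    for (i in seq_len(nrow(t1))) {
      say(t1$label[i],
          sprintf("%d/%d", t1$events[i], t1$n[i]),
          sprintf("%s (%s to %s)", fmt_pct(t1$risk_pct[i], 2),
                  fmt_pct(t1$conf.low[i], 2), fmt_pct(t1$conf.high[i], 2)),
          if (!is.null(t1$p_vs_no_nodules) && !is.na(t1$p_vs_no_nodules[i]))
            fmt_p(t1$p_vs_no_nodules[i]) else "-",
          if (!is.na(t1$pct_of_nodule_participants[i]))
            fmt_pct(t1$pct_of_nodule_participants[i]) else "-",
          fmt_triplet(t1, i, "sensitivity", "sens_low", "sens_high"),
          fmt_triplet(t1, i, "specificity", "spec_low", "spec_high"),
          fmt_triplet(t1, i, "npv", "npv_low", "npv_high"))
    }
  } else if (!is.null(report$rule_out)) {
    message("rule-out section empty; omitted from rendering")
  }

  if (!is.null(report$rule_in) && nrow(report$rule_in) > 0) {
    t2 <- report$rule_in
    say("")
    say("== Rule-in thresholds ==")
    say("Threshold", "Cancers/positives", "Sensitivity (CI)",
        "Specificity (CI)", "PPV (CI)")
    for (i in seq_len(nrow(t2))) {
      say(t2$label[i], sprintf("%d/%d", t2$tp[i], t2$positives[i]),
          fmt_triplet(t2, i, "sensitivity", "sens_low", "sens_high"),
          fmt_triplet(t2, i, "specificity", "spec_low", "spec_high"),
          fmt_triplet(t2, i, "ppv", "ppv_low", "ppv_high"))
    }
  }

  if (!is.null(report$net_benefit) && nrow(report$net_benefit) > 0) {
    nb <- report$net_benefit
    say("")
    say("== Net benefit ==")
    for (i in seq_len(nrow(nb))) {
      say(nb$comparison[i],
          sprintf("%+0.2f (CI %+0.2f to %+0.2f) [W=%g, p: %s]",
                  round_half_up(nb$estimate[i], 2),
                  round_half_up(nb$conf.low[i], 2),
                  round_half_up(nb$conf.high[i], 2),
                  nb$weight[i], nb$prevalence_source[i]))
    }
  }

  if (!is.null(report$roc) && nrow(report$roc) > 0) {
    say("")
    say("== AUROC ==")
    for (i in seq_len(nrow(report$roc))) {
      say(report$roc$score[i],
          sprintf("AUC %.3f (SE %.4f)", report$roc$auc[i],
                  sqrt(report$roc$variance[i])))
    }
    if (!is.null(report$roc_compare)) {
      say(sprintf("DeLong diameter vs volume: diff %+0.4f, p %s",
                  report$roc_compare$difference[1],
                  fmt_p(report$roc_compare$p_value[1])))
    }
    if (!is.null(report$brock_roc)) {
      say(sprintf("Brock (rule-in sized): AUC %.3f, Youden threshold %.4f",
                  report$brock_roc$auc[1], report$brock_roc$threshold[1]))
    }
  }
  lines
}

fmt_triplet <- function(tab, i, est, lo, hi) {
  if (!est %in% names(tab) || is.na(tab[[est]][i])) return("-")
  sprintf("%s (%s to %s)", fmt_pct(tab[[est]][i]),
          fmt_pct(tab[[lo]][i]), fmt_pct(tab[[hi]][i]))
}

#' @export
print.nodule_report <- function(x, ...) {
  cat(render_table(x), sep = "\n")
  invisible(x)
}

utils::globalVariables(c("diameter_mm", "volume_mm3", "brock_probability"))
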