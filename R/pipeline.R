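# End-to-end orchestration: the packaged 30-lesion cohort fixture, the
# lesion-level prevalence table engine, and the full synthetic analysis
# run (cohort tables, fibrillary clustering, report CSVs).

#' Load the packaged 30-lesion cohort fixture
#'
#' Thirty basal-cell-carcinoma lesions from 22 patients with per-lesion
#' covariates (body site, subtype components superficial/nodular/
#' infiltrative, ulceration, age, gender). The covariates are transcribed
#' from the study cohort this package's analyses are designed around; the
#' per-lesion TLS outcome columns (`any_tls`, `primary_tls`) are
#' SYNTHETIC — reconstructed by constraint search so that every stratum
#' margin of the published lesion-level prevalence analysis is matched
#' exactly (per-lesion outcomes were not published). One lesion has
#' unknown age and gender.
#'
#' @return data.frame of 30 lesion rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_lesions.csv", package = "tmefib")
  if (path == "") path <- file.path("inst", "extdata", "table1_lesions.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

table2_factor_row <- function(lesions, sel_present, sel_absent, outcome) {
  a <- sum(lesions[[outcome]] == 1 & sel_present)
  b <- sum(lesions[[outcome]] == 0 & sel_present)
  c <- sum(lesions[[outcome]] == 1 & sel_absent)
  d <- sum(lesions[[outcome]] == 0 & sel_absent)
  orw <- odds_ratio_wald(a, b, c, d)
  data.frame(n_true = a, n_false = b, or = orw$or, or_lower = orw$lower,
             or_upper = orw$upper, corrected = orw$corrected,
             fisher_p = fisher_exact_2x2(a, b, c, d))
}

#' Lesion-level TLS prevalence table (Table 2 engine)
#'
#' For each factor (body site, gender, infiltrative, nodular,
#' superficial, ulceration): counts, row proportions, odds ratio with
#' Wald 95% CI against the referent level, and Fisher's exact p — for
#' both outcomes (any TLS; primary TLS). Age is compared by Student's
#' t test over known ages. Referent rows carry OR 1 and `referent =
#' TRUE`; lesions with unknown level are excluded from that factor's
#' test but retained in totals.
#'
#' @param lesions cohort data.frame as from [load_table1_fixture()] (or
#'   [generate_cohort()]'s `lesions` with `any_tls`; `primary_tls`
#'   optional).
#' @return list with `rows` (data.frame, one row per factor level and
#'   outcome), `age` (data.frame with group means and t-test p per
#'   outcome), `totals`.
#' @export
build_table2 <- function(lesions) {
  outcomes <- intersect(c("any_tls", "primary_tls"), names(lesions))
  stopifnot(length(outcomes) >= 1)
  for (oc in outcomes) {
    if (all(lesions[[oc]] == 1) || all(lesions[[oc]] == 0))
      warning("outcome ", oc, " has a zero column; odds ratios undefined")
  }
  factors <- list(
    list(name = "body_site", levels = c("trunk", "extremity"),
         referent = "head_neck",
         sel = function(l, lev) l$body_site == lev),
    list(name = "gender", levels = "F", referent = "M",
         sel = function(l, lev) l$gender == lev),
    list(name = "infiltrative", levels = "present", referent = "absent",
         sel = function(l, lev) l$infiltrative == (lev == "present")),
    list(name = "nodular", levels = "present", referent = "absent",
         sel = function(l, lev) l$nodular == (lev == "present")),
    list(name = "superficial", levels = "present", referent = "absent",
         sel = function(l, lev) l$superficial == (lev == "present")),
    list(name = "ulceration", levels = "TRUE", referent = "FALSE",
         sel = function(l, lev) l$ulceration == (lev == "TRUE")))
  rows <- list()
  for (oc in outcomes) {
    for (f in factors) {
      known <- if (f$name == "gender") lesions$gender %in% c("F", "M")
        else rep(TRUE, nrow(lesions))
      lk <- lesions[known, , drop = FALSE]
      ref_sel <- f$sel(lk, f$referent)
      for (lev in f$levels) {
        pres <- f$sel(lk, lev)
        rr <- table2_factor_row(lk, pres, ref_sel, oc)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(outcome = oc, factor = f$name, level = lev,
                     referent = FALSE, n = sum(pres)), rr)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, factor = f$name, level = f$referent, referent = TRUE,
        n = sum(ref_sel), n_true = sum(lk[[oc]] == 1 & ref_sel),
        n_false = sum(lk[[oc]] == 0 & ref_sel), or = 1, or_lower = NA,
        or_upper = NA, corrected = FALSE, fisher_p = NA)
    }
  }
  age_rows <- list()
  for (oc in outcomes) {
    known <- !is.na(lesions$age)
    a1 <- lesions$age[known & lesions[[oc]] == 1]
    a0 <- lesions$age[known & lesions[[oc]] == 0]
    tt <- if (length(a1) >= 2 && length(a0) >= 2)
      welch_or_student_t(a1, a0, "student")
    else list(t = NA_real_, p = NA_real_)
    age_rows[[length(age_rows) + 1L]] <- data.frame(
      outcome = oc,
      mean_true = if (length(a1)) mean(a1) else NA_real_,
      mean_false = if (length(a0)) mean(a0) else NA_real_,
      t = tt$t, p = tt$p)
  }
  list(rows = do.call(rbind, rows), age = do.call(rbind, age_rows),
       totals = data.frame(
         n = nrow(lesions),
         n_tls = sum(lesions$any_tls == 1),
         mean_age = mean(lesions$age, na.rm = TRUE)))
}

#' Tumor-level TIL analysis (Table 3 analog)
#'
#' Mean TIL count (with IQR) by TLS stage / proximity group, and the
#' mixed-model contrast of Box-Cox-transformed TIL counts between
#' primary- and aggregate-proximal tumors with a random intercept per
#' lesion (Wald p).
#'
#' @param tumors tumor records (as from [generate_cohort()]):
#'   columns `til_count`, `stage`, `proximity`, `lesion_id`.
#' @return list with `groups` (data.frame) and `stage_contrast`
#'   (mixed_fit or NULL when undeterminable).
#' @export
build_table3 <- function(tumors) {
  grp <- ifelse(tumors$proximity == "control", "control", tumors$stage)
  groups <- do.call(rbind, lapply(split(tumors$til_count, grp), function(v)
    data.frame(n = length(v), mean_til = mean(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))))
  groups$group <- rownames(groups); rownames(groups) <- NULL
  prox <- tumors[tumors$proximity == "proximal" &
                   tumors$stage %in% c("primary", "aggregate"), ]
  contrast <- NULL
  if (length(unique(prox$stage)) == 2 && length(unique(prox$lesion_id)) >= 2) {
    bc <- boxcox_transform(prox$til_count)
    contrast <- fit_random_intercept_lmm(
      bc$values, data.frame(primary = as.integer(prox$stage == "primary")),
      prox$lesion_id)
  }
  list(groups = groups, stage_contrast = contrast)
}

#' TLS-level composition analysis (Table 4 / maturation analog)
#'
#' Stage-wise medians of TLS properties and the mixed-model contrast of
#' log-transformed counts between primary and aggregate TLS (random
#' intercept per lesion).
#'
#' @param tls TLS records: `stage`, `t_count`, `b_count`, `area_mm2`,
#'   `lesion_id`.
#' @return list with `medians` and `contrasts` (one mixed_fit per
#'   property, when fittable).
#' @export
build_table4 <- function(tls) {
  tls$total_count <- tls$t_count + tls$b_count
  tls$b_fraction <- ifelse(tls$total_count > 0,
                           tls$b_count / tls$total_count, NA)
  props <- c("b_count", "total_count", "area_mm2", "b_fraction")
  medians <- do.call(rbind, lapply(split(tls, tls$stage), function(d)
    cbind(data.frame(stage = d$stage[1], n = nrow(d)),
          as.data.frame(lapply(d[props], stats::median, na.rm = TRUE)))))
  rownames(medians) <- NULL
  contrasts <- list()
  if (length(unique(tls$stage)) == 2 && length(unique(tls$lesion_id)) >= 2) {
    for (pr in props) {
      y <- log(tls[[pr]] + 0.5)
      ok <- is.finite(y)
      contrasts[[pr]] <- tryCatch(fit_random_intercept_lmm(
        y[ok],
        data.frame(primary = as.integer(tls$stage == "primary"))[ok, ,
                                                                 drop = FALSE],
        tls$lesion_id[ok]), error = function(e) NULL)
    }
  }
  list(medians = medians, contrasts = contrasts)
}

#' Fibrillary clustering analysis (Fig 3 engine)
#'
#' Spearman screen of the 13 metrics against TIL counts, PCA,
#' HCPC (k clusters on retained PCs), per-metric cluster
#' characterization, and pairwise TIL comparisons across clusters.
#'
#' @param metrics data.frame with the 13 metric columns plus `til_count`.
#' @param k clusters (default 3).
#' @param retain PCs retained (default 7).
#' @return list with `spearman`, `pca`, `clusters`, `characterization`,
#'   `til_comparison`.
#' @export
analyze_fibrillary <- function(metrics, k = 3, retain = 7) {
  mcols <- intersect(METRIC_COLUMNS, names(metrics))
  X <- metrics[, mcols, drop = FALSE]
  sp <- spearman_matrix(X, metrics$til_count)
  pca <- fit_pca(X)
  cl <- hcpc(pca, k = k, retain = retain)
  labs_full <- rep(NA_integer_, nrow(X))
  labs_full[pca$rows_used] <- cl$labels
  char <- characterize_clusters(X[pca$rows_used, , drop = FALSE], cl$labels)
  tilcmp <- cluster_til_comparison(metrics$til_count[pca$rows_used],
                                   cl$labels)
  list(spearman = sp, pca = pca, clusters = cl, labels = labs_full,
       characterization = char, til_comparison = tilcmp)
}

write_csv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a seeded synthetic cohort, a two-phenotype fibrillary
#' cohort measured with the package's morphometrics, runs the
#' prevalence, TIL, TLS and clustering analyses and writes all report
#' CSVs (plus the dendrogram as Newick) under `out_dir`. Every CSV
#' records the seed in a header comment.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for every stage.
#' @param n_lesions cohort size.
#' @param n_regions fibrillary regions (half per phenotype).
#' @param roi_px fibrillary ROI side in px.
#' @return (invisibly) list with all in-memory results.
#' @export
run_pipeline <- function(out_dir = tempfile("tmefib_"), seed = 1,
                         n_lesions = 30, n_regions = 60, roi_px = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cohort_gen_params(n_lesions = n_lesions,
                                              seed = seed))
  t2 <- build_table2(cohort$lesions)
  t3 <- build_table3(cohort$tumors)
  t4 <- if (!is.null(cohort$tls)) build_table4(cohort$tls) else NULL
  metrics <- simulate_phenotype_cohort(n_regions = n_regions,
                                       roi_px = roi_px, seed = seed)
  fib <- analyze_fibrillary(metrics)
  write_csv_seeded(cohort$lesions, file.path(out_dir, "lesions.csv"), seed)
  write_csv_seeded(cohort$tumors, file.path(out_dir, "tumor_records.csv"), seed)
  if (!is.null(cohort$tls))
    write_csv_seeded(cohort$tls, file.path(out_dir, "tls_records.csv"), seed)
  write_csv_seeded(t2$rows, file.path(out_dir, "table2_prevalence.csv"), seed)
  write_csv_seeded(t3$groups, file.path(out_dir, "table3_til_groups.csv"), seed)
  if (!is.null(t4))
    write_csv_seeded(t4$medians, file.path(out_dir, "table4_tls_medians.csv"),
                     seed)
  write_csv_seeded(metrics, file.path(out_dir, "fiber_metrics.csv"), seed)
  write_csv_seeded(
    data.frame(region = seq_along(fib$labels), cluster = fib$labels,
               phenotype = metrics$phenotype),
    file.path(out_dir, "clusters.csv"), seed)
  write_csv_seeded(fib$characterization,
                   file.path(out_dir, "characterization.csv"), seed)
  write_csv_seeded(fib$til_comparison,
                   file.path(out_dir, "cluster_til_comparison.csv"), seed)
  writeLines(hclust_to_newick(fib$clusters$tree),
             file.path(out_dir, "dendrogram.nwk"))
  invisible(list(cohort = cohort, table2 = t2, table3 = t3, table4 = t4,
                 metrics = metrics, fibrillary = fib, out_dir = out_dir))
}
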