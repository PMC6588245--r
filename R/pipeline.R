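#' Run the concatenation validation experiment on a set of recordings
#'
#' For every input series and every cutting scheme: detect heel strikes,
#' cut into short segments, concatenate them back into one continuous
#' series; then crop the uninterrupted series (`fullTS`) and all
#' concatenated variants of that recording to a common length and compute
#' the nonlinear measures (Wolf LyE, delayed sample entropy; embedding
#' re-estimated per analysed series) on the analysis marker's vertical
#' trajectory. Failures are quarantined per series: the run continues and
#' failed rows carry the error message in `error`.
#'
#' @param series_list named list of [trajectory_series()] (names become
#'   `series_id`), or a single series.
#' @param schemes list of [cut_scheme()]; defaults to the three presets.
#' @param window_frames transition window length; default `round(rate/3)`.
#' @param weights per-marker weight vector or `NULL` for uniform.
#' @param marker analysis (and event) marker name.
#' @param group optional character vector labelling each series with an
#'   experimental condition (e.g. `"normg"` vs a perturbation); recycled
#'   onto the result rows for [evaluate_experiment()].
#' @param min_cycle_s,smooth_window heel-strike detector settings.
#' @param wolf,sampen estimator settings ([wolf_params()],
#'   [sampen_params()]).
#' @param embedding optional fixed [embedding_params()] reused for every
#'   analysed series instead of per-series AMI/FNN re-estimation.
#' @return data.frame with one row per (series, condition): `series_id`,
#'   `group`, `condition` (`"fullTS"` or a scheme name), `n_frames_used`,
#'   `lye`, `se`, `tau`, `dim`, `n_transitions`, `n_fallback`,
#'   `fnn_saturated`, `se_undefined`, `error`.
#' @export
run_experiment <- function(series_list, schemes = cut_presets(),
                           window_frames = NULL, weights = NULL,
                           marker = "RHEE", group = NULL,
                           min_cycle_s = 0.4, smooth_window = 5L,
                           wolf = wolf_params(), sampen = sampen_params(),
                           embedding = NULL) {
  if (inherits(series_list, "trajectory_series"))
    series_list <- list(series_list)
  if (is.null(names(series_list)) || any(!nzchar(names(series_list))))
    names(series_list) <- paste0("S", seq_along(series_list))
  if (is.null(group)) group <- rep(NA_character_, length(series_list))
  group <- rep_len(group, length(series_list))

  rows <- list()
  for (si in seq_along(series_list)) {
    id <- names(series_list)[si]
    series <- series_list[[si]]
    res <- tryCatch({
      events <- detect_heel_strikes(series, marker = marker,
                                    min_cycle_s = min_cycle_s,
                                    smooth_window = smooth_window)
      n <- if (is.null(window_frames)) as.integer(round(series$rate / 3))
           else as.integer(window_frames)
      variants <- list(fullTS = list(series = series, transitions = list()))
      for (sc in schemes) {
        segs <- cut_series(series, events, sc)
        variants[[sc$name]] <- concatenate_all(segs, n = n, weights = weights)
      }
      cropped <- crop_common(lapply(variants, `[[`, "series"))
      out <- list()
      for (cond in names(variants)) {
        z <- marker_coordinate(cropped[[cond]], marker)
        nl <- nonlinear_measures(z, params = embedding, wolf = wolf,
                                 sampen = sampen)
        tr <- variants[[cond]]$transitions
        # transitions located inside the cropped analysis window; cropping
        # to the shortest variant is what makes this count differ by scheme
        n_tr <- sum(vapply(tr, function(t) t$joint_frame, numeric(1)) <
                      length(z))
        out[[cond]] <- data.frame(
          series_id = id, group = group[si], condition = cond,
          n_frames_used = length(z),
          lye = nl$lye, se = nl$se,
          tau = nl$params$tau, dim = nl$params$dim,
          n_transitions = n_tr,
          n_fallback = sum(vapply(tr, function(t) t$fallback, logical(1))),
          fnn_saturated = nl$flags$fnn_saturated,
          se_undefined = nl$flags$se_undefined,
          error = NA_character_, stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }, error = function(e) {
      data.frame(series_id = id, group = group[si], condition = NA_character_,
                 n_frames_used = NA_integer_, lye = NA_real_, se = NA_real_,
                 tau = NA_integer_, dim = NA_integer_,
                 n_transitions = NA_integer_, n_fallback = NA_integer_,
                 fnn_saturated = NA, se_undefined = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[si]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_failed <- sum(!is.na(out$error))
  if (n_failed)
    warning(sprintf("%d series failed and were quarantined", n_failed))
  # traceability: the settings that produced these rows travel with them
  attr(out, "metadata") <- list(
    schemes = vapply(schemes, function(s) sprintf("%s(%d,%d)", s$name,
                                                  s$c_in, s$c_ex),
                     character(1)),
    window_frames = window_frames, marker = marker,
    min_cycle_s = min_cycle_s, smooth_window = smooth_window,
    weights = weights,
    embedding = if (is.null(embedding)) "per-series AMI/FNN"
                else sprintf("fixed tau=%d dim=%d", embedding$tau,
                             embedding$dim),
    n_series = length(series_list),
    package_version = as.character(utils::packageVersion("gaitsplice")))
  out
}

#' Agreement and effect-size evaluation of an experiment table
#'
#' Pairs the `fullTS` row of each series with each concatenated condition
#' and reports ICC(3,1), SEM and Bland-Altman statistics per (metric,
#' condition). When the table carries at least two `group` labels, paired
#' effect sizes between `reference_group` and every other group are
#' computed for each cutting condition (including `fullTS`), plus the CoV
#' of the effect size across conditions.
#'
#' @param results data.frame from [run_experiment()].
#' @param metrics which outcome columns to evaluate.
#' @param reference_group group label treated as unperturbed baseline;
#'   defaults to the first label present.
#' @return list with `agreement` (data.frame) and, when groups are
#'   present, `effect_sizes` (data.frame) and `es_cov` (data.frame).
#' @export
evaluate_experiment <- function(results, metrics = c("lye", "se"),
                                reference_group = NULL) {
  results <- results[is.na(results$error), , drop = FALSE]
  conds <- setdiff(unique(results$condition), "fullTS")
  groups <- unique(stats::na.omit(results$group))
  if (is.null(reference_group) && length(groups))
    reference_group <- groups[1]
  # reliability is assessed on the unperturbed reference recordings
  ref <- if (length(groups) >= 2L)
    results[results$group %in% reference_group, , drop = FALSE] else results
  full <- ref[ref$condition == "fullTS", , drop = FALSE]
  if (!nrow(full)) stop("no fullTS rows in results", call. = FALSE)

  agree <- list()
  for (metric in metrics) {
    for (cond in conds) {
      cut <- ref[ref$condition == cond, , drop = FALSE]
      ids <- intersect(full$series_id, cut$series_id)
      x <- full[[metric]][match(ids, full$series_id)]
      y <- cut[[metric]][match(ids, cut$series_id)]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) {
        agree[[paste(metric, cond)]] <- data.frame(
          metric = metric, condition = cond, n = sum(ok), icc = NA_real_,
          sem = NA_real_, relative_sem = NA_real_, bias = NA_real_,
          loa_low = NA_real_, loa_high = NA_real_)
        next
      }
      rep <- agreement_report(x[ok], y[ok])
      agree[[paste(metric, cond)]] <- data.frame(
        metric = metric, condition = cond, n = rep$n, icc = rep$icc,
        sem = rep$sem, relative_sem = rep$relative_sem, bias = rep$bias,
        loa_low = rep$loa_low, loa_high = rep$loa_high)
    }
  }
  out <- list(agreement = do.call(rbind, c(agree, make.row.names = FALSE)))

  if (length(groups) >= 2L) {
    others <- setdiff(groups, reference_group)
    es <- list()
    for (metric in metrics) {
      for (g in others) {
        for (cond in c("fullTS", conds)) {
          a <- results[[metric]][results$group == reference_group &
                                   results$condition == cond]
          b <- results[[metric]][results$group == g &
                                   results$condition == cond]
          a <- a[is.finite(a)]; b <- b[is.finite(b)]
          d <- if (length(a) >= 2L && length(b) >= 2L)
            cohens_d_pooled(a, b)$d else NA_real_
          es[[paste(metric, g, cond)]] <- data.frame(
            metric = metric, contrast = paste0(reference_group, "-", g),
            condition = cond, d = d)
        }
      }
    }
    es <- do.call(rbind, c(es, make.row.names = FALSE))
    cov <- stats::aggregate(d ~ metric + contrast, data = es,
                            FUN = function(v) cov_of_es(v[is.finite(v)]))
    names(cov)[names(cov) == "d"] <- "cov_percent"
    out$effect_sizes <- es
    out$es_cov <- cov
  }
  out
}
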