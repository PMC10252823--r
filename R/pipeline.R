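# io_config module: end-to-end pipeline orchestration.

#' Run the full food-web analysis pipeline
#'
#' Sequences the analysis end to end: preprocessing (lipid normalization
#' where C:N is available, trophic-discrimination correction, source
#' screening, source summaries, mixing-polygon feasibility), community
#' metrics (Layman metrics per area on taxon means, ellipse areas per
#' area x season), Bayesian mixing models per (area, season, taxon group),
#' dietary-niche hypervolumes with Sorensen overlap of each area against
#' the reference area, and environmental statistics (correlation PCA,
#' Kruskal-Wallis with Dunn-Bonferroni post-hocs).
#'
#' @param consumers consumer table (see [load_samples()] consumer schema).
#' @param sources source table (source schema).
#' @param env environmental table (environment schema), or NULL to skip the
#'   environmental stage.
#' @param config an `analysis_config` from [default_config()]/[load_config()].
#' @param mcmc_settings MCMC profile; defaults to `config$mcmc`. Use
#'   [mcmc_desk_profile()] for desk-scale runs.
#' @param out_dir optional directory; when given, per-stage CSVs, a JSON
#'   summary and a run log (seed + config fingerprint) are written.
#' @param make_figures also write PNG figures (requires a PNG device).
#' @return an object of class `foodweb_results`: list with `consumers`
#'   (corrected, with polygon probabilities), `screening`,
#'   `source_summaries`, `layman`, `ellipses`, `mixing` (list of
#'   `mixing_result`), `niches`, `overlaps`, `envstats`, `log`.
#' @export
run_pipeline <- function(consumers, sources, env = NULL,
                         config = default_config(),
                         mcmc_settings = NULL, out_dir = NULL,
                         make_figures = FALSE) {
  mcmc_settings <- mcmc_settings %||% config$mcmc
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_input("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  note("seed: ", config$seed)
  note("config fingerprint: ", config_fingerprint(config))

  ## -- preprocess ----------------------------------------------------------
  bundle <- stage("preprocess", {
    consumers <- validate_samples(consumers, "consumer")
    sources <- validate_samples(sources, "source")
    if ("c_to_n" %in% names(consumers) && any(!is.na(consumers$c_to_n))) {
      consumers$d13c <- suppressWarnings(
        as.numeric(lipid_normalize(consumers$d13c, consumers$c_to_n,
                                   config$lipid_cn_threshold)))
      note("lipid normalization applied where C:N > ",
           config$lipid_cn_threshold)
    } else {
      note("lipid normalization skipped: no C:N data")
    }
    consumers <- trophic_correct(consumers, config$trophic_levels,
                                 config$tdf_per_level)
    scr <- screen_sources(sources, alpha = config$alpha,
                          threshold = config$correlation_threshold,
                          priority = config$source_priority)
    if (length(scr$dropped)) {
      note("sources dropped by screening: ",
           paste(scr$dropped, collapse = ", "))
    }
    retained <- sources[sources$source %in% scr$retained, ]
    summaries <- summarize_sources(retained)
    list(consumers = consumers, sources = sources, screening = scr,
         summaries = summaries)
  })
  consumers <- bundle$consumers
  summaries <- bundle$summaries

  consumers <- stage("mixing_polygon", {
    out <- vector("list", 0)
    for (s in unique(consumers$season)) {
      ss <- summaries[summaries$season == s & !summaries$flagged, ]
      cc <- consumers[consumers$season == s, ]
      chk <- mixing_polygon_check(cc, ss, n_iter = 500,
                                  threshold = config$polygon_threshold,
                                  seed = derive_seed(config$seed,
                                                     paste0("poly-", s)))
      cc$inside_prob <- chk$inside_prob
      cc$polygon_flagged <- chk$flagged
      out[[s]] <- cc
    }
    cc <- do.call(rbind, out)
    if (any(cc$polygon_flagged)) {
      note(sum(cc$polygon_flagged),
           " consumer(s) flagged outside the mixing polygon and excluded ",
           "from mixing models")
    }
    cc
  })

  ## -- community metrics ---------------------------------------------------
  metrics <- stage("community_metrics", {
    layman <- do.call(rbind, lapply(split(consumers, consumers$area),
      function(cc) {
        cbind(area = cc$area[1], layman_metrics(community_points(cc)))
      }))
    ell <- list()
    for (a in unique(consumers$area)) {
      for (s in unique(consumers$season)) {
        cc <- consumers[consumers$area == a & consumers$season == s, ]
        if (nrow(cc) < 3) next
        e <- tryCatch(
          sea_bayesian(community_points(cc, by_individual = TRUE),
                       n_draws = 2000,
                       seed = derive_seed(config$seed,
                                          paste0("seab-", a, "-", s))),
          error = function(e) NULL)
        if (!is.null(e)) ell[[paste(a, s, sep = "_")]] <- e
      }
    }
    list(layman = layman, ellipses = ell)
  })

  ## -- mixing models -------------------------------------------------------
  mixing <- stage("mixing_model", {
    ok <- consumers[!consumers$polygon_flagged, ]
    fits <- list()
    for (a in unique(ok$area)) {
      for (s in unique(ok$season)) {
        for (g in unique(ok$taxon_group)) {
          cc <- ok[ok$area == a & ok$season == s & ok$taxon_group == g, ]
          if (nrow(cc) < 2) next
          ss <- summaries[summaries$season == s & !summaries$flagged, ]
          key <- paste(a, s, g, sep = "_")
          fits[[key]] <- fit_mixing_model(
            cc, ss, model_tdf = config$model_tdf,
            settings = mcmc_settings, credibility = config$credibility,
            seed = derive_seed(config$seed, paste0("mix-", key)),
            group = list(area = a, season = s, taxon_group = g))
        }
      }
    }
    note(length(fits), " mixing models fitted")
    fits
  })

  ## -- niche hypervolumes --------------------------------------------------
  niche <- stage("niche_hypervolume", {
    skipped <- list(niches = NULL, hypervolumes = NULL, overlaps = NULL)
    areas <- unique(consumers$area)
    by_area <- NULL
    if (length(areas) < 2) {
      note("hypervolume overlap skipped: single area")
    } else {
      by_area <- lapply(areas, function(a) {
        res <- Filter(function(r) identical(r$group$area, a), mixing)
        if (length(res) < 2) NULL else assemble_niche_points(res, area = a)
      })
      names(by_area) <- areas
      by_area <- Filter(Negate(is.null), by_area)
      if (length(by_area) < 2) {
        note("hypervolume overlap skipped: fewer than 2 areas with niches")
        by_area <- NULL
      }
    }
    if (is.null(by_area)) skipped else {
      zt <- z_transform(by_area)
      hv <- lapply(names(zt$sets), function(a) {
        build_hypervolume(zt$sets[[a]]$points,
                          mass_quantile = config$hypervolume$mass_quantile,
                          point_density = config$hypervolume$point_density,
                          n_mc = config$hypervolume$n_mc,
                          seed = derive_seed(config$seed, paste0("hv-", a)))
      })
      names(hv) <- names(zt$sets)
      ref <- config$reference_area
      overlaps <- list()
      if (ref %in% names(hv)) {
        for (a in setdiff(names(hv), ref)) {
          overlaps[[paste(a, ref, sep = "_vs_")]] <- sorensen_overlap(
            hv[[a]], hv[[ref]],
            bootstrap_reps = config$hypervolume$bootstrap_reps,
            seed = derive_seed(config$seed, paste0("ov-", a)))
        }
      } else {
        note("reference area '", ref, "' absent; no overlaps computed")
      }
      list(niches = zt, hypervolumes = hv, overlaps = overlaps)
    }
  })

  ## -- environmental statistics -------------------------------------------
  envres <- if (is.null(env)) NULL else stage("envstats", {
    env <- validate_samples(env, "environment")
    pca <- pca_correlation(env, config$pca_loading_threshold)
    kw <- list()
    dunn <- list()
    for (v in ENV_VARIABLES) {
      for (fac in c("season", "area")) {
        groups <- split(env[[v]], env[[fac]])
        key <- paste(v, fac, sep = "_by_")
        kw[[key]] <- kruskal_wallis(groups)
        if (kw[[key]]$p < config$alpha) {
          dunn[[key]] <- dunn_bonferroni(groups)
        }
      }
    }
    for (iso in c("d13c", "d15n")) {
      for (fac in c("season", "area")) {
        key <- paste("consumer", iso, "by", fac, sep = "_")
        kw[[key]] <- kruskal_wallis(split(consumers[[iso]],
                                          consumers[[fac]]))
      }
    }
    list(pca = pca, kruskal = kw, dunn = dunn)
  })

  results <- structure(list(
    consumers = consumers,
    screening = bundle$screening,
    source_summaries = summaries,
    layman = metrics$layman,
    ellipses = metrics$ellipses,
    mixing = mixing,
    niches = niche$niches,
    hypervolumes = niche$hypervolumes,
    overlaps = niche$overlaps,
    envstats = envres,
    config = config,
    log = log_lines), class = "foodweb_results")

  if (!is.null(out_dir)) {
    write_results(results, out_dir, make_figures = make_figures)
  }
  results
}

config_fingerprint <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967291)
}

#' Mixing-model summary table
#'
#' Long-format summary of a pipeline's mixing results: one row per
#' (area, season, taxon group, source) with the posterior median and
#' credible interval, mirroring a per-source contribution table.
#'
#' @param mixing list of `mixing_result` objects (e.g. `results$mixing`).
#' @return a data.frame.
#' @export
mixing_summary_table <- function(mixing) {
  do.call(rbind, lapply(mixing, function(r) {
    data.frame(
      area = r$group$area %||% NA, season = r$group$season %||% NA,
      taxon_group = r$group$taxon_group %||% NA,
      source = r$sources,
      median = unname(r$medians),
      lower = r$ci95["lower", ], upper = r$ci95["upper", ],
      rhat = unname(r$rhat), geweke_z = unname(r$geweke_z),
      n_consumers = r$n_consumers, row.names = NULL)
  }))
}

write_results <- function(results, out_dir, make_figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(results$consumers, "consumers_corrected.csv")
  w(results$source_summaries, "source_summaries.csv")
  w(results$layman, "layman_metrics.csv")
  if (length(results$mixing)) {
    w(mixing_summary_table(results$mixing), "mixing_summary.csv")
  }
  if (length(results$ellipses)) {
    ell <- do.call(rbind, lapply(names(results$ellipses), function(k) {
      e <- results$ellipses[[k]]
      data.frame(community = k, sea = e$sea, sea_c = e$sea_c,
                 sea_b_median = e$sea_b_median,
                 sea_b_lower95 = e$credible_intervals$`95`[1],
                 sea_b_upper95 = e$credible_intervals$`95`[2], n = e$n)
    }))
    w(ell, "ellipse_areas.csv")
  }
  summary_json <- list(
    overlaps = lapply(results$overlaps, function(o) {
      list(sorensen = o$sorensen, v1 = o$v1, v2 = o$v2,
           ci95 = as.numeric(o$ci95))
    }),
    hypervolume_volumes = lapply(results$hypervolumes,
                                 function(h) h$volume),
    pca_first_two_axes = if (!is.null(results$envstats)) {
      sum(results$envstats$pca$variance_explained[1:2])
    } else NULL)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(results$log, file.path(out_dir, "run_log.txt"))
  if (make_figures) {
    save_figures(results, out_dir)
  }
  invisible(out_dir)
}

#' @export
print.foodweb_results <- function(x, ...) {
  cat("Food-web analysis results\n")
  cat(" consumers:", nrow(x$consumers), "  mixing models:",
      length(x$mixing), "\n")
  cat(" areas:", paste(unique(x$consumers$area), collapse = ", "), "\n")
  if (length(x$overlaps)) {
    for (k in names(x$overlaps)) {
      cat(sprintf(" overlap %s: Sorensen = %.2f\n", k,
                  x$overlaps[[k]]$sorensen))
    }
  }
  invisible(x)
}
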