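#' Pipeline configuration
#'
#' Assembles the full analysis configuration: the synthetic-cohort
#' generator settings plus every downstream constant. Reference
#' constants (theta 4-7 Hz, display threshold 0.55, pinning tiers
#' 1.24/1.4, top-10 pinned nodes, alpha 0.05) are named keys defaulted
#' to those values.
#'
#' @param synth A [synth_config()]; its `seed` is the master seed for
#'   every stochastic stage (subject seeds, clustering restarts,
#'   surrogate rewiring are all derived from it).
#' @param broad_band Apply the 0.5-60 Hz band-pass with 49-51 Hz notch
#'   before theta extraction (default TRUE).
#' @param theta Length-2 theta band in Hz (default `c(4, 7)`).
#' @param min_distance_ms GFP-peak spacing in ms (default 10).
#' @param restarts Clustering restarts used by the pipeline (default 20).
#' @param max_peaks_per_subject Cap on pooled peak maps per subject
#'   (default 200; peaks are subsampled evenly beyond it).
#' @param smoothing_ms Backfit minimum-duration smoothing in ms
#'   (default 0 = off).
#' @param min_len Minimum per-class sample count for a reliable PLV
#'   network (default 100).
#' @param display_threshold PLV display threshold (default 0.55).
#' @param sw_n_rand Surrogates for small-worldness (default 50; 0 skips
#'   Sw).
#' @param pinning A [pinning_spec()] applied to each group-average
#'   network, or `NULL` to skip pinning.
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg correction across each family of
#'   group tests (default FALSE; the uncorrected default mirrors the
#'   reference analysis and is recorded in the report).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), broad_band = TRUE,
                            theta = c(4, 7), min_distance_ms = 10,
                            restarts = 20, max_peaks_per_subject = 200,
                            smoothing_ms = 0, min_len = 100,
                            display_threshold = 0.55, sw_n_rand = 50,
                            pinning = pinning_spec(), alpha = 0.05,
                            fdr = FALSE) {
  stopifnot(inherits(synth, "synth_config"))
  structure(list(synth = synth, broad_band = broad_band, theta = theta,
                 min_distance_ms = min_distance_ms, restarts = restarts,
                 max_peaks_per_subject = max_peaks_per_subject,
                 smoothing_ms = smoothing_ms, min_len = min_len,
                 display_threshold = display_threshold,
                 sw_n_rand = sw_n_rand, pinning = pinning, alpha = alpha,
                 fdr = fdr),
            class = "pipeline_config")
}

# preprocessing chain of one recording: the broadband signal feeds the
# microstate stage (GFP, clustering, backfitting, where fast topography
# switching must be preserved), and its theta-band extraction feeds the
# phase/PLV stage (narrowband assumption of the analytic-signal phase)
preprocess_recording <- function(rec, cfg) {
  rec <- average_reference(rec)
  broad <- if (cfg$broad_band) {
    bandpass(rec, 0.5, 60, notch = c(49, 51))
  } else rec
  list(broad = broad,
       theta = bandpass(broad, cfg$theta[1], cfg$theta[2]))
}

#' Run the full microstate network-dynamics pipeline
#'
#' Executes, in order: cohort generation (or use of a supplied cohort),
#' preprocessing (average reference, optional broad band-pass + notch,
#' theta extraction), GFP-peak pooling across all subjects of both
#' groups, polarity-invariant clustering into 4 templates labelled
#' against the generator's planted maps, per-subject backfitting and
#' temporal parameters, per-subject per-class PLV networks, weighted
#' topology + synchronizability + controllability per network, pinning
#' gains on each group-average network, and group statistics (Welch
#' tests per class x metric, and Pearson correlations of state-D
#' occurrence/coverage with the state-D synchronizability eigenratio).
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional precomputed [make_cohort()] result; generated
#'   from `cfg$synth` when `NULL`.
#' @param out_dir Optional directory; when given, tidy CSV tables and a
#'   JSON manifest are written there.
#' @param stages Character vector of stages to run after networks:
#'   any of `"topology"`, `"control"`, `"pinning"` (default all).
#' @param verbose Print stage progress (default FALSE).
#' @return List of class `pipeline_report` with elements `templates`,
#'   `params` (tidy per subject x class), `metrics` (tidy network-level
#'   metrics), `group_tests`, `correlations`, `pinning`,
#'   `group_networks`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         out_dir = NULL,
                         stages = c("topology", "control", "pinning"),
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  sc <- cfg$synth

  say("stage synth: %d subjects/group", sc$n_subjects_per_group)
  if (is.null(cohort)) cohort <- make_cohort(sc)
  lay <- channel_layout(sc$n_channels)
  planted <- make_templates(sc$n_channels, seed = sc$seed)
  frontal <- region_channels(lay, c("frontal-left", "frontal-right"))
  min_dist <- max(1L, round(cfg$min_distance_ms * sc$fs / 1000))

  say("stage preprocess + GFP peaks")
  pre <- lapply(cohort, function(s) preprocess_recording(s$recording, cfg))
  gfps <- lapply(pre, function(p) compute_gfp(p$broad))
  peak_idx <- lapply(gfps, find_gfp_peaks, min_distance = min_dist)
  pool_maps <- list()
  pool_w <- list()
  for (id in names(pre)) {
    pk <- peak_idx[[id]]
    if (length(pk) > cfg$max_peaks_per_subject) {
      pk <- pk[round(seq(1, length(pk),
                         length.out = cfg$max_peaks_per_subject))]
    }
    pool_maps[[id]] <- t(pre[[id]]$broad$signal[, pk, drop = FALSE])
    pool_w[[id]] <- gfps[[id]]$values[pk]
  }
  peak_maps <- do.call(rbind, pool_maps)
  peak_w <- unlist(pool_w)

  say("stage microstates: clustering %d pooled peak maps", nrow(peak_maps))
  templates <- cluster_microstates(peak_maps, k = 4,
                                   restarts = cfg$restarts,
                                   seed = sc$seed, gfp_weights = peak_w,
                                   canonical = planted)

  say("stage backfit + parameters + networks")
  params <- list()
  metrics <- list()
  nets_by <- list()   # nets_by[[class]][[subject]]
  for (cl in templates$class_labels) nets_by[[cl]] <- list()
  for (id in names(pre)) {
    rec <- pre[[id]]$broad
    grp <- rec$group
    seg <- backfit(rec, templates, min_duration_ms = cfg$smoothing_ms)
    pars <- microstate_parameters(seg, rec$fs, gfp = gfps[[id]])
    pars$subject <- id
    pars$group <- grp
    params[[id]] <- pars
    ph <- instantaneous_phase(pre[[id]]$theta)
    for (cl in templates$class_labels) {
      if (!cl %in% seg$labels[ph$valid_mask]) next
      net <- microstate_network(ph, seg, cl, min_len = cfg$min_len,
                                subject_id = id)
      nets_by[[cl]][[id]] <- net
      if (!net$reliable) next
      row <- data.frame(subject = id, group = grp, class = cl,
                        len = net$n_samples_used)
      if ("topology" %in% stages) {
        topo <- topology(net, n_rand = cfg$sw_n_rand, seed = sc$seed)
        sync <- sync_index(net)
        row$Cp <- topo$Cp; row$Lp <- topo$Lp; row$Eg <- topo$Eg
        row$Eloc <- topo$Eloc; row$Sw <- topo$Sw
        row$sync_M <- sync$M
        row$lambda2 <- sync$lambda2; row$lambda_max <- sync$lambda_max
      }
      if ("control" %in% stages) {
        prof <- control_profile(net)
        row$mean_ac <- mean(prof$ac); row$mean_mc <- mean(prof$mc)
        row$frontal_ac <- mean(prof$ac[frontal])
        row$frontal_mc <- mean(prof$mc[frontal])
      }
      metrics[[paste(id, cl)]] <- row
    }
  }
  params <- do.call(rbind, params)
  rownames(params) <- NULL
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL

  say("stage group averages + pinning")
  group_networks <- list()
  pinning <- list()
  for (cl in templates$class_labels) {
    for (grp in c("HC", "SZ")) {
      sel <- Filter(function(x) {
        isTRUE(x$reliable) &&
          cohort[[x$subject_id]]$recording$group == grp
      }, nets_by[[cl]])
      if (!length(sel)) next
      key <- paste(grp, cl, sep = ".")
      gnet <- group_average(unname(sel))
      group_networks[[key]] <- gnet
      if ("pinning" %in% stages && !is.null(cfg$pinning)) {
        pr <- pinning_gains(gnet, cfg$pinning)
        pinning[[key]] <- pr
      }
    }
  }

  say("stage statistics")
  group_tests <- NULL
  correlations <- NULL
  if (!is.null(metrics)) {
    long <- list()
    for (cl in unique(params$class)) {
      for (m in c("coverage", "occurrence", "duration", "contribution")) {
        sub <- params[params$class == cl, ]
        x <- sub[[m]][sub$group == "HC"]
        y <- sub[[m]][sub$group == "SZ"]
        x <- x[is.finite(x)]; y <- y[is.finite(y)]
        if (length(x) < 2 || length(y) < 2) next
        tt <- two_sample_test(x, y, alpha = cfg$alpha)
        tt$class <- cl; tt$metric <- m; tt$family <- "microstate"
        long[[paste(cl, m)]] <- tt
      }
      net_metrics <- intersect(
        c("Cp", "Lp", "Eg", "Eloc", "Sw", "sync_M",
          "mean_ac", "mean_mc", "frontal_ac", "frontal_mc"),
        names(metrics))
      for (m in net_metrics) {
        sub <- metrics[metrics$class == cl, ]
        x <- sub[[m]][sub$group == "HC"]
        y <- sub[[m]][sub$group == "SZ"]
        x <- x[is.finite(x)]; y <- y[is.finite(y)]
        if (length(x) < 2 || length(y) < 2) next
        tt <- two_sample_test(x, y, alpha = cfg$alpha)
        tt$class <- cl; tt$metric <- m
        tt$family <- if (m %in% c("sync_M")) "synchronization"
                     else if (grepl("ac$|mc$", m)) "controllability"
                     else "topology"
        long[[paste(cl, m)]] <- tt
      }
    }
    group_tests <- do.call(rbind, long)
    rownames(group_tests) <- NULL
    if (cfg$fdr && !is.null(group_tests)) {
      group_tests$p_adj <- stats::ave(group_tests$p, group_tests$family,
                                      FUN = function(p) {
                                        stats::p.adjust(p, "BH")
                                      })
      group_tests$significant <- group_tests$p_adj < cfg$alpha
    }
    # microstate-parameter vs synchronizability correlations, per class
    if ("sync_M" %in% names(metrics)) {
      cors <- list()
      for (cl in unique(metrics$class)) {
        sub <- metrics[metrics$class == cl, c("subject", "sync_M")]
        for (m in c("occurrence", "coverage")) {
          pp <- params[params$class == cl, c("subject", m)]
          mg <- merge(sub, pp, by = "subject")
          if (nrow(mg) < 3) next
          cr <- correlation(mg[[m]], mg$sync_M)
          cr$class <- cl; cr$metric <- m
          cors[[paste(cl, m)]] <- cr
        }
      }
      correlations <- do.call(rbind, cors)
      rownames(correlations) <- NULL
    }
  }

  report <- structure(list(
    templates = templates, params = params, metrics = metrics,
    group_tests = group_tests, correlations = correlations,
    pinning = pinning, group_networks = group_networks,
    fdr_applied = isTRUE(cfg$fdr), config = cfg
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report as tidy CSVs plus a JSON manifest
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sig6 <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  utils::write.csv(sig6(report$params),
                   file.path(out_dir, "microstate_params.csv"),
                   row.names = FALSE)
  if (!is.null(report$metrics)) {
    utils::write.csv(sig6(report$metrics),
                     file.path(out_dir, "network_metrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$group_tests)) {
    utils::write.csv(report$group_tests, file.path(out_dir, "group_tests.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  if (length(report$pinning)) {
    rows <- list()
    for (key in names(report$pinning)) {
      pr <- report$pinning[[key]]
      gl <- strsplit(key, ".", fixed = TRUE)[[1]]
      tier <- rep("third", length(pr$gains))
      tier[pr$tiers$second] <- "second"
      tier[pr$tiers$first] <- "first"
      rows[[key]] <- data.frame(
        group = gl[1], class = gl[2],
        node = seq_along(pr$gains), channel = names(pr$gains),
        gain = as.numeric(pr$gains),
        rank = match(seq_along(pr$gains), pr$ranking),
        pinned = seq_along(pr$gains) %in% pr$pinned_set, tier = tier)
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "pinning_gains.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    n_subjects_per_group = report$config$synth$n_subjects_per_group,
    n_channels = report$config$synth$n_channels,
    fs = report$config$synth$fs,
    duration = report$config$synth$duration,
    seed = report$config$synth$seed,
    alpha = report$config$alpha,
    fdr_applied = report$fdr_applied,
    canonical_corr = as.numeric(report$templates$canonical_corr),
    gev = report$templates$gev
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
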