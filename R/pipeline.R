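#' Configuration of the full analysis pipeline
#'
#' @param input path to a band-matrix CSV (with optional `popmap` and
#'   `primer_map` paths), or `NULL` to simulate input from
#'   `simulation`.
#' @param popmap,primer_map optional companion files for `input`.
#' @param simulation a [sim_config()] used when `input` is `NULL`.
#' @param out_dir output directory (created if needed).
#' @param modules character subset of
#'   `c("metrics", "diversity", "distance", "pca", "admixture")`.
#' @param distance_level `"individual"` or `"population"` for the Nei
#'   matrices and UPGMA tree.
#' @param admixture an [admixture_config()].
#' @param k_range K values scanned by the admixture stage.
#' @param membership_threshold purity cut-off for Q classification.
#' @param digits report precision.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, popmap = NULL,
                            primer_map = NULL,
                            simulation = sim_config(),
                            out_dir = tempfile("bandpop_run_"),
                            modules = c("metrics", "diversity",
                                        "distance", "pca", "admixture"),
                            distance_level = "individual",
                            admixture = admixture_config(),
                            k_range = 1:6,
                            membership_threshold = 0.60,
                            digits = 4, seed = 1L) {
  modules <- match.arg(modules, several.ok = TRUE)
  structure(list(input = input, popmap = popmap,
                 primer_map = primer_map, simulation = simulation,
                 out_dir = out_dir, modules = modules,
                 distance_level = distance_level,
                 admixture = admixture, k_range = k_range,
                 membership_threshold = membership_threshold,
                 digits = digits, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dominant-marker analysis pipeline
#'
#' Sequences, on one input band matrix (read from file or simulated):
#' per-primer diversity report, per-primer marker-efficiency report, Nei
#' identity/distance matrices with a UPGMA Newick tree and Ward heatmap
#' orders, a PCA report, and the admixture scan with Evanno table,
#' per-cluster fixation indices and Q-membership classification. Every
#' table is written via [write_report()] under `cfg$out_dir` together
#' with a JSON run manifest (resolved configuration, seed, stage
#' timings). A stage failure aborts with the stage name; earlier outputs
#' are kept.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the in-memory results of every stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  results <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  m <- stage("input", {
    if (is.null(cfg$input)) {
      sim <- simulate_band_matrix(cfg$simulation)
      jsonlite::write_json(
        list(Q_true = sim$truth$Q_true, F_k = sim$truth$F_k,
             seed = sim$truth$seed),
        file.path(cfg$out_dir, "simulation_truth.json"),
        digits = NA, auto_unbox = TRUE)
      results$truth <- sim$truth
      sim$bands
    } else {
      read_band_matrix(cfg$input, cfg$popmap, cfg$primer_map)
    }
  })
  results$bands <- m
  write_band_matrix(m, file.path(cfg$out_dir, "band_matrix.csv"),
                    file.path(cfg$out_dir, "popmap.csv"))

  if ("diversity" %in% cfg$modules) {
    results$diversity <- stage("diversity", {
      pd <- primer_diversity(m)
      write_report(rbind_mean(pd),
                   file.path(cfg$out_dir, "diversity_per_primer"),
                   cfg$digits)
      part <- partition_diversity(m)
      list(per_primer = pd, partition = part)
    })
  }
  if ("metrics" %in% cfg$modules) {
    results$metrics <- stage("metrics", {
      pm <- primer_metrics(m)
      write_report(rbind_mean(pm),
                   file.path(cfg$out_dir, "marker_metrics"), cfg$digits)
      pm
    })
  }
  if ("distance" %in% cfg$modules) {
    results$distance <- stage("distance", {
      nm <- pairwise_matrix(m, cfg$distance_level)
      tr <- upgma(nm$distance, cap = 10)
      write_newick(tr, file.path(cfg$out_dir, "upgma.nwk"))
      rep <- nei_report(nm)
      utils::write.csv(round(rep, cfg$digits),
                       file.path(cfg$out_dir,
                                 "nei_identity_distance.csv"))
      ho <- heatmap_orders(m)
      writeLines(c(paste(ho$rows, collapse = ","),
                   paste(ho$cols, collapse = ",")),
                 file.path(cfg$out_dir, "heatmap_orders.txt"))
      list(nei = nm, tree = tr, heatmap = ho)
    })
  }
  if ("pca" %in% cfg$modules) {
    results$pca <- stage("pca", {
      pr <- pca_report(m)
      write_report(pr$axes, file.path(cfg$out_dir, "pca_axes"),
                   cfg$digits)
      write_report(pr$scores, file.path(cfg$out_dir, "pca_scores"),
                   cfg$digits)
      pr
    })
  }
  if ("admixture" %in% cfg$modules) {
    results$admixture <- stage("admixture", {
      scan <- admixture_scan(m, cfg$k_range, cfg$admixture,
                             seed = cfg$seed)
      if (!is.null(scan$evanno))
        write_report(scan$evanno$table,
                     file.path(cfg$out_dir, "evanno"), cfg$digits)
      bk <- scan$best_k
      if (!is.na(bk)) {
        best <- scan$fits[[as.character(bk)]][[1L]]
        cls <- classify_membership(scan$mean_Q[[as.character(bk)]],
                                   cfg$membership_threshold)
        write_report(cls, file.path(cfg$out_dir, "membership"),
                     cfg$digits)
        fst_tab <- data.frame(cluster = names(best$F_k),
                              fst = unname(best$F_k),
                              interpretation =
                                fst_interpretation(best$F_k),
                              within_het = unname(best$cluster_het))
        write_report(fst_tab, file.path(cfg$out_dir, "cluster_fst"),
                     cfg$digits)
        utils::write.csv(round(best$net_distance, cfg$digits),
                         file.path(cfg$out_dir, "net_distance.csv"))
        scan$classification <- cls
        scan$fst <- fst_tab
      }
      scan
    })
  }

  manifest <- list(schema = "bandpop-manifest/1",
                   seed = cfg$seed, modules = cfg$modules,
                   distance_level = cfg$distance_level,
                   k_range = cfg$k_range,
                   simulated = is.null(cfg$input),
                   timings_sec = timings,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

rbind_mean <- function(df) {
  agg <- aggregate_metrics(df, sd_row = TRUE)
  first <- names(df)[1L]
  pad <- data.frame(x = agg$statistic)
  names(pad) <- first
  out <- rbind(df, cbind(pad, agg[-1L])[, names(df), drop = FALSE])
  out
}
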