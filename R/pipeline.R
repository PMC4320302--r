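# End-to-end pipeline: read (or generate) -> project -> (optionally) select
# the number of projections from the singular-value decay -> segment ->
# profile, writing every artifact plus a manifest (all seeds, parameters,
# checksums) sufficient to reproduce the run bit-exactly.

#' Pipeline run configuration
#'
#' @param input path to an `.imzML` file, or an MSI reader object, or the
#'   string `"phantom"` for the built-in liver-like phantom.
#' @param output_dir run directory to create (must not be an existing
#'   non-empty directory unless `overwrite = TRUE`).
#' @param n_projections integer, or `"auto"` to select the count from the
#'   decay of the normalized first singular value (project an initial batch,
#'   fit, extend the basis until the elbow is reached).
#' @param n_clusters number of k-means clusters (required).
#' @param fraction curvature fraction for `"auto"` selection (default 2/3).
#' @param seed_basis,seed_kmeans,seed_eval seeds for the projection basis,
#'   the clustering, and evaluation subsampling.
#' @param initial_projections first batch size in `"auto"` mode (default 64).
#' @param max_projections hard cap in `"auto"` mode (default 512).
#' @param subset_policy,svalue_norm passed to [decay_curve()].
#' @param bin_width Daltons, required for processed-mode imzML input.
#' @param stability_counts optional integer vector: also run
#'   [stability_experiment()] at these projection counts.
#' @param stability_repeats repeats for the stability experiment (default 3).
#' @param n_restarts k-means restarts (default 10).
#' @param write_png also render the label map to a PNG (default FALSE; text
#'   outputs are always written).
#' @param overwrite allow writing into an existing directory.
#' @return a `run_config` list.
#' @export
run_config <- function(input, output_dir, n_projections = "auto", n_clusters,
                       fraction = 2 / 3, seed_basis = 1L, seed_kmeans = 1L,
                       seed_eval = 1L, initial_projections = 64L,
                       max_projections = 512L,
                       subset_policy = c("prefix", "random"),
                       svalue_norm = c("s1_over_k", "s1sq_over_k"),
                       bin_width = NULL, stability_counts = NULL,
                       stability_repeats = 3L, n_restarts = 10L,
                       write_png = FALSE, overwrite = FALSE) {
  if (missing(n_clusters)) config_error("`n_clusters` is required")
  if (!identical(n_projections, "auto") &&
      (!is.numeric(n_projections) || n_projections < 1)) {
    config_error("`n_projections` must be a positive integer or \"auto\"")
  }
  structure(list(
    input = input, output_dir = output_dir, n_projections = n_projections,
    n_clusters = as.integer(n_clusters), fraction = fraction,
    seed_basis = as.integer(seed_basis), seed_kmeans = as.integer(seed_kmeans),
    seed_eval = as.integer(seed_eval),
    initial_projections = as.integer(initial_projections),
    max_projections = as.integer(max_projections),
    subset_policy = match.arg(subset_policy),
    svalue_norm = match.arg(svalue_norm), bin_width = bin_width,
    stability_counts = stability_counts,
    stability_repeats = as.integer(stability_repeats),
    n_restarts = as.integer(n_restarts), write_png = isTRUE(write_png),
    overwrite = isTRUE(overwrite)), class = "run_config")
}

open_input <- function(config) {
  input <- config$input
  if (inherits(input, "msi_dataset") || inherits(input, "imzml_reader")) return(input)
  if (identical(input, "phantom")) {
    return(generate_phantom(default_liver_like_spec())$dataset)
  }
  if (is.character(input) && length(input) == 1L) {
    return(read_imzml(input, bin_width = config$bin_width))
  }
  config_error("`input` must be an imzML path, an MSI reader, or \"phantom\"")
}

subset_sizes_for <- function(k, n_points = 14L) {
  sizes <- unique(round(exp(seq(log(2), log(k), length.out = n_points))))
  sizes[sizes >= 2 & sizes <= k]
}

msirp_log <- function(...) message(sprintf("[msirp] %s", sprintf(...)))

#' Run the full pipeline
#'
#' Stages: open input, build/extend the projection basis, compute scores,
#' optionally select the number of projections from the decay curve
#' (`"auto"`), k-means segment, recompute per-cluster molecular profiles from
#' the raw spectra, write everything as delimited text plus `manifest.json`.
#' Any stage failure leaves partial outputs plus a `FAILED` marker naming the
#' stage and re-signals the error.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in the run directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (dir.exists(out) && length(dir(out)) > 0 && !config$overwrite) {
    config_error(paste0("output directory exists and is not empty: ", out))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste0("stage: ", stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(e)
  }

  manifest <- tryCatch({
    stage <- "read"
    reader <- open_input(config)
    n <- n_pixels(reader); m <- n_channels(reader)
    msirp_log("input: %d pixels x %d channels", n, m)

    stage <- "project"
    auto <- identical(config$n_projections, "auto")
    k0 <- if (auto) min(config$initial_projections, config$max_projections)
          else as.integer(config$n_projections)
    basis <- make_basis(k0, m, config$seed_basis)
    scores <- project_dataset(reader, basis)
    msirp_log("projected %d pixels onto %d random directions", n, k0)

    selection <- NULL
    if (auto) {
      stage <- "select"
      extended <- FALSE
      repeat {
        curve <- decay_curve(scores, subset_sizes_for(basis$k),
                             policy = config$subset_policy,
                             norm = config$svalue_norm)
        fit <- fit_exponential(curve)
        if (!fit$converged || fit$degenerate || fit$a <= 0 || fit$b <= 0) {
          numerical_error("decay-curve fit is degenerate; cannot select a projection count automatically")
        }
        k_est <- select_projection_count(fit, config$fraction)
        if (elbow_reached(curve, fit, config$fraction) ||
            basis$k >= config$max_projections) {
          break
        }
        grow <- min(max(k_est - basis$k, basis$k),
                    config$max_projections - basis$k)
        msirp_log("elbow not reached at k=%d (k_est=%d); extending basis by %d",
                  basis$k, k_est, grow)
        basis <- extend_basis(basis, grow)
        new_rows <- (basis$k - grow + 1L):basis$k
        sub_basis <- structure(list(matrix = basis$matrix[new_rows, , drop = FALSE],
                                    k = grow, m = m, seed = basis$seed,
                                    generator_id = basis$generator_id),
                               class = "projection_basis")
        scores$scores <- rbind(scores$scores, project_dataset(reader, sub_basis)$scores)
        scores$k <- basis$k
        extended <- TRUE
      }
      k_use <- min(k_est, basis$k)
      msirp_log("selected k_est=%d (x*=%.2f); using %d projections",
                k_est, max_curvature_point(fit), k_use)
      scores$scores <- scores$scores[seq_len(k_use), , drop = FALSE]
      scores$k <- k_use
      selection <- list(k_est = k_est, k_used = k_use,
                        x_star = max_curvature_point(fit),
                        fraction = config$fraction, extended = extended,
                        fit = list(a = fit$a, b = fit$b, c = fit$c,
                                   rss = fit$rss, converged = fit$converged))
      utils::write.table(
        data.frame(subset_size = curve$subset_sizes, value = curve$values,
                   fitted = fit$a * exp(-fit$b * curve$subset_sizes) + fit$c),
        file.path(out, "decay_curve.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(selection, file.path(out, "selection.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    write_scores(scores, file.path(out, "scores.tsv"))

    stage <- "segment"
    map <- kmeans_segment(scores, config$n_clusters, seed = config$seed_kmeans,
                          n_restarts = config$n_restarts)
    msirp_log("k-means: %d clusters, inertia %.6g", map$n_clusters, map$inertia)
    coords <- pixel_coords(reader)
    utils::write.table(
      data.frame(x = coords[, "x"], y = coords[, "y"], label = map$labels),
      file.path(out, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    dmat <- centroid_distance_matrix(map)
    utils::write.table(round(dmat, 10), file.path(out, "centroid_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = paste0("cluster_", seq_len(ncol(dmat))))
    if (config$write_png) {
      img <- render_map(map)
      try({
        grDevices::png(file.path(out, "map.png"), width = ncol(img),
                       height = nrow(img), type = "cairo")
        graphics_image(img)
        grDevices::dev.off()
      }, silent = TRUE)
    }

    stage <- "profiles"
    profiles <- cluster_mean_spectra(reader, map)
    prof_tab <- data.frame(mz = profiles$mz, profiles$mean_spectrum)
    names(prof_tab) <- c("mz", paste0("cluster_", seq_len(map$n_clusters)))
    utils::write.table(prof_tab, file.path(out, "cluster_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stability <- NULL
    if (!is.null(config$stability_counts)) {
      stage <- "stability"
      st <- stability_experiment(reader, config$stability_counts,
                                 config$stability_repeats, config$n_clusters,
                                 seed = config$seed_eval,
                                 n_restarts = config$n_restarts)
      utils::write.table(st, file.path(out, "stability.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(attr(st, "summary"),
                         file.path(out, "stability_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stability <- attr(st, "summary")
    }

    stage <- "manifest"
    files <- setdiff(dir(out), "manifest.json")
    manifest <- list(
      package = "msirp",
      version = as.character(utils::packageVersion("msirp")),
      parameters = list(
        n_projections = config$n_projections, k_used = scores$k,
        n_clusters = config$n_clusters, fraction = config$fraction,
        subset_policy = config$subset_policy, svalue_norm = config$svalue_norm,
        bin_width = config$bin_width, n_restarts = config$n_restarts),
      seeds = list(basis = config$seed_basis, kmeans = config$seed_kmeans,
                   eval = config$seed_eval),
      data = list(n_pixels = n, n_channels = m),
      selection = selection,
      generator_id = scores$basis_ref$generator_id,
      files = lapply(stats::setNames(files, files), function(f) {
        list(md5 = unname(tools::md5sum(file.path(out, f))))
      })
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = on_fail)
  invisible(manifest)
}

graphics_image <- function(img) {
  pal <- attr(img, "palette")
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), col = pal,
                  axes = FALSE, useRaster = TRUE)
}
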