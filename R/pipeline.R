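#' Run the full recovery-time-course pipeline
#'
#' Orchestrates the stages end to end: simulate (or load) a probe-level
#' expression table, log-transform and quantile-normalize it, collapse
#' probes to transcripts, select transcripts tracking cellularity, cluster
#' them, annotate the clusters with cell populations, optionally run
#' over-representation analysis against a GMT collection and quantify
#' stained-section images. All stage outputs plus a JSON run manifest
#' (package version, parameters, derived seeds, input and output checksums)
#' are written to the output directory; a rerun with the same configuration
#' reproduces the outputs bit-identically.
#'
#' @param config Configuration list or path to a YAML file with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{global integer seed; every stage seed derives from it.}
#'     \item{simulate}{`TRUE` to generate the default synthetic study, or a
#'       list of [sim_config()] arguments; `FALSE`/absent to read inputs.}
#'     \item{expression, probe_annotation}{input TSV paths when not
#'       simulating.}
#'     \item{scale}{scale of the input table, `"linear"` (default; analysis
#'       proceeds on log2(signal + 1)) or `"log2"`.}
#'     \item{selection}{list of [selection_config()] overrides.}
#'     \item{clustering}{list: `k` (`"auto"` or integer), `k_min`, `k_max`,
#'       `rho_max`.}
#'     \item{markers}{`"packaged"` (default) or a marker TSV path.}
#'     \item{gmt}{optional GMT path for per-cluster ORA.}
#'     \item{images}{optional list of lists: `path`, `um2_per_pixel`,
#'       optional `day`, `min_red_area_um2`, `connectivity`.}
#'   }
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 42L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package = "gapwave",
                   version = as.character(utils::packageVersion("gapwave")),
                   seed = seed, stages = list())
  inputs <- character(0)

  # --- input: simulate or load -------------------------------------------
  sim_requested <- isTRUE(config$simulate) || is.list(config$simulate)
  if (sim_requested) {
    sim <- stage("simulate", {
      args <- if (is.list(config$simulate)) config$simulate else list()
      args$rng_seed <- seed
      do.call(sim_config, args)
    })
    sim_out <- stage("simulate", simulate_expression(sim))
    probes <- sim_out$probes
    ann <- sim_out$annotation
    utils::write.table(sim_out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ann, file.path(out_dir, "probe_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$simulate <- list(seed = seed,
                                     n_noise = sim$n_noise_transcripts,
                                     probes_per_transcript =
                                       sim$probes_per_transcript)
    scale_in <- "linear"
  } else {
    probes <- stage("load", {
      if (is.null(config$expression)) stop("no expression table configured")
      read_expression_table(config$expression,
                            scale = config$scale %||% "linear")
    })
    ann <- stage("load", {
      if (is.null(config$probe_annotation))
        stop("no probe annotation configured")
      read_probe_annotation(config$probe_annotation)
    })
    inputs <- c(inputs, config$expression, config$probe_annotation)
    scale_in <- config$scale %||% "linear"
  }

  # --- normalize + collapse ----------------------------------------------
  collapsed <- stage("normalize", {
    m <- if (scale_in == "linear") log2_transform(probes) else probes
    qn <- quantile_normalize(m)
    collapse_probes_median(qn, ann)
  })

  # --- selection ----------------------------------------------------------
  sel_seed <- seed + 1L
  sel_cfg <- stage("select", {
    args <- config$selection %||% list()
    args$rng_seed <- sel_seed
    do.call(selection_config, args)
  })
  sel <- stage("select", select_transcripts(collapsed, sel_cfg))
  write_selection(sel, file.path(out_dir, "selection.tsv"))
  manifest$stages$select <- list(seed = sel_seed,
                                 n_selected = sum(sel$selected),
                                 fdr_threshold = sel_cfg$fdr_threshold,
                                 sd_threshold = sel_cfg$sd_threshold,
                                 n_permutations = sel_cfg$n_permutations)

  # --- clustering ---------------------------------------------------------
  cl_cfg <- config$clustering %||% list()
  cl_res <- stage("cluster", {
    picked <- sel$transcript_id[sel$selected]
    if (length(picked) < 3L) stop("fewer than 3 selected transcripts")
    sub <- collapsed$values[picked, , drop = FALSE]
    subm <- expression_matrix(sub, collapsed$days, scale = collapsed$scale)
    d <- correlation_distance(z_scale_profiles(subm))
    k <- cl_cfg$k %||% "auto"
    if (identical(k, "auto")) {
      k <- choose_k(d, subm,
                    k_range = (cl_cfg$k_min %||% 2L):(cl_cfg$k_max %||% 10L),
                    rho_max = cl_cfg$rho_max %||% 0.8)
    }
    cl <- pam_cluster(d, as.integer(k))
    list(cl = cl, profiles = median_z_profiles(subm, cl$labels))
  })
  write_clusters(cl_res$cl, file.path(out_dir, "clusters.tsv"))
  utils::write.table(
    data.frame(cluster = rownames(cl_res$profiles),
               signif(cl_res$profiles, 6L), check.names = FALSE),
    file.path(out_dir, "cluster_profiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$cluster <- list(k = cl_res$cl$k,
                                  sizes = unname(tabulate(cl_res$cl$labels,
                                                          cl_res$cl$k)))

  # --- annotation ---------------------------------------------------------
  ct <- stage("annotate", {
    mk_src <- config$markers %||% "packaged"
    markers <- if (identical(mk_src, "packaged")) testis_markers()
               else read_marker_table(mk_src)
    if (!identical(mk_src, "packaged")) inputs <- c(inputs, mk_src)
    ev <- map_markers(markers, cl_res$cl$labels)
    assign_cell_types(cl_res$profiles, ev)
  })
  write_cell_types(ct, file.path(out_dir, "cell_types.json"))
  manifest$stages$annotate <- list(labels = as.list(ct$labels))

  # --- ORA (optional) -----------------------------------------------------
  if (!is.null(config$gmt)) {
    stage("enrich", {
      sets <- read_gmt(config$gmt)
      inputs <- c(inputs, config$gmt)
      universe <- rownames(collapsed$values)
      for (k in sort(unique(cl_res$cl$labels))) {
        genes <- names(cl_res$cl$labels)[cl_res$cl$labels == k]
        res <- suppressWarnings(hypergeom_ora(genes, sets, universe))
        utils::write.table(as.data.frame(res),
                           file.path(out_dir, sprintf("ora_cluster%d.tsv", k)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
    manifest$stages$enrich <- list(gmt = config$gmt)
  }

  # --- image quantification (optional) ------------------------------------
  if (!is.null(config$images)) {
    quant <- stage("quantify_images", {
      rows <- lapply(config$images, function(im) {
        qc <- quant_config(
          um2_per_pixel = im$um2_per_pixel,
          min_red_area_um2 = im$min_red_area_um2 %||% 20,
          connectivity = im$connectivity %||% 8L)
        qs <- quantify_section(im$path, qc)
        data.frame(image = im$path, day = im$day %||% NA_integer_,
                   red_um2 = qs$areas_um2[["red"]],
                   blue_um2 = qs$areas_um2[["blue"]],
                   background_um2 = qs$areas_um2[["background"]],
                   ratio = qs$ratio, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    inputs <- c(inputs, vapply(config$images, `[[`, character(1), "path"))
    utils::write.table(quant, file.path(out_dir, "image_quant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$quantify_images <- list(n_images = length(config$images))
  }

  # --- manifest -----------------------------------------------------------
  if (length(inputs) > 0L)
    manifest$input_md5 <- as.list(tools::md5sum(inputs))
  outs <- setdiff(list.files(out_dir, full.names = TRUE),
                  file.path(out_dir, "manifest.json"))
  manifest$output_md5 <- as.list(tools::md5sum(outs))
  names(manifest$output_md5) <- basename(names(manifest$output_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
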