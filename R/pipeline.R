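#' Retrieval pipeline configuration
#'
#' Defaults encode the settings that performed best in superfamily
#' retrieval: backbone-atom surface, outlier detection on (p = 0.9, 3
#' rounds), 50% mesh decimation, moment order 20, rPCA unit-ball scale
#' factor, and the fully penalised distance metric with gamma_s = -0.05 and
#' gamma_v = -0.1.
#'
#' @param surface_mode `"backbone"` or `"all_atom"`.
#' @param decimation_factor fraction of facets to remove, in `[0, 0.95]`.
#' @param outlier_p,outlier_rounds confidence level and maximum rounds of
#'   the outlier detection; `outlier_rounds = 0` disables elimination.
#' @param scale_method unit-ball scale factor method (see [scale_factor]).
#' @param rpca_p confidence level of the `rpca` scale factor.
#' @param moment_order ZC moment order (<= 35).
#' @param distance a [distance_config].
#' @param msms_path path to an MSMS-compatible surface binary (NULL: no
#'   external surface tool; supply meshes directly).
#' @param msms_density,msms_hdensity optional MSMS density settings; the
#'   program's defaults are used when NULL.
#' @param probe_radius solvent probe radius in Å (default 1.4).
#' @param decimator decimation backend for [decimate_adapter] (NULL: none).
#' @param verbose log one line per pipeline stage (default FALSE).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(surface_mode = c("backbone", "all_atom"),
                            decimation_factor = 0.5,
                            outlier_p = 0.9, outlier_rounds = 3,
                            scale_method = "rpca", rpca_p = 0.95,
                            moment_order = 20,
                            distance = distance_config(),
                            msms_path = NULL, msms_density = NULL,
                            msms_hdensity = NULL, probe_radius = 1.4,
                            decimator = NULL, verbose = FALSE) {
  surface_mode <- match.arg(surface_mode)
  if (decimation_factor < 0 || decimation_factor > 0.95) {
    stop("pipeline_config: decimation_factor must lie in [0, 0.95]")
  }
  if (moment_order > 35) {
    stop("pipeline_config: moment_order must be <= 35 (numerical ",
         "instability of double precision above order 35)")
  }
  structure(list(surface_mode = surface_mode,
                 decimation_factor = decimation_factor,
                 outlier_p = outlier_p, outlier_rounds = outlier_rounds,
                 scale_method = scale_method, rpca_p = rpca_p,
                 moment_order = moment_order, distance = distance,
                 msms_path = msms_path, msms_density = msms_density,
                 msms_hdensity = msms_hdensity,
                 probe_radius = probe_radius,
                 decimator = decimator, verbose = verbose),
            class = "pipeline_config")
}

pipe_log <- function(cfg, stage, fmt, ...) {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

#' Run the molecular-surface program on an xyzr file
#'
#' Invokes an MSMS-compatible binary with `-probe_radius`,
#' `-free_vertices` and `-all_components` (the latter two keep multi-chain
#' surfaces complete). If the run fails with `-all_components` — the
#' program has a hard limit on the number of surface components — it is
#' automatically retried once without that flag. The resulting .vert/.face
#' pair is parsed into a mesh.
#'
#' @param xyzr_path input file written by [write_xyzr].
#' @param cfg a [pipeline_config] with `msms_path` set.
#' @return a [tri_mesh].
#' @export
msms_adapter <- function(xyzr_path, cfg = pipeline_config()) {
  if (is.null(cfg$msms_path)) {
    stop("msms_adapter: no surface binary configured (set msms_path in ",
         "pipeline_config)")
  }
  if (!file.exists(cfg$msms_path)) {
    stop("msms_adapter: surface binary not found at msms_path = '",
         cfg$msms_path, "'")
  }
  out_prefix <- tempfile("msms")
  base_args <- c("-if", xyzr_path, "-of", out_prefix,
                 "-probe_radius", format(cfg$probe_radius),
                 "-free_vertices")
  if (!is.null(cfg$msms_density)) {
    base_args <- c(base_args, "-density", format(cfg$msms_density))
  }
  if (!is.null(cfg$msms_hdensity)) {
    base_args <- c(base_args, "-hdensity", format(cfg$msms_hdensity))
  }
  run <- function(args) {
    suppressWarnings(system2(cfg$msms_path, args, stdout = TRUE,
                             stderr = TRUE))
  }
  out <- run(c(base_args, "-all_components"))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    pipe_log(cfg, "surface", "retrying without -all_components")
    out <- run(base_args)
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("msms_adapter: surface calculation failed:\n",
           paste(out, collapse = "\n"))
    }
  }
  read_msms_surface(paste0(out_prefix, ".vert"),
                    paste0(out_prefix, ".face"))
}

#' Decimate (simplify) a mesh through a backend
#'
#' Mesh decimation itself is delegated: `backend` is either an R function
#' `function(mesh, factor) -> tri_mesh` (for example a wrapper around an
#' external uniform/quadric decimation tool) or NULL. With `factor = 0` the
#' mesh is returned unchanged; with a positive factor and no backend a
#' configuration error is raised.
#'
#' @param mesh a [tri_mesh].
#' @param factor fraction of facets to remove, `[0, 0.95]`.
#' @param backend decimation backend (see above).
#' @return a [tri_mesh].
#' @export
decimate_adapter <- function(mesh, factor, backend = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (factor < 0 || factor > 0.95) {
    stop("decimate_adapter: factor must lie in [0, 0.95]")
  }
  if (factor == 0) return(mesh)
  if (is.null(backend)) {
    stop("decimate_adapter: no decimation backend configured (set ",
         "decimator in pipeline_config or pass factor = 0)")
  }
  if (!is.function(backend)) {
    stop("decimate_adapter: backend must be a function(mesh, factor)")
  }
  out <- backend(mesh, factor)
  if (!inherits(out, "tri_mesh")) {
    stop("decimate_adapter: backend did not return a tri_mesh")
  }
  out
}

#' Compute the feature vector of one structure
#'
#' Executes the retrieval pipeline for a single input: parse and clean the
#' PDB file, apply the selection, detect and remove outlier residues,
#' obtain the molecular surface (externally, or from a supplied mesh),
#' decimate, extract the geometric features, place the mesh in the unit
#' ball and compute the normalized ZC descriptor vector.
#'
#' Any stage can be bypassed by supplying its product: `structure` skips
#' parsing, `mesh` skips the surface and decimation stages. A mesh-only
#' call (no PDB, no structure) uses the mesh vertices in place of the
#' effective atoms for the histogram and size features.
#'
#' @param pdb_path path to a PDB file (optional if `structure` or `mesh`
#'   is given).
#' @param selection optional selection expression for [select_fragment].
#' @param cfg a [pipeline_config].
#' @param mesh optional pre-computed [tri_mesh] (bypasses the surface
#'   program and decimation).
#' @param structure optional pre-parsed `zc_structure`.
#' @param id identifier stored in the metadata (default: file base name).
#' @return a [protein_features] object.
#' @export
run_descriptor_pipeline <- function(pdb_path = NULL, selection = NULL,
                                    cfg = pipeline_config(), mesh = NULL,
                                    structure = NULL, id = NULL) {
  if (is.null(pdb_path) && is.null(structure) && is.null(mesh)) {
    stop("run_descriptor_pipeline: need a PDB file, a structure or a mesh")
  }
  s <- NULL
  if (!is.null(structure)) {
    s <- structure
  } else if (!is.null(pdb_path)) {
    s <- clean_structure(parse_pdb(pdb_path))
    pipe_log(cfg, "clean", "%d atoms in %d chains", nrow(s$atoms),
             length(s$chain_order))
  }
  if (is.null(id)) {
    id <- if (!is.null(pdb_path)) {
      sub("\\.[^.]*$", "", basename(pdb_path))
    } else "input"
  }
  if (!is.null(s) && !is.null(selection)) {
    s <- select_fragment(s, selection)
    pipe_log(cfg, "select", "'%s' -> %d atoms", selection, nrow(s$atoms))
  }

  # effective points driving outlier detection and the atom-based features
  points <- if (!is.null(s)) effective_atoms(s) else point_cloud(mesh$vertices)
  det <- detect_outliers(points, p = cfg$outlier_p, r = cfg$outlier_rounds)
  guide <- det$guide_mask
  pipe_log(cfg, "outliers", "%d guides / %d outliers in %d rounds",
           sum(guide), sum(!guide), det$rounds_used)

  if (is.null(mesh)) {
    if (is.null(s)) stop("run_descriptor_pipeline: no mesh and no structure")
    guide_res <- points$labels[guide]
    a <- s$atoms
    akey <- paste0(a$chain, ":", a$resno, a$insert)
    sg <- s
    sg$atoms <- a[akey %in% guide_res, , drop = FALSE]
    sg$chain_order <- unique(sg$atoms$chain)
    if (cfg$surface_mode == "backbone") {
      parts <- lapply(backbone_chains(sg), function(chain_s) {
        xyzr <- tempfile(fileext = ".xyzr")
        on.exit(unlink(xyzr), add = TRUE)
        write_xyzr(chain_s, xyzr)
        msms_adapter(xyzr, cfg)
      })
      mesh <- merge_meshes(parts)
    } else {
      xyzr <- tempfile(fileext = ".xyzr")
      on.exit(unlink(xyzr), add = TRUE)
      write_xyzr(sg, xyzr)
      mesh <- msms_adapter(xyzr, cfg)
    }
    pipe_log(cfg, "surface", "%d vertices, %d facets", nrow(mesh$vertices),
             nrow(mesh$facets))
    mesh <- decimate_adapter(mesh, cfg$decimation_factor, cfg$decimator)
    pipe_log(cfg, "decimate", "factor %.2f -> %d facets",
             cfg$decimation_factor, nrow(mesh$facets))
  }

  guide_pc <- point_cloud(points$coords[guide, , drop = FALSE],
                          points$labels[guide])
  aligned_guides <- point_cloud(
    det$aligned_points$coords[guide, , drop = FALSE])
  hist <- smooth_histogram(distance_histogram(aligned_guides))
  size <- size_descriptor(aligned_guides)
  volume <- mesh_volume(mesh)
  center <- colMeans(guide_pc$coords)
  sf <- scale_factor(mesh, guide_pc, size, method = cfg$scale_method,
                     p = cfg$rpca_p, center = center)
  pipe_log(cfg, "features", "volume %.1f, sigma (%.2f %.2f %.2f), %s = %.2f",
           volume, size[1], size[2], size[3], cfg$scale_method, sf)

  unit <- center_and_scale(mesh, sf, center = center)
  cache <- build_coefficient_cache(cfg$moment_order)
  zcdv <- normalize_zcdv(zc_descriptors(zc_moments(
    geometric_moments(unit, cfg$moment_order, cache), cache)))
  pipe_log(cfg, "zc", "order %d, %d descriptors", cfg$moment_order,
           length(zcdv$values))

  protein_features(zcdv, hist, size, volume, metadata = list(
    id = id, selection = selection, surface_mode = cfg$surface_mode,
    scale_method = cfg$scale_method,
    scale_factor = attr(unit, "effective_factor"),
    guide_count = sum(guide), outlier_count = sum(!guide),
    moment_order = cfg$moment_order))
}

#' Rank a feature database against a query
#'
#' Computes the configured distance from the query to every database entry
#' (linear time in the database size), sorts ascending, and flags entries
#' below the similarity threshold with their tier.
#'
#' @param query a [protein_features].
#' @param database non-empty list of [protein_features].
#' @param cfg a [distance_config].
#' @param threshold similarity threshold (default 0.5).
#' @return data frame with `id`, `distance`, `tier`, `similar`, sorted by
#'   distance.
#' @export
retrieve <- function(query, database, cfg = distance_config(),
                     threshold = 0.5) {
  if (length(database) == 0) stop("retrieve: empty database")
  d <- vapply(database, function(f) combined_distance(query, f, cfg), 0)
  ids <- vapply(seq_along(database), function(i) {
    id <- database[[i]]$metadata$id
    if (is.null(id)) as.character(i) else as.character(id)
  }, "")
  tier <- vapply(d, function(x) similarity_tier(x)$index, 0L)
  out <- data.frame(id = ids, distance = d, tier = tier,
                    similar = d < threshold, stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Benchmark retrieval on a directory suite
#'
#' Each subdirectory of `root` holds the structures of one class (for
#' proteins: one domain superfamily); pairs from the same directory are the
#' positives. Features are computed for every `.pdb` and `.obj` file (OBJ
#' meshes take the mesh-only route), the pairwise distances are evaluated
#' for each requested metric, and ROC curves with tier-boundary operating
#' points summarise the discrimination ability. Per-file failures are
#' skipped with a warning and counted.
#'
#' @param root suite directory with >= 2 class subdirectories.
#' @param cfg a [pipeline_config].
#' @param metrics distance metrics to evaluate (default all five).
#' @return a `benchmark_report`: list with `labels`, `files`,
#'   `pair_counts`, `failures`, and per-metric `auroc`, `roc`,
#'   `tier_points`.
#' @export
benchmark_suite <- function(root, cfg = pipeline_config(),
                            metrics = c("z", "zd", "zds", "zdv", "zdsv")) {
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) < 2) {
    stop("benchmark_suite: need at least 2 class directories under ", root)
  }
  feats <- list(); labels <- character(0); files <- character(0)
  failures <- 0L
  for (d in dirs) {
    for (f in list.files(d, pattern = "\\.(pdb|obj)$", full.names = TRUE)) {
      ft <- tryCatch({
        if (grepl("\\.obj$", f)) {
          run_descriptor_pipeline(mesh = read_obj(f), cfg = cfg,
                                  id = basename(f))
        } else {
          run_descriptor_pipeline(pdb_path = f, cfg = cfg)
        }
      }, error = function(e) {
        warning("benchmark_suite: skipping ", f, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(ft)) { failures <- failures + 1L; next }
      feats[[length(feats) + 1L]] <- ft
      labels <- c(labels, basename(d))
      files <- c(files, f)
    }
  }
  if (length(unique(labels)) < 2) {
    stop("benchmark_suite: fewer than 2 classes produced features")
  }
  n <- length(feats)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  pair_lab <- labels[pair_i] == labels[pair_j]
  per_metric <- list()
  for (m in metrics) {
    dcfg <- cfg$distance; dcfg$metric <- m
    pm <- pairwise_matrix(feats, dcfg)
    pd <- pm[cbind(pair_i, pair_j)]
    roc <- roc_curve(pair_lab, pd)
    per_metric[[m]] <- list(auroc = roc$auroc, roc = roc,
                            tier_points = tier_operating_points(pair_lab,
                                                                pd),
                            distances = pd)
  }
  structure(list(labels = labels, files = files,
                 pair_counts = label_pair_counts(labels),
                 failures = failures, metrics = per_metric,
                 features = feats,
                 pairs = data.frame(i = pair_i, j = pair_j,
                                    positive = pair_lab)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: %d structures, %d classes, %d failures\n",
              length(x$labels), length(unique(x$labels)), x$failures))
  for (m in names(x$metrics)) {
    cat(sprintf("  %-5s AUROC %.4f\n", m, x$metrics[[m]]$auroc))
  }
  invisible(x)
}

#' Export benchmark results
#'
#' `write_benchmark_json` writes the per-metric AUROCs, tier operating
#' points and pair counts; `write_pairwise_tsv` writes one row per
#' unordered pair with all distance components and the similarity tier;
#' `write_roc_tsv` writes the ROC points of one metric.
#'
#' @param report a `benchmark_report`.
#' @param path output path.
#' @export
write_benchmark_json <- function(report, path) {
  doc <- list(
    schema = "zcmesh/benchmark/1",
    structures = length(report$labels),
    classes = length(unique(report$labels)),
    failures = report$failures,
    pair_counts = report$pair_counts,
    metrics = lapply(report$metrics, function(m) {
      list(auroc = m$auroc, tier_points = m$tier_points)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_benchmark_json
#' @param features list of [protein_features].
#' @param cfg a [distance_config].
#' @export
write_pairwise_tsv <- function(features, cfg, path) {
  n <- length(features)
  rows <- list()
  ids <- vapply(seq_len(n), function(i) {
    id <- features[[i]]$metadata$id
    if (is.null(id)) as.character(i) else as.character(id)
  }, "")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sd <- shape_distances(features[[i]], features[[j]], cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j], delta_z = sd$z, delta_d = sd$d,
      delta_s = sd$s, delta_v = sd$v, value = sd$value,
      tier = similarity_tier(sd$value)$index, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_benchmark_json
#' @param metric which metric's ROC points to write.
#' @export
write_roc_tsv <- function(report, metric, path) {
  roc <- report$metrics[[metric]]$roc
  utils::write.table(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
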