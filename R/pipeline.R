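#' Run the full RNA-chromatin landscape pipeline
#'
#' Wires the stages into one reproducible run: read inputs, annotate
#' contacts (gene + class + locality), compute the class landscape and
#' per-gene profiles, call trans-acting RNAs, export interaction maps for
#' the top-ranked genes, and — when signal tracks and a region set are
#' configured — build the mark-enrichment matrix and its C1..Ck
#' clustering. All stage outputs are written under `out_dir` together with
#' a JSON manifest recording the config, input checksums, seed, package
#' version and the count reconciliation (pairs in = annotated out,
#' cis + trans = total).
#'
#' @param config A named list or path to a YAML file. Required keys:
#'   `pairs`, `gtf`, `chrom_sizes`, `out_dir`. Optional: `regions`,
#'   `tracks` (named list mark -> bedGraph path), `track_bin_size` (default
#'   1000), `min_contacts` (10), `min_trans_fraction` (0.2), `priority`
#'   (character vector), `k` (4), `seed` (7), `labeling_mark` ("H3K27ac"),
#'   `map_bin_size` (1e6), `top_n_maps` (5), `allow_antisense` (FALSE),
#'   `swap_sides` (FALSE).
#' @return The run manifest (a list), invisibly. Errors are signalled as
#'   condition class `carna_validation_error` (bad config) or
#'   `carna_stage_error` (a stage failed; the condition names the stage).
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      validation_error("config file not found: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "carna",
    version = as.character(utils::packageVersion("carna")),
    seed = cfg$seed,
    config = lapply(cfg[setdiff(names(cfg), "out_dir")], unclass),
    inputs = input_checksums(cfg),
    counts = list(),
    outputs = character()
  )

  assembly <- run_stage("read_assembly", read_chrom_sizes(cfg$chrom_sizes))
  genes <- run_stage("read_annotation",
                     read_gene_annotation(cfg$gtf, assembly))
  pairs <- run_stage("read_pairs",
                     read_pairs(cfg$pairs, assembly,
                                swap_sides = cfg$swap_sides))
  ann <- run_stage("annotate",
                   annotate_contacts(pairs, build_gene_index(genes),
                                     priority = cfg$priority,
                                     allow_antisense = cfg$allow_antisense))
  land <- run_stage("landscape", class_landscape(ann))
  prof <- run_stage("profiles", gene_profiles(ann))
  calls <- run_stage("trans_acting",
                     call_trans_acting(prof, cfg$min_contacts,
                                       cfg$min_trans_fraction))

  out <- function(name) file.path(cfg$out_dir, name)
  write_annotated(ann, out("annotated.tsv"))
  write_landscape_tsv(land, out("landscape.tsv"))
  write_table_tsv(prof, out("profiles.tsv"))
  write_table_tsv(calls, out("trans_acting.tsv"))
  manifest$outputs <- c("annotated.tsv", "landscape.tsv", "profiles.tsv",
                        "trans_acting.tsv")

  top <- utils::head(calls$gene_id, cfg$top_n_maps)
  if (length(top)) {
    dir.create(out("maps"), showWarnings = FALSE)
    for (g in top) {
      m <- run_stage("interaction_map",
                     interaction_map(g, ann, genes, assembly,
                                     cfg$map_bin_size))
      write_interaction_map(m, out(file.path("maps", paste0(g, ".tsv"))))
      manifest$outputs <- c(manifest$outputs,
                            file.path("maps", paste0(g, ".tsv")))
    }
  }

  if (!is.null(cfg$tracks) && !is.null(cfg$regions)) {
    regions <- run_stage("read_regions", read_bed(cfg$regions, assembly))
    tracks <- run_stage("read_tracks", lapply(
      cfg$tracks, read_signal_bedgraph, assembly = assembly,
      bin_size = cfg$track_bin_size))
    em <- run_stage("score_regions", score_regions(regions, tracks))
    cl <- run_stage("cluster_regions",
                    cluster_regions(em, k = cfg$k, seed = cfg$seed,
                                    labeling_mark = cfg$labeling_mark))
    mat <- data.frame(regions[, c("chrom", "start", "end", "name")],
                      em$scores, cluster = as.character(cl$labels),
                      stringsAsFactors = FALSE)
    write_table_tsv(mat, out("overlay_matrix.tsv"))
    manifest$outputs <- c(manifest$outputs, "overlay_matrix.tsv")
    manifest$counts$n_regions <- nrow(regions)
    manifest$counts$cluster_sizes <- as.list(table(cl$labels))
  }

  # reconciliation: every pair read must come out annotated, and the
  # locality partition must be exact
  manifest$counts$n_pairs <- nrow(pairs)
  manifest$counts$n_skipped_records <- attr(pairs, "skipped")
  manifest$counts$n_annotated_out <- nrow(ann)
  manifest$counts$n_cis <- land$n_cis
  manifest$counts$n_trans <- land$n_trans
  manifest$counts$n_unannotated <- land$n_unannotated
  manifest$counts$n_genes <- nrow(genes)
  manifest$counts$n_trans_acting <- nrow(calls)
  manifest$counts$reconciliation_ok <-
    nrow(ann) == nrow(pairs) && land$n_cis + land$n_trans == nrow(pairs)
  if (!manifest$counts$reconciliation_ok) {
    stage_error("reconciliation",
                "pairs in != annotated out; pipeline is dropping records")
  }
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

validation_error <- function(...) {
  stop(structure(class = c("carna_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stage_error <- function(stage, msg) {
  stop(structure(class = c("carna_stage_error", "error", "condition"),
                 list(message = paste0("stage '", stage, "' failed: ", msg),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "carna_stage_error")) stop(e)
    stage_error(stage, conditionMessage(e))
  })
}

validate_config <- function(config) {
  if (!is.list(config)) validation_error("config must be a list")
  for (key in c("pairs", "gtf", "chrom_sizes", "out_dir")) {
    if (is.null(config[[key]])) {
      validation_error("config is missing required key '", key, "'")
    }
  }
  for (key in c("pairs", "gtf", "chrom_sizes", "regions")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      validation_error("config path does not exist: ", key, " = ", p)
    }
  }
  if (!is.null(config$tracks)) {
    if (is.null(names(config$tracks))) {
      validation_error("tracks must be a named list (mark -> path)")
    }
    missing <- !vapply(config$tracks, file.exists, TRUE)
    if (any(missing)) {
      validation_error("track file does not exist: ",
                       config$tracks[[which(missing)[1L]]])
    }
  }
  defaults <- list(min_contacts = 10, min_trans_fraction = 0.2,
                   priority = class_priority(), k = 4, seed = 7,
                   labeling_mark = "H3K27ac", map_bin_size = 1e6,
                   top_n_maps = 5, allow_antisense = FALSE,
                   swap_sides = FALSE, track_bin_size = 1000)
  for (key in names(defaults)) {
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  }
  if (!inherits(config$priority, "class_priority")) {
    config$priority <- class_priority(as.character(config$priority))
  }
  config
}

input_checksums <- function(cfg) {
  paths <- c(pairs = cfg$pairs, gtf = cfg$gtf,
             chrom_sizes = cfg$chrom_sizes)
  if (!is.null(cfg$regions)) paths <- c(paths, regions = cfg$regions)
  if (!is.null(cfg$tracks)) {
    tp <- unlist(cfg$tracks)
    names(tp) <- paste0("track_", names(cfg$tracks))
    paths <- c(paths, tp)
  }
  as.list(tools::md5sum(paths))
}

write_table_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_landscape_tsv <- function(land, path) {
  tab <- land$classes
  tab$global_cis_fraction <- land$global_cis_fraction
  tab$n_unannotated <- land$n_unannotated
  write_table_tsv(tab, path)
}
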