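# End-to-end pipeline: enumerate -> relax/annotate -> deduplicate ->
# summarize, with per-stage manifests and idempotent resume.  Each stage
# writes its outputs plus a manifest recording the configuration hash; a
# stage whose manifest matches the current configuration is skipped on
# rerun.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis with defaults equal to the
#' study's printed values where one exists.  Serializes to/from JSON
#' round-trip stably.
#'
#' @param sequence heptapeptide sequence.
#' @param phi_psi_step,chi_values,free,frozen grid parameters
#'   (see [grid_spec()]).
#' @param fe_sg_max,cb_sg_fe_angle_range,lj_max screen parameters
#'   (see [filter_criteria()]).
#' @param hbond hydrogen-bond criteria as a list of [hbond_criteria()]
#'   arguments.
#' @param relax_cycles,relax_tol relaxation settings used for ensemble
#'   annotation.
#' @param dedup_threshold leader-clustering radius, Angstrom.
#' @param mode,n_sample,seed enumeration mode settings.
#' @param out_dir run directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(sequence = "CGGCGGC", phi_psi_step = 60,
                       chi_values = c(-180, -60, 60),
                       free = c(setdiff(torsion_names(), c("chi2", "chi3")),
                                "chi2"),
                       frozen = c(chi3 = -180),
                       fe_sg_max = 3.0, cb_sg_fe_angle_range = c(120, 180),
                       lj_max = 0,
                       hbond = list(), relax_cycles = 400, relax_tol = 1e-2,
                       dedup_threshold = 0.5,
                       mode = "pruned", n_sample = NULL, seed = NULL,
                       out_dir = "ferrotopo_run") {
  structure(list(sequence = sequence, phi_psi_step = phi_psi_step,
                 chi_values = chi_values, free = free, frozen = as.list(frozen),
                 fe_sg_max = fe_sg_max,
                 cb_sg_fe_angle_range = cb_sg_fe_angle_range, lj_max = lj_max,
                 hbond = hbond, relax_cycles = relax_cycles,
                 relax_tol = relax_tol, dedup_threshold = dedup_threshold,
                 mode = mode, n_sample = n_sample, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a pipeline configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `read_config` returns the `run_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$frozen <- as.list(raw$frozen)
  if (!is.null(raw$hbond)) raw$hbond <- as.list(raw$hbond)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # relocating a run directory must not invalidate it
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

isTRUE_vec <- function(x) !is.na(x) & x

stage_done <- function(dir, hash) {
  mf <- file.path(dir, "stage_manifest.json")
  file.exists(mf) &&
    identical(jsonlite::read_json(mf)$config_hash, hash)
}

write_stage_manifest <- function(dir, hash, info = list()) {
  jsonlite::write_json(c(list(config_hash = hash,
                              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         info),
                       file.path(dir, "stage_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: `enumerate` (grid screen), `annotate` (relax each survivor and
#' measure topology, hydrogen bonds, stabilization energy), `dedup`
#' (leader clustering of relaxed survivors) and `summarize` (class counts,
#' histograms, scatter tables).  Each stage writes TSV/JSON outputs and a
#' manifest into its subdirectory of `config$out_dir`; rerunning with an
#' identical configuration skips completed stages, so deleting one stage's
#' directory re-executes only that stage and those after it depend on it.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list with `survivors` (annotated, with cluster assignment and
#'   `representative` flag), `summary` (an `ensemble_summary`), and
#'   `run_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  rd <- config$out_dir
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(rd, "config.json"))
  spec <- grid_spec(config$sequence, config$phi_psi_step, config$chi_values,
                    free = config$free,
                    frozen = unlist(config$frozen))
  criteria <- filter_criteria(config$fe_sg_max, config$cb_sg_fe_angle_range,
                              config$lj_max)
  hb <- do.call(hbond_criteria, config$hbond)

  # ---- enumerate ---------------------------------------------------------
  d1 <- file.path(rd, "enumerate")
  if (!stage_done(d1, hash)) {
    if (verbose) message("stage enumerate ...")
    dir.create(d1, showWarnings = FALSE)
    res <- run_enumeration(spec, criteria, mode = config$mode,
                           n_sample = config$n_sample, seed = config$seed,
                           out_dir = d1, verbose = verbose)
    write_stage_manifest(d1, hash, list(n_survivors = nrow(res$survivors)))
  }
  survivors <- utils::read.table(file.path(d1, "survivors.tsv"), sep = "\t",
                                 header = TRUE)

  # ---- annotate ----------------------------------------------------------
  d2 <- file.path(rd, "annotate")
  if (!stage_done(d2, hash)) {
    if (verbose) message("stage annotate ...")
    dir.create(d2, showWarnings = FALSE)
    ann <- annotate_survivors(survivors, config$sequence, relax = TRUE,
                              relax_cycles = config$relax_cycles,
                              relax_tol = config$relax_tol, criteria = hb)
    utils::write.table(ann, file.path(d2, "annotated.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_stage_manifest(d2, hash)
  }
  ann <- utils::read.table(file.path(d2, "annotated.tsv"), sep = "\t",
                           header = TRUE)

  # ---- dedup -------------------------------------------------------------
  # Duplicates arise when distinct grid states minimize onto one structure,
  # so clustering applies to the relaxed subset from the annotate stage;
  # unrelaxed survivors are distinct grid states and stay singletons.
  d3 <- file.path(rd, "dedup")
  if (!stage_done(d3, hash)) {
    if (verbose) message("stage dedup ...")
    dir.create(d3, showWarnings = FALSE)
    relaxed_rows <- which(isTRUE_vec(ann$relaxed))
    cluster <- integer(nrow(ann))
    representative <- rep(TRUE, nrow(ann))
    if (length(relaxed_rows) > 1L) {
      xyz <- lapply(relaxed_rows, function(r) {
        v <- as.numeric(ann[r, torsion_names()])
        cx <- build_complex(config$sequence, vector_to_state(v))
        relax_complex(cx, max_cycles = config$relax_cycles,
                      grad_rms_tol = config$relax_tol)$complex
      })
      dd <- deduplicate_conformations(xyz, config$dedup_threshold)
      cluster[relaxed_rows] <- dd$assignment
      representative[relaxed_rows] <-
        seq_along(relaxed_rows) %in% dd$representatives
    }
    singletons <- which(cluster == 0L)
    cluster[singletons] <- max(cluster) + seq_along(singletons)
    utils::write.table(data.frame(index = ann$index, cluster = cluster,
                                  representative = representative),
                       file.path(d3, "clusters.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_stage_manifest(d3, hash,
                         list(n_clusters = length(unique(cluster))))
  }
  dd <- utils::read.table(file.path(d3, "clusters.tsv"), sep = "\t",
                          header = TRUE)
  ann$cluster <- dd$cluster[match(ann$index, dd$index)]
  ann$representative <- dd$representative[match(ann$index, dd$index)]

  # ---- summarize ---------------------------------------------------------
  d4 <- file.path(rd, "summarize")
  if (!stage_done(d4, hash)) {
    if (verbose) message("stage summarize ...")
    dir.create(d4, showWarnings = FALSE)
    summarize_ensemble(ann[ann$representative, , drop = FALSE], out_dir = d4)
    utils::write.table(ann, file.path(d4, "survivors_full.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_stage_manifest(d4, hash)
  }
  summary <- summarize_ensemble(ann[ann$representative, , drop = FALSE])
  list(survivors = ann, summary = summary, run_dir = rd)
}
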