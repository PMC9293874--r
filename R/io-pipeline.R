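# Session layout on disk, NIfTI/TSV round-trips, and the end-to-end pipeline.

#' Save a synthetic subject to a session directory
#'
#' Layout: `subject/<run>/{bold.nii.gz, events.tsv, physio_cardiac.tsv,
#' physio_resp.tsv, motion.tsv}` plus subject-level `compartments.nii.gz`,
#' `groundtruth.json` (synthetic parameters) and `meta.json`.
#'
#' @param subject an `nf_subject`.
#' @param path subject directory (created if missing).
#' @return `path`, invisibly.
#' @export
save_subject <- function(subject, path) {
  stopifnot(inherits(subject, "nf_subject"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  geom <- subject$geometry
  nii_write <- function(arr, file) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(geom$affine, code = 2L))
    RNifti::writeNifti(img, file)
  }
  nii_write(geom$compartments + 0, file.path(path, "compartments.nii.gz"))
  gt <- subject$ground_truth
  class(gt) <- NULL
  jsonlite::write_json(gt, file.path(path, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(id = subject$id, seed = subject$seed,
               voxel_size = geom$voxel_size, dim = geom$dim,
               roi_center = geom$roi$center, roi_radius = geom$roi$radius,
               effect_margin_mm = geom$effect_margin_mm,
               runs = lapply(subject$runs, function(r) list(
                 run_type = attr(r$schedule, "run_type"),
                 tr = attr(r$schedule, "tr"),
                 n_dummy = attr(r$schedule, "n_dummy"),
                 n_volumes = attr(r$schedule, "n_volumes"))))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (run in names(subject$runs)) {
    rr <- subject$runs[[run]]
    rd <- file.path(path, run)
    dir.create(rd, showWarnings = FALSE)
    nii_write(rr$volumes$data, file.path(rd, "bold.nii.gz"))
    write_events(rr$schedule, file.path(rd, "events.tsv"))
    readr::write_tsv(rr$physio[, c("time", "cardiac")],
                     file.path(rd, "physio_cardiac.tsv"), progress = FALSE)
    readr::write_tsv(rr$physio[, c("time", "resp")],
                     file.path(rd, "physio_resp.tsv"), progress = FALSE)
    readr::write_tsv(rr$motion, file.path(rd, "motion.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' Load a saved session back into an `nf_subject`
#'
#' Performs dimensional consistency checks: motion rows must equal retained
#' volumes, and the physiological recording must cover the full run; any
#' mismatch names the file and both counts.
#'
#' @param path subject directory written by [save_subject()].
#' @return an `nf_subject` (ground truth restored from the sidecar).
#' @export
load_session <- function(path) {
  need <- function(f) {
    if (!file.exists(f)) stop("missing session file: ", f)
    f
  }
  meta <- jsonlite::read_json(need(file.path(path, "meta.json")),
                              simplifyVector = TRUE)
  gt <- jsonlite::read_json(need(file.path(path, "groundtruth.json")),
                            simplifyVector = TRUE)
  truth <- do.call(ground_truth, gt[names(gt) %in% names(formals(ground_truth))])
  comp_img <- RNifti::readNifti(need(file.path(path, "compartments.nii.gz")))
  geom <- default_geometry(dim(comp_img)[1],
                           as.numeric(meta$voxel_size)[1],
                           as.numeric(meta$roi_center),
                           as.numeric(meta$roi_radius),
                           as.numeric(meta$effect_margin_mm))
  if (!identical(array(as.integer(comp_img), dim(comp_img)),
                 geom$compartments))
    stop(file.path(path, "compartments.nii.gz"),
         ": compartment labels do not match the reconstructed geometry")
  runs <- list()
  for (run in names(meta$runs)) {
    rd <- file.path(path, run)
    rm_ <- meta$runs[[run]]
    sched <- read_events(need(file.path(rd, "events.tsv")), rm_$run_type,
                         tr = rm_$tr, n_dummy = rm_$n_dummy)
    bold <- RNifti::readNifti(need(file.path(rd, "bold.nii.gz")))
    card <- readr::read_tsv(need(file.path(rd, "physio_cardiac.tsv")),
                            show_col_types = FALSE, progress = FALSE)
    resp <- readr::read_tsv(need(file.path(rd, "physio_resp.tsv")),
                            show_col_types = FALSE, progress = FALSE)
    motion <- readr::read_tsv(need(file.path(rd, "motion.tsv")),
                              show_col_types = FALSE, progress = FALSE)
    n_ret <- attr(sched, "n_volumes")
    if (nrow(motion) != n_ret)
      stop(file.path(rd, "motion.tsv"), ": expected ", n_ret,
           " rows (retained volumes), found ", nrow(motion))
    run_dur <- n_ret * rm_$tr
    if (max(card$time) < run_dur - PHYSIO_DT - 1e-9)
      stop(file.path(rd, "physio_cardiac.tsv"), ": covers ",
           max(card$time), " s but the run lasts ", run_dur, " s")
    if (nrow(card) != nrow(resp))
      stop(rd, ": cardiac and respiratory clocks differ in length (",
           nrow(card), " vs ", nrow(resp), ")")
    runs[[run]] <- list(
      schedule = sched,
      volumes = volume_series(array(as.numeric(bold), dim(bold)), geom,
                              tr = rm_$tr, n_dummy = rm_$n_dummy),
      physio = physio_recording(card$cardiac, resp$resp),
      motion = motion)
  }
  structure(list(id = meta$id, runs = runs, geometry = geom,
                 ground_truth = truth, seed = meta$seed),
            class = "nf_subject")
}

#' Pipeline configuration
#'
#' @param n_subjects cohort size.
#' @param runs task runs to simulate and analyze.
#' @param grid_n simulation grid size per axis.
#' @param seed master seed.
#' @param truth [ground_truth()] parameters.
#' @param coupling optional PPI coupling, `list(base =, gain =)`.
#' @return list of class `nf_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 6,
                            runs = c("OBS", "NF1", "NF2", "NF3", "TRS"),
                            grid_n = 16, seed = 1,
                            truth = ground_truth(), coupling = NULL) {
  structure(list(n_subjects = n_subjects, runs = runs, grid_n = grid_n,
                 seed = seed, truth = truth, coupling = coupling),
            class = "nf_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `n_subjects`, `runs`, `grid_n`, `seed`, `coupling`
#' (mapping with `base`/`gain`), and a `truth` mapping whose entries override
#' [ground_truth()] defaults.
#'
#' @param path YAML file.
#' @return an `nf_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr_args <- y$truth %||% list()
  cfg <- pipeline_config(
    n_subjects = y$n_subjects %||% 6,
    runs = unlist(y$runs) %||% c("OBS", "NF1", "NF2", "NF3", "TRS"),
    grid_n = y$grid_n %||% 16,
    seed = y$seed %||% 1,
    truth = do.call(ground_truth, tr_args),
    coupling = y$coupling)
  cfg
}

#' Run the end-to-end pipeline
#'
#' simulate -> real-time processing -> feedback -> offline GLM -> group
#' statistics, fully deterministic under the master seed. Per-run ROI percent
#' signal change (Focus-Describe contrast) feeds one-sample t-tests, the
#' mixed-model run comparison with Tukey follow-ups, and ICC(3,k); a PPI
#' analysis over the coupling box summarizes connectivity recovery.
#'
#' @param config an [pipeline_config()] (or path to a YAML file).
#' @return list of class `nf_report`: `psc` (subject x run tibble),
#'   `one_sample` (per-run t table), `lme` (`nf_lme`), `tukey`, `icc`,
#'   `feedback` (per subject/run mean late-Focus bar height), `ppi`
#'   (per-subject mean PPI t over the coupling box, if coupling enabled),
#'   and a `provenance` attribute (seed, config hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "nf_pipeline_config"))
  geom <- default_geometry(config$grid_n)
  schedules <- lapply(stats::setNames(config$runs, config$runs),
                      build_run_schedule)
  cohort <- generate_cohort(config$n_subjects, schedules, geom,
                            config$truth, config$seed,
                            coupling = config$coupling)
  psc <- list()
  fb <- list()
  ppi_rows <- list()
  cv <- coupling_voxels(geom)
  for (s in cohort) {
    for (run in config$runs) {
      rt <- run_realtime(s, run, geom$roi)
      prep <- preprocess_offline(s, run)
      fit <- fit_offline_glm(prep)
      psc[[length(psc) + 1]] <- tibble::tibble(
        subject = s$id, run = run, measure = "psc",
        value = extract_roi_psc(fit, geom$roi))
      if (run %in% c("NF1", "NF2", "NF3")) {
        tr_fb <- feedback_trace(rt)
        late <- !is.na(tr_fb$bar) & !is.na(tr_fb$within) & tr_fb$within >= 5
        fb[[length(fb) + 1]] <- tibble::tibble(
          subject = s$id, run = run, mean_late_bar = mean(tr_fb$bar[late]))
      }
      if (!is.null(config$coupling) && run == "NF1") {
        sel <- match(cv, prep$vox_keep)
        sel <- sel[!is.na(sel)]
        dl <- prep$drop_lead
        mot_rows <- as.matrix(prep$motion)
        if (dl > 0) mot_rows <- mot_rows[-seq_len(dl), , drop = FALSE]
        nuis <- cbind(mot_rows, legendre_basis(nrow(prep$series), 4))
        roi_idx <- roi_voxels(geom$roi, geom$dim, geom$affine)
        roi_sel <- match(intersect(roi_idx, prep$vox_keep), prep$vox_keep)
        fd_rows <- if (dl > 0) prep$fd[-seq_len(dl)] else prep$fd
        pp <- run_ppi(prep$series[, sel, drop = FALSE],
                      rowMeans(prep$series[, roi_sel, drop = FALSE]),
                      prep$schedule, nuis, fd = fd_rows, drop_lead = dl)
        ppi_rows[[length(ppi_rows) + 1]] <- tibble::tibble(
          subject = s$id, run = run, mean_ppi_t = mean(pp$t))
      }
    }
  }
  psc <- dplyr::bind_rows(psc)
  ages <- withr::with_seed(config$seed + 7L,
                           tibble::tibble(
                             subject = unique(psc$subject),
                             age = sample(13:17, config$n_subjects, TRUE),
                             sex = sample(c("F", "M"), config$n_subjects,
                                          TRUE)))
  psc <- dplyr::left_join(psc, ages, by = "subject")
  one_sample <- psc |>
    dplyr::group_by(.data$run) |>
    dplyr::reframe(one_sample_t(.data$value))
  lme <- lme_condition(psc)
  tk <- tukey_pairwise(lme)
  wide <- tidyr::pivot_wider(psc[, c("subject", "run", "value")],
                             names_from = "run", values_from = "value")
  icc <- icc3k(as.matrix(wide[, -1]))
  report <- list(psc = psc, one_sample = one_sample, lme = lme, tukey = tk,
                 icc = icc,
                 feedback = if (length(fb)) dplyr::bind_rows(fb) else NULL,
                 ppi = if (length(ppi_rows)) dplyr::bind_rows(ppi_rows)
                 else NULL)
  structure(report,
            provenance = list(seed = config$seed,
                              config_hash = rlang::hash(config),
                              package_version =
                                as.character(utils::packageVersion("rtnf")),
                              created = "run_pipeline"),
            class = "nf_report")
}

#' Write the pipeline report as delimited tables
#'
#' Each table gains provenance columns (seed, config hash, package version).
#'
#' @param report an `nf_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "nf_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- attr(report, "provenance")
  stamp <- function(d) dplyr::mutate(d, seed = prov$seed,
                                     config_hash = prov$config_hash,
                                     package_version = prov$package_version)
  readr::write_tsv(stamp(report$psc), file.path(dir, "roi_psc.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(report$one_sample), file.path(dir, "one_sample.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(report$lme$anova), file.path(dir, "lme_anova.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(report$tukey), file.path(dir, "tukey.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(report$icc), file.path(dir, "icc.tsv"),
                   progress = FALSE)
  if (!is.null(report$feedback))
    readr::write_tsv(stamp(report$feedback), file.path(dir, "feedback.tsv"),
                     progress = FALSE)
  if (!is.null(report$ppi))
    readr::write_tsv(stamp(report$ppi), file.path(dir, "ppi.tsv"),
                     progress = FALSE)
  invisible(dir)
}
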