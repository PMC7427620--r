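#' Pipeline run configuration
#'
#' Validated bundle of every option of an end-to-end run.  The validated
#' configuration is written verbatim into the result's provenance record.
#'
#' @param input an [eeg_epochs] object or the path of an epoch text file.
#' @param reference re-reference target (`"AVG"`, `"A1A2"`, a channel
#'   label, or `NULL` to keep the recording reference).
#' @param gsf logical: estimate and remove the Global Scale Factor
#'   (requires scalp norms).
#' @param fmax_hz upper frequency limit of the analysis grid.
#' @param taper `"none"` or `"hann"`.
#' @param bands a [default_bands()]-style band set.
#' @param montage an [eeg_montage] or built-in name, for the lead field and
#'   topographic export.
#' @param leadfield a [lead_field], or `"spherical"` to build one from the
#'   montage, or `NULL` to skip source analysis.
#' @param lambda ridge penalty: a number, or `"gcv"`.
#' @param scalp_norms,source_norms [norm_model] objects or norms-file
#'   paths; `NULL` skips the corresponding z-scoring stage.
#' @param age subject age override (default: taken from the epochs).
#' @param alpha nominal family-wise error level for the corrected
#'   threshold.
#' @param correction `"maxstat-iid"`, `"maxstat-empirical"` (needs norms
#'   fitted with retained residual fields) or `"none"`.
#' @param seed integer seed recorded and set before any stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, reference = "AVG", gsf = TRUE,
                       fmax_hz = 19.5, taper = "none",
                       bands = default_bands(), montage = "10-20-19",
                       leadfield = "spherical", lambda = "gcv",
                       scalp_norms = NULL, source_norms = NULL,
                       age = NULL, alpha = 0.05,
                       correction = c("maxstat-iid", "maxstat-empirical", "none"),
                       seed = 1L) {
  correction <- match.arg(correction)
  if (is.character(montage)) montage <- load_montage(montage)
  if (is.character(scalp_norms)) scalp_norms <- read_norms(scalp_norms)
  if (is.character(source_norms)) source_norms <- read_norms(source_norms)
  if (gsf && is.null(scalp_norms))
    stop("GSF correction requires scalp norms", call. = FALSE)
  structure(list(input = input, reference = reference, gsf = gsf,
                 fmax_hz = fmax_hz, taper = taper, bands = bands,
                 montage = montage, leadfield = leadfield, lambda = lambda,
                 scalp_norms = scalp_norms, source_norms = source_norms,
                 age = age, alpha = alpha, correction = correction,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stop <- function(stage, code, msg)
  stop(sprintf("[stage %s | %s] %s", stage, code, msg), call. = FALSE)

#' Run the full quantitative EEG pipeline
#'
#' Executes, in order: reading/re-referencing, FFT and epoch-averaged
#' cross-spectra, narrow-band power, coherence and phase, broad-band
#' parameters, Global Scale Factor correction, the ridge source inverse,
#' z-scoring of scalp and source log spectra against age norms, and the
#' corrected maximum-statistic threshold.  Stages whose inputs are not
#' configured (no lead field, no norms) are skipped with a logged notice.
#' Identical configuration, inputs and seed give an identical bundle.
#'
#' @param cfg a [run_config].
#' @param quiet suppress stage messages.
#' @return An object of class `qeeg_result` with elements `nb` (raw scalp
#'   spectra), `nb_log`, `broadband`, `coherence`, `gsf`, `source` (raw
#'   source spectra), `z_scalp`, `z_source`, `threshold`, and `provenance`.
#' @export
run_pipeline <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  note <- function(...) if (!quiet) message(sprintf(...))
  set.seed(cfg$seed)

  e <- cfg$input
  if (is.character(e)) e <- read_epochs_text(e)
  if (!inherits(e, "eeg_epochs"))
    pipeline_stop("read", "E_INPUT", "input must be eeg_epochs or a file path")
  age <- cfg$age %||% e$subject$age

  if (!is.null(cfg$reference)) e <- rereference(e, cfg$reference)
  else note("stage reference: skipped (keeping recording reference)")

  grid <- build_frequency_grid(n_samples(e), e$fs, cfg$fmax_hz)
  cs <- cross_spectrum(e, grid, taper = cfg$taper)
  nb <- narrowband_power(cs)
  cp <- coherence_phase(cs)
  bb <- broadband_params(nb, cfg$bands)
  nb_log <- transform_spectra(nb)

  g <- NULL
  if (cfg$gsf) {
    mu <- evaluate_norm(cfg$scalp_norms, age)$mu
    y <- align_locations(nb_log$power, cfg$scalp_norms$locations)
    g <- estimate_gsf(y, mu)
    nb_log$power <- nb_log$power - g$log10_value
    note("stage gsf: log10 factor %.4f removed", g$log10_value)
  } else note("stage gsf: skipped")

  src <- NULL; op <- NULL
  if (!is.null(cfg$leadfield)) {
    lf <- cfg$leadfield
    if (identical(lf, "spherical")) {
      mt <- align_montage(cfg$montage, e$channel_labels)
      lf <- spherical_leadfield(mt)
    }
    lam <- cfg$lambda
    if (identical(lam, "gcv")) lam <- as.numeric(select_lambda_gcv(lf, e, grid))
    op <- ridge_inverse_operator(lf, lam)
    src <- source_spectra(op, cs)
    src_log <- transform_spectra(src)
    if (cfg$gsf) src_log$power <- src_log$power - g$log10_value
  } else note("stage inverse: skipped (no lead field)")

  z_scalp <- NULL
  if (!is.null(cfg$scalp_norms)) z_scalp <- z_score(nb_log, cfg$scalp_norms, age)
  else note("stage z-scalp: skipped (no scalp norms)")
  z_source <- NULL
  if (!is.null(cfg$source_norms) && !is.null(src))
    z_source <- z_score(src_log, cfg$source_norms, age)
  else note("stage z-source: skipped")

  thr <- NULL
  if (cfg$correction != "none" && !is.null(z_scalp)) {
    thr <- switch(cfg$correction,
      "maxstat-iid" = max_stat_threshold_iid(length(z_scalp$z), cfg$alpha),
      "maxstat-empirical" = {
        rz <- cfg$scalp_norms$residual_z
        if (is.null(rz))
          pipeline_stop("threshold", "E_NO_RESIDUALS",
                        "empirical correction needs norms fitted with keep_residual_fields = TRUE")
        max_stat_threshold_empirical(rz, cfg$alpha)
      })
    z_scalp <- apply_threshold(z_scalp, thr)
    if (!is.null(z_source)) {
      thr_src <- if (cfg$correction == "maxstat-iid")
        max_stat_threshold_iid(length(z_source$z), cfg$alpha) else thr
      z_source <- apply_threshold(z_source, thr_src)
    }
  }

  structure(list(
    nb = nb, nb_log = nb_log, broadband = bb, coherence = cp, gsf = g,
    source = src, inverse = op, z_scalp = z_scalp, z_source = z_source,
    threshold = thr,
    provenance = list(
      package_version = as.character(utils::packageVersion("qeegnorm")),
      seed = cfg$seed, reference = cfg$reference, gsf = cfg$gsf,
      taper = cfg$taper, fmax_hz = cfg$fmax_hz, lambda = cfg$lambda,
      lambda_used = if (!is.null(op)) op$lambda else NA_real_,
      alpha = cfg$alpha, correction = cfg$correction, age = age,
      coherence_convention = "magnitude-squared",
      bands = unclass(cfg$bands))),
    class = "qeeg_result")
}

align_locations <- function(power, locations) {
  idx <- match(tolower(locations), tolower(rownames(power)))
  if (anyNA(idx))
    stop("locations missing from the data: ",
         paste(locations[is.na(idx)], collapse = ", "), call. = FALSE)
  power[idx, , drop = FALSE]
}

align_montage <- function(montage, labels) {
  idx <- match(tolower(labels), tolower(montage$labels))
  if (anyNA(idx))
    stop("montage is missing electrode(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  eeg_montage(montage$labels[idx], montage$positions[idx, , drop = FALSE])
}

#' @export
print.qeeg_result <- function(x, ...) {
  cat("<qeeg_result>\n")
  cat(sprintf("  narrow band: %d channels x %d bins; broad band: %d bands\n",
              nrow(x$nb$power), ncol(x$nb$power), nrow(x$broadband$ap)))
  if (!is.null(x$gsf)) cat(sprintf("  GSF log10 %.4f\n", x$gsf$log10_value))
  if (!is.null(x$source)) cat(sprintf("  source spectra: %d voxels\n",
                                      nrow(x$source$power)))
  if (!is.null(x$z_scalp)) print(x$z_scalp)
  invisible(x)
}

#' Export a result bundle to tidy CSV tables
#'
#' Writes one CSV per measure (narrow-band raw and log spectra, broad-band
#' parameters, coherence/phase, source spectra with voxel coordinates,
#' scalp/source z-maps with the corrected threshold) plus a JSON provenance
#' record.
#'
#' @param b a `qeeg_result`.
#' @param outdir output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
export_maps <- function(b, outdir) {
  stopifnot(inherits(b, "qeeg_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(tidy(b$nb), "narrowband_raw.csv")
  wr(tidy(b$nb_log), "narrowband_log.csv")
  wr(tidy(b$broadband), "broadband.csv")
  wr(tidy(b$coherence), "coherence_phase.csv")
  if (!is.null(b$source)) {
    st <- tidy(b$source)
    xyz <- b$inverse$voxel_xyz
    vi <- as.integer(sub("^v", "", st$channel))
    st$x <- xyz[vi, 1]; st$y <- xyz[vi, 2]; st$z <- xyz[vi, 3]
    wr(st, "source_spectra.csv")
  }
  if (!is.null(b$z_scalp)) wr(tidy(b$z_scalp), "z_scalp.csv")
  if (!is.null(b$z_source)) wr(tidy(b$z_source), "z_source.csv")
  jsonlite::write_json(b$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(outdir, "provenance.json"))
  invisible(files)
}
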