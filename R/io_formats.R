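#' Read epoched EEG from the plain-text interchange format
#'
#' The text format is a deliberately simple, diffable carrier for expert-
#' selected artifact-free epochs.  Layout:
#' \preformatted{
#' QEEGT-TEXT 1
#' fs=<Hz> n_epochs=<E> n_samples=<N> n_channels=<C> units=uV reference=<ref> age=<years> state=<EC|EO|HV>
#' <label 1> <label 2> ... <label C>
#' <E blocks of N rows x C whitespace-separated decimal values, blank line between blocks>
#' }
#'
#' @param path path to a file in the format above.
#' @return An [eeg_epochs] object (values in microvolts).
#' @seealso [write_epochs_text()]
#' @export
read_epochs_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("epoch text format error at line 1: file truncated", call. = FALSE)
  if (!identical(trimws(lines[1L]), "QEEGT-TEXT 1"))
    stop("epoch text format error at line 1: expected 'QEEGT-TEXT 1'", call. = FALSE)
  hdr <- parse_kv_header(lines[2L], lineno = 2L)
  req <- c("fs", "n_epochs", "n_samples", "n_channels", "units", "reference", "age", "state")
  missing <- setdiff(req, names(hdr))
  if (length(missing))
    stop("epoch text format error at line 2: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(hdr[["units"]], "uV"))
    stop("epoch text format error at line 2: units must be 'uV', got '",
         hdr[["units"]], "'", call. = FALSE)
  fs <- as_num_or_fail(hdr[["fs"]], "fs", 2L)
  E <- as_int_or_fail(hdr[["n_epochs"]], "n_epochs", 2L)
  N <- as_int_or_fail(hdr[["n_samples"]], "n_samples", 2L)
  C <- as_int_or_fail(hdr[["n_channels"]], "n_channels", 2L)
  age <- as_num_or_fail(hdr[["age"]], "age", 2L)

  labels <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (length(labels) != C)
    stop("epoch text format error at line 3: expected ", C,
         " channel labels, found ", length(labels), call. = FALSE)
  if (anyDuplicated(labels))
    stop("epoch text format error at line 3: duplicate channel label '",
         labels[duplicated(labels)][1L], "'", call. = FALSE)

  body <- lines[-(1:3)]
  body_ln <- seq_along(body) + 3L
  keep <- nzchar(trimws(body))
  rows <- body[keep]
  rows_ln <- body_ln[keep]
  if (length(rows) != E * N)
    stop("epoch text format error at line ", if (length(rows_ln)) max(rows_ln) else 4L,
         ": expected ", E * N, " data rows (", E, " epochs x ", N,
         " samples), found ", length(rows), call. = FALSE)

  data <- array(NA_real_, dim = c(E, N, C))
  for (i in seq_along(rows)) {
    vals <- strsplit(trimws(rows[i]), "\\s+")[[1L]]
    if (length(vals) != C)
      stop("epoch text format error at line ", rows_ln[i], ": expected ", C,
           " values, found ", length(vals), call. = FALSE)
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num))
      stop("epoch text format error at line ", rows_ln[i],
           ": non-numeric token '", vals[which(is.na(num))[1L]], "'", call. = FALSE)
    ep <- ((i - 1L) %/% N) + 1L
    sm <- ((i - 1L) %% N) + 1L
    data[ep, sm, ] <- num
  }
  eeg_epochs(data, fs = fs, channel_labels = labels,
             reference = hdr[["reference"]], age = age, state = hdr[["state"]])
}

#' Write epoched EEG to the plain-text interchange format
#'
#' @param e an [eeg_epochs] object; must contain only finite values.
#' @param path output path.
#' @param digits significant digits written per sample (default 10, which
#'   round-trips well below the 1e-6 microvolt tolerance of the format).
#' @return `path`, invisibly.
#' @export
write_epochs_text <- function(e, path, digits = 10L) {
  stopifnot(inherits(e, "eeg_epochs"))
  if (!all(is.finite(e$data)))
    stop("refusing to write epochs containing non-finite values", call. = FALSE)
  d <- dim(e$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("QEEGT-TEXT 1", con)
  writeLines(sprintf(
    "fs=%.10g n_epochs=%d n_samples=%d n_channels=%d units=uV reference=%s age=%.10g state=%s",
    e$fs, d[1], d[2], d[3], e$reference, e$subject$age, e$subject$state), con)
  writeLines(paste(e$channel_labels, collapse = " "), con)
  for (ep in seq_len(d[1])) {
    block <- format(e$data[ep, , , drop = FALSE], digits = digits,
                    scientific = TRUE, trim = TRUE)
    dim(block) <- d[2:3]
    writeLines(apply(block, 1L, paste, collapse = " "), con)
    if (ep < d[1]) writeLines("", con)
  }
  invisible(path)
}

parse_kv_header <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1L]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("epoch text format error at line ", lineno, ": malformed token '",
         toks[bad][1L], "'", call. = FALSE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

as_num_or_fail <- function(x, field, line) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("epoch text format error at line ", line, ": field ", field,
                     " is not numeric ('", x, "')", call. = FALSE)
  v
}

as_int_or_fail <- function(x, field, line) {
  v <- as_num_or_fail(x, field, line)
  if (v != round(v) || v < 1)
    stop("epoch text format error at line ", line, ": field ", field,
         " must be a positive integer", call. = FALSE)
  as.integer(v)
}

#' Electrode montage on the unit sphere
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix `[n x 3]` of electrode positions.  Head
#'   radius is normalized to 1; positions within 10% of unit norm are
#'   rescaled with a warning, anything farther off is an error.
#' @return An object of class `eeg_montage` with unit-norm `positions`.
#' @export
eeg_montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (anyDuplicated(labels))
    stop("duplicate electrode label: ", labels[duplicated(labels)][1L], call. = FALSE)
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stop("`positions` must be an [n x 3] matrix matching `labels`", call. = FALSE)
  nrm <- sqrt(rowSums(positions^2))
  if (any(!is.finite(nrm)) || any(nrm == 0))
    stop("electrode positions must be finite and nonzero", call. = FALSE)
  off <- abs(nrm - 1)
  if (any(off > 0.1))
    stop("electrode position norm deviates from 1 by more than 10% (label ",
         labels[which.max(off)], ")", call. = FALSE)
  if (any(off > 1e-9)) {
    warning("electrode positions re-normalized to the unit sphere", call. = FALSE)
    positions <- positions / nrm
  }
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions), class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes: %s\n", length(x$labels),
              paste(utils::head(x$labels, 8), collapse = ", ")))
  invisible(x)
}

# 10-20 system, 19 leads; spherical angles (theta from +z, phi from +x through
# nasion) of the standard placement, head radius 1.
ten_twenty_19 <- function() {
  ang <- matrix(c(
    # label     theta  phi   (degrees)
    # frontal pole / frontal / central / parietal / occipital midline chain
    72, 108,   # Fp1
    72,  72,   # Fp2
    51, 129,   # F3
    51,  51,   # F4
    36, 180,   # C3
    36,   0,   # C4
    51, 231,   # P3
    51, 309,   # P4
    72, 252,   # O1
    72, 288,   # O2
    72, 144,   # F7
    72,  36,   # F8
    72, 180,   # T3
    72,   0,   # T4
    72, 216,   # T5
    72, 324,   # T6
    36,  90,   # Fz
     0,   0,   # Cz
    36, 270    # Pz
  ), ncol = 2, byrow = TRUE)
  labels <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
              "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  pos <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  eeg_montage(labels, pos)
}

#' Load an electrode montage
#'
#' @param name_or_path the built-in name `"10-20-19"` (the 19 leads of the
#'   10--20 International System) or the path of a text file with one
#'   `label x y z` row per electrode.
#' @return An [eeg_montage].
#' @export
load_montage <- function(name_or_path) {
  if (identical(name_or_path, "10-20-19")) return(ten_twenty_19())
  if (!file.exists(name_or_path))
    stop("unknown montage name or missing file: '", name_or_path, "'", call. = FALSE)
  tab <- utils::read.table(name_or_path, header = FALSE,
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  eeg_montage(tab$label, as.matrix(tab[, c("x", "y", "z")]))
}

#' Serialize a fitted normative model to a versioned norms file
#'
#' Norms files are JSON documents (schema tag `qeegnorm-v1`) holding the
#' age-regression coefficient arrays at full double precision together with
#' the frequency grid, location labels, state and transform tags.
#'
#' @param nm a [norm_model] as returned by [fit_norm_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_norms <- function(nm, path) {
  stopifnot(inherits(nm, "norm_model"))
  doc <- list(
    format = "qeegnorm-v1",
    state = nm$state, level = nm$level, transform = nm$transform,
    age_transform = nm$age_transform, degree = nm$degree,
    n_subjects = nm$n_subjects, age_range = nm$age_range,
    sigma_floor = nm$sigma_floor,
    locations = nm$locations,
    grid = list(bin_hz = nm$grid$bin_hz, resolution_hz = nm$grid$resolution_hz),
    dim = dim(nm$beta_mu),
    beta_mu = as.vector(nm$beta_mu),
    beta_sigma = as.vector(nm$beta_sigma))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a norms file written by [write_norms()]
#'
#' @param path path to a `qeegnorm-v1` norms file.
#' @param expect_state optionally, the recording state the norms will be
#'   applied to; a mismatch raises a warning (state-specific norms are not
#'   interchangeable between EC/EO/HV).
#' @return A [norm_model].
#' @export
read_norms <- function(path, expect_state = NULL) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("norms file parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(doc$format))
    stop("norms file parse error: no format tag", call. = FALSE)
  if (!identical(doc$format, "qeegnorm-v1"))
    stop("norms file version mismatch: got '", doc$format,
         "', expected 'qeegnorm-v1'", call. = FALSE)
  dm <- as.integer(doc$dim)
  if (length(doc$beta_mu) != prod(dm) || length(doc$beta_sigma) != prod(dm))
    stop("norms file shape inconsistency: coefficient length does not match dim",
         call. = FALSE)
  nm <- norm_model(
    beta_mu = array(as.numeric(doc$beta_mu), dim = dm),
    beta_sigma = array(as.numeric(doc$beta_sigma), dim = dm),
    degree = as.integer(doc$degree), state = doc$state, level = doc$level,
    grid = frequency_grid_from_bins(as.numeric(doc$grid$bin_hz),
                                    as.numeric(doc$grid$resolution_hz)),
    locations = as.character(doc$locations),
    n_subjects = as.integer(doc$n_subjects),
    age_range = as.numeric(doc$age_range),
    sigma_floor = as.numeric(doc$sigma_floor))
  if (!is.null(expect_state) && !identical(nm$state, expect_state))
    warning("norms were fitted for state ", nm$state,
            " but will be applied to state ", expect_state, call. = FALSE)
  nm
}
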