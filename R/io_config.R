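#' Write a table of typed records to CSV
#'
#' All quantitative outputs go through this writer: one header row, floats
#' at full precision (17 significant digits), rows in input order. If a list
#' of single-row records is supplied they must share one schema.
#'
#' @param records a data.frame, or a list of data.frames / named lists
#'   sharing identical column names and types.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- records_to_df(records)
  num <- vapply(df, is.double, logical(1L))
  out <- df
  out[num] <- lapply(df[num], function(x) formatC(x, digits = 17,
                                                  format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

records_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (!is.list(records)) stop("records must be a data.frame or list")
  if (length(records) == 0L) {
    stop("cannot infer a schema from an empty record list; ",
         "pass a 0-row data.frame instead")
  }
  rows <- lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE))
  schema <- names(rows[[1L]])
  ok <- vapply(rows, function(r) identical(names(r), schema), logical(1L))
  if (!all(ok)) stop("heterogeneous record schema: rows ",
                     paste(which(!ok), collapse = ", "),
                     " differ from the first record")
  do.call(rbind, rows)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' A flat named list of defaults used across the pipeline; every threshold
#' has a documented default equal to the published value where one exists.
#' `read_config()` loads a YAML file and overlays it on the defaults;
#' entries passed as `...` (e.g. from CLI flags) take highest precedence.
#'
#' @param ... overrides of the built-in defaults.
#' @return named list of class `rnp_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    pixel_size_um = 0.084,     # S2-cell granule imaging scale (3 px = 0.252 um)
    frame_interval_s = 1.0878, # FRAP acquisition interval
    z_step_um = 0.39,
    n_pre = 2L,                # pre-bleach frames
    k_sigma = 3,               # granule detection threshold multiplier
    min_area_px = 9L,          # >= 3 x 3 px granule rule
    circ_threshold = 0.8,      # circular vs amorphic morphology cut
    v_min_um_s = 0.138,        # transport speed floor (= pixel size / s)
    transport_dt_s = 4.84,     # 484 s / 100 frames
    rolling_ball_radius_px = 50,
    spot_threshold_factor = 5,
    psf_sigma_px = 1.3,
    distal_um = 10,            # neurite granule distal cut-off
    seed = 1L,
    outdir = ".",
    log_level = "info")
  utils::modifyList(structure(defaults, class = "rnp_config"), list(...))
}

#' @param path YAML config file.
#' @rdname run_config
#' @export
read_config <- function(path, ...) {
  cfg <- run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  utils::modifyList(cfg, list(...))
}

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Leveled plain-text logging
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... message parts, pasted together.
#' @export
rnp_log <- function(level, ...) {
  thr <- getOption("rnpquant.log_level", "info")
  if (log_levels[[level]] >= log_levels[[thr]]) {
    message(sprintf("[%s] %s %s", toupper(level),
                    format(Sys.time(), "%H:%M:%S"), paste0(...)))
  }
  invisible(NULL)
}
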