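#' Normalize dual-luciferase reporter readings
#'
#' Per-well ratio = FLuc / RLuc; technical replicates are averaged to one
#' ratio per construct per plate; each construct's ratio is divided by the
#' control construct's ratio on the same plate. When several plates
#' (independent experiments) are supplied, the across-plate mean and
#' standard error of the normalized value are reported — plates, not
#' wells, are the unit of error.
#'
#' Wells with RLuc <= 0 are excluded with a warning; a zero or negative
#' control ratio is fatal.
#'
#' @param wells data.frame with columns `construct`, `replicate`, `fluc`,
#'   `rluc` and optionally `plate` (default: one plate).
#' @param control name of the control construct (present on every plate).
#' @return list with `per_plate` (construct x plate normalized ratios) and
#'   `summary` (per-construct mean, SE over plates, `n_plates`,
#'   `fold_repression` = 1 / normalized ratio).
#' @export
normalize_reporter <- function(wells, control = "control") {
  stopifnot(all(c("construct", "fluc", "rluc") %in% names(wells)))
  if (is.null(wells$plate)) wells$plate <- 1L
  bad <- wells$rluc <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with RLuc <= 0 excluded")
    wells <- wells[!bad, , drop = FALSE]
  }
  if (!control %in% wells$construct) {
    stop("control construct '", control, "' not found")
  }
  wells$ratio <- wells$fluc / wells$rluc
  per_plate <- do.call(rbind, lapply(split(wells, wells$plate),
                                     function(pw) {
    agg <- stats::aggregate(ratio ~ construct, pw, mean)
    ctrl <- agg$ratio[agg$construct == control]
    if (length(ctrl) != 1L || ctrl <= 0) {
      stop("control ratio on plate ", pw$plate[1L],
           " is missing or <= 0; cannot normalize")
    }
    data.frame(plate = pw$plate[1L], construct = agg$construct,
               ratio = agg$ratio, normalized = agg$ratio / ctrl)
  }))
  rownames(per_plate) <- NULL
  se <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  summary <- do.call(rbind, lapply(split(per_plate, per_plate$construct),
                                   function(g) {
    data.frame(construct = g$construct[1L],
               normalized_mean = mean(g$normalized),
               normalized_se = se(g$normalized),
               n_plates = nrow(g),
               fold_repression = 1 / mean(g$normalized))
  }))
  rownames(summary) <- NULL
  list(per_plate = per_plate, summary = summary)
}
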