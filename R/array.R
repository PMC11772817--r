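# Cytokine antibody-array quantification: exposure selection, background
# subtraction, positive-control normalization, and condition fold changes.
# Arrays are run at n = 1 per condition, so no statistics happen here —
# downstream significance uses a configurable effect floor instead.

.membrane_spots <- function(x, condition, exposure) {
  sp <- x$spots
  sp[sp$condition == condition & sp$exposure_s == exposure, , drop = FALSE]
}

.mean_volume <- function(sp, class, target = NULL) {
  sel <- sp$spot_class == class
  if (!is.null(target)) sel <- sel & !is.na(sp$target) & sp$target == target
  mean(sp$volume[sel])
}

#' Select the film exposure for one array target
#'
#' Returns the shortest exposure at which the target's mean duplicate-spot
#' volume exceeds the detection threshold while staying below the
#' saturation ceiling.  If the target is never detected the `undetected`
#' flag is set; if it is detected only at saturation, the shortest
#' saturated exposure is used and `saturated_all_exposures` is set.
#'
#' @param x An [array_experiment()].
#' @param target Protein target id.
#' @param condition Condition (membrane) label.
#' @param detect_threshold Detection threshold on mean spot volume;
#'   default 3 x the membrane's mean background volume at each exposure.
#' @return List with `exposure_s`, `undetected`, `saturated_all_exposures`.
#' @export
select_exposure <- function(x, target, condition, detect_threshold = NULL) {
  stopifnot(inherits(x, "array_experiment"))
  sp <- x$spots
  if (!condition %in% sp$condition) stop("unknown condition: ", condition)
  if (!target %in% sp$target) stop("unknown target: ", target)
  exposures <- sort(unique(sp$exposure_s[sp$condition == condition]))
  sat_first <- NA_real_
  for (ex in exposures) {
    mem <- .membrane_spots(x, condition, ex)
    thr <- if (is.null(detect_threshold))
      3 * .mean_volume(mem, "background") else detect_threshold
    v <- .mean_volume(mem, "target", target)
    if (v > thr && v < x$saturation_ceiling)
      return(list(exposure_s = ex, undetected = FALSE,
                  saturated_all_exposures = FALSE))
    if (v >= x$saturation_ceiling && is.na(sat_first)) sat_first <- ex
  }
  if (!is.na(sat_first))
    return(list(exposure_s = sat_first, undetected = FALSE,
                saturated_all_exposures = TRUE))
  list(exposure_s = NA_real_, undetected = TRUE,
       saturated_all_exposures = FALSE)
}

#' Quantify one array target on its selected membrane exposure
#'
#' Intensity = max(0, mean duplicate volume - mean background volume)
#' divided by the background-subtracted mean positive-control (reference)
#' volume, all on the same membrane and exposure.  Undetected targets get
#' intensity 0.
#'
#' @inheritParams select_exposure
#' @return One-row data.frame: target, condition, chosen_exposure_s,
#'   normalized_intensity, undetected, saturated_all_exposures.
#' @export
quantify_target <- function(x, target, condition, detect_threshold = NULL) {
  sel <- select_exposure(x, target, condition, detect_threshold)
  if (sel$undetected)
    return(data.frame(target = target, condition = condition,
                      chosen_exposure_s = NA_real_,
                      normalized_intensity = 0,
                      undetected = TRUE, saturated_all_exposures = FALSE,
                      stringsAsFactors = FALSE))
  mem <- .membrane_spots(x, condition, sel$exposure_s)
  bg <- .mean_volume(mem, "background")
  ref <- .mean_volume(mem, "reference") - bg
  if (!is.finite(ref) || ref <= 0)
    stop("zero reference signal after background subtraction on membrane ",
         mem$membrane[1], " at ", sel$exposure_s, "s")
  val <- max(0, .mean_volume(mem, "target", target) - bg) / ref
  data.frame(target = target, condition = condition,
             chosen_exposure_s = sel$exposure_s,
             normalized_intensity = val,
             undetected = FALSE,
             saturated_all_exposures = sel$saturated_all_exposures,
             stringsAsFactors = FALSE)
}

#' Quantify every target on a condition's membrane
#'
#' @inheritParams select_exposure
#' @return data.frame with one [quantify_target()] row per target.
#' @export
quantify_array <- function(x, condition, detect_threshold = NULL) {
  targets <- sort(unique(stats::na.omit(
    x$spots$target[x$spots$spot_class == "target"])))
  out <- do.call(rbind, lapply(targets, quantify_target, x = x,
                               condition = condition,
                               detect_threshold = detect_threshold))
  rownames(out) <- NULL
  out
}

#' Fold changes between two conditions' array intensities
#'
#' log2((test + pseudo) / (ref + pseudo)) per target, with a direction
#' call by sign outside a dead-band `eps` (default 0: any nonzero change
#' is directional).  Never produces NaN: undetected targets enter as
#' intensity 0.
#'
#' @param test,ref data.frames from [quantify_array()] over the same
#'   target universe.
#' @param pseudo Positive pseudo-intensity.
#' @param eps Dead-band half-width on the log2 ratio.
#' @return data.frame: target, intensity_ref, intensity_test, log2_ratio,
#'   direction ("up"/"down"/"unchanged").
#' @export
array_fold_changes <- function(test, ref, pseudo = 0.01, eps = 0) {
  stopifnot(pseudo > 0)
  if (!setequal(test$target, ref$target))
    stop("test and ref must cover the same target universe")
  ref <- ref[match(test$target, ref$target), ]
  lr <- log2((test$normalized_intensity + pseudo) /
             (ref$normalized_intensity + pseudo))
  dir <- ifelse(lr > eps, "up", ifelse(lr < -eps, "down", "unchanged"))
  out <- data.frame(target = test$target,
                    intensity_ref = ref$normalized_intensity,
                    intensity_test = test$normalized_intensity,
                    log2_ratio = lr, direction = dir,
                    stringsAsFactors = FALSE)
  out[order(out$target), , drop = FALSE]
}
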