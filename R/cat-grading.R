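# Catalase (CAT) activity from permanganate titration, and mold-level
# assignment from CAT values. CAT activity is the volume (mL) of 0.005 mol/L
# potassium permanganate consumed per gram of sample per hour; it tracks mold
# metabolic activity and is the basis for the four-level grading.

#' CAT activity from a titration record
#'
#' `value = (V1 - V2) / (M * T)`, where `V1` and `V2` are the titrated
#' permanganate volumes (mL) of the control and sample groups, `M` the sample
#' mass (g) and `T` the unit time (h). All arguments are vectorized.
#'
#' @param v1,v2 control and sample titration volumes, mL (`v1 >= v2 >= 0`).
#' @param m sample mass in g (> 0).
#' @param t unit time in h (> 0).
#' @return CAT activity in mL/(h*g).
#' @export
cat_activity <- function(v1, v2, m, t) {
  if (any(m <= 0) || any(t <= 0)) stop("sample mass and time must be positive")
  if (any(v2 < 0)) stop("titration volumes must be nonnegative")
  if (any(v2 > v1)) stop("V2 > V1: negative CAT activity is nonphysical")
  (v1 - v2) / (m * t)
}

#' Default CAT cut points between mold levels
#'
#' Midpoints between adjacent class means of the CAT distribution
#' (mild/moderate and moderate/severe); with the default distribution these
#' are 1.74 and 2.075 mL/(h*g).
#'
#' @param params a [cat_params].
#' @return Numeric vector of 2 strictly increasing cut points.
#' @export
default_cat_cuts <- function(params = cat_params()) {
  m <- params$means
  c((m[2] + m[3]) / 2, (m[3] + m[4]) / 2)
}

#' Assign a mold level from a CAT activity value
#'
#' A value at or below `eps0` is healthy (sterilized kernels titrate to
#' exactly zero); otherwise the level is chosen by interval membership with
#' right-open intervals, so a value exactly at a cut point goes to the upper
#' level — the conservative call for food safety.
#'
#' @param value CAT activity, mL/(h*g); vectorized.
#' @param cuts 2 strictly increasing positive cut points
#'   (mild/moderate, moderate/severe).
#' @param eps0 healthy tolerance (default `1e-6`).
#' @return Factor of mold levels with attribute `thresholds`.
#' @export
assign_level <- function(value, cuts = default_cat_cuts(), eps0 = 1e-6) {
  stopifnot(length(cuts) == 2, all(cuts > 0), diff(cuts) > 0)
  if (any(value < 0)) stop("CAT activity cannot be negative")
  lev <- ifelse(value <= eps0, "healthy",
         ifelse(value < cuts[1], "mild",
         ifelse(value < cuts[2], "moderate", "severe")))
  structure(factor(lev, levels = mold_levels()),
            thresholds = c(eps0 = eps0, cuts))
}
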