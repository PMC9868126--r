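#' Locomotor path length of a centroid track
#'
#' Sums the Euclidean distance `sqrt((q1 - p1)^2 + (q2 - p2)^2)` between the
#' centroid positions at consecutive frames. Distances are in the track's
#' input units unless a pixel-to-cm scale is supplied.
#'
#' @param track a `centroid_track` (data frame with `x`, `y`) or any
#'   two-column matrix of positions.
#' @param scale multiplicative unit conversion (e.g. cm per pixel).
#' @return total distance travelled.
#' @export
path_length <- function(track, scale = 1) {
  m <- if (is.data.frame(track)) cbind(track$x, track$y) else as.matrix(track)
  if (any(!is.finite(m))) stop("positions must be finite")
  if (nrow(m) < 2) {
    warning("track has a single frame; path length is 0")
    return(0)
  }
  sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)) * scale
}

#' Two-bottle preference index
#'
#' Time spent drinking from one bottle over the total time spent drinking
#' from both bottles during the session.
#'
#' @param licks a [lick_record()]
#' @param side `"left"` or `"right"`
#' @return fraction in `[0, 1]`, NA with a warning when no drinking occurred.
#' @export
preference_index <- function(licks, side = c("left", "right")) {
  side <- match.arg(side)
  tot <- licks$t_left + licks$t_right
  if (tot == 0) {
    warning("no drinking recorded; preference undefined")
    return(NA_real_)
  }
  (if (side == "left") licks$t_left else licks$t_right) / tot
}

#' Per-day locomotion summary across animals
#'
#' @param distances animals x days matrix (or data frame) of daily path
#'   lengths; one column per injection day.
#' @return data frame `day`, `mean`, `sem`, `n`; SEM is NA for a single
#'   animal.
#' @export
sensitization_table <- function(distances) {
  m <- as.matrix(distances)
  if (ncol(m) < 1) stop("need at least one day")
  days <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
  data.frame(day = days,
             mean = colMeans(m, na.rm = TRUE),
             sem = apply(m, 2, function(v) {
               v <- v[!is.na(v)]
               if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
             }),
             n = apply(m, 2, function(v) sum(!is.na(v))),
             row.names = NULL)
}
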