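# Batch recipe scheduling: staggered batches at a fixed cycle time over the
# annual operating window, Gantt construction and annualization of per-batch
# material balances.

#' Batch recipe
#'
#' An ordered list of unit occupancies (unit id, start offset within the
#' batch, duration), the resulting batch time and the stagger (cycle) time
#' between consecutive batch starts.
#'
#' @param operations data.frame with columns \code{unit_id},
#'   \code{duration_h}, \code{offset_h}
#' @param cycle_time_h stagger between batch starts, h (> 0)
#' @param batch_time_h total recipe duration, h; defaults to
#'   \code{max(offset + duration)}
#' @return object of class \code{recipe}
#' @export
recipe <- function(operations, cycle_time_h, batch_time_h = NULL) {
  stopifnot(is.data.frame(operations),
            all(c("unit_id", "duration_h", "offset_h") %in% names(operations)))
  if (any(operations$duration_h < 0) || any(operations$offset_h < 0))
    stop("durations and offsets must be >= 0")
  span <- max(operations$offset_h + operations$duration_h)
  if (is.null(batch_time_h)) batch_time_h <- span
  if (batch_time_h < span - 1e-9)
    stop("batch_time_h (", batch_time_h, ") is shorter than the recipe span (",
         span, ")")
  if (cycle_time_h <= 0) stop("cycle_time_h must be > 0")
  if (cycle_time_h > batch_time_h + 1e-9)
    stop("cycle_time_h must not exceed batch_time_h")
  structure(list(operations = operations, batch_time_h = batch_time_h,
                 cycle_time_h = cycle_time_h),
            class = "recipe")
}

#' The default plant recipe
#'
#' Main stages of one hour each run back-to-back through the plant, followed
#' by a quarter-hour product transfer, giving the plant's 7.25 h batch time;
#' batches start every 2.75 h.
#'
#' @return a \code{\link{recipe}} with batch time 7.25 h and cycle time 2.75 h
#' @export
default_recipe <- function() {
  ops <- data.frame(
    unit_id = c("WSH-101", "GR-101", "BR-101", "MF-101", "MF-102",
                "DC-101", "C-101", "P-11"),
    duration_h = c(1, 1, 1, 1, 1, 1, 1, 0.25),
    offset_h = c(0, 1, 2, 3, 4, 5, 6, 7),
    stringsAsFactors = FALSE
  )
  recipe(ops, cycle_time_h = 2.75)
}

#' Number of batches fitting in the annual operating window
#'
#' With staggered starts every \code{cycle_time} hours and the last batch
#' required to finish within the operating window:
#' \code{floor((annual - batch_time)/cycle_time) + 1}.
#'
#' @param annual_operating_time h/yr (plant default 7919)
#' @param batch_time h (default 7.25)
#' @param cycle_time h (default 2.75)
#' @return integer batch count (0, with a warning, when one batch does not fit)
#' @export
#' @examples
#' n_batches(7919, 7.25, 2.75)  # 2878
n_batches <- function(annual_operating_time, batch_time, cycle_time) {
  if (annual_operating_time <= 0 || batch_time <= 0 || cycle_time <= 0)
    stop("all timing inputs must be > 0")
  if (batch_time > annual_operating_time) {
    warning("batch_time exceeds the annual operating time; 0 batches fit")
    return(0L)
  }
  # small epsilon so exact multiples are not lost to floating-point division
  as.integer(floor((annual_operating_time - batch_time) / cycle_time + 1e-9) + 1)
}

#' Schedule summary for a campaign
#'
#' @param annual_operating_time,batch_time,cycle_time hours; defaults are the
#'   plant's 7919 / 7.25 / 2.75
#' @return list of class \code{schedule_summary} with the three inputs and
#'   \code{n_batches}
#' @export
schedule_summary <- function(annual_operating_time = 7919,
                             batch_time = 7.25, cycle_time = 2.75) {
  structure(list(annual_operating_time_h = annual_operating_time,
                 batch_time_h = batch_time, cycle_time_h = cycle_time,
                 n_batches = n_batches(annual_operating_time, batch_time,
                                       cycle_time)),
            class = "schedule_summary")
}

#' @export
print.schedule_summary <- function(x, ...) {
  cat("<schedule_summary>\n")
  cat(sprintf("  Annual Operating Time   %10.2f h\n", x$annual_operating_time_h))
  cat(sprintf("  Recipe Batch Time       %10.2f h\n", x$batch_time_h))
  cat(sprintf("  Recipe Cycle Time       %10.2f h\n", x$cycle_time_h))
  cat(sprintf("  Number of Batches/Year  %10d\n", x$n_batches))
  invisible(x)
}

#' Build the campaign Gantt chart
#'
#' Batch k's operations are shifted by k x cycle_time. A unit whose occupancy
#' exceeds the cycle time would be claimed by two batches at once; that is
#' reported as an equipment conflict naming the unit (the schedulability
#' condition for single equipment items).
#'
#' @param rec a \code{\link{recipe}}
#' @param n number of batches (>= 1)
#' @return data.frame with columns \code{batch_index} (1-based),
#'   \code{unit_id}, \code{start_h}, \code{end_h}
#' @export
build_gantt <- function(rec, n) {
  if (!inherits(rec, "recipe")) stop("rec must be a recipe")
  if (n < 1) stop("n must be >= 1")
  conflict <- rec$operations$duration_h > rec$cycle_time_h + 1e-9
  if (n > 1 && any(conflict))
    stop("equipment conflict: unit(s) ",
         paste(rec$operations$unit_id[conflict], collapse = ", "),
         " occupied longer than the cycle time (",
         rec$cycle_time_h, " h)")
  ops <- rec$operations
  k <- rep(seq_len(n) - 1, each = nrow(ops))
  data.frame(
    batch_index = k + 1L,
    unit_id = rep(ops$unit_id, n),
    start_h = rep(ops$offset_h, n) + k * rec$cycle_time_h,
    end_h = rep(ops$offset_h + ops$duration_h, n) + k * rec$cycle_time_h,
    stringsAsFactors = FALSE
  )
}

#' Annualize per-batch material quantities
#'
#' @param per_batch named numeric vector, kg/batch (>= 0)
#' @param n batches per year (>= 0)
#' @return named numeric vector, kg/yr
#' @export
#' @examples
#' annualize(c(alcalase = 100, larvae = 10000), 2878)
annualize <- function(per_batch, n) {
  if (n < 0) stop("n must be >= 0")
  if (any(per_batch < 0)) stop("per-batch masses must be >= 0")
  per_batch * n
}
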