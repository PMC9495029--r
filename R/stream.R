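#' Create a process stream
#'
#' A stream is a labelled per-batch component mass vector with temperature,
#' pressure and phase metadata. Masses are kg per batch; metadata never alters
#' downstream mass splits (the separation models are split-fraction based, not
#' equilibrium based).
#'
#' @param label stream label, e.g. \code{"Oil feed"}
#' @param masses named numeric vector of component masses in kg (>= 0)
#' @param temperature degC
#' @param pressure bar
#' @param phase one of \code{"solid-slurry"}, \code{"liquid"}, \code{"vapor"},
#'   \code{"mixed"}
#' @return an object of class \code{stream}
#' @export
#' @examples
#' s <- stream("Larvae feed", c(water = 6730, protein = 1462))
#' total_mass(s)
stream <- function(label, masses = numeric(0), temperature = 25,
                   pressure = 1.013, phase = "mixed") {
  masses <- masses[masses != 0]
  s <- structure(
    list(label = as.character(label),
         masses = masses,
         temperature = temperature, pressure = pressure,
         phase = match.arg(phase, c("solid-slurry", "liquid", "vapor", "mixed"))),
    class = "stream"
  )
  validate_stream(s)
  s
}

#' @noRd
validate_stream <- function(s) {
  if (!inherits(s, "stream")) stop("not a stream")
  m <- s$masses
  if (length(m) && (is.null(names(m)) || any(names(m) == "")))
    stop("stream '", s$label, "': masses must be a named vector")
  if (any(m < 0)) {
    bad <- names(m)[m < 0]
    stop("stream '", s$label, "': negative component mass for ",
         paste(bad, collapse = ", "))
  }
  invisible(s)
}

#' Total mass of a stream (kg per batch)
#' @param s a \code{stream}
#' @return numeric scalar
#' @export
total_mass <- function(s) sum(s$masses)

#' Mass of one component in a stream
#' @param s a \code{stream}
#' @param comp component name
#' @return numeric scalar (0 if absent)
#' @export
component_mass <- function(s, comp) {
  m <- unname(s$masses[comp])
  if (is.na(m)) 0 else m
}

#' @noRd
set_masses <- function(s, masses, label = s$label, phase = s$phase,
                       temperature = s$temperature) {
  masses <- masses[!is.na(masses) & masses != 0]
  s$masses <- masses
  s$label <- label
  s$phase <- phase
  s$temperature <- temperature
  validate_stream(s)
  s
}

#' @noRd
add_masses <- function(a, b) {
  nm <- union(names(a), names(b))
  out <- setNames(numeric(length(nm)), nm)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' @export
print.stream <- function(x, ...) {
  cat(sprintf("<stream> %s  [%s, %.1f degC, %.3f bar]\n",
              x$label, x$phase, x$temperature, x$pressure))
  if (length(x$masses)) {
    m <- sort(x$masses, decreasing = TRUE)
    for (nm in names(m)) cat(sprintf("  %-20s %12.3f kg\n", nm, m[[nm]]))
    cat(sprintf("  %-20s %12.3f kg\n", "TOTAL", sum(m)))
  } else cat("  (empty)\n")
  invisible(x)
}

#' Tabulate a set of streams
#'
#' Long-format stream table matching the plant's flow report: one row per
#' stream x component, with metadata columns.
#'
#' @param streams named list of \code{stream} objects
#' @return data.frame with columns label, component, kg_per_batch,
#'   temperature_c, pressure_bar, phase
#' @export
stream_table <- function(streams) {
  rows <- lapply(streams, function(s) {
    if (!length(s$masses)) return(NULL)
    data.frame(label = s$label, component = names(s$masses),
               kg_per_batch = unname(s$masses),
               temperature_c = s$temperature, pressure_bar = s$pressure,
               phase = s$phase, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
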