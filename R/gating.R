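#' Define a 2-D gate
#'
#' A gate names a channel pair and a region: either an axis-aligned
#' rectangle (`xmin, xmax, ymin, ymax`) or a simple (non-self-intersecting)
#' polygon given as an n x 2 vertex matrix in intensity units. Events on the
#' region boundary are inside — membership is boundary-inclusive so edge
#' ties are deterministic.
#'
#' @param name Gate label, e.g. `"P1"`.
#' @param x_channel,y_channel Channel names the gate is drawn on.
#' @param rect Numeric `c(xmin, xmax, ymin, ymax)` (exclusive with `polygon`).
#' @param polygon n x 2 matrix of ordered vertices, `n >= 3`.
#' @return A `gate` object.
#' @export
gate <- function(name, x_channel, y_channel, rect = NULL, polygon = NULL) {
  if (is.null(rect) == is.null(polygon))
    stop_flowmrd("gate '%s': give exactly one of rect or polygon", name)
  if (!is.null(rect)) {
    rect <- as.numeric(rect)
    if (length(rect) != 4L || rect[1] > rect[2] || rect[3] > rect[4])
      stop_flowmrd("gate '%s': rect must be c(xmin, xmax, ymin, ymax) with ordered bounds",
                   name)
  } else {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L)
      stop_flowmrd("gate '%s': polygon needs >= 3 (x, y) vertices", name)
    if (polygon_self_intersects(polygon))
      stop_flowmrd("gate '%s': polygon is self-intersecting", name)
  }
  structure(list(name = name, x_channel = x_channel, y_channel = y_channel,
                 rect = rect, polygon = polygon),
            class = "gate")
}

# Proper-crossing test between non-adjacent edges (shared endpoints allowed).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2 per edge
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Combine gates with logical AND
#'
#' @param ... `gate` objects (or a single list of them).
#' @return A `gate_set` whose combination is AND over all members.
#' @export
gate_set <- function(...) {
  gates <- list(...)
  if (length(gates) == 1L && !inherits(gates[[1]], "gate")) gates <- gates[[1]]
  if (length(gates) < 1L) stop_flowmrd("a gate set needs at least one gate")
  stopifnot(all(vapply(gates, inherits, logical(1), "gate")))
  structure(list(gates = gates, combination = "AND"), class = "gate_set")
}

# Crossing-number point-in-polygon with an explicit on-boundary test; points
# on an edge or vertex count as inside. Vectorised over points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-12
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    # boundary: collinear and within the segment's bounding box
    cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    scale <- abs(x2 - x1) + abs(y2 - y1) + 1
    onseg <- abs(cr) <= eps * scale * scale &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    on_edge <- on_edge | onseg
    # half-open crossing rule avoids double-counting vertices
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Apply one gate to a specimen
#'
#' @param events An [event_matrix()].
#' @param g A [gate()].
#' @return Logical mask, `TRUE` where the event's `(x, y)` point lies inside
#'   or on the boundary of the gate region.
#' @export
apply_gate <- function(events, g) {
  stopifnot(inherits(events, "event_matrix"), inherits(g, "gate"))
  missing <- setdiff(c(g$x_channel, g$y_channel), events$channels$short_name)
  if (length(missing))
    stop_flowmrd("gate '%s': unknown channel(s): %s", g$name,
                 paste(missing, collapse = ", "))
  px <- events$values[, g$x_channel]
  py <- events$values[, g$y_channel]
  if (!is.null(g$rect))
    px >= g$rect[1] & px <= g$rect[2] & py >= g$rect[3] & py <= g$rect[4]
  else
    points_in_polygon(px, py, g$polygon)
}

#' Gated leukemic-cell fraction
#'
#' The conventional manual readout: the percentage of events passing the
#' logical AND of all gates (e.g. "P1 AND P2 AND P3").
#'
#' @param events An [event_matrix()].
#' @param gates A [gate_set()] (a single [gate()] is accepted).
#' @return Percentage in `[0, 100]`.
#' @export
gated_fraction <- function(events, gates) {
  if (inherits(gates, "gate")) gates <- gate_set(gates)
  stopifnot(inherits(gates, "gate_set"))
  if (nrow(events$values) == 0L) stop_flowmrd("cannot gate an empty specimen")
  mask <- rep(TRUE, nrow(events$values))
  for (g in gates$gates) mask <- mask & apply_gate(events, g)
  100 * sum(mask) / length(mask)
}

#' Write / read a gate-set definition file
#'
#' YAML schema: a `gates` list whose entries carry `name`, `x_channel`,
#' `y_channel` and either `rect: [xmin, xmax, ymin, ymax]` or
#' `polygon: [[x, y], ...]`.
#'
#' @param gates A [gate_set()].
#' @param path File path.
#' @return `path` (writer) or a [gate_set()] (reader).
#' @export
write_gate_set <- function(gates, path) {
  stopifnot(inherits(gates, "gate_set"))
  out <- list(combination = "AND",
              gates = lapply(gates$gates, function(g) {
                e <- list(name = g$name, x_channel = g$x_channel,
                          y_channel = g$y_channel)
                if (!is.null(g$rect)) e$rect <- as.numeric(g$rect)
                else e$polygon <- lapply(seq_len(nrow(g$polygon)),
                                         function(i) as.numeric(g$polygon[i, ]))
                e
              }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_gate_set
#' @export
read_gate_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  gate_set(lapply(cfg$gates, function(e) {
    gate(e$name, e$x_channel, e$y_channel,
         rect = if (!is.null(e$rect)) unlist(e$rect),
         polygon = if (!is.null(e$polygon))
           matrix(unlist(e$polygon), ncol = 2, byrow = TRUE))
  }))
}
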