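#' Electrode specifications
#'
#' Electrodes are not meshed as conductors; each is mapped to the set of
#' admittance-network nodes nearest its metal surface and treated as a
#' current-injection node set ([place_electrode()]).
#'
#' @param centre centre of the ring (m), length-3.
#' @param normal ring plane normal (need not be unit length).
#' @param diameter centreline diameter of the ring (m).
#' @param wire_diameter wire diameter (m); geometric bookkeeping only, the
#'   node mapping uses the centreline.
#' @param role `"stimulating"` or `"return"`.
#' @return An `electrode_spec`.
#' @export
electrode_ring <- function(centre, normal, diameter, wire_diameter = 0.27e-3,
                           role = c("stimulating", "return")) {
  role <- match.arg(role)
  stopifnot(length(centre) == 3L, length(normal) == 3L,
            diameter > 0, wire_diameter > 0)
  structure(list(kind = "ring", centre = as.numeric(centre),
                 normal = as.numeric(normal) / sqrt(sum(normal^2)),
                 diameter = diameter, wire_diameter = wire_diameter,
                 role = role),
            class = "electrode_spec")
}

#' @rdname electrode_ring
#' @param tip needle tip position (m).
#' @param direction shaft direction from the tip.
#' @param exposed_length exposed (conducting) shaft length (m).
#' @export
electrode_needle <- function(tip, direction, exposed_length,
                             role = c("return", "stimulating")) {
  role <- match.arg(role)
  stopifnot(length(tip) == 3L, length(direction) == 3L, exposed_length > 0)
  structure(list(kind = "needle", tip = as.numeric(tip),
                 direction = as.numeric(direction) / sqrt(sum(direction^2)),
                 exposed_length = exposed_length, role = role),
            class = "electrode_spec")
}

#' @method print electrode_spec
#' @export
print.electrode_spec <- function(x, ...) {
  cat("<electrode_spec> ", x$kind, " (", x$role, ")\n", sep = "")
  invisible(x)
}

snap_points_to_nodes <- function(grid, pts) {
  h <- grid$spacing
  ijk <- round(sweep(pts, 2L, grid$origin, "-") / h - 0.5)
  ijk <- pmax(ijk, 0)
  ijk <- sweep(ijk, 2L, grid$dims - 1L, pmin)
  storage.mode(ijk) <- "integer"
  sort(unique(node_index(grid$dims, ijk)))
}

#' Map an electrode to admittance-network nodes
#'
#' Rings map to the nodes nearest the torus centreline (the centreline is
#' sampled at a quarter-spacing arc step and snapped to voxel centres);
#' needles map to the nodes along the exposed shaft. The resulting set is
#' the equipotential current-injection surface used by
#' [solve_unit_field()].
#'
#' @param grid a [voxel_grid()].
#' @param spec an [electrode_ring()] or [electrode_needle()].
#' @return Sorted vector of 1-based linear node indices.
#' @export
place_electrode <- function(grid, spec) {
  stopifnot(inherits(spec, "electrode_spec"))
  h <- grid$spacing
  if (spec$kind == "ring") {
    r <- spec$diameter / 2
    n <- spec$normal
    # orthonormal frame in the ring plane
    a <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * n) * n; u <- u / sqrt(sum(u^2))
    v <- c(n[2L] * u[3L] - n[3L] * u[2L],
           n[3L] * u[1L] - n[1L] * u[3L],
           n[1L] * u[2L] - n[2L] * u[1L])
    nth <- max(16L, ceiling(2 * pi * r / (h / 4)))
    th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
    pts <- outer(cos(th), u) * r + outer(sin(th), v) * r
    pts <- sweep(pts, 2L, spec$centre, "+")
  } else {
    nseg <- max(2L, ceiling(spec$exposed_length / (h / 4)))
    s <- seq(0, spec$exposed_length, length.out = nseg)
    pts <- sweep(outer(s, spec$direction), 2L, spec$tip, "+")
  }
  inb <- pts[, 1L] >= grid$origin[1L] & pts[, 1L] <= grid$origin[1L] + grid$dims[1L] * h &
    pts[, 2L] >= grid$origin[2L] & pts[, 2L] <= grid$origin[2L] + grid$dims[2L] * h &
    pts[, 3L] >= grid$origin[3L] & pts[, 3L] <= grid$origin[3L] + grid$dims[3L] * h
  if (!any(inb))
    stop("electrode geometry does not intersect the grid")
  nodes <- snap_points_to_nodes(grid, pts[inb, , drop = FALSE])
  if (!length(nodes)) stop("electrode mapped to an empty node set")
  nodes
}

#' Electrode presets for the two transcorneal stimulation setups
#'
#' `TES1`: a stimulating ring on the temporal (+x) side of the eyeball and a
#' return ring mirrored on the nasal side, both lying on the eye surface.
#' `TES2`: a stimulating ring on the cornea (+z pole of the eye) and a
#' return needle in the head tissue on the temporal side.
#'
#' @param grid a grid built by [build_head_eye_model()].
#' @param name `"TES1"` or `"TES2"`.
#' @param ring_diameter centreline diameter of the rings (m); default the
#'   3 mm corneal electrode.
#' @param wire_diameter ring wire diameter (m).
#' @param needle_offset distance of the TES2 needle shaft from the temporal
#'   eye surface (m).
#' @param needle_length exposed needle length (m).
#' @param config geometry config of the grid; taken from the grid attribute
#'   by default.
#' @return list with `stimulating` and `return` node index vectors and the
#'   underlying `specs`; class `electrode_set`.
#' @export
tes_preset <- function(grid, name = c("TES2", "TES1"),
                       ring_diameter = 3e-3, wire_diameter = 0.27e-3,
                       needle_offset = 2e-3, needle_length = 5e-3,
                       config = attr(grid, "config")) {
  name <- match.arg(name)
  if (is.null(config))
    stop("grid has no geometry config; pass `config` explicitly")
  ec <- config$eye_centre
  R <- config$eye_diameter / 2
  a <- ring_diameter / 2
  if (a >= R) stop("ring diameter exceeds the eye diameter")
  b <- sqrt(R^2 - a^2)  # offset of the ring plane so the circle lies on the eye
  if (name == "TES1") {
    stim <- electrode_ring(ec + c(b, 0, 0), c(1, 0, 0), ring_diameter,
                           wire_diameter, role = "stimulating")
    ret <- electrode_ring(ec - c(b, 0, 0), c(1, 0, 0), ring_diameter,
                          wire_diameter, role = "return")
  } else {
    stim <- electrode_ring(ec + c(0, 0, b), c(0, 0, 1), ring_diameter,
                           wire_diameter, role = "stimulating")
    # subdermal needle in the temporal head tissue, level with the
    # posterior pole of the eye, shaft running away from the cornea
    tipx <- ec[1L] + R + needle_offset
    ret <- electrode_needle(c(tipx, ec[2L], ec[3L] - R), c(0, 0, -1),
                            needle_length, role = "return")
  }
  s_nodes <- place_electrode(grid, stim)
  r_nodes <- place_electrode(grid, ret)
  if (length(intersect(s_nodes, r_nodes)))
    stop("stimulating and return node sets overlap")
  structure(list(name = name, stimulating = s_nodes, return = r_nodes,
                 specs = list(stimulating = stim, return = ret)),
            class = "electrode_set")
}

#' @method print electrode_set
#' @export
print.electrode_set <- function(x, ...) {
  cat("<electrode_set> ", x$name, ": ", length(x$stimulating),
      " stimulating / ", length(x$return), " return nodes\n", sep = "")
  invisible(x)
}
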