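#' Morphologies
#'
#' A `morphology` is an ordered set of conical/cylindrical sections forming
#' a connected tree: each row has a region tag, 3D start/end points and
#' start/end diameters, all in micrometres (local cell frame). Section 1 is
#' the root; `parent` refers to the section whose distal end the section
#' attaches to (0 for the root).
#'
#' @param sections data.frame with columns `region`, `parent`,
#'   `x0,y0,z0,x1,y1,z1`, `d0`, `d1` (micrometres).
#' @param cell_type free-form label (`"bc"`, `"rgc"`, ...).
#' @return object of class `morphology`.
#' @export
morphology <- function(sections, cell_type = "cell") {
  need <- c("region", "parent", "x0", "y0", "z0", "x1", "y1", "z1", "d0", "d1")
  if (!all(need %in% names(sections)))
    stop("sections must have columns: ", paste(need, collapse = ", "))
  if (any(sections$d0 <= 0) || any(sections$d1 <= 0))
    stop("all diameters must be > 0")
  p <- sections$parent
  if (p[1L] != 0L) stop("section 1 must be the root (parent 0)")
  if (nrow(sections) > 1L) {
    idx <- seq_along(p)[-1L]
    if (any(p[-1L] < 1L) || any(p[-1L] >= idx))
      stop("sections must form a tree ordered with parents before children")
  }
  structure(list(sections = sections, cell_type = cell_type),
            class = "morphology")
}

#' @method print morphology
#' @export
print.morphology <- function(x, ...) {
  s <- x$sections
  len <- section_length(x)
  cat("<morphology> ", x$cell_type, ": ", nrow(s), " sections, total length ",
      format(sum(len), digits = 4), " um\n", sep = "")
  agg <- tapply(len, s$region, sum)
  for (nm in names(agg))
    cat(sprintf("  %-22s %8.1f um\n", nm, agg[[nm]]))
  invisible(x)
}

#' Section lengths (micrometres)
#' @param morph a [morphology()].
#' @export
section_length <- function(morph) {
  s <- morph$sections
  sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2 + (s$z1 - s$z0)^2)
}

section_row <- function(region, parent, p0, p1, d0, d1 = d0) {
  data.frame(region = region, parent = parent,
             x0 = p0[1L], y0 = p0[2L], z0 = p0[3L],
             x1 = p1[1L], y1 = p1[2L], z1 = p1[3L],
             d0 = d0, d1 = d1, stringsAsFactors = FALSE)
}

#' Build the parametric DB4 spiking bipolar cell morphology
#'
#' A five-region chain along the local +z axis (the retina-depth axis),
#' ordered terminal -> presynaptic terminal -> axon -> soma -> dendrite so
#' that z = 0 is the vitread (terminal) end and the dendritic apex points
#' sclerad. The default cell height is 65 um. The soma is represented as a
#' cylinder of equal diameter and length.
#'
#' @param dendrite_length,soma_diameter,axon_length,presyn_length,terminal_length
#'   section lengths / soma size in micrometres.
#' @param dendrite_diameter,axon_diameter,terminal_diameter diameters (um).
#' @return a [morphology()] with regions
#'   `soma, dendrite, axon, presynaptic_terminal, terminal`.
#' @export
build_db4_bc <- function(dendrite_length = 10, soma_diameter = 10,
                         axon_length = 35, presyn_length = 5,
                         terminal_length = 5,
                         dendrite_diameter = 1, axon_diameter = 1,
                         terminal_diameter = 1.5) {
  lens <- c(terminal_length, presyn_length, axon_length, soma_diameter,
            dendrite_length)
  if (any(lens <= 0)) stop("all section lengths must be > 0")
  z <- cumsum(c(0, lens))
  secs <- rbind(
    section_row("terminal", 0L, c(0, 0, z[1L]), c(0, 0, z[2L]), terminal_diameter),
    section_row("presynaptic_terminal", 1L, c(0, 0, z[2L]), c(0, 0, z[3L]),
                terminal_diameter),
    section_row("axon", 2L, c(0, 0, z[3L]), c(0, 0, z[4L]), axon_diameter),
    section_row("soma", 3L, c(0, 0, z[4L]), c(0, 0, z[5L]), soma_diameter),
    section_row("dendrite", 4L, c(0, 0, z[5L]), c(0, 0, z[6L]), dendrite_diameter))
  m <- morphology(secs, "bc")
  attr(m, "detect_region") <- "axon"
  m
}

#' Build the parametric A2 retinal ganglion cell morphology
#'
#' Soma (20 um sphere-equivalent cylinder) with a stylized planar
#' bifurcating dendritic arbor spanning `dendritic_field` um tip-to-tip in
#' the local x-y (retinal) plane, and an axon running along local +x
#' through the axon hillock (AH), sodium-channel band (SOCB), narrow
#' segment (NS) and distal axon (DA), 1000 um in total.
#'
#' @param soma_diameter soma diameter (um).
#' @param dendritic_field tip-to-tip dendritic span (um).
#' @param axon_lengths named lengths (um) of `AH`, `SOCB`, `NS`, `DA`; must
#'   sum to `axon_total`.
#' @param axon_total total axon length (um).
#' @param axon_diameters named diameters; AH tapers from `AH0` to `AH1`.
#' @return a [morphology()] with regions
#'   `soma, dendrite, AH, SOCB, NS, DA`.
#' @export
build_a2_rgc <- function(soma_diameter = 20, dendritic_field = 320,
                         axon_lengths = c(AH = 40, SOCB = 40, NS = 90, DA = 830),
                         axon_total = 1000,
                         axon_diameters = c(AH0 = 2, AH1 = 1, SOCB = 1,
                                            NS = 0.4, DA = 1)) {
  if (abs(sum(axon_lengths) - axon_total) > 1e-9)
    stop("axon segment lengths must sum to the total axon length (",
         axon_total, " um)")
  if (any(axon_lengths <= 0)) stop("axon segment lengths must be > 0")
  rs <- soma_diameter / 2
  secs <- section_row("soma", 0L, c(0, 0, -rs), c(0, 0, rs), soma_diameter)

  # planar arbor: four primaries, each bifurcating once; branch length set
  # so the tips sit exactly at dendritic_field/2 from the soma centre
  spread <- 25 * pi / 180
  # branch length such that tips land exactly at dendritic_field/2 from the
  # soma centre: |u*(rs + Lb) + Lb*dir(spread)| = dendritic_field/2
  cc <- 1 + cos(spread); dd <- sin(spread); rr <- dendritic_field / 2
  Lb <- (-2 * rs * cc + sqrt(4 * rs^2 * cc^2 -
          4 * (cc^2 + dd^2) * (rs^2 - rr^2))) / (2 * (cc^2 + dd^2))
  prim_dirs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  parent_of_prim <- integer(4)
  for (pidx in 1:4) {
    u <- prim_dirs[pidx, ]
    p0 <- c(u * rs, 0)         # leave from the soma equator
    p1 <- c(u * (rs + Lb), 0)
    secs <- rbind(secs, section_row("dendrite", 1L, p0, p1, 1.5))
    nr <- nrow(secs)
    parent_of_prim[pidx] <- nr
    ang0 <- atan2(u[2L], u[1L])
    for (sgn in c(-1, 1)) {
      a <- ang0 + sgn * spread
      q0 <- p1
      q1 <- p1 + c(cos(a), sin(a), 0) * Lb
      secs <- rbind(secs, section_row("dendrite", nr, q0, q1, 1.0))
    }
  }

  # axon along +x from the soma equator
  x0 <- rs
  ax_regions <- c("AH", "SOCB", "NS", "DA")
  dia0 <- c(axon_diameters[["AH0"]], axon_diameters[["SOCB"]],
            axon_diameters[["NS"]], axon_diameters[["DA"]])
  dia1 <- c(axon_diameters[["AH1"]], axon_diameters[["SOCB"]],
            axon_diameters[["NS"]], axon_diameters[["DA"]])
  parent <- 1L
  for (k in seq_along(ax_regions)) {
    L <- axon_lengths[[ax_regions[k]]]
    secs <- rbind(secs, section_row(ax_regions[k], parent,
                                    c(x0, 0, 0), c(x0 + L, 0, 0),
                                    dia0[k], dia1[k]))
    parent <- nrow(secs)
    x0 <- x0 + L
  }
  m <- morphology(secs, "rgc")
  attr(m, "detect_region") <- "DA"
  m
}

#' Read / write SWC morphology files
#'
#' Standard 7-column SWC (`id type x y z radius parent`, 1-based parents,
#' root parent -1, radii are half-diameters). Consecutive points become
#' sections; SWC structure types are mapped to region tags through
#' `type_map`.
#'
#' @param path file path.
#' @param type_map named character vector, SWC type code -> region tag.
#' @param cell_type label for the resulting morphology.
#' @return a [morphology()].
#' @export
read_swc <- function(path,
                     type_map = c("1" = "soma", "2" = "axon",
                                  "3" = "dendrite", "4" = "dendrite"),
                     cell_type = "swc") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty SWC file: ", path)
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  if (ncol(m) != 7L) stop("SWC file must have 7 columns")
  id <- as.integer(m[, 1L]); typ <- as.integer(m[, 2L])
  par <- as.integer(m[, 7L])
  ord <- order(id)
  m <- m[ord, , drop = FALSE]; id <- id[ord]; typ <- typ[ord]; par <- par[ord]
  row_of <- match(seq_len(max(id)), id)
  # cycle / validity checks
  for (k in seq_along(id)) {
    seen <- integer(0); cur <- k
    while (TRUE) {
      pk <- par[cur]
      if (pk == -1L) break
      prow <- row_of[pk]
      if (is.na(prow)) stop("SWC parent ", pk, " does not exist")
      if (prow %in% seen || prow == cur) stop("cyclic parent links in SWC file")
      seen <- c(seen, cur)
      cur <- prow
      if (length(seen) > length(id)) stop("cyclic parent links in SWC file")
    }
  }
  unknown <- setdiff(as.character(unique(typ)), names(type_map))
  if (length(unknown))
    stop("unknown SWC structure type(s) without mapping: ",
         paste(unknown, collapse = ", "))

  roots <- which(par == -1L)
  if (length(roots) != 1L) stop("SWC file must have exactly one root")
  secs <- NULL
  sec_of_point <- integer(length(id))  # section ending at this point
  # root point: a soma sphere becomes an equal-diameter cylinder
  r0 <- m[roots, 6L]
  p0 <- m[roots, 3:5]
  secs <- section_row(type_map[[as.character(typ[roots])]], 0L,
                      p0 - c(0, 0, r0), p0 + c(0, 0, r0), 2 * r0)
  sec_of_point[roots] <- 1L
  for (k in seq_along(id)) {
    if (par[k] == -1L) next
    prow <- row_of[par[k]]
    secs <- rbind(secs, section_row(type_map[[as.character(typ[k])]],
                                    sec_of_point[prow],
                                    m[prow, 3:5], m[k, 3:5],
                                    2 * m[prow, 6L], 2 * m[k, 6L]))
    sec_of_point[k] <- nrow(secs)
  }
  mo <- morphology(secs, cell_type)
  attr(mo, "swc_points") <- data.frame(id = id, type = typ,
                                       x = m[, 3L], y = m[, 4L], z = m[, 5L],
                                       radius = m[, 6L], parent = par)
  mo
}

#' @rdname read_swc
#' @param morph a morphology read by [read_swc()] (point table preserved) or
#'   any morphology (sections are written as two-point segments).
#' @export
write_swc <- function(morph, path) {
  pts <- attr(morph, "swc_points")
  if (is.null(pts)) {
    s <- morph$sections
    n <- nrow(s)
    # root start point + one point per section end
    type_of <- function(region)
      switch(region, soma = 1L, axon = 2L, dendrite = 3L, 2L)
    pts <- data.frame(id = seq_len(n + 1L),
                      type = c(type_of(s$region[1L]),
                               vapply(s$region, type_of, 1L)),
                      x = c(s$x0[1L], s$x1), y = c(s$y0[1L], s$y1),
                      z = c(s$z0[1L], s$z1),
                      radius = c(s$d0[1L] / 2, s$d1 / 2),
                      parent = c(-1L, s$parent + 1L))
    pts$parent[2L] <- 1L
  }
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   pts$id, pts$type, pts$x, pts$y, pts$z, pts$radius,
                   pts$parent)
  writeLines(c("# SWC written by retistim", lines), path)
  invisible(path)
}

#' Rigidly transform a morphology
#'
#' @param morph a [morphology()].
#' @param rotation 3x3 rotation matrix applied in the local frame (um).
#' @param translation length-3 shift (um) applied after rotation.
#' @export
transform_morphology <- function(morph, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  s <- morph$sections
  p0 <- t(rotation %*% t(as.matrix(s[, c("x0", "y0", "z0")]))) +
    matrix(translation, nrow(s), 3L, byrow = TRUE)
  p1 <- t(rotation %*% t(as.matrix(s[, c("x1", "y1", "z1")]))) +
    matrix(translation, nrow(s), 3L, byrow = TRUE)
  s[, c("x0", "y0", "z0")] <- p0
  s[, c("x1", "y1", "z1")] <- p1
  out <- morphology(s, morph$cell_type)
  attr(out, "detect_region") <- attr(morph, "detect_region")
  out
}

#' Rotation matrix about an axis
#' @param axis rotation axis (length-3).
#' @param angle angle in radians.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * tcrossprod(u)
}
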