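#' Tissue resistivities of the rat head-eye voxel model
#'
#' Default resistivity table (ohm metre) for every tissue that can appear in
#' the reduced head-eye voxel model. The homogeneous retina entry of
#' 1.5 ohm m stands in for the layered (degenerated) retina.
#'
#' @return Named numeric vector, tissue name -> resistivity in ohm m.
#' @export
default_tissue_table <- function() {
  c(muscle          = 4.82,
    skin            = 5000,
    fat             = 64.61,
    bone_marrow     = 762.95,
    bone_cancellous = 12.67,
    brain           = 25.72,
    vitreous        = 0.666,
    retina          = 1.5,
    lens            = 3.15,
    cornea          = 2.4)
}

#' Construct a voxel grid
#'
#' A `voxel_grid` is a labelled 3D tissue map: `dims` voxels of uniform edge
#' `spacing` whose corner (voxel index `(0,0,0)`) sits at `origin`. Voxel
#' corners are the geometric nodes (`voxel_to_world()`); the admittance
#' network built from the grid places one electrical node at each voxel
#' centre (see [assemble_network()]).
#'
#' @param labels integer 3D array (`dims`) of tissue codes indexing `tissues`.
#' @param spacing voxel edge length in metres (uniform).
#' @param origin world position (m) of the corner of voxel `(0,0,0)`.
#' @param tissues character vector mapping label codes to tissue names.
#' @param resistivity_table named numeric, tissue name -> resistivity (ohm m).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(labels, spacing, origin, tissues, resistivity_table) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (metres)")
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  used <- sort(unique(as.integer(labels)))
  if (any(used < 1L) || any(used > length(tissues)))
    stop("labels contain codes outside the tissue list")
  missing <- setdiff(tissues[used], names(resistivity_table))
  if (length(missing))
    stop("no resistivity for tissue(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(resistivity_table)) || any(resistivity_table <= 0))
    stop("all resistivities must be finite and > 0")
  structure(list(dims = dim(labels), spacing = spacing, origin = origin,
                 labels = labels, tissues = tissues,
                 resistivity_table = resistivity_table),
            class = "voxel_grid")
}

#' @method print voxel_grid
#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels @ ", format(x$spacing * 1e3), " mm\n", sep = "")
  tab <- table(x$tissues[as.integer(x$labels)])
  for (nm in names(tab))
    cat(sprintf("  %-16s %8d voxels  (%g ohm m)\n", nm, tab[[nm]],
                x$resistivity_table[[nm]]))
  invisible(x)
}

#' Resistivity of every voxel
#' @param grid a [voxel_grid()].
#' @return numeric 3D array of resistivities (ohm m).
#' @export
grid_resistivity <- function(grid) {
  rho <- grid$resistivity_table[grid$tissues[as.integer(grid$labels)]]
  array(unname(rho), dim = grid$dims)
}

#' Voxel-corner index to world coordinates (and back)
#'
#' Indices are 0-based triples; `world = origin + index * spacing`.
#'
#' @param grid a [voxel_grid()].
#' @param index integer matrix (n x 3) of 0-based corner indices.
#' @return `voxel_to_world()`: n x 3 matrix of positions (m).
#' @export
voxel_to_world <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep(index * grid$spacing, 2L, grid$origin, "+")
}

#' @rdname voxel_to_world
#' @param world numeric matrix (n x 3) of world positions (m).
#' @return `world_to_voxel()`: n x 3 integer matrix of nearest corner indices.
#' @export
world_to_voxel <- function(grid, world) {
  world <- matrix(as.numeric(world), ncol = 3L)
  idx <- round(sweep(world, 2L, grid$origin, "-") / grid$spacing)
  storage.mode(idx) <- "integer"
  idx
}

#' World coordinates of voxel centres (electrical nodes)
#' @param grid a [voxel_grid()].
#' @param index integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of centre positions (m).
#' @export
voxel_centre <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep((index + 0.5) * grid$spacing, 2L, grid$origin, "+")
}

# linear (1-based) node index of voxel (i,j,k) 0-based
node_index <- function(dims, ijk) {
  1L + ijk[, 1L] + dims[1L] * (ijk[, 2L] + dims[2L] * ijk[, 3L])
}

node_ijk <- function(dims, idx) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1L]
  j <- (idx0 %/% dims[1L]) %% dims[2L]
  k <- idx0 %/% (dims[1L] * dims[2L])
  cbind(i, j, k)
}

#' Positions (m) of electrical nodes given linear indices
#' @param grid a [voxel_grid()].
#' @param idx 1-based linear node (voxel) indices.
#' @export
node_position <- function(grid, idx) {
  voxel_centre(grid, node_ijk(grid$dims, as.integer(idx)))
}

#' Default geometry for the reduced head-eye model
#'
#' All lengths in metres. The defaults give a 20 mm cube at 0.2 mm spacing
#' (1e6 computational cells) holding a layered spherical eye: cornea cap,
#' lens, vitreous body and a one-voxel retina shell, embedded in a head
#' block of muscle with skin and fat shells, a bone slab and a brain
#' compartment behind the eye. The cornea faces +z.
#'
#' @param spacing voxel edge (m).
#' @param domain cube edge lengths (m), length-3.
#' @param eye_diameter outer eye diameter (m).
#' @param retina_thickness posterior retina shell thickness (m).
#' @param cornea_thickness anterior cornea cap thickness (m).
#' @param cornea_cap_angle half-angle of the cornea cap from the +z eye axis
#'   (degrees).
#' @param lens_diameter lens diameter (m).
#' @param eye_centre world position of the eye centre; default places the
#'   cornea apex about 2.9 mm below the +z face.
#' @param skin_thickness,fat_thickness outer shell thicknesses (m).
#' @param bone_z z-range (m) of the bone slab behind the eye.
#' @param brain_zmax brain occupies z below this plane (m).
#' @param tissues resistivity table, see [default_tissue_table()].
#' @return list of geometry parameters (class `head_eye_config`).
#' @export
head_eye_config <- function(spacing = 0.2e-3,
                            domain = c(20e-3, 20e-3, 20e-3),
                            eye_diameter = 6.3e-3,
                            retina_thickness = 0.2e-3,
                            cornea_thickness = 0.3e-3,
                            cornea_cap_angle = 45,
                            lens_diameter = 3.5e-3,
                            eye_centre = NULL,
                            skin_thickness = NULL,
                            fat_thickness = NULL,
                            bone_z = c(4e-3, 5e-3),
                            brain_zmax = 4e-3,
                            tissues = default_tissue_table()) {
  if (is.null(eye_centre))
    eye_centre <- c(domain[1L] / 2, domain[2L] / 2, 0.7 * domain[3L])
  if (is.null(skin_thickness)) skin_thickness <- spacing
  if (is.null(fat_thickness)) fat_thickness <- spacing
  structure(list(spacing = spacing, domain = domain,
                 eye_diameter = eye_diameter,
                 retina_thickness = retina_thickness,
                 cornea_thickness = cornea_thickness,
                 cornea_cap_angle = cornea_cap_angle,
                 lens_diameter = lens_diameter,
                 eye_centre = eye_centre,
                 skin_thickness = skin_thickness,
                 fat_thickness = fat_thickness,
                 bone_z = bone_z, brain_zmax = brain_zmax,
                 tissues = tissues),
            class = "head_eye_config")
}

#' Build the reduced parametric head-eye voxel model
#'
#' Embeds a layered spherical eye (cornea cap, lens, vitreous, posterior
#' retina shell) in a head block of muscle / skin / fat / bone / brain
#' compartments, all on a uniform voxel lattice. Every voxel is labelled and
#' every label resolves to a resistivity through the config's tissue table;
#' the retina is homogeneous at its table value (default 1.5 ohm m).
#'
#' @param config a [head_eye_config()].
#' @return A [voxel_grid()].
#' @export
build_head_eye_model <- function(config = head_eye_config()) {
  stopifnot(inherits(config, "head_eye_config"))
  h <- config$spacing
  R <- config$eye_diameter / 2
  if (h > config$retina_thickness)
    stop("spacing (", h, " m) exceeds retina thickness (",
         config$retina_thickness, " m): the retina shell would vanish")
  if (config$retina_thickness + config$cornea_thickness >= R)
    stop("layer thicknesses exceed the eye radius")
  lensR <- config$lens_diameter / 2
  # lens centre sits on the eye axis, anterior of the eye centre
  lens_c <- config$eye_centre + c(0, 0, 0.25 * R)
  if (lensR + 0.25 * R + config$cornea_thickness >= R)
    stop("lens does not fit inside the eye")

  dims <- as.integer(round(config$domain / h))
  if (any(dims < 4L)) stop("domain too small for the requested spacing")
  origin <- c(0, 0, 0)
  tissues <- names(config$tissues)
  code <- function(nm) {
    k <- match(nm, tissues)
    if (is.na(k)) stop("tissue '", nm, "' missing from the tissue table")
    k
  }

  xc <- (seq_len(dims[1L]) - 0.5) * h
  yc <- (seq_len(dims[2L]) - 0.5) * h
  zc <- (seq_len(dims[3L]) - 0.5) * h
  lab <- array(code("muscle"), dim = dims)

  Z <- rep(zc, each = dims[1L] * dims[2L])
  # head compartments behind / below the eye
  lab[Z < config$brain_zmax] <- code("brain")
  lab[Z >= config$bone_z[1L] & Z < config$bone_z[2L]] <- code("bone_cancellous")

  # outer shells: skin then fat beneath it
  near_face <- function(v, len, t) v < t | v > len - t
  X <- rep(xc, times = dims[2L] * dims[3L])
  Y <- rep(rep(yc, each = dims[1L]), times = dims[3L])
  tsk <- config$skin_thickness
  tft <- tsk + config$fat_thickness
  fat <- near_face(X, config$domain[1L], tft) | near_face(Y, config$domain[2L], tft) |
    near_face(Z, config$domain[3L], tft)
  lab[fat] <- code("fat")
  skin <- near_face(X, config$domain[1L], tsk) | near_face(Y, config$domain[2L], tsk) |
    near_face(Z, config$domain[3L], tsk)
  lab[skin] <- code("skin")

  # the eye overwrites everything inside its sphere
  dx <- X - config$eye_centre[1L]
  dy <- Y - config$eye_centre[2L]
  dz <- Z - config$eye_centre[3L]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  inside <- r <= R
  if (!any(inside)) stop("eye sphere lies outside the domain")
  lab[inside] <- code("vitreous")
  # polar angle from the +z (corneal) axis
  cosang <- ifelse(r > 0, dz / pmax(r, 1e-300), 1)
  cap <- cosang >= cos(config$cornea_cap_angle * pi / 180)
  lab[inside & cap & r > R - config$cornea_thickness] <- code("cornea")
  lab[inside & !cap & r > R - config$retina_thickness] <- code("retina")
  dl <- sqrt((X - lens_c[1L])^2 + (Y - lens_c[2L])^2 + (Z - lens_c[3L])^2)
  lab[dl <= lensR] <- code("lens")

  # seal the shells: a vitreous voxel with a face neighbour outside the eye
  # becomes retina (or cornea inside the cap), guaranteeing the shell is at
  # least one voxel thick despite centre-based labelling of a curved surface
  eye_codes <- vapply(c("vitreous", "retina", "cornea", "lens"), code, 1L)
  outside <- !array(lab %in% eye_codes, dim = dims)
  labarr <- array(lab, dim = dims)
  exposed <- array(FALSE, dim = dims)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  exposed[-nx, , ] <- exposed[-nx, , ] | outside[-1, , ]
  exposed[-1, , ]  <- exposed[-1, , ]  | outside[-nx, , ]
  exposed[, -ny, ] <- exposed[, -ny, ] | outside[, -1, ]
  exposed[, -1, ]  <- exposed[, -1, ]  | outside[, -ny, ]
  exposed[, , -nz] <- exposed[, , -nz] | outside[, , -1]
  exposed[, , -1]  <- exposed[, , -1]  | outside[, , -nz]
  fix <- as.vector(exposed) & lab == code("vitreous")
  lab[fix & cap] <- code("cornea")
  lab[fix & !cap] <- code("retina")

  grid <- voxel_grid(lab, h, origin, tissues, config$tissues)
  attr(grid, "config") <- config
  check_retina_shell(grid, config)
  grid
}

# the retina shell must be at least one voxel thick wherever it exists:
# march radial rays through the posterior eye and require a retina voxel
check_retina_shell <- function(grid, config) {
  R <- config$eye_diameter / 2
  capc <- cos(config$cornea_cap_angle * pi / 180)
  dirs <- expand.grid(theta = seq(config$cornea_cap_angle + 10, 175, by = 15),
                      phi = seq(0, 345, by = 30))
  th <- dirs$theta * pi / 180; ph <- dirs$phi * pi / 180
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  rs <- seq(R - config$retina_thickness - grid$spacing, R,
            by = grid$spacing / 8)
  rcode <- match("retina", grid$tissues)
  for (d in seq_len(nrow(u))) {
    pts <- sweep(outer(rs, u[d, ]), 2L, config$eye_centre, "+")
    ijk <- floor(sweep(pts, 2L, grid$origin, "-") / grid$spacing)
    ok <- ijk[, 1L] >= 0 & ijk[, 2L] >= 0 & ijk[, 3L] >= 0 &
      ijk[, 1L] < grid$dims[1L] & ijk[, 2L] < grid$dims[2L] & ijk[, 3L] < grid$dims[3L]
    if (!any(ok)) next
    codes <- grid$labels[node_index(grid$dims, ijk[ok, , drop = FALSE])]
    if (!any(codes == rcode))
      stop("retina shell vanished along direction (",
           paste(signif(u[d, ], 3), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Homogeneous grid of a single tissue
#'
#' Degenerate uniform medium, mainly for oracle tests of the field solver.
#'
#' @param dims integer triple of voxel counts.
#' @param spacing voxel edge (m).
#' @param tissue tissue name.
#' @param rho resistivity (ohm m); defaults to the tissue's table value.
#' @export
uniform_grid <- function(dims, spacing, tissue = "vitreous",
                         rho = default_tissue_table()[[tissue]]) {
  tab <- stats::setNames(rho, tissue)
  voxel_grid(array(1L, dim = as.integer(dims)), spacing, c(0, 0, 0),
             tissue, tab)
}

#' Export a grid to plain-text files
#'
#' Writes `labels.csv` (linear voxel index, i, j, k, tissue) and
#' `meta.json` (dims, spacing, origin, resistivity table).
#'
#' @param grid a [voxel_grid()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ijk <- node_ijk(grid$dims, seq_len(prod(grid$dims)))
  df <- data.frame(index = seq_len(prod(grid$dims)),
                   i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L],
                   tissue = grid$tissues[as.integer(grid$labels)])
  write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- list(dims = grid$dims, spacing = grid$spacing, origin = grid$origin,
               resistivity_table = as.list(grid$resistivity_table))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
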