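#' Discretize a morphology into compartments
#'
#' Each section is split into compartments of length at most
#' `max_compartment_length`. A compartment carries its region tag, lateral
#' membrane area (`pi * d * L` of a frustum), the axial resistance from its
#' midpoint to its parent's midpoint (from the intracellular resistivity
#' and the frustum geometry) and its midpoint position. Compartments are
#' ordered with parents before children (required by the cable solver).
#'
#' @param morph a [morphology()].
#' @param max_compartment_length maximum compartment length (um).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param ri intracellular resistivity (ohm cm).
#' @return A `compartment_chain`: data.frame `compartments` with columns
#'   `region, parent, area_cm2, r_axial_Mohm, x, y, z, diam, length` and the
#'   proximal/distal half-resistances `r_half_prox`, `r_half_dist`
#'   (positions um, local frame) plus `cm`, `ri`.
#' @export
compartmentalize <- function(morph, max_compartment_length = 5,
                             cm = 1, ri = 100) {
  stopifnot(inherits(morph, "morphology"), max_compartment_length > 0,
            cm > 0, ri > 0)
  s <- morph$sections
  lens <- section_length(morph)
  comps <- vector("list", nrow(s))
  # per-section: first/last compartment global index
  first_idx <- integer(nrow(s)); last_idx <- integer(nrow(s))
  ntot <- 0L

  # axial resistance (Mohm) of a frustum piece: Ri * L / (pi r0 r1), with
  # Ri in ohm cm and lengths in um -> ohm cm * um / um^2 = 1e4 ohm * (um/um^2) ...
  # work in cm: R[ohm] = Ri * L_cm / (pi * r0_cm * r1_cm)
  frustum_R <- function(L_um, d0, d1) {
    ri * (L_um * 1e-4) / (pi * (d0 / 2 * 1e-4) * (d1 / 2 * 1e-4)) / 1e6
  }

  for (k in seq_len(nrow(s))) {
    L <- lens[k]
    n <- max(1L, ceiling(L / max_compartment_length))
    f0 <- (seq_len(n) - 1) / n
    f1 <- seq_len(n) / n
    fm <- (f0 + f1) / 2
    p0 <- as.numeric(s[k, c("x0", "y0", "z0")])
    p1 <- as.numeric(s[k, c("x1", "y1", "z1")])
    dvec <- p1 - p0
    d_at <- function(f) s$d0[k] + (s$d1[k] - s$d0[k]) * f
    Lc <- L / n
    dm0 <- d_at(f0); dm1 <- d_at(f1)
    # lateral (frustum) area in cm^2: pi * (d0+d1)/2 * L, um^2 -> cm^2
    area <- pi * (dm0 + dm1) / 2 * Lc * 1e-8
    mid <- sweep(outer(fm, dvec), 2L, p0, "+")
    # half-resistances of each compartment (proximal and distal halves)
    dmid <- d_at(fm)
    rh_prox <- frustum_R(Lc / 2, dm0, dmid)
    rh_dist <- frustum_R(Lc / 2, dmid, dm1)
    comps[[k]] <- data.frame(region = s$region[k], parent = NA_integer_,
                             area_cm2 = area, r_axial_Mohm = NA_real_,
                             x = mid[, 1L], y = mid[, 2L], z = mid[, 3L],
                             diam = dmid, length = Lc,
                             rh_prox = rh_prox, rh_dist = rh_dist,
                             stringsAsFactors = FALSE)
    first_idx[k] <- ntot + 1L
    ntot <- ntot + n
    last_idx[k] <- ntot
  }
  df <- do.call(rbind, comps)
  # wire up parents: within a section, each compartment's parent is the
  # previous one; the first attaches to the last compartment of the parent
  # section (resistance = its own proximal half + the parent's distal half)
  for (k in seq_len(nrow(s))) {
    ids <- first_idx[k]:last_idx[k]
    if (length(ids) > 1L) {
      df$parent[ids[-1L]] <- ids[-length(ids)]
      df$r_axial_Mohm[ids[-1L]] <- df$rh_prox[ids[-1L]] + df$rh_dist[ids[-length(ids)]]
    }
    if (s$parent[k] > 0L) {
      pk <- last_idx[s$parent[k]]
      df$parent[ids[1L]] <- pk
      df$r_axial_Mohm[ids[1L]] <- df$rh_prox[ids[1L]] + df$rh_dist[pk]
    }
  }
  names(df)[names(df) == "rh_prox"] <- "r_half_prox"
  names(df)[names(df) == "rh_dist"] <- "r_half_dist"
  df$parent[is.na(df$parent)] <- 0L
  if (sum(df$parent == 0L) != 1L)
    stop("compartments do not form a single tree")
  structure(list(compartments = df, cm = cm, ri = ri,
                 cell_type = morph$cell_type,
                 detect_region = attr(morph, "detect_region")),
            class = "compartment_chain")
}

#' @method print compartment_chain
#' @export
print.compartment_chain <- function(x, ...) {
  df <- x$compartments
  cat("<compartment_chain> ", x$cell_type, ": ", nrow(df),
      " compartments, total area ",
      format(sum(df$area_cm2), digits = 4), " cm^2 (Cm = ", x$cm,
      " uF/cm^2, Ri = ", x$ri, " ohm cm)\n", sep = "")
  invisible(x)
}

#' Channel density tables
#'
#' A `channel_table` maps region x channel to a maximum conductance
#' density. Values are stored in the units they are conventionally printed
#' in (`units` attribute, `"mS/cm2"` or `"S/cm2"`); [assign_channels()]
#' converts to mS/cm^2 internally. Missing entries mean zero density.
#'
#' @param densities data.frame, one row per region (rownames = region tags),
#'   one column per channel.
#' @param units `"mS/cm2"` or `"S/cm2"`.
#' @param leak_erev leak reversal potential (mV).
#' @return object of class `channel_table`.
#' @export
channel_table <- function(densities, units = c("mS/cm2", "S/cm2"),
                          leak_erev = -60) {
  units <- match.arg(units)
  if (any(as.matrix(densities) < 0, na.rm = TRUE))
    stop("channel densities must be >= 0")
  if (!"leak" %in% names(densities) || any(densities$leak <= 0, na.rm = TRUE))
    stop("every region needs a positive leak density")
  structure(list(densities = densities, units = units,
                 leak_erev = leak_erev),
            class = "channel_table")
}

#' @method print channel_table
#' @export
print.channel_table <- function(x, ...) {
  cat("<channel_table> [", x$units, "], leak reversal ", x$leak_erev,
      " mV\n", sep = "")
  print(x$densities)
  invisible(x)
}

#' @rdname channel_table
#' @details `bc_channel_table()` ships the spiking DB4 bipolar-cell
#' densities (mS/cm^2): Na confined to the axon at 1000 mS/cm^2, slow K on
#' soma/dendrite, fast K on the axon, L-type Ca on the presynaptic
#' terminal, T-type Ca on soma/dendrite, HCN on the presynaptic terminal
#' and a uniform 0.033 mS/cm^2 leak.
#' @export
bc_channel_table <- function() {
  d <- data.frame(
    Na    = c(0,    0,   1000, 0,    0),
    Kslow = c(0.6,  2.4, 0,    0,    0),
    Kfast = c(0,    0,   2,    0,    0),
    CaL   = c(0,    0,   0,    1,    0),
    CaT   = c(1,    1,   0,    0,    0),
    HCN   = c(0,    0,   0,    3.25, 0),
    leak  = c(0.033, 0.033, 0.033, 0.033, 0.033),
    row.names = c("soma", "dendrite", "axon", "presynaptic_terminal",
                  "terminal"))
  channel_table(d, units = "mS/cm2", leak_erev = -60)
}

#' @rdname channel_table
#' @details `rgc_channel_table()` ships the A2 ganglion-cell densities
#' (S/cm^2) across soma, dendrite and the four axonal regions (AH, SOCB,
#' NS, DA); the A-type K density is slaved to `3 * g_K`, the
#' calcium-activated K density to `0.004 * g_K` (soma and dendrite only),
#' and the leak is uniform at 0.05 mS/cm^2 with a -60 mV reversal.
#' @export
rgc_channel_table <- function() {
  gK <- c(0.12, 0.05, 0.6, 0.8, 0.6, 0.6)
  d <- data.frame(
    Na  = c(0.35, 0.1, 0.8, 2.4, 0.9, 0.8),
    K   = gK,
    KA  = 3 * gK,
    KCa = c(0.004 * gK[1:2], 0, 0, 0, 0),
    Ca  = c(0.137, 0.05, 0, 0, 0, 0),
    h   = c(0, 0, 0, 0, 0, 0),
    T   = c(0.004, 0, 0, 0, 0, 0),
    leak = rep(0.05e-3, 6),  # 0.05 mS/cm^2 in S/cm^2
    row.names = c("soma", "dendrite", "AH", "SOCB", "NS", "DA"))
  channel_table(d, units = "S/cm2", leak_erev = -60)
}

#' Density table in mS/cm^2 regardless of printed units
#' @param table a [channel_table()].
#' @export
densities_mS <- function(table) {
  m <- as.matrix(table$densities)
  if (table$units == "S/cm2") m <- m * 1e3
  m
}

#' Attach channel densities to a compartment chain
#'
#' Every compartment receives the densities of its region; regions absent
#' from the table are an error, absent channel entries mean zero. The
#' result bundles the chain, the density matrix and the kinetics registry
#' into a simulatable cell.
#'
#' @param chain a [compartmentalize()] result.
#' @param table a [channel_table()].
#' @param kinetics a kinetics registry ([bc_kinetics()], [rgc_kinetics()],
#'   or one read with [read_kinetics()]). Defaults by cell type.
#' @return object of class `cable_cell`.
#' @export
assign_channels <- function(chain, table, kinetics = NULL) {
  stopifnot(inherits(chain, "compartment_chain"),
            inherits(table, "channel_table"))
  regions <- unique(chain$compartments$region)
  missing <- setdiff(regions, rownames(table$densities))
  if (length(missing))
    stop("region tag(s) not in channel table: ", paste(missing, collapse = ", "))
  if (is.null(kinetics))
    kinetics <- switch(chain$cell_type, bc = bc_kinetics(),
                       rgc = rgc_kinetics(),
                       stop("no default kinetics for cell type '",
                            chain$cell_type, "'; pass `kinetics`"))
  km <- densities_mS(table)
  chans <- vapply(kinetics$channels, function(ch) ch$name, "")
  unknown <- setdiff(colnames(km), chans)
  if (length(unknown))
    stop("channel(s) missing from kinetics registry: ",
         paste(unknown, collapse = ", "))
  dens <- matrix(0, nrow = length(chans), ncol = nrow(chain$compartments),
                 dimnames = list(chans, NULL))
  for (ch in colnames(km))
    dens[ch, ] <- km[chain$compartments$region, ch]
  structure(list(chain = chain, densities = dens, kinetics = kinetics,
                 leak_erev = table$leak_erev,
                 cell_type = chain$cell_type,
                 detect_region = chain$detect_region,
                 state = NULL),
            class = "cable_cell")
}

#' @method print cable_cell
#' @export
print.cable_cell <- function(x, ...) {
  cat("<cable_cell> ", x$cell_type, ": ", ncol(x$densities),
      " compartments, channels: ",
      paste(rownames(x$densities)[rowSums(x$densities) > 0], collapse = ", "),
      if (!is.null(x$state)) "  [settled]" else "", "\n", sep = "")
  invisible(x)
}

#' Compartment midpoints in world coordinates
#'
#' @param cell a `cable_cell` (or `compartment_chain`).
#' @param at world position (m) the local origin maps to.
#' @param rotation 3x3 rotation applied to local coordinates first.
#' @return n x 3 matrix of positions in metres.
#' @export
compartment_positions <- function(cell, at = c(0, 0, 0), rotation = diag(3)) {
  chain <- if (inherits(cell, "cable_cell")) cell$chain else cell
  p <- as.matrix(chain$compartments[, c("x", "y", "z")]) * 1e-6
  sweep(t(rotation %*% t(p)), 2L, at, "+")
}

#' Index of the spike-detection compartment
#'
#' The compartment nearest the midpoint of the cell's detection region
#' (axon for the bipolar cell, distal axon for the ganglion cell).
#' @param cell a `cable_cell`.
#' @export
detection_compartment <- function(cell) {
  df <- cell$chain$compartments
  reg <- cell$detect_region
  if (is.null(reg)) reg <- df$region[which.max(tapply(df$area_cm2, df$region, sum))]
  ids <- which(df$region == reg)
  if (!length(ids)) stop("detection region '", reg, "' not present")
  ids[ceiling(length(ids) / 2)]
}

#' Export a cell as JSON (compartments, areas, positions, densities)
#' @param cell a `cable_cell`.
#' @param path output path.
#' @export
write_cell_json <- function(cell, path) {
  df <- cell$chain$compartments
  out <- list(cell_type = cell$cell_type, cm = cell$chain$cm,
              ri = cell$chain$ri, compartments = df,
              densities_mS_cm2 = as.data.frame(t(cell$densities)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
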