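#' Specify a ring array of chromophore attachment sites
#'
#' A cpTMV-style double disk presents its dyes as one or two stacked circular
#' rings of equally spaced attachment sites. The ring is parameterised by the
#' number of sites and the nearest-neighbour (chord) spacing rather than by an
#' explicit radius, because the spacing between adjacent dyes within one disk
#' is what is known experimentally (about 1.95 nm for 17 sites per ring).
#'
#' @param sites_per_ring Integer >= 2, number of attachment sites per ring
#'   (default 17, one per monomer of a cpTMV disk layer).
#' @param nn_spacing Distance in nm between adjacent sites within one ring
#'   (default 1.95).
#' @param n_layers 1 or 2 rings per disk (default 2, one per layer of a
#'   double disk).
#' @param layer_separation Axial distance in nm between the two rings of a
#'   double disk (default 2.5, half the ~5 nm disk height). Ignored when
#'   `n_layers == 1`.
#' @param azimuthal_offset Rotation in radians of the second layer relative to
#'   the first (default 0, sites eclipsed).
#'
#' @return An object of class `ring_array_spec`.
#' @seealso [build_disk()], [couple_disks()]
#' @export
#' @examples
#' ring_array_spec()                     # cpTMV defaults
#' ring_array_spec(6, 1.0, n_layers = 1) # a single hexagonal ring
ring_array_spec <- function(sites_per_ring = 17, nn_spacing = 1.95,
                            n_layers = 2, layer_separation = 2.5,
                            azimuthal_offset = 0) {
  sites_per_ring <- as.integer(sites_per_ring)
  n_layers <- as.integer(n_layers)
  if (is.na(sites_per_ring) || sites_per_ring < 2L)
    stop("`sites_per_ring` must be an integer >= 2", call. = FALSE)
  if (!is.finite(nn_spacing) || nn_spacing <= 0)
    stop("`nn_spacing` must be a positive length in nm", call. = FALSE)
  if (!n_layers %in% c(1L, 2L))
    stop("`n_layers` must be 1 or 2", call. = FALSE)
  if (!is.finite(layer_separation) || layer_separation < 0)
    stop("`layer_separation` must be >= 0", call. = FALSE)
  if (!is.finite(azimuthal_offset))
    stop("`azimuthal_offset` must be finite", call. = FALSE)
  structure(
    list(sites_per_ring = sites_per_ring, nn_spacing = nn_spacing,
         n_layers = n_layers, layer_separation = layer_separation,
         azimuthal_offset = azimuthal_offset),
    class = "ring_array_spec")
}

#' @export
print.ring_array_spec <- function(x, ...) {
  cat(sprintf("Ring array: %d sites/ring x %d layer(s), spacing %.3g nm",
              x$sites_per_ring, x$n_layers, x$nn_spacing))
  if (x$n_layers == 2L)
    cat(sprintf(", layer separation %.3g nm", x$layer_separation))
  cat(sprintf("\n  ring radius %.4g nm\n",
              ring_radius(x$sites_per_ring, x$nn_spacing)))
  invisible(x)
}

#' Radius of a ring with given site count and nearest-neighbour spacing
#'
#' Inverts the chord formula: `n` points uniformly spaced on a circle of
#' radius `r` have adjacent spacing `s = 2 r sin(pi/n)`.
#'
#' @param n Number of sites on the ring (>= 2).
#' @param s Nearest-neighbour spacing in nm (> 0).
#' @return Ring radius in nm.
#' @export
#' @examples
#' ring_radius(17, 1.95) # ~5.306 nm, the cpTMV dye ring
#' ring_radius(6, 1)     # regular hexagon: radius equals side
ring_radius <- function(n, s) {
  if (!is.finite(n) || n < 2)
    stop("`n` must be >= 2", call. = FALSE)
  if (!is.finite(s) || s <= 0)
    stop("`s` must be > 0", call. = FALSE)
  s / (2 * sin(pi / n))
}

#' Place the chromophores of one disk in 3-D
#'
#' Builds the explicit site coordinates for a ring-array disk: each layer is a
#' ring of `sites_per_ring` points at [ring_radius()] in a plane normal to the
#' z axis, the two layers of a double disk displaced by +/- half the layer
#' separation. Site 1 of layer 1 sits at the reference azimuth
#' (`facing_azimuth`), which [couple_disks()] uses to aim one site of each
#' disk straight at its partner.
#'
#' @param spec A [ring_array_spec()].
#' @param center Numeric length-3 disk centre in nm.
#' @param label Disk identifier, e.g. `"donor"` or `"acceptor"`.
#' @param facing_azimuth Azimuth in radians of site 1, layer 1 (default 0,
#'   along +x).
#' @return A `chromophore_set`: a data frame with columns `disk_label`,
#'   `layer_index`, `site_index`, `x_nm`, `y_nm`, `z_nm`, carrying the spec
#'   and centre as attributes.
#' @export
#' @examples
#' d <- build_disk(ring_array_spec(), label = "donor")
#' nrow(d) # 34 sites: 17 per layer x 2 layers
build_disk <- function(spec, center = c(0, 0, 0), label = "disk",
                       facing_azimuth = 0) {
  stopifnot(inherits(spec, "ring_array_spec"))
  if (length(center) != 3L || !all(is.finite(center)))
    stop("`center` must be a finite length-3 point in nm", call. = FALSE)
  r <- ring_radius(spec$sites_per_ring, spec$nn_spacing)
  base_ang <- facing_azimuth +
    2 * pi * (seq_len(spec$sites_per_ring) - 1L) / spec$sites_per_ring
  z_off <- if (spec$n_layers == 2L)
    c(-spec$layer_separation / 2, spec$layer_separation / 2) else 0
  rows <- lapply(seq_len(spec$n_layers), function(l) {
    ang <- base_ang + (l - 1L) * spec$azimuthal_offset
    data.frame(disk_label = label, layer_index = l,
               site_index = seq_len(spec$sites_per_ring),
               x_nm = center[1] + r * cos(ang),
               y_nm = center[2] + r * sin(ang),
               z_nm = center[3] + z_off[l])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, spec = spec, center = center,
            class = c("chromophore_set", "data.frame"))
}

site_matrix <- function(set) {
  as.matrix(set[, c("x_nm", "y_nm", "z_nm")])
}

cross_distances <- function(a, b) {
  pa <- site_matrix(a); pb <- site_matrix(b)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  dz <- outer(pa[, 3], pb[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Couple a donor and an acceptor disk at their peripheries
#'
#' Places two ring-array disks side by side with parallel, coaxial-normal
#' orientation (both disk normals along z, centres on the x axis) and solves
#' for the centre separation at which the *closest* donor-acceptor site pair
#' sits exactly at `closest_pair` nm. One site of each disk is aligned on the
#' inter-centre axis facing the partner, so for disks whose layers sit at the
#' same heights the solution is simply
#' `center_separation = closest_pair + r_donor + r_acceptor`; otherwise the
#' separation is found numerically to the same calibration tolerance.
#'
#' @param spec_d,spec_a [ring_array_spec()] for the donor and acceptor disk.
#' @param closest_pair Target minimum donor-acceptor site distance in nm
#'   (default 7.5, the closest S23C-S23C distance estimated for peripherally
#'   coupled cpTMV disks).
#' @return A `coupled_disk_geometry`: list with elements `donor`, `acceptor`
#'   (chromophore sets), `center_separation`, `closest_pair`.
#' @export
#' @examples
#' geom <- couple_disks()
#' geom$center_separation           # ~18.11 nm
#' range(inter_disk_distances(geom)) # 7.5 .. ~28.7 nm
couple_disks <- function(spec_d = ring_array_spec(),
                         spec_a = ring_array_spec(),
                         closest_pair = 7.5) {
  stopifnot(inherits(spec_d, "ring_array_spec"),
            inherits(spec_a, "ring_array_spec"))
  if (!is.finite(closest_pair) || closest_pair <= 0)
    stop("`closest_pair` must be > 0", call. = FALSE)
  r_d <- ring_radius(spec_d$sites_per_ring, spec_d$nn_spacing)
  r_a <- ring_radius(spec_a$sites_per_ring, spec_a$nn_spacing)

  build_pair <- function(D) {
    donor <- build_disk(spec_d, center = c(0, 0, 0), label = "donor",
                        facing_azimuth = 0)
    # acceptor rotated by pi so its reference site faces the donor
    acceptor <- build_disk(spec_a, center = c(D, 0, 0), label = "acceptor",
                           facing_azimuth = pi)
    list(donor = donor, acceptor = acceptor)
  }
  min_dist <- function(D) min(cross_distances(build_pair(D)$donor,
                                              build_pair(D)$acceptor))

  same_heights <- spec_d$n_layers == spec_a$n_layers &&
    isTRUE(all.equal(spec_d$layer_separation, spec_a$layer_separation)) ||
    (spec_d$n_layers == 1L && spec_a$n_layers == 1L)
  if (same_heights) {
    D <- closest_pair + r_d + r_a
  } else {
    upper <- closest_pair + r_d + r_a +
      max(spec_d$layer_separation, spec_a$layer_separation) + 1
    f <- function(D) min_dist(D) - closest_pair
    if (f(upper) < 0)
      stop("cannot calibrate coupled geometry to closest pair ",
           closest_pair, " nm", call. = FALSE)
    lower <- closest_pair / 2
    while (f(lower) > 0 && lower > 1e-9) lower <- lower / 2
    if (f(lower) > 0)
      stop("cannot calibrate coupled geometry to closest pair ",
           closest_pair, " nm", call. = FALSE)
    D <- stats::uniroot(f, c(lower, upper), tol = 1e-12)$root
  }
  if (D <= 0)
    stop("coupling geometry unsolvable: non-positive centre separation",
         call. = FALSE)
  pair <- build_pair(D)
  realised <- min(cross_distances(pair$donor, pair$acceptor))
  if (abs(realised - closest_pair) > 1e-6)
    stop(sprintf(
      "calibration failed: realised minimum %.9g nm != target %.9g nm",
      realised, closest_pair), call. = FALSE)
  structure(
    list(donor = pair$donor, acceptor = pair$acceptor,
         center_separation = D, closest_pair = closest_pair),
    class = "coupled_disk_geometry")
}

#' @export
print.coupled_disk_geometry <- function(x, ...) {
  d <- inter_disk_distances(x)
  cat(sprintf(paste0(
    "Coupled disks: %d donor and %d acceptor sites\n",
    "  centre separation %.4g nm; donor-acceptor distances %.4g .. %.4g nm\n"),
    nrow(x$donor), nrow(x$acceptor), x$center_separation, min(d), max(d)))
  invisible(x)
}

#' All donor-acceptor interchromophore distances
#'
#' @param geom A `coupled_disk_geometry`.
#' @return Numeric matrix of Euclidean distances in nm, donor sites in rows
#'   and acceptor sites in columns.
#' @export
inter_disk_distances <- function(geom) {
  stopifnot(inherits(geom, "coupled_disk_geometry"))
  cross_distances(geom$donor, geom$acceptor)
}

#' Distance-only pathway contributions between coupled disks
#'
#' Under Foerster transfer the pairwise rate scales as `1/R^6`, so with no
#' information about dipole orientations the fraction of total transfer
#' expected through the donor-acceptor pair at distance `R_i` is
#' `p_i = R_i^-6 / sum_j R_j^-6`. By default the sum runs over all
#' donor-acceptor pairs; `top_k` restricts and renormalises over the `top_k`
#' nearest pairs (e.g. the 25 nearest neighbours).
#'
#' @param geom A `coupled_disk_geometry` from [couple_disks()].
#' @param top_k Optional number of nearest pairs to keep (weights are then
#'   renormalised over that subset).
#' @return A `pathway_table`: data frame with columns `donor_site`,
#'   `acceptor_site` (row indices into the respective chromophore sets),
#'   `R_nm` and `weight`, sorted by ascending distance; weights sum to 1.
#' @export
#' @examples
#' tab <- pathway_table(couple_disks())
#' max(tab$weight) # no single pathway dominates
pathway_table <- function(geom, top_k = NULL) {
  dmat <- inter_disk_distances(geom)
  if (length(dmat) == 0L) stop("empty geometry", call. = FALSE)
  tab <- data.frame(donor_site = as.vector(row(dmat)),
                    acceptor_site = as.vector(col(dmat)),
                    R_nm = as.vector(dmat))
  tab <- tab[order(tab$R_nm, tab$donor_site, tab$acceptor_site), ]
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k < 1L || top_k > nrow(tab))
      stop("`top_k` must be between 1 and the number of pairs (",
           nrow(tab), ")", call. = FALSE)
    tab <- tab[seq_len(top_k), ]
  }
  w <- tab$R_nm^-6
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(tab, normalization = if (is.null(top_k)) "all" else
    sprintf("top_%d", top_k),
    class = c("pathway_table", "data.frame"))
}

#' Fold change in pairwise transfer rate under a distance change
#'
#' The Foerster rate for a single donor-acceptor pair scales as `1/R^6`, so
#' shrinking the distance from `R_from` to `R_to` speeds transfer (shortens
#' the pairwise transfer timescale) by `(R_from / R_to)^6`.
#'
#' @param R_from,R_to Distances in nm (both > 0).
#' @return Dimensionless rate fold change.
#' @export
#' @examples
#' rate_fold_change(7.5, 3) # > 200-fold speed-up
rate_fold_change <- function(R_from, R_to) {
  if (any(!is.finite(R_from)) || any(!is.finite(R_to)) ||
      any(R_from <= 0) || any(R_to <= 0))
    stop("distances must be positive", call. = FALSE)
  (R_from / R_to)^6
}

#' Expected number of modified monomers per assembly
#'
#' Converts a bulk modification fraction (e.g. from mass spectrometry) into
#' the expected number of modified monomers on one assembly: a 34-monomer
#' cpTMV double disk that is 31% modified carries on average
#' 0.31 x 34 = 10.5 modifications.
#'
#' @param fraction Modified fraction in `[0, 1]`.
#' @param monomers_per_assembly Monomer count per assembly (default 34).
#' @return List with `expected` (unrounded) and `nearest` (nearest integer).
#' @export
#' @examples
#' modified_monomer_count(0.31, 34) # expected 10.54, i.e. ~10.5 per assembly
modified_monomer_count <- function(fraction, monomers_per_assembly = 34) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(monomers_per_assembly) || monomers_per_assembly <= 0)
    stop("`monomers_per_assembly` must be > 0", call. = FALSE)
  expected <- fraction * monomers_per_assembly
  list(expected = expected, nearest = round(expected))
}

#' Write chromophore coordinates or a pathway table to delimited text
#'
#' @param x A `chromophore_set`, `coupled_disk_geometry` (both disks are
#'   written) or `pathway_table`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(x, path, sep = "\t") {
  if (inherits(x, "coupled_disk_geometry"))
    x <- rbind(as.data.frame(x$donor), as.data.frame(x$acceptor))
  else if (inherits(x, "chromophore_set") || inherits(x, "pathway_table"))
    x <- as.data.frame(x)
  else stop("unsupported object for geometry export", call. = FALSE)
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
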