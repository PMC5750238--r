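## Coarse-grained 3D model of a 2H-AE apta-FRET tile: two parallel A-form
## helix axes a fixed distance apart, fluorophores placed helically by
## stem offset and flip state, giving inter-fluorophore distances, steric
## clash flags, dipole orientation factors and transfer efficiencies.

#' A-form helix parameters for the coarse-grained tile model
#'
#' Defaults are A-form RNA (rise 0.281 nm/bp, twist 32.7 deg/bp) with an
#' inter-axis spacing of 2.4 nm. The fluorophore sits `fluorophore_radial_nm`
#' off its host-stem axis and `fluorophore_axial_ext_bp` bp-equivalents
#' beyond the stem end; these two values are calibrated so the model
#' reproduces the ~18 nm fluorophore separation of the S(-31)-M30 no-FRET
#' control measured on atomistic models.
#'
#' @param rise_nm_per_bp helical rise, nm/bp (> 0).
#' @param twist_deg_per_bp helical twist, degrees/bp (0, 360).
#' @param interaxis_nm center-to-center helix spacing, nm.
#' @param fluorophore_radial_nm fluorophore offset from the stem axis, nm.
#' @param fluorophore_axial_ext_bp bp-equivalents beyond the stem end.
#' @param phase0_deg azimuth of bp index 0, degrees.
#' @return object of class `helix_params`.
#' @export
helix_params <- function(rise_nm_per_bp = 0.281, twist_deg_per_bp = 32.7,
                         interaxis_nm = 2.4, fluorophore_radial_nm = 0.9,
                         fluorophore_axial_ext_bp = 1.5, phase0_deg = 0) {
  assert_that(rise_nm_per_bp > 0, "rise must be > 0")
  assert_that(twist_deg_per_bp > 0 && twist_deg_per_bp < 360,
              "twist must be in (0, 360) degrees")
  assert_that(interaxis_nm >= 0 && fluorophore_radial_nm >= 0,
              "radii must be >= 0")
  structure(list(rise_nm_per_bp = rise_nm_per_bp,
                 twist_deg_per_bp = twist_deg_per_bp,
                 interaxis_nm = interaxis_nm,
                 fluorophore_radial_nm = fluorophore_radial_nm,
                 fluorophore_axial_ext_bp = fluorophore_axial_ext_bp,
                 phase0_deg = phase0_deg),
            class = "helix_params")
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  assert_that(nv > 0, "zero vector has no direction")
  v / nv
}

#' Build the 3D scene for a construct
#'
#' The donor helix axis runs along z through the origin, the acceptor
#' helix axis parallel to it at `interaxis_nm` along x; the reference
#' crossover sits at z = 0. Each fluorophore is placed at axial coordinate
#' `(offset + sign(offset) * fluorophore_axial_ext_bp) * rise` along the
#' shared z axis (positive and negative offsets lie on opposite sides of
#' the crossover), at azimuth `offset * twist + phase0` (+180 deg for a
#' flipped donor), displaced radially by `fluorophore_radial_nm`. The
#' donor dipole points toward the acceptor helix axis in its normal
#' orientation and away when flipped; the acceptor dipole direction is
#' unknown (its fluorophore cannot be docked rigidly) and defaults to the
#' local tangent, configurable via `acceptor_dipole`.
#'
#' @param spec a [construct_spec()].
#' @param hp [helix_params()].
#' @param acceptor_dipole `"tangential"`, `"radial_in"`, `"radial_out"`,
#'   `"axial"`, or a unit 3-vector.
#' @return a `scene_model`: list with `donor` and `acceptor` poses
#'   (each `position` nm, `dipole` unit vector), the axis geometry and
#'   the generating parameters.
#' @export
build_scene <- function(spec, hp = helix_params(),
                        acceptor_dipole = "tangential") {
  stopifnot(inherits(spec, "construct_spec"), inherits(hp, "helix_params"))
  rad <- pi / 180

  place <- function(offset_bp, flipped, axis_x) {
    z <- (offset_bp + sign(offset_bp) * hp$fluorophore_axial_ext_bp) *
      hp$rise_nm_per_bp
    phi <- (offset_bp * hp$twist_deg_per_bp + hp$phase0_deg +
              if (flipped) 180 else 0) * rad
    list(pos = c(axis_x + hp$fluorophore_radial_nm * cos(phi),
                 hp$fluorophore_radial_nm * sin(phi), z),
         phi = phi)
  }
  d <- place(spec$spinach_offset_bp, spec$spinach_flipped, 0)
  a <- place(spec$mango_offset_bp, FALSE, hp$interaxis_nm)
  d_pos <- d$pos
  a_pos <- a$pos

  ## donor dipole: toward the acceptor helix axis (normal) or away (flipped)
  to_axis <- c(hp$interaxis_nm - d_pos[1], -d_pos[2], 0)
  d_dip <- unit(to_axis) * if (spec$spinach_flipped) -1 else 1

  ## acceptor frame from its azimuth (well defined even at zero radial offset)
  a_radial <- c(cos(a$phi), sin(a$phi), 0)
  a_dip <- if (is.numeric(acceptor_dipole)) unit(acceptor_dipole)
  else switch(acceptor_dipole,
              tangential = c(-a_radial[2], a_radial[1], 0),
              radial_in = -a_radial,
              radial_out = a_radial,
              axial = c(0, 0, 1),
              abort2("unknown acceptor_dipole", "aptafret_invalid"))

  structure(list(
    donor = list(position = d_pos, dipole = d_dip),
    acceptor = list(position = a_pos, dipole = a_dip),
    axes = list(donor_origin = c(0, 0, 0),
                acceptor_origin = c(hp$interaxis_nm, 0, 0),
                donor_dir = c(0, 0, 1), acceptor_dir = c(0, 0, -1)),
    spec = spec, params = hp), class = "scene_model")
}

#' Distance between the donor and acceptor fluorophores
#'
#' @param scene a [build_scene()] result.
#' @return Euclidean distance, nm.
#' @export
pair_distance <- function(scene) {
  stopifnot(inherits(scene, "scene_model"))
  assert_that(!is.null(scene$donor) && !is.null(scene$acceptor),
              "scene lacks a fluorophore pose", "aptafret_invalid")
  sqrt(sum((scene$donor$position - scene$acceptor$position)^2))
}

## distance from a point to the segment [a, b]
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((p - a - t * ab)^2))
}

#' Steric clash between the acceptor aptamer and the donor-carrying stem
#'
#' The acceptor aptamer is modelled as a sphere at the acceptor
#' fluorophore position; the donor stem as a finite cylinder along the
#' donor helix axis from the reference crossover (z = 0) to the donor's
#' axial coordinate. A clash is flagged when the sphere center comes
#' closer to the stem axis segment than the sum of the radii.
#'
#' @param scene a [build_scene()] result.
#' @param aptamer_radius_nm acceptor aptamer core radius (default 1.5 nm).
#' @param stem_radius_nm stem (double helix) radius (default 1.0 nm).
#' @return list with `clash` (logical) and `min_separation_nm` (distance
#'   between the sphere center and the stem axis segment).
#' @export
detect_clash <- function(scene, aptamer_radius_nm = 1.5, stem_radius_nm = 1.0) {
  stopifnot(inherits(scene, "scene_model"))
  stem_a <- scene$axes$donor_origin
  stem_b <- c(0, 0, scene$donor$position[3])
  d <- point_segment_distance(scene$acceptor$position, stem_a, stem_b)
  list(clash = d < aptamer_radius_nm + stem_radius_nm, min_separation_nm = d)
}

#' Scan inter-fluorophore distance over aptamer stem lengths
#'
#' Mirrors the optimization scans used to position Mango: one aptamer's
#' stem offset is varied while the other is fixed, recording the
#' coarse-grained fluorophore distance and the steric clash flag at each
#' length. Distance minima recur roughly every helical turn
#' (360 / twist, about 11 bp).
#'
#' @param spec_template a [construct_spec()] providing the fixed offsets.
#' @param vary `"mango"` or `"spinach"`.
#' @param range_bp stem offsets to scan (nonempty integer vector).
#' @param hp [helix_params()].
#' @param ... passed to [detect_clash()].
#' @return data.frame with columns `stem_bp`, `distance_nm`, `clash`.
#' @export
distance_scan <- function(spec_template, vary = c("mango", "spinach"),
                          range_bp, hp = helix_params(), ...) {
  vary <- match.arg(vary)
  assert_that(length(range_bp) > 0, "range_bp must be nonempty")
  rows <- lapply(range_bp, function(k) {
    spec <- spec_template
    if (vary == "mango") spec$mango_offset_bp <- as.integer(k)
    else spec$spinach_offset_bp <- as.integer(k)
    scene <- build_scene(spec, hp)
    data.frame(stem_bp = k, distance_nm = pair_distance(scene),
               clash = detect_clash(scene, ...)$clash)
  })
  do.call(rbind, rows)
}

#' Dipole orientation factor kappa squared
#'
#' `kappa^2 = (cos theta_T - 3 cos theta_D cos theta_A)^2` where theta_T
#' is the angle between the transition dipoles and theta_D, theta_A the
#' angles each makes with the donor-acceptor separation vector. Ranges
#' over [0, 4]; the isotropic dynamic average is 2/3.
#'
#' @param d_donor,d_acceptor dipole direction vectors (normalized internally).
#' @param r_vec donor-to-acceptor separation vector (nonzero).
#' @return kappa squared, dimensionless.
#' @export
kappa_squared <- function(d_donor, d_acceptor, r_vec) {
  if (sqrt(sum(r_vec^2)) == 0)
    abort2("zero separation: orientation factor undefined",
           "aptafret_undefined_orientation")
  dd <- unit(d_donor); da <- unit(d_acceptor); rr <- unit(r_vec)
  (sum(dd * da) - 3 * sum(dd * rr) * sum(da * rr))^2
}

#' Forster radius from photophysical inputs
#'
#' `R0^6 = 8.79e-5 * kappa^2 * n^-4 * Q_D * J` with J in
#' M^-1 cm^-1 nm^4 and R0 in Angstrom (returned in nm). Monotone
#' increasing in each of kappa^2, Q_D and J.
#'
#' @param J spectral overlap integral, M^-1 cm^-1 nm^4.
#' @param kappa2 orientation factor in [0, 4].
#' @param Q_D donor quantum yield in (0, 1].
#' @param n_refr refractive index (> 1).
#' @return Forster radius R0, nm.
#' @export
forster_radius <- function(J, kappa2 = 2 / 3, Q_D = 0.7, n_refr = 1.4) {
  assert_that(J >= 0, "spectral overlap must be >= 0")
  assert_that(kappa2 >= 0 && kappa2 <= 4, "kappa^2 must be in [0, 4]")
  assert_that(Q_D > 0 && Q_D <= 1, "quantum yield must be in (0, 1]")
  assert_that(n_refr > 1, "refractive index must be > 1")
  r0_angstrom <- (8.79e-5 * kappa2 * n_refr^-4 * Q_D * J)^(1 / 6)
  r0_angstrom / 10
}

#' FRET efficiency at a given separation
#'
#' `E = 1 / (1 + (r / R0)^6)`: 1/2 at r = R0, strictly decreasing in r.
#'
#' @param r donor-acceptor distance, nm (>= 0).
#' @param R0 Forster radius, nm (> 0).
#' @return transfer efficiency in [0, 1].
#' @export
fret_efficiency <- function(r, R0) {
  assert_that(all(R0 > 0), "Forster radius must be > 0")
  assert_that(all(r >= 0), "distance must be >= 0")
  1 / (1 + (r / R0)^6)
}
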