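#' Coordinate models
#'
#' A `protein_model` is a tibble of C-alpha scattering/interaction centers,
#' one row per residue, with columns `chain` ("A"/"B"), `resno` (1-based
#' residue number in JIP3 numbering), `res` (one-letter code) and `x`, `y`,
#' `z` (Angstrom). The idealized builders produce backbone-trace models at
#' this one-center-per-residue resolution; side chains are represented
#' implicitly by per-residue scattering weights and bead radii downstream.
#'
#' @param df Data frame with the columns above.
#' @param provenance Optional character note stored as an attribute.
#' @return A `protein_model` tibble.
#' @export
new_protein_model <- function(df, provenance = NULL) {
  need <- c("chain", "resno", "res", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste("protein_model needs columns:", paste(need, collapse = ", ")))
  }
  out <- as_tibble(df[, need])
  out$resno <- as.integer(out$resno)
  class(out) <- c("protein_model", class(tibble()))
  attr(out, "provenance") <- provenance
  validate_protein_model(out)
  out
}

#' @export
print.protein_model <- function(x, ...) {
  ch <- split(x$resno, x$chain)
  cat(sprintf("<protein_model> %d centers, %d chain(s)\n", nrow(x), length(ch)))
  for (nm in names(ch)) {
    cat(sprintf("  chain %s: residues %d-%d (%d)\n", nm, min(ch[[nm]]),
                max(ch[[nm]]), length(ch[[nm]])))
  }
  if (!is.null(attr(x, "provenance"))) cat(" ", attr(x, "provenance"), "\n")
  invisible(x)
}

#' Validate the structural invariants of a model
#'
#' Residue numbers must be strictly increasing within each chain, chains of
#' a dimer must cover identical residue ranges, and no two centers may be
#' closer than 1.0 Angstrom.
#'
#' @param m A `protein_model`.
#' @return `m`, invisibly; aborts on violation.
#' @export
validate_protein_model <- function(m) {
  for (ch in split(m$resno, m$chain)) {
    if (any(diff(ch) <= 0)) abort("residue numbers must strictly increase within a chain")
  }
  rng <- lapply(split(m$resno, m$chain), range)
  if (length(rng) > 1 && !all(vapply(rng, identical, TRUE, y = rng[[1]]))) {
    abort("chains of a dimer must cover identical residue ranges")
  }
  if (nrow(m) > 1) {
    dmin <- min(dist(model_xyz(m)))
    if (dmin < 1.0) abort(sprintf("atoms closer than 1.0 A (min %.2f A)", dmin))
  }
  invisible(m)
}

model_xyz <- function(m) cbind(x = m$x, y = m$y, z = m$z)

with_xyz <- function(m, xyz) {
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  m
}

model_select <- function(m, start = NULL, end = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(m))
  if (!is.null(start)) keep <- keep & m$resno >= start
  if (!is.null(end)) keep <- keep & m$resno <= end
  if (!is.null(chain)) keep <- keep & m$chain %in% chain
  m[keep, , drop = FALSE]
}

#' Per-residue scattering/mass weights of a model
#'
#' @param m A `protein_model`.
#' @return Numeric vector of average residue masses (Da), one per center.
#' @export
residue_weights <- function(m) unname(AA_MASS[m$res])

#' Build an ideal alpha-helix C-alpha trace
#'
#' Places one center per residue on an ideal alpha-helix: 1.5 A rise per
#' residue, 3.6 residues per turn, 2.3 A radius about the axis.
#'
#' @param seq A [seq_record()] providing residues and numbering.
#' @param origin Helix-axis point of the first residue.
#' @param axis Helix axis direction (need not be unit length).
#' @param rise,radius,twist_deg Helix parameters.
#' @param phase_deg Azimuthal phase of the first residue (degrees).
#' @param chain Chain identifier.
#' @return A `protein_model` with one chain.
#' @export
#' @examples
#' h <- build_ideal_helix(seq_record("h", "AAAAAAAAAA"))
#' max_extent(h)
build_ideal_helix <- function(seq, origin = c(0, 0, 0), axis = c(0, 0, 1),
                              rise = 1.5, radius = 2.3, twist_deg = 100,
                              phase_deg = 0, chain = "A") {
  stopifnot(inherits(seq, "seq_record"))
  fr <- frame_from_axis(axis)
  n <- length(seq)
  j <- seq_len(n) - 1
  ang <- (phase_deg + j * twist_deg) * pi / 180
  xyz <- t(vapply(seq_len(n), function(k) {
    origin + fr$w * rise * j[k] + radius * (cos(ang[k]) * fr$u + sin(ang[k]) * fr$v)
  }, numeric(3)))
  new_protein_model(tibble(chain = chain, resno = residue_numbers(seq),
                           res = seq_residues(seq),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                    provenance = "ideal alpha-helix")
}

#' Crick parameters for a parallel dimeric coiled coil
#'
#' Defaults describe a canonical left-handed two-stranded parallel coiled
#' coil: superhelix radius 4.9 A and pitch 190 A, minor-helix radius 2.26 A,
#' two minor-helix turns per heptad, 1.485 A axial rise per residue. The
#' two chains are related by a 180 degree rotation about the superhelical
#' axis.
#'
#' @param superhelix_radius,superhelix_pitch,alpha_radius Angstrom.
#' @param residues_per_turn_minor Minor-helix periodicity measured in the
#'   rotating superhelical frame. The default 3.5 (two turns per heptad)
#'   makes the hydrophobic a/d seam track the dimer interface exactly and
#'   corresponds to a laboratory-frame periodicity of about 3.6 at the
#'   default pitch.
#' @param rise_per_residue Axial rise per residue (Angstrom).
#' @param register_phase Heptad register letter of the first residue.
#' @param chain_offset_deg Rotation between chains (180 for a dimer).
#' @return A `crick_params` list.
#' @export
crick_params <- function(superhelix_radius = 4.9, superhelix_pitch = 190,
                         alpha_radius = 2.26, residues_per_turn_minor = 3.5,
                         rise_per_residue = 1.485, register_phase = "a",
                         chain_offset_deg = 180) {
  stopifnot(superhelix_radius > 0, superhelix_pitch > 0, alpha_radius > 0,
            residues_per_turn_minor > 0, rise_per_residue > 0)
  if (superhelix_pitch <= 20 * rise_per_residue) {
    abort("superhelix pitch must exceed 20x the per-residue rise")
  }
  if (!register_phase %in% letters[1:7]) abort("register_phase must be a-g")
  structure(list(superhelix_radius = superhelix_radius,
                 superhelix_pitch = superhelix_pitch,
                 alpha_radius = alpha_radius,
                 residues_per_turn_minor = residues_per_turn_minor,
                 rise_per_residue = rise_per_residue,
                 register_phase = register_phase,
                 chain_offset_deg = chain_offset_deg),
            class = "crick_params")
}

# Minor-helix phase bookkeeping: the a/d core points toward the superhelix
# axis, so psi of an 'a' residue is chosen such that the short angular
# separation between 'a' (k = 0) and 'd' (k = 3) brackets psi = pi.
crick_phase_setup <- function(p) {
  dpsi <- 2 * pi / p$residues_per_turn_minor
  delta <- ((3 * dpsi + pi) %% (2 * pi)) - pi
  psi_a <- pi - delta / 2
  list(dpsi = dpsi, psi_a = psi_a)
}

crick_chain_xyz <- function(n, p, z_first = 0, rot = 0) {
  ph <- crick_phase_setup(p)
  off <- match(p$register_phase, letters[1:7]) - 1
  j0 <- (7 - off) %% 7 # residues until the next 'a'
  psi0 <- ph$psi_a - j0 * ph$dpsi
  j <- seq_len(n) - 1
  z <- z_first - j * p$rise_per_residue
  phi <- 2 * pi * z / p$superhelix_pitch + rot
  psi <- psi0 + j * ph$dpsi
  r0 <- p$superhelix_radius; r1 <- p$alpha_radius
  t(vapply(seq_len(n), function(k) {
    nhat <- c(cos(phi[k]), sin(phi[k]), 0)
    that <- unit3(c(-r0 * sin(phi[k]) * 2 * pi / p$superhelix_pitch,
                    r0 * cos(phi[k]) * 2 * pi / p$superhelix_pitch, 1))
    bhat <- c(that[2] * nhat[3] - that[3] * nhat[2],
              that[3] * nhat[1] - that[1] * nhat[3],
              that[1] * nhat[2] - that[2] * nhat[1])
    c(r0 * cos(phi[k]), r0 * sin(phi[k]), z[k]) +
      r1 * (cos(psi[k]) * nhat + sin(psi[k]) * bhat)
  }, numeric(3)))
}

#' Build a straight parallel dimeric coiled coil (Crick parameterization)
#'
#' Winds one minor alpha-helix per chain on a common superhelix; the second
#' chain is related to the first by the chain offset rotation about the
#' superhelical (z) axis. The first residue sits at `z = z_first` and the
#' chain descends in z; the axial length is `(n - 1) * rise_per_residue`.
#'
#' @param seq A [seq_record()] (length >= 7).
#' @param params A [crick_params()].
#' @param z_first z coordinate of the first residue.
#' @return A two-chain `protein_model`.
#' @export
#' @examples
#' lzi <- extract_region(fixture_sequences()$jip3, 74, 177)
#' cc <- build_parallel_dimer_cc(lzi)
#' axial_length(cc) # about 150 A
build_parallel_dimer_cc <- function(seq, params = crick_params(),
                                    z_first = 0) {
  stopifnot(inherits(seq, "seq_record"))
  if (length(seq) < 7) abort("coiled-coil build needs at least 7 residues")
  if (!inherits(params, "crick_params")) abort("params must be crick_params()")
  n <- length(seq)
  A <- crick_chain_xyz(n, params, z_first = z_first, rot = 0)
  B <- crick_chain_xyz(n, params, z_first = z_first,
                       rot = params$chain_offset_deg * pi / 180)
  base <- tibble(resno = residue_numbers(seq), res = seq_residues(seq))
  new_protein_model(
    dplyr::bind_rows(
      dplyr::mutate(base, chain = "A", x = A[, 1], y = A[, 2], z = A[, 3]),
      dplyr::mutate(base, chain = "B", x = B[, 1], y = B[, 2], z = B[, 3])
    ),
    provenance = "Crick parallel dimeric coiled coil"
  )
}

#' Geometry of the RH1 four-helix bundle
#'
#' Two antiparallel helices per protomer, the two protomers related by a
#' two-fold axis along the bundle axis; helix axes sit on the corners of a
#' square whose side is the interhelix distance.
#'
#' @param interhelix_distance Distance between adjacent helix axes (A).
#' @param loop_start,loop_end Residue range of the alpha1-alpha2 loop.
#' @return A `bundle_geometry` list.
#' @export
bundle_geometry <- function(interhelix_distance = 10.5, loop_start = 44L,
                            loop_end = 49L) {
  stopifnot(interhelix_distance > 0, loop_start <= loop_end)
  if (interhelix_distance < 8) {
    abort("four-helix bundle needs helix axes at least 8 A apart")
  }
  structure(list(interhelix_distance = interhelix_distance,
                 loop_start = as.integer(loop_start),
                 loop_end = as.integer(loop_end)),
            class = "bundle_geometry")
}

# Cubic bezier resampled at uniform arc length (interior points only).
bezier_arc_points <- function(p0, c1, c2, p3, n_interior) {
  tt <- seq(0, 1, length.out = 400)
  bez <- t(vapply(tt, function(s) {
    (1 - s)^3 * p0 + 3 * (1 - s)^2 * s * c1 + 3 * (1 - s) * s^2 * c2 + s^3 * p3
  }, numeric(3)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(bez)^2))))
  want <- seq(0, arc[length(arc)], length.out = n_interior + 2)[2:(n_interior + 1)]
  idx <- vapply(want, function(a) which.min(abs(arc - a)), integer(1))
  bez[idx, , drop = FALSE]
}

# Rotate a helix about its own axis so that residue `idx` points along
# `want_dir` (xy-plane direction) from the axis at `corner`.
spin_helix_xy <- function(xyz, corner, idx, want_dir) {
  v <- xyz[idx, 1:2] - corner
  th <- atan2(want_dir[2], want_dir[1]) - atan2(v[2], v[1])
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  xyz[, 1:2] <- sweep(sweep(xyz[, 1:2, drop = FALSE], 2, corner) %*% t(R), 2, -corner)
  xyz
}

# One protomer of the RH1 bundle (chain A coordinates), placed with the
# alpha2 corner at angle 0 and the alpha1 corner at angle 90 degrees on a
# circle of radius interhelix/sqrt(2); the bundle axis is +z and alpha2 ends
# (residue a2_end) at z = z_base, pointing inward, ready to hand over to the
# coiled coil below.
rh1_protomer_xyz <- function(seq, geom, a1_range = c(26L, 43L),
                             a2_range = c(50L, 73L), z_base = 2.7) {
  rc <- geom$interhelix_distance / sqrt(2)
  corner_a2 <- c(rc, 0)
  corner_a1 <- c(0, rc)
  n1 <- a1_range[2] - a1_range[1] + 1
  n2 <- a2_range[2] - a2_range[1] + 1
  z50 <- z_base + (n2 - 1) * 1.5
  a2 <- build_ideal_helix(extract_region(seq, a2_range[1], a2_range[2]),
                          origin = c(corner_a2, z50), axis = c(0, 0, -1))
  a2xyz <- spin_helix_xy(model_xyz(a2), corner_a2, n2, c(-1, 0))
  z26 <- z_base + 3.3
  a1 <- build_ideal_helix(extract_region(seq, a1_range[1], a1_range[2]),
                          origin = c(corner_a1, z26), axis = c(0, 0, 1))
  a1xyz <- spin_helix_xy(model_xyz(a1), corner_a1, 1, c(0, -1))
  nl <- geom$loop_end - geom$loop_start + 1
  p0 <- a1xyz[n1, ]; p3 <- a2xyz[1, ]
  mid <- (p0 + p3) / 2
  up <- max(p0[3], p3[3])
  c1 <- c(p0[1:2] * 1.35, up + 8.5)
  c2 <- c(p3[1:2] * 1.35, up + 8.5)
  loop <- bezier_arc_points(p0, c1, c2, p3, nl)
  list(a1 = a1xyz, loop = loop, a2 = a2xyz,
       resno = c(a1_range[1]:a1_range[2], geom$loop_start:geom$loop_end,
                 a2_range[1]:a2_range[2]))
}

#' Build the dimeric RH1 four-helix bundle
#'
#' Two antiparallel helices (alpha1 26-43 ascending, alpha2 50-73
#' descending) per protomer connected by a short loop, the two protomers
#' related by a two-fold rotation about the bundle (z) axis. The bundle is
#' roughly 40 A long.
#'
#' @param alpha1,alpha2,loop [seq_record()]s for the two helices and the
#'   connecting loop (consecutive residue ranges).
#' @param geom A [bundle_geometry()].
#' @return A two-chain `protein_model` covering alpha1 through alpha2.
#' @export
build_rh1_dimer <- function(alpha1, alpha2, loop, geom = bundle_geometry()) {
  for (s in list(alpha1, loop, alpha2)) stopifnot(inherits(s, "seq_record"))
  r1 <- range(residue_numbers(alpha1))
  r2 <- range(residue_numbers(alpha2))
  rl <- range(residue_numbers(loop))
  if (rl[1] != r1[2] + 1 || r2[1] != rl[2] + 1) {
    abort("alpha1, loop and alpha2 must cover consecutive residue ranges")
  }
  geom$loop_start <- rl[1]; geom$loop_end <- rl[2]
  seq_all <- seq_record("rh1", paste0(alpha1$residues, loop$residues,
                                      alpha2$residues), r1[1])
  pro <- rh1_protomer_xyz(seq_all, geom, a1_range = r1, a2_range = r2)
  xyzA <- rbind(pro$a1, pro$loop, pro$a2)
  xyzB <- xyzA %*% diag(c(-1, -1, 1))
  res <- seq_residues(seq_all) # resno already in sequence order
  m <- new_protein_model(
    dplyr::bind_rows(
      tibble(chain = "A", resno = pro$resno, res = res,
             x = xyzA[, 1], y = xyzA[, 2], z = xyzA[, 3]),
      tibble(chain = "B", resno = pro$resno, res = res,
             x = xyzB[, 1], y = xyzB[, 2], z = xyzB[, 3])
    ),
    provenance = "idealized RH1 four-helix bundle"
  )
  dmin <- min_nonbonded_distance(m)
  if (dmin < 2.0) abort(sprintf("bundle build produced clashes (%.2f A)", dmin))
  m
}

# Minimum distance over pairs that are not sequence neighbours.
min_nonbonded_distance <- function(m, exclude_within = 1L) {
  xyz <- model_xyz(m)
  D <- as.matrix(dist(xyz))
  same_chain <- outer(m$chain, m$chain, "==")
  dres <- abs(outer(m$resno, m$resno, "-"))
  excl <- same_chain & dres <= exclude_within
  diag(excl) <- TRUE
  min(D[!excl])
}

#' Assemble the idealized RH1-LZI tandem dimer
#'
#' Constructs the full two-chain model of the GSH+22-187 construct: the RH1
#' four-helix bundle on top, the helical hinge (74-77) opening into the LZI
#' coiled coil (78-180) with its helical C-terminal continuation (181-187)
#' below, and the flexible N-terminal tag remnant plus residues 22-25. The
#' bundle axis is collinear with the coiled-coil axis (z), giving a straight
#' particle about 210 A long and about 20 A thick.
#'
#' @param full_seq A [seq_record()] for GSH+22-187 (see
#'   [construct_record()]); defaults to the packaged JIP3 fixture.
#' @param cc_params [crick_params()] for the coiled-coil segment. The
#'   register phase is taken from the LZI annotation (`"f"` at residue 74 so
#'   that the first full core position is 76).
#' @param geom [bundle_geometry()] for the RH1 domain.
#' @return A two-chain `protein_model` covering residues 19-187.
#' @export
#' @examples
#' \donttest{
#' m <- assemble_rh1_lzi_dimer()
#' max_extent(m) # about 210 A
#' }
assemble_rh1_lzi_dimer <- function(full_seq = NULL,
                                   cc_params = crick_params(register_phase = "f"),
                                   geom = bundle_geometry()) {
  if (is.null(full_seq)) full_seq <- construct_record(fixture_sequences()$jip3)
  rn <- residue_numbers(full_seq)
  need <- 19:187
  if (!all(need %in% rn)) {
    abort("full_seq must cover residues 19-187 (GSH tag remnant + 22-187)")
  }
  # coiled coil: hinge 74-77 + LZI 78-180 + C-terminal continuation 181-187
  coil_seq <- extract_region(full_seq, 74L, 187L)
  coil <- build_parallel_dimer_cc(coil_seq, cc_params, z_first = 0)
  # bundle on top, alpha2 handing over to the coil at z ~ 0
  pro <- rh1_protomer_xyz(full_seq, geom, z_base = 2.7)
  # N-terminal tag + 22-25: straight coil running down from the alpha1 base
  nt_res <- 19:25
  d <- unit3(c(0, 0.12, -1)) * 3.8
  a1_first <- pro$a1[1, ]
  nt <- t(vapply(rev(seq_along(nt_res)), function(k) a1_first + k * d, numeric(3)))
  res_of <- function(nums) {
    seq_residues(full_seq)[match(nums, rn)]
  }
  topA <- rbind(nt, pro$a1, pro$loop, pro$a2)
  topno <- c(nt_res, pro$resno)
  topB <- topA %*% diag(c(-1, -1, 1))
  top <- dplyr::bind_rows(
    tibble(chain = "A", resno = topno, res = res_of(topno),
           x = topA[, 1], y = topA[, 2], z = topA[, 3]),
    tibble(chain = "B", resno = topno, res = res_of(topno),
           x = topB[, 1], y = topB[, 2], z = topB[, 3])
  )
  m <- new_protein_model(
    dplyr::arrange(dplyr::bind_rows(top, as_tibble(coil)[, c("chain", "resno", "res", "x", "y", "z")]),
                   .data$chain, .data$resno),
    provenance = "idealized RH1-LZI tandem dimer (GSH+22-187)"
  )
  dmin <- min_nonbonded_distance(m, exclude_within = 2L)
  if (dmin < 2.0) {
    abort(sprintf("assembled model has clashes (min non-bonded %.2f A)", dmin))
  }
  axis_angle <- acos(min(1, abs(sum(
    principal_axis(model_xyz(model_select(m, 26, 66))) *
      principal_axis(model_xyz(model_select(m, 78, 176)))
  )))) * 180 / pi
  if (axis_angle > 15) {
    abort(sprintf("bundle axis deviates %.1f deg from the coil axis", axis_angle))
  }
  m
}

#' Axial length of a selection
#'
#' Extent of the selected centers projected onto their first principal axis.
#'
#' @param m A `protein_model`.
#' @param start,end Optional inclusive residue range to select.
#' @return Length in Angstrom (0 for a single residue).
#' @export
axial_length <- function(m, start = NULL, end = NULL) {
  sel <- model_select(m, start, end)
  if (nrow(sel) == 0) abort("empty selection")
  if (nrow(sel) == 1) return(0)
  X <- model_xyz(sel)
  ax <- principal_axis(X)
  pr <- X %*% ax
  diff(range(pr))
}

#' Maximum extent of a model
#'
#' Maximum pairwise center-center distance (the model-side counterpart of
#' the experimental Dmax).
#'
#' @param m A `protein_model` (>= 2 centers).
#' @return Distance in Angstrom.
#' @export
max_extent <- function(m) {
  if (nrow(m) < 2) abort("max_extent needs at least 2 centers")
  max(dist(model_xyz(m)))
}

#' Thickness of an elongated model
#'
#' Twice the maximum distance of any center from the first principal axis.
#'
#' @param m A `protein_model` (>= 2 centers).
#' @return Thickness in Angstrom.
#' @export
model_thickness <- function(m) {
  if (nrow(m) < 2) abort("thickness needs at least 2 centers")
  X <- model_xyz(m)
  Xc <- sweep(X, 2, colMeans(X))
  ax <- principal_axis(X)
  pr <- Xc %*% ax
  2 * sqrt(max(rowSums(Xc^2) - pr[, 1]^2))
}

#' Coordinate radius of gyration
#'
#' Mass-weighted radius of gyration of the point centers (no bead-size
#' term; see [rg_from_beads()] for the hydrated-bead version).
#'
#' @param m A `protein_model`.
#' @param weights Per-center weights (default: average residue masses).
#' @return Rg in Angstrom.
#' @export
model_rg <- function(m, weights = NULL) {
  if (is.null(weights)) weights <- residue_weights(m)
  X <- model_xyz(m)
  cen <- colSums(X * weights) / sum(weights)
  sqrt(sum(weights * rowSums(sweep(X, 2, cen)^2)) / sum(weights))
}

#' Chain-to-chain symmetry RMSD of a dimer
#'
#' RMSD between chain A and chain B after optimal superposition; near zero
#' for a model with exact two-fold symmetry.
#'
#' @param m A two-chain `protein_model`.
#' @return RMSD in Angstrom.
#' @export
dimer_symmetry_rmsd <- function(m) {
  a <- model_select(m, chain = "A")
  b <- model_select(m, chain = "B")
  if (nrow(a) == 0 || nrow(b) == 0 || nrow(a) != nrow(b)) {
    abort("dimer_symmetry_rmsd needs two chains with matched residues")
  }
  kabsch_rmsd(model_xyz(a), model_xyz(b))
}
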