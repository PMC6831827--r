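#' Flexibility mask for rigid-body refinement
#'
#' Partitions the model into rigid bodies and flexible ranges. The defaults
#' follow the refinement protocol for the RH1-LZI tandem: the RH1 domain
#' (26-66) and the LZI coiled coil (78-176) are kept as rigid bodies, while
#' the N-terminus (tag remnant + 22-25), the inter-domain linker with a few
#' preceding residues (67-77) and the C-terminus (177-187) are allowed to
#' move.
#'
#' @param rigid List of inclusive residue ranges kept rigid.
#' @param flexible List of inclusive residue ranges allowed to move.
#' @param amplitude_deg Rotation amplitude (degrees) used by the moves.
#' @return A `flexibility_mask`.
#' @export
flexibility_mask <- function(rigid = list(c(26, 66), c(78, 176)),
                             flexible = list(c(19, 25), c(67, 77), c(177, 187)),
                             amplitude_deg = 10) {
  rigid <- lapply(rigid, as.integer)
  flexible <- lapply(flexible, as.integer)
  covered <- sort(unlist(c(lapply(rigid, function(r) r[1]:r[2]),
                           lapply(flexible, function(r) r[1]:r[2]))))
  if (anyDuplicated(covered)) {
    abort("rigid and flexible ranges must be disjoint")
  }
  structure(list(rigid = rigid, flexible = flexible,
                 amplitude_deg = amplitude_deg),
            class = "flexibility_mask")
}

#' Linker-only mask (pool generation)
#'
#' Only the flexible linker (67-77) moves; everything on either side is
#' rigid. Used for conformer-pool generation in the ensemble analysis.
#'
#' @param amplitude_deg Bend amplitude in degrees (pools explore large
#'   bends; default 90).
#' @return A `flexibility_mask`.
#' @export
linker_only_mask <- function(amplitude_deg = 90) {
  flexibility_mask(rigid = list(c(19, 66), c(78, 187)),
                   flexible = list(c(67, 77)),
                   amplitude_deg = amplitude_deg)
}

mask_check_cover <- function(mask, m) {
  covered <- sort(unlist(c(lapply(mask$rigid, function(r) r[1]:r[2]),
                           lapply(mask$flexible, function(r) r[1]:r[2]))))
  resnos <- sort(unique(m$resno))
  if (!all(resnos %in% covered)) {
    abort(sprintf("mask does not cover residues: %s",
                  paste(head(setdiff(resnos, covered), 5), collapse = ", ")))
  }
  invisible(TRUE)
}

in_ranges <- function(resno, ranges) {
  out <- rep(FALSE, length(resno))
  for (r in ranges) out <- out | (resno >= r[1] & resno <= r[2])
  out
}

# Classify each flexible range: internal linker (rigid on both sides),
# leading tail (nothing before) or trailing tail (nothing after).
classify_flexible <- function(mask, m) {
  resnos <- sort(unique(m$resno))
  lapply(mask$flexible, function(fr) {
    before <- (fr[1] - 1) %in% resnos
    after <- (fr[2] + 1) %in% resnos
    kind <- if (before && after) "linker" else if (!before) "head" else "tail"
    list(range = fr, kind = kind)
  })
}

# Helix segment threaded through two fixed anchor points. Returns the
# n_steps - 1 interior points. The twist is snapped to a divisor of a full
# turn so that the helix passes exactly through both anchors; the radius is
# set so consecutive points are ~3.8 A apart (near-helical basin).
chord_helix_points <- function(p0, p1, n_steps, u_ref = c(0, 0, 1)) {
  if (n_steps < 2) abort("chord_helix_points needs n_steps >= 2")
  chord <- p1 - p0
  len <- sqrt(sum(chord^2))
  rise <- len / n_steps
  if (n_steps < 4 || rise > 3.7) {
    # nearly straight: plain interpolation
    j <- seq_len(n_steps - 1)
    return(t(vapply(j, function(k) p0 + chord * k / n_steps, numeric(3))))
  }
  k <- max(1, round(n_steps * 100 / 360))
  omega <- 2 * pi * k / n_steps
  r2 <- (3.8^2 - rise^2) / (2 * (1 - cos(omega)))
  r <- sqrt(max(r2, 0.01))
  fr <- frame_from_axis(chord, u_ref)
  j <- seq_len(n_steps - 1)
  t(vapply(j, function(jj) {
    p0 + fr$w * rise * jj +
      r * (cos(omega * jj) - 1) * fr$u + r * sin(omega * jj) * fr$v
  }, numeric(3)))
}

rebuild_linker <- function(m, fr) {
  for (ch in unique(m$chain)) {
    sel <- m$chain == ch
    sub <- m[sel, ]
    i0 <- which(sub$resno == fr[1] - 1)
    i1 <- which(sub$resno == fr[2] + 1)
    idx <- which(sub$resno >= fr[1] & sub$resno <= fr[2])
    pts <- chord_helix_points(as.numeric(sub[i0, c("x", "y", "z")]),
                              as.numeric(sub[i1, c("x", "y", "z")]),
                              n_steps = length(idx) + 1)
    sub$x[idx] <- pts[, 1]; sub$y[idx] <- pts[, 2]; sub$z[idx] <- pts[, 3]
    m[sel, ] <- sub
  }
  m
}

C2Z <- diag(c(-1, -1, 1))

# One stochastic move set over all flexible ranges. Internal linkers bend
# the whole upstream unit (both chains, keeping the RH1 bundle intact) about
# a pivot at the downstream anchor and re-thread the linker; tails rotate
# per chain with two-fold-conjugated rotations so tail moves preserve the
# dimer symmetry exactly.
apply_moves <- function(m, mask, amplitude_deg) {
  classes <- classify_flexible(mask, m)
  xyz <- model_xyz(m)
  relink <- list()
  for (cl in classes) {
    fr <- cl$range
    th <- runif(1, -amplitude_deg, amplitude_deg) * pi / 180
    if (abs(th) < 1e-12) next
    axis <- unit3(rnorm(3))
    if (cl$kind == "linker") {
      anchor_dn <- m$resno == fr[2] + 1
      pivot <- colMeans(xyz[anchor_dn, , drop = FALSE])
      upstream <- m$resno < fr[1]
      R <- rotation3(axis, th)
      xyz[upstream, ] <- rotate_about(xyz[upstream, , drop = FALSE], R, pivot)
      relink <- c(relink, list(fr))
    } else {
      anchor_no <- if (cl$kind == "head") fr[2] + 1 else fr[1] - 1
      R <- rotation3(axis, th)
      for (ch in unique(m$chain)) {
        sel <- m$chain == ch & m$resno >= fr[1] & m$resno <= fr[2]
        piv_row <- m$chain == ch & m$resno == anchor_no
        pivot <- as.numeric(xyz[piv_row, ])
        Rch <- if (ch == "A") R else C2Z %*% R %*% C2Z
        xyz[sel, ] <- rotate_about(xyz[sel, , drop = FALSE], Rch, pivot)
      }
    }
  }
  m <- with_xyz(m, xyz)
  for (fr in relink) m <- rebuild_linker(m, fr)
  m
}

#' Perturb a model at its flexible regions
#'
#' Draws one random move per flexible range: internal linkers bend the
#' upstream rigid unit (the RH1 bundle travels as one body, so its internal
#' geometry is exact) about a pivot at the downstream anchor and re-thread
#' the linker residues within a near-helical basin; terminal tails rotate
#' about their anchor residue with two-fold-paired rotations on the two
#' chains. Conformers with non-bonded contacts closer than `clash_cutoff`
#' are rejected and resampled (up to `max_tries`).
#'
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param m A `protein_model`.
#' @param mask A [flexibility_mask()] covering the model.
#' @param amplitude_deg Move amplitude; defaults to the mask's.
#' @param clash_cutoff Minimum allowed non-bonded distance (Angstrom).
#' @param max_tries Resampling budget.
#' @return A perturbed `protein_model`.
#' @export
perturb_flexible <- function(m, mask = flexibility_mask(),
                             amplitude_deg = NULL, clash_cutoff = 2.5,
                             max_tries = 50) {
  stopifnot(inherits(m, "protein_model"), inherits(mask, "flexibility_mask"))
  mask_check_cover(mask, m)
  if (is.null(amplitude_deg)) amplitude_deg <- mask$amplitude_deg
  if (amplitude_deg == 0) return(m)
  for (try in seq_len(max_tries)) {
    cand <- apply_moves(m, mask, amplitude_deg)
    if (min_nonbonded_distance(cand, exclude_within = 2L) >= clash_cutoff) {
      return(cand)
    }
  }
  abort(sprintf("no clash-free perturbation in %d tries", max_tries))
}

#' Deterministic bent decoys
#'
#' Bends the upstream unit (RH1 side) about the linker by the requested
#' angles around a fixed axis, re-threading the linker; used as ground-truth
#' targets for refinement-recovery experiments.
#'
#' @param m A `protein_model`.
#' @param bend_angles_deg Hinge bend angles in degrees.
#' @param mask A [flexibility_mask()]; the first internal linker is used.
#' @param axis Bend axis (default y, which keeps the flexible tails in
#'   open space for the standard model).
#' @param clash_cutoff Minimum allowed non-bonded distance.
#' @return A list of `protein_model`s, one per angle.
#' @export
make_decoys <- function(m, bend_angles_deg, mask = flexibility_mask(),
                        axis = c(0, 1, 0), clash_cutoff = 2.0) {
  classes <- classify_flexible(mask, m)
  link <- NULL
  for (cl in classes) if (cl$kind == "linker") { link <- cl$range; break }
  if (is.null(link)) abort("mask has no internal linker range")
  xyz0 <- model_xyz(m)
  lapply(bend_angles_deg, function(ang) {
    if (ang == 0) return(m)
    anchor_dn <- m$resno == link[2] + 1
    pivot <- colMeans(xyz0[anchor_dn, , drop = FALSE])
    R <- rotation3(axis, ang * pi / 180)
    xyz <- xyz0
    up <- m$resno < link[1]
    xyz[up, ] <- rotate_about(xyz0[up, , drop = FALSE], R, pivot)
    out <- rebuild_linker(with_xyz(m, xyz), link)
    if (min_nonbonded_distance(out, exclude_within = 2L) < clash_cutoff) {
      abort(sprintf("decoy at %g degrees clashes", ang))
    }
    out
  })
}

#' Hinge angle between the RH1 bundle and the coiled coil
#'
#' Acute angle (degrees) between the first principal axes of the two rigid
#' ranges.
#'
#' @param m A `protein_model`.
#' @param range1,range2 Residue ranges of the two bodies.
#' @return Angle in degrees (0 for a straight tandem).
#' @export
hinge_angle <- function(m, range1 = c(26, 66), range2 = c(78, 176)) {
  a1 <- principal_axis(model_xyz(model_select(m, range1[1], range1[2])))
  a2 <- principal_axis(model_xyz(model_select(m, range2[1], range2[2])))
  acos(min(1, abs(sum(a1 * a2)))) * 180 / pi
}
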