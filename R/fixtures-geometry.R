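# Rigid-geometry coordinate fixtures for exercising the geometric
# annotator.  Base atom templates are idealized nucleoside coordinates
# (heavy atoms; chemical component dictionary geometry), flattened into the
# base plane so fixtures can be composed by in-plane rigid motions plus
# out-of-plane translations.

GUANINE_TEMPLATE <- matrix(c(
  0.675, -0.220, -0.507,   # C1'
  2.927,  0.560, -1.066,   # O2'
 -0.297,  0.162, -1.534,   # N9
 -1.440,  0.880, -1.334,   # C8
 -2.066,  1.037, -2.464,   # N7
 -1.364,  0.431, -3.453,   # C5
 -1.556,  0.279, -4.846,   # C6
 -2.534,  0.755, -5.397,   # O6
 -0.626, -0.401, -5.551,   # N1
  0.459, -0.934, -4.923,   # C2
  1.384, -1.626, -5.664,   # N2
  0.649, -0.800, -3.630,   # N3
 -0.226, -0.134, -2.868    # C4
), ncol = 3L, byrow = TRUE,
  dimnames = list(c("C1'", "O2'", "N9", "C8", "N7", "C5", "C6", "O6",
                    "N1", "C2", "N2", "N3", "C4"), NULL))

CYTOSINE_TEMPLATE <- matrix(c(
 -0.924, -0.729,  1.317,   # C1'
 -3.228, -0.059,  1.806,   # O2'
 -0.036, -0.470,  2.453,   # N1
  0.652,  0.683,  2.514,   # C2
  0.529,  1.504,  1.620,   # O2
  1.467,  0.945,  3.535,   # N3
  1.620,  0.070,  4.520,   # C4
  2.464,  0.350,  5.569,   # N4
  0.916, -1.151,  4.483,   # C5
  0.087, -1.399,  3.442    # C6
), ncol = 3L, byrow = TRUE,
  dimnames = list(c("C1'", "O2'", "N1", "C2", "O2", "N3", "C4", "N4",
                    "C5", "C6"), NULL))

# express a template in its base-plane frame (ring centroid at origin,
# plane = xy, all atoms projected into the plane)
planar_template <- function(tmpl) {
  ring_names <- if ("N9" %in% rownames(tmpl)) PURINE_RING else PYRIMIDINE_RING
  ring <- tmpl[rownames(tmpl) %in% ring_names, , drop = FALSE]
  c0 <- colMeans(ring)
  sv <- svd(sweep(ring, 2L, c0))
  frame <- sv$v[, 1:2]
  out <- sweep(tmpl, 2L, c0) %*% frame
  cbind(out, 0)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3L, 3L,
         byrow = TRUE)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3L, 3L,
         byrow = TRUE)
}

transform_atoms <- function(xyz, rot = diag(3), shift = c(0, 0, 0),
                            mirror = FALSE) {
  m <- xyz
  if (mirror) m[, 2L] <- -m[, 2L]
  sweep(m %*% t(rot), 2L, shift, `+`)
}

# in-plane placement of a mobile base so that selected atom pairs reach
# hydrogen-bond targets: minimizes squared distance-constraint violations
# plus a soft steric term, over rotation + translation (deterministic
# multi-start Nelder-Mead)
place_by_contacts <- function(fixed, mobile, contacts, target = 2.9,
                              clash = 2.6) {
  objective <- function(par) {
    m <- transform_atoms(mobile, rot_z(par[1L]), c(par[2L], par[3L], 0))
    viol <- vapply(seq_len(nrow(contacts)), function(k) {
      d <- sqrt(sum((fixed[contacts[k, 1L], ] - m[contacts[k, 2L], ])^2))
      (d - target)^2
    }, numeric(1))
    dall <- sqrt(outer(rowSums(fixed^2), rowSums(m^2), `+`) -
                 2 * fixed %*% t(m))
    sum(viol) + sum(pmax(0, clash - dall)^2)
  }
  best <- NULL
  for (th in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(th, 6, 0), objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  transform_atoms(mobile, rot_z(best$par[1L]),
                  c(best$par[2L], best$par[3L], 0))
}

build_coord_model <- function(placed, bases, chain = NULL, number = NULL) {
  n <- length(placed)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(number)) number <- stats::ave(seq_len(n), chain, FUN = seq_along)
  resid_of <- c(G = "G", C = "C", A = "A", U = "U", T = "DT")
  residues <- data.frame(chain = chain, number = as.integer(number),
                         icode = "", base = bases,
                         resid = unname(resid_of[bases]),
                         stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_len(n), function(k)
    data.frame(res = k, name = rownames(placed[[k]]),
               x = placed[[k]][, 1L], y = placed[[k]][, 2L],
               z = placed[[k]][, 3L], stringsAsFactors = FALSE)))
  rownames(atoms) <- NULL
  structure(list(residues = residues, atoms = atoms), class = "coord_model")
}

#' Coordinate fixtures with known annotation ground truth
#'
#' Small rigid-geometry models for testing the geometric annotator:
#'
#' * `fixture_gg_cwh()` — two guanines paired Watson-Crick edge to
#'   Hoogsteen edge (N1/N2 donating to O6/N7) in the same plane, as in a
#'   G-tetrad; expected annotation: one cis W/H pair.
#' * `fixture_distant_pair(separation)` — two guanines far apart; expected:
#'   no pair.
#' * `fixture_gc_wc()` — a canonical Watson-Crick G:C pair (three
#'   hydrogen-bond contacts, the cytosine face flipped as in a duplex);
#'   expected: one canonical cis W/W pair.
#' * `fixture_gc_step()` — two stacked G:C pairs related by a 36 degree
#'   helical twist and 3.4 Angstrom rise (a B-form-like step); expected:
#'   two canonical pairs plus inter-pair stacking.
#' * `fixture_stacked_bases(rise, twist, lateral, tilt)` — two guanines
#'   related by the given rigid motion; defaults give an ideal coaxial
#'   stack at 3.3 Angstrom.
#' * `fixture_gtetrad(n_layers)` — a four-fold symmetric G-tetrad (each
#'   guanine's Watson-Crick edge donating to the next guanine's Hoogsteen
#'   edge), optionally stacked in layers 3.3 Angstrom apart with a 30
#'   degree twist.
#'
#' All placements are deterministic.
#'
#' @param separation centre-to-centre distance for the distant pair.
#' @param rise,twist,lateral,tilt rigid motion between the two stacked
#'   bases (Angstrom / degrees).
#' @param n_layers number of stacked tetrad layers.
#' @return A `coord_model`.
#' @name coordinate_fixtures
NULL

#' @rdname coordinate_fixtures
#' @export
fixture_gg_cwh <- function() {
  g <- planar_template(GUANINE_TEMPLATE)
  g2 <- place_by_contacts(g, g, contacts = cbind(
    match(c("N1", "N2"), rownames(g)), match(c("O6", "N7"), rownames(g))))
  build_coord_model(list(g, g2), c("G", "G"))
}

#' @rdname coordinate_fixtures
#' @export
fixture_distant_pair <- function(separation = 30) {
  g <- planar_template(GUANINE_TEMPLATE)
  g2 <- transform_atoms(g, shift = c(separation, 0, 0))
  build_coord_model(list(g, g2), c("G", "G"))
}

#' @rdname coordinate_fixtures
#' @export
fixture_gc_wc <- function() {
  g <- planar_template(GUANINE_TEMPLATE)
  c_flip <- transform_atoms(planar_template(CYTOSINE_TEMPLATE), mirror = TRUE)
  c2 <- place_by_contacts(g, c_flip, contacts = cbind(
    match(c("O6", "N1", "N2"), rownames(g)),
    match(c("N4", "N3", "O2"), rownames(c_flip))))
  build_coord_model(list(g, c2), c("G", "C"))
}

#' @rdname coordinate_fixtures
#' @export
fixture_gc_step <- function() {
  base_pair <- fixture_gc_wc()
  g1 <- res_coords(base_pair, 1L); c1 <- res_coords(base_pair, 2L)
  step <- rot_z(36)
  g2 <- transform_atoms(g1, step, c(0, 0, 3.4))
  c2 <- transform_atoms(c1, step, c(0, 0, 3.4))
  build_coord_model(list(g1, g2, c2, c1), c("G", "G", "C", "C"),
                    chain = c("A", "A", "B", "B"))
}

#' @rdname coordinate_fixtures
#' @export
fixture_stacked_bases <- function(rise = 3.3, twist = 30, lateral = 0,
                                  tilt = 0) {
  g <- planar_template(GUANINE_TEMPLATE)
  g2 <- transform_atoms(g, rot_x(tilt) %*% rot_z(twist),
                        c(lateral, 0, rise))
  build_coord_model(list(g, g2), c("G", "G"))
}

#' @rdname coordinate_fixtures
#' @export
fixture_gtetrad <- function(n_layers = 1L) {
  g <- planar_template(GUANINE_TEMPLATE)
  # place one guanine relative to the 4-fold axis at the origin so that its
  # Watson-Crick edge meets the Hoogsteen edge of its 90-degree copy
  objective <- function(par) {
    g1 <- transform_atoms(g, rot_z(par[1L]), c(par[2L], par[3L], 0))
    g2 <- transform_atoms(g1, rot_z(90))
    d1 <- sqrt(sum((g1["N1", ] - g2["O6", ])^2))
    d2 <- sqrt(sum((g1["N2", ] - g2["N7", ])^2))
    dall <- sqrt(outer(rowSums(g1^2), rowSums(g2^2), `+`) -
                 2 * g1 %*% t(g2))
    (d1 - 2.9)^2 + (d2 - 2.9)^2 + sum(pmax(0, 2.6 - dall)^2)
  }
  best <- NULL
  for (th in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(th, 4, 0), objective, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  g1 <- transform_atoms(g, rot_z(best$par[1L]),
                        c(best$par[2L], best$par[3L], 0))
  layer <- lapply(c(0, 90, 180, 270), function(a) transform_atoms(g1, rot_z(a)))
  placed <- layer
  if (n_layers > 1L) for (l in seq(2L, n_layers)) {
    lift <- rot_z(30 * (l - 1L))
    placed <- c(placed, lapply(layer, function(m)
      transform_atoms(m, lift, c(0, 0, 3.3 * (l - 1L)))))
  }
  build_coord_model(placed, rep("G", length(placed)))
}
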