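#' Edge atom map
#'
#' Polar heavy atoms operationalizing the three Leontis-Westhof edges of
#' each base letter.  Used by [detect_base_pairs()] to decide which edge of
#' a residue participates in a contact.  `"?"` bases fall back to the purine
#' map when ring atoms N7/N9 are present, else the pyrimidine map.
#'
#' @format list: base letter -> list(W, H, S) of atom-name vectors.
#' @export
EDGE_ATOM_MAP <- list(
  A = list(W = c("N1", "N6"),       H = c("N6", "N7"), S = c("N3", "O2'")),
  G = list(W = c("N1", "N2", "O6"), H = c("O6", "N7"), S = c("N2", "N3", "O2'")),
  C = list(W = c("N3", "N4", "O2"), H = c("N4", "C5"), S = c("O2", "O2'")),
  U = list(W = c("N3", "O2", "O4"), H = c("O4", "C5"), S = c("O2", "O2'")),
  T = list(W = c("N3", "O2", "O4"), H = c("O4", "C5"), S = c("O2", "O2'"))
)

PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

edge_map_for <- function(base, atom_names) {
  if (base %in% names(EDGE_ATOM_MAP)) return(EDGE_ATOM_MAP[[base]])
  if (any(c("N7", "N9") %in% atom_names)) EDGE_ATOM_MAP$G else EDGE_ATOM_MAP$U
}

res_coords <- function(model, k) {
  at <- model$atoms[model$atoms$res == k, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$name
  m
}

ring_coords <- function(xyz) {
  ring <- if ("N9" %in% rownames(xyz)) PURINE_RING else PYRIMIDINE_RING
  xyz[rownames(xyz) %in% ring, , drop = FALSE]
}

base_normal <- function(ring) {
  c0 <- colMeans(ring)
  sv <- svd(sweep(ring, 2L, c0))
  sv$v[, 3L]
}

#' Detect base pairs from atomic coordinates
#'
#' A pair is emitted between two residues when at least `min_contacts`
#' polar-atom contacts (N/O heavy-atom distance at most `hbond_dist`) link
#' their bases.  Each residue's Leontis-Westhof edge is the edge whose
#' atoms participate in most contacts (ties resolved W > H > S); the
#' cis/trans orientation comes from the glycosidic-bond direction criterion
#' (both glycosidic bonds pointing to the same side of the axis joining the
#' glycosidic nitrogens, projected into the mean base-pair plane, is cis).
#' Residues missing base atoms are skipped with a warning.
#'
#' @param model a `coord_model` from [read_structure()] or a fixture
#'   generator.
#' @param hbond_dist maximum donor-acceptor heavy-atom distance in Angstrom
#'   (default 3.5).
#' @param min_contacts minimum number of contacts to call a pair (default 2).
#' @return data frame of pairs as accepted by [annotation_graph()].
#' @export
detect_base_pairs <- function(model, hbond_dist = 3.5, min_contacts = 2L) {
  n <- nrow(model$residues)
  coords <- lapply(seq_len(n), res_coords, model = model)
  usable <- vapply(coords, function(m) nrow(ring_coords(m)) >= 3L, logical(1))
  if (any(!usable))
    warning("skipping ", sum(!usable), " residue(s) with missing base atoms")
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a || !usable[a] || !usable[b]) next
    pr <- pair_geometry(model, a, b, coords[[a]], coords[[b]],
                        hbond_dist, min_contacts)
    if (!is.null(pr)) out <- rbind(out, pr)
  }
  if (is.null(out)) return(empty_pairs_df())
  rownames(out) <- NULL
  out
}

pair_geometry <- function(model, a, b, xa, xb, hbond_dist, min_contacts) {
  base_a <- model$residues$base[a]; base_b <- model$residues$base[b]
  map_a <- edge_map_for(base_a, rownames(xa))
  map_b <- edge_map_for(base_b, rownames(xb))
  polar <- function(xyz) {
    nm <- rownames(xyz)
    keep <- grepl("^[NO]", nm) & (nm %in% unlist(EDGE_ATOM_MAP) |
                                  nm %in% c("N1", "N3", "N7", "O6", "O2", "O4",
                                            "N2", "N4", "N6", "O2'"))
    xyz[keep, , drop = FALSE]
  }
  pa <- polar(xa); pb <- polar(xb)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NULL)
  d <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
             Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
  hits <- which(d <= hbond_dist, arr.ind = TRUE)
  if (nrow(hits) < min_contacts) return(NULL)
  # base-pair hydrogen bonds run within the base planes: reject contacts
  # whose inter-centroid direction points along the base normal (stacking)
  # or whose planes are closer to perpendicular than parallel
  ra <- ring_coords(xa); rb <- ring_coords(xb)
  ca <- colMeans(ra); cb <- colMeans(rb)
  dir <- (cb - ca) / sqrt(sum((cb - ca)^2))
  na_ <- base_normal(ra); nb_ <- base_normal(rb)
  if (abs(sum(na_ * nb_)) < cos(65 * pi / 180)) return(NULL)
  if (abs(sum(dir * na_)) > 0.5 || abs(sum(dir * nb_)) > 0.5) return(NULL)
  atoms_a <- rownames(pa)[hits[, 1L]]
  atoms_b <- rownames(pb)[hits[, 2L]]
  edge_a <- dominant_edge(atoms_a, map_a)
  edge_b <- dominant_edge(atoms_b, map_b)
  ori <- glycosidic_orientation(xa, xb)
  data.frame(i = a, j = b, orientation = ori,
             edge_i = edge_a, edge_j = edge_b, stringsAsFactors = FALSE)
}

dominant_edge <- function(atoms, map) {
  counts <- vapply(c("W", "H", "S"), function(e) sum(atoms %in% map[[e]]),
                   integer(1))
  if (all(counts == 0L)) return(NA_character_)
  c("W", "H", "S")[which.max(counts)]   # which.max keeps W > H > S on ties
}

# cis/trans from the glycosidic bonds: project both N(glycosidic)->C1'
# vectors into the plane orthogonal to the axis joining the two glycosidic
# nitrogens (within the mean base plane); same side = cis
glycosidic_orientation <- function(xa, xb) {
  gn <- function(xyz) if ("N9" %in% rownames(xyz)) xyz["N9", ] else xyz["N1", ]
  c1 <- function(xyz) if ("C1'" %in% rownames(xyz)) xyz["C1'", ] else NULL
  n1 <- gn(xa); n2 <- gn(xb)
  c1a <- c1(xa); c1b <- c1(xb)
  if (is.null(c1a) || is.null(c1b)) return(NA_character_)
  axis <- n2 - n1
  axis <- axis / sqrt(sum(axis^2))
  both <- rbind(ring_coords(xa), ring_coords(xb))
  normal <- base_normal(both)
  side <- function(v) {
    w <- v - sum(v * axis) * axis       # remove axis component
    w <- w - sum(w * normal) * normal   # stay in the mean plane
    w
  }
  s1 <- side(c1a - n1); s2 <- side(c1b - n2)
  if (sum(s1 * s2) >= 0) "cis" else "trans"
}

#' Detect base-stacking contacts from atomic coordinates
#'
#' A contact is emitted when the base-ring centroids are within
#' `centroid_dist`, the ring planes are within `max_angle` degrees of
#' parallel, and the rings actually overlap when projected onto their mean
#' plane (some projected atom of one ring falls inside the convex outline
#' of the other).
#'
#' @param model a `coord_model`.
#' @param centroid_dist maximum centroid-centroid distance in Angstrom
#'   (default 4.5).
#' @param max_angle maximum inter-plane angle in degrees (default 30).
#' @return data frame of stacking contacts (`i`, `j`).
#' @export
detect_stacking <- function(model, centroid_dist = 4.5, max_angle = 30) {
  n <- nrow(model$residues)
  rings <- lapply(seq_len(n), function(k) ring_coords(res_coords(model, k)))
  usable <- vapply(rings, function(m) nrow(m) >= 3L, logical(1))
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a || !usable[a] || !usable[b]) next
    ca <- colMeans(rings[[a]]); cb <- colMeans(rings[[b]])
    if (sqrt(sum((ca - cb)^2)) > centroid_dist) next
    na_ <- base_normal(rings[[a]]); nb_ <- base_normal(rings[[b]])
    ang <- acos(pmin(1, abs(sum(na_ * nb_)))) * 180 / pi
    if (ang > max_angle) next
    if (!rings_overlap(rings[[a]], rings[[b]])) next
    out <- rbind(out, data.frame(i = a, j = b))
  }
  if (is.null(out)) return(data.frame(i = integer(), j = integer()))
  rownames(out) <- NULL
  out
}

# project both rings onto the mean plane (normal = average of the two ring
# normals) and test convex-polygon overlap
rings_overlap <- function(ra, rb) {
  c0 <- (colMeans(ra) + colMeans(rb)) / 2
  na_ <- base_normal(ra); nb_ <- base_normal(rb)
  if (sum(na_ * nb_) < 0) nb_ <- -nb_
  normal <- na_ + nb_
  normal <- normal / sqrt(sum(normal^2))
  u <- c(1, 0, 0) - normal[1L] * normal
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - normal[2L] * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2L] * u[3L] - normal[3L] * u[2L],
         normal[3L] * u[1L] - normal[1L] * u[3L],
         normal[1L] * u[2L] - normal[2L] * u[1L])
  proj <- function(m) {
    sw <- sweep(m, 2L, c0)
    cbind(sw %*% u, sw %*% v)
  }
  pa <- proj(ra); pb <- proj(rb)
  any(points_in_hull(pb, pa)) || any(points_in_hull(pa, pb))
}

# which rows of pts lie inside the convex hull of poly (2D)
points_in_hull <- function(pts, poly) {
  h <- grDevices::chull(poly)
  hull <- poly[h, , drop = FALSE]
  nh <- nrow(hull)
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    sgn <- vapply(seq_len(nh), function(e) {
      a <- hull[e, ]; b <- hull[if (e == nh) 1L else e + 1L, ]
      (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
    }, numeric(1))
    all(sgn >= -1e-9) || all(sgn <= 1e-9)
  }, logical(1))
}

#' Annotate a coordinate model into an annotation graph
#'
#' Runs the built-in geometric annotator ([detect_base_pairs()] and
#' [detect_stacking()]) and assembles the result into an
#' [annotation_graph()].  Used when no pre-computed DSSR-style annotation is
#' supplied.
#'
#' @param model a `coord_model`.
#' @param hbond_dist,min_contacts passed to [detect_base_pairs()].
#' @param centroid_dist,max_angle passed to [detect_stacking()].
#' @return An [annotation_graph()].
#' @export
annotate_geometry <- function(model, hbond_dist = 3.5, min_contacts = 2L,
                              centroid_dist = 4.5, max_angle = 30) {
  pairs <- detect_base_pairs(model, hbond_dist, min_contacts)
  stacks <- detect_stacking(model, centroid_dist, max_angle)
  annotation_graph(model$residues[, c("chain", "number", "icode", "base")],
                   pairs, stacks)
}
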