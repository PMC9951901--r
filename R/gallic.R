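#' Idealized heavy-atom template of gallic acid
#'
#' Returns the rigid heavy-atom body-frame coordinates used for every
#' synthetic antioxidant placement.  The geometry is idealized (synthetic,
#' not taken from a crystal structure): a planar aromatic ring of side
#' 1.397 A with the para axis along x, the carboxyl carbon C7 on C1, the
#' carboxyl oxygens O1/O2 on C7, the para hydroxyl oxygen O4 on C4, and the
#' meta hydroxyl oxygens O3 (on C3) and O0 (on C5).  Hydrogens are omitted:
#' all geometric observables (center of mass, para axis, ring plane) depend
#' only on the heavy atoms.
#'
#' Conventions baked into the template and relied on downstream:
#' * ring atoms C1..C6 are exactly coplanar (z = 0);
#' * O4, C4, C1, C7 are exactly collinear (the para axis, oriented O4 to C7);
#' * coordinates are in angstroms, masses in amu.
#'
#' @return data.frame with columns `atom`, `x`, `y`, `z`, `mass`.
#' @examples
#' tpl <- gallic_acid_template()
#' nrow(tpl)  # 12 heavy atoms
#' @export
gallic_acid_template <- function() {
  path <- system.file("extdata", "gallic_acid_template_ideal.csv",
                      package = "emulsiphase", mustWork = TRUE)
  tpl <- utils::read.csv(path, stringsAsFactors = FALSE)
  tpl$atom <- as.character(tpl$atom)
  tpl
}

# Body-frame reference geometry derived from the template: center of mass,
# unit para axis a (O4 -> C7), unit COM->C6 vector b, unit ring normal n,
# and the fixed angle delta between a and b (degrees).
ga_body_frame <- function(tpl = gallic_acid_template()) {
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  com <- colSums(xyz * tpl$mass) / sum(tpl$mass)
  at <- function(lbl) xyz[match(lbl, tpl$atom), ]
  a <- unit3(at("C7") - at("O4"))
  b <- unit3(at("C6") - com)
  ring <- xyz[match(paste0("C", 1:6), tpl$atom), ]
  n <- ring_normal(ring)
  list(tpl = tpl, xyz = xyz, com = com, a = a, b = b, n = n,
       delta = angle_deg(a, b))
}

# Unit normal of the least-squares plane through a set of points (SVD).
ring_normal <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(ctr)
  if (sv$d[2L] < 1e-9)
    stop("degenerate (collinear) ring geometry", call. = FALSE)
  unit3(sv$v[, 3L])
}

# Total-least-squares unit direction through a set of points, oriented so
# that it points from the first toward the last row.
tls_direction <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  v <- svd(ctr)$v[, 1L]
  if (sum(v * (pts[nrow(pts), ] - pts[1L, ])) < 0) v <- -v
  unit3(v)
}
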