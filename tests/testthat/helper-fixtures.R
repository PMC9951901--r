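# Shared fixture builders: all synthetic, constructed in code at test time.

# a bare frame from explicit atom records
make_frame <- function(species, molid, atom, xyz, mass) {
  structure(data.frame(species = species, molid = molid, atom = atom,
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       mass = mass, stringsAsFactors = FALSE),
            class = c("droplet_frame", "data.frame"))
}

# single oleic point at the origin: pins the droplet center for toy frames
anchor_oleic <- function() {
  make_frame("OLE", 1L, "C", matrix(0, 1L, 3L), 282.468)
}

# gallic-acid molecule rigidly rotated by Q and centered at `com` (A)
place_gallic <- function(Q = diag(3L), com = c(0, 0, 31), molid = 1L) {
  tpl <- gallic_acid_template()
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  body_com <- colSums(xyz * tpl$mass) / sum(tpl$mass)
  rot <- sweep(xyz, 2L, body_com) %*% t(Q)
  make_frame("GAL", molid, tpl$atom, sweep(rot, 2L, com, `+`), tpl$mass)
}

# small fast droplet spec
tiny_spec <- function(..., seed = 11L) {
  args <- list(n_oleic = 60L, n_surfactant = 10L, n_antioxidant = 8L,
               n_water = 150L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(species_spec, args)
}

# independent angle oracle: plain dot-product formulas, no shared code path
oracle_angles <- function(frame, molid, center = c(0, 0, 0)) {
  mol <- frame[frame$species == "GAL" & frame$molid == molid, ]
  xyz <- as.matrix(mol[, c("x", "y", "z")])
  rownames(xyz) <- mol$atom
  com <- colSums(xyz * mol$mass) / sum(mol$mass)
  rvec <- center - com
  ang <- function(u, v) {
    cth <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
    acos(max(-1, min(1, cth))) * 180 / pi
  }
  a <- xyz["C7", ] - xyz["O4", ]                    # exact para axis
  b <- xyz["C6", ] - com
  n <- c(crossprod_oracle(xyz["C2", ] - xyz["C1", ],
                          xyz["C4", ] - xyz["C1", ]))
  th <- ang(rvec, n)
  list(alpha = ang(rvec, a), beta = ang(rvec, b),
       gamma = 90 - min(th, 180 - th))
}

crossprod_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Euler-angle rotation (independent of the package quaternion sampler)
euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3L, 3L)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3L, 3L)
  rz(a) %*% ry(b) %*% rz(c)
}
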